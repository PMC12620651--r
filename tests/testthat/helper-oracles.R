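# Independent oracles used across test files. These stay deliberately
# brute-force / closed-form so they never share code with the package paths
# they check.

# Expected progeny mean of a diploid cross by exhaustive enumeration of the
# four gamete combinations per locus. Each parent transmits the tracked
# allele with probability p (its within-parent frequency); a locus with
# offspring dosage g contributes a*(g - 1) for homozygotes (g = 0 or 2) and
# d for heterozygotes.
enum_cross_mean <- function(a, d, p1, p2) {
  total <- 0
  for (i in seq_along(a)) {
    pr1 <- c(1 - p1[i], p1[i])
    pr2 <- c(1 - p2[i], p2[i])
    probs <- outer(pr1, pr2)
    vals <- matrix(c(-a[i], d[i], d[i], a[i]), 2, 2)
    total <- total + sum(probs * vals)
  }
  total
}

# Additive genotypic score of one diploid parent under the same value
# convention: sum over loci of a * (dosage - 1).
parent_additive_score <- function(a, dosage) sum(a * (dosage - 1))

# Single-kernel (additive GBLUP) REML by eigen-rotation and 1-D golden
# search over the variance ratio: an algorithm wholly different from the
# package's EM/AI multi-kernel solver.
additive_reml_oracle <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  dv <- pmax(eig$values, 0)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  prof <- function(log_lambda) {
    lam <- exp(log_lambda)
    v <- lam * dv + 1
    W <- Xt / v
    XtVX <- crossprod(Xt, W)
    beta <- solve(XtVX, crossprod(W, yt))
    r <- yt - drop(Xt %*% beta)
    s2e <- sum(r^2 / v) / (n - p)
    0.5 * (sum(log(v)) + (n - p) * log(s2e) +
             determinant(XtVX, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(prof, c(-12, 12), tol = 1e-10)
  lam <- exp(opt$minimum)
  v <- lam * dv + 1
  W <- Xt / v
  XtVX <- crossprod(Xt, W)
  beta <- solve(XtVX, crossprod(W, yt))
  r <- yt - drop(Xt %*% beta)
  s2e <- sum(r^2 / v) / (n - p)
  list(var_additive = lam * s2e, var_residual = s2e)
}

# marker_effects object built by hand (for unit tests that need known
# effects without a model fit)
manual_effects <- function(markers, additive, dominance, centers_z = NULL,
                           ploidy = 2) {
  out <- tibble::tibble(marker = markers, additive = additive,
                        dominance = dominance, dominance_dev = dominance)
  structure(out,
            centers_z = centers_z %||% rep(0, length(markers)),
            centers_w = rep(0, length(markers)),
            ploidy = ploidy, trait = "manual",
            class = c("marker_effects", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
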