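#' Assemble the directional-dominance design from phenotypes and genotypes
#'
#' Joins a phenotype table to a genotype panel and builds the pieces of the
#' mixed model `y = X beta + f b + Z a + W d* + e`: replicate records are
#' averaged per genotype x fixed-factor cell, `X` is a full-rank
#' treatment-coded incidence matrix, `f` holds genomic inbreeding
#' coefficients, and the dosage (`Z`) and heterozygosity (`W`) codings are
#' column mean-centered on the training panel. Individuals without genotypes
#' are dropped with a message. Heterozygosity and inbreeding are computed
#' from observed calls; missing dosages are then mean-imputed.
#'
#' @param pheno Data frame of phenotype records, one row per plot or
#'   observation.
#' @param G A [geno_matrix()] covering the training individuals.
#' @param response Name of the trait column.
#' @param genotype_id Name of the genotype-ID column (default
#'   `"germplasmName"`).
#' @param fixed Character vector of fixed-factor column names.
#' @return A list with elements `y`, `X`, `f`, `Z`, `W`, `geno`,
#'   `centers_z`, `centers_w`, `scale_a`, `scale_d`, `marker_ids`, `ploidy`
#'   and `f_dropped`.
#' @export
build_design <- function(pheno, G, response, genotype_id = "germplasmName",
                         fixed = character()) {
  pheno <- tibble::as_tibble(pheno)
  for (col in c(genotype_id, response, fixed)) {
    if (!col %in% names(pheno)) {
      stop("column '", col, "' not found in phenotype table", call. = FALSE)
    }
  }
  ids <- as.character(pheno[[genotype_id]])
  in_panel <- ids %in% individual_ids(G)
  if (!any(in_panel)) {
    stop("no overlap between phenotype IDs and genotype IDs", call. = FALSE)
  }
  n_drop <- length(unique(ids[!in_panel]))
  if (n_drop > 0) {
    message(n_drop, " phenotyped genotype(s) without marker data dropped")
  }
  pheno <- pheno[in_panel, , drop = FALSE]
  pheno[[genotype_id]] <- as.character(pheno[[genotype_id]])

  cell <- pheno |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(genotype_id, fixed)))) |>
    dplyr::summarise(
      .y = mean(.data[[response]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$.y))
  if (nrow(cell) == 0) stop("no non-missing phenotype records", call. = FALSE)

  geno <- cell[[genotype_id]]
  y <- cell$.y

  if (length(fixed) > 0) {
    fdat <- cell[fixed]
    fdat[] <- lapply(fdat, function(x) factor(as.character(x)))
    X <- stats::model.matrix(~ ., data = fdat)
  } else {
    X <- matrix(1, nrow(cell), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  # per-individual codings from observed calls, then mean imputation
  panel_ids <- unique(geno)
  Gsub <- geno_matrix(G$dosages[panel_ids, , drop = FALSE], G$ploidy, G$map)
  W_ind <- het_matrix(Gsub)
  f_ind <- inbreeding_coefficients(Gsub)
  D_ind <- Gsub$dosages
  if (anyNA(D_ind)) {
    mu <- colMeans(D_ind, na.rm = TRUE)
    idx <- which(is.na(D_ind), arr.ind = TRUE)
    D_ind[idx] <- mu[idx[, 2]]
  }
  if (anyNA(W_ind)) {
    muw <- colMeans(W_ind, na.rm = TRUE)
    idx <- which(is.na(W_ind), arr.ind = TRUE)
    W_ind[idx] <- muw[idx[, 2]]
  }

  centers_z <- colMeans(D_ind)
  centers_w <- colMeans(W_ind)
  Z <- sweep(D_ind[geno, , drop = FALSE], 2, centers_z)
  W <- sweep(W_ind[geno, , drop = FALSE], 2, centers_w)

  # VanRaden-style denominators so variance components sit on the
  # phenotypic scale: p_bar is the panel mean allele frequency per marker.
  rho <- Gsub$ploidy
  p_bar <- centers_z / rho
  scale_a <- sum(2 * p_bar * (1 - p_bar)) * (rho / 2)
  scale_d <- sum((2 * p_bar * (1 - p_bar))^2)

  f <- unname(f_ind[geno])
  f_dropped <- FALSE
  if (stats::sd(f) < 1e-10) {
    warning("inbreeding covariate is constant (aliased with the intercept); ",
            "directional-dominance slope b dropped", call. = FALSE)
    f_dropped <- TRUE
  }

  list(y = y, X = X, f = f, Z = Z, W = W, geno = geno,
       centers_z = centers_z, centers_w = centers_w,
       scale_a = scale_a, scale_d = scale_d,
       marker_ids = marker_ids(Gsub), ploidy = rho, f_dropped = f_dropped)
}

#' Fit the additive + directional-dominance model by REML
#'
#' Fits `y = X beta + f b + Z a + W d* + e` with `a ~ N(0, I sigma2_a /
#' scale_a)` and `d* ~ N(0, I sigma2_d / scale_d)` — the marker-effects
#' (ridge) parameterisation, equivalent to GBLUP with additive kernel
#' `Z Z' / scale_a` and dominance kernel `W W' / scale_d`. Variance
#' components are estimated by EM-REML with average-information
#' acceleration: AI steps are taken when they increase the restricted
#' likelihood and remain in the parameter space, otherwise the monotone EM
#' update is used, so the log-likelihood trace never decreases. The
#' genomic-inbreeding slope `b` and the factor effects `beta` are fixed
#' effects.
#'
#' @inheritParams build_design
#' @param dominance Include the dominance kernel (`W d*`). When `FALSE` the
#'   model reduces to standard additive GBLUP.
#' @param directional Include the genomic-inbreeding covariate `f b`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum REML iterations.
#' @return An object of class `dirdom_fit` with variance components, fixed
#'   effects, the restricted log-likelihood trace, and back-solved marker
#'   effects. See [marker_effects()], [tidy.dirdom_fit()],
#'   [glance.dirdom_fit()].
#' @export
fit_dirdom <- function(pheno, G, response, genotype_id = "germplasmName",
                       fixed = character(), dominance = TRUE,
                       directional = TRUE, tol = 1e-6, max_iter = 200) {
  des <- build_design(pheno, G, response, genotype_id, fixed)
  n <- length(des$y)
  if (n < ncol(des$X) + 3) {
    stop("too few phenotype records (", n, ") for the fixed effects",
         call. = FALSE)
  }

  Xf <- des$X
  use_f <- directional && !des$f_dropped
  if (use_f) Xf <- cbind(Xf, f = des$f)

  kernels <- list(additive = tcrossprod(des$Z) / des$scale_a)
  q_sizes <- c(additive = ncol(des$Z))
  if (dominance) {
    if (des$scale_d < 1e-12 || sum(des$W^2) < 1e-12) {
      warning("heterozygosity coding is constant; dominance component ",
              "dropped", call. = FALSE)
      dominance <- FALSE
    } else {
      kernels$dominance <- tcrossprod(des$W) / des$scale_d
      q_sizes <- c(q_sizes, dominance = ncol(des$W))
    }
  }

  res <- reml_em_ai(des$y, Xf, kernels, q_sizes, tol = tol,
                    max_iter = max_iter)

  beta <- res$beta
  b <- if (use_f) unname(beta[length(beta)]) else NA_real_
  Py <- res$Py
  a_hat <- drop(res$sigma2[["additive"]] / des$scale_a * crossprod(des$Z, Py))
  d_hat <- if (dominance) {
    drop(res$sigma2[["dominance"]] / des$scale_d * crossprod(des$W, Py))
  } else {
    rep(0, ncol(des$W))
  }

  structure(
    list(
      response = response,
      beta = beta[seq_len(ncol(des$X))],
      b_inbreeding = b,
      var_additive = unname(res$sigma2[["additive"]]),
      var_dominance = if (dominance) unname(res$sigma2[["dominance"]]) else 0,
      var_residual = unname(res$sigma2[["residual"]]),
      loglik_reml = res$loglik,
      loglik_trace = res$trace,
      converged = res$converged,
      n_iterations = res$iterations,
      n_records = n,
      a = a_hat,
      d_star = d_hat,
      u_additive = drop(res$sigma2[["additive"]] *
                          (kernels$additive %*% Py)),
      geno = des$geno,
      marker_ids = des$marker_ids,
      centers_z = des$centers_z,
      centers_w = des$centers_w,
      scale_a = des$scale_a,
      scale_d = des$scale_d,
      ploidy = des$ploidy,
      dominance = dominance,
      directional = use_f
    ),
    class = "dirdom_fit"
  )
}

# EM-REML with average-information acceleration over dense kernels.
# q_sizes are the numbers of underlying iid effects per kernel (markers for
# ridge kernels); the residual uses n. Variance floor 1e-8 * var(y).
reml_em_ai <- function(y, X, kernels, q_sizes, tol = 1e-6, max_iter = 200) {
  n <- length(y)
  k <- length(kernels)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) {
    stop("response has (near-)zero variance; REML is undefined",
         call. = FALSE)
  }
  # the centered kernels are singular along the intercept direction, so the
  # residual floor must keep V well conditioned
  floor_v <- c(rep(1e-8 * vy, k), 1e-6 * vy)
  sigma2 <- stats::setNames(rep(vy / (k + 1), k + 1),
                            c(names(kernels), "residual"))
  sigma2 <- pmax(sigma2, floor_v)

  eval_at <- function(s2) {
    V <- diag(s2[["residual"]], n)
    for (i in seq_len(k)) V <- V + s2[[i]] * kernels[[i]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    dcv <- diag(cV)
    if (min(dcv) / max(dcv) < 1e-9) return(NULL)  # numerically singular V
    Vinv <- chol2inv(cV)
    XtViX <- crossprod(X, Vinv %*% X)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    ViX <- Vinv %*% X
    P <- Vinv - ViX %*% chol2inv(cX) %*% t(ViX)
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    ll <- -0.5 * (2 * sum(log(dcv)) + 2 * sum(log(diag(cX))) + yPy)
    if (!is.finite(ll) || yPy < -1e-8 * vy) return(NULL)
    list(P = P, Py = Py, ll = ll, Vinv = Vinv, XtViX = XtViX)
  }

  st <- eval_at(sigma2)
  if (is.null(st)) stop("initial covariance matrix not positive definite",
                        call. = FALSE)
  trace <- st$ll
  converged <- FALSE
  iter <- 0

  em_update <- function(st, s2) {
    out <- s2
    for (i in seq_len(k)) {
      # tr(P K) via elementwise product (both symmetric)
      trPK <- sum(st$P * kernels[[i]])
      quad <- sum(st$Py * (kernels[[i]] %*% st$Py))
      out[[i]] <- s2[[i]] + s2[[i]]^2 * (quad - trPK) / q_sizes[[i]]
    }
    quad_e <- sum(st$Py^2)
    out[["residual"]] <- s2[["residual"]] +
      s2[["residual"]]^2 * (quad_e - sum(diag(st$P))) / n
    pmax(out, floor_v)
  }

  ai_update <- function(st, s2) {
    PKPy <- vector("list", k + 1)
    score <- numeric(k + 1)
    for (i in seq_len(k)) {
      KPy <- drop(kernels[[i]] %*% st$Py)
      PKPy[[i]] <- drop(st$P %*% KPy)
      score[i] <- -0.5 * (sum(st$P * kernels[[i]]) - sum(st$Py * KPy))
    }
    PKPy[[k + 1]] <- drop(st$P %*% st$Py)
    score[k + 1] <- -0.5 * (sum(diag(st$P)) - sum(st$Py^2))
    AI <- matrix(0, k + 1, k + 1)
    KPy_all <- c(lapply(seq_len(k), function(i) kernels[[i]] %*% st$Py),
                 list(st$Py))
    for (i in seq_len(k + 1)) {
      for (j in i:(k + 1)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy_all[[i]] * PKPy[[j]])
      }
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # clamp at the variance floor rather than rejecting boundary moves;
    # the caller still verifies the likelihood does not decrease
    pmax(s2 + stats::setNames(step, names(s2)), floor_v)
  }

  for (iter in seq_len(max_iter)) {
    ll_old <- st$ll
    s2_new <- NULL
    st_new <- NULL
    if (iter > 2) {
      cand <- ai_update(st, sigma2)
      if (!is.null(cand)) {
        st_try <- eval_at(cand)
        if (!is.null(st_try) && is.finite(st_try$ll) &&
              st_try$ll >= ll_old - 1e-10) {
          s2_new <- cand
          st_new <- st_try
        }
      }
    }
    if (is.null(s2_new)) {
      # the EM increment is a positive rescaling of the score, so some
      # fraction of it must ascend unless we sit at a (boundary) optimum
      target <- em_update(st, sigma2)
      for (h in 0:8) {
        cand <- pmax(sigma2 + (target - sigma2) / 2^h, floor_v)
        st_try <- eval_at(cand)
        if (!is.null(st_try) && st_try$ll >= ll_old - 1e-12) {
          s2_new <- cand
          st_new <- st_try
          break
        }
      }
      if (is.null(s2_new)) {
        converged <- TRUE
        break
      }
    }
    sigma2 <- s2_new
    st <- st_new
    trace <- c(trace, st$ll)
    if (abs(st$ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("REML did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  pinned <- names(sigma2)[sigma2 <= floor_v * (1 + 1e-9)]
  if (length(pinned) > 0 && any(pinned != "residual")) {
    message("variance component(s) at lower bound: ",
            paste(setdiff(pinned, "residual"), collapse = ", "))
  }

  beta <- drop(solve(st$XtViX, crossprod(X, st$Vinv %*% y)))
  names(beta) <- colnames(X)
  list(sigma2 = sigma2, beta = beta, loglik = st$ll, trace = trace,
       converged = converged, iterations = iter, Py = st$Py)
}

#' @export
print.dirdom_fit <- function(x, ...) {
  cat("<dirdom_fit> trait:", x$response, "\n")
  cat(sprintf("  var components: additive %.4g, dominance %.4g, residual %.4g\n",
              x$var_additive, x$var_dominance, x$var_residual))
  if (x$directional) {
    cat(sprintf("  inbreeding slope b: %.4g\n", x$b_inbreeding))
  }
  cat(sprintf("  REML logLik %.4f, %s in %d iterations\n", x$loglik_reml,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Tidy a directional-dominance fit
#'
#' @param x A [fit_dirdom()] object.
#' @param ... Unused.
#' @return A tibble with one row per estimated term (fixed effects,
#'   inbreeding slope, variance components).
#' @exportS3Method generics::tidy
tidy.dirdom_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$beta), type = "fixed",
                   estimate = unname(x$beta)),
    if (x$directional) {
      tibble::tibble(term = "b_inbreeding", type = "fixed",
                     estimate = x$b_inbreeding)
    },
    tibble::tibble(
      term = c("var_additive", "var_dominance", "var_residual"),
      type = "variance",
      estimate = c(x$var_additive, x$var_dominance, x$var_residual)
    )
  )
}

#' One-row model summary
#'
#' @param x A [fit_dirdom()] object.
#' @param ... Unused.
#' @return A tibble with the log-likelihood, convergence status and
#'   variance partitions.
#' @exportS3Method generics::glance
glance.dirdom_fit <- function(x, ...) {
  tot <- x$var_additive + x$var_dominance + x$var_residual
  tibble::tibble(
    logLik = x$loglik_reml,
    converged = x$converged,
    n_iterations = x$n_iterations,
    nobs = x$n_records,
    h2_additive = x$var_additive / tot,
    prop_dominance = x$var_dominance / tot
  )
}
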