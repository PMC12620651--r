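#' Predicted mean genotypic value of one F1 cross
#'
#' Closed-form progeny mean from per-marker additive and dominance effects
#' and the two parents' within-parent allele frequencies:
#' \deqn{M_{F1} = \sum_i a_i (p_i - q_i - y_i) + d_i (2 p_i q_i + y_i (p_i - q_i))}
#' with \eqn{q_i = 1 - p_i} and \eqn{y_i = p_i - p'_i} the parental
#' frequency difference. The value is symmetric in parent order and, for
#' diploids, equals the exact enumeration of gamete combinations per locus.
#' It applies unchanged to polyploid parents (frequencies `dosage/ploidy`),
#' though no polysomic-enumeration equivalence is claimed beyond diploids.
#'
#' @param additive,dominance Numeric effect vectors, one entry per marker.
#' @param p1,p2 Parental allele-frequency vectors in `[0, 1]`.
#' @return The predicted F1 mean genotypic value (scalar, centered model
#'   scale).
#' @export
cross_mean <- function(additive, dominance, p1, p2) {
  m <- length(additive)
  if (length(dominance) != m || length(p1) != m || length(p2) != m) {
    stop("effect and parent-frequency vectors must have equal length",
         call. = FALSE)
  }
  q1 <- 1 - p1
  y <- p1 - p2
  sum(additive * (p1 - q1 - y) + dominance * (2 * p1 * q1 + y * (p1 - q1)))
}

#' Sex compatibility of a parent pair
#'
#' Codes follow the dioecious/monoecious convention: 1 = male, 2 = female,
#' 3 = monoecious male (m > f), 4 = monoecious female (f > m). A pair is
#' incompatible only when both parents are strictly male (1 x 1) or
#' strictly female (2 x 2); monoecious plants and parents with no recorded
#' sex are compatible with anything.
#'
#' @param s1,s2 Integer sex codes in `{1, 2, 3, 4}` or `NA`.
#' @return Logical: can the pair produce seed?
#' @export
sex_compatible <- function(s1, s2) {
  check_sex_codes(c(s1, s2))
  if (is.na(s1) || is.na(s2)) return(TRUE)
  !((s1 == 1 && s2 == 1) || (s1 == 2 && s2 == 2))
}

check_sex_codes <- function(codes) {
  bad <- codes[!is.na(codes) & !codes %in% 1:4]
  if (length(bad) > 0) {
    stop("invalid sex code(s): ", paste(unique(bad), collapse = ", "),
         "; expected 1 (male), 2 (female), 3/4 (monoecious)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Rank all candidate crosses by predicted performance
#'
#' Scores every unordered parent pair with [cross_mean()], combines traits
#' through linear selection-index weights, removes sex-incompatible pairs
#' when sex codes are supplied, and returns the top crosses in descending
#' merit order. All `n (n - 1) / 2` pairs are scored (plus `n` selfs when
#' `allow_self = TRUE`); work proceeds in blocks of parents so peak memory
#' stays at `O(block x n)` even for panels with tens of thousands of
#' candidate combinations. Ties are broken by parent IDs, and each pair is
#' stored with the lexicographically smaller ID as `parent1`, so output is
#' reproducible byte for byte.
#'
#' @param effects A [marker_effects()] object, or a named list of them (one
#'   per trait) for index selection.
#' @param G_parents A [geno_matrix()] of candidate parents on the same
#'   marker panel.
#' @param weights Named numeric vector of selection-index weights, names
#'   matching the effect list. Defaults to weight 1 for a single trait.
#' @param sexes Optional data frame with columns `individual` and `sex`
#'   (codes 1-4), or a named vector.
#' @param n_crosses Number of top crosses to return.
#' @param allow_self Keep self-crosses (default `FALSE`; clonal outcrossers
#'   are the target use case).
#' @param block_size Parents per scoring block.
#' @return A tibble of class `cross_table` with columns `id` (1-based
#'   rank), `parent1`, `parent2`, `merit`, and `sex1`/`sex2` when sex data
#'   were supplied.
#' @export
predict_crosses <- function(effects, G_parents, weights = NULL, sexes = NULL,
                            n_crosses = 100, allow_self = FALSE,
                            block_size = 512) {
  if (inherits(effects, "marker_effects")) {
    effects <- stats::setNames(list(effects),
                               attr(effects, "trait") %||% "trait")
  }
  stopifnot(is.list(effects), length(effects) >= 1, n_crosses >= 1)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(effects)), names(effects))
  }
  if (!all(names(weights) %in% names(effects))) {
    stop("weights name traits absent from `effects`: ",
         paste(setdiff(names(weights), names(effects)), collapse = ", "),
         call. = FALSE)
  }

  ids <- individual_ids(G_parents)
  n <- length(ids)
  if (n < 2 && !allow_self) stop("need at least 2 candidate parents",
                                 call. = FALSE)
  P <- parental_frequencies(G_parents)
  if (anyNA(P)) {
    mu <- colMeans(P, na.rm = TRUE)
    idx <- which(is.na(P), arr.ind = TRUE)
    P[idx] <- mu[idx[, 2]]
  }

  # index-combined effects: merit is linear in (a, d), so weights fold in
  ref_markers <- effects[[names(weights)[1]]]$marker
  if (!all(ref_markers %in% marker_ids(G_parents))) {
    stop("candidate panel lacks markers present in the effect estimates",
         call. = FALSE)
  }
  P <- P[, ref_markers, drop = FALSE]
  a_w <- numeric(ncol(P))
  d_w <- numeric(ncol(P))
  for (tr in names(weights)) {
    eff <- effects[[tr]]
    if (!identical(eff$marker, ref_markers)) {
      stop("marker panels differ across traits (trait '", tr, "')",
           call. = FALSE)
    }
    a_w <- a_w + weights[[tr]] * eff$additive
    d_w <- d_w + weights[[tr]] * eff$dominance
  }

  sex_vec <- resolve_sexes(sexes, ids)

  # M(j,k) = sum_i a_i (p + p' - 1) + d_i (p + p' - 2 p p'),
  # the expanded, explicitly symmetric form of the F1-mean equation
  u <- drop(P %*% a_w) - sum(a_w) / 2   # per-parent additive half-merit
  v <- drop(P %*% d_w)
  Pd <- sweep(P, 2, d_w, `*`)

  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  pieces <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    cross_dd <- Pd[rows, , drop = FALSE] %*% t(P)  # |rows| x n
    res <- list()
    for (ri in seq_along(rows)) {
      j <- rows[ri]
      ks <- if (allow_self) j:n else if (j < n) (j + 1L):n else integer(0)
      if (length(ks) == 0) next
      merit <- unname((u[j] + u[ks]) + (v[j] + v[ks] - 2 * cross_dd[ri, ks]))
      res[[ri]] <- tibble::tibble(p1 = j, p2 = ks, merit = merit)
    }
    pieces[[bi]] <- dplyr::bind_rows(res)
  }
  tab <- dplyr::bind_rows(pieces)

  # canonical pair orientation + sex filter
  id1 <- ids[tab$p1]
  id2 <- ids[tab$p2]
  swap <- id2 < id1
  parent1 <- ifelse(swap, id2, id1)
  parent2 <- ifelse(swap, id1, id2)
  out <- tibble::tibble(parent1 = parent1, parent2 = parent2,
                        merit = tab$merit)
  if (!is.null(sex_vec)) {
    s1 <- sex_vec[out$parent1]
    s2 <- sex_vec[out$parent2]
    keep <- !((!is.na(s1) & !is.na(s2)) &
                ((s1 == 1 & s2 == 1) | (s1 == 2 & s2 == 2)))
    out <- out[keep, , drop = FALSE]
    out$sex1 <- unname(s1[keep])
    out$sex2 <- unname(s2[keep])
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$merit), .data$parent1,
                        .data$parent2)
  if (n_crosses > nrow(out)) {
    warning("requested ", n_crosses, " crosses but only ", nrow(out),
            " pairs survive; returning all", call. = FALSE)
    n_crosses <- nrow(out)
  }
  out <- out[seq_len(n_crosses), , drop = FALSE]
  out <- tibble::add_column(out, id = seq_len(nrow(out)), .before = 1)
  class(out) <- c("cross_table", class(out))
  out
}

resolve_sexes <- function(sexes, ids) {
  if (is.null(sexes)) return(NULL)
  if (is.data.frame(sexes)) {
    stopifnot(all(c("individual", "sex") %in% names(sexes)))
    vec <- stats::setNames(as.integer(sexes$sex),
                           as.character(sexes$individual))
  } else {
    vec <- stats::setNames(as.integer(sexes), names(sexes))
  }
  check_sex_codes(vec)
  out <- vec[ids]
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
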