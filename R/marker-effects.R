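#' Extract per-marker additive and dominance effects
#'
#' Returns the BLUP marker effects from the ridge parameterisation of a
#' [fit_dirdom()] model. The `dominance` column is the total per-marker
#' dominance effect used by the cross-mean equation: the deviation `d*_i`
#' plus the directional component folded in as `-b/m` per marker (with the
#' mean-homozygosity definition of the inbreeding covariate `f`, a unit of
#' heterozygosity at one of `m` markers lowers `f` by `1/m`, so the
#' phenotypic contribution of `b` per unit heterozygosity is `-b/m`).
#' Inbreeding depression (`b < 0`) therefore contributes positive
#' directional dominance. Set `fold_directional = FALSE` to keep only the
#' deviations.
#'
#' @param fit A [fit_dirdom()] object.
#' @param fold_directional Distribute the inbreeding slope across markers
#'   (default `TRUE`).
#' @return A tibble of class `marker_effects` with columns `marker`,
#'   `additive`, `dominance` and `dominance_dev`, carrying the centering
#'   vectors and ploidy as attributes.
#' @export
marker_effects <- function(fit, fold_directional = TRUE) {
  stopifnot(inherits(fit, "dirdom_fit"))
  if (!fit$converged) {
    warning("extracting marker effects from a non-converged fit",
            call. = FALSE)
  }
  m <- length(fit$marker_ids)
  dir_share <- if (fold_directional && fit$directional) {
    -fit$b_inbreeding / m
  } else {
    0
  }
  out <- tibble::tibble(
    marker = fit$marker_ids,
    additive = unname(fit$a),
    dominance_dev = unname(fit$d_star),
    dominance = unname(fit$d_star) + dir_share
  )
  structure(
    out[, c("marker", "additive", "dominance", "dominance_dev")],
    centers_z = fit$centers_z,
    centers_w = fit$centers_w,
    ploidy = fit$ploidy,
    trait = fit$response,
    class = c("marker_effects", class(out))
  )
}

#' Genomic estimated breeding values
#'
#' Sums centered allele dosages times estimated additive marker effects:
#' `GEBV_j = sum_i (dosage_ji - center_i) a_i`. Centering uses the training
#' panel means stored with the effects, so an individual at the panel mean
#' everywhere scores zero. Dominance effects play no part; this is the
#' classical additive selection criterion.
#'
#' @param effects A [marker_effects()] tibble (or a [fit_dirdom()] object).
#' @param G A [geno_matrix()] of candidates on the same marker panel.
#' @return A tibble with columns `individual` and `gebv`, sorted by `gebv`
#'   descending.
#' @export
gebv <- function(effects, G) {
  if (inherits(effects, "dirdom_fit")) effects <- marker_effects(effects)
  stopifnot(inherits(effects, "marker_effects"))
  missing_mk <- setdiff(effects$marker, marker_ids(G))
  if (length(missing_mk) > 0) {
    stop("candidate panel lacks ", length(missing_mk), " marker(s): ",
         paste(utils::head(missing_mk, 5), collapse = ", "),
         if (length(missing_mk) > 5) ", ...", call. = FALSE)
  }
  D <- G$dosages[, effects$marker, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  Zc <- sweep(D, 2, attr(effects, "centers_z"))
  tibble::tibble(
    individual = individual_ids(G),
    gebv = unname(drop(Zc %*% effects$additive))
  ) |>
    dplyr::arrange(dplyr::desc(.data$gebv))
}
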