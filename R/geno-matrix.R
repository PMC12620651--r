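#' Ploidy-aware genotype dosage matrix
#'
#' Container for per-individual, per-marker allele dosages. A dosage is the
#' count of the tracked allele in one genotype call, so it lies in
#' `0..ploidy`: 0/1/2 for diploids, 0..4 for tetraploids, 0..6 for
#' hexaploids. Missing calls are stored as `NA`. After mean imputation (see
#' [filter_markers()]) dosages may be real-valued; the constructor accepts
#' both but validates the range.
#'
#' @param dosages Numeric matrix, individuals in rows and markers in columns.
#'   Row names are individual IDs, column names marker IDs (generated when
#'   absent).
#' @param ploidy Even integer: 2, 4 or 6.
#' @param map Optional data frame of marker metadata with columns `marker`,
#'   `chrom`, `pos` (1-based positions, carried as metadata only).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, ploidy, map = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!ploidy %in% c(2L, 4L, 6L)) {
    stop("`ploidy` must be 2, 4 or 6, got ", ploidy, call. = FALSE)
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("individual IDs must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(dosages))) {
    stop("marker IDs must be unique", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (nrow(dosages) && ncol(dosages) && !all(is.na(dosages)) &&
      (rng[1] < 0 || rng[2] > ploidy)) {
    stop("dosages must lie in [0, ", ploidy, "]", call. = FALSE)
  }
  if (!is.null(map)) {
    map <- tibble::as_tibble(map)
    stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  }
  structure(
    list(dosages = dosages, ploidy = as.integer(ploidy), map = map),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d markers, ploidy %d, %.1f%% missing\n",
    nrow(x$dosages), ncol(x$dosages), x$ploidy,
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Individual and marker identifiers
#' @param G A [geno_matrix()].
#' @return Character vector of IDs.
#' @export
individual_ids <- function(G) rownames(G$dosages)

#' @rdname individual_ids
#' @export
marker_ids <- function(G) colnames(G$dosages)

#' Per-call heterozygosity coefficients
#'
#' For a call with dosage `k` at ploidy `rho`, returns the fraction of the
#' `choose(rho, 2)` within-individual allele pairs that join unlike alleles:
#' `k * (rho - k) / choose(rho, 2)`. For diploids this is the usual 0/1
#' heterozygote indicator; for a tetraploid duplex call (k = 2) it is 2/3.
#' This coding forms the `W` matrix of the directional-dominance model.
#' Missing dosages propagate as `NA`.
#'
#' @param G A [geno_matrix()].
#' @return Numeric matrix of the same shape as the dosages, entries in
#'   `[0, 1]`.
#' @export
het_matrix <- function(G) {
  rho <- G$ploidy
  G$dosages * (rho - G$dosages) / choose(rho, 2)
}

#' Genomic inbreeding coefficients
#'
#' One minus the mean heterozygosity coefficient across an individual's
#' non-missing markers: 1 for an individual homozygous everywhere, 0 for a
#' diploid heterozygous everywhere. This genomic definition makes the
#' directional-dominance covariate a pure function of the heterozygosity
#' matrix and needs no reference panel.
#'
#' @param G A [geno_matrix()].
#' @return Named numeric vector, one coefficient in `[0, 1]` per individual.
#' @export
inbreeding_coefficients <- function(G) {
  W <- het_matrix(G)
  n_obs <- rowSums(!is.na(W))
  if (any(n_obs == 0)) {
    bad <- individual_ids(G)[n_obs == 0]
    stop("individual(s) with no non-missing markers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  1 - rowMeans(W, na.rm = TRUE)
}

#' Within-parent allele frequencies
#'
#' The frequency of the tracked allele within one parent's genotype:
#' `dosage / ploidy`. These are the per-parent frequencies consumed by the
#' F1 progeny-mean equation (their products, e.g. `2 p q`, require the
#' `[0, 1]` scale).
#'
#' @param G A [geno_matrix()].
#' @return Numeric matrix of frequencies in `[0, 1]`, same shape as dosages.
#' @export
parental_frequencies <- function(G) {
  G$dosages / G$ploidy
}

#' Filter markers and impute missing dosages
#'
#' Removes markers whose minor-allele frequency falls below `min_maf` or
#' whose missing fraction exceeds `max_missing`, then fills remaining
#' missing dosages with the marker's mean dosage (so imputed dosages are
#' real-valued). Heterozygosity and inbreeding coefficients should be taken
#' from observed calls before imputation; [build_design()] does so.
#'
#' @param G A [geno_matrix()].
#' @param min_maf Minimum minor-allele frequency in `[0, 0.5]`.
#' @param max_missing Maximum per-marker missing fraction in `[0, 1]`.
#' @return A filtered, imputed [geno_matrix()].
#' @export
filter_markers <- function(G, min_maf = 0, max_missing = 1) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_missing >= 0, max_missing <= 1)
  D <- G$dosages
  p <- colMeans(D, na.rm = TRUE) / G$ploidy
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(D))
  keep <- !is.na(maf) & maf >= min_maf & miss <= max_missing
  if (!any(keep)) {
    stop("all markers removed by MAF/missingness filters", call. = FALSE)
  }
  D <- D[, keep, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  map <- G$map
  if (!is.null(map)) map <- map[map$marker %in% colnames(D), , drop = FALSE]
  geno_matrix(D, G$ploidy, map)
}

#' Coerce a genotype matrix to a long tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `individual`, `marker`, `dosage`.
#' @exportS3Method tibble::as_tibble
as_tibble.geno_matrix <- function(x, ...) {
  tibble::as_tibble(x$dosages, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "marker",
                        values_to = "dosage")
}
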