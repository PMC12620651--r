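#' Predict cross performance from phenotype and genotype files
#'
#' End-to-end pipeline: read the genotype file (VCF or HapMap), fit the
#' additive + directional-dominance model by REML for each weighted trait,
#' back-solve marker effects, and rank all candidate parental combinations
#' by index-weighted predicted F1 mean. This mirrors the workflow of the
#' BreedBase cross-prediction tool: phenotype CSV plus genotype file in,
#' ranked cross table out.
#'
#' @param pheno Phenotype data frame (or path to a CSV file), one row per
#'   plot/observation.
#' @param geno A [geno_matrix()], or path to a VCF (`.vcf`/`.vcf.gz`) or
#'   HapMap file.
#' @param traits Character vector of trait column names.
#' @param weights Numeric selection-index weights, one per trait (default
#'   all 1).
#' @param genotype_id Genotype-ID column name (default `"germplasmName"`).
#' @param fixed Fixed-factor column names.
#' @param ploidy Ploidy for genotype file parsing (2, 4 or 6).
#' @param n_crosses Number of top crosses to report.
#' @param sexes Optional sex codes (see [predict_crosses()]).
#' @param allow_self Keep self-crosses.
#' @param min_maf,max_missing Marker QC thresholds applied before fitting.
#' @param verbose Log variance components per trait with `message()`.
#' @return A `cross_table` tibble (see [predict_crosses()]) with the
#'   per-trait fits attached as attribute `"fits"`.
#' @export
run_gpcp <- function(pheno, geno, traits, weights = rep(1, length(traits)),
                     genotype_id = "germplasmName", fixed = character(),
                     ploidy = 2, n_crosses = 100, sexes = NULL,
                     allow_self = FALSE, min_maf = 0.01, max_missing = 0.6,
                     verbose = TRUE) {
  if (length(weights) != length(traits)) {
    stop("`traits` and `weights` must have the same length", call. = FALSE)
  }
  if (is.character(pheno)) {
    pheno <- utils::read.csv(pheno, check.names = FALSE)
  }
  G <- resolve_geno(geno, ploidy)
  G <- filter_markers(G, min_maf = min_maf, max_missing = max_missing)

  fits <- list()
  eff <- list()
  for (tr in traits) {
    fit <- fit_dirdom(pheno, G, response = tr, genotype_id = genotype_id,
                      fixed = fixed)
    if (verbose) {
      message(sprintf(
        "trait %s: var_a %.4g, var_d %.4g, var_e %.4g, b %.4g (%s)",
        tr, fit$var_additive, fit$var_dominance, fit$var_residual,
        fit$b_inbreeding,
        if (fit$converged) "converged" else "not converged"))
    }
    fits[[tr]] <- fit
    eff[[tr]] <- marker_effects(fit)
  }

  keep <- intersect(individual_ids(G), unique(fits[[1]]$geno))
  G_parents <- geno_matrix(G$dosages[keep, , drop = FALSE], G$ploidy, G$map)
  out <- predict_crosses(eff, G_parents,
                         weights = stats::setNames(weights, traits),
                         sexes = sexes, n_crosses = n_crosses,
                         allow_self = allow_self)
  attr(out, "fits") <- fits
  out
}

resolve_geno <- function(geno, ploidy) {
  if (inherits(geno, "geno_matrix")) return(geno)
  if (!is.character(geno) || length(geno) != 1) {
    stop("`geno` must be a geno_matrix or a file path", call. = FALSE)
  }
  if (grepl("\\.vcf(\\.gz)?$", geno, ignore.case = TRUE)) {
    read_vcf(geno, ploidy)
  } else {
    read_hapmap(geno, ploidy)
  }
}
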