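#' Specification for a deterministic test fixture
#'
#' Describes a marker panel with known effects and a phenotype set
#' simulated forward from the additive + directional-dominance model, so
#' downstream expected values can be computed from the stored truth
#' instead of re-derived. A seed is mandatory: there are no unseeded
#' fixtures.
#'
#' @param n_individuals,n_markers Panel dimensions.
#' @param ploidy 2, 4 or 6.
#' @param var_additive,var_dominance,var_residual True variance components
#'   (all `>= 0`; a zero residual gives noiseless phenotypes).
#' @param b_inbreeding True slope on the genomic inbreeding covariate.
#' @param mu True intercept.
#' @param fixed_factor_levels Number of levels of an optional fixed factor
#'   (0 for none); records are replicated across levels.
#' @param seed Integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_individuals, n_markers, ploidy = 2,
                         var_additive = 1, var_dominance = 0.5,
                         var_residual = 1, b_inbreeding = -0.5, mu = 10,
                         fixed_factor_levels = 0, seed) {
  if (missing(seed)) stop("fixture seed is mandatory", call. = FALSE)
  stopifnot(var_additive >= 0, var_dominance >= 0, var_residual >= 0,
            ploidy %in% c(2, 4, 6))
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_markers = as.integer(n_markers), ploidy = as.integer(ploidy),
         var_additive = var_additive, var_dominance = var_dominance,
         var_residual = var_residual, b_inbreeding = b_inbreeding,
         mu = mu, fixed_factor_levels = as.integer(fixed_factor_levels),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a marker panel with known effects
#'
#' Dosages are binomial(ploidy, p_i) draws with per-marker frequencies
#' p_i ~ U(0.05, 0.95); true additive and dominance-deviation effects are
#' drawn N(0, sigma2 / scale) with the same VanRaden-style scales the model
#' uses, so the realized genetic variances match the requested components.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `G` (a [geno_matrix()]) and `truth`, a tibble of
#'   per-marker `a` and `d_star` plus the scale constants as attributes.
#' @export
make_panel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  m <- spec$n_markers
  rho <- spec$ploidy
  p <- stats::runif(m, 0.05, 0.95)
  D <- matrix(stats::rbinom(n * m, rho, rep(p, each = n)), nrow = n,
              dimnames = list(sprintf("ind%03d", seq_len(n)),
                              sprintf("snp%04d", seq_len(m))))
  G <- geno_matrix(D, rho)
  p_bar <- colMeans(D) / rho
  scale_a <- sum(2 * p_bar * (1 - p_bar)) * (rho / 2)
  scale_d <- sum((2 * p_bar * (1 - p_bar))^2)
  truth <- tibble::tibble(
    marker = colnames(D),
    p = p,
    a = stats::rnorm(m, 0, sqrt(spec$var_additive / max(scale_a, 1e-12))),
    d_star = if (spec$var_dominance > 0) {
      stats::rnorm(m, 0, sqrt(spec$var_dominance / max(scale_d, 1e-12)))
    } else {
      rep(0, m)
    }
  )
  attr(truth, "scale_a") <- scale_a
  attr(truth, "scale_d") <- scale_d
  list(G = G, truth = truth)
}

#' Simulate phenotypes forward from the directional-dominance model
#'
#' Assembles `y = mu + X beta + f b + Z_c a + W_c d* + e` exactly: centered
#' dosage and heterozygosity codings, the panel's genomic inbreeding
#' coefficients, the true effects from [make_panel()], and iid Gaussian
#' residuals. The generating values are returned as a truth list alongside
#' the records.
#'
#' @param panel Output of [make_panel()].
#' @param spec The same [fixture_spec()].
#' @return A list with `pheno` (tibble: `germplasmName`, optional `block`,
#'   `trait`) and `truth` (list of generating values).
#' @export
make_phenotypes <- function(panel, spec) {
  G <- panel$G
  set.seed(spec$seed + 1L)
  D <- G$dosages
  W <- het_matrix(G)
  f <- inbreeding_coefficients(G)
  Zc <- sweep(D, 2, colMeans(D))
  Wc <- sweep(W, 2, colMeans(W))
  g <- unname(drop(Zc %*% panel$truth$a + Wc %*% panel$truth$d_star))
  n <- nrow(D)

  n_lev <- max(1L, spec$fixed_factor_levels)
  beta_lev <- if (spec$fixed_factor_levels > 1) {
    seq(0, by = 1, length.out = n_lev)
  } else {
    rep(0, n_lev)
  }
  recs <- tidyr::expand_grid(idx = seq_len(n), level = seq_len(n_lev))
  e <- stats::rnorm(nrow(recs), 0, sqrt(spec$var_residual))
  pheno <- tibble::tibble(
    germplasmName = individual_ids(G)[recs$idx],
    trait = spec$mu + beta_lev[recs$level] +
      spec$b_inbreeding * unname(f)[recs$idx] + g[recs$idx] + e
  )
  if (spec$fixed_factor_levels > 1) {
    pheno$block <- paste0("B", recs$level)
  }
  list(
    pheno = pheno,
    truth = list(mu = spec$mu, beta_levels = beta_lev,
                 b_inbreeding = spec$b_inbreeding,
                 a = panel$truth$a, d_star = panel$truth$d_star,
                 genetic_values = g, f = f,
                 var_additive = spec$var_additive,
                 var_dominance = spec$var_dominance,
                 var_residual = spec$var_residual)
  )
}

#' Write a genotype matrix as a VCF file
#'
#' Plain-text VCF 4.2 with GT calls reconstructed from integer dosages
#' (REF `A`, ALT `C`; the ALT count equals the dosage). Missing dosages
#' become `./.`-style calls. Real-valued (imputed) dosages are not
#' representable and raise an error.
#'
#' @param G A [geno_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  D <- G$dosages
  rho <- G$ploidy
  if (any(abs(D - round(D)) > 1e-9, na.rm = TRUE)) {
    stop("cannot write real-valued (imputed) dosages as GT calls",
         call. = FALSE)
  }
  map <- G$map %||% tibble::tibble(marker = marker_ids(G), chrom = "1",
                                   pos = seq_len(ncol(D)))
  gt_strings <- vapply(0:rho, function(k) {
    paste(c(rep("0", rho - k), rep("1", k)), collapse = "/")
  }, "")
  miss <- paste(rep(".", rho), collapse = "/")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individual_ids(G)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(D)), function(i) {
    calls <- ifelse(is.na(D[, i]), miss, gt_strings[round(D[, i]) + 1L])
    paste(c(map$chrom[i], map$pos[i], map$marker[i], "A", "C", ".", "PASS",
            ".", "GT", calls), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a diploid genotype matrix as a HapMap file
#'
#' Tab-delimited HapMap with the 11 standard metadata columns; calls are
#' `AA`/`AC`/`CC` with `NN` for missing, alleles listed as `A/C` so the
#' counted (second) allele matches [write_vcf()]'s ALT. Polyploid panels
#' are rejected: HapMap cannot encode partial polyploid dosage.
#'
#' @inheritParams write_vcf
#' @return Invisibly, `path`.
#' @export
write_hapmap <- function(G, path) {
  if (G$ploidy != 2) {
    stop("HapMap output supports diploids only", call. = FALSE)
  }
  D <- G$dosages
  if (any(abs(D - round(D)) > 1e-9, na.rm = TRUE)) {
    stop("cannot write real-valued (imputed) dosages as HapMap calls",
         call. = FALSE)
  }
  map <- G$map %||% tibble::tibble(marker = marker_ids(G), chrom = "1",
                                   pos = seq_len(ncol(D)))
  calls <- c("AA", "AC", "CC")
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID",
                    "QCcode", individual_ids(G)), collapse = "\t")
  body <- vapply(seq_len(ncol(D)), function(i) {
    cl <- ifelse(is.na(D[, i]), "NN", calls[round(D[, i]) + 1L])
    paste(c(map$marker[i], "A/C", map$chrom[i], map$pos[i], "+", "NA", "NA",
            "NA", "NA", "NA", "NA", cl), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a complete fixture set to disk
#'
#' Paired VCF and (diploid) HapMap encodings of the same panel, the
#' phenotype CSV, and a truth sidecar CSV of the generating marker
#' effects, so reading either genotype encoding reproduces the dosage
#' matrix exactly and test oracles never re-simulate.
#'
#' @param panel Output of [make_panel()].
#' @param phenotypes Output of [make_phenotypes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of paths.
#' @export
write_fixture <- function(panel, phenotypes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             pheno = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.csv"))
  write_vcf(panel$G, paths[["vcf"]])
  if (panel$G$ploidy == 2) {
    paths <- c(paths, hapmap = file.path(dir, "panel.hmp.txt"))
    write_hapmap(panel$G, paths[["hapmap"]])
  }
  utils::write.csv(phenotypes$pheno, paths[["pheno"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(
    data.frame(marker = panel$truth$marker, a = panel$truth$a,
               d_star = panel$truth$d_star),
    paths[["truth"]], row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}
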