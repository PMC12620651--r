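#' Configuration for the forward breeding-programme simulation
#'
#' Bundles and validates all knobs of the clonal-pipeline experiment. The
#' defaults reproduce the reference experimental design: founder populations
#' with 18 chromosomes of 5400 segregating sites, a 1000-SNP-per-chromosome
#' marker panel (18 000 SNPs total), 56 QTL overall, a 10-generation
#' random-mating burn-in, 40 selection cycles, a baseline of 400 crosses,
#' and the four-stage clonal pipeline CE -> PYT -> AYT -> UYT with plot
#' heritabilities 0.15/0.25/0.45/0.65, replications 1/2/3/3 and advancement
#' fractions 0.90/0.80/0.70/0.60. Trait architecture is controlled by the
#' mean dominance degree (`mean_dd` in 0/0.5/1/2/4 in the reference
#' scenarios, paired with trait heritabilities 0.6/0.3/0.3/0.3/0.1).
#'
#' @param n_founders Founder population size (reference levels 250, 500,
#'   750, 1000).
#' @param n_chromosomes Number of chromosomes.
#' @param sites_per_chr Segregating sites simulated per chromosome.
#' @param markers_per_chr SNP-panel sites per chromosome (disjoint from
#'   QTL).
#' @param n_qtl Total QTL count across the genome.
#' @param mean_dd,var_dd Mean and variance of the per-QTL dominance degree
#'   `delta_i`; dominance effects are `d_i = |a_i| * delta_i`.
#' @param h2_trait Narrow-sense trait heritability used for burn-in
#'   phenotyping.
#' @param burn_in_cycles Random-mating generations before selection starts.
#' @param n_cycles Selection cycles per arm after burn-in.
#' @param n_crosses Crosses advanced per cycle (reference baseline B =
#'   400).
#' @param progeny_per_cross Progeny per cross; default keeps the census
#'   near `n_founders`.
#' @param stage_h2,stage_reps,stage_advance Length-4 vectors for the
#'   CE/PYT/AYT/UYT stages: plot heritability, replications, and the
#'   fraction advanced (floor rounding).
#' @param parent_usage Target number of crosses each selected parent
#'   enters in the GEBV arm: the top `2 * n_crosses / parent_usage`
#'   candidates are chain-mated round-robin, so larger values concentrate
#'   matings on fewer elite parents.
#' @param uc_selected_fraction Within-progeny selected fraction used for
#'   the usefulness criterion; defaults to the product of the stage
#'   advancement fractions (clamped inside (0, 1)).
#' @param map_length Chromosome genetic length in Morgans (Poisson
#'   crossovers, no interference).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 250, n_chromosomes = 18,
                       sites_per_chr = 5400, markers_per_chr = 1000,
                       n_qtl = 56, mean_dd = 0, var_dd = 0.2,
                       h2_trait = 0.6, burn_in_cycles = 10, n_cycles = 40,
                       n_crosses = 400,
                       progeny_per_cross = NULL,
                       stage_h2 = c(0.15, 0.25, 0.45, 0.65),
                       stage_reps = c(1, 2, 3, 3),
                       stage_advance = c(0.90, 0.80, 0.70, 0.60),
                       parent_usage = 4,
                       uc_selected_fraction = NULL,
                       map_length = 1.0) {
  if (is.null(progeny_per_cross)) {
    progeny_per_cross <- max(1L, round(n_founders / n_crosses))
  }
  if (is.null(uc_selected_fraction)) {
    uc_selected_fraction <- min(0.99, max(0.01, prod(stage_advance)))
  }
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_chromosomes = as.integer(n_chromosomes),
    sites_per_chr = as.integer(sites_per_chr),
    markers_per_chr = as.integer(markers_per_chr),
    n_qtl = as.integer(n_qtl),
    mean_dd = mean_dd, var_dd = var_dd, h2_trait = h2_trait,
    burn_in_cycles = as.integer(burn_in_cycles),
    n_cycles = as.integer(n_cycles),
    n_crosses = as.integer(n_crosses),
    progeny_per_cross = as.integer(progeny_per_cross),
    stage_h2 = stage_h2, stage_reps = as.integer(stage_reps),
    stage_advance = stage_advance,
    parent_usage = as.integer(parent_usage),
    uc_selected_fraction = uc_selected_fraction,
    map_length = map_length
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- character()
  chk <- function(ok, msg) if (!ok) probs <<- c(probs, msg)
  chk(cfg$n_founders >= 4, "n_founders must be >= 4")
  chk(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  qtl_per_chr <- ceiling(cfg$n_qtl / cfg$n_chromosomes)
  chk(cfg$markers_per_chr + qtl_per_chr <= cfg$sites_per_chr,
      "markers_per_chr + QTL per chromosome exceed sites_per_chr")
  chk(cfg$n_qtl >= 1, "n_qtl must be >= 1")
  chk(cfg$var_dd >= 0, "var_dd must be >= 0")
  chk(cfg$h2_trait > 0 && cfg$h2_trait < 1, "h2_trait must be in (0,1)")
  chk(length(cfg$stage_h2) == 4 && all(cfg$stage_h2 > 0 & cfg$stage_h2 < 1),
      "stage_h2 must be 4 values in (0,1)")
  chk(length(cfg$stage_reps) == 4 && all(cfg$stage_reps >= 1),
      "stage_reps must be 4 values >= 1")
  chk(length(cfg$stage_advance) == 4 &&
        all(cfg$stage_advance > 0 & cfg$stage_advance <= 1),
      "stage_advance must be 4 fractions in (0,1]")
  chk(cfg$uc_selected_fraction > 0 && cfg$uc_selected_fraction < 1,
      "uc_selected_fraction must be in (0,1)")
  chk(cfg$n_crosses >= 1, "n_crosses must be >= 1")
  chk(cfg$parent_usage >= 1, "parent_usage must be >= 1")
  chk(cfg$progeny_per_cross >= 1, "progeny_per_cross must be >= 1")
  chk(cfg$burn_in_cycles >= 0, "burn_in_cycles must be >= 0")
  chk(cfg$n_cycles >= 0, "n_cycles must be >= 0")
  chk(cfg$map_length >= 0, "map_length must be >= 0")
  if (length(probs) > 0) {
    stop("invalid simulation config:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}
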