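#' Run one cohort through the multi-stage clonal pipeline
#'
#' Clonal evaluation (CE), preliminary (PYT), advanced (AYT) and uniform
#' (UYT) yield trials: at each stage the surviving entries are phenotyped
#' at that stage's plot heritability and replication, ranked on phenotype,
#' and the configured top fraction advances (floor rounding, at least two
#' kept). Only the UYT survivors form the candidate parent set; every
#' phenotype record from every stage is returned for model training.
#'
#' @param pop A `sim_population` cohort entering CE.
#' @param cfg A [sim_config()].
#' @return A list with `candidates` (indices of UYT survivors) and
#'   `records`, a tibble of (`individual`, `stage`, `pheno`, `reps`).
#' @export
run_stage_pipeline <- function(pop, cfg) {
  stages <- c("CE", "PYT", "AYT", "UYT")
  alive <- seq_len(pop_size(pop))
  g <- genetic_values(pop)
  vg <- stats::var(g)
  recs <- vector("list", 4)
  for (s in 1:4) {
    h2 <- cfg$stage_h2[s]
    reps <- cfg$stage_reps[s]
    # a fixed population (vg = 0) yields informationless, noise-free records
    se2 <- if (vg > 1e-12) vg * (1 - h2) / h2 else 0
    ph <- g[alive] + stats::rnorm(length(alive), 0, sqrt(se2 / reps))
    recs[[s]] <- tibble::tibble(individual = alive, stage = stages[s],
                                pheno = ph, reps = reps)
    n_keep <- max(2L, floor(cfg$stage_advance[s] * length(alive) + 1e-9))
    n_keep <- min(n_keep, length(alive))
    alive <- alive[order(ph, decreasing = TRUE)[seq_len(n_keep)]]
    alive <- sort(alive)
  }
  list(candidates = alive, records = dplyr::bind_rows(recs))
}

# Replication-weighted phenotype means per individual across pipeline stages
training_phenotypes <- function(records) {
  records |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(
      y = stats::weighted.mean(.data$pheno, .data$reps),
      .groups = "drop"
    )
}

#' Select parents and produce the next cycle's progeny
#'
#' Trains a genomic model on the current cycle's pipeline phenotypes, then
#' either (method `"gebv"`) ranks the UYT candidates on additive GEBV and
#' chain-mates the top parents round-robin until the configured number of
#' crosses is reached, or (method `"gpcp"`) ranks all candidate pairs on
#' predicted F1 mean (additive + directional dominance) and mates the top
#' crosses. Both methods produce `n_crosses * progeny_per_cross` progeny,
#' so the arms stay comparable.
#'
#' @param pop The current cohort.
#' @param pipeline Output of [run_stage_pipeline()] on `pop`.
#' @param method `"gebv"` or `"gpcp"`.
#' @param cfg A [sim_config()].
#' @return A list with the progeny `pop`, the per-progeny genotypic values
#'   `g`, and the selected cross table.
#' @export
select_and_mate <- function(pop, pipeline, method = c("gebv", "gpcp"), cfg) {
  method <- match.arg(method)
  cand <- pipeline$candidates
  if (length(cand) < 2) stop("fewer than 2 candidate parents", call. = FALSE)

  G <- marker_genotypes(pop)
  train <- training_phenotypes(pipeline$records)
  pheno <- tibble::tibble(
    germplasmName = individual_ids(G)[train$individual],
    y = train$y
  )
  # markers fixed during selection carry no information and no variance;
  # if training collapses entirely (all markers or the trait fixed), fall
  # back to random mating among the candidates
  fit <- tryCatch({
    Gq <- filter_markers(G, min_maf = 1e-9, max_missing = 1)
    suppressWarnings(suppressMessages(
      fit_dirdom(pheno, Gq, response = "y",
                 dominance = method == "gpcp",
                 directional = method == "gpcp",
                 max_iter = 100)
    ))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    i <- seq_len(cfg$n_crosses)
    p1 <- cand[sample.int(length(cand), cfg$n_crosses, replace = TRUE)]
    p2 <- vapply(p1, function(j) {
      others <- cand[cand != j]
      others[sample.int(length(others), 1)]
    }, integer(1))
    prog <- mate_crosses(pop, p1, p2, cfg$progeny_per_cross)
    return(list(pop = prog, g = genetic_values(prog),
                crosses = tibble::tibble(
                  parent1 = individual_ids(G)[p1],
                  parent2 = individual_ids(G)[p2])))
  }
  eff <- suppressWarnings(marker_effects(fit))
  cand_ids <- individual_ids(G)[cand]
  G_cand <- geno_matrix(Gq$dosages[cand_ids, , drop = FALSE], 2)

  if (method == "gebv") {
    ranked <- gebv(eff, G_cand)
    np <- min(nrow(ranked),
              max(2L, ceiling(2 * cfg$n_crosses / cfg$parent_usage)))
    parents <- match(ranked$individual[seq_len(np)], individual_ids(G))
    i <- seq_len(cfg$n_crosses)
    p1 <- parents[(i - 1L) %% np + 1L]
    p2 <- parents[i %% np + 1L]
    crosses <- tibble::tibble(parent1 = individual_ids(G)[p1],
                              parent2 = individual_ids(G)[p2])
  } else {
    ct <- suppressWarnings(
      predict_crosses(eff, G_cand, n_crosses = cfg$n_crosses)
    )
    p1 <- match(ct$parent1, individual_ids(G))
    p2 <- match(ct$parent2, individual_ids(G))
    crosses <- ct[, c("parent1", "parent2", "merit")]
  }

  prog <- mate_crosses(pop, p1, p2, cfg$progeny_per_cross)
  list(pop = prog, g = genetic_values(prog), crosses = crosses)
}

#' Run the GEBV-vs-GPCP selection experiment
#'
#' Simulates founders, runs the shared random-mating burn-in (both arms
#' are bit-identical through cycle 0), then advances a GEBV arm and a GPCP
#' arm independently from the same post-burn-in state for `n_cycles`
#' cycles of pipeline phenotyping, genomic model training, parent
#' selection and mating. Per cycle and arm the usefulness criterion of the
#' new progeny and the panel mean heterozygosity are recorded, along with
#' the arm differences `delta_uc = UC_GPCP - UC_GEBV` and
#' `delta_h = H_GPCP - H_GEBV`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; every source of randomness derives from it.
#' @return A tibble of class `sim_trajectory` with columns `cycle` (burn-in
#'   cycles are non-positive), `arm`, `uc`, `mean_het`, `delta_uc`,
#'   `delta_h`.
#' @export
run_experiment <- function(cfg, seed = 1) {
  validate_sim_config(cfg)
  set.seed(seed)
  pop <- simulate_founders(cfg)

  burn_rows <- list()
  if (cfg$burn_in_cycles > 0) {
    for (cy in seq_len(cfg$burn_in_cycles)) {
      n <- pop_size(pop)
      n_cross <- max(1L, n %/% 2L)
      p1 <- sample.int(n, n_cross, replace = TRUE)
      p2 <- vapply(p1, function(j) sample(setdiff(seq_len(n), j), 1),
                   integer(1))
      ppc <- max(1L, ceiling(cfg$n_founders / n_cross))
      pop <- mate_crosses(pop, p1, p2, ppc)
      # burn-in evaluates phenotypes but applies no selection
      invisible(sim_phenotypes(pop, cfg$h2_trait))
      uc <- usefulness_criterion(genetic_values(pop),
                                 cfg$uc_selected_fraction)
      h <- mean_heterozygosity(pop)
      burn_rows[[cy]] <- tibble::tibble(
        cycle = cy - cfg$burn_in_cycles,
        arm = c("gebv", "gpcp"), uc = uc, mean_het = h
      )
    }
  }

  base_pop <- pop
  arm_rows <- list()
  for (arm in c("gebv", "gpcp")) {
    set.seed(seed + if (arm == "gebv") 104729L else 224737L)
    pop_a <- base_pop
    for (cy in seq_len(cfg$n_cycles)) {
      pipe <- run_stage_pipeline(pop_a, cfg)
      step <- select_and_mate(pop_a, pipe, method = arm, cfg = cfg)
      pop_a <- step$pop
      arm_rows[[length(arm_rows) + 1]] <- tibble::tibble(
        cycle = cy, arm = arm,
        uc = usefulness_criterion(step$g, cfg$uc_selected_fraction),
        mean_het = mean_heterozygosity(pop_a)
      )
    }
  }

  traj <- dplyr::bind_rows(c(burn_rows, arm_rows))
  if (nrow(traj) > 0) {
    wide <- traj |>
      tidyr::pivot_wider(id_cols = "cycle", names_from = "arm",
                         values_from = c("uc", "mean_het"))
    wide$delta_uc <- wide$uc_gpcp - wide$uc_gebv
    wide$delta_h <- wide$mean_het_gpcp - wide$mean_het_gebv
    traj <- dplyr::left_join(
      traj, wide[, c("cycle", "delta_uc", "delta_h")], by = "cycle"
    ) |>
      dplyr::arrange(.data$cycle, .data$arm)
  }
  class(traj) <- c("sim_trajectory", class(traj))
  attr(traj, "config") <- cfg
  attr(traj, "seed") <- seed
  traj
}

#' Run the experiment across several seeds
#'
#' Single-replicate trajectories are noisy; running a handful of seeds and
#' averaging is the package default for trend statements.
#'
#' @param cfg A [sim_config()].
#' @param seeds Integer vector of seeds.
#' @return A `sim_trajectory` tibble with a `seed` column.
#' @export
run_experiment_multi <- function(cfg, seeds) {
  out <- purrr::map(seeds, function(s) {
    tr <- run_experiment(cfg, seed = s)
    tr$seed <- s
    tr
  }) |>
    dplyr::bind_rows()
  class(out) <- c("sim_trajectory", class(tibble::tibble()))
  attr(out, "config") <- cfg
  out
}

#' Export a simulated population for the file-based pipeline
#'
#' Writes the marker-panel genotypes as VCF and phenotypes (one simulated
#' record at the configured trait heritability) as CSV, so a simulation
#' snapshot can be pushed through [run_gpcp()] end to end.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if needed).
#' @param h2 Heritability for the exported phenotype record.
#' @return Invisibly, the paths written.
#' @export
export_population <- function(pop, dir, h2 = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- marker_genotypes(pop)
  vcf_path <- file.path(dir, "population.vcf")
  csv_path <- file.path(dir, "phenotypes.csv")
  write_vcf(G, vcf_path)
  utils::write.csv(
    data.frame(germplasmName = individual_ids(G),
               trait = sim_phenotypes(pop, h2)),
    csv_path, row.names = FALSE, quote = FALSE
  )
  invisible(c(vcf = vcf_path, pheno = csv_path))
}
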