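small_cfg <- function(...) {
  args <- list(n_founders = 60, n_chromosomes = 2, sites_per_chr = 200,
               markers_per_chr = 80, n_qtl = 20, mean_dd = 1, var_dd = 0.2,
               h2_trait = 0.3, burn_in_cycles = 2, n_cycles = 2,
               n_crosses = 15, progeny_per_cross = 4)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("config validation names every offending field", {
  expect_s3_class(small_cfg(), "sim_config")
  expect_error(small_cfg(markers_per_chr = 195, n_qtl = 40),
               "exceed sites_per_chr")
  expect_error(small_cfg(h2_trait = 1.2), "h2_trait")
  expect_error(small_cfg(stage_advance = c(0.9, 0.8)), "stage_advance")
  err <- tryCatch(small_cfg(h2_trait = 2, n_qtl = 0), error = identity)
  expect_match(conditionMessage(err), "h2_trait")
  expect_match(conditionMessage(err), "n_qtl")
})

test_that("founders are normalized to unit additive variance, zero mean", {
  set.seed(1)
  cfg <- small_cfg()
  pop <- simulate_founders(cfg)
  D <- crosskit:::qtl_dosages(pop)
  expect_equal(var(drop(D %*% pop$qtl$a)), 1, tolerance = 1e-10)
  expect_equal(mean(genetic_values(pop)), 0, tolerance = 1e-10)
  expect_equal(nrow(pop$qtl), 20L)
  # QTL and marker panel are disjoint within each chromosome
  for (c_i in 1:2) {
    expect_length(intersect(pop$qtl$site[pop$qtl$chrom == c_i],
                            pop$markers[[c_i]]), 0)
  }
})

test_that("dominance-degree settings shape QTL effects", {
  set.seed(2)
  pop0 <- simulate_founders(small_cfg(mean_dd = 0, var_dd = 0))
  expect_true(all(pop0$qtl$d == 0))
  set.seed(2)
  pop4 <- simulate_founders(small_cfg(mean_dd = 4, var_dd = 0))
  expect_equal(pop4$qtl$d, 4 * abs(pop4$qtl$a), tolerance = 1e-12)
})

test_that("meiosis transmits parental alleles faithfully", {
  set.seed(3)
  cfg <- small_cfg()
  pop <- simulate_founders(cfg)
  # a homozygous parent transmits its haplotype regardless of crossovers
  pop$haplos[[1]][1, ] <- pop$haplos[[1]][2, ]
  pop$haplos[[2]][1, ] <- pop$haplos[[2]][2, ]
  g <- crosskit:::meiosis(pop, 1)
  expect_equal(g[[1]], pop$haplos[[1]][1, ])
  # zero map length: whole parental haplotype, one of the two
  pop0 <- pop
  pop0$map_length <- 0
  g0 <- crosskit:::meiosis(pop0, 2)
  expect_true(identical(g0[[1]], pop0$haplos[[1]][3, ]) ||
                identical(g0[[1]], pop0$haplos[[1]][4, ]))
  # an Aa locus segregates 1:1 over many gametes
  pop$haplos[[1]][3, 1] <- 1L
  pop$haplos[[1]][4, 1] <- 0L
  alleles <- replicate(4000, crosskit:::meiosis(pop, 2)[[1]][1])
  expect_lt(abs(mean(alleles) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("phenotypes are unbiased with heritability-scaled noise", {
  set.seed(4)
  cfg <- small_cfg(n_founders = 400)
  pop <- simulate_founders(cfg)
  g <- genetic_values(pop)
  y <- sim_phenotypes(pop, h2 = 0.25)
  expect_equal(unname(coef(lm(y ~ g))[2]), 1, tolerance = 0.2)
  # variance ratio close to the target h2
  expect_equal(var(g) / var(y), 0.25, tolerance = 0.08)
  # near-perfect heritability returns the genotypic values
  expect_equal(sim_phenotypes(pop, h2 = 1 - 1e-12), g, tolerance = 1e-4)
  # replicate means shrink the error variance
  y3 <- replicate(200, sim_phenotypes(pop, h2 = 0.25, n_reps = 3))
  err_var <- mean(apply(y3 - g, 1, var))
  expect_equal(err_var, var(g) * 3 / 0.25 * (1 - 0.25) / 3 / 3,
               tolerance = 0.15)
})

test_that("stage advancement follows the floor-fraction chain", {
  set.seed(5)
  cfg <- small_cfg(n_founders = 1000, sites_per_chr = 60, markers_per_chr = 20,
                   n_qtl = 10)
  pop <- simulate_founders(cfg)
  pipe <- run_stage_pipeline(pop, cfg)
  # 1000 -> 900 -> 720 -> 504 -> 302
  expect_length(pipe$candidates, 302L)
  expect_equal(nrow(pipe$records), 1000 + 900 + 720 + 504)
  # all-1.0 advancement keeps everyone
  cfg_id <- small_cfg(n_founders = 50, stage_advance = rep(1, 4))
  set.seed(5)
  pop50 <- simulate_founders(cfg_id)
  expect_length(run_stage_pipeline(pop50, cfg_id)$candidates, 50L)
})

test_that("later stages rank candidates closer to true genetic merit", {
  set.seed(6)
  cfg <- small_cfg(n_founders = 500, sites_per_chr = 100,
                   markers_per_chr = 30, n_qtl = 30)
  pop <- simulate_founders(cfg)
  g <- genetic_values(pop)
  cors <- replicate(40, {
    ce <- g + rnorm(500, 0, sqrt(var(g) * (1 - 0.15) / 0.15))
    uyt <- g + rnorm(500, 0, sqrt(var(g) * (1 - 0.65) / 0.65 / 3))
    c(cor(ce, g), cor(uyt, g))
  })
  expect_gt(mean(cors[2, ]), mean(cors[1, ]))
})

test_that("selection-intensity arithmetic matches the normal model", {
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_equal(selection_intensity(0.5), 0.7979, tolerance = 1e-4)
  expect_equal(usefulness_criterion(c(-1, 0, 1) * 0 + 5, 0.3), 5)
  g <- rnorm(500)
  expect_equal(usefulness_criterion(g, 0.1),
               mean(g) + dnorm(qnorm(0.9)) / 0.1 * sd(g), tolerance = 1e-12)
  expect_equal(dnorm(qnorm(0.9)) / 0.1, 1.755, tolerance = 1e-3)
})

test_that("mean heterozygosity hits its boundary cases", {
  set.seed(7)
  cfg <- small_cfg(n_founders = 10)
  pop <- simulate_founders(cfg)
  inbred <- pop
  for (c_i in 1:2) {
    odd <- seq(1, 20, by = 2)
    inbred$haplos[[c_i]][odd + 1, ] <- inbred$haplos[[c_i]][odd, ]
  }
  expect_equal(mean_heterozygosity(inbred), 0)
  allhet <- pop
  for (c_i in 1:2) {
    odd <- seq(1, 20, by = 2)
    allhet$haplos[[c_i]][odd, ] <- 0L
    allhet$haplos[[c_i]][odd + 1, ] <- 1L
  }
  expect_equal(mean_heterozygosity(allhet), 1)
  # Hardy-Weinberg draws at p = 0.5: H about 0.5
  hw <- pop
  for (c_i in 1:2) {
    hw$haplos[[c_i]][] <- rbinom(length(hw$haplos[[c_i]]), 1, 0.5)
  }
  n_calls <- 10 * 80 * 2
  expect_lt(abs(mean_heterozygosity(hw) - 0.5), 4 * sqrt(0.25 / n_calls))
})

test_that("burn-in mating conserves allele frequencies", {
  cfg <- small_cfg(n_founders = 150, n_cycles = 0, burn_in_cycles = 6)
  set.seed(8)
  pop <- simulate_founders(cfg)
  before <- mean(unlist(lapply(pop$haplos, colMeans)))
  for (cy in 1:6) {
    n <- crosskit:::pop_size(pop)
    p1 <- sample.int(n, n %/% 2, replace = TRUE)
    p2 <- vapply(p1, function(j) sample(setdiff(seq_len(n), j), 1),
                 integer(1))
    pop <- crosskit:::mate_crosses(pop, p1, p2, 2)
  }
  after <- mean(unlist(lapply(pop$haplos, colMeans)))
  expect_lt(abs(before - after), 0.02)
})

test_that("experiments are deterministic and share the burn-in state", {
  cfg <- small_cfg()
  tr1 <- run_experiment(cfg, seed = 42)
  tr2 <- run_experiment(cfg, seed = 42)
  expect_equal(tibble::as_tibble(tr1), tibble::as_tibble(tr2))
  burn <- tr1[tr1$cycle <= 0, ]
  expect_equal(nrow(burn), 4L)  # 2 burn-in cycles x 2 arms
  expect_true(all(burn$delta_uc == 0))
  expect_true(all(burn$delta_h == 0))
  # delta columns equal the arm differences exactly
  wide <- tidyr::pivot_wider(tibble::as_tibble(tr1), id_cols = cycle,
                             names_from = arm, values_from = c(uc, mean_het,
                                                               delta_uc))
  expect_equal(wide$delta_uc_gebv, wide$uc_gpcp - wide$uc_gebv)
  # zero selection cycles -> burn-in rows only
  tr0 <- run_experiment(small_cfg(n_cycles = 0), seed = 1)
  expect_true(all(tr0$cycle <= 0))
})

test_that("selection erodes heterozygosity over cycles", {
  cfg <- small_cfg(n_cycles = 6, burn_in_cycles = 3)
  tr <- run_experiment(cfg, seed = 9)
  for (a in c("gebv", "gpcp")) {
    h <- tr$mean_het[tr$arm == a]
    expect_lt(h[length(h)], h[1])
  }
})

test_that("population export feeds the file-based pipeline end to end", {
  cfg <- small_cfg(n_founders = 40)
  set.seed(10)
  pop <- simulate_founders(cfg)
  dir <- withr::local_tempdir()
  paths <- export_population(pop, dir, h2 = 0.5)
  G <- read_vcf(paths[["vcf"]], ploidy = 2)
  expect_equal(dim(G$dosages), c(40L, 160L))
  ct <- suppressMessages(
    run_gpcp(paths[["pheno"]], paths[["vcf"]], traits = "trait",
             n_crosses = 5, verbose = FALSE))
  expect_equal(nrow(ct), 5L)
})
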