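make_fit_fixture <- function(n = 150, m = 200, seed = 7, ...) {
  spec <- fixture_spec(n_individuals = n, n_markers = m, seed = seed, ...)
  panel <- make_panel(spec)
  ph <- make_phenotypes(panel, spec)
  list(spec = spec, panel = panel, pheno = ph$pheno, truth = ph$truth)
}

test_that("design assembly codes factors, averages replicates, joins on ID", {
  fx <- make_fit_fixture(n = 12, m = 10, seed = 3)
  # no fixed factors -> X is a column of ones
  des <- build_design(fx$pheno, fx$panel$G, "trait")
  expect_equal(unname(des$X), matrix(1, 12, 1))
  expect_equal(unname(colMeans(des$Z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(colMeans(des$W)), rep(0, 10), tolerance = 1e-12)
  # one 2-level factor -> intercept + treatment contrast
  fx2 <- make_fit_fixture(n = 8, m = 6, seed = 4, fixed_factor_levels = 2)
  des2 <- build_design(fx2$pheno, fx2$panel$G, "trait", fixed = "block")
  expect_equal(ncol(des2$X), 2L)
  expect_equal(nrow(des2$X), 16L)  # one cell per genotype x block
  # replicate plots within a cell are averaged
  ph_rep <- dplyr::bind_rows(fx$pheno, fx$pheno |>
                               dplyr::mutate(trait = trait + 2))
  des_rep <- build_design(ph_rep, fx$panel$G, "trait")
  expect_equal(length(des_rep$y), 12L)
  expect_equal(sort(des_rep$y),
               sort(fx$pheno$trait + 1), tolerance = 1e-12)
  # disjoint ID sets are an error
  ph_bad <- fx$pheno |> dplyr::mutate(germplasmName = paste0("x_",
                                                             germplasmName))
  expect_error(build_design(ph_bad, fx$panel$G, "trait"), "no overlap")
})

test_that("REML log-likelihood is monotone and the fit converges", {
  for (seed in 1:3) {
    fx <- make_fit_fixture(n = 120, m = 150, seed = seed)
    fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait")
    expect_true(fit$converged)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_gte(fit$var_additive, 0)
    expect_gte(fit$var_dominance, 0)
    expect_gt(fit$var_residual, 0)
  }
})

test_that("a null dominance component is estimated near zero", {
  fx <- make_fit_fixture(n = 250, m = 300, seed = 21, var_dominance = 0)
  fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait")
  # truth: var_a = 1, var_d = 0, var_e = 1
  expect_lt(fit$var_dominance, 0.25)
})

test_that("additive-only reduction agrees with an independent REML solver", {
  fx <- make_fit_fixture(n = 120, m = 150, seed = 9, var_dominance = 0,
                         b_inbreeding = 0)
  fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait", dominance = FALSE,
                    directional = FALSE, tol = 1e-10)
  des <- build_design(fx$pheno, fx$panel$G, "trait")
  K <- tcrossprod(des$Z) / des$scale_a
  oracle <- additive_reml_oracle(des$y, des$X, K)
  expect_equal(fit$var_additive, oracle$var_additive, tolerance = 0.02)
  expect_equal(fit$var_residual, oracle$var_residual, tolerance = 0.02)
})

test_that("marker-effect BLUPs reproduce the individual-level BLUPs", {
  fx <- make_fit_fixture(n = 50, m = 200, seed = 13)
  fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait")
  des <- build_design(fx$pheno, fx$panel$G, "trait")
  expect_equal(drop(des$Z %*% fit$a), fit$u_additive, tolerance = 1e-6)
})

test_that("flipping the counted allele leaves predictions unchanged", {
  fx <- make_fit_fixture(n = 100, m = 80, seed = 17)
  G <- fx$panel$G
  fit1 <- fit_dirdom(fx$pheno, G, "trait")
  flip <- seq(1, 80, by = 3)
  D2 <- G$dosages
  D2[, flip] <- G$ploidy - D2[, flip]
  G2 <- geno_matrix(D2, G$ploidy)
  fit2 <- fit_dirdom(fx$pheno, G2, "trait")
  # GEBVs invariant
  g1 <- gebv(marker_effects(fit1), G)
  g2 <- gebv(marker_effects(fit2), G2)
  expect_equal(g1$gebv[order(g1$individual)], g2$gebv[order(g2$individual)],
               tolerance = 1e-4)
  # cross predictions invariant after re-estimation under the new coding
  ct1 <- predict_crosses(marker_effects(fit1), G, n_crosses = 10)
  ct2 <- predict_crosses(marker_effects(fit2), G2, n_crosses = 10)
  expect_equal(ct1$parent1, ct2$parent1)
  expect_equal(ct1$merit, ct2$merit, tolerance = 1e-4)
})

test_that("a fully inbred panel drops b and the dominance kernel", {
  D <- matrix(sample(c(0, 2), 20 * 15, replace = TRUE), 20, 15)
  D[, 1] <- c(rep(0, 10), rep(2, 10))  # keep the panel polymorphic
  G <- geno_matrix(D, 2)
  pheno <- tibble::tibble(germplasmName = individual_ids(G),
                          trait = rnorm(20) + D[, 1])
  expect_warning(
    expect_warning(fit <- fit_dirdom(pheno, G, "trait"), "constant"),
    "dominance")
  expect_true(is.na(fit$b_inbreeding))
  expect_equal(fit$var_dominance, 0)
})

test_that("directional dominance folds into marker effects as -b/m", {
  fx <- make_fit_fixture(n = 100, m = 50, seed = 23)
  fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait", dominance = FALSE,
                    directional = TRUE)
  eff <- marker_effects(fit)
  # with no dominance deviations the dominance vector is the constant -b/m
  expect_equal(eff$dominance, rep(-fit$b_inbreeding / 50, 50))
  expect_equal(eff$dominance_dev, rep(0, 50))
  eff_raw <- marker_effects(fit, fold_directional = FALSE)
  expect_equal(eff_raw$dominance, rep(0, 50))
})

test_that("GEBVs are centered dot products of dosages and effects", {
  eff <- manual_effects(c("m1", "m2"), additive = c(0.5, 0.2),
                        dominance = c(0, 0), centers_z = c(1, 1))
  G <- geno_matrix(matrix(c(2, 1, 0, 1), 2, 2,
                          dimnames = list(c("hi", "mid"), c("m1", "m2"))), 2)
  out <- gebv(eff, G)
  # hi: centered (1, -1) . (0.5, 0.2) = 0.3; mid: (0, 0) -> 0
  expect_equal(out$gebv[out$individual == "hi"], 0.3)
  expect_equal(out$gebv[out$individual == "mid"], 0)
  # zero effects -> all zero
  eff0 <- manual_effects(c("m1", "m2"), c(0, 0), c(0, 0), centers_z = c(1, 1))
  expect_true(all(gebv(eff0, G)$gebv == 0))
  # marker mismatch errors informatively
  effx <- manual_effects(c("m1", "mX"), c(1, 1), c(0, 0))
  expect_error(gebv(effx, G), "mX")
})

test_that("tidy and glance summarise the fit", {
  fx <- make_fit_fixture(n = 60, m = 40, seed = 29)
  fit <- fit_dirdom(fx$pheno, fx$panel$G, "trait")
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "b_inbreeding", "var_additive") %in%
                    td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$h2_additive >= 0 && gl$h2_additive <= 1)
})
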