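#' Simulate a diploid founder population
#'
#' Per-site allele frequencies are drawn from the U-shaped Beta(0.5, 0.5)
#' spectrum and founder haplotypes are sampled independently per site;
#' linkage structure is built up afterwards by the random-mating burn-in
#' generations (see [run_experiment()]). QTL are sampled without
#' replacement from the segregating sites, disjoint from the SNP marker
#' panel. Additive QTL effects start as N(0, 1) draws and are rescaled so
#' the founder additive-value variance is exactly 1 with mean genotypic
#' value 0; dominance effects are `d_i = |a_i| * delta_i` with
#' `delta_i ~ N(mean_dd, var_dd)`, so `mean_dd = 0, var_dd = 0` gives a
#' purely additive trait.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_population`: per-chromosome haplotype
#'   matrices (2n rows of 0/1 per chromosome), site genetic positions, the
#'   QTL map with effects, marker-panel site indices, and the genotypic
#'   value offset.
#' @export
simulate_founders <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_founders
  nc <- cfg$n_chromosomes
  L <- cfg$sites_per_chr

  haplos <- vector("list", nc)
  pos <- vector("list", nc)
  for (c_i in seq_len(nc)) {
    p <- stats::rbeta(L, 0.5, 0.5)
    p <- pmin(pmax(p, 0.02), 0.98)  # keep sites segregating at small n
    H <- matrix(stats::rbinom(2L * n * L, 1L, rep(p, each = 2L * n)),
                nrow = 2L * n, ncol = L)
    haplos[[c_i]] <- H
    pos[[c_i]] <- sort(stats::runif(L))
  }

  # distribute QTL over chromosomes, disjoint from the marker panel
  qtl_per_chr <- diff(round(seq(0, cfg$n_qtl, length.out = nc + 1)))
  markers <- vector("list", nc)
  qtl_sites <- vector("list", nc)
  for (c_i in seq_len(nc)) {
    sites <- sample.int(L, cfg$markers_per_chr + qtl_per_chr[c_i])
    markers[[c_i]] <- sort(sites[seq_len(cfg$markers_per_chr)])
    qtl_sites[[c_i]] <- sort(sites[-seq_len(cfg$markers_per_chr)])
  }

  n_qtl <- sum(lengths(qtl_sites))
  a <- stats::rnorm(n_qtl)
  delta <- stats::rnorm(n_qtl, cfg$mean_dd, sqrt(cfg$var_dd))

  pop <- structure(
    list(haplos = haplos, pos = pos, markers = markers,
         qtl = tibble::tibble(
           chrom = rep(seq_len(nc), lengths(qtl_sites)),
           site = unlist(qtl_sites),
           a = a, d = abs(a) * delta
         ),
         offset = 0, map_length = cfg$map_length),
    class = "sim_population"
  )

  # rescale so founder additive variance = 1, then center total value at 0
  D <- qtl_dosages(pop)
  g_add <- drop(D %*% pop$qtl$a)
  s <- stats::sd(g_add)
  if (s < 1e-12) stop("founder additive variance is zero; increase n or QTL",
                      call. = FALSE)
  pop$qtl$a <- pop$qtl$a / s
  pop$qtl$d <- pop$qtl$d / s
  pop$offset <- 0
  pop$offset <- -mean(genetic_values(pop))
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d individuals, %d chromosomes, %d QTL, %d panel SNPs\n",
    pop_size(x), length(x$haplos), nrow(x$qtl), sum(lengths(x$markers))))
  invisible(x)
}

pop_size <- function(pop) nrow(pop$haplos[[1]]) %/% 2L

# n x nQTL dosage matrix at the QTL sites
qtl_dosages <- function(pop) {
  do.call(cbind, lapply(seq_along(pop$haplos), function(c_i) {
    sites <- pop$qtl$site[pop$qtl$chrom == c_i]
    if (length(sites) == 0) return(NULL)
    H <- pop$haplos[[c_i]][, sites, drop = FALSE]
    odd <- seq(1, nrow(H), by = 2)
    H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
  }))
}

#' True genotypic values of a simulated population
#'
#' `g_j = offset + sum_QTL a_i * dosage_ji + d_i * [dosage_ji == 1]` for
#' the diploid biallelic model: homozygotes contribute `0` or `2 a_i`,
#' heterozygotes `a_i + d_i`.
#'
#' @param pop A `sim_population`.
#' @return Numeric vector of genotypic values.
#' @export
genetic_values <- function(pop) {
  D <- qtl_dosages(pop)
  drop(D %*% pop$qtl$a + (D == 1) %*% pop$qtl$d) + pop$offset
}

#' Marker-panel genotypes of a simulated population
#'
#' @param pop A `sim_population`.
#' @param prefix Individual-ID prefix.
#' @return A [geno_matrix()] (diploid) over the SNP panel.
#' @export
marker_genotypes <- function(pop, prefix = "ind") {
  D <- do.call(cbind, lapply(seq_along(pop$haplos), function(c_i) {
    H <- pop$haplos[[c_i]][, pop$markers[[c_i]], drop = FALSE]
    odd <- seq(1, nrow(H), by = 2)
    M <- H[odd, , drop = FALSE] + H[odd + 1, , drop = FALSE]
    colnames(M) <- paste0("chr", c_i, "_s", pop$markers[[c_i]])
    M
  }))
  rownames(D) <- sprintf("%s%04d", prefix, seq_len(nrow(D)))
  geno_matrix(D, ploidy = 2)
}

# One recombinant gamete per chromosome for parent j (1-based individual
# index). Crossover count ~ Poisson(map_length), positions uniform, no
# interference; with zero crossovers a random parental haplotype is
# transmitted whole.
meiosis <- function(pop, j) {
  lapply(seq_along(pop$haplos), function(c_i) {
    H <- pop$haplos[[c_i]]
    h1 <- H[2L * j - 1L, ]
    h2 <- H[2L * j, ]
    k <- stats::rpois(1, pop$map_length)
    start <- stats::rbinom(1, 1, 0.5)
    if (k == 0) {
      if (start == 0) h1 else h2
    } else {
      xo <- sort(stats::runif(k))
      use2 <- (start + findInterval(pop$pos[[c_i]], xo)) %% 2L == 1L
      out <- h1
      out[use2] <- h2[use2]
      out
    }
  })
}

# Build the next generation from a table of crosses (parent index pairs),
# each producing n_progeny offspring. QTL map, marker panel and offset are
# inherited from the parent population.
mate_crosses <- function(pop, parent1, parent2, n_progeny) {
  stopifnot(length(parent1) == length(parent2))
  n_new <- length(parent1) * n_progeny
  nc <- length(pop$haplos)
  new_h <- lapply(seq_len(nc), function(c_i) {
    matrix(0L, nrow = 2L * n_new, ncol = ncol(pop$haplos[[c_i]]))
  })
  row <- 0L
  cross_of <- integer(n_new)
  for (ci in seq_along(parent1)) {
    for (pr in seq_len(n_progeny)) {
      g1 <- meiosis(pop, parent1[ci])
      g2 <- meiosis(pop, parent2[ci])
      row <- row + 1L
      cross_of[row] <- ci
      for (c_i in seq_len(nc)) {
        new_h[[c_i]][2L * row - 1L, ] <- g1[[c_i]]
        new_h[[c_i]][2L * row, ] <- g2[[c_i]]
      }
    }
  }
  out <- pop
  out$haplos <- new_h
  attr(out, "cross_of") <- cross_of
  out
}

#' Simulate phenotype means
#'
#' Adds plot-level Gaussian noise to true genotypic values at a given
#' plot heritability: the plot error variance is
#' `var(g) * (1 - h2) / h2`, and the phenotype mean over `n_reps`
#' independent plots has error variance reduced by `1 / n_reps`.
#'
#' @param pop A `sim_population`.
#' @param h2 Plot-level heritability in (0, 1).
#' @param n_reps Number of replicate plots averaged.
#' @return Numeric vector of phenotype means.
#' @export
sim_phenotypes <- function(pop, h2, n_reps = 1) {
  stopifnot(h2 > 0, h2 < 1, n_reps >= 1)
  g <- genetic_values(pop)
  vg <- stats::var(g)
  if (vg < 1e-12) stop("zero genetic variance: heritability undefined",
                       call. = FALSE)
  se2 <- vg * (1 - h2) / h2
  g + stats::rnorm(length(g), 0, sqrt(se2 / n_reps))
}

#' Panel mean heterozygosity
#'
#' Mean over individuals and marker-panel loci of the heterozygote
#' indicator.
#'
#' @param pop A `sim_population`.
#' @return Scalar in `[0, 1]`.
#' @export
mean_heterozygosity <- function(pop) {
  tot <- 0
  cnt <- 0
  for (c_i in seq_along(pop$haplos)) {
    H <- pop$haplos[[c_i]][, pop$markers[[c_i]], drop = FALSE]
    odd <- seq(1, nrow(H), by = 2)
    het <- H[odd, , drop = FALSE] != H[odd + 1, , drop = FALSE]
    tot <- tot + sum(het)
    cnt <- cnt + length(het)
  }
  tot / cnt
}

#' Standardized selection intensity
#'
#' The mean deviation (in SD units) of the selected upper fraction of a
#' standard normal distribution: `i = dnorm(qnorm(1 - p)) / p`.
#'
#' @param selected_fraction Fraction selected, in (0, 1).
#' @return Selection intensity `i`.
#' @export
selection_intensity <- function(selected_fraction) {
  stopifnot(all(selected_fraction > 0), all(selected_fraction < 1))
  stats::dnorm(stats::qnorm(1 - selected_fraction)) / selected_fraction
}

#' Usefulness criterion of a progeny set
#'
#' `UC = mean(g) + i * sd(g)`: the expected mean of the selected upper
#' fraction of progeny, combining the progeny mean with the standardized
#' selection intensity times the genetic standard deviation. With zero
#' variance the UC reduces to the mean.
#'
#' @param g Progeny genotypic values (length >= 2).
#' @param selected_fraction Within-progeny selected fraction, in (0, 1).
#' @return Scalar UC.
#' @export
usefulness_criterion <- function(g, selected_fraction) {
  stopifnot(length(g) >= 2)
  s <- stats::sd(g)
  if (!is.finite(s)) s <- 0
  mean(g) + selection_intensity(selected_fraction) * s
}

#' Percentage of candidates selected
#'
#' Convenience helper reporting `100 * n_selected / n_total`, the selected
#' percentage breeders quote as "selection intensity" for a campaign (e.g.
#' 158 clones kept out of 2302 progenies is 6.86%).
#'
#' @param n_selected,n_total Counts.
#' @return Percentage (0-100 scale).
#' @export
selected_percentage <- function(n_selected, n_total) {
  stopifnot(n_selected >= 0, n_total > 0, n_selected <= n_total)
  100 * n_selected / n_total
}
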