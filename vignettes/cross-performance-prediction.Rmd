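---
title: "Predicting cross performance with additive and directional dominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross performance with additive and directional dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crosskit)
```

## The problem

Classical genomic selection ranks *individuals* by their genomic estimated
breeding value (GEBV), the sum of estimated additive marker effects. For
clonally propagated outcrossers — yam, cassava, potato — much of the economic
merit sits in non-additive gene action: inbreeding depression and heterosis
are pervasive, and what a breeder actually chooses each season is a set of
*crosses*, not a set of individuals. crosskit implements genomic prediction
of cross performance: it predicts the mean genotypic value of the F1 family
of every candidate parent pair from additive *and* dominance marker effects,
and ranks pairs rather than parents.

## The model

Marker effects come from the directional-dominance mixed model

$$y = X\beta + f b + Z a + W d^* + e,$$

where $y$ holds phenotype means (replicate plots averaged per genotype and
fixed-factor cell), $X\beta$ are ordinary fixed effects, and two genomic
codings enter per marker: the dosage matrix $Z$ (0..ploidy counts of the
tracked allele) scaling additive effects $a$, and the heterozygosity matrix
$W$ scaling dominance deviations $d^*$. For a call with dosage $k$ at ploidy
$\rho$, the $W$ entry is $k(\rho-k)/\binom{\rho}{2}$ — the fraction of
within-individual allele pairs that are heterozygous — which reduces to the
usual 0/1 heterozygote indicator for diploids.

The *directional* part of dominance is carried by $f b$: $f_j$ is the
genomic inbreeding coefficient of individual $j$ and $b$ the regression of
performance on inbreeding (negative $b$ = inbreeding depression). The
literature this model descends from leaves the computation of $f$ open; we
define it as mean homozygosity, $f_j = 1 - \bar W_{j\cdot}$, which needs no
reference panel and makes $fb$ a pure function of the heterozygosity coding
(so the whole dominance structure is testable from the genotype matrix
alone).

Random effects are iid within component: $a \sim N(0, I\sigma^2_a /
s_a)$, $d^* \sim N(0, I\sigma^2_{d^*} / s_d)$, $e \sim N(0, I\sigma^2_e)$.
The scales are VanRaden-style sums, $s_a = \tfrac{\rho}{2}\sum_i 2\bar
p_i(1-\bar p_i)$ and $s_d = \sum_i (2\bar p_i(1-\bar p_i))^2$, so the
variance components land on the phenotypic scale. This marker-effects
(ridge) parameterisation is exactly equivalent to GBLUP with kernels $Z_c
Z_c'/s_a$ and $W_c W_c'/s_d$; we fit the kernel form and back-solve
$\hat a = (\sigma^2_a/s_a) Z_c' P y$, which the test suite checks against
individual-level BLUPs and against an independent eigen-decomposition REML
solver for the additive-only reduction.

### REML algorithm

The paper-trail packages in this area delegate variance-component estimation
to general mixed-model software; crosskit ships its own solver so the whole
path is inspectable. It is EM-REML with average-information (AI)
acceleration: AI steps are proposed from iteration 3 onward and accepted
only if they keep all components at or above the variance floor *and* do not
decrease the restricted likelihood; otherwise the monotone EM update is
used, with step-halving along the EM direction (a positive rescaling of the
score) when a boundary clamp would otherwise break monotonicity. If no
ascent step exists the solver is at a constrained optimum and stops.
Defaults: relative log-likelihood tolerance `1e-6`, at most 200 iterations,
component floors of $10^{-8}\,\mathrm{var}(y)$ (kernels) and
$10^{-6}\,\mathrm{var}(y)$ (residual — the centered kernels are singular
along the intercept direction, so the residual floor is what keeps $V$
well conditioned). The log-likelihood trace is stored on the fit and is
non-decreasing by construction.

### From fit to cross ranking

The predicted F1 mean for parents with within-parent allele frequencies
$p_i$ and $p'_i$ (dosage divided by ploidy) is

$$M_{F1} = \sum_i \left[a_i(p_i - q_i - y_i) + d_i(2p_iq_i + y_i(p_i - q_i))\right],
\qquad q_i = 1-p_i,\; y_i = p_i - p'_i.$$

For diploids this is algebraically identical to enumerating the four gamete
combinations per locus and averaging — the acceptance suite verifies the
identity to $10^{-10}$ over a thousand random cases — and with $d \equiv 0$
it collapses to the midparent additive score. It is applied unchanged to
polyploid parents; no claim of equivalence with polysomic progeny
enumeration is made beyond diploids.

The per-marker dominance effect feeding this equation is $d_i = d^*_i -
b/m$: with $f$ defined as mean homozygosity, one unit of heterozygosity at
one of $m$ markers lowers $f$ by $1/m$, so the phenotypic contribution of
the inbreeding slope per unit heterozygosity is $-b/m$. Inbreeding
depression ($b<0$) therefore adds uniform positive dominance, which is the
intended behaviour; `marker_effects(fit, fold_directional = FALSE)` turns
the fold-in off.

Design choices in the ranking itself: each unordered pair appears once with
the lexicographically smaller ID first; ties in merit break on (parent1,
parent2) so output files are reproducible byte for byte; self-crosses are
excluded by default (clonal outcrossers are the target users); merits are
reported on the centered model scale, with no intercept added, so they
compare within a run, not across runs. Multi-trait indices fit each trait
separately and combine *merits* linearly with the user's weights — merit is
linear in $(a, d)$, so weighting effects or weighting merits is the same
thing, and a multivariate REML is not needed. Sex codes (1 = male, 2 =
female, 3/4 = monoecious) only ever *remove* pairs: two strict males or two
strict females cannot be crossed; monoecious or unknown-sex parents pass.

All $n(n-1)/2$ pairs are scored — complexity $O(n^2 m)$ — in blocks of
parents so peak memory stays at $O(\text{block} \times n)$; panels in the
tens of thousands of combinations are routine.

## The simulator

`run_experiment()` reproduces a forward-in-time comparison of GEBV-based
and cross-performance-based recurrent selection in a clonal breeding
programme. Default configuration (see `sim_config()`): 250 founders, 18
chromosomes of 5400 segregating sites, a 1000-SNP-per-chromosome panel
disjoint from 56 QTL, 10 random-mating burn-in generations, then 40 cycles
in which each cohort passes a four-stage yield-trial pipeline — CE, PYT,
AYT, UYT with plot heritabilities 0.15/0.25/0.45/0.65, replications
1/2/3/3 and advancement fractions 0.90/0.80/0.70/0.60 (floor rounding) —
before the UYT survivors become the candidate parents.

What the generator emulates, and how:

* **Founders.** Per-site allele frequencies from the U-shaped
  Beta(0.5, 0.5) spectrum (clamped to [0.02, 0.98] so sites segregate at
  small $n$), haplotypes drawn independently per site. Linkage
  disequilibrium is *not* simulated coalescently; it is built by the
  burn-in generations of recombination and mating, which is what the
  experimental design relies on anyway. Consequence: early-burn-in LD is
  weaker than in a coalescent founder population, and tests run after
  burn-in only.
* **Trait architecture.** Additive QTL effects are N(0, 1) rescaled so the
  founder additive variance is exactly 1 at mean genotypic value 0;
  dominance effects are $d_i = |a_i|\,\delta_i$ with $\delta_i \sim
  N(\texttt{mean\_dd}, \texttt{var\_dd})$. `mean_dd = 0, var_dd = 0` is a
  purely additive trait; `var_dd` defaults to 0.2, the conventional value
  in stochastic-simulation practice, since only the mean dominance degree
  is a design factor.
* **Meiosis.** Crossover count per chromosome is Poisson with mean equal to
  the 1-Morgan map length, positions uniform, no interference.
* **Selection arms.** Each cycle both arms retrain on every phenotyped
  entry of the current cohort (records weighted by replication). The GEBV
  arm fits the additive-only model and chain-mates the top $2
  \cdot \texttt{n\_crosses}/\texttt{parent\_usage}$ candidates round-robin
  (default `parent_usage = 4`, i.e. each elite parent enters about four
  crosses — the mating design behind "top parents" is not dictated by the
  experimental design, so it is a configurable knob). The GPCP arm fits the
  full directional-dominance model and mates the top `n_crosses` pairs by
  predicted F1 mean. Both arms produce identical progeny counts.
* **Tracking.** Per cycle and arm: the usefulness criterion $UC =
  \bar g + i\,\mathrm{sd}(g)$ of the new progeny, with $i =
  \phi(z_p)/p$ the standardized selection intensity at the within-progeny
  selected fraction $p$ (default: the product of the stage advancement
  fractions, ≈ 0.30), and panel mean heterozygosity $H$; plus $\Delta UC =
  UC_{GPCP} - UC_{GEBV}$ and $\Delta H = H_{GPCP} - H_{GEBV}$. The UC is
  computed on the selected crosses' progeny (the new cohort), one of two
  defensible readings of the design.
* **Degenerate states.** A population that fixes every QTL has undefined
  heritability; the pipeline then produces noise-free, informationless
  records, and if model training collapses entirely (trait or all markers
  fixed) the cycle falls back to random mating among candidates rather
  than aborting a long run.

Both arms restart from a bit-identical post-burn-in state, so during
burn-in $\Delta UC \equiv 0$ by construction — the neutral-baseline check is
that the shared burn-in drifts nowhere, and the experimental contrast is
attributable entirely to the selection rule.

What the simulator does **not** model: coalescent demographic history,
polysomic (tetraploid/hexaploid) meiosis, epistasis, genotype-by-environment
interaction, cost structure, or selection on cross *variance* (the ranking
criterion is the F1 mean only). Passing trend tests at reduced scale shows
the mechanism — dominance-aware pair selection preserving heterozygosity —
not calibrated magnitudes for any real crop.

### Problem sizes used in the shipped checks

The test and acceptance runs use a reduced scale chosen to exercise every
code path with comfortable margins: 100 founders, 2 chromosomes of 500
sites, a 500-SNP panel, 40 QTL, 25 crosses of 4 progeny, 10 burn-in and 10
selection cycles, 5 seeds; REML parameter recovery uses n = 500
individuals, m = 1000 markers and 20 seeds against generating components
$(\sigma^2_a, \sigma^2_{d^*}, \sigma^2_e, b) = (1, 0.5, 1, -0.5)$. The
full-scale design is a multi-hour single-CPU job and ships as
`inst/extdata/config/paper_scale.yaml` plus `scripts/long_run.R`. One
caveat made explicit: under binomial genotype sampling the inbreeding
covariate $f$ varies only a few hundredths across individuals, so
$\hat b$ has a standard error in the units range at these sizes — it is
unbiased (checked within Monte-Carlo error) but not tightly estimable,
while its $-b/m$ share of the cross ranking stays negligible relative to
$d^*$. With sparser, more structured panels (real breeding data) $f$
spreads much wider and $b$ identifies better.

## Numerical and interface conventions

* Counted allele: ALT in VCF, the second listed allele in HapMap. All
  downstream quantities are invariant to flips of the counted allele once
  effects are re-estimated under the same coding (property-tested).
* Missing genotype handling: heterozygosity and inbreeding use observed
  calls only; dosages are then mean-imputed per marker. Markers below the
  MAF threshold or above the missingness threshold are dropped before
  fitting (`min_maf = 0.01`, `max_missing = 0.6` in `run_gpcp()`).
* HapMap cannot express partial polyploid dosage, so heterozygous HapMap
  calls at ploidy > 2 are rejected rather than guessed.
* Genotype IDs are always treated as random ("germplasmName" by default);
  fixed factors are treatment-coded with aliased columns dropped and named
  in a warning. A panel with constant $f$ (fully inbred) drops $b$; a
  constant $W$ drops the dominance kernel — both with warnings, neither
  fatally.
* Every entry point that touches an RNG takes an explicit seed, and the
  command-line wrappers write a JSON manifest (resolved config, seed, input
  MD5 checksums, package version) next to each output.

## Known limitations

The dominance coding is the classical heterozygosity coding, not the
natural-and-orthogonal (NOIA) parameterisation, so additive and dominance
variance partitions are correlated in inbred material. The multi-trait
index assumes effects estimated on a shared marker panel. The usefulness
criterion uses the normal-theory selection intensity, which overstates
gains for very small families. And the GEBV arm's mating design (chain
mating among top candidates) is one reasonable reading of truncation
selection on individuals; `parent_usage` exposes the knob because the
comparison's magnitude — not its direction — depends on it.
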