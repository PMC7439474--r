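---
title: "Methods: in vitro SCFA screening and multinomial logistic-normal regression"
author: "scfaferm maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vitro SCFA screening and multinomial logistic-normal regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfaferm)
```

# The experimental design the package models

An in vitro fermentation screen incubates a buffered fecal slurry from
each donor with each of several prebiotic carbohydrates, plus one
unsupplemented control vessel per donor, in duplicate, and measures the
C2–C5 short-chain fatty acids (SCFAs) produced after 24 h of anaerobic
incubation.  Because donors differ in viable biomass and in how much
fermentable substrate their stool already carries, the acidogenic
response is expressed as a *fold change*: the treatment vessel's total
SCFA divided by the matched control vessel's total.  The analysis then
asks two questions: do donor, prebiotic and their interaction shape the
fold change (two-way ANOVA), and which genera in the starting community
predict it (compositional regression)?

# SCFA quantification

Detector responses are converted to concentrations with a per-acid,
unweighted linear OLS calibration against an external standard series
(default 0.1, 0.2, 0.5, 1, 2, 4, 8, 16 mM — `scfaStandardSeries()`),
which is the standard GC-FID practice for this assay.  Back-calculated
concentrations below zero (responses below the fitted intercept) are
physically impossible and are floored to 0 mM with a warning rather than
propagated as negative values.

Fold changes pair each treatment replicate with the control replicate of
the same index; when the replicate structure is ragged, the mean control
total of that donor is used as the denominator.  The pairing rule is a
package choice — with duplicate vessels either convention is defensible,
and the two agree exactly when replicate noise is absent.  Whether fold
changes should be formed per replicate or on replicate means before
division is genuinely open; the package computes them per replicate,
which preserves the replicate dimension for the ANOVA, and
`buildCovariates()` averages replicates only when building the regression
design matrix.

A small arithmetic helper, `fiberDoseEquivalent()`, converts the in
vitro prebiotic:slurry mixing ratio into an equivalent daily fiber
intake: a 0.5% (w/v) prebiotic in a 5% (w/v) slurry corresponds, at 200
g/day of stool, to 20 g/day of dietary fiber.

# Univariate statistics

* **Two-way ANOVA** (`twoWayAnova()`): classical fixed-effects
  decomposition on a balanced design with replicate-level rows (technical
  replicates enter as separate observations).  Unbalanced designs are
  rejected outright: in a balanced design the decomposition is unique,
  while an unbalanced one would silently commit to one of the type-I/II/III
  sums-of-squares conventions, a consequential and easily-missed choice.
  A constant response is reported as all-zero sums of squares with `F =
  NaN` and `p = 1` rather than an error.
* **Spearman correlation** (`spearmanCorrelation()`): Pearson correlation
  of mid-ranks; the two-sided p-value uses the t approximation
  `t = rho * sqrt((n-2)/(1-rho^2))`, the common convention at n of
  roughly 17–40.  An exact permutation p-value is used for n ≤ 10 when
  the data are tie-free.
* **Shannon diversity** (`shannonDiversity()`): natural-log entropy
  (nats).  The base is a reporting convention only; nats are the default
  of the ecology tooling this package delegates to.
* **Differential abundance** (`differentialAbundance()`): per-taxon
  two-sided Wilcoxon rank-sum tests on per-sample relative abundances
  with the tie-corrected normal approximation, BH step-up adjustment
  across taxa, calls at adjusted p < 0.05.  A taxon with identical
  relative abundance everywhere carries no evidence and is assigned
  p = 1 rather than an error.

# The compositional regression

Counts are first amalgamated to the genus level (`amalgamateToGenus()`;
sequence variants with unresolved genus are pooled under
`unclassified_<lowest resolved rank>` so that sample sums are conserved)
and prevalence-filtered (`filterPrevalence()`): a taxon is retained when
it has at least `minCount` (3) counts in each of at least `minSamples`
(3) samples.  The phrase "at least three counts in at least three
samples" admits a second reading (total ≥ 3 spread over ≥ 3 samples);
the package implements the per-sample reading, which is the stricter of
the two and the one that matches how presence thresholds are usually
applied to count tables.  The retained fraction of counts is recorded on
the result.

The model for the retained D-genus table is

$$Y_j \sim \mathrm{Multinomial}(\pi_j),\quad
\pi_j = \mathrm{alrInv}(\eta_j),\quad
\eta_j \sim N(\Lambda x_j, \Sigma),$$
$$\Lambda \sim \mathrm{MN}(\Theta, \Sigma, \Gamma),\quad
\Sigma \sim \mathrm{IW}(\Xi, \upsilon),$$

on additive log-ratio (ALR) coordinates with the **last taxon (after
label sorting) as reference**.  The reference is an internal bookkeeping
choice: all reported effects are transformed to centred log-ratio (CLR)
coordinates, which are reference-free, and a test asserts that CLR
summaries are invariant to permuting which taxon sits in the reference
slot (up to Monte-Carlo error).

## Priors and their meaning

`defaultPriors(D, Q)` builds:

* `Theta = 0` ((D−1) × Q): no prior association between any covariate
  and any taxon.  (The prior mean is naturally stated per taxon, i.e.
  D × Q; on ALR coordinates it is realised at (D−1) × Q — for a zero
  matrix the distinction is purely notational.)
* `Gamma` (Q × Q): intercept variance 500 — the mean composition across
  donors is essentially unconstrained — slope variance 2 and slope–slope
  covariance 0.6, i.e. a prior correlation of 0.3 between the effects of
  any two prebiotics, reflecting that substrates fermented by overlapping
  guilds should have correlated effects.
* `upsilon = D + 3` and `Xi` with diagonal `upsilon − D` = 3 and
  off-diagonals 1.5.  Under this choice `E[Sigma] = Xi / 3` has every
  off-diagonal equal to half its diagonal, which is exactly the ALR image
  of taxa that are uncorrelated on the absolute-abundance scale — a weak
  "no real correlation structure" statement.

`priorPredictive()` simulates count tables from these priors so the user
can check that they generate plausible data before fitting.

## Covariates

The design matrix is `x_j = (1, FC_inulin, FC_FOS, FC_GOS, FC_XOS,
FC_dextrin)'` by default (Q = 6): raw fold changes, uncentred and
unlogged, because the interpretive contract — a CLR effect of 1 equals a
unit fold change associated with a unit CLR change — presumes the raw
scale.  Any subset of prebiotics can be requested, e.g. the
four-prebiotic configuration (Q = 5) used in some published analyses of
this assay family; the default includes all five tested substrates since
each contributes information.

## Inference

The fitting strategy in `pibble()` is deliberate:

1. **Collapse.**  `Lambda` and `Sigma` are conjugate to the latent
   Gaussian layer and are integrated out analytically, leaving `eta`
   with a matrix-T prior: location `Theta X`, row scale `Xi`, column
   scale `I_N + X' Gamma X`, degrees of freedom `upsilon`.  The
   collapsed posterior is the multinomial log-likelihood plus the
   matrix-T log-kernel
   `−((upsilon+N)/2) log det(Xi + E B E')`, `E = eta − Theta X`,
   `B = (I_N + X' Gamma X)^{-1}`.
2. **Optimise.**  `eta` is initialised at the ALR of the
   0.5-pseudocounted proportions (cheap and in the right basin; the
   pseudocount never enters the likelihood), warm-started with L-BFGS,
   then polished by damped Newton steps using the exact dense Hessian
   until the gradient sup-norm is ≤ 1e-6 (configurable; maximum 10,000
   iterations).  Step halving guarantees monotone ascent, and a test
   asserts the optimum dominates the initialisation.  The dense Hessian
   is (D−1)N × (D−1)N; at the desk scales this package targets (D ≤
   ~150, N ≤ ~60) that is at most a few thousand rows and Cholesky
   factorisation is cheap, so no structure-exploiting factorisation is
   attempted.
3. **Laplace.**  Posterior draws of `eta` are Gaussian draws at the
   mode with covariance `(−H)^{-1}`.
4. **Uncollapse.**  Each `eta` draw yields exact conjugate draws
   `Sigma ~ IW(Xi + E B E', upsilon + N)` and
   `Lambda | Sigma ~ MN(ThetaN, Sigma, GammaN)`.

Non-convergence is reported with the final gradient norm in the fit's
diagnostics and a warning — never silently accepted.  An uncollapsed
Metropolis-within-Gibbs sampler of the identical model lives in the test
suite (not as a user path) as an independent oracle: on a small problem
(D = 3, Q = 1, N = 15, depth 5000) the Laplace posterior means of every
`Lambda` entry agree with the long-run chain within 3 combined
Monte-Carlo standard errors, and the posterior SDs within 10%.

`summarizePosterior()` maps each `Lambda` draw to CLR coordinates via
the linear contrast (zero row inserted at the reference, column means
subtracted), then reports equal-tailed quantile intervals at 50/80/95/99%.
Equal-tailed intervals (rather than HPD) are used because they are the
convention of the model family's reporting; they are also
transformation-monotone and cheap to compute from draws.  The credible
flag marks 95% intervals excluding zero.

# The synthetic-data generator

`makeStudyLikeDataset()` fixes the emulated study conditions:

* 17 donors × 5 prebiotics (inulin, FOS, GOS, XOS, dextrin) × duplicate
  vessels plus one control per donor × replicate; 97 genera; one stool
  sample (count column) per donor.
* Per-prebiotic mean fold changes are anchored at 2.35 (inulin) and 3.55
  (GOS) — the range characteristic of this assay class — with the other
  substrates spaced inside it.
* Replicate noise is **multiplicative lognormal** (mean-preserving) with
  CV 0.1.  Fold changes are strictly positive ratios, so a ratio-scale
  noise model is the natural choice; the replicate-level variance of the
  real assay is not published, making the CV a free parameter of the
  emulation, not a calibrated quantity.
* Donor-to-donor variation enters twice: a baseline acidogenic capacity
  (which cancels in the fold change, affecting only absolute mM) and a
  ratio-scale donor response times donor × prebiotic idiosyncrasy (both
  lognormal, mean-preserving), which the ANOVA sees as donor and
  interaction effects.
* Ground-truth CLR effects: intercept column drawn from a centred
  N(0, 1.5²) (a realistic spread of mean log-abundances); 15 injected
  (genus, prebiotic) slope effects of magnitude 1 (11 positive, 4
  negative), columns re-centred to satisfy the CLR zero-sum constraint.
  Magnitude 1 is the interpretable unit of the model (one fold change ↔
  one CLR unit).  The injected set is returned as a logical mask so
  screening can be evaluated against truth.
* ALR noise covariance: diagonal 1, off-diagonal 0.5 — the same
  "uncorrelated absolute abundances" structure the prior encodes.
  Sequencing depth ~20,000 per sample (uniformly ±25%).

What the generator does **not** emulate: read-level artefacts (quality,
chimeras), taxonomic misassignment, zero-inflation beyond multinomial
sampling, donor-level covariate confounding, or compositional outliers.
Passing tests therefore demonstrate that the machinery is correct under
the model's own assumptions, not that the model is adequate for any
particular real dataset.

# Numerical choices and degenerate inputs

* ALR requires strictly positive compositions; zeros are an error, not
  silently imputed.  The 0.5 pseudocount appears only in optimizer
  initialisation.
* `alrInv()` and the internal softmax subtract the column maximum before
  exponentiation, so large coordinates cannot overflow.
* Cholesky factorisations back every determinant/inverse; the Laplace
  Hessian gets a tiny ridge (1e-8 of the diagonal scale) only if its
  factorisation fails outright.
* Ties in rank statistics use mid-ranks; `p = 1` conventions for
  no-evidence degenerate inputs are described above.
* All generators and samplers take explicit seeds (`withr::with_seed`),
  never mutating the caller's RNG state; identical seeds give
  byte-identical outputs.

# Problem sizes used by the shipped checks

The package's own validation suite runs at deliberately modest sizes
chosen to exercise the claims convincingly on a single CPU: the
credible-interval calibration study uses 50 datasets at D = 10, Q = 3,
N = 40, depth 5000 and 500 draws per fit (1350 pooled intervals); there
the generating and fitting priors share the default structure with the
intercept variance set to 2, since datasets drawn from a 500-variance
intercept prior are astronomically concentrated compositions that no
real assay produces (with matched priors the nominal 95% coverage is the
exact Bayesian benchmark the check verifies).  The MCMC cross-check uses
40,000 Gibbs sweeps; the ANOVA null calibration 1000 simulated balanced
5 × 5 × 2 designs; the study-emulation screen runs at the full 97 × 17
scale with 1000–2000 draws.

# Known limitations

* The Laplace approximation is exact only asymptotically; at very low
  sequencing depth (hundreds of counts per sample) posterior means
  acquire visible small bias relative to MCMC, which is why the shipped
  cross-check runs at a realistic depth.
* Desk-scale dense-Hessian inference: memory grows as ((D−1)N)², so
  hundreds of samples × hundreds of taxa would need a
  structure-exploiting refactor.
* The ANOVA path handles balanced designs only, by design.
* Absolute-abundance statements are out of reach: all regression output
  is compositional (CLR), and a CLR association does not imply a change
  in absolute cell numbers.
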