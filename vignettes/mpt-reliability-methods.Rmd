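---
title: "Methods: reliability and stability of MPT parameters for the IAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability and stability of MPT parameters for the IAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Responses on the race Implicit Association Test (IAT) are driven by several
cognitive processes at once.  Multinomial processing tree (MPT) models
decompose trial accuracy in the eight condition cells of the task (four
stimulus categories -- White faces, Black faces, good words, bad words --
crossed with the two critical-block pairings) into interpretable process
parameters.  `mptstab` asks two psychometric questions of those parameters:

* **Reliability within a measurement occasion**: if the fitted individual
  parameters were the truth, would refitting the model to data they generate
  return the same individual differences?  This is parameter recovery, and
  we summarize it by the Pearson correlation between original and recovered
  individual estimates (conventionally acceptable when *r* > .70).
* **Stability between measurement occasions**: do individuals keep their
  rank order across two administrations?  This is consistency, summarized
  by the two-way mixed-effects intraclass correlation ICC(3,1).

Both kinds of estimates are then pooled across datasets by random-effects
meta-analysis on the Fisher-z scale.

## The two shipped model trees

The Quad model (`mpt_quad()`) has five parameters: association activation
`AC_wg` (White-good) and `AC_bb` (Black-bad), detection `D`, overcoming
bias `OB`, and guessing `G`.  The PDP (`mpt_pdp()`) has stimulus-specific
control `C_White, C_Black, C_good, C_bad` and automatic evaluations
`A_White, A_Black`.  Both trees are frozen as EQN text files under
`inst/extdata/` with a branch-by-branch commentary; everything downstream
(probabilities, JAGS code, simulation) is generated from those files, so
the trees are the single normative source.

Two structural choices deserve explicit documentation because the tree
diagrams in the literature leave them implicit for attribute-word trials:

* In the Quad tree, `AC_wg` applies on White-face *and* good-word trials,
  `AC_bb` on Black-face *and* bad-word trials.  The activated association
  drives the response toward the key currently holding the associated
  pair, which is the correct key everywhere in compatible blocks and the
  wrong key everywhere in incompatible blocks.  `OB` therefore enters the
  tree only in incompatible blocks, where a detected correct response
  conflicts with the association-driven one.  `G` is the probability of
  guessing the key to which "good" is currently assigned, not a left/right
  key bias.
* In the PDP tree, when control fails on an attribute-word trial the
  automatic evaluation of the *target category sharing the response key*
  drives the response: good words are pulled toward "good" with
  probability `A_White` in compatible blocks and `A_Black` in incompatible
  blocks; bad words are the mirror image.  This is the standard
  full-design reading and keeps the six parameters identified from the
  sixteen cell frequencies.  We treat it as a documented modeling
  assumption of the package.

Both trees satisfy, and are continuously tested against, the partition
property: for every parameter vector in the unit hypercube, the branch
probabilities of each condition sum to exactly 1.

## Hierarchical estimation

Individual probability-scale parameters are modeled on the probit scale:
`theta_i = pnorm(eta_i)` with `eta_i ~ MVN(mu, Sigma)` across participants.
Each participant contributes eight binomial cell counts whose success
probabilities come from the tree.  Priors follow the latent-trait
convention of the standard tooling for these models: `mu_p ~ N(0, 1)` on
the probit scale (weakly informative: it puts 95% of group-mean mass
between probabilities .025 and .975), and a scaled inverse-Wishart prior
on `Sigma` (Wishart with identity scale and `P + 1` degrees of freedom on
the raw precision, with `Unif(0, 10)` scale factors).  The raw-effect
parameterization (`eta_i = mu + xi * etaRaw_i`) keeps the Wishart
conjugate, which is what makes Gibbs sampling practical.

Sampling runs in JAGS on BUGS code generated directly from the model's
branch table; any EQN-defined tree can be fitted, not just the two shipped
ones.  Cell probabilities are linearly squeezed away from the exact 0/1
boundary by 1e-9 before entering the binomial likelihood, so parameter
vectors at the corners of the hypercube cannot produce a zero-density
state.  Chains are seeded deterministically (`seed + chain index`), and
convergence is judged by split R-hat on every group-level quantity (all
means and all covariance entries) against a threshold of 1.05.
Non-convergence flags the fit; it does not raise an error.  Individual
point estimates default to posterior means (`point_estimate = "median"` is
available).

Practical MCMC sizing, from the package's own calibrations: group means
of well-identified parameters (detection, control, associations)
stabilize quickly; the group mean of `OB` -- weakly identified because it
enters only via three-factor products on incompatible trials -- and the
covariance entries tied to weakly informed parameters are the mixing
bottleneck.  Under the conjugate parameter-expanded Gibbs scheme those
covariance entries can hold split R-hats near 1.06-1.10 even after tens
of thousands of iterations at realistic sample sizes, so a strict
all-quantities R-hat < 1.05 typically demands chain lengths well beyond
desk budgets; group means themselves reach the criterion much sooner.
Default settings (`mcmc_control()`) suit exploratory fits and individual
point estimation; increase them for converged group-level covariance
summaries, and judge convergence from the per-quantity `rhats` table of
the fit rather than the single flag alone.

`fit_mle_individual()` provides a deliberately separate, non-hierarchical
maximum-likelihood estimator (numeric optimization of the product-binomial
likelihood) used as an independent oracle in tests: in the large-count
limit it must agree with the generating parameters, and hierarchical
posterior means must show shrinkage relative to it.

## Consistency, recovery, and pooling

`icc31()` implements the consistency ICC from the two-way mean-squares
decomposition, `(MS_B - MS_E) / (MS_B + MS_E)` for two occasions, with
F-based confidence limits and p values.  Consistency deliberately ignores
occasion mean shifts; the tests assert both that invariance and its
failure under rescaling.  Interpretation bins are the conventional ones
(< .40 poor, .40-.60 fair, .60-.75 good, > .75 excellent), with boundary
values resolving toward the better label -- the published ranges are
open at the textual level, so the tie policy is documented here rather
than inferred.

Recovery (`run_recovery()`) follows the four-step procedure: fit, simulate
from the individual point estimates with the observed per-cell trial
totals (binomial per cell, equivalently multinomial over
correct/incorrect), refit, and correlate.  Simulation uses point estimates
rather than posterior draws, matching the "original parameters" reading;
per-cell totals reuse the observed design so the simulated data carry the
same information content.  `repeatability()` quantifies how tightly a
fitted parameter set pins down behavior, by correlating simulated
frequency vectors among themselves and against the original data.

Meta-analysis is delegated to `metafor` (the standard engine for this
step) behind the package's own surface: `meta_random()` (REML between-study
variance, Wald CIs on the z scale back-transformed to r),
`meta_multilevel()` (random intercepts for study and occasion-within-study,
used for recovery effects, which arrive twice per study),
`meta_moderators()` (orthogonal polynomial contrasts of the ordered
time-interval rank, with the omnibus Q_M), and `compare_by_ci()` (two
pooled estimates count as different only when their intervals are
disjoint; touching at a point is overlap).  Standard errors of ICCs on the
z scale use Fisher's `sqrt(1/(n-3))`; for a two-occasion consistency ICC,
which is numerically close to a Pearson correlation, this is the standard
choice, and it only affects meta-analytic weights.  The heterogeneity
statistic Q uses fixed-effect weights; the package reports
`I2 = max(0, (Q - df)/Q) * 100` and also carries the REML-based I2 of the
fitted model (`i2_reml`), which is what the applied literature usually
prints -- the two differ and both are exposed.

## The synthetic-data generator

`generate_iat()` exists so every stage can be tested against known ground
truth.  Occasion-1 latents are `MVN(mu, Sigma)`; occasion-2 latents are
`mu + diag(rho) (eta1 - mu) + e` with `e` drawn so marginals are
preserved, giving per-parameter latent test-retest correlation `rho` --
the minimal generative structure whose downstream ICC has a known target.
Defaults are chosen once to represent a realistic race-IAT regime:
group-mean probabilities of .20 (associations), .65 (detection), .40
(overcoming bias), .50 (guessing) for the Quad model, and .60 control /
.60 and .45 automatic for the PDP, all with probit-scale SD 0.5 and
independent parameters; these imply cell accuracies of roughly .70-.95.
Between-occasion stability defaults to `rho = 0.5` for every parameter.
Designs follow the 7-block task (60 critical trials per pairing, 15 per
cell) or the abbreviated 5-block variant (two 32-trial critical blocks,
8 per cell).  `preset_panel()` provides a six-dataset two-occasion panel
(n = 1240, 105, 80, 463, 116, 32; the two 1-4-day studies abbreviated;
time-interval ranks 1, 2, 3, 3, 4, 5) and can be scaled down with a
single factor (rounded half-up, floored at 4 participants).

What the generator does *not* emulate: response latencies, practice
blocks, stimulus-level item effects, trial-order effects, and any
systematic occasion-2 mean shift (practice or habituation).  Passing
tests therefore show that the pipeline recovers what this generative
model encodes; they do not certify the behavior of real IAT data, where
those unmodeled features exist.

## The full pipeline and its bookkeeping

`run_study()` chains everything: generate or load trials, apply the
exclusion rules (participants lacking critical trials at either occasion;
error rate above 50% at either occasion -- the stricter per-occasion
reading of a participant-level rule, documented here because the
published description does not specify pooled-versus-per-occasion),
aggregate, fit per occasion, ICC and recovery per dataset, pool per
parameter, compare by CI overlap, and moderate by time rank.  By
construction the recovery meta-analysis consumes exactly twice as many
effect records per parameter as the consistency meta-analysis.  All fit
and refit seeds, R-hats and convergence flags are logged in the report.

## Problem sizes and numerical choices

The test suite and the acceptance script run the expensive stages at
deliberately chosen sizes: smoke-level fits at 16-60 participants with
short chains; the calibration check at 200 participants and 40 trials per
cell; the stability-recovery check at 300 participants with 10^4 trials
per cell (large counts pin individual estimates so the ICC target is the
generating `rho`); the end-to-end panel at a 0.05-0.1 scale of the full
design.  Degenerate inputs are handled explicitly: zero-trial cells are
retained with a warning (the hierarchical likelihood tolerates them),
zero between-participant variance makes the ICC undefined and flagged,
|r| = 1 maps to an infinite Fisher z with a warning, and inestimable
moderator designs reduce the polynomial degree rather than fail.

## Known limitations

Only accuracy is modeled; latency-based and diffusion-style accounts are
out of scope, as are non-race IAT variants.  The multilevel recovery
pooling estimates two variance components from few clusters and is
correspondingly noisy.  CI-overlap comparison is conservative relative to
a formal contrast test.  The Wald CI on the pooled z under-covers
slightly at small study counts; the Knapp-Hartung adjustment is exposed
as an option but off by default to match standard practice.
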