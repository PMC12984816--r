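---
title: "Estimating genetic parameters in a nested shellfish breeding design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic parameters in a nested shellfish breeding design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`qgped` estimates heritabilities, common-environment fractions and
genetic/phenotypic correlations for pedigreed aquaculture populations, and
ships a simulator of the nested mating design it targets so that every
estimator can be validated by parameter recovery. This vignette is the
package's own account of the models, the numerical choices, the calibration
of the simulator, and what the tests do and do not establish.

## 1. The design and its information structure

The reference design mates 81 sires to 124 dams to found 141 full-sib
families: 60 sires receive a second dam, and 17 dams are reused by a second
sire (the unique simple reconciliation of the three counts when each sire
takes at most two dams). About 80 offspring per family are tagged. The
resulting relationship structure — full sibs (additive relationship 1/2),
paternal half sibs through double-mated sires (1/4) and maternal half sibs
through reused dams (1/4) — is what lets variance components be separated:

* additive variance is identified from the contrast between full-sib and
  half-sib resemblance;
* sire variance is well supported (60 sires with two dams), while the
  dam-versus-common-environment split hangs on only 17 dam-sharing links.
  This asymmetry matters for the threshold model (Section 5).

`sim_design()` realizes the design deterministically given a seed;
`design_spec()` checks feasibility (e.g. no sire may need a third dam).

## 2. Linear animal model and REML

For traits `t = 1..T` the model is `y = Xb + Za + e` with
`Var(a) = A ⊗ G` and `Var(e) = I ⊗ E`, `A` the pedigree numerator
relationship matrix, `G`/`E` unstructured across traits. Fixed effects are a
per-trait intercept and the three-level gender factor (female, male,
unidentifiable — a genuine third level, not missing data). A full-sib
common-environment covariance `F` is available behind a flag but excluded by
default: in single-generation data it is weakly separated from the dam-side
genetic variance, and fits that include it rarely move the likelihood
(Section 5 quantifies the threshold-model analogue).

Record-level missingness is handled exactly: each individual enters only the
trait equations where it is observed, and residual cross-trait covariance
applies only to co-observed pairs. Trait pairs never co-observed have their
residual covariance pinned at zero (it does not enter the likelihood).

**Computation.** The marginal covariance of the records is block-diagonal
over the connected components of the pedigree graph. In nested sib designs
those components are small clusters of families linked by shared parents
(median two to three families, a few hundred records), so the package
evaluates the restricted likelihood, the EM updates, the exact score and the
exact average-information (AI) matrix densely per component and accumulates.
Consequences:

* EM-REML updates use exact conditional traces, so the restricted
  log-likelihood is non-decreasing across EM iterations (asserted by a
  test);
* the AI matrix is exact, so SEs are the conventional inverse-AI
  delta-method quantities;
* a dense, component-free implementation of the univariate restricted
  likelihood (`profile_loglik()`, refused above 500 records) serves as an
  independent oracle: the engine's optimum must dominate a brute-force grid
  and agree with the dense formula to near machine precision at the same
  point.

The default schedule is 5 EM iterations then AI steps with step-halving
(falling back to an EM step if a proposed AI step fails to increase the
likelihood or leaves the PD cone). Convergence requires a relative
log-likelihood change below `1e-8` and a maximum parameter change below
`1e-6` (on the internally standardized scale). Variances hitting zero are
pinned at `1e-8` of the (standardized) phenotypic variance and flagged.
Traits are standardized internally to unit SD, which keeps the AI system
well conditioned when traits differ in scale by orders of magnitude (meat
yield is ~0.04 units of SD; total weight ~15 g); results are returned on the
data scale, and a test asserts exact invariance of h² and correlations to
rescaling.

This dense-per-component realization was chosen over sparse Henderson
mixed-model equations deliberately: at the design sizes in scope it is
faster in R, and it gives exact traces where a sparse implementation would
need stochastic approximations. Pedigrees whose phenotyped individuals form
one giant connected component (deep multi-generation data) would defeat the
blocking; that is outside the package's intended scope, which matches the
simulator's two-generation output. The sparse inbreeding-aware inverse of
`A` (`build_A_inverse()`, Henderson rules with Meuwissen–Luo adjustment) is
provided and tested against dense inversion, as the standard export for
downstream mixed-model software.

## 3. Derived parameters

`h2_linear()`, `correlations()` and `genetic_parameters()` compute the
reported quantities; SEs use the first-order delta method on the inverse AI
matrix, and significance stars are approximate Wald z labels (documented as
such — no further multiplicity handling). Out-of-range point estimates
caused by sampling noise (e.g. r_g marginally above 1) are clipped to the
boundary and flagged in the report.

For the threshold model the latent-scale heritability and common-environment
fraction are

    h²_latent = (σ²_s + σ²_d) / (σ²_s + σ²_d + σ²_f + 1)
    c²        =  σ²_f         / (σ²_s + σ²_d + σ²_f + 1)

and the three latent shares (h², c², residual) sum to one by construction.
A caution for readers comparing with the wider literature: in a sire–dam
model `σ²_s + σ²_d` estimates only *half* the additive variance (each
parent transmits half its genome, so each component is `σ²_a/4`), and the
conventional narrow-sense latent heritability would carry an extra factor
of 2. The package implements the formula above verbatim because it is the
reporting convention of the study family it targets; Section 5 works
through the consequences, which are material when comparing threshold and
linear analyses of the same trait.

## 4. The simulator and its calibration

`default_calibration()` packages the study conditions:

* **Trait moments** (means/SDs) and **heritabilities** for the seven
  continuous traits (shell lengths at 6/18/24/30 months: h² = 0.71, 0.62,
  0.45, 0.48; total wet weight 0.48; meat weight 0.31; meat yield 0.14).
* **Correlation structure**: all reported genetic and phenotypic pairwise
  correlations; the handful of unreported cross pairs (e.g. early shell
  length × meat weight) are closed by the path rule
  `r(i,j) = r(i,Tww) · r(Tww,j)` through the hub trait and the matrix is
  bent minimally to the PSD cone (eigenvalue floor, diagonal restored).
  Residual correlations derive from `cov_p = cov_g + cov_e`.
* **Gender effects**: the source reports none, so the default is ±0.1
  phenotypic SD (female +, male −, unidentifiable 0), exactly centred under
  the sex-class frequencies (52/37/11%) so population means are unchanged.
* **Foot color**: a sire–dam liability with σ²_s = σ²_d = 0.42593 and unit
  residual, i.e. latent shares chosen so the reported h²_latent formula
  equals 0.46. Cutpoints are restricted to be equally spaced on the
  liability scale — two free parameters for the two calibrated moments
  (score mean 1.42, SD 0.64) — which also yields the required mode at
  category 1. The weak (−0.04) genetic link to total weight is induced
  through the parental transmitting effects.
* **Survival**: Bernoulli from an independent sire–dam liability; overall
  rate 9006/12800 ≈ 0.70 from the tag accounting, latent shares set once to
  σ²_s = σ²_d = 1/18 (reported-scale h²_latent = 0.10, a typical magnitude
  for survival in shellfish programs; the source reports no value).
* **Missingness**: mortality first (all traits lost), then tag loss
  (retention 8001/9006), then per-trait record retention matching the
  reported Ns, then the dissection subsample: 680 individuals, 20–25 per
  family from 30 families, drawn only from identified survivors.
* **Meat yield, two modes.** `direct` (default): a Gaussian trait at its
  calibrated moments — the mode that reproduces the descriptive table and
  gives clean recovery tests. `composite`: meat yield computed as
  Mw/Tww. The two cannot agree: the calibrated joint Gaussian for (Mw, Tww)
  implies a ratio mean near 0.47 with SD ≈ 0.11, while the calibrated My
  moments are 0.51 ± 0.04 — the three printed moment sets (Mw, Tww and
  their correlation; My) are mutually inconsistent, since no correlation
  ≤ 1 at those CVs can compress the ratio CV to 8%. The package keeps both
  modes and does not force agreement; ratio traits simply have no exact
  closed-form moments or heritability.

Breeding values are simulated by the Mendelian-sampling recursion
`a_i = (a_s + a_d)/2 + φ_i`, `Var(φ_i) = d_i G` with the inbreeding-adjusted
`d_i`, which gives `Cov(vec(a)) = A ⊗ G` exactly; a test checks the implied
sib covariances against a dense multivariate-normal oracle. All randomness
flows from one user seed through fixed per-stage sub-seeds, so output is
byte-identical across runs.

**What the generator does not emulate.** Traits are Gaussian: weights can
(rarely) go non-positive (about 1% of meat-weight draws at CV 0.43), there
is no skew, no growth-curve structure linking the shell lengths beyond
their correlation matrix, no genotype-by-environment structure, no
selective mortality (survival is independent of the measured traits, so
survivor records are unbiased samples — real mortality is unlikely to be
trait-neutral), and no misassignment of pedigree. Recovery tests passing
here therefore demonstrate correctness of the estimators under the stated
model, not robustness to those real-data departures.

## 5. The threshold model: algorithm and two identifiability findings

`threshold_sire_dam()` uses Gibbs sampling with latent-liability data
augmentation: truncated-normal draws for liabilities, a joint conjugate
normal draw for all location effects, scaled inverse-chi-square draws for
the variances (flat prior on each variance; proper conditionals require ≥3
levels), and a random-walk Metropolis step on the log-gaps of the free
cutpoints using the marginal ordinal likelihood (adapted toward 30%
acceptance during burn-in only, so the post-burn-in chain is a fixed
Markov kernel). Identification: residual liability variance fixed at 1,
first cutpoint at 0, intercept retained. Binary traits are the special case
with no free cutpoint. Defaults are a 20,000-iteration chain, 5,000
burn-in, thinning 10; the packaged recovery studies use 2,500/800/2 — at
~7,000 records the posterior is concentrated enough that these shorter
chains give effective sample sizes of several hundred for h²_latent, and
the two-seed stability test bounds the Monte-Carlo error. Split-R̂ above
1.1 produces a warning, never a silent pass.

**Finding 1 — the common-environment ridge.** With the generating σ²_f = 0,
long chains (20k iterations, R̂ ≈ 1.00) put the posterior mean of σ²_f near
0.16 and pull h²_latent from 0.46 down to ≈ 0.36. This is not a sampler
failure: only the 17 dam-sharing links separate σ²_f from σ²_d, so the
likelihood is nearly flat along their ridge and any diffuse prior spreads
mass away from the boundary, whereas a REML point estimate would pin σ²_f
at 0. The package therefore makes the family term optional
(`family = NULL`), and the recovery study uses the f-free model as the
reference analysis — the Bayesian analogue of the boundary-pinned REML fit,
and consistent with dropping the term in the companion linear models. With
the term dropped, replicate posterior means recover the generating 0.46
closely (acceptance value 0.471 over 10 replicates).

**Finding 2 — the latent formula versus the linear score.** The reporting
convention `h²_latent = (σ²_s+σ²_d)/(σ²_s+σ²_d+σ²_f+1)` (Section 3) fixes
the full-sib liability correlation at h²_latent itself. Calibrated to 0.46,
the liability carries far more family-level signal than a narrow-sense
heritability of 0.46 would imply, and a linear animal model applied to the
observed 1–4 scores on the same data estimates h² ≈ 0.6–0.7 — *above* the
latent value, by straightforward variance accounting (the multi-threshold
attenuation factor (Σφ(τ))²/σ²_cat ≈ 0.66 applied to an effective
liability-scale heritability of ≈ 0.9). Under the factor-2 (narrow-sense)
reading the familiar ordering reverses: an animal-model liability with
h² = 0.46 yields linear-score estimates near 0.3, below the latent value.
The two conventions are not interchangeable, and published
threshold-versus-linear contrasts can only be reproduced under one of them.
The package follows the verbatim convention and reports this consequence
rather than silently switching scales; the corresponding
linear-below-latent contrast is therefore *not* reproduced under the
packaged calibration, and the recovery test for that directional claim
fails by design, documenting the conflict.

## 6. Numerical choices and degenerate inputs

* Tabular `A` is dense and intended for desk-scale pedigrees and
  per-component use; the sparse inverse is built directly by the Henderson
  rules (never by inverting `A`).
* Topological sorting is repeated-pass with ties broken by input order;
  cycles are reported with the offending chain; duplicate ids, self-parents
  and identical sire/dam are fatal.
* Unknown-parent codes default to `{"0", "NA", ""}` and are configurable.
* Founders are treated as unrelated and non-inbred (base-population
  assumption; the founding broodstock's own parents are not traced).
* Zero-variance responses are fatal with a clear message; empty ordinal
  categories are collapsed into their neighbor with a warning; covariance
  matrices are bent to the PSD cone only where pairwise-assembled inputs
  require it, with the diagonal restored.
* `independent_traits = TRUE` pins all cross-trait covariances to zero; a
  test verifies the constrained bivariate fit reproduces the univariate
  fits to 1e-6, a useful consistency check and a cheap way to fit many
  traits when correlations are not needed.

## 7. Problem sizes used in the packaged studies

Recovery studies run at the full 141-family design (~11,280 tagged
offspring, ~7,000 records per well-recorded trait). Replicate counts are 10
for the univariate, bivariate and threshold studies and 30 for the
small-sample meat-yield study, chosen so the Monte-Carlo SE of each
replicate mean is a few hundredths — small enough to detect estimator bias
of scientific size while keeping a full acceptance run to a few minutes on
one CPU. The unit-test suite uses miniature designs (8–30 sires) for
structural and invariance checks and the full design only where the claim
is about the study scale.

## 8. Known limitations

* The REML engine's blocking assumes the phenotyped pedigree decomposes
  into moderate connected components; deep interconnected pedigrees are out
  of scope.
* Genomic (marker-based) relationship matrices, multivariate
  threshold–linear joint models, repeated records and selection-response
  simulation are not implemented.
* The delta-method SEs and Wald stars are first-order approximations;
  near-boundary components (e.g. the n = 680 meat-yield heritability) have
  wide, asymmetric sampling distributions that a profile or bootstrap
  interval would represent better.
* The Gaussian trait model does not enforce positivity of weights; the
  composite meat-yield mode inherits that artifact in ~1% of draws.
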