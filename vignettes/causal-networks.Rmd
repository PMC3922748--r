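---
title: "Causal networks among correlated traits: model, search and SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal networks among correlated traits: model, search and SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multi-trait mixed models describe *marginal* associations among traits.
When the scientific question is what would happen to trait B if trait A
were changed by an intervention, marginal covariances are not enough:
one needs a causal structure among the traits and the magnitudes of the
direct effects. `icsem` implements the three-stage workflow for
pedigreed populations in which correlated additive-genetic effects are a
known confounder of any phenotype-level causal search:

1. fit a Bayesian multi-trait animal model and extract posterior samples
   of the **residual** covariance matrix `R0` — the covariance among
   traits *conditional on* genetic and systematic effects;
2. run the Inductive Causation (IC) algorithm on those posterior
   samples, deciding conditional independence by whether the highest
   posterior density (HPD) interval of each partial correlation covers
   zero;
3. quantify the resulting (prior-knowledge-oriented) structure with a
   recursive structural equation model (SEM) and compare it with the
   multi-trait model by DIC.

Running the search on the residual covariance rather than on raw
phenotypes is the crucial adaptation: genetic covariances generate
trait–trait correlation that is *not* causal at the phenotype level, and
would otherwise be read as edges.

## Stage 1: the latent-factor multi-trait animal model

For `t` traits on `n` animals, `y = X beta + Z u + e`, with
`u ~ N(0, G0 ⊗ A)` and `e ~ N(0, R0 ⊗ I)`; `A` is the numerator
relationship matrix built from the pedigree by the tabular method.
Fixed effects per trait are: an intercept, days in milk as a Wilmink
pair `{DIM, exp(-0.05 DIM)}` (exponent configurable, 0.05 per day is
the canonical lactation-curve value), age at first calving and its
square, and reference-coded calving season, sire code and herd.
Phenotypes are standardized to mean 0, SD 1 before fitting; all
reported covariances live on that scale unless back-transformed.

Sets of many strongly correlated traits make an unstructured `R0`/`G0`
mix badly. Both matrices therefore carry a latent-factor structure:
`k` latent vectors per structure with free loadings, plus an
independent remaining variance per trait, so that
`Sigma = L'L + diag(tau^2)`. The remaining variances have uniform
`[0.02, Inf)` priors: at least 2% of each standardized trait's variance
stays trait-specific, which bounds implied heritabilities to
`[0.02, 0.98]` (when the total is 1) and keeps correlations strictly
below 1. The floor is enforced by inverse-CDF sampling of the truncated
scaled-inverse-chi-square conditional, never by clamping. `k` is chosen
by PCA of the trait correlation matrix: the smallest number of
components explaining 90% of the variance (threshold configurable).

The sampler is Gibbs throughout — every conditional is conjugate
(normal for effects, latent vectors and loadings; truncated scaled
inverse chi-square for variances). Pedigree-correlated vectors are
updated single-site against the sparse precision matrix `A^-1`, built
directly from the pedigree and the tabular inbreeding coefficients, so
one sweep costs O(nnz). Loadings are not identified (sign/rotation);
only reconstructed covariances are monitored, and ESS/split-Rhat
diagnostics are computed on covariance entries, never on loadings.

## Stage 2: the IC search on posterior covariance samples

For every pair of traits and every subset of the remaining traits
(`t(t-1)/2` pairs × `2^(t-2)` subsets), the partial correlation is
computed from each posterior `R0` draw by submatrix inversion,
`-Omega_ij / sqrt(Omega_ii Omega_jj)`. A pair is declared dependent
given a subset when the Chen–Shao HPD interval (shortest sorted window;
ties broken at the lowest start) excludes zero.

* **Step 1** keeps an edge only if *every* subset yields dependence;
  all zero-covering subsets of non-adjacent pairs are recorded as
  separating sets.
* **Step 2** orients an unshielded triple `i - m - j` as a collider
  `i -> m <- j` iff `m` lies in *no* recorded separating set of
  `(i, j)`. Conflicting demands abort with a report rather than being
  resolved silently.
* **Step 3** closes the graph under the two rules that forbid new
  unshielded colliders and cycles (`a -> b - c` with `a, c`
  non-adjacent forces `b -> c`; `a -> b -> c` with `a - c` forces
  `a -> c`).

No multiple-testing correction is applied: the decision rule is exactly
per-(pair, subset) HPD exclusion. Because a narrower interval still
excludes zero whenever a wider one does, lowering the HPD content
(default ladder 95, 90, 85, 80%) can only add edges; the package
re-runs all three steps at each content.

Two practical consequences of this decision rule are worth keeping in
mind. First, a truly-zero partial correlation is retained with
probability roughly equal to the HPD content, so an exactly-calibrated
95% rule will miss a true independence in about one run in twenty —
structure-recovery rates slightly above 95% are the expected ceiling,
not a defect. Second, the search is exponential in `t`
(`count_ic_tests(14)` gives 91 pairs × 4096 subsets = 372 736 partial
correlations per posterior draw); a `max_cond_size` cap is available
for larger trait sets, with the full enumeration as the default.

## Stage 3: the recursive SEM and DIC

Given an acyclic structure, `y = (Lambda ⊗ I) y + X beta* + Z u* + e*`
with *diagonal* residual covariance `Psi0` — the diagonality is what
identifies the structural coefficients. Each coefficient is a
regression of the child trait on its causal parent(s) within the Gibbs
sweep (flat prior); the direct-genetic covariance `G0*` uses the same
latent-factor device and floor as the multi-trait model. `Psi0` itself
carries no floor by default: near-zero direct residual variances are a
genuine feature of tightly coupled traits, and the diagonal structure
needs no floor for identifiability (a `psi_floor` argument exists).

Because the sampler works on standardized traits, a coefficient on the
measurement scale (g/kg milk) is recovered as
`lambda_std * sd(child) / sd(parent)`; `structural_coefficients()` does
this per posterior draw. Reduced-form covariances
(`(I-Lambda)^-1 G0* (I-Lambda)^-T`, likewise for `Psi0`) link SEM
parameters to multi-trait ones: direct versus overall effects.

**DIC.** Both models are scored by the deviance of `y` conditional on
the sampled location effects (fixed effects, genetic effects including
their latent vectors, structural coefficients) under the model's
residual covariance — the reconstructed `R0` for the multi-trait
model, `Psi0` for the SEM. Marginalizing over the *residual* factor
structure (rather than conditioning on it) is what makes the two
deviances comparable: conditioning on the residual latent vectors would
let the multi-trait model score an essentially saturated fit.
`pD = mean(D) - D(at posterior means)`, `DIC = mean(D) + pD`.

One comparison caveat: the posterior for a single structural
coefficient under the correlated-genetic-effects device is wider than a
plain regression posterior would suggest, because the shared genetic
factor admits a confounding pathway that plain regression excludes.
The package's tests therefore check that the coefficient posterior
*centers* on the collapsed regression estimate; an exact closed-form
match would require fixing `Psi0` and removing the genetic device,
a model this package deliberately does not fit.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream stage is validated.

* **Design defaults**: 1902 phenotyped cows on 397 herds, at least 3
  cows per herd (minimum guaranteed, remainder multinomial), days in
  milk uniform on 63–282, age at first calving N(24, 2) months, 3
  calving seasons, 2 sire codes, a 4-generation pedigree. Each
  ancestral layer holds ~49% as many animals as there are cows (5%
  males), which reproduces the ~2.5 ancestors-per-cow ratio of a
  typical field pedigree; the exact herd-size distribution beyond the
  guaranteed minimum is not a modelled quantity.
* **Generating model**: the SEM reduced form
  `y = (I - Lambda)^-1 (X beta + u + e)` on the standardized scale,
  mapped to g/kg with per-trait reference means/SDs (the 14
  milk-fatty-acid values in `milk_fa_reference()`). Genetic effects are
  gene-dropped: founders `N(0, G0*)`, offspring get the parent average
  plus a Mendelian term with variance factor
  `0.5 - 0.25 (F_s + F_d)`, so `Var(vec(u)) = G0* ⊗ A` exactly.
* **Default truth**: the de novo chain
  `C4:0 -> C6:0 -> C8:0 -> C10:0 -> C12:0` with coefficients
  (1.05, 0.90, 0.85, 0.95) on the standardized scale, direct-genetic
  variances (0.460, 0.114, 0.073, 0.066, 0.026), direct residual
  variances (0.455, 0.010, 0.010, 0.010, 0.059). The two smallest
  residual variances were raised to 0.010 so the generative model stays
  comfortably non-degenerate. Posterior summaries of direct-genetic
  *correlations* under a five-trait chain are not a reliable template
  for a generative covariance (a matrix assembled from such summaries
  need not be positive definite — the assembled matrix here has a
  smallest eigenvalue of about −0.5), so the default uses an
  exchangeable direct-genetic correlation of 0.3: a moderate positive
  value appropriate for traits sharing synthesis machinery. The fixed
  effects share one systematic score across traits (Wilmink pair, AFC
  linear + quadratic, season, sire code, herd effects N(0, 0.3²)).

What the generator does **not** emulate: measurement error structure of
gas-chromatography phenotyping, selection or assortative mating, and
non-linear causal links. Passing tests therefore demonstrate correct
behaviour of the machinery under a linear, causally sufficient,
multivariate-normal world — not robustness to those violations.

## Numerical choices and problem sizes

* Tabular (recursive) construction of `A`; unknown parents contribute
  zero; the sparse `A^-1` used by the samplers comes from the standard
  generalized-inverse decomposition with tabular inbreeding
  coefficients, and pedigrees at most one generation deep skip the
  dense tabular pass (all `F` are exactly zero there).
* Truncated variance conditionals are sampled by inverse CDF on the
  gamma scale; a numerically exhausted tail collapses to the floor.
* Singular covariance submatrices during the IC plan raise an error
  carrying the condition number; within posterior evaluation such draws
  are excluded and counted.
* HPD windows use `ceiling(content * N)` sorted draws.
* The test suite fits the recovery models at n = 2000 cows
  (3-generation pedigree, 2 chains × 8000–10000 iterations, burn-in
  20–25%, thinning 10) and the DIC battery at n = 350 over ten seeds
  (2 chains × 6000 iterations per fit — long enough that Monte-Carlo
  noise in the deviance means no longer masks the model ranking);
  the acceptance script runs the full default design (1902 cows, 397
  herds) with 2 chains × 6000 iterations per fit. These sizes are the
  package's desk-scale defaults: posterior SDs are small enough for
  3-posterior-SD recovery checks while a complete run stays in the
  minutes range. Production-scale settings (more and longer chains)
  remain plain configuration.

## Known limitations

* The search space excludes cyclic structures and latent confounders
  (causal sufficiency is assumed); edges among measured traits may
  reflect unmeasured common causes.
* With strongly coupled traits the variance floor biases near-unity
  residual correlations slightly downward (by construction, at most
  the floor's share of each trait's variance); recovery checks on such
  entries must allow for this. The same constraint affects the IC
  stage: when the generating process leaves a trait with *less*
  idiosyncratic residual variance than the floor (as the default
  near-deterministic chain does — 0.4–1% against the 2% floor), the
  best floor-respecting `R0` turns exact-zero partial correlations
  into clearly nonzero ones, and with enough data the search reports
  a denser graph than the generating chain. This is a property of the
  floored model class, not of the search: on data whose conditional
  structure respects the floor, the search recovers the generating
  skeleton and colliders at the expected rate.
* DIC with a conditional focus is sensitive to the chosen focus; the
  package fixes one coherent focus for both models and documents it,
  but DIC magnitudes are not comparable across focuses or software.
* Single-site updates of pedigree-correlated vectors mix slowly when
  families are large and variance partitions are weakly identified;
  the convergence diagnostics (`$diagnostics`) should be inspected
  before interpreting variance components from short runs.
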