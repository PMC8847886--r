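---
title: "Methods: the positive-negative mode pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the positive-negative mode pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Large population imaging cohorts make it possible to ask whether a single
low-dimensional mode of covariation links resting-state functional
connectivity to behavioural, cognitive and demographic subject measures
(SMs) — the "positive-negative axis": SMs usually regarded as positive
(cognition, education, income) load on one end, and those regarded as
negative (rule-breaking, ADHD symptoms, substance use) on the other, with a
matching pattern of connectome edges. `pnaxis` implements the full analysis
as a tested, reusable pipeline: motion quality control, ridge
partial-correlation network matrices, SM preparation, canonical correlation
analysis (CCA) with family-restricted permutation inference, post hoc axis
and edge analyses, and family-respecting cross-validation. Because cohort
data of this kind are access-restricted, the package ships a synthetic
cohort generator that plants a known cross-view mode, so every stage can be
validated against ground truth.

## The model

Let $N_5$ ($n \times d$) and $S_5$ ($n \times d$) be the PCA-reduced
connectome and SM matrices. CCA finds demixing matrices $A, B$ maximizing
$\mathrm{corr}(N_5 a_k, S_5 b_k)$ subject to mutual decorrelation of the
variates $U = N_5 A$, $V = S_5 B$. Significance of each mode's canonical
correlation $r_k = \mathrm{corr}(U_k, V_k)$ is assessed against a
permutation null that preserves the twin/sibling family structure:
monozygotic (MZ) co-twins may swap with each other, dizygotic (DZ) co-twins
with each other, non-twin siblings with each other, and whole families with
identical role signatures may swap wholesale. Familywise error is controlled
with the max-statistic (first canonical correlation) null and the
$(1+b)/(1+P)$ p-value convention.

One inference detail matters at moderate sample sizes. Both prepared views
are residualized against the same 12-regressor confound design, so they
live in a common confound-orthogonal subspace; permuting SM rows moves the
SM side out of that subspace and shrinks the null canonical correlations,
inflating type-I error by roughly the ratio of confound count to sample
size (negligible at $n \approx 8000$, but measurably anticonservative at
$n \approx 100$-$300$). `permutation_null()` therefore re-residualizes each
permuted SM matrix against the confound design — the Freedman-Lane scheme
standard in restricted-permutation neuroimaging inference — whenever
confounds are supplied, which leaves the observed statistic untouched (the
prepared SM side is already confound-orthogonal) and restores nominal
calibration.

Variance explained by mode $k$ in an original data matrix $X$ (the raw edge
matrix $N_0$ on the connectome side, the Gaussianized SM matrix $S_2$ on the
SM side) is the variance-weighted mean squared correlation
$\mathrm{ve}_k = \sum_j r^2(U_k, x_j)\,\mathrm{var}(x_j) / \sum_j
\mathrm{var}(x_j)$, compared to its permutation null through z-scores
(observed minus null mean over null sd, so larger-than-null is positive) and
5th/95th percentile bands. A mode is *primary* when its variance explained
is significant in both views; the pre-registered criteria additionally ask
for z-ratios of at least 2 (connectome) and 3 (SM) over the next-best mode
and an FWE p below 0.001 for the mode's weight correlation.

## Stage-by-stage conventions

**Motion QC.** Time points with framewise displacement (FD) above 0.3 mm
are censored, and surviving low-motion segments shorter than 5 points are
also removed. A run is good when its mean FD is strictly below 0.3 mm and
its raw length is at least half the expected 380 points (190). Subjects
need at least 2 good runs, at least 750 post-censor points (10 min at
TR = 0.8 s; "10 minutes" is operationalized in time points, following the
parenthetical definition), a mean FD inside the central 99.5% of the
candidate distribution (linear-interpolation quantiles, exclusion strictly
beyond the bound, computed over subjects surviving the first two criteria),
and an anatomical QC pass. The exclusion ledger attributes each subject to
the *first* failed criterion, in that order, so sequential exclusion counts
can be reported.

**Netmats.** Partial correlations use an L2-regularized precision: the
node covariance is normalized by its mean diagonal (making `rho` scale-free;
the reference ridge netmat estimator's exact internal scaling is not
published, so this normalization is declared rather than inferred), `rho *
I` (default 0.01) is added, and partial correlations
$-P_{ij}/\sqrt{P_{ii}P_{jj}}$ are Fisher-z transformed (plain `atanh`, with
$|r| = 1$ capped at $1 - 10^{-15}$ under a warning). Edges are the strict
upper triangle in row-major order, 1-based in all reports.

**SM preparation.** The quantitative filter drops SMs with under 50%
data, 95%-or-more identical values, or an extreme outlier
($\max(Y) > 100\,\mathrm{mean}(Y)$, $Y = (X - \mathrm{median}(X))^2$),
attributing each drop to the first failing criterion. Note the outlier
ratio is bounded above by the sample size, so criterion 3 can only fire
when $n > 100$ — at pipeline scale this is immaterial. Gaussianization is
the rank-based inverse normal transform with the Blom offset
($\Phi^{-1}((\mathrm{rank} - 3/8)/(m + 1/4))$, average ranks for ties); the
offset choice is ours, as only "rank-based inverse Gaussian transformation"
is specified by convention in this literature. Confounds are the 7 base
variables (site, scanner, mean FD, weight, BMI, cube-root brain and
intracranial volumes), demeaned with missing values imputed as zero, plus
demeaned squares of the quantitative confounds 3-7, for 12 regressors;
categorical confounds expand to indicator blocks counted as one logical
confound each. Deconfounding regresses `[intercept, confounds]` out of each
column over that column's observed rows (the intercept subsumes demeaning;
the original order of demeaning versus projection is not stated, and the
intercept makes the choice immaterial). Missing data are handled without
imputation by a pairwise-complete subjects-by-subjects covariance, projected
to the nearest positive-definite matrix by symmetric eigenvalue clipping
(Frobenius-optimal for symmetric input) with a Cholesky-verified jitter
loop; the fidelity check reported for this step is the correlation between
the covariance before and after projection (essentially 1 when missingness
is a few percent); PCA scores are $u_k\sqrt{\lambda_k}$. Downstream canonical
correlations are invariant to that $\sqrt{\lambda}$ scaling.

**Connectome preparation.** From the subjects-by-edges matrix $N_0$:
$N_1$ is column-demeaned and globally variance-normalized; $N_2$ divides
each column by the *absolute* value of its mean and drops columns with
$|\mathrm{mean}| < 0.1$ (the absolute value is our resolution of an
ambiguous rule: z-valued partial-correlation edges can be negative, and
division by near-zero signed means is unstable), then demeans and globally
normalizes; $N_3 = [N_1 | N_2]$ is deconfounded into $N_4$ and reduced by
truncated SVD into $N_5$.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates:

- **Family structure**: MZ/DZ twin pairs, sibling groups and singletons in
  proportions chosen to mirror a large developmental cohort (desk scale:
  11 MZ + 15 DZ pairs, 24 sibling pairs, 200 singletons; 300 subjects).
- **Familial similarity** via shared/unique Gaussian components,
  $\mathrm{score} = \sqrt{\rho}\,f + \sqrt{1-\rho}\,u$, with defaults
  $\rho_{MZ} = 0.8 \ge \rho_{DZ} = 0.5 \ge \rho_{sib} = 0.4$ — ACE-like
  values typical of cognitive phenotypes; the construction gives the target
  correlation exactly in expectation.
- **A planted mode**: 12 SMs load at magnitudes 0.5-0.9 (mixed signs) with
  unit noise (so the strongest SM-score correlations are ~0.67 after
  attenuation), and 25 disjoint node-pair edges of magnitude 0.12 perturb
  the precision matrix, $\Omega_i = \Omega_{base} - s_i \Lambda$. Putting
  the perturbation in the precision (not correlation) makes ridge partial
  correlation the matched estimator. Disjoint edges keep
  $\|\Lambda\|_2$ equal to the edge magnitude; if a subject's minimum
  eigenvalue would fall below 0.05, its loading contribution is scaled
  down.
- **Confound effects, missingness, motion**: a common confound signature
  added to every SM; 2% missing cells completely at random (near the ~1.7%
  seen in practice); lognormal FD baselines with exponential spikes, a
  small fraction of deliberately bad runs, and rare anatomical QC failures.
- **Pathological SM columns** (constant, >95% identical, extreme outlier,
  >50% missing) appended at fixed trailing positions with metadata flags so
  the filter tests are deterministic.

The reference study gives no generative model (it is empirical); all
distributional choices here are artifact decisions. The generator does not
simulate raw fMRI volumes, scanner/site batch effects beyond additive
confounds, autocorrelated time series, or non-Gaussian SM families — so
passing tests demonstrate the pipeline's correctness and calibration under
a Gaussian, correctly-specified world, not robustness to real-data
pathologies.

## Cross-validation conventions

Splits assign whole families greedily (largest first, randomized among
equal sizes) until the 80% target is met, so no family spans train and
test. The test-side matrices are, by default, re-estimated within the test
subset (deconfounding and PCA recomputed) and projected through the
training demixing matrices, following the literal description of the
procedure; a strict-generalization mode (training betas and bases applied
to test data) is available via `strict = TRUE`. Because independently
re-estimated PCA components carry an arbitrary sign, each test component is
sign-aligned to its training counterpart through shared feature-space
loadings (the `N1` edge block on the connectome side, shared SM columns on
the SM side); without this the held-out correlation's sign would be
undefined. PCA components themselves carry a deterministic sign convention
(largest-magnitude feature-space loading positive), as does each CCA mode
(largest-magnitude SM loading positive). Per-repetition significance
shuffles test-side SM rows within test-set family blocks.

## Numerical choices and degenerate inputs

- Correlations of magnitude 1 are capped at $1 - 10^{-15}$ before `atanh`.
- `nearest_spd` clips eigenvalues at $10^{-10} \lambda_{max}$ and doubles
  the floor until `chol()` succeeds.
- Rank-deficient CCA inputs reduce the mode count with a warning;
  rank-deficient confound designs drop dependent columns with a warning.
- Zero-variance columns are excluded (with warnings) from variance
  explained and from the axis.
- Ties in `top_edges` break by edge id; cluster leaf order is the `hclust`
  dendrogram order (deterministic; optimal leaf ordering was considered and
  rejected to avoid an extra dependency for a purely cosmetic gain).
- All permutation machinery uses R's RNG under the caller's seed;
  `run_pipeline(seed=)` makes full runs bit-reproducible.

## Problem sizes

Desk-scale defaults — 300 subjects, 50 nodes, 750 time points, 74 SMs,
30 PCA/CCA dimensions, 500-1000 permutations, 10 cross-validation
repetitions — were chosen so that a complete pipeline run finishes in about
two minutes on one CPU while every statistical property (type-I
calibration, planted-mode recovery, held-out generalization) remains
testable. Full cohort-scale settings (200 nodes, 70 dimensions, 100 000
permutations) are plain arguments. Reference-scale headline numbers
(canonical r around 0.4-0.5, SM variance explained around 5%, held-out r
around 0.2) arise from a specific restricted-access cohort and are not
reproduced by the synthetic generator; the package's claims are about
correctness and calibration, which the test suite and the acceptance script
compute directly.

## Known limitations

- The ridge netmat's covariance normalization matches the declared
  convention above; other implementations may scale differently, changing
  edge z-values (but not downstream CCA results materially).
- The SM-side PCA operates in subject space via the completed covariance;
  the strict-generalization CV mode therefore maps test subjects through a
  pseudo-inverse SM-space basis, which is exact only when the training
  scores span the SM space.
- Permutation inference treats preprocessing as fixed (rows of the
  prepared matrices are permuted); the null is faithful to the described
  procedure but does not propagate preprocessing variability.
- With fewer than ~100 subjects the outlier filter criterion cannot fire,
  by the arithmetic of its ratio statistic.
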