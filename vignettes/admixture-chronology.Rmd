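---
title: "Dating admixture events: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating admixture events: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixchron)
```

This vignette is the package's own account of the statistics it
implements: what each model assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where the numerically delicate corners are.

## The scientific chain

The package answers one composite question: *how long before a directly
dated individual lived did the admixture event happen that formed their
ancestry, in calendar years?* The chain is

1. establish that the target is admixed and measure the mixture
   proportions (f4-statistics, qpAdm-style fitting);
2. date the admixture pulse in generations from the decay of admixture
   linkage disequilibrium;
3. calibrate the radiocarbon date of the anchor individual;
4. combine (2), a generation interval, and (3) into a calendar date with
   all three uncertainties propagated.

## f4-statistics and the block jackknife

For populations A, B, C, D with alternate-allele frequencies `p`,
`f4(A,B;C,D)` is the average over SNPs of `(pA − pB)(pC − pD)`. Under a
population tree in which (A,B) and (C,D) form clades with no cross-clade
gene flow, allele-frequency changes on the (A,B) branch are independent of
those on the (C,D) branch and the expectation is zero; correlated drift —
admixture — makes it non-zero. Each statistic uses every SNP at which its
own four frequencies are defined (the "allsnps" convention), which
maximises data per statistic on sparse pseudo-haploid data; a strict
intersection can be enforced upstream with `restrict()` when exact
cross-statistic arithmetic (e.g. the additivity identity) is required on
missing data.

SNPs are linked, so naive SEs are anti-conservative. We use the weighted
delete-one-block jackknife with contiguous 5 cM blocks by default —
comfortably longer than the LD range of the statistics while leaving
hundreds of blocks genome-wide — with per-block SNP counts as weights
(unequal-weight pseudovalue scheme; it reduces to the textbook jackknife
at equal weights). The dating module jackknifes whole chromosomes instead,
because its statistic couples pairs of SNPs across the whole within-
chromosome distance range.

Frequency estimates are plain counts: a diploid call contributes two
allele slots, a pseudo-haploid call or a male X call one. No
"inbreed"-style unbiasing of frequency products is applied: with a single
sampled allele per individual there is no within-individual heterozygosity
term to correct, which is the dominant concern for these data. This is a
documented deviation from pipelines that apply small-sample corrections to
diploid panels.

## The f4 regression

`f4_regression()` fits `y = a + b·x` across populations where `x` and `y`
are f4-statistics measuring two different affinities, weighting each point
by `1/sy²` (inverse variance). Residual standard errors come from deleting
each jackknife block, rebuilding every f4 input from its per-block
decomposition, refitting, and applying the pseudovalue jackknife to the
point's residual; residual Z-scores flag populations off the cline. When
no block decomposition is supplied the leverage-based WLS formula
`sy·sqrt(1 − h)` is used instead.

## qpAdm-style mixture fitting

With sources S1..Sk and rights R0..Rm (R0 fixed as base), the system is
`y_j = f4(T, R0; R_j, R0)` and `X_ij = f4(S_i, R0; R_j, R0)`. If T is the
mixture `sum_i w_i S_i` relative to everything the rights can see, then
`y = X'w`. We minimise `(y − X'w)' Σ⁻¹ (y − X'w)` subject to `sum w = 1`,
where Σ is the block-jackknife covariance of the residual vector. Σ
depends on `w`, so the estimate and covariance are iterated to their
self-consistent fixed point — which also makes the weights invariant to
the (arbitrary) choice of base right, a property the test suite checks to
1e-6. Model fit is judged by the minimised quadratic form against
`chi²((m−1) − (k−1))`; this is the plain chi-square approximation, not the
Hotelling small-sample correction — with the block counts typical here
(hundreds) the difference is a few percent, and the null-calibration test
(uniform fit p-values over 200 null replicates) confirms the
approximation is adequate at the scales the package targets. Ill-
conditioned covariances (few rights, few blocks) get a ridge of
`1e-6 · trace/m` with a warning rather than a hard failure.

Weight standard errors come from delete-one-block refits of the whole
system. The sex-bias statistic is
`Z = (w_auto − w_X) / sqrt(se_auto² + se_X²)` for one source's weight
fitted separately on autosomes and X; because males transmit no X to sons,
a male-dominated source contributes less X ancestry, so positive Z for the
Papuan-like source means male-biased Papuan admixture.

PCA (`pca_fit_project()`) is an overview figure, not a headline number:
axes from reference samples (frequency-centred, `sqrt(p(1−p))`-normalised,
missing set to the mean), other samples placed by least squares on their
non-missing sites. Projection shrinkage ("autoshrink") is not implemented;
projected samples sit slightly toward the origin when references are few,
which does not affect the between-centroid ordering the package uses it
for.

## Dating by admixture-LD decay

A single admixture pulse `n` generations ago leaves ancestry blocks whose
covariance between loci at genetic distance `d` Morgans is
`alpha(1−alpha)·exp(−n·d)`: each generation recombination breaks ancestry
associations at rate `d`. The estimator probes ancestry through the
source frequency difference: SNP `s` has weight `w_s = p1_s − p2_s` and
individual residual `x_is = g_is/2 − mu_s`, with `mu_s` the mixture mean
at fraction `alpha`. Binned over same-chromosome pairs,

```
curve(d) = sum_pairs w_s w_t mean_i(x_is x_it) / sum_pairs |w_s w_t|
```

and `fit_exponential()` fits `A·exp(−n·d) + c` by a coarse logarithmic
grid on `n` (the model is linear in `A`, `c` given `n`) followed by local
refinement. Defaults: `binsize = 0.001` M, `mindis = 0.005` M (bins below
~0.5 cM are contaminated by background LD shared with the sources),
`maxdis = 1.0` M (detects even the long blocks of recent admixture). All
distances are Morgans; a map in cM must be converted first
(`cm_to_morgans()`), a unit trap flagged here deliberately. The affine
term `c` is fitted by default to absorb residual background covariance and
can be pinned to zero.

`alpha` is re-estimated internally by least squares on the single-SNP
signals (regressing mean target dosage on the frequency difference), with
an override for users who prefer the qpAdm estimate; the decay *rate* is
insensitive to modest error in `alpha`, which shifts mainly the
amplitude. The per-SNP normalisation above is a documented, oracle-tested
scheme chosen for transparency: it is expected to agree with established
admixture-LD software in the decay-rate parameter (the quantity used for
dating), not necessarily in amplitude.

Errors come from a delete-one-chromosome jackknife of the complete fit,
weighted by per-chromosome normalising weight. Coverage of the resulting
95% CIs is validated by simulation (100 replicates at `n = 30`; at the
test's problem size — 16 chromosomes × 1000 SNPs, 12 targets — coverage
is near-nominal; it degrades below ~10 chromosomes, where the jackknife
has too few leave-out units).

## Radiocarbon calibration

Calibration inverts a curve `mu(cal) ± sigma(cal)` under a flat calendar
prior: `posterior(cal) ∝ N(age_measured; mu(cal), sqrt(sigma_m² +
sigma(cal)²))`, normalised over the grid. Bone collagen from mixed
marine/terrestrial diets requires a blended curve: with marine-protein
fraction `p ± sigma_p` and a reservoir-corrected marine curve
(`mu + ΔR`, `sigma ⊕ sigma_ΔR`),

```
mu_mix    = (1−p) mu_T + p mu_M
sigma_mix = sqrt((1−p)² sigma_T² + p² sigma_M² + sigma_p² (mu_M − mu_T)²)
```

— mixing in the 14C-age domain with a first-order diet-uncertainty term,
which matches the behaviour of standard calibration software's curve
mixing to the accuracy relevant here. The internal posterior grid is 1
calendar year (curves are interpolated from their native 5-year grid) so
that the 95.4% highest-posterior-density region has mass within
[0.949, 0.959] regardless of how sharp the posterior is; HPD regions may
be multi-interval on wiggly curves, and the single printed "95.4% CI" is
the envelope, with the full interval list retained. Both posterior
moments (mean ± sd) and the HPD are reported, since published summaries
mix the two conventions and the HPD is generally asymmetric about the
mean.

Directions worth remembering (both verified in the tests): more *negative*
ΔR means the local ocean is closer to the atmosphere than the global
model assumes, so less of the measured age is attributed to reservoir and
the calibrated date comes out *older*; a *larger* marine diet fraction
attributes more of the measured 14C age to reservoir, so for a fixed
measurement the calibrated date comes out *younger*.

## Propagating to a calendar admixture date

The admixture date is `T + n·g` with `T` the calibrated anchor (calBP),
`n` the decay fit (generations) and `g` the generation interval
(default 28.4 ± 0.7 years). Two propagation modes:

- `propagate_gaussian()`: delta method,
  `sd² = (g·se_n)² + (n·sd_g)² + sd_T²`, CI = point ± 1.96 sd. Exact for
  the linear terms; ignores the second-order `se_n·sd_g` term of the
  product.
- `propagate_monte_carlo()`: independent draws (Gaussian for `n` and `g`;
  Gaussian *or* the full calibrated posterior for `T`), CI from the
  2.5/97.5 percentiles. Captures the product's mild non-Gaussianity; with
  1e6 draws the bounds are seed-stable to ~±3 years and agree with the
  closed form within 1% of the half-width on Gaussian inputs.

Monte Carlo percentiles are the headline numbers; the analytic mode is
reported alongside as a transparency check. The 95% multiplier is 1.96,
not 2.0; calendar bounds are reported to the year, with rounding left to
presentation. `threshold_test()` asks whether the *young* CI bound still
predates a reference horizon; a bound exactly on the threshold is flagged
as boundary, not passing — the conservative reading for a claim of
precedence. `chronology_sensitivity()` crosses the propagation with a
grid of (ΔR, diet-fraction) anchors so the precedence claim can be shown
robust, or not, to the calibration assumptions.

## The synthetic-data generator

`simulate_cohort()` emulates exactly the features the estimators consume:

- **Drift**: Balding–Nichols transitions along a small population tree —
  two sources, one clade-mate right for each source, two deep outgroups.
  The shared clade branches are essential: with purely star-shaped drift,
  the qpAdm design matrix rows would be equal in expectation and mixture
  weights unidentifiable. Defaults (terminal F 0.02–0.15, clade F
  0.06/0.08) give f4 signals and FST in the range typical of the
  Southeast Asia/Oceania panels this mirrors.
- **Admixture**: one pulse, `alpha = 0.4` Papuan-like, `n = 30`
  generations by default (the regime of interest), realised as Poisson
  ancestry tracts per haploid genome copy with i.i.d. ancestry redraws at
  breakpoints — the standard one-pulse approximation whose ancestry
  autocovariance is exactly the exponential the dating module fits. This
  is not a coalescent simulation: background LD within sources,
  time-heterogeneous recombination maps and multi-pulse histories are
  deliberately absent, so passing tests certify estimator correctness
  under the one-pulse model, not robustness to every real-data
  complication.
- **Ancient-DNA genotyping**: pseudo-haploid collapse (one allele sampled
  per site, mirroring random-read genotyping), i.i.d. missingness
  (default 5%), haploid male X, and sex-biased admixture expressed
  directly as `alpha_X ≠ alpha_autosome` (default 0.25 vs 0.40) — the
  quantity the Z-test measures — rather than via explicit per-generation
  migration sex ratios.
- **Calibration toys**: monotone linear(+wiggle) curve pairs with a
  constant reservoir offset, enough to exercise mixing, inversion, HPD
  and sensitivity logic; they are *synthetic stand-ins*, not IntCal/Marine
  approximations.

Every generator is deterministic given `seed`; truth objects (tracts,
alphas, `n`) ride along with each dataset and are read only by tests.

## Numerical choices and degenerate inputs

- Jackknife: blocks with zero weight are dropped; fewer than two blocks is
  an error. The f4 Z is defined as 0 when the estimate and SE are both 0
  (target = baseline in a scan).
- qpAdm: `k = 1` skips the weight solve (`w = 1`) and becomes a pure
  symmetry test with `df = m − 1`. A target literally duplicating a
  source's samples makes the residual exactly collinear with the source
  contrast and the fit degenerates — validation uses a target *drawn
  from* the source population instead.
- Decay fit: at least 5 usable bins; a non-positive fitted amplitude is
  reported as "no decay signal" rather than returning a meaningless rate;
  the grid search spans 0.5–500 generations logarithmically before local
  refinement, so initialisation cannot latch onto a local optimum at the
  scales tested.
- Calibration: a measurement with vanishing likelihood everywhere on the
  curve errors out ("off curve") instead of returning a normalised
  artefact.
- Problem sizes in the test suite (thousands of SNPs per chromosome, tens
  of samples, 100–200 replicate nulls) were chosen as the smallest scales
  at which the statistical properties under test are stable; the same
  estimators run unchanged on panels hundreds of times larger.

## Known limitations

- Single-pulse dating only: continuous or multi-pulse admixture biases
  `n` toward an average; founder-event and phase-aware variants are out
  of scope.
- The chi-square model-fit p-value lacks the Hotelling correction; with
  very few blocks it is slightly anti-conservative.
- No frequency-product unbiasing for small diploid reference panels.
- PCA projection has no shrinkage correction.
- Calibration assumes a flat calendar prior and independence between the
  anchor's date and the decay fit; Bayesian sequence modelling across
  multiple anchors is not attempted.
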