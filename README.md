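# admixchron

Ancestry statistics and calendar dating of admixture events from ancient
DNA.

`admixchron` is an R toolkit for a question that comes up repeatedly in
archaeogenetics: **when, in calendar years, did two ancestral populations
mix to form the people sampled at an archaeological site?** It was built
around the analysis of Papuan–East Asian admixture in ancient Remote
Oceania, but every stage is generic. The package chains five pieces of
machinery that are usually run as separate command-line tools, and makes
the whole chain testable against simulated cohorts with known truth:

1. **f4-statistics** with weighted block-jackknife errors — tests of
   treeness/admixture of the form
   `f4(A, B; C, D) = E[(pA − pB)(pC − pD)]`, plus symmetry scans and an
   inverse-variance-weighted f4 regression with jackknife residual
   Z-scores.
2. **qpAdm-style mixture fitting** — a target's f4 profile against a set of
   "right" outgroups is expressed as a mixture of source profiles; weights
   are estimated by constrained generalised least squares with a
   block-jackknife covariance, with a chi-square model-fit p-value, and an
   autosome-vs-X Z-test for sex-biased admixture.
3. **Admixture-LD decay dating** — the covariance of ancestry between
   linked loci decays as `A·exp(−n·d) + c` with distance `d` in Morgans;
   the decay rate `n` is the age of the admixture pulse in generations,
   with a delete-one-chromosome jackknife error.
4. **Radiocarbon calibration** — mixed terrestrial/marine calibration with
   marine reservoir offsets (ΔR) and diet-fraction uncertainty, returning
   full posteriors and 95.4% HPD intervals.
5. **Uncertainty propagation** — the calendar admixture date is
   `T + n·g` (anchor date + generations × generation interval); its three
   uncertainties are combined analytically (delta method) and by Monte
   Carlo, with sensitivity grids over ΔR and diet fraction and a
   threshold test ("does the whole CI predate event X?").

A first-class synthetic-data module (`sim_config()`, `simulate_cohort()`)
generates pseudo-haploid admixed cohorts with known mixture proportion,
admixture time, sex bias and drift, plus toy calibration curves, so the
entire pipeline runs and is validated without any external downloads.

## Worked example

Simulate a cohort whose truth is 40% Papuan-like ancestry acquired 30
generations before sampling, then recover both numbers:

```r
library(admixchron)

cfg <- sim_config(n_snps_per_chrom = 2000, n_chroms = 20, n_admixed = 20,
                  alpha_autosome = 0.4, admixture_generations = 30, seed = 42)
coh <- simulate_cohort(cfg)

model <- admixture_model("Admixed", c("SourceEA", "SourcePAP"),
                         c("RightDeep1", "RightEA", "RightPAP", "RightDeep2"))
qpadm(coh$ds, model)
#> <admixture_fit> target Admixed ~ SourceEA + SourcePAP
#>   SourceEA     0.605 +/- 0.008
#>   SourcePAP    0.395 +/- 0.008
#>   fit: chisq 1.85 on 2 df, p = 0.396 (40000 SNPs, 400 blocks)

adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
fit <- fit_exponential(
  ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP"))
fit
#> <decay_fit> n = 30.9 +/- 3.4 generations (95% CI 37-24), A = 0.00341, c = 2.31e-05
```

The estimated proportion (39.5% ± 0.8%) and date (30.9 ± 3.4 generations)
recover the simulated truth within one standard error. Converting a decay
fit of 30.1 ± 3.5 generations to calendar years with a generation interval
of 28.4 ± 0.7 years and a calibrated anchor of 2799 ± 53 calBP:

```r
propagate_monte_carlo(30.1, 3.5, 28.4, 0.7, 2799, 53, n_draws = 1e6, seed = 1)
#> <propagated_date> 3654 +/- 115 calBP, 95% CI 3880-3430 (monte_carlo)
threshold_test(propagate_monte_carlo(30.1, 3.5, 28.4, 0.7, 2799, 53,
                                     n_draws = 1e6, seed = 1), 3200)
#> # A tibble: 1 x 4
#>   predates margin boundary threshold
#>   <lgl>     <dbl> <lgl>        <dbl>
#> 1 TRUE       230. FALSE         3200
```

The point estimate is the anchor plus `30.1 × 28.4 ≈ 855` years; the
standard deviation combines the three error sources in quadrature; the
verdict says the entire 95% CI is older than a 3200 calBP reference
horizon, with about 230 years to spare.

The full chain — simulate, f4 scan, qpAdm (autosomes and X), PCA, dating,
calibration, propagation, sensitivity grid, figures — runs from one YAML
config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "admixchron"))
```

## Notes

- Genotypes are read/written in EIGENSTRAT format (`.geno`/`.snp`/`.ind`,
  packed or unpacked); genetic positions are Morgans throughout.
- Real calibration curves (IntCal20, Marine20) are user-supplied `.14c`
  files (freely available from intcal.org); the test suite and demo use
  synthetic curves only.
- The methods vignette (`vignettes/admixture-chronology.Rmd`) documents the
  statistical models, defaults and their rationale, and known limitations.
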