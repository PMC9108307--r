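# domadmix

Quantifying introgression of domesticated Atlantic salmon into wild
populations — and what it does to their life history.

Escapees from salmon farms interbreed with wild fish; after a few
generations a river population carries variable per-individual *admixture*,
the fraction of the genome attributable to the domesticated source (0 = pure
wild, 1 = pure domesticated). `domadmix` implements, as a tested and
reusable R pipeline, the full inference chain used to measure that admixture
from SNP-array genotypes and relate it to phenotypes:

1. **Marker QC and panel selection** — call-rate filters (SNP 0.97, sample
   0.85), per-locus Weir–Cockerham $F_{ST}$
   ($\hat\theta = a/(a+b+c)$, negative estimates retained, multilocus value
   as ratio of summed components), DAPC locus contributions (mean-impute,
   centre/scale, PCA, one discriminant axis back-projected to loci), and a
   panel formed as the **intersection** of the top-$q\%$ lists under both
   criteria (`filter_call_rate()`, `weir_cockerham_fst()`,
   `dapc_contributions()`, `select_panel()`).
2. **Supervised admixture estimation** — one unlabeled test individual per
   run against fixed wild/farm reference panels (leave-one-in protocol),
   under the two-population admixture model with uncorrelated frequencies
   and Beta(1) priors. A Gibbs sampler (default 10,000 burn-in / 100,000
   sweeps, batch-means Monte-Carlo SE) and a deterministic EM engine share
   the likelihood (`estimate_admixture_single()`, `leave_one_in()`).
   Raw estimates are calibrated with held-out reference self-assignment
   means: $(\,p(\text{wild}) - \mathrm{Farm}_{ref})/(\mathrm{Wild}_{ref} -
   \mathrm{Farm}_{ref})$ (`compute_reference_constants()`, `calibrate()`).
3. **Validation** — simulated F1 hybrids (true admixture 0.5, frequency-based
   gametes via `hybridize()`) scored by mean squared error and the empirical
   central 95% interval (`evaluate_hybrid_accuracy()`).
4. **Association models** — linear models
   $Y = \mathrm{SW} + \mathrm{sex} + \mathrm{admix} + \mathrm{year} + e$
   for size and river-entry date (1-df partial-F admixture test), and
   binomial logit models with an admix×sex interaction for 3-year smolt age
   and one-sea-winter maturation, with per-sex likelihood-ratio tests and
   sex-specific probability curves (`fit_size_model()`,
   `fit_growth_model()`, `fit_binary_model()`, `predict_at_admixture()`).

A synthetic-data module (`sim_baseline_frequencies()` — Balding–Nichols
divergence, `sim_genotypes()`, `sim_admixed_genotypes()`,
`sim_missingness()`, `sim_phenotypes()`) generates systems with known truth,
so every stage is testable without any field data. Genotypes travel as
dosage TSV or VCF, phenotypes as CSV, and a classic STRUCTURE-format
writer/reader is included (`write_structure_file()`).

## Worked example

Simulate a study-shaped system (2,000 candidate loci at expected
$F_{ST} = 0.15$, 150+150 references with 40+40 calibration holdouts, 750
contemporary individuals with Beta(2, 6) true admixture) and run every
stage:

```r
library(domadmix)

cfg <- pipeline_config(
  seed = 42,
  simulate = list(n_loci = 2000, divergence = 0.15, n_wild_ref = 150,
                  n_farm_ref = 150, n_contemporary = 750,
                  admixture_beta = c(2, 6)),
  panel    = list(fraction = 0.05),
  sampler  = list(engine = "em", burn_in = 1000, repetitions = 10000),
  holdout  = list(n_wild = 40, n_farm = 40),
  validate = list(n_hybrids = 100),
  associate = c("return_day", "smolt_age_3plus"))
res <- run_pipeline(cfg, "run1")

res$constants
#> calibration constants: Wild_ref = 0.9807 (n = 40), Farm_ref = 0.0233 (n = 40)
res$distribution$mean_calibrated_admixture
#> 0.243
res$accuracy
#> F1 accuracy: 100 hybrids, 80 markers
#>   mean estimate 0.493, MSE 0.0027, central 95% interval [0.403, 0.589]
res$models$return_day
#> ...
#> admixture         20.2229     5.9876  3.3775   0.0008
#> admixture term: df = 1, F = 11.4, p = 0.00077
#> predictions at fixed admixture:
#>  admixture      fit      lwr      upr       se      date
#>        0.0 199.3258 195.8640 202.7875 1.766207   July 18
#>        0.5 209.4372 206.0052 212.8693 1.751041   July 28
#>        1.0 219.5487 210.5800 228.5173 4.575832 August 08
res$models$smolt_age_3plus$admix_test
#>      sex df chi_square    p_value
#> 1 female  1 0.03286206 0.85614863
#> 2   male  1 4.02987641 0.04470122
```

Reading the output: the calibration constants show that even held-out pure
reference fish do not self-assign at exactly 1 or 0, which the affine
calibration corrects; the population mean calibrated admixture lands at 24%
(the generator draws truth with mean 25%); F1 hybrids are recovered at 0.49
with MSE 0.003; fully admixed fish are predicted to enter the river ~20 days
later than nonadmixed fish (the generating value, 26 days, sits inside the
95% CI), around a mid-July baseline; and the 3-year-smolt probability
declines with admixture in males but not females — the sex-specific pattern
the generator encodes.

## Package layout

* `R/simdata.R` — synthetic genotype/phenotype generators
* `R/qc_markers.R` — QC, $F_{ST}$, DAPC, panel selection
* `R/admixture.R` — supervised estimation engines and calibration
* `R/validation.R` — F1 accuracy and admixture-distribution summaries
* `R/phenomodels.R` — association models and predictions
* `R/io.R`, `R/pipeline.R` — formats, config, end-to-end driver
* `vignettes/admixture-pipeline.Rmd` — methods: model, assumptions,
  parameter choices, limitations
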