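---
title: "Quantifying domesticated-salmon admixture and its phenotypic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying domesticated-salmon admixture and its phenotypic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domadmix)
```

## The problem

Escaped domesticated Atlantic salmon interbreed with wild populations, and
after several generations a wild river population carries variable individual
levels of *admixture*: the fraction of each fish's genome attributable to the
domesticated source, expressed on a scale from 0 (pure wild ancestry) to 1
(pure domesticated). `domadmix` implements the complete inference chain needed
to quantify that admixture from SNP array genotypes and to relate it to life
history traits:

1. call-rate QC of genotypes and selection of a compact ancestry-informative
   marker panel (per-locus Weir–Cockerham $F_{ST}$ jointly with DAPC
   discriminant contributions);
2. supervised per-individual admixture estimation against historical-wild and
   farm reference panels, with reference-based affine calibration;
3. accuracy validation on simulated F1 hybrids;
4. linear and binomial-logit association models between admixture and
   phenotypes (river-entry date, size, smolt age, age at maturation).

Because the motivating field data (a wild river population sampled at an
upstream trap, plus historical and farm reference collections) cannot be
bundled, a first-class synthetic-data module generates genotype and phenotype
systems with exactly the statistical structure the estimators assume, so every
stage is testable end to end.

## Marker selection

Samples are filtered at a call rate of 0.85 and SNPs at 0.97 (samples first,
then loci; both strict). For the two reference pools the package computes, per
locus:

* the Weir & Cockerham (1984) variance-components estimator
  $\hat\theta = a/(a+b+c)$, with missing genotypes excluded pairwise,
  negative estimates retained, and the multilocus value formed as
  $\sum_\ell a_\ell / \sum_\ell (a+b+c)_\ell$ (ratio of sums, not mean of
  ratios);
* a DAPC contribution: dosages are mean-imputed, centred, scaled by the
  binomial standard deviation $\sqrt{2p(1-p)}$ (allele frequency floored at
  0.005 so near-monomorphic loci do not explode), reduced by PCA to
  $\min(\lfloor n/3\rfloor, 100)$ components, a linear discriminant axis is
  fitted to the scores for the two groups, and the axis is back-projected to
  locus space; the squared locus coordinates are normalised to sum to one.

A panel at fraction $q$ is the **intersection** of the top $\lceil qL\rceil$
loci by $F_{ST}$ and by DAPC contribution. We read "simultaneously the
highest $q\%$" as set intersection because it is the only reading under which
the panel can be, and in practice is, smaller than $\lceil qL\rceil$
(e.g. 142 markers where 1% of 22,571 loci would be 226). Ties are broken by
locus order; the quantile base is the QC-passing loci (configurable). Whether
the DAPC inputs should be scaled as well as centred is genuinely open; both
modes are exposed (`scale =` in `dapc_contributions()`), scaling being the
default because it stops high-frequency loci from dominating the PCA.

## Supervised admixture estimation

Each test individual is estimated in its own run against fixed reference
panels (the leave-one-in protocol). The model is the two-population
admixture model with uncorrelated allele frequencies: conditional on the
individual's wild proportion $q$, each of its two allele copies at locus
$\ell$ originates from the wild pool with probability $q$ and carries the
reference allele with that pool's frequency. Reference individuals enter the
frequency conditionals as fixed-origin data with a symmetric Beta($\lambda$),
$\lambda = 1$, prior. This is a deliberate, documented divergence from
STRUCTURE's default *correlated*-frequencies model, whose extra hierarchy is
unidentifiable from a single test individual and unreported in the protocol
we follow.

Two engines share this likelihood:

* **Gibbs** — samples latent per-copy origins, then
  $q \sim \mathrm{Beta}(1 + \#\text{wild copies}, 1 + \#\text{farm copies})$,
  then per-locus frequencies with the assigned test copies folded in.
  Defaults are 10,000 burn-in and 100,000 retained sweeps; the posterior mean
  of $q$ is reported with a batch-means Monte-Carlo standard error.
* **EM** — fixes each reference frequency at its posterior mean
  $(\text{count}+\lambda)/(\text{total}+2\lambda)$ and maximises the
  individual's likelihood over $q$ by EM to $10^{-10}$. It is deterministic,
  orders of magnitude faster, and the test suite verifies it coincides with a
  brute-force likelihood grid (step 0.001) and with the Gibbs posterior mean
  within Monte-Carlo error.

Per-individual seeds derive from the base seed and the individual id, so
batch results are invariant to processing order.

**Calibration.** Held-out wild and farm reference individuals (100 + 100 by
default), never members of the reference panels — the protocol does not say
whether the original holdouts were excluded from their own reference panels;
we enforce exclusion because self-assignment of a panel member would bias the
constants upward — are run as unlabeled tests. Their group means
$\mathrm{Wild}_{ref}$ and $\mathrm{Farm}_{ref}$ define the affine rescaling

$$\text{proportion of wild genome} =
  \frac{\bar p(\text{Wild}) - \mathrm{Farm}_{ref}}
       {\mathrm{Wild}_{ref} - \mathrm{Farm}_{ref}},$$

applied by `calibrate()`. Calibrated values are unclamped by default (they
can fall slightly outside $[0,1]$; a flag clamps). Association models use the
*raw* admixture $1 - p(\text{wild})$, reserving calibration for
population-level summaries, which is how the protocol applies it.

## Validation on simulated hybrids

`hybridize()` generates F1 individuals by drawing, per locus, one gamete from
each parental pool's *empirical allele frequency* (matching the behaviour of
the classical `hybridize` tool; a pair-sampling variant is behind
`method = "pairs"`). Every F1 has true admixture 0.5.
`evaluate_hybrid_accuracy()` reports the mean squared difference from 0.5 and
the empirical central 95% interval, taken as the 2.5/97.5 percentiles — the
natural operationalisation of "95% of estimates were included in the
interval"; a min/max-after-trimming reading would be compatible but less
stable, and the choice is flagged here.

## The synthetic-data generator

No generative model is stated for the real wild–farm differentiation, so the
generator uses the Balding–Nichols model: ancestral frequencies uniform on
$[0.05, 0.95]$, each population's frequency drawn from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$. The divergence parameter $F$ is
documented as an expected $F_{ST}$ and defaults to 0.15 — a stand-in for the
unpublished empirical distribution of the QC-passing SNPs, and deliberately
configurable. Genotypes are Binomial(2, freq) dosages; admixed individuals
draw each allele copy from the wild frequency with probability $q$;
missingness is injected independently per entry from locus and sample rates.
True admixture of contemporary simulants follows Beta(2, 6) (mean 0.25,
matching the ~24% population mean reported for the motivating river).

What the generator does **not** emulate: linkage disequilibrium, pedigree
structure over generations, selection, batch effects in genotyping, or any
correlation between missingness and genotype. Passing tests therefore show
the estimator chain is correct *under its own assumptions*; they do not show
robustness to LD between panel markers or to ascertainment bias of the array.

Phenotypes follow
$Y = \mathrm{SW} + \mathrm{sex} + \beta\,\mathrm{admix} + \mathrm{year} + e$
for continuous traits and logit-linear Bernoulli models with an
admix-by-sex interaction for the two binary traits. Defaults reproduce the
published contrasts: +26 days river-entry delay per unit admixture around a
July 16 baseline; +3.8 cm / +0.7 kg (males) and +8.3 cm / +1.9 kg (females)
at return; +2.0 cm smolt length; +5.0 cm first-sea-winter length; male
P(3-year smolt) falling from 57% at admixture 0 to 11% at admixture 1 (so
89% migrate as 2-year smolts), with no female effect. Quantities never
printed were fixed once at field-plausible values: residual sds of 25 d
(return day), 5 cm (length), 1 kg (weight), 2 cm (smolt length), 3.5 cm
(first-sea-winter length); intercepts 197 d, 65 cm, 3.5 kg, 12 cm, 35 cm;
male P(1 sea winter) 0.30 at admixture 0 with logit slope +1.5 (females
flat). Year and sea-winter effects default to zero but the columns are always
generated as factors so model code must handle them.

## Association models

`fit_size_model()` fits the linear model above by least squares (sex and
year categorical, female/first-year reference levels; sea winters numeric)
and tests the admixture term by the 1-df partial F, which for a single-df
term equals the squared t of its coefficient (asserted to $10^{-10}$ in the
tests). `fit_growth_model()` drops the sea-winter covariate for the
back-calculated lengths. `fit_binary_model()` codes the admix-by-sex
interaction as separate female and male admixture slopes and reports, per
sex, the 1-df marginal (drop-one) likelihood-ratio chi-square — the exact
test construction behind the published sex-specific statistics is unstated,
and marginal tests are the defensible default. The smolt-age analysis is
restricted to ages 2–3 (99% of fish; others counted and dropped). The "+ e"
written in the source logit formulas is read as the binomial error structure,
since a GLM has no additive residual term. Complete separation is detected
(perfect classification or diverging coefficients) and raised as an explicit
error.

Predictions at admixture 0 / 0.5 / 1 are population-averaged: numeric
covariates at their means, factor levels at observed frequencies — the
covariate profile behind the published predicted dates is unstated, so exact
reproduction of July 16 / July 27 / August 10 is not claimed; with the
generator defaults the predicted contrast is 26 days and the baseline lands
mid-July. Day-of-year predictions are rendered as calendar dates by
day-of-year arithmetic in the stated year. Logit-scale bands use the delta
method and are inverse-logit transformed, matching the standard construction
of GLM confidence ribbons.

## Numerical choices and degenerate inputs

* EM convergence $|q_{t+1}-q_t| < 10^{-10}$, max 1000 iterations; $q$ can
  reach the boundary and the grid-equivalence test covers that case.
* $F_{ST}$ is `NA` (never selected) for loci monomorphic overall or with
  fewer than two non-missing genotypes in either population.
* Rank ties (identical $F_{ST}$ or contributions) break by locus order.
* A zero-divergence system yields a near-uniform contribution vector and a
  valid (if uninformative) panel — a warning, not a crash, if intersection is
  empty.
* A single capture-year level is absorbed into the intercept rather than
  raising a rank-deficiency error; genuinely aliased covariates raise an
  error naming the offending columns.
* Rows with missing model variables are dropped listwise and counted.

## Problem sizes used by the test suite

The shipped tests exercise the full study geometry once — 20,000 loci,
250+250 references, a ~1% panel, 200 F1 hybrids with the EM engine — and use
smaller systems (hundreds of loci, tens of individuals, shortened Gibbs
chains) for the oracle, property and invariant suites: 50 EM-vs-grid
instances, 50 random $F_{ST}$ loci against the hand-coded 1984 transcription,
50 parameter-recovery replicates at n = 750, and 500 reduced replicates for
the type-I error of the admixture F test. These sizes give stable pass/fail
behaviour at nominal tolerances while keeping the default suite quick.

## Known limitations

* Strictly supervised, two populations, K = 2; no unsupervised clustering,
  no correlated-frequencies prior, no linkage model.
* The Gibbs engine treats loci as independent; with markers selected for
  extreme differentiation on a real genome, residual LD would understate the
  Monte-Carlo error.
* Calibration is affine and global; it corrects mean shift from imperfect
  reference separation but not compression that varies with true admixture.
* The phenotype generator is a statistical emulator, not a biological model:
  effect sizes are linear on the chosen scales and noise is Gaussian.
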