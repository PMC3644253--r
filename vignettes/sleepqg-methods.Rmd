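---
title: "Models and methods behind sleepqg"
author: "sleepqg developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sleepqg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepqg)
```

# The problem

Panels of fully inbred lines (a DGRP-style reference panel) turn a
quantitative trait into a replicable quantity: every line is a fixed
homozygous genotype that can be measured in many individuals, so both the
*mean* of a trait and its *within-genotype environmental variability* are
heritable quantities that can be mapped. `sleepqg` implements that program
for Drosophila sleep measured with activity monitors: sleep phenotyping
from beam-crossing streams, variance partitioning and broad-sense
heritability for trait means and for the coefficient of environmental
variation (CV~E~), single-SNP genome-wide association with
genotype-by-sex models, LD/inversion proxy collapsing, and iterative
additive multi-SNP models — all exercised against a bundled synthetic-data
generator, because the original panel's raw data are not redistributable at
package scale.

# Sleep phenotypes

A fly's record is a minute-binned count vector over seven 24-h days under a
12 h light : 12 h dark cycle, starting at lights-on. A *sleep bout* is a
maximal run of zero-count minutes lasting at least `min_bout = 5` minutes
(the standard five-minute inactivity rule). Seven traits are derived per
fly: night and day sleep duration (minutes per 12-h phase, averaged over
days), night and day bout number, night and day average bout length, and
waking activity (total counts divided by total non-sleeping minutes).

Two conventions had to be fixed where the field's tooling is silent:

* **Boundary-spanning bouts** are split at the phase transition and each
  segment counts as one bout in its phase *without* re-applying the
  five-minute rule. This keeps per-phase sleep additive (day + night sleep
  equals total qualifying zero-run minutes) at the cost of occasionally
  scoring a sub-5-minute segment as a bout.
* **Waking activity** is computed over the whole record, not per phase.

Dead flies cannot be identified by visual inspection in silico; the
deterministic stand-in flags a fly whose final 24 h contain no counts
(`detect_dead`). Flagged flies are excluded from all phenotype tables.

The environmental coefficient of variation is computed per line x sex x
replicate cell as CV~E~ = (sigma~E~ / mu) x 100, with the sample (n-1)
standard deviation as sigma~E~. Cells with fewer than two flies or a
non-positive mean are dropped with a logged reason.

# Variance partitioning and heritability

The observational model is the nested mixed ANOVA

Y = mu + B + S + L(B) + SxL(B) + R(B) + SxR(B) + RxL(B) + SxRxL(B) + e

with sex S fixed and block B, line L and replicate R random. Components
are estimated by REML (lme4, bobyqa with a tight convergence tolerance).
Pooled broad-sense heritability is
H^2^ = (sigma^2^~L~ + sigma^2^~SL~) / (sigma^2^~L~ + sigma^2^~SL~ +
sigma^2^~E~), where sigma^2^~E~ is the sum of every other component;
per-sex fits use the reduced model and
H^2^ = sigma^2^~L~ / (sigma^2^~L~ + sigma^2^~E~). Negative estimates are
truncated at zero only inside ratios. The cross-sex genetic correlation is
r~MF~ = sigma^2^~L~(pooled) / sqrt(sigma^2^~LM~ sigma^2^~LF~), and
between-trait genetic correlations are product-moment correlations of
sex-averaged line means — with 32 flies per sex per line the line-mean
sampling error is small, and a full bivariate REML would add machinery
without changing the conclusions the package is tested on.

Component significance, when requested, is a REML likelihood-ratio test of
the component-deleted model with the 0.5(chi^2^~0~ + chi^2^~1~) boundary
correction.

**A subtlety worth recording.** On balanced data, ANOVA (expected mean
squares) estimators usually coincide with REML. We verified numerically
that the pooled model above *lacks orthogonal block structure*, because it
contains SxR(B) but omits SxB; its canonical decomposition has one more
stratum than it has variance parameters, and REML genuinely differs from
the method of moments there. The EMS cross-check oracle
(`ems_variance_components`, an exact projection-based solver) is therefore
asserted to match REML only where the theory guarantees it: per-sex
reduced fits, and pooled fits on a single block. Agreement there is limited
only by optimizer termination (~1e-5 relative).

An isogenic control line measured in every block distinguishes
environmental block effects from line-sampling block effects
(`control_block_check`): Y = mu + B + S + BxS + R(B) + SxR(B) + e, with B
tested over R(B) and BxS over SxR(B). Endosymbiont (Wolbachia) infection
is tested on line x sex means with infection over the line stratum; where
significant at alpha = 0.05 for a trait x sex, that sex's line means are
centered within infection class, which preserves the grand mean exactly.

# Genome-wide association

The unit of observation for GWA is the line x sex mean (pooled model) or
the per-sex line mean (reduced model); per-fly data are never used. Sites
enter the scan if their minor allele is present in at least 4 lines and
sequence coverage is strictly between 2 and 30; with 168 lines the minimum
testable MAF is 4/168 = 2.4%.

The pooled model Y = mu + SNP + S + SNPxS + L(SNP) + e is a split-plot:
lines are whole plots, sex is the sub-plot factor. The SNP F statistic
uses MS(SNP)/MS(L(SNP)) — lines are the error stratum for genotype, which
protects against pseudo-replication over sexes — and SNPxS is tested over
the residual. With both sexes present in every line this reduces exactly
to two one-way ANOVAs (on sex-averaged line means, and on within-line
male-female differences), which is how the genome scan is vectorized; the
equivalence to a generic least-squares decomposition is asserted to 1e-8
in the acceptance suite.

Per-trait p-value lists (pooled, male, female) each get Benjamini-Hochberg
step-up q-values; the significant set is q <= 0.01. Effects are reported
as a (half the difference between marker-class means, signed
major-minus-minor), a/sigma~P~ (sigma~P~ = SD across line x sex means),
and the genetic variance V~G~ = 4pqa^2^ appropriate to an inbred panel.
Significant sites are classified *sex-specific* (significant in one sex),
*sex-antagonistic* (both sexes, opposite signs), *sex-biased* (both sexes,
same sign, interaction p < 0.05) or *equal*; the interaction threshold is
the package's operationalization of "greater effect in one sex", which has
no canonical numeric criterion.

Site classes (CDS > 5'UTR > 3'UTR > intron > intergenic) come from GFF3
interval containment via GenomicRanges.

# LD, inversions and proxy SNPs

For homozygous lines every line is one haplotype, so r^2^ between two
sites is both the squared Pearson correlation of 0/1 columns and
D^2^/(p~1~q~1~p~2~q~2~); the package computes the former and tests the
identity against a haplotype-counting oracle to 1e-12. There is no
canonical definition of a "region of local LD"; the package uses
single-linkage chaining (r^2^ >= 0.8 within a configurable max gap,
transitive closure per arm) and exposes both knobs. Segregating
inversions, scored presence/absence per line, are tested with the
fixed-effects model Y = mu + Inv + S + InvxS + e on line x sex means.
Significant sites inside a trait-associated inversion collapse to one
proxy per inversion; each LD block collapses to its most significant
member (ties by position); the output reports raw and collapsed counts.

# Multi-SNP models

Forward selection on per-sex line means fits
Y = mu + SNP~1~ + ... + SNP~N~ + e, adding at each step the candidate with
the smallest partial-F p-value given the sites already selected. A raw-R^2^
"maximal" rule cannot terminate before saturation, so the default stop is
the first step at which adjusted R^2^ would decrease, with a partial-F
p > 0.05 stop exposed as the alternative. Reported per-step R^2^ values
are recomputed by exact least squares on the selected sites, so refitting
reproduces them to numerical precision. The fraction of *genetic* variance
explained divides adjusted R^2^ by the trait's per-sex H^2^ (the divisor is
a package choice; a phenotypic-variance denominator would only rescale),
capped at 1 with a warning.

# The synthetic panel

The generator states one world and the tests measure it; its defaults are
not tuned to outcomes.

* **Design:** 168 lines in 4 disjoint blocks, 4 replicates per block, 8
  flies per sex per replicate (32 flies/sex/line), 7 recording days.
* **Genotypes:** biallelic homozygous sites; minor-line count k from
  P(k) ~ k^-2.9 over 4..n/2, placing ~80% of sites at MAF <= 0.05 (the
  low-frequency skew reported for panel-significant sites); coverage in
  3..29 so every emitted site passes the GWA filter. Local LD blocks copy
  an intermediate-frequency template with per-line flip probability
  1 - copy_fidelity (a rare template would not survive flips as a
  recognizable haplotype); in-inversion sites track per-line karyotypes
  the same way.
* **Phenotypes:** the observational model run forward, in minutes of night
  sleep: mu = 500, sigma^2^~L~ = 4800, sigma^2^~SL~ = 600 and environmental
  terms summing to 4600, i.e. H^2^ = 0.54 exactly (the reported night-sleep
  point). Causal-site variance counts *inside* the targets; the polygenic
  remainder tops them up.
* **Environmental variance:** residual SD per line is exp(log sigma~E~),
  with genetic variance 0.09 on the log scale (chosen to put H^2^(CV~E~)
  near the reported ~0.7 for night sleep) and correlation -0.8 with the
  polygenic mean — short-sleeping lines are the most environmentally
  sensitive. The log scale guarantees positivity; the intercept is solved
  so the mean residual variance hits its target exactly.
* **Activity:** a two-state sleep/wake Markov chain per minute with
  phase-specific transition probabilities (defaults give ~600 min night
  sleep, ~40 min night bouts); wake minutes carry 1 + Poisson counts; a
  configurable fraction of flies dies with an all-zero suffix >= 24 h, so
  the dead-fly detector is exercised rather than bypassed.
* **Residual distribution within line x sex is Gaussian** — a stated
  default, not a claim about real flies.

What a green test does *not* establish: the generator has no sequencing
error, no missing genotypes by default, no real chromosome lengths or
allele-frequency spectra per site, genetically independent traits on the
direct route (the activity route derives all seven traits from one stream,
hence correlated), and Gaussian within-line residuals. Recovery results
say the estimators are consistent with their own model, not that the model
is true.

# Pipeline and reproducibility

`run_pipeline()` orchestrates simulate, phenotype, quantgen, gwas, ld and
multisnp stages; stages communicate only through TSV files in the run
directory, so any stage can be replaced by user-supplied tables of the
same layout. The default phenotype route draws per-fly values directly
from the observational model; the `activity` route (full DAM-dialect
streams through the sleep-metrics stage) is exact but an order of
magnitude heavier at panel scale, so it is the tested-but-not-default
path. One global seed drives every stream through fixed offsets; identical
config + seed give byte-identical outputs, recorded with MD5 sums in
`manifest.json`.

# Numerical notes and limitations

* Monomorphic genotype columns get p = 1 by convention (with a warning);
  they cannot occur after filtering.
* Ties in forward selection and proxy choice break by genomic order /
  smaller position, for determinism.
* `r_MF` is clipped to [-1, 1] for reporting (raw value kept as an
  attribute); cross-sex and trait correlations are undefined (NA) when a
  variance in the denominator is zero.
* The LRT boundary correction halves the chi-squared tail; it is
  conservative for components other than the one tested.
* No kinship/relatedness correction and no imputation: the panel is
  assumed unstructured and fully genotyped, per its published design.
* The Beavis effect (inflation of effect sizes at selected sites) is real
  and unmodelled; planted-effect recovery tests condition on the truth,
  not on significance, and are immune to it, but users comparing V~G~ sums
  to heritability on real data should expect inflation.
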