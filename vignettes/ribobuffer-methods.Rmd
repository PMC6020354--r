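---
title: "Methods: cross-species divergence and buffering across the expression cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species divergence and buffering across the expression cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Gene regulation acts in layers: transcript abundance (RNA-seq), ribosome
occupancy (ribosome profiling, a proxy for translation), and steady-state
protein level (quantitative mass spectrometry, here SILAC-style log ratios).
When two closely related species differ at one layer, the difference may
propagate downstream, or be attenuated — *buffered* — at the next layer.
`ribobuffer` implements the statistical machinery for asking, gene by gene:

* Is the gene differentially expressed between species at a given layer?
* Is its **translation efficiency** (occupancy beyond what transcript level
  explains) divergent?
* Is a divergence present upstream but *absent* downstream
  (**translational** buffering: RNA diverged, occupancy not;
  **post-translational** buffering: occupancy diverged, protein not)?

All tests run on a common representation: gene x sample log2 matrices with
optional per-observation precision weights, and tibble results with effect,
moderated t, nominal p, Bonferroni FWER, BH FDR and Storey q-value columns.

## Normalisation

Counts are filtered for joint quantifiability (at least one read in at least
three individuals of *every* species), scaled with TMM factors, transformed
to `log2((count + 0.5) / (lib * factor + 1) * 1e6)` (log2 CPM), and
converted to log2 RPKM by subtracting `log2(length / 1000)` with the gene
length of the *sample's* species — orthologous exonic lengths differ between
species, and using each species' own length keeps the values comparable.
Observation-level precision weights come from the mean-variance trend of the
log2 CPM values (voom). Protein log ratios are centred per sample at a 30%
trimmed mean; genes need non-missing ratios in at least three individuals
per species.

Two expression-category calls are provided for genes that fail the joint
filter: "expressed in species s" (mean within-species linear RPKM above a
threshold, conventionally the first quartile of detectable-gene RPKM, plus
at least three quantifiable individuals) and "specific to s" (expressed in s
and quantifiable in at most one individual of each other species). The
threshold is taken on the linear RPKM scale; `rpkm_q1_threshold()` computes
it by pooling per-species mean RPKM of detectable genes — the pooling rule
is this package's choice, documented here because the convention is not
fixed by the method family.

## Batch adjustment

`adjust_batch_eb()` is a parametric empirical-Bayes location/scale
adjustment: per gene the data are standardised against a least-squares fit
that protects chosen covariates (species by default — a cross-species matrix
whose batches are not balanced across species would otherwise lose real
signal; a flag disables protection), per-batch per-gene location and scale
estimates are shrunk toward normal / inverse-gamma priors whose
hyperparameters come from method-of-moments across genes, and the data are
back-transformed. The EB iteration runs to a relative change of 1e-8.
Missing values are excluded from estimation and preserved in the output.
Samples included only to make a batch estimable can be dropped after
adjustment (`keep_individuals` in `run_pipeline()`).

Two properties worth stating precisely: shrinkage places every adjusted
batch location between the raw estimate and the prior mean; but the
adjustment is *not* exactly idempotent for multiple batches (a second pass
re-shrinks the noise-level batch means and moves values by an amount of
order noise/sqrt(n)), and per-gene grand means are preserved only
approximately under balanced designs — exact preservation would require the
no-shrinkage limit. The tests assert the single-batch identity and a small
tolerance for the balanced case. Routing a nuisance label such as sex
through `batch_key` removes that effect with the same machinery.

## The divergence tests

Every test is a gene-wise (weighted) least-squares fit plus empirical-Bayes
variance moderation:

* the residual variances `s_g^2` with `d_g` residual df are modelled as
  scaled F variates around a prior `s_0^2` with prior df `d_0`, estimated by
  matching mean and variance of `log s_g^2` via the digamma/trigamma system;
* the posterior variance `(d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)` replaces
  `s_g^2`, and `t = beta / (s~ * unscaled SD)` is referred to a t
  distribution with `d_0 + d_g` df (the normal limit when `d_0` is
  infinite; when the spread of log variances does not exceed pure sampling
  noise the prior df is infinite and the common value is the pooled mean
  variance).

**Species divergence** fits a cell-means species model across all species
and tests pairwise contrasts; the effect is the log2 ratio between the two
species of the pair.

**Translation-efficiency divergence** stacks, per gene, the RNA and
occupancy observations of a species pair and fits
`E = mu + b1*S + b2*T + b3*S*T + e`, with `S` the species indicator and `T`
the datatype indicator, both layers carrying their precision weights. The
interaction `b3` is the datatype-dependent species difference — the log2
ratio of translation efficiency — and is tested with the moderated t.

**Buffering** is a two-stage regression: stage 1 regresses the upstream
trait on the downstream trait per gene (ordinary LS with intercept); stage 2
models the stage-1 residuals with a species indicator, whose coefficient is
the residual upstream divergence not propagated downstream — the buffering
effect size — tested with the moderated t across genes. Only the two species
of the pair enter. Stage 2 is unweighted: the residuals are continuous and
the protein layer carries no count-derived weights. This two-stage
construction is deliberately conservative: when the downstream trait has
little variance, the stage-1 slope is estimated poorly and chance
correlation with the species pattern removes part of a true upstream effect.
That conservativeness is a property of the method, quantified in the tests
(sensitivity about 0.8 under idealised Gaussian conditions at effect 2.0,
SD 0.3, n = 4 per species, and at or just below 0.7 on the full synthetic
default which adds counting noise and protein missingness).

Numerical edge cases: genes whose available observations leave no residual
df are flagged untestable and excluded from adjustment; a zero-variance
downstream trait sets the stage-1 slope to 0 (residual = centred upstream)
and flags the gene rather than failing; if *every* gene's stage-2 residual
is numerically zero (perfect propagation) the test reports zero effects with
p = 1 instead of attempting moderation. Result rows are ordered by gene id,
which also breaks ties deterministically in ranked outputs.

## Multiple testing

Bonferroni (`min(1, m p)`, m = tested genes) gives the FWER column used for
the `significant` flag at the 0.05 default; BH gives the FDR column; Storey
q-values use a smoother pi0 estimate (`pi0(lambda)` on lambda = 0.05 ... 0.95,
df-3 smoothing spline evaluated at the largest lambda). Nominal p and the
FWER are the primary outputs; q-values are included for completeness but can
fall below the nominal p when pi0 < 1 — that is their definition, not a bug
— and deserve caution when the p-value distribution is irregular.

## Ribosome-profiling QC

**Codon periodicity.** Fixed-width (100 bp) windows are centred on each
gene's first CDS base (plus strand only); windows whose mean per-base
conservation reaches 0.9 are retained ("conserved initiation sites").
Footprint 5' ends falling in the windows are aggregated by position and
normalised by the total in-window count, so the profile is a probability
mass; reported coordinates are shifted 12 nt downstream to centre the
pattern at the ribosomal P site (display only — the mass is unchanged).
Window placement is centred (50 nt either side); the anchor convention is a
package choice since "flanking the first position" admits asymmetric
readings.

**Footprint mappability.** Species-specific mappable gene lengths are the
number of exonic start positions whose k-mer (k = 29, the median footprint
length; exon-local, never junction-spanning) occurs exactly once in the
genome counting both strands. Exact k-mer uniqueness is a deterministic,
oracle-checkable stand-in for alignment-based uniqueness with mismatches;
it is stricter, and documented as such. `log2cpm_to_log2rpkm(use_mappable =
TRUE)` then normalises by mappable length instead of total exonic length.

## Downstream statistics

* `compare_effect_sizes()`: rank-sum comparison of absolute effect sizes
  between layers (exact null for small tie-free inputs, normal approximation
  with tie correction otherwise), intended for genes already diverged at the
  protein level.
* `propagation_r2()`: for each protein-divergence FDR cutoff, the squared
  Pearson correlation between protein and occupancy divergence effects, raw
  and after regressing transcript divergence out of both. The residualised
  curve estimates how much protein divergence is attributable to
  translation beyond pre-existing transcript divergence.
* `feature_enrichment()` / `enrich_features()`: Pearson correlation between
  a per-gene feature (PTM site counts, Ka, GC, binary term membership,
  collapsed to one row per gene by isoform medians / any-isoform OR) and
  `-log10` of the nominal buffering p; the sign gives the direction; BH
  across features for term scans.
* `variance_relaxation()`: do buffered genes vary more across a population
  panel? Per-gene SD across individuals; either a Pearson enrichment
  (unmatched) or, matched, a resampling test: buffered set = FWER <= 0.05,
  background sets drawn preserving the buffered set's expression-decile
  histogram (bins empty of background genes merge downward), empirical
  `p = (1 + #{null >= observed}) / (1 + n_resample)`. Decile binning with
  histogram-preserving resampling is this package's construction of the
  "expression-matched background".

## The synthetic-data generator

`simulate_multiomic()` draws a three-species, multi-individual dataset with
known truth. Per gene: baseline log2 expression ~ N(3, 1.5^2); a disjoint
divergence class (propagating transcript divergence, translation-efficiency
divergence, translational buffering, post-translational buffering, or none),
each divergent gene carrying a signed offset in one random non-reference
species; counts negative binomial around
`2^(mu + offsets + batch shift + biological noise)` scaled to the sample's
library size; protein values Gaussian on the log-ratio scale with
missingness; per-batch per-gene location/scale effects on the occupancy
layer, assigned round-robin within species so batch and species stay
estimable.

Default choices, and why:

* **Within-species SD.** Biological log2 SD 0.28, so that the *realised*
  per-observation SD (biological plus counting noise at default depth) is
  0.30 — the study condition the package's recovery tests are written
  against. Protein noise SD 0.30.
* **Depth.** Library sizes 3-5 million over 5000 genes, i.e. roughly
  600-1000 reads per gene — comparable to a ribosome-profiling experiment
  with ~12 million usable reads spread over a genome-wide quantifiable set.
* **NB dispersion.** Mean 0.002 (shape 10, so nearly constant). Biological
  variation is injected explicitly as the log-normal component, so the NB
  dispersion represents only residual technical overdispersion beyond
  Poisson; giving it a biological-scale magnitude would double-count
  variance.
* **Effects.** Transcript divergence 2.0 log2 in 10% of genes; TE divergence
  1.0 log2 in 2%; 4% post-translationally and 0.4% translationally buffered
  (effect 2.0) — an order-of-magnitude contrast matching the biology the
  tests should reproduce qualitatively (many more post-translational than
  translational buffering events).
* **Protein missingness.** 5% per observation, enough to exercise the
  three-individuals-per-species filter.

What the generator does **not** emulate: read-level artifacts (adapter
contamination, rRNA, junction reads, mapping bias), abundance-dependent
protein missingness, correlated gene modules, compositional extremes that
stress TMM, or phylogenetic structure beyond fixed per-species offsets.
Passing recovery tests on these simulations therefore demonstrates
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real data.

## Problem sizes used by the test-suite

The packaged checks run on one core in a few minutes: oracle equivalence on
randomized fixtures of 4-80 genes; prior recovery on 50,000 simulated
variances; calibration on one 10,000-gene null dataset plus forty 1000-gene
null replicates; truth recovery pooled over three 5000-gene default
datasets; TE recovery over 200 replicate 50-gene datasets; relaxation
calibration over 500 resampling replicates and power over 20 replicates of
a 10,000 x 72 panel.

## Known limitations

* The two-stage buffering test's sensitivity sits at its conservative
  boundary under the full default generator (see above); interpret absolute
  sensitivity figures together with the idealised-condition benchmark.
* The EB batch adjustment is not exactly idempotent and preserves grand
  means only approximately (shrinkage trade-off, shared with any parametric
  EB location/scale adjuster).
* Mappability is exact-match k-mer uniqueness, stricter than
  mismatch-tolerant alignment.
* q-values inherit the usual instability of pi0 estimation on irregular
  p-value distributions; the FWER column is the primary significance call.
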