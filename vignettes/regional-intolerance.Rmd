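---
title: "Regional intolerance scoring and pathogenic-variant localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional intolerance scoring and pathogenic-variant localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srvis)
```

## The problem

Ranking whole genes by their intolerance to functional variation has proved
valuable for interpreting patient genomes, but the gene is a coarse unit:
pathogenic mutations frequently cluster in specific parts of a protein. A
gene that looks tolerant overall may contain a short, strongly intolerant
segment that causes disease when mutated, and conversely the tolerant bulk
of a disease gene is a plausible source of false-positive database entries.
`srvis` scores *sub-regions* of genes for intolerance using standing human
variation, then tests whether those scores predict where reported
pathogenic mutations localize.

## Dividing genes into sub-regions

Two divisions of each gene's CDS are supported, both producing a tiling of
`[0, cds_length)` with no gaps or overlaps:

* **Domain division** (`build_domain_regions()`): profile-search alignments
  of the translated CDS against a conserved-domain collection, given in
  1-based inclusive protein coordinates, are converted to CDS nucleotides
  as `[(aa_start-1)*3, aa_end*3)`. Alignments with E-value above `1e-2`
  (default `max_evalue`) are discarded; overlaps are resolved greedily by
  descending bit score, dropping any alignment that overlaps an
  already-kept one (ties break to lower E-value, then lexicographic domain
  id). Every maximal unaligned stretch becomes its own region.
* **Exon division** (`build_exon_regions()`): one region per coding exon in
  transcription order.

Design choices that were genuinely open:

* *Terminal unaligned stretches* are included as regions. Only the
  stretches *between* alignments are strictly required by the domain
  definition, but the termini must be covered for a division to tile the
  CDS — and tiling is what makes the size-permutation null (below)
  well-defined.
* *Overlap handling* drops the lower-scoring alignment entirely rather
  than truncating it. "The better alignment was kept" is a pairwise rule;
  greedy resolution by bit score is its natural transitive extension, and
  truncation would manufacture domain fragments with no alignment support.
* *Coordinates*: genomic intervals are 0-based half-open (BED convention),
  protein input 1-based inclusive (BLAST convention); all conversions are
  explicit. A CDS length that is not a codon multiple is tolerated with a
  warning — annotation slop should not abort a genome-wide run. Alignments
  extending past the CDS are rejected per-alignment with a warning record.
* *Canonical transcript*: given several transcripts, the longest CDS wins,
  with ties broken lexicographically so the choice is deterministic.
* Zero-length gaps between abutting alignments produce no region.

`permute_region_sizes()` re-lays a gene's regions contiguously from CDS
position 0 in random order. Count and size multiset are conserved exactly;
the layout is deterministic given the seed.

## Intolerance scores

`subrvis()` fits, across **all** sub-regions of a division jointly, the
ordinary least-squares regression of common functional variant counts
(non-synonymous, folded MAF strictly > 0.1%) on total qualifying variant
counts, and scores each region by its studentized residual. Qualifying
sites need ≥10× mean coverage, and variant sites a PASS filter.

Numerical and statistical choices:

* *Direction of regression*: the response is the common functional count,
  the predictor the total count, matching the interpretation of the score
  as the departure of observed common functional variation from the
  expectation given total variation. Raw residuals are then orthogonal to
  the total tally by construction (asserted in tests at `1e-10`).
* *Studentization*: externally studentized (leave-one-out variance) by
  default, `studentize = "internal"` available. At realistic region counts
  the difference is negligible, but the convention must be pinned for
  reproducibility; tests compare against an independent hat-matrix oracle.
* *Degenerate inputs*: fewer than 3 regions or a zero-variance predictor
  is an error. Exactly collinear counts studentize to 0/0; a numerically
  zero residual is reported as a zero score.
* *Boundary MAF*: the common threshold is a strict inequality. Folded
  frequencies are computed as `min(AF, 1-AF)`, and `1 - 0.999` is
  `0.001 + 9e-19` in floating point, so the comparison adds a `1e-12`
  epsilon to keep mathematically-boundary sites non-common.
* Regions are unweighted in the regression; weighting by region size is a
  plausible variant but the score is defined on counts, not rates.

`compute_subgerp()` averages a per-base conservation track over each
region's genomic blocks, using available bases only (`NA` when none).
`region_mutation_rates()` sums trinucleotide-context substitution rates
over every position and all three alternates; sequences carry one flanking
base per side so terminal positions have contexts, and contexts containing
`N` are skipped and counted. `gene_variability_score()` summarizes per-gene
score spread (sample SD, requiring ≥3 scored regions).

## The pathogenic test set

`filter_pathogenic()` keeps confidently pathogenic clinical entries
(ClinVar "Pathogenic", HGMD "DM") that are canonical-transcript missense
calls and not splice-adjacent or truncating
(`incomplete_terminal_codon_variant`, `splice_region_variant`,
`stop_gained`, `stop_lost` all excluded). Loss-of-function classes damage
the protein wherever they fall, so they carry no localization signal.
Records duplicated across sources collapse on (chrom, pos, alt). The filter
is idempotent.

## Gene-specific permutation test

For gene *g*: expected counts `E = sum(Y) * Z / sum(Z)`, statistic
`C_g = cov(Y - E, X)` with the n−1 sample covariance (pinned by a worked
example in the tests), null draws from `Multinomial(sum(Y), Z/sum(Z))`,
inclusive tail `G = #{C* <= C_g}`, p-value `(G+1)/(n_p+1)` with
`n_p = 20000` by default, Benjamini–Hochberg adjustment across genes.
Genes with fewer than two regions, no pathogenic variant, non-positive
rates, or missing scores are skipped with a structured reason rather than
an error; missing scores are never imputed.

The observed and permuted statistics are evaluated through the identical
arithmetic expression, so a permutation that reproduces the observed
placement ties the observed value exactly — without this, floating-point
jitter silently converts the inclusive tail into an exclusive one (the
package's tests caught exactly that against a full-enumeration oracle).
Each gene draws from an RNG substream derived from the run seed and a hash
of the gene id, so results are independent of gene processing order.

Because counts are discrete, permuted statistics tie the observed one with
non-negligible probability when a gene has few pathogenic variants and few
regions; the inclusive tail then makes the p-value conservative (empirical
type-I below nominal), exactly as for any exact permutation test on a
coarse outcome space. The calibration test therefore uses genes with many
pathogenic variants (mean total 25 over 4–12 regions), where the null
statistic is near-continuous and the p-value is approximately uniform;
validity (never anti-conservative) is checked separately on small-count
genes.

## Genome-wide model

`fit_region_model()` fits
`logit(Pr(Y=1)) = alpha + beta1*log(Z) + beta2*X` by maximum likelihood,
with natural log, Wald p-values, and AIC. Score vectors are scaled by
their population SD (n denominator, computed over all supplied regions
before any model-specific subsetting) so effect sizes are per score-SD. A
gene-constant score vector is just another column, which is how the
regional-vs-genic comparison is expressed. Perfect separation — detected
through glm's non-convergence or saturated-probability warnings plus a
coefficient-magnitude guard — rejects the fit with a classed condition.

`resample_response()` draws null presence vectors as weighted samples
without replacement of size `sum(Y)` with probabilities proportional to
`Z` (successive draws over the remaining regions, the scheme base R's
`sample.int(prob = )` implements), so every resample preserves the number
of pathogenic regions exactly. `resampling_pvalue()` is
`(R - C + 1)/(R + 1)` with `C` counting null p-values *strictly* larger
than the observed one. `aic_probability()` is `exp((AICmin - AICmax)/2)`,
and `division_permutation_test()` is `(n_p - K + 1)/(n_p + 1)` with `K`
the count of permuted effect sizes strictly smaller in absolute value.

## Hot-zone analysis

Variant effect scores: synonymous 0; canonical splice, stop gain/loss 1;
missense takes its PolyPhen-2 HumVar probability (missing score excludes
the variant). A mutation is hot-zone when effect ≥ 0.95 **and** its
region's score percentile ≤ 25, both inclusive; the percentile of a score
is the percentage of scored regions at or below it, so intolerant regions
rank low. Variants in unscored regions leave both numerator and
denominator. Enrichment is a two-sided Fisher exact test (two-sided
reproduces the published example table's p = 0.018; sidedness was
otherwise unstated).

The prediction-to-score conversion for Bayes-classifier output maps
`polymorphism` to its probability, `disease_causing` to one minus it, and
flips database-backed `_automatic` labels first when the classifier
disagrees (probability < 0.5). Disease-causing results land in [0, 0.5]
and polymorphism results in [0.5, 1]; the non-automatic labels are defined
only for probabilities above 0.5.

## Synthetic cohorts

`simulate_cohort()` generates every input the pipeline reads, with planted
structure chosen to emulate human coding-gene scale: ~5 coding exons of
mean length 170 nt per gene, domain alignments covering part of each
protein, per-base variant density 0.05 in the reference cohort, 20% of
regions intolerant, five-fold suppression of common functional variation
in intolerant regions and five-fold pathogenic enrichment toward them.
Totals per region are Poisson in region length; common functional counts
are binomial thinnings (further thinned by the suppression factor);
pathogenic variants are placed per gene from
`Multinomial(N, Z*enrichment^intolerant)` — so `enrichment = 1` reproduces
the gene-test null *exactly*, which is what the calibration tests rely on.
Sequences are i.i.d. uniform ACGT; the default rate table is a simple
deterministic transition/transversion model with elevated CpG transitions.
Two presets (`sim_preset()`) mirror archetypal profiles: `"concentrated"`
(mostly tolerant gene, small highly intolerant portion) and `"graded"`
(two moderate tiers).

What the generator does **not** emulate: realistic human mutation spectra,
linkage structure, coverage heterogeneity along real exomes, annotation
error, and database ascertainment bias. Passing tests therefore establish
that the machinery is correct and calibrated under its stated model — not
that real-data effect sizes will match.

Problem sizes used by the test suite were chosen to keep the full run at
desk scale while leaving the statistical checks well-powered: calibration
uses 2,000 synthetic genes (near-continuous regime, above) at 2,000
permutations each; coefficient
recovery uses 20,000 regions; the division-permutation conservation check
uses a 500-gene cohort; the β₂-recovery property uses twenty 1,200-gene
cohorts.

## Known limitations

* Scores are only as fine as the reference cohort is deep; short regions
  have noisy residuals, and the regression is unweighted.
* The genome-wide test conditions on genes with reported pathogenic
  variants, inheriting any ascertainment bias in those reports.
* The mutation-rate covariate is sequence-composition only; regional
  variation in mutability beyond trinucleotide context is not modelled.
* The domain division depends on the profile-search inputs; multi-domain
  models must be excluded upstream (an input-filter concern, as CDD-style
  membership metadata is external to this package).
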