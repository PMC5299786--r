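---
title: "Quantifying functional variation in metagenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional variation in metagenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcvar)
```

# The problem

Shotgun metagenomic studies of the gut microbiome routinely summarize a
sample as a vector of gene-family (KEGG Orthology, "KO") abundances and
then as pathway abundances. Compared across people, these functional
profiles look strikingly uniform — far more uniform than the taxonomic
composition of the same communities. A large part of that apparent
uniformity is an artifact of how the profiles are computed. Four common
processing practices each compress true between-sample variation:

1. **Relative normalization.** Dividing each gene's read count by the
   sample's total mapped reads removes sequencing depth, but it also
   divides by the community's average genome size. When the taxa driving a
   gene's abundance also carry large genomes, the numerator and the
   denominator rise together and the gene's variation is damped.
2. **Genome-prevalent gene families.** Genes carried at near-constant copy
   number by essentially every genome (ribosomal proteins, core
   metabolism) contribute a large, almost constant baseline to every
   profile, diluting the informative part.
3. **Annotation-based aggregation.** KEGG pathways group genes by curated
   function, not by which organisms carry them. Genes of the same pathway
   frequently *anti*-correlate across samples (alternative strategies used
   by different taxa), so summing them cancels signal.
4. **Uniform mapping of shared genes.** A gene annotated to several
   pathways is usually split evenly among them (or counted fully in each),
   although in any particular community its abundance may be driven by one
   pathway only.

`funcvar` implements one remedy per practice — single-copy marker
normalization, copy-number-CoV prevalence filtering, genome co-occurrence
aggregation, and support-based non-uniform mapping — together with the
statistics used to compare processing schemes, a case/control association
layer, a per-individual functional fingerprint, and a synthetic community
simulator that makes each claim testable offline with planted ground
truth.

# The methods

## Single-copy marker normalization

Let $x_{sg}$ be the observed abundance of gene family $g$ in sample $s$,
and let $M$ be a set of universal single-copy marker families (one copy in
every bacterial genome). The normalized value is

$$\tilde{x}_{sg} = \frac{x_{sg}}{\operatorname{median}_{m \in M} x_{sm}}.$$

Because every genome carries each marker exactly once, the marker level
tracks "number of genomes sequenced," and $\tilde{x}_{sg}$ reads as the
average copy number of $g$ per genome in the community. The estimator is
invariant both to sequencing depth and to average genome size; on a
noise-free simulated community it reproduces the weighted average copy
number $\sum_t w_{st} c_{tg}$ exactly (the test suite checks agreement to
1e-9).

Choices made here:

* **Median center.** A robust center is needed because individual markers
  suffer annotation noise. The median is used by default (a trimmed mean
  is available via `center = "trimmed_mean"`). We make no claim of
  numerical identity with released marker-normalization tools, which may
  center differently and learn additional intra-sample corrections; such
  learned corrections are out of scope here.
* **Absent markers are gaps, not zeros.** A marker missing from the
  profile's columns usually reflects an annotation difference, so it is
  dropped from the median rather than counted as zero (which would bias
  the yardstick downward). A sample whose marker center is zero has no
  yardstick and is a hard error.

## Prevalence filtering

For each gene family the coefficient of variation of its copy number
across a genome collection is computed with genomes *lacking* the gene
counted as zeros. A gene is "genome-prevalent" when CoV < 1.5 (strict
inequality, matching the definition's wording; at threshold 0 nothing is
flagged). Zero-inclusion is what makes a low CoV mean both "nearly
universal" and "nearly constant copy number". The same operation applied
to a gut-dwelling genome subset yields gut-prevalent genes. The
standard-deviation denominator is $n-1$ by default (`sd_type =
"population"` switches), since the source definition does not specify it;
both options are exposed because the flagged set can differ near the
threshold.

## Genome co-occurrence aggregation

The similarity of two gene families is the fraction of genomes carrying
both out of genomes carrying either; clustering uses the complementary
Jaccard *distance* $1 - |A \cap B| / |A \cup B|$ (a distance is what
complete linkage requires). Complete-linkage hierarchical clustering is
cut to a requested number of aggregates — a natural default is the number
of annotation pathways, so the two aggregation bases are comparable.
Genes are sorted lexicographically before clustering so dendrogram ties
resolve identically on every platform. Genes present in no genome have an
undefined union with other absent genes and are excluded with a warning.

## Support-based pathway mapping

For pathway $P$ and sample $s$, the *support* is the mean abundance of
$P$'s non-shared genes (those mapped to $P$ only) present in the profile
— evidence for $P$'s presence untouched by multi-mapping ambiguity. A
shared gene $g$ with value $x_{sg}$ and pathway set $\mathcal{P}(g)$
contributes

$$x_{sg} \cdot \frac{\text{supp}(s, P)}{\sum_{Q \in \mathcal{P}(g)} \text{supp}(s, Q)}$$

to each $P \in \mathcal{P}(g)$; pathway abundance is that plus the full
values of the pathway's non-shared genes. Uniform fractional
($x_{sg}/|\mathcal{P}(g)|$) and uniform complete ($x_{sg}$ to every
pathway) schemes are provided for comparison.

Scoring is restricted to pathways with at least 10 non-shared genes in the
*annotation map* (a database property, deliberately not dependent on the
profile) and mean fractional-mapped relative abundance above 0.05%.
Design decisions:

* **Eligibility before mapping.** Shared-gene degree counts only eligible
  pathways, which keeps the scheme mass-conserving over the genes that map
  to at least one scored pathway; `keep_ineligible_in_degree = TRUE`
  restores full-degree splitting for users who prefer fidelity to the raw
  annotation over conservation.
* **Zero support.** If all of a gene's scored pathways have zero support
  in a sample, the gene falls back to a uniform fractional split there;
  discarding its abundance would silently break conservation.
* **Pathways without a support basis** (all non-shared genes absent from
  the profile, e.g. removed by prevalence filtering upstream) cannot be
  scored and are dropped with a warning.
* When all supports are equal in a sample the scheme reduces exactly to
  uniform fractional mapping — a useful sanity limit that the tests
  assert.

## Variation, distance and association statistics

The variability measure throughout is the coefficient of variation
(sd/mean, $n-1$ denominator, scale-invariant; an infinite sentinel flags a
zero mean). Between-sample functional distance is Bray–Curtis,
$1 - 2\sum_f \min(x_{if}, x_{jf}) / (\sum_f x_{if} + \sum_f x_{jf})$.
Agreement of two distance structures uses a one-sided Mantel permutation
test with the $+1$ correction, $p = (1 + \#\{r^* \ge r\})/(1 + n_{perm})$,
so a permutation p-value is never zero. Within-pathway coherence is
summarized as the fraction of gene pairs with Pearson $r$ below a
threshold (default $-0.3$); zero-variance genes have no defined
correlation and are excluded with a logged count rather than treated as
$r = 0$.

Case/control association per pathway is a two-sided Wilcoxon rank-sum
test with Benjamini–Hochberg adjustment across pathways. The association
*score* is the tie-corrected standardized rank-sum $z$, signed so that
positive means enriched in cases — the source analysis reports a
"disease-association score" without defining it, and the signed $z$ of the
very test it uses is the most conservative reading. Fold changes are
plain ratios to the across-sample mean (log2 via a flag), matching how
such panels are usually drawn.

The two preset pipelines compared by `run_pipeline()` are *standard*
(relative normalization, all genes, uniform fractional mapping) and
*revised* (single-copy normalization, prevalence filter, support-based
mapping).

## Functional metagenomic codes

For each individual, candidate markers are the gene families for which
that individual's first-visit sample is the *strict* maximum across
individuals (relative abundances; ties disqualify the gene for everyone).
Candidates are ranked by the ratio to the second-highest individual; a
second-highest of zero ranks as infinitely specific, such genes ordered
among themselves by own abundance and then gene ID so construction is
deterministic. The top $k = 20$ (sizes 1–20 supported) form the code;
strict-argmax construction makes codes pairwise disjoint, so $n$
individuals contribute up to $20n$ marker genes. Identification scores
each second-visit sample by counting code genes for which it is the
community-wide strict maximum, assigns each sample to the highest-scoring
individual, and treats tied assignments as unassigned-and-incorrect (a
conservative accuracy). Agreement scores are bounded by the code size by
construction.

# The synthetic world

`simulate_world()` plants every structure the pipeline stages need:

* **Markers** at copy number exactly 1 in every genome — the ground truth
  that makes marker normalization exact.
* A **universal background block** (copy 1 everywhere): genome-prevalent
  by construction (copy-number CoV 0), the target of the prevalence
  filter.
* **Six ordinary blocks**, two carried by each "small" genome and one by
  each "large" genome (~25% genome coverage, CoV ≈ 1.7): recoverable
  co-occurrence units that survive the prevalence filter.
* A **restricted block** carried only by the large half of the genomes:
  the planted size-confounded variable genes.

Every genome carries background plus exactly two equal-size blocks, so
genome sizes are identical unless asked otherwise: with
`genome_size_spread` $= \gamma > 0$, `simulate_profiles()` inflates the
background copies of large genomes by $1 + \gamma$, making average genome
size a function of large-genome biomass. Read-space abundance is
$\text{depth} \cdot \sum_t w_{st} c_{tg} / \sum_t w_{st} |G_t|$ with
Dirichlet taxa weights, i.e. a fixed read budget spread over the
community's total gene content — exactly the mechanism that makes
relative abundance genome-size-confounded while the marker yardstick is
not. At $\gamma = 0$ the two normalizations give identical per-gene CoV;
at $\gamma > 0$ the restricted-block genes rise and fall together with
the denominator and their relative-abundance CoV is structurally smaller
than the true copy-number CoV (the masking effect).

Noise is multiplicative lognormal with mean 1 and a chosen CV: the
pipeline operates on abundance tables, not reads, so count-level noise
models would add a layer the methods never see. Pathways are contiguous
block-aligned slices of the gene list with a configurable fraction of
genes given a second random pathway (the shared genes).

`simulate_case_control()` multiplies the affected pathway's gene copy
numbers by `effect` in cases; with `confound_genome_size = TRUE` it also
rescales each case's background genes so total genome size grows by
exactly `effect`. This is a *designed worst case*: the planted enrichment
cancels exactly in relative-abundance space (the standard pipeline sees a
null) while marker-normalized copy numbers still carry it (the revised
pipeline detects it). `simulate_two_visit_cohort()` gives each individual
disjoint boosted signature genes on a shared baseline; strength 0 yields
a pure null in which identification succeeds at chance
(slightly below $1/n$, because tied assignments count as incorrect).

What the simulator does **not** emulate: phylogenetic correlation between
genomes, read-level error and mapping ambiguity, annotation errors in the
gene-to-pathway map, compositional count noise, and covariate structure in
cohorts. Passing the planted-truth tests therefore demonstrates the
algorithms implement their definitions and are calibrated under clean
conditions — not that real HMP- or cohort-scale numbers are reproduced,
which depend on database snapshots this package deliberately does not
ship.

# Numerical choices and validation sizes

* All validators use strict tolerances: profile round-trips are written
  with 15 significant digits and checked to 1e-12 relative; distance
  symmetry to 1e-12; mass conservation to 1e-9.
* Degenerate inputs fail loudly: all-zero samples, empty maps,
  single-genome CoV, assignment ties, missing cells and ragged rows are
  errors or logged exclusions, never silent repairs.
* The validation suite runs the support-based mapper against an
  independently written per-gene brute-force loop on 100 random instances
  (≤ 20 samples × 50 genes × 8 pathways); normalization recovery and the
  masking effect on 100 simulated communities of 20 samples; block
  recovery on 50 planted 5-block presence matrices (40 genomes × 100
  genes, 5% bit flips, adjusted-Rand ≥ 0.9); test size for the rank-sum
  and Mantel tests on 500 null replicates each; the hidden-association
  contrast on 50 case/control cohorts (20 + 20 samples); and fingerprint
  accuracy on 36-individual two-visit cohorts. These sizes were chosen so
  each property is measured with useful precision while the whole suite
  runs in well under a minute on a laptop; `scripts/acceptance.R`
  recomputes the same quantities end to end.

# Known limitations

* Only the marker-yardstick normalization is implemented; learned
  intra-sample corrections (e.g. lasso over marker variability) are not.
* Gut-prevalent gene lists require the user to supply the gut genome
  subset; no genome catalog is bundled.
* The Wilcoxon z is a normal approximation; for very small groups the
  reported p (exact where ties permit) and the score can disagree slightly
  in rank.
* `eligible_pathways()` evaluates mean relative abundance on the profile
  it is given; callers comparing pipelines should pass the same raw
  profile stage to both arms, as `run_pipeline()` does.
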