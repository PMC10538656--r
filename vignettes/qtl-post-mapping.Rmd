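---
title: "Post-mapping curation of molecular QTLs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-mapping curation of molecular QTLs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`qtlcurator` implements the computational stages that sit *after* read
alignment, quantification and fine-mapping in a molecular QTL study:
genotype quality control (including the X chromosome), normalisation of five
transcriptional phenotypes, cis association scanning with group-level
permutations, fine-mapping-based filtering of transcript-level summary
statistics, signal-level colocalisation from log Bayes factors, and
genotype-stratified read-coverage visualisation. Alignment, quantification,
imputation and the fine-mapping model fit itself are out of scope: their
outputs (count matrices, dosage VCFs, credible sets and per-signal log Bayes
factors) are input contracts.

This vignette records the statistical models, the tunable parameters and the
design decisions that were genuinely open, so a maintainer can tell which
behaviour is a contract and which is a choice.

# Genotype quality control

Variant-level QC excludes a variant when any of three conditions holds:
exact Hardy–Weinberg p-value < 1e-6, missingness > 0.05, or minor allele
frequency < 0.01. All three inequalities are strict, so a variant at
exactly 5% missingness or exactly MAF 0.01 survives. The Hardy–Weinberg
test is the two-sided exact test conditional on allele counts: the p-value
sums the probabilities of all heterozygote counts no more probable than the
observed one. It is computed in log space and checked in the test suite
against a full-enumeration oracle for cohort sizes up to 200.

MAF is computed from dosages (folded mean/2) rather than hard calls, which
keeps the estimate consistent for imputed data; hard calls (rounded dosage)
are used only for the Hardy–Weinberg genotype counts.

On the X chromosome, all three statistics are computed on female samples
only and the decisions are inherited by males — male hemizygosity breaks
both the Hardy–Weinberg null and the MAF scale. Variants on X with no
female samples in the cohort are flagged unevaluable. After imputation,
male dosages in the non-pseudoautosomal region are doubled onto the 0–2
diploid scale, and a male non-PAR call that rounds to heterozygous —
impossible on a haploid region — is set to missing *before* doubling, so
that an artefactual call cannot inflate the dosage. We harmonise the male
dosages first and compute MAF afterwards, so that male and female alleles
contribute on the same scale; the alternative order changes MAF by at most
a factor related to the sex ratio and is not exposed as an option.
Pseudoautosomal boundaries default to GRCh38 (PAR1 chrX:10,001–2,781,479,
PAR2 chrX:155,701,383–156,030,895) and are overridable.

The post-imputation filter keeps a variant when MAF ≥ 0.01 *and* imputation
R² ≥ 0.4; a variant with no R² recorded is excluded rather than silently
kept.

# Normalisation of the five trait types

Gene and exon counts follow the count route: GC-trend correction, the
low-expression filter (gene level), then the inverse normal transform.
Transcript, transcriptional-event and splice-junction expression follow the
usage route: usage ratios within the trait group, then the inverse normal
transform.

* **TPM** — `count / effective_length`, rescaled so each sample sums to
  1e6.
* **Low-expression filter** — a gene is dropped when at least 95% of the
  samples have TPM < 1. The boundary is read as *reaching* 95% triggers
  exclusion (95/100 low samples excludes). The filter applies to the gene
  level by default; exon traits can opt in via the same function.
* **Usage ratios** — each trait divided by the per-sample total over its
  group (all transcripts of a gene; all junctions of a cluster). A zero
  group total yields missing usages for that sample rather than zeros, and
  singleton groups are flagged degenerate (usage identically one carries no
  signal).
* **Inverse normal transform** — `qnorm((rank - 0.5)/n)` with average ranks
  for ties. The offset convention is the common QTL-pipeline choice; only
  ranks matter, so any monotone transformation of the input gives identical
  output, which the suite asserts directly.
* **GC correction** — per sample, a loess curve of length-normalised log2
  counts on trait GC content is fitted and subtracted, then each trait is
  re-centred on its original mean. This removes the dominant
  library-chemistry artefact (a smooth per-sample GC trend). It is
  deliberately *trend removal only*, not full conditional quantile
  normalisation: quantile-specific GC effects are out of scope, and the
  function says so in its documentation. Below 20 traits the fit is
  unidentifiable and the correction is skipped with a warning.

# Cis association scanning

The cis window is ±1 Mb around the strand-aware transcription start
(leftmost base for `+` genes, rightmost for `-`), clamped at chromosome
bounds. Traits with fewer than five cis variants or zero variance are
skipped with a classed condition rather than silently dropped.

The nominal scan is per-variant ordinary least squares of the trait on
dosage plus covariates (the first six genotype and six phenotype principal
components by convention), with pairwise-complete handling of missing
dosages. Effect, standard error and two-sided t-test p-value are reported
together with allele summaries (AC/AN/MAF) computed from the observed
dosages. Phenotype PCs are computed on the standardised (post-INT) matrix;
computing them pre-INT differs only through the rank transform and was not
worth a second code path.

Group-level significance uses direct permutations: the observed statistic
is the minimum nominal p over all (trait, variant) pairs of the group, each
permutation shuffles sample labels of the trait matrix — the same shuffle
for every trait, preserving trait–trait correlation, which is what makes
the group-minimum valid — and the empirical p-value is the add-one
estimator `(1 + #{perm ≤ obs}) / (1 + n_perm)` with 1000 permutations by
default. We use exact permutation rather than a fitted beta-distribution
tail approximation: at the problem sizes this package targets the direct
approach is affordable and has no approximation error to validate. For the
permutation machinery, covariates are projected out of both traits and
dosages first (Frisch–Waugh), and missing dosages are mean-imputed; the
covariate-adjusted and residualised scans agree on the effect estimate,
which the suite checks at 1e-8.

Dataset-level FDR is Benjamini–Hochberg across group empirical p-values at
1%.

# Fine-mapping-based filtering

This is the package's core curation step. Transcript-level quantifications
(exon, transcript usage, event usage, junction usage) test many correlated
traits per gene; most of their summary statistics describe the same
underlying signals. Per group (gene, or junction cluster):

1. **Credible-set QC** — discard credible sets whose maximum absolute
   univariate z over *members* is below 3, or with more than 200 member
   variants. Both inequalities strict; both reasons recorded when both
   hold. The z maximum is taken over credible-set members, not the whole
   region — the credible set is the object being judged.
2. **Connected components** — credible sets sharing at least one variant
   (canonical `chr_pos_ref_alt` equality; no LD-based merging) are linked;
   components are the transitive closure. Filtering precedes graph
   construction, so a discarded oversized set cannot bridge two components.
   Components are ordered by smallest member cs_id, making results
   independent of input row order.
3. **Tag selection** — per component, the credible set with the largest
   per-variant PIP maximum wins and its trait becomes the tag. PIP is a
   per-variant quantity in single-effect fine-mapping output, so "the trait
   with the highest PIP" is interpreted through that maximum; exact ties
   break by lexicographically smallest trait id then cs_id, so selection is
   deterministic. Distinct signals of one trait may land in different
   components and both become tags — the unit is the (trait, signal) pair.
4. **Row filtering** — all rows of tag traits are retained; a group with no
   surviving credible set contributes nothing. Gene-level (`ge`) statistics
   bypass the filter entirely: one trait per gene has no redundancy to
   remove.

On fixtures with 20 correlated traits sharing one signal the reduction is
95% (19 of 20 traits dropped); the suite requires ≥ 90%.

# Colocalisation from log Bayes factors

Signal-level colocalisation consumes per-signal, per-variant natural-log
Bayes factors from two studies, intersected on canonical variant ids (with
a rescue for complement-swapped representations of the same variant). With
`S1 = logsumexp(a)`, `S2 = logsumexp(b)`, `S12 = logsumexp(a + b)`, the
five hypothesis weights are `1`, `p1·e^{S1}`, `p2·e^{S2}`,
`p1·p2·(e^{S1+S2} − e^{S12})` and `p12·e^{S12}`, normalised by softmax; all
arithmetic stays in log space and the H3 (distinct causal variants) term is
clamped to zero when only one variant is shared or when `S1+S2 ≤ S12`
numerically. The implementation is tested to 1e-10 against a brute-force
summation over causal-variant configurations.

Priors default to `p1 = p2 = 1e-4`, `p12 = 5e-6` — the conventional choices
for this family of methods — and are exposed as arguments. The scan
evaluates all cross pairs of signals per region, caps signals at 10 per
locus (extra signals dropped with a warning), and flags pairs with PP4
*strictly* above 0.9.

# Coverage plots

The figure used to interpret a transcript-level QTL has three aligned
panels on a shared axis in which every intron is compressed to a fixed 50
nt: (A) mean read coverage per genotype class of the lead variant, (B)
per-exon effect sizes of that variant with 95% confidence intervals,
significant exons (Benjamini–Hochberg FDR ≤ 1% within the gene)
highlighted, and (C) the transcript structures.

The coordinate map is piecewise linear, length-preserving (hence exactly
invertible) on exonic bases, and its total target length is
`Σ merged-exon lengths + 50 × gaps + 2 × flank` — asserted directly in the
suite. Genotype classes come from rounding dosages with a 0.25 tolerance;
samples further from an integer are dropped and counted, so hard-called
VCFs are unaffected and imputed dosages have an explicit contract. Class
assignment happens before averaging; low-confidence samples are excluded
rather than fractionally weighted. Each sample's coverage is divided by its
own mean over the plotted span before class-averaging, which cancels
per-sample sequencing depth exactly (asserted to 1e-12); counts-per-million
or no normalisation are alternatives a caller can apply upstream. Coverage
is consumed as 5-bp-binned bedGraph, the convention of standard coverage
generators; bigWig input is out of scope to keep the dependency footprint
light. Every rendered number is also written as a plain table so the figure
is testable without image diffing.

# Synthetic fixtures

The generators exist so the whole pipeline is exercisable without
controlled-access data, and their defaults define the package's study
conditions:

* **Genotypes** — hard calls under Hardy–Weinberg equilibrium at the
  requested allele frequencies (two sampled haplotypes per individual),
  with optional block LD by haplotype copying. Default MAF 0.3 and cohort
  sizes of a few hundred reflect a typical single-dataset eQTL cohort.
* **Splicing gene** — a five-exon, two-transcript gene whose transcripts
  differ in the length of exon 4; the short form's usage follows
  `plogis(base + effect · dosage + noise)` with a default effect of 1 on
  the logit scale (a strong but realistic splicing QTL), baseline logit −1,
  logit noise SD 0.3 and gene depth 500. Each transcript contributes its
  usage fraction uniformly over its exonic bases, so shared bases sit at a
  dosage-independent level and only the alternative segment carries signal:
  a pure splicing QTL with no expression component. Counts are Poisson;
  negative-binomial overdispersion, realistic LD panels and population
  structure are deliberately not modelled, so passing tests demonstrate
  correctness of the machinery, not robustness to every artefact of real
  data.
* **Fine-mapping outputs** — single-effect Wakefield approximate Bayes
  factors, `ln ABF = ½·ln(se²/(se²+W)) + ½·z²·W/(se²+W)` with prior effect
  variance `W = 0.15²`, PIPs as normalised ABFs, and the credible set as
  the smallest variant set reaching 0.95 cumulative PIP. This is sufficient
  to exercise the filtering and colocalisation contracts; multi-signal
  fixtures are built by superposing independent single-effect signals, and
  re-fitting a full sum-of-single-effects model is a non-goal.

In recovery tests the "affected trait" is the exon-4 trait of the fixture
gene: with two complementary transcripts the usage traits carry identical
information (their statistics are mirror images), so the exon-level group
is where tag selection has a uniquely right answer.

# Problem sizes and numerical choices

The test suite and the reproduction script run oracle comparisons at
enumeration scale (cohorts ≤ 200 for Hardy–Weinberg, ≤ 5 variants for the
colocalisation configuration sum, ≤ 50 credible sets for components),
recovery at n = 500 samples × 30 cis variants × 50 replicates, permutation
calibration at 200 replicates × 2000 permutations, and confidence-interval
calibration over 2000 null intervals. These sizes give binomial standard
errors comfortably inside the asserted bands while keeping a full run in a
few minutes on one core.

Numerical conventions: internal coordinates are 0-based half-open
everywhere, converted at I/O boundaries (GFF3 1-based closed, bedGraph
0-based half-open, VCF positions 1-based); log-space accumulation for
Hardy–Weinberg masses, Bayes factors and posterior weights;
`log(e^x − e^y)` via `x + log1p(−exp(y−x))` with a guard for `y ≥ x`;
principal components get a deterministic sign (largest-magnitude loading
positive); permutation streams are seeded explicitly and every generator is
reproducible from its seed argument.

# Known limitations

* The GC correction removes smooth per-sample trends only; datasets with
  quantile-dependent GC effects need a full conditional quantile method
  upstream.
* The permutation scan mean-imputes missing dosages; heavy genotype
  missingness should be handled by QC before scanning.
* Usage ratios for two-trait groups produce perfectly anti-correlated
  traits; their standardised forms carry identical information, and tag
  selection between them is resolved by the documented tie-break rather
  than by evidence.
* Colocalisation assumes the log Bayes factors of the two studies are on
  comparable priors; it does not re-scale them.
* The coverage renderer writes static images; interactive viewers and
  batch orchestration across many signals are out of scope.
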