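---
title: "Multi-omic subtyping of leiomyosarcoma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic subtyping of leiomyosarcoma: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmsomics)
```

## The problem

Leiomyosarcoma (LMS) is an aggressive smooth-muscle sarcoma that splits, at
the transcriptome level, into a homogeneous subtype ("hLMS") — well
differentiated, intra-abdominal, enriched in females, with a distinctive
smooth-muscle/cell-cycle expression program — and a heterogeneous remainder
("oLMS"). `lmsomics` implements the analysis machinery needed to define and
exploit that split across omics layers: cross-platform expression
harmonization, co-expression module detection, a nearest-centroid subtype
classifier, clinical and survival enrichment, miRNA-mRNA network
integration, copy-number recurrence, and somatic-variant/mutational-signature
summaries. Because the original cohorts are controlled-access, the package
ships a seeded synthetic-data module that generates every input with the
statistical structure the analyses assume, so the full pipeline is
exercised end-to-end by the test suite.

## Cross-platform harmonization

Two cohorts profiled on different microarray platforms are merged in three
steps.

1. **Reproducible-gene selection** (`select_reproducible_genes`). Using the
   samples hybridized on both platforms, a gene is kept when the Pearson
   correlation of its two measurement vectors exceeds 0.8, *or* when its
   self-correlation beats its cross-correlation with every other gene in
   both directions. The second clause rescues genes whose absolute
   reproducibility is modest but which still track themselves better than
   anything else; we apply it symmetrically (a-vs-b and b-vs-a) and expose
   `both_directions = FALSE` for the one-directional reading, since the
   procedure's verbal description admits either. Genes with zero variance
   on either platform have undefined correlations and are dropped with a
   warning.
2. **Quantile normalization** (`quantile_normalize`): each column is mapped
   onto the mean-of-sorted-values reference distribution, averaging tied
   ranks (delegated to `limma::normalizeQuantiles`, which implements
   exactly this and reproduces the hand-computable two-column example in
   the tests). The step is idempotent. A single-gene matrix degenerates to
   assigning every sample the mean.
3. **Merge and re-center** (`merge_and_harmonize`): each experiment is
   quantile-normalized separately, the concatenation is quantile-normalized
   again, and each gene is median-centred within each experiment, then
   shifted by the mean of its two experiment medians. The normalization
   order follows the order in which the source procedure states the steps.
   After this, per-gene platform medians agree to machine precision, so the
   platform label carries no location information; on simulated dual-platform
   cohorts with per-gene shifts of SD 1 log2 unit, the platform explains
   under 5% of the first principal component.

## Co-expression modules and sample clustering

`build_coexpression_graph` keeps genes with expression variance above 2 (on
the log2 scale of the input — the threshold is meaningful only on that
scale) and connects pairs with Pearson correlation above 0.7.
`detect_communities` applies Girvan–Newman edge-betweenness community
detection (`igraph::cluster_edge_betweenness`), cutting the dendrogram at
maximum modularity, and flags communities with at least 5 genes as modules.
Disjoint graph components are never merged, and on instances up to a few
hundred genes the graph equals a brute-force O(p²) correlation scan (a test
asserts this).

`cluster_samples` re-implements the PCA-then-hierarchical workflow used for
the published sample clustering: PCA on the centred (unscaled) feature
submatrix; retain the smallest number of components explaining ≥ 95%
variance; Ward linkage (`ward.D2`) on the component scores; cut where the
relative loss of within-cluster inertia between successive merges is
largest; consolidate with a single k-means pass initialized at the cluster
means. Each element (variance fraction, maximum k) is an argument. Features
default to the member genes of detected modules; per-module mean scores are
a trivial variation the user can compute and pass instead. The open choice
between those two feature sets is resolved in favour of member genes, which
reproduces the planted-partition fixtures exactly.

## The centroid classifier

`welch_de` performs per-gene two-tailed Welch t-tests (Satterthwaite
degrees of freedom), oriented h-minus-o, with Holm step-down family-wise
correction; zero-variance genes report t = 0, p = 1. `build_centroids`
stores per-group per-gene means (medians optional) over a signature gene
set; `classify_samples` / `predict` computes, for every sample, the
distance **1 − Spearman ρ** to each centroid (average ranks on ties) and
assigns the nearer subtype when that distance is below 0.6, else
"unclassified". The Spearman distance is bounded in [0, 2] and invariant
under strictly monotone transforms of a sample's profile — both asserted as
properties — which is what makes the classifier portable across platforms
and normalizations.

The alternative `gmm` mode reproduces the mixture-model reading of the
assignment step: 1-D Gaussian mixtures with 1–4 components, equal and
unequal variance, are fitted to the distance-to-h distribution and selected
by BIC (`mclust`, the same tool family the original analysis used — we
deliberately call it rather than hand-rolling EM); the lowest-mean
component is labeled h, the highest-mean o, and intermediate components
stay unclassified. When BIC prefers a single component the threshold rule
is applied instead, since a one-component fit carries no group information.
The precedence between the 0.6 cutoff and the mixture fit is left
unreconciled upstream, so both modes are first-class; `threshold` is the
default because the cutoff is the operative description of who was
classified.

Missing signature genes at prediction time are dropped pairwise, with a
warning above 10% missing and an error above 50% (or below 3 shared genes,
where rank correlation is meaningless). Models serialize to JSON and
round-trip exactly.

`call_high_expression` flags samples whose expression of one gene strictly
exceeds the third quartile of the pooled all-genes-all-samples
distribution, computed per platform when a platform tag partitions the
samples; quantiles are linear-interpolation (type 7) throughout the
package.

## Clinical enrichment and survival

Categorical features are tested with the two-sided Fisher exact test on
reference-level-vs-rest × group tables; continuous features with the
two-sided Wilcoxon rank-sum, exact by enumeration for total n ≤ 50 without
ties and normal-approximated with tie correction otherwise. The
expression-homogeneity contrast compares the two per-gene within-group
variance vectors by rank-sum — the per-gene reading is the only one that
yields a rank test over thousands of observations, matching the reported
orders of magnitude; a per-patient variant sits behind `per = "patient"`.
`km_logrank` fits product-limit curves per group and the two-group log-rank
test via the `survival` package; a hand-computed O−E/V oracle in the tests
pins the statistic, and the module consumes generic (time, event) pairs —
the endpoint's clinical meaning (metastasis-free survival in the motivating
study) is the caller's concern.

## miRNA differential expression and network integration

Mature miRNAs are kept when their summed raw count exceeds 10 *and* some
sample has at least 5 reads (`filter_expressed`). `normalize_and_de` scales
counts to CPM with TMM factors (`edgeR::calcNormFactors`, whose defaults
are the stated trim parameters) and tests group differences by Welch t on
log2(CPM + 0.5) with Holm correction. The published selection is driven by
its thresholds — |log2FC| > 1, adjusted p < 0.01, median normalized count
> 1 in ≥ 1 group (CPM chosen as the normalized scale) — rather than by the
test family, so the simple Welch test stands behind the same interface a
moderated count-model fit could occupy; the substitution is isolated in
this one function. Exact scale-invariance under count doubling holds up to
the depth-dependent precision weights inside the trimmed mean (sub-0.1%
effects).

`premirna_expression` averages the mature rows of each precursor.
`integrate_interactions` takes a pair database, keeps pairs whose miRNA and
target both pass the fold-change and DE-p filters, computes Pearson
correlations across shared samples, tests one-sided for negative
correlation, adjusts by Benjamini–Hochberg across candidates (Holm
optional), and retains anti-correlated pairs with adjusted p < 0.01. Every
retained record therefore satisfies all four published predicates, which a
test asserts record-by-record. `logfc_concordance` regresses one cohort's
fold-changes on another's and reports R²; membership lists (e.g. an
imprinted miRNA cluster) can be summarized by ordinary subsetting of the DE
table, so no coordinates are hard-coded.

## Copy-number recurrence

`segments_to_genes` discards CN = 128 artifact segments, assigns every
(gene, patient) the minimum copy number over overlapping segments
(half-open 0-based intervals; overlap via `GenomicRanges`), marks genes
with no overlap missing, and drops genes missing in more than one third of
patients. `classify_events` maps CN 0/1/2/3–5/≥6 to homozygous deletion /
heterozygous deletion / normal / gain / amplification. The amplification
boundary is genuinely ambiguous upstream ("gain of four copies or more"
could mean CN ≥ 4 or +4 over diploid); we use CN ≥ 6, consistent with the
companion in-situ-hybridization rule that six or more signals define
amplification, and expose `amp_min`.

`cnv_penetrance` reports per-gene, per-group event frequencies among
non-missing patients, plus merged loss (homdel + hetdel) and gain + amp
views. `cnv_group_enrichment` tests each gene's merged loss and gain for
h-enrichment with one-tailed Fisher at p < 0.01 (swap labels for the other
tail); `cytoband_enrichment` then tests each band for over-representation
of significant genes per event type, Holm-corrected across bands within
event type, keeping the single most significant surviving event per band.
Genes straddling a band boundary belong to the band containing their start.

## Somatic variants, alteration summaries, signatures

`filter_somatic` applies the full somatic rule set — tumor depth ≥ 14,
normal depth ≥ 8, tumor allele fraction ≥ 0.3, normal allele fraction
exactly 0 (a tolerance argument exists for noisy normals), population
allele frequency < 0.1%, coding, non-synonymous, and RNA support ≥ 5 reads
when reported — logging the first failing rule of each rejected record.
Mutation classes are taken as labels from the input; no annotation engine
is re-implemented.

`aggregate_alterations` counts, per gene and group, patients with ≥ 1
mutation-class record, ≥ 1 structural variant, ≥ 1 loss, and ≥ 1 of any
category (each patient once per category), reporting percentages at
1-decimal half-away-from-zero rounding. `biallelic_pattern` classifies
biallelically inactivated patients into one-mechanism vs two-mechanism and
tests the 2×2 against groups. `tmb` is variants per megabase.
`context_matrix` resolves SNVs to pyrimidine-strand trinucleotide contexts
(purine-reference records reverse-complemented) in the fixed
A[C>A]A … T[T>G]T order, and `fit_signatures` refits exposures per patient:
catalog signatures with cosine similarity > 0.75 to the observed profile
enter a non-negative least-squares fit (`pracma::lsqnonneg`); candidate
selection precedes the joint fit, exposures of non-candidates are zero, and
the reconstruction cosine is reported.

## The synthetic-data module

All generators draw from one seed through a scoped RNG (`sim_config`
validates every field; identical configurations give byte-identical
outputs, which the determinism tests assert at the file level).

* **Expression** (`gen_subtype_cohort`): Normal noise on the log2 scale.
  Gene-level structure — baseline means, which genes are DE with which
  sign, which genes form modules — depends only on the structural
  parameters, *not* on the cohort seed: it is a property of the simulated
  disease, so independently seeded cohorts share the same true signature
  and can play train/validation roles. Defaults encode the training-cohort
  conditions: 2000 genes, 40 h / 20 o samples, 10% DE at 2 log2 units with
  alternating sign, within-group noise SD 1 in h and variance ratio 10/7 in
  o (the reported median per-gene variances are 0.7 vs 1.0), five 20-gene
  modules driven by latent factors with loading 3 (within-block correlation
  ≈ 0.9, variance ≈ 10 > the variance-filter threshold), clinical category
  probabilities matching the reported group contrasts, log-normal mitotic
  counts (medians ≈ 17 vs 24.5), and exponential survival with hazard ratio
  3 against uniform (12, 120)-month censoring.
* **Dual platform** (`gen_dual_platform_cohort`): 87 shared samples by
  default; 80% of genes concordant (shared latent signal + per-gene
  Normal(0, platform_shift_sd) shift + technical noise), the rest
  scrambled.
* **miRNA** (`gen_mirna_cohort`): negative-binomial mature counts (size 50)
  over a latent log2 layer; DE assigned at precursor level (|log2FC| = 2)
  so both mature forms and the averaged precursor agree; true-interaction
  target genes are negative linear responses to precursor expression with
  noise calibrated so the Pearson correlation equals `interaction_pcc` in
  expectation; decoy database pairs link null genes. An all-zero miRNA and
  a max-count-below-5 miRNA are always present to exercise the filter.
* **CNV** (`gen_cnv_cohort`): toy genome of 2 × 1 Mb chromosomes, 10 bands
  each, 1 kb genes every 5 kb, BED half-open 0-based; one band-aligned
  segment per band per patient; the enriched band is lost in 80% of h vs
  20% of o patients; fixtures include a split CN 1/CN 3 segment through a
  gene, a CN = 128 artifact, and a band left uncovered in half the patients
  so the missingness rule fires.
* **Variants** (`gen_variant_cohort`): contexts drawn from the mixture of a
  synthetic catalog whose signatures put 30% of mass on one substitution
  class and 70% on a flat background shared across the catalog
  (inter-signature cosine ≈ 0.5–0.6, like the flatter published
  signatures); this peak-plus-background shape is what makes cosine-gated
  refitting meaningful — with near-orthogonal signatures a 0.4-weight
  mixture component can never pass a 0.75 cosine gate, so recovery of such
  mixtures would be impossible for *any* implementation of the procedure.
  Positions are globally unique on the toy genome; half the records sit on
  the purine strand; a fixed panel of fixture records each fails exactly
  one somatic-filter rule.

What the generators do **not** emulate: probe-level microarray artifacts,
correlated gene-gene noise outside the implanted modules, miRNA isoform
complexity, subclonal copy-number states, indel/SV signatures, and any
linkage between the omics layers beyond the implanted structures. Passing
tests therefore demonstrate that the implementations recover the structures
they target at realistic noise levels — not that the pipeline's biological
conclusions transfer to any particular real cohort.

## Numerical choices and degenerate inputs

Quantiles are type 7 everywhere; ranks average ties; Holm is the step-down
`p.adjust` method; the Wilcoxon exact/approximate switch sits at total
n = 50; Fisher two-sided p sums hypergeometric probabilities ≤ the observed
one with the conventional 1e-7 relative tie tolerance (the enumeration
oracle in the tests reproduces it to 1e-12). Constant genes are excluded
from correlation-based steps with warnings; empty 2×2 margins give p = 1
with a warning; all-tied rank tests give p = 1; a gene/group with no
informative patient reports missing penetrance; patients with no candidate
signature get zero exposures and a flag. Community and clustering
tie-breaks are deterministic (sorted node order; fixed component order in
k-means initialization), so every stage is reproducible bit-for-bit.

## Problem sizes used by the test and acceptance runs

The suites run the generators at the scale that makes each check
statistically decisive while staying light: 2000-gene cohorts for DE and
homogeneity; 100 replicates for family-wise error; 200 replicate cohorts of
n = 100 for log-rank power; 40-sample miRNA cohorts with 50 true + 200
decoy interactions; a 100-patient CNV cohort (the merged multi-cohort scale
of the published copy-number analysis); 5000 mutations per patient for
signature refitting. These sizes are the package's own choices for decisive
synthetic power analyses.

## Known limitations

* The miRNA DE test is a Welch t on log-CPM, not a moderated
  negative-binomial fit; at very small group sizes a quasi-likelihood or
  empirical-Bayes test would be more powerful. The interface isolates the
  substitution.
* TMM normalization leaves residual composition bias when a large fraction
  of features changes in one direction; the package inherits this known
  property of library-size normalization.
* The classifier assumes the signature genes' ranks are informative in the
  target cohort; heavy missingness (> 50%) is refused rather than imputed.
* `biallelic_pattern` trusts the per-allele status calls it is given; it
  does not infer allelic configuration from raw variants.
* The cytoband enrichment assigns each gene to one band by start position;
  genes straddling boundaries contribute to a single band only.
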