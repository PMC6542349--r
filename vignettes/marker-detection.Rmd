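---
title: "Replicate-block marker detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-block marker detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerBlocks)
```

## The problem

A marker gene is a gene whose expression is characteristically high in one
sample type — a tissue, a cell type, a condition — and low or absent in all
others profiled alongside it. Differential expression analysis finds such
genes by pairwise contrasts, but with many sample types the number of
contrasts grows quadratically, and with few replicates per type the tests
lack power. The detector in this package takes a different, parameter-light
route that is particularly suited to reference matrices with a handful of
replicates per type: it asks, per gene, whether the *replicates themselves*
group at the top of the expression profile.

The input is a `MarkerExperiment`: a normalized expression matrix $X$ with
$n$ genes and $s$ samples belonging to $t$ sample types ($t < s$), each type
with at least two replicates. The matrix must already be normalized so that
values are comparable *between* samples (log2-transformed FPKM/RPKM, TMM,
RLE, or size-factor-normalized counts all qualify); the package never
re-normalizes. Helper steps cover the usual preprocessing: a
log2(x + 1) transform (`log2Pseudocount()`) and a detectability filter that
keeps genes with positive values in at least two samples
(`filterExpressed()`). "Expressed" is read as *strictly positive*, the
natural reading for zero-inflated count-derived data.

## The detection rule

For each gene:

1. Replicate counts per type are taken from the annotation.
2. The gene's values are sorted decreasingly. The sort is stable with ties
   broken by original sample index, so results are bit-reproducible.
3. Let $T$ be the type of the largest value and $r$ its replicate count.
   The gene is a **candidate marker of $T$** if the first $r$ sorted values
   (i) all belong to $T$, (ii) are all $\ge$ the expression cutoff
   (default 1), and (iii) are strictly separated from the value at position
   $r+1$ (see *Boundary ties* below). Position $r$ is **cut-point 1**.
4. The comparison block starts at position $r+1$. It initially spans as
   many values as the type found there has replicates and is grown
   rightward until every type appearing inside it has all of its replicates
   inside it; growth stops at the end of the profile at the latest. Its end
   is **cut-point 2**.
5. The **specificity score** is the mean of the comparison block divided by
   the mean of the top block. The profile is non-increasing, so the score
   lies in $[0, 1]$: 0 means no other type expresses the gene at all
   (maximal specificity), values near 1 mean the next type expresses it
   just as highly (no specificity). Within each type, calls are ranked
   ascending by score.

```{r toy}
x <- rbind(g1 = c(10, 9, 8, 4, 3, 2))
colnames(x) <- paste0("s", 1:6)
markerCalls(detectMarkers(x, sampleType = c("A", "A", "A", "B", "B", "C")))
```

Here the three A replicates hold the top block (cut-point 1 at 3), the two
B replicates form the comparison block (cut-point 2 at 5), and the score is
$\mathrm{mean}(4,3)/\mathrm{mean}(10,9,8) = 7/18 \approx 0.389$.

### Tunable parameters

* **Expression cutoff** (default 1, the value commonly used for calling a
  gene expressed on the log2 scale): every value of the top block must
  reach it. It is applied to the matrix exactly as provided; if your matrix
  is on a different scale, scale the cutoff with it — jointly scaling
  matrix and cutoff by any $c > 0$ provably leaves the detected set and all
  scores unchanged, because the score is a ratio.
* **Replicate expectation**: the procedure is designed for $\ge 2$
  replicates per type. Types with one replicate are tolerated (with a
  warning at construction) because every step remains well defined; their
  calls rest on a single observation and should be treated accordingly.

### Boundary ties

The prose rule "all values before the cut-point come from the same type" is
ambiguous when the value at cut-point 1 ties exactly with the next value,
which necessarily belongs to another type: whether the block "comes from
one type" then depends on how the sort ordered the tie. We resolve the
ambiguity conservatively: such genes are **not** called, and their ids are
recorded in `detectorParameters(result)$boundary_ties`. This makes
candidacy independent of sample column order (a pure positional tie-break
would call every constant-across-samples gene a score-1 "marker" of
whichever type happens to be listed first) at the price of dropping genes
whose evidence is genuinely ambiguous at the cut. Ties *below* cut-point 1
are handled positionally; they can only shift which equal values sit inside
the comparison block, and equal values do not change its mean in the common
case.

Exact cross-type ties essentially never occur in continuous expression
data; the rule matters for constant background genes, integer-valued toy
data and heavily imputed matrices.

## Baseline detectors

Two classical specificity scores are included for benchmarking, both
computed on the per-type mean profile $(x_1, \dots, x_t)$ of each gene so
that all detectors rank genes per type on the same footing (the original
formulations write them per sample; collapsing replicates to their mean is
the natural grouped analogue and keeps the published cutoffs applicable):

* **SPM** (`spmMarkers()`): $\mathrm{SPM}_i = x_i / \lVert x \rVert_2$, the
  cosine between the profile and the one-hot vector of type $i$; selection
  cutoff 0.4. The cosine normalization (rather than a raw dot product)
  keeps scores in $[0,1]$ with $\sum_i \mathrm{SPM}_i^2 = 1$.
* **z-score** (`zscoreMarkers()`): $z_i = (x_i - \mu(x))/\sigma(x)$ with the
  $n-1$ sample standard deviation (the conventional estimator; the choice
  only rescales all cutoffs jointly); selection cutoff 1.
* **Random** (`randomMarkers()`): uniform per-type draws without
  replacement, size-matched to the detector under comparison; the chance
  floor for every benchmark.

## Evaluation harness

Two complementary protocols:

**Clustering quality.** Samples are embedded with PCA (samples as
observations, gene features centered but not scaled — the variance
structure of expression data is informative; unit scaling is available as
a flag) and the first two principal components are clustered with k-means,
$k$ = number of annotated types. Because k-means starts from random
centroids, `kmeansQuality()` repeats it (default 100 restarts; Lloyd
iterations, at most 300) and reports mean and sd of NMI, purity and the
adjusted Rand index against the annotated labels. Initial centroids are
drawn uniformly from the *distinct* observed coordinates: with exact
replicate coordinates (as in noise-free synthetic data) duplicate centers
would otherwise abort `stats::kmeans`. If there are fewer distinct
coordinates than $k$, samples are grouped by coordinate instead, which
yields the intuitive degenerate answers (e.g. purity = majority class
share when all samples coincide). NMI uses the arithmetic-mean
normalization of the two entropies by default (`sqrt`, `min`, `max`
variants available); ARI uses the standard hypergeometric chance
correction.

**Gold-standard agreement.** Given per-type reference marker lists, each
detector's ranked per-type list is swept from most to least specific (tied
scores enter together) to build precision–recall and ROC curves.
AUPRC uses the non-interpolated step summation
$\sum_k (R_k - R_{k-1}) P_k$; AUROC is computed as the tie-aware
Mann–Whitney probability (midranks), so all-tied scores give exactly 0.5.
Gold genes absent from a ranking count as unreachable recall. Set-level
agreement is additionally tested with `overlapZTest()`: the observed
intersection with the gold list is compared against 1000 random same-size
gene sets via a z statistic with a one-sided upper-tail normal p-value —
one-sided because the scientific question is enrichment above chance.

## The synthetic generator

`simulateExpression()` emulates the structure of a grouped reference
matrix on the log2 scale: per type, a block of planted marker genes whose
own-type level is drawn once per gene from a normal distribution (i.e.
log-normal expression) around `markerHigh` and whose other-type level is
`markerLow`; a background of housekeeping-like genes with a gene-specific
level shared by all samples; and silent genes at zero. Per-value Gaussian
technical noise (`noiseSd`), optional Bernoulli dropout (independent of
expression level — deliberately the simplest scRNA-seq-like degradation,
not a full zero-inflation model), and clipping at zero complete the model.
Defaults — 5 types × 3 replicates, 10 markers per type, 500 background
genes split evenly between housekeeping-like (level $\sim N(4,1)$) and
silent, marker levels $\sim N(8,1)$ over 0, noise sd 0.5, no dropout —
describe a small, clean bulk-like reference panel; marker/housekeeping
levels sit where log2-expression of strongly and moderately expressed
genes typically falls, and 0.5 is a realistic technical CV on that scale.

What passing on this generator shows — and what it does not: planted
markers are exactly the block-structured, one-type-high genes the detector
targets, so zero-noise recovery is a correctness check, not evidence about
real data. The generator has no library-size or gene-length biases, no
correlated gene modules, no expression-dependent dropout and no
doublet-like mixtures; real-data performance depends on normalization
quality and on how cleanly replicates group, which the discussion of
boundary ties and replicate counts above qualifies.

## Numerical choices and degenerate inputs

* All-zero genes are skipped before sorting (they cannot pass candidacy).
* The score denominator is the top-block mean, which is $\ge$ cutoff > 0
  whenever the cutoff is positive; a zero denominator (possible only with
  cutoff $\le$ 0) raises an error rather than returning NaN.
* PCA signs are fixed by making each component's largest-magnitude loading
  positive, so embeddings are platform-reproducible.
* k-means: tolerance is `stats::kmeans`'s Lloyd convergence with
  `iter.max = 300`; each restart gets its own seed derived from the master
  seed, so any run count is reproducible.
* The overlap z-test falls back to p = 0/1 with a warning when the random
  overlap distribution is degenerate (sd = 0), which happens when the
  predicted set is the whole universe.
* All file formats are plain text (TSV; Matrix Market for sparse input)
  with exact decimal round-trips for the values the package writes.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen to make every stochastic check stable under its pinned seed:
oracle comparisons on 500 random 6-sample matrices plus the exhaustive
4^6-value grid of a canonical layout; score-contract checks on 10,000
random genes; the parameter-recovery construction at the generator's
default 550 genes × 15 samples with 100 k-means restarts and 1000-draw
overlap tests; and a noise sweep over sd ∈ {0, 1, 2, 3, 4} with 20
simulations per point.

## Known limitations

* A type whose replicates never co-occupy the head of any profile yields
  no calls; with many replicates per type this becomes increasingly likely
  (the grouping probability falls), which bounds the method's reach on
  large-replicate designs — it shines where replication is scarce.
* Marker lists are relative to the sample panel: adding or removing a type
  changes the competition at the top of each profile, so calls are
  context-specific by design, not universal markers.
* No p-value accompanies the specificity score; ranking and the evaluation
  harness are the intended inference tools.
* Gene-id mapping is an offline table lookup (`mapGeneIds()`); curating
  that table is the user's responsibility.
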