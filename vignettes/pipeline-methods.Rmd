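---
title: "Methods: screen hit calling, expression signatures, enrichment maps and repair-foci scoring"
author: "dsbpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen hit calling, expression signatures, enrichment maps and repair-foci scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbpipe)
```

dsbpipe re-implements, as a tested and reusable pipeline, the
computational stages of a glioblastoma stem-cell DNA-damage study: calling
gene knockdowns that induce DNA double-strand breaks specifically in
stem-like tumor cells, post-processing a paired knockdown RNA-seq
experiment into signatures, organising enriched gene sets into an
annotated enrichment map, and scoring DNA-repair pathway choice from
per-cell imaging data. Every input can be simulated in-package with
planted ground truth, so each stage is testable end to end without any
external download.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated. They are first-class, tested code, not fixtures.

**Screen** (`gen_screen`). One well per library gene per cell population
(stem-like `GSC` and differentiated `DGC`), plus 16 scrambled-control and
4 positive-control wells per population — a 296-gene chromatin-remodeling
library by default. Per-cell gamma-H2AX mean intensity (MI) is modelled as
plate baseline x gene effect x cell noise, with a single multiplicative
log-normal noise term whose coefficient of variation is `plate_cv`
(default 0.05). Strictly positive intensities and direct CV
parameterisation motivated the log-normal choice; with `plate_cv = 0` the
model degenerates exactly to baseline x effect, which the tests exploit.
Planted hits multiply MI by `effect_gsc` (default 1.4) in GSCs and
`effect_dgc` (default 1.0) in DGCs.

**Paired counts** (`gen_counts`). Negative-binomial counts around
per-gene log-normal baselines; the two members of a replicate pair share
a random baseline factor (CV 0.1), and condition-B means are scaled by
`2^true_lfc`. Dispersion 0.05 is a typical bulk RNA-seq value for
well-replicated designs; dispersion 0 falls back to Poisson. Gene lengths
(uniform 300-8000 bp) are attached so RPKM is computable, and a
log-normal per-gene mRNA half-life (median 5 h) supports the bias check.

**Gene sets** (`gen_genesets`). Sets of a planted cluster draw members
from a shared pool of 1.5x the maximum set size, which puts the expected
within-cluster Jaccard similarity near 0.5; pools of different clusters
are disjoint, so between-cluster similarity is zero. Set names
concatenate the source label, two cluster vocabulary words and a filler
token, which is what makes tf-idf titling testable.

**Cells** (`gen_cells`). Phases are drawn from a mixture (defaults: G1
0.55, S 0.20, G2 0.15, M 0.03, polyploid 0.07). Channel intensities are
two-component log-normal mixtures: EdU high iff S, cyclin A high iff
S/G2, H3S10 high iff M. The separation between the negative and positive
modes is 2 natural-log units with component sd 0.35; at that separation
per-channel misgating is about 0.2%, so automatic gating stays above 98%
accuracy, and the separation is a dial for making gating harder. DNA
content anchors G1 at 2N (sd 0.12), S uniform on 2.3-3.7N, G2/M at 4N
(sd 0.18) and polyploid above 4.8N. Foci counts are Poisson at a planted
(marker, phase, condition) rate; nuclear area is log-normal (mean 100,
CV 0.2).

All generators derive their RNG stream from one root seed and a fixed
stage label (`stream_seed`), so stages are reproducible independently of
execution order, and fixed seeds give byte-identical outputs.

What the generators do *not* emulate matters for interpreting green
tests: there are no plate-position or batch effects, no siRNA off-target
structure, no correlation between genes beyond the shared pair baseline,
no segmentation errors in the per-cell table, and channel mixtures are
cleanly bimodal. Passing recovery tests therefore show the estimators are
correct under the stated model, not that they are robust to every
artefact of real screens.

## Screen hit calling

Wells are summarised by their mean MI; wells with fewer than `min_cells`
(default 50, chosen to stabilise well means) fail QC and are excluded.
Fold change is the well mean divided by the mean of the qc-passing
scrambled-control wells of the same plate and population. A gene is a hit
when its fold change is at least 1.20 (a 20% induction, inclusive) in
GSCs and below 1.20 in DGCs: the differential rule operates on fold
change, with z-scores reported for ranking context.

The z-score reference population is all qc-passing sample wells of the
same plate and population: hits are rare, so the sample wells approximate
a null distribution. The scale is the n-1 sample standard deviation, with
the convention z = 0 when the SD is 0. A robust variant (median and MAD)
is available via `zscore(robust = TRUE)` for plates where strong hits
would otherwise inflate the reference SD — on a plate carrying planted
effects the plain scrambled-well z-scores are compressed by construction,
which is why calibration is assessed on effect-free plates. Ranking sorts
hits by the chosen key with ties broken lexicographically by gene symbol.

The three-siRNA pool of the emulated screen is modelled as one well per
gene; per-siRNA deconvolution and spatial plate correction are out of
scope.

## Expression filtering, paired testing and signatures

Genes are kept when their RPKM (counts x 1e9 / (length x library size))
is strictly greater than 1 in at least three samples; the filter uses raw
library sizes because it precedes normalization (a flag switches to
TMM-effective sizes). TMM factors follow the published trimmed-mean
recipe: the reference sample is the one whose upper-quartile count rate
is closest to the mean; gene-wise log ratios (M) and average log
abundances (A) against the reference are trimmed by 30% (each M tail) and
5% (each A tail); the surviving M values are combined with
inverse-variance weights; and factors are rescaled to geometric mean 1.
The unit tests cross-check the implementation against an independent
reference implementation on random matrices.

Expression is log2(CPM + 1) on TMM-effective library sizes. The
differential test is a per-gene two-sided paired t-test on within-pair
differences of log-CPM, with the mean difference reported as the log2
fold change. This is a deliberate, documented approximation of the
NB-GLM likelihood-ratio workflow the design emulates — it honors the
paired structure while keeping the pipeline self-contained — and DE
tables produced externally can be supplied to every downstream stage in
the same schema. Degenerate genes whose paired differences are all equal
get p = 1 (all zero) or p = 0 (all equal, nonzero). With three pairs the
test has two degrees of freedom: planted effects of |log2 FC| = 1.5 are
estimated accurately (Spearman 0.87 against planted truth over the DE
genes) but rarely reach FDR significance, which is the expected behavior
of a paired design this small, not an implementation defect.

Multiple testing uses Benjamini-Hochberg throughout. Signatures take the
top n (default 500) genes per direction sorted by p-value, with ties
broken by |log2 FC| descending and then gene symbol for determinism; the
top-250 variant builds a derived stem-cell-style gene set. Cross-dataset
concordance is the Spearman correlation of log2 fold changes over shared
genes, with a sliding-window trend (window = ceil(5% of genes), stepping
one gene, symmetric and truncated at the ends, SE = SD/sqrt(window)) and
2D bin counts for density plotting. The half-life bias check correlates
fold changes with per-gene mRNA half-lives and summarises the mean change
per half-life quartile, flagging |r_s| > 0.3: a global transcription
slow-down masquerading as differential expression shows up here.

## Overrepresentation and the enrichment map

Overrepresentation is a one-sided (greater) Fisher exact test of the
2x2 table [[k, n-k], [m-k, N-n-m+k]] — computed as the hypergeometric
upper tail, which is identical — with the sample cross-product odds
ratio (0/0 reported NaN, x/0 reported Inf). Set members are intersected
with the universe before testing; the natural universe is the genes
surviving the expression filter. BH runs within each direction
separately. Keyword curation matches substrings on lower-cased set names
("non_homologous" only matches as a substring, hence substring rather
than token matching); the stem-cell rule's exclusion list is applied
after inclusion, and against the set name because GMT description fields
are inconsistently populated. GO sets are reduced to one ontology level
(default 6) to avoid the bulk of gene duplication; non-GO sets pass
through.

The enrichment map connects significant sets (FDR < 0.01; up and down
clustered separately) by edges requiring Jaccard similarity >= 0.15 and
overlap >= 5 genes, both inclusive. Louvain community detection runs on
the Jaccard-weighted graph (an unweighted switch exists): greedy local
moving in a seed-shuffled node order, aggregation into super-nodes,
iterated to convergence, with a node-level refinement pass and repeated
rounds until modularity stops improving. Because the greedy sweep is
order-dependent and cannot make coordinated multi-node moves, the
procedure restarts ten times per call keeping the highest-modularity
partition, and finishes with a merge-and-refine pass: every pair of
communities is tentatively merged, local moving is re-run, and
improvements are accepted until stable. On all small graphs where
exhaustive enumeration is feasible this lands on the true optimum. Ties between candidate moves resolve to the
first-scanned best community, and the seed is recorded in the partition.

Cluster titles tokenise set names on runs of non-alphanumeric characters
(underscores split, numerals kept — the names this targets are
underscore-delimited), lower-case them and drop stop words: a fixed,
versioned English snapshot shipped in the package plus the six
domain-specific tokens reactome, kegg, dn, up, network, corr. Each
cluster's token multiset is a document; tf is the within-cluster relative
frequency, idf the natural log of (number of clusters / clusters
containing the word), with no smoothing — the common text-mining default.
The top 10 words per cluster are emitted, ties broken by frequency then
alphabetically. With a single cluster all idf are zero and the title
falls back to the most frequent words. Clusters drawing sets from at
least two sources are annotated; single-source clusters keep their
scores but are flagged NA. Removing unconnected clusters for figure
clarity is a visualization choice and is not applied to the data.

## Cell-cycle gating and repair scoring

Positivity thresholds are automatic and deterministic: 2-means on log
intensity with centers initialised at the 25th and 99.5th percentiles
(so positive populations of a few percent still seed the upper cluster)
and the threshold at the midpoint of the fitted centers. When the fitted
centers sit closer than one natural-log unit the channel is treated as
unimodal — a single Gaussian mode cannot separate its 2-means centers by
more than about 1.6 sd, roughly 0.56 log units here — and the threshold
falls back to the channel maximum, calling nothing positive. An
interactive gate cannot be reproduced; this rule can.

Phase calls use the precedence polyploid > M > S > G2 > G1: polyploid
when DNA content exceeds 1.125x the G2 mode (4.5N with G1 anchored at
2N; the G2 mode is estimated as twice the primary DNA-content density
peak, and the cut is configurable because real gates vary), M when H3S10
is positive, S when EdU is positive, G2 when cyclin A is positive, else
G1. The precedence resolves double-positives deterministically — an
EdU+/cyclin A+ cell is S. A DNA-content-only mode bands the histogram
instead, for tables without the antibody channels.

Foci densities are counts normalised to nuclear area, summarised as mean
± SEM per group. The dNHEJ score — the readout for de-regulated end
joining — is the 53BP1 foci density restricted to cells gated S or G2,
where 53BP1-marked end joining should be suppressed in favour of
homologous recombination; its companions are the HR proxy (BRCA1 density
in S/G2) and the NHEJ proxy (53BP1 density in G1). Population fractions
(EdU+, mitotic, polyploid, apoptotic) are simple gated percentages;
reporter repair rates count GFP+ cells among BFP+ (transduced) cells.
Relative qPCR expression uses the delta-delta-Ct rule with fold =
2^(-ddCt); ChIP enrichment adjusts the input Ct for the input fraction
(Ct' = Ct_input - log2(1/fraction)) and reports percent input and the
IP/IgG fold. Two-group comparisons default to the equal-variance
two-sided t-test to match the convention of the assays this mirrors,
with Welch as an option.

## Numerical conventions and edge cases

- Fisher p-values come from `phyper` upper tails (exact, no asymptotics);
  BH delegates to `p.adjust`.
- z = 0 when a plate's well SD is 0; paired-test p is 0/1 for
  zero-variance differences as described above.
- The identical-groups t-test returns t = 0, p = 1 rather than an error.
- Louvain community ids are contiguous from 0 in node order; titles and
  memberships are invariant to node relabeling and name case.
- All writers emit plain TSV/GMT/JSON/GraphML; a fixed seed reproduces
  every output byte for byte.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at the scale of the
emulated study: 100 seeded screens of 296 genes x 2 populations at 200
cells/well; 50 seeded null RNA-seq datasets of 2000 genes x 3 pairs plus
a signed-effect recovery run; 20 seeded 4-cluster gene-set collections of
8 sets each; 5000 cells per condition for gating and scoring; and
exhaustive oracles (all 2x2 tables with N <= 12, all partitions of
graphs with <= 8 nodes). These sizes keep the full validation run in the
low minutes on a single core while leaving the statistical checks
well-powered.

## Known limitations

- The paired t-test on log-CPM is an approximation; with very few pairs
  it is conservative in FDR terms. Supply an external DE table when exact
  NB-GLM results are required.
- The screen model has no spatial plate structure, so no position
  correction is implemented or needed on synthetic data.
- Keyword curation reads set names, not GMT descriptions.
- The GO level filter consumes level metadata as provided; no ontology
  traversal is performed.
- Automatic gating assumes roughly bimodal log-intensity channels;
  heavily skewed real channels may need explicit thresholds, which every
  gating function accepts.
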