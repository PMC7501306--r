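# dsbpipe

Reusable R implementation of the computational stages of a glioblastoma
stem-cell DNA-damage study, for computational biologists who want to run,
test or adapt the analysis without the original imaging and sequencing
infrastructure:

- **Screen hit calling** — per-well gamma-H2AX mean-intensity (MI)
  summaries, fold change over scrambled controls, per-plate z-scores, and
  the differential rule *fc_GSC >= 1.20 and fc_DGC < 1.20* that selects
  knockdowns inducing DNA double-strand breaks in stem-like (GSC) but not
  differentiated (DGC) tumor cells.
- **Expression signatures** — RPKM > 1 in >= 3 samples filtering, TMM
  normalization, a paired t-test on log2(CPM+1) honoring the replicate
  pairing, Benjamini-Hochberg correction, MA summaries, top-n-by-p
  signature extraction (CMap-style up/down lists), cross-dataset Spearman
  concordance with a sliding-window trend, and an mRNA half-life bias
  check.
- **Enrichment maps** — one-sided Fisher overrepresentation
  (p = hypergeometric upper tail of [[k, n−k], [m−k, N−n−m+k]]), BH
  within direction, keyword-based set curation, a Jaccard gene-set graph
  (J >= 0.15, overlap >= 5), Louvain community detection on the weighted
  graph, tf-idf cluster titling (tf = within-cluster word frequency,
  idf = ln(C / clusters containing the word)) and multi-source cluster
  annotation.
- **Per-cell repair scoring** — automatic cell-cycle gating
  (EdU/cyclin A/H3S10/DNA content), nuclear-area-normalized foci
  densities, the dNHEJ score (53BP1 foci density in S/G2 cells) with
  HR/NHEJ proxies, population fractions, GFP/BFP reporter repair rates,
  delta-delta-Ct and ChIP percent-input arithmetic.
- **Synthetic data with planted truth** — seeded generators for screen
  plates, paired NB count matrices, clustered gene-set collections and
  per-cell assay tables, so every stage above is testable end to end.

## Worked example

```r
library(dsbpipe)

truth <- screen_truth(hit_genes = c("GENE0003", "GENE0017"),
                      effect_gsc = 1.4, plate_cv = 0.05,
                      cells_per_well = 200)
screen <- gen_screen(truth, n_genes = 296, seed = 42)
hits <- screen_call_hits(screen, min_cells = 50, hit_threshold = 1.2)
head(hits[, c("gene", "fc_gsc", "fc_dgc", "z_gsc", "is_hit", "rank")], 3)
#>       gene    fc_gsc    fc_dgc      z_gsc is_hit rank
#> 1 GENE0017 1.4052471 0.9984240 12.1305554   TRUE    1
#> 2 GENE0003 1.3983826 0.9975749 11.9236917   TRUE    2
#> 3 GENE0001 0.9993462 0.9983047 -0.1013969  FALSE   NA
```

Both planted hits are recovered: their MI fold change over scrambled
controls is ~1.4 in the stem-like population and ~1.0 in the
differentiated one, so the differential rule calls exactly them, and
their z-scores (~12 plate SDs) rank them far above the null wells.

The `analysis/` directory holds the numbered drivers for the full
workflow — `01_simulate.R` through `05_assay_scoring.R` — each a thin
narrative script over the package functions that prints what it found and
writes its tables under `results/`. Running stages 1, 2 and 5 prints,
among other lines:

```
hits called: 8; planted recovered: 8 / 8; false hits: 0
gating accuracy vs planted phases: 0.995
dNHEJ (53BP1 density in S/G2): control 0.0206, treated 0.0420, ratio 2.04
```

i.e. the screen recovers all planted hits with no false calls, automatic
gating agrees with the planted cell-cycle phases for 99.5% of cells, and
the planted two-fold increase in S/G2 53BP1 foci is read out as a dNHEJ
ratio of 2.04.

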