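#!/usr/bin/env Rscript
# Stage 4: gene-set overrepresentation (one-sided Fisher, BH within
# direction), enrichment-map clustering of the FDR < 0.01 sets (Jaccard
# >= 0.15 and overlap >= 5, Louvain communities), tf-idf cluster titles
# and multi-source annotation, plus the keyword curation rules.

library(dsbpipe)

coll <- read_gmt("results/data/sets.gmt")
universe <- readLines("results/data/universe.txt")
truth <- jsonlite::read_json("results/data/sets_truth.json")

# build query lists overlapping two planted clusters so overrepresentation
# has signal: the union of two sets (one per cluster), plus random filler
set.seed(44)
cl <- unlist(truth$cluster_of_set)
up_sets <- names(cl)[cl %in% c(1, 2)][c(1, 9)]
up <- unique(unlist(coll$members[up_sets]))
down_sets <- names(cl)[cl %in% c(3, 4)][c(1, 9)]
down <- setdiff(unique(unlist(coll$members[down_sets])), up)

oa <- run_oa(up, down, coll, universe, fdr_cut = 0.05)
write_oa_tsv(oa, "results/oa.tsv")
cat(sprintf("overrepresentation: %d tests, %d significant at FDR < 0.05\n",
            nrow(oa), sum(oa$significant)))

for (dir in c("up", "down")) {
  sig_sets <- oa$set[oa$direction == dir & oa$fdr < 0.01]
  if (length(sig_sets) < 2) {
    cat(sprintf("%s: fewer than 2 sets at FDR < 0.01, skipping map\n", dir))
    next
  }
  sub <- coll
  keep <- coll$names %in% sig_sets
  sub$names <- coll$names[keep]
  sub$members <- coll$members[sub$names]
  sub$source <- coll$source[sub$names]
  sub$go_level <- coll$go_level[sub$names]
  g <- build_graph(sub, j_min = 0.15, k_min = 5, direction = dir)
  p <- annotate_clusters(title_clusters(louvain_cluster(g, seed = 7)))
  write_edges_tsv(g, sprintf("results/map_%s_edges.tsv", dir))
  write_clusters_tsv(p, sprintf("results/map_%s_clusters.tsv", dir))
  write_titles_tsv(p, sprintf("results/map_%s_titles.tsv", dir))
  write_graphml(g, sprintf("results/map_%s.graphml", dir))
  cat(sprintf("%s map: %d sets, %d edges, %d communities (Q = %.3f)\n",
              dir, nrow(g$nodes), nrow(g$edges), length(p$communities),
              p$modularity))
  for (cid in names(p$communities)) {
    cat(sprintf("  community %s (%s): %s\n", cid,
                if (isTRUE(p$annotated[[cid]])) "annotated" else "NA",
                paste(utils::head(p$titles[[cid]], 5), collapse = " ")))
  }
}

# keyword curation on a demonstration collection with realistic names
demo <- set_collection(list(
  GO_DOUBLE_STRAND_BREAK_REPAIR = letters[1:6],
  REACTOME_HOMOLOGOUS_RECOMBINATION = letters[2:8],
  KEGG_NON_HOMOLOGOUS_END_JOINING = letters[3:9],
  BOQUEST_STEM_CELL_UP = letters[4:10],
  HEMATOPOIETIC_STEM_CELL_UP = letters[5:11],
  HALLMARK_GLYCOLYSIS = letters[6:12]))
cat("dna_repair curation:",
    paste(select_keyword_sets(demo, "dna_repair")$names, collapse = ", "),
    "\n")
cat("stem_cell curation:",
    paste(select_keyword_sets(demo, "stem_cell")$names, collapse = ", "),
    "\n")
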