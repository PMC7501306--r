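#!/usr/bin/env Rscript
# Stage 1: simulate every input the pipeline consumes, with planted truth.
#
# Emulated study design: a 296-gene chromatin-remodeling siRNA screen read
# out by gamma-H2AX mean intensity in matched stem-like (GSC) and
# differentiated (DGC) tumor populations; a paired 3-replicate RNA-seq
# knockdown experiment; an MSigDB-style gene-set collection with four
# planted overlap clusters; and per-cell imaging tables for two
# conditions differing in S/G2 53BP1 foci load.

library(dsbpipe)

seed <- 42
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# screen: 8 planted GSC-specific hits at 1.4x, no DGC effect
hit_genes <- sprintf("GENE%04d", c(3, 17, 58, 101, 150, 204, 260, 296))
scr_truth <- screen_truth(hit_genes = hit_genes, effect_gsc = 1.4,
                          effect_dgc = 1.0, plate_cv = 0.05,
                          cells_per_well = 200)
screen <- gen_screen(scr_truth, n_genes = 296, seed = seed)
write_screen_tsv(screen, file.path(out, "screen.tsv"))
write_truth_json(c(unclass(scr_truth), list(hit_genes = hit_genes)),
                 file.path(out, "screen_truth.json"))
cat(sprintf("screen: %d cells in %d wells, %d planted hits\n",
            nrow(screen), length(unique(screen$well)), length(hit_genes)))

# paired counts: 10% DE genes, balanced signed lfc +/-1.5
de_genes <- sprintf("G%05d", 1:200)
lfc <- stats::setNames(rep(c(1.5, -1.5), each = 100), de_genes)
cnt_truth <- de_truth(de_genes = de_genes, true_lfc = lfc, dispersion = 0.05)
cm <- gen_counts(cnt_truth, n_genes = 2000, n_pairs = 3, seed = seed)
write_counts_tsv(cm, out)
write_tsv(data.frame(gene = names(cm$true_lfc), true_lfc = cm$true_lfc,
                     half_life_h = cm$half_life),
          file.path(out, "counts_truth.tsv"))
cat(sprintf("counts: %d genes x %d samples, %d DE genes planted\n",
            nrow(cm$counts), ncol(cm$counts), length(de_genes)))

# gene sets: four planted clusters, three sources
gs <- gen_genesets(cluster_truth(n_clusters = 4, sets_per_cluster = 8),
                   universe_size = 2000, seed = seed)
write_gmt(gs$collection, file.path(out, "sets.gmt"))
writeLines(gs$universe, file.path(out, "universe.txt"))
write_truth_json(list(cluster_of_set = as.list(gs$truth$cluster_of_set),
                      vocab = gs$truth$vocab_of_cluster),
                 file.path(out, "sets_truth.json"))
cat(sprintf("gene sets: %d sets over %d genes, 4 planted clusters\n",
            length(gs$collection), length(gs$universe)))

# cells: control vs treated with doubled S/G2 53BP1 rate (dNHEJ induction)
rate_tab <- function(sg2) data.frame(
  marker = c("53bp1", "53bp1", "brca1", "gH2AX"),
  phase = c("SG2", "G1", "SG2", "*"),
  condition = "*", rate = c(sg2, 3, 5, 4))
ctl <- gen_cells(cell_truth(foci_rate = rate_tab(2)), n_cells = 5000,
                 condition = "control", seed = seed)
trt <- gen_cells(cell_truth(foci_rate = rate_tab(4)), n_cells = 5000,
                 condition = "treated", seed = seed + 1)
cells <- rbind(as.data.frame(ctl), as.data.frame(trt))
write_tsv(cells, file.path(out, "cells.tsv"))
cat(sprintf("cells: %d per condition, planted dNHEJ ratio 2\n", nrow(ctl)))
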