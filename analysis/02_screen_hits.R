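#!/usr/bin/env Rscript
# Stage 2: per-well summaries, fold changes over scrambled controls,
# per-plate z-scores, and the differential hit call (>= 20% gamma-H2AX
# MI induction in GSCs but not in DGCs).

library(dsbpipe)

screen <- read_screen_tsv("results/data/screen.tsv")
truth <- jsonlite::read_json("results/data/screen_truth.json")
planted <- unlist(truth$hit_genes)

wells <- summarize_wells(screen, min_cells = 50)
fc <- control_fold_change(wells)
z <- zscore(wells)
hits <- rank_hits(call_hits(fc, z, hit_threshold = 1.20), by = "fc_gsc")
write_hits_tsv(hits, "results/hits.tsv")

called <- hits$gene[hits$is_hit]
cat(sprintf("wells passing QC: %d / %d\n", sum(wells$qc_pass), nrow(wells)))
cat(sprintf("hits called: %d; planted recovered: %d / %d; false hits: %d\n",
            length(called), length(intersect(called, planted)),
            length(planted), length(setdiff(called, planted))))
cat("top 5 by GSC fold change:\n")
print(utils::head(hits[, c("gene", "fc_gsc", "fc_dgc", "z_gsc", "rank")], 5),
      row.names = FALSE)
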