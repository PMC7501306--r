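#!/usr/bin/env Rscript
# Stage 5: per-cell cell-cycle gating, nuclear-area-normalized foci
# densities, the dNHEJ score (53BP1 foci in S/G2) with HR/NHEJ proxies,
# flow-style population fractions, reporter repair rates, and the qPCR /
# ChIP arithmetic.

library(dsbpipe)

cells <- read_cells_tsv("results/data/cells.tsv")
ph <- gate_phases(cells)
write_tsv(ph, "results/phases.tsv")
acc <- mean(ph$phase == cells$true_phase)
cat(sprintf("gating accuracy vs planted phases: %.3f\n", acc))

sc <- dnhej_score(cells, ph)
write_tsv(sc, "results/repair_scores.tsv")
d <- sc[sc$metric == "dnhej", ]
cat(sprintf("dNHEJ (53BP1 density in S/G2): control %.4f, treated %.4f, ratio %.2f\n",
            d$mean[d$condition == "control"], d$mean[d$condition == "treated"],
            d$mean[d$condition == "treated"] / d$mean[d$condition == "control"]))

ctl <- cells[cells$condition == "control", ]
fractions <- data.frame(
  metric = c("edu_positive_pct", "mitotic_pct", "polyploid_pct"),
  value = c(population_fraction(ctl, "edu_pos"),
            population_fraction(ctl, "h3s10_pos"),
            population_fraction(ctl, "polyploid")))
write_tsv(fractions, "results/population_fractions.tsv")
print(fractions, row.names = FALSE)
cat(sprintf("reporter repair rate (GFP+ of BFP+): %.1f%%\n",
            repair_rate(ctl)))

# two-group comparison of per-cell dNHEJ densities between conditions
sg2 <- cells[ph$phase[match(cells$cell, ph$cell)] %in% c("S", "G2"), ]
dens <- foci_density(sg2, "53bp1")$per_cell
tt <- compare_groups(dens$density[dens$group == "control"],
                     dens$density[dens$group == "treated"])
cat(sprintf("unpaired t-test control vs treated dNHEJ: t = %.2f, p = %.3g\n",
            tt$t, tt$p))

# qPCR and ChIP arithmetic on worked examples
ct <- data.frame(
  sample = rep(paste0("s", 1:6), each = 2),
  condition = rep(rep(c("control", "kd"), each = 2), 3),
  gene = rep(c("HPRT1", "BRCA1"), 6),
  ct = c(20, 25, 20, 27, 20.1, 25.2, 20.2, 27.1, 19.9, 24.9, 19.8, 26.9))
dd <- ddct(ct, housekeeping = "HPRT1", reference_condition = "control")
write_tsv(dd, "results/ddct.tsv")
cat(sprintf("qPCR fold change (kd vs control): %.2f\n",
            dd$fold[dd$condition == "kd"]))
chip <- chip_enrichment(ct_ip = 24, ct_igg = 27, ct_input = 22,
                        input_fraction = 0.10)
cat(sprintf("ChIP fold enrichment over IgG: %.1f (%.2f%% input)\n",
            chip$fold_enrichment, chip$percent_input_ip))
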