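#' Split a channel into negative and positive populations
#'
#' Deterministic 2-means on log intensity (centers initialized at the
#' 25th and 99.5th percentiles, so positive populations as small as a few
#' percent of cells seed the upper cluster); the positivity threshold is
#' the midpoint
#' of the two fitted centers on the log scale. When the fitted centers
#' are closer than `min_sep` log units the channel is treated as
#' unimodal (a 2-means split of a single Gaussian mode can separate its
#' centers by at most ~1.6 sd, well under one log unit here) and the
#' threshold falls back to an upper quantile -- at the default
#' `fallback_q = 1` the threshold is the channel maximum, so no cell is
#' called positive.
#'
#' @param x Positive intensity values.
#' @param min_sep Minimum center separation (natural-log units) to accept
#'   the bimodal split.
#' @param fallback_q Quantile used for the unimodal fallback.
#' @return The threshold on the intensity (not log) scale.
#' @export
split_threshold <- function(x, min_sep = 1, fallback_q = 1) {
  .check(all(x > 0), "intensities must be > 0")
  lx <- log(x)
  q <- stats::quantile(lx, c(0.25, 0.995), names = FALSE)
  if (diff(q) < 1e-12) return(exp(stats::quantile(lx, fallback_q, names = FALSE)))
  km <- stats::kmeans(lx, centers = matrix(q, ncol = 1))
  ctr <- sort(km$centers[, 1])
  if (diff(ctr) < min_sep) {
    return(exp(stats::quantile(lx, fallback_q, names = FALSE)))
  }
  exp(mean(ctr))
}

# primary DNA-content density peak (the G1 mode, since G1 dominates)
.g1_mode <- function(dna) {
  d <- stats::density(dna, n = 512)
  d$x[which.max(d$y)]
}

#' Gate cells into cell-cycle phases
#'
#' Precedence polyploid > M > S > G2 > G1: a cell is polyploid when its
#' DNA content exceeds the polyploid cut (1.125 x the G2 mode, i.e.
#' 4.5N with G1 anchored at 2N; the G2 mode is taken as twice the primary
#' DNA-content density peak), otherwise M when H3S10 is positive, S when
#' EdU is positive, G2 when cyclin A is positive, else G1. Positivity
#' thresholds come from [split_threshold()] per channel. Mode
#' `"edu_cyclin"` uses the EdU + cyclin A channels; mode `"dna"` bands
#' the DNA content instead (S between 1.25x and 1.75x the G1 mode pair).
#'
#' @param cells A `cell_table`.
#' @param mode Gating mode, `"edu_cyclin"` or `"dna"`.
#' @param poly_factor Polyploid cut as a multiple of the G2 mode.
#' @param thresholds Optional named list overriding per-channel
#'   thresholds (`edu`, `cyclin_a`, `h3s10`, `poly_cut`).
#' @return A data frame `cell, phase` with the thresholds used attached
#'   as attribute `"gates"`.
#' @export
gate_phases <- function(cells, mode = c("edu_cyclin", "dna"),
                        poly_factor = 1.125, thresholds = list()) {
  mode <- match.arg(mode)
  need <- if (mode == "edu_cyclin") c("edu", "cyclin_a", "dna_content")
  else "dna_content"
  miss <- setdiff(need, names(cells))
  .check(length(miss) == 0, "missing channel(s) for mode %s: %s", mode,
         paste(miss, collapse = ", "))
  n <- nrow(cells)
  g1_mode <- .g1_mode(cells$dna_content)
  g2_mode <- 2 * g1_mode
  poly_cut <- if (!is.null(thresholds$poly_cut)) thresholds$poly_cut
  else poly_factor * g2_mode
  thr <- function(ch) {
    if (!is.null(thresholds[[ch]])) thresholds[[ch]]
    else split_threshold(cells[[ch]])
  }
  phase <- rep("G1", n)
  gates <- list(poly_cut = poly_cut, g1_mode = g1_mode)
  has_h3 <- "h3s10" %in% names(cells)
  if (has_h3) gates$h3s10 <- thr("h3s10")
  if (mode == "edu_cyclin") {
    gates$edu <- thr("edu")
    gates$cyclin_a <- thr("cyclin_a")
    phase[cells$cyclin_a > gates$cyclin_a] <- "G2"
    phase[cells$edu > gates$edu] <- "S"
  } else {
    lo <- 1.25 * g1_mode
    hi <- 1.75 * g1_mode
    phase[cells$dna_content >= lo & cells$dna_content < hi] <- "S"
    phase[cells$dna_content >= hi] <- "G2"
  }
  if (has_h3) phase[cells$h3s10 > gates$h3s10] <- "M"
  phase[cells$dna_content > poly_cut] <- "polyploid"
  structure(data.frame(cell = cells$cell, phase = phase,
                       stringsAsFactors = FALSE),
            gates = gates)
}

#' Nuclear-area-normalized foci density
#'
#' Per-cell density = foci count / nuclear area; group means and
#' standard errors are reported over cells within each level of
#' `group_by`.
#'
#' @param cells A `cell_table`.
#' @param marker Foci marker (`"gH2AX"`, `"53bp1"` or `"brca1"`; the
#'   corresponding `foci_<marker>` column must exist).
#' @param group_by Grouping column (default `"condition"`).
#' @return A list: `per_cell` (cell, group, density) and `summary`
#'   (group, mean, sem, n).
#' @export
foci_density <- function(cells, marker = "53bp1", group_by = "condition") {
  col <- paste0("foci_", marker)
  .check(col %in% names(cells), "marker column %s not present", col)
  .check(all(cells$nuclear_area > 0), "nuclear_area must be > 0")
  dens <- cells[[col]] / cells$nuclear_area
  grp <- cells[[group_by]]
  agg <- lapply(split(dens, grp), function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  summ <- data.frame(group = names(agg),
                     mean = vapply(agg, `[[`, numeric(1), "mean"),
                     sem = vapply(agg, `[[`, numeric(1), "sem"),
                     n = vapply(agg, function(a) as.integer(a[["n"]]),
                                integer(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(per_cell = data.frame(cell = cells$cell, group = grp, density = dens,
                             stringsAsFactors = FALSE),
       summary = summ)
}

#' De-regulated NHEJ score and its companion repair-pathway proxies
#'
#' dNHEJ = nuclear-area-normalized 53BP1 foci density restricted to
#' cells gated S or G2 (53BP1-marked end joining in replicating cells);
#' the HR proxy is the BRCA1 density in S/G2 and the NHEJ proxy the
#' 53BP1 density in G1, each summarized per condition.
#'
#' @param cells A `cell_table`.
#' @param phases Phase calls from [gate_phases()].
#' @return A data frame `condition, metric, mean, sem, n` with metrics
#'   `dnhej`, `hr_proxy`, `nhej_proxy`.
#' @export
dnhej_score <- function(cells, phases) {
  ph <- phases$phase[match(cells$cell, phases$cell)]
  sg2 <- cells[ph %in% c("S", "G2"), , drop = FALSE]
  .check(nrow(sg2) > 0, "no S/G2 cells")
  g1 <- cells[ph == "G1", , drop = FALSE]
  part <- function(sub, marker, metric) {
    if (!nrow(sub)) return(NULL)
    s <- foci_density(sub, marker)$summary
    data.frame(condition = s$group, metric = metric, mean = s$mean,
               sem = s$sem, n = s$n, stringsAsFactors = FALSE)
  }
  out <- rbind(part(sg2, "53bp1", "dnhej"),
               part(sg2, "brca1", "hr_proxy"),
               part(g1, "53bp1", "nhej_proxy"))
  rownames(out) <- NULL
  out
}

#' Percentage of cells satisfying a gating predicate
#'
#' @param cells A `cell_table`.
#' @param predicate One of `edu_pos`, `h3s10_pos`, `annexin_pos`,
#'   `casp3_pos` (channel positivity via [split_threshold()]) or
#'   `polyploid` (DNA content above the polyploid cut).
#' @param thresholds Optional overrides as in [gate_phases()].
#' @return Percentage in `[0, 100]`.
#' @export
population_fraction <- function(cells, predicate = c("edu_pos", "h3s10_pos",
                                                     "annexin_pos",
                                                     "casp3_pos",
                                                     "polyploid"),
                                thresholds = list()) {
  predicate <- match.arg(predicate)
  .check(nrow(cells) > 0, "zero cells")
  if (predicate == "polyploid") {
    cut <- if (!is.null(thresholds$poly_cut)) thresholds$poly_cut
    else 1.125 * 2 * .g1_mode(cells$dna_content)
    return(100 * mean(cells$dna_content > cut))
  }
  ch <- sub("_pos$", "", predicate)
  ch <- c(edu = "edu", h3s10 = "h3s10", annexin = "annexin",
          casp3 = "casp3")[[ch]]
  .check(ch %in% names(cells), "channel %s not present", ch)
  thr <- if (!is.null(thresholds[[ch]])) thresholds[[ch]]
  else split_threshold(cells[[ch]])
  100 * mean(cells[[ch]] > thr)
}

#' Reporter repair rate from GFP/BFP double positivity
#'
#' Restricting to transduced (BFP+) cells, the percentage that are also
#' GFP+ (i.e. repaired the reporter).
#'
#' @param cells A `cell_table` with `gfp` and `bfp` channels.
#' @param thresholds Optional named overrides (`gfp`, `bfp`).
#' @return Percentage of BFP+ cells that are GFP+.
#' @export
repair_rate <- function(cells, thresholds = list()) {
  .check(all(c("gfp", "bfp") %in% names(cells)),
         "gfp and bfp channels required")
  thr_g <- if (!is.null(thresholds$gfp)) thresholds$gfp
  else split_threshold(cells$gfp)
  thr_b <- if (!is.null(thresholds$bfp)) thresholds$bfp
  else split_threshold(cells$bfp)
  bfp_pos <- cells$bfp > thr_b
  .check(any(bfp_pos), "no BFP-positive cells")
  100 * sum(bfp_pos & cells$gfp > thr_g) / sum(bfp_pos)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, delta-Ct = Ct(target) - Ct(housekeeping); per condition
#' and target, delta-delta-Ct is the mean delta-Ct minus the reference
#' condition's mean delta-Ct, and fold change = 2^(-ddCt).
#'
#' @param ct_table Data frame `sample, condition, gene, ct`.
#' @param housekeeping Housekeeping gene (default `"HPRT1"`); must have a
#'   Ct in every sample.
#' @param reference_condition Baseline condition.
#' @return A data frame `gene, condition, ddct, fold`.
#' @export
ddct <- function(ct_table, housekeeping = "HPRT1",
                 reference_condition = "control") {
  hk <- ct_table[ct_table$gene == housekeeping, c("sample", "ct")]
  samples <- unique(ct_table$sample)
  miss <- setdiff(samples, hk$sample)
  .check(length(miss) == 0, "missing housekeeping Ct for sample(s): %s",
         paste(miss, collapse = ", "))
  tgt <- ct_table[ct_table$gene != housekeeping, , drop = FALSE]
  tgt$dct <- tgt$ct - hk$ct[match(tgt$sample, hk$sample)]
  agg <- stats::aggregate(dct ~ gene + condition, tgt, mean)
  out <- list()
  for (g in unique(agg$gene)) {
    sub <- agg[agg$gene == g, , drop = FALSE]
    ref <- sub$dct[sub$condition == reference_condition]
    .check(length(ref) == 1, "reference condition missing for gene %s", g)
    out[[g]] <- data.frame(gene = g, condition = sub$condition,
                           ddct = sub$dct - ref,
                           fold = 2^(-(sub$dct - ref)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' ChIP-qPCR fold enrichment relative to input
#'
#' The input Ct is first adjusted for the input fraction
#' (Ct' = Ct_input - log2(1 / fraction)); percent input of a sample is
#' 100 * 2^(Ct' - Ct_sample), and fold enrichment is the IP percent
#' input divided by the IgG percent input.
#'
#' @param ct_ip,ct_igg,ct_input Ct values (finite).
#' @param input_fraction Fraction of chromatin kept as input
#'   (default 0.10).
#' @return A list: `percent_input_ip`, `percent_input_igg`,
#'   `fold_enrichment`.
#' @export
chip_enrichment <- function(ct_ip, ct_igg, ct_input, input_fraction = 0.10) {
  .check(input_fraction > 0 && input_fraction <= 1,
         "input_fraction must be in (0, 1]")
  .check(all(is.finite(c(ct_ip, ct_igg, ct_input))), "Ct values must be finite")
  ct_adj <- ct_input - log2(1 / input_fraction)
  pct <- function(ct) 100 * 2^(ct_adj - ct)
  list(percent_input_ip = pct(ct_ip),
       percent_input_igg = pct(ct_igg),
       fold_enrichment = pct(ct_ip) / pct(ct_igg))
}

#' Two-group comparison by unpaired t-test
#'
#' Student's two-sample t-test (equal variance by default, Welch via
#' `var_equal = FALSE`), two-sided.
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @param var_equal Assume equal variances (Student) or not (Welch).
#' @return A list: `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  .check(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(t = 0, df = length(a) + length(b) - 2,
                p = if (mean(a) == mean(b)) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
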