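#' Filter genes by RPKM expression level
#'
#' Keeps genes expressed at more than `rpkm_min` RPKM in at least
#' `min_samples` samples, with RPKM = counts * 1e9 / (length_bp *
#' library size). The strictly-greater comparison means a gene sitting at
#' exactly `rpkm_min` everywhere is removed. Raw library sizes are used
#' by default (filtering precedes normalization); set
#' `use_effective = TRUE` together with `factors` to filter on
#' TMM-effective sizes instead.
#'
#' @param cm A `count_matrix`.
#' @param rpkm_min RPKM threshold (strictly greater; default 1).
#' @param min_samples Minimum number of samples above threshold
#'   (default 3).
#' @param use_effective Use TMM-effective library sizes.
#' @param factors Per-sample scale factors (required when
#'   `use_effective`).
#' @return The filtered `count_matrix`.
#' @export
filter_expressed <- function(cm, rpkm_min = 1, min_samples = 3,
                             use_effective = FALSE, factors = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  missing_len <- setdiff(rownames(cm$counts), names(cm$lengths))
  .check(length(missing_len) == 0, "missing gene lengths for: %s",
         paste(utils::head(missing_len, 5), collapse = ", "))
  lib <- colSums(cm$counts)
  if (use_effective) {
    .check(!is.null(factors), "factors required when use_effective = TRUE")
    lib <- lib * factors
  }
  len <- cm$lengths[rownames(cm$counts)]
  rpkm <- cm$counts * 1e9 / outer(len, lib)
  keep <- rowSums(rpkm > rpkm_min) >= min_samples
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm$lengths <- cm$lengths[rownames(cm$counts)]
  for (f in c("true_lfc", "half_life")) {
    if (!is.null(cm[[f]])) cm[[f]] <- cm[[f]][rownames(cm$counts)]
  }
  cm
}

# 75th percentile of the count/library-size rate, used to pick the TMM
# reference sample
.quantile_rate <- function(counts, p = 0.75) {
  lib <- colSums(counts)
  vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], p, names = FALSE), numeric(1))
}

# TMM factor of one sample against the reference column
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.30, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  # precision weights: inverse of the asymptotic variance of M
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Published TMM recipe: the reference is the sample whose upper-quartile
#' count rate is closest to the mean upper quartile; for each sample,
#' gene-wise log ratios M and average log abundances A against the
#' reference are trimmed (30% of M at each tail, 5% of A) and the
#' remaining M are averaged with precision weights. Factors are rescaled
#' so their geometric mean is 1; they multiply library sizes to give
#' effective sizes.
#'
#' @param cm A `count_matrix` or a bare counts matrix.
#' @param logratio_trim Fraction of M trimmed at each tail.
#' @param sum_trim Fraction of A trimmed at each tail.
#' @return A named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  .check(ncol(counts) >= 2, "need >= 2 samples")
  lib <- colSums(counts)
  .check(all(lib > 0), "sample(s) with all-zero counts: %s",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- .quantile_rate(counts)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else .tmm_pair(counts[, j], counts[, ref],
                                   lib[j], lib[ref],
                                   logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' log2 counts-per-million with a pseudocount
#'
#' CPM = counts * 1e6 / effective library size (library size times the
#' TMM factor); returned as log2(CPM + pseudocount).
#'
#' @param cm A `count_matrix` or counts matrix.
#' @param factors Per-sample scale factors (default all ones).
#' @param pseudocount Added before the log (default 1).
#' @return A genes x samples matrix of log2 expression.
#' @export
log_cpm <- function(cm, factors = NULL, pseudocount = 1) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- colSums(counts) * factors
  log2(sweep(counts * 1e6, 2, eff, "/") + pseudocount)
}

#' Paired differential expression test on log-CPM
#'
#' Per gene, a two-sided paired t-test on the within-pair differences of
#' log2 expression (condition B minus A); the log2 fold change is the
#' mean within-pair difference. This is a documented approximation of
#' the NB-GLM likelihood-ratio workflow used with a paired design;
#' externally produced DE tables with the same schema are accepted
#' downstream. Degenerate genes whose paired differences are all equal
#' get p = 1 when the common difference is 0 and p = 0 otherwise.
#'
#' @param expr log2 expression matrix from [log_cpm()].
#' @param samples Sample metadata with columns `sample, condition, pair`
#'   (conditions `A`/`B`, each pair one of each).
#' @return A `de_table` data frame: `gene, log2fc, mean_log2cpm, p, fdr`.
#' @export
paired_de <- function(expr, samples) {
  .check(all(c("sample", "condition", "pair") %in% names(samples)),
         "samples needs columns sample, condition, pair")
  .check(all(samples$condition %in% c("A", "B")), "conditions must be A/B")
  pairs <- unique(samples$pair)
  .check(length(pairs) >= 2, "need >= 2 complete pairs")
  a_idx <- b_idx <- integer(length(pairs))
  for (i in seq_along(pairs)) {
    a <- samples$sample[samples$pair == pairs[i] & samples$condition == "A"]
    b <- samples$sample[samples$pair == pairs[i] & samples$condition == "B"]
    .check(length(a) == 1 && length(b) == 1,
           "pair %s is not one A + one B sample", pairs[i])
    a_idx[i] <- match(a, colnames(expr))
    b_idx[i] <- match(b, colnames(expr))
  }
  d <- expr[, b_idx, drop = FALSE] - expr[, a_idx, drop = FALSE]
  n <- length(pairs)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  degenerate <- s == 0
  p[degenerate] <- ifelse(m[degenerate] == 0, 1, 0)
  out <- data.frame(gene = rownames(expr), log2fc = m,
                    mean_log2cpm = rowMeans(expr), p = p,
                    fdr = bh_adjust(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  .check(all(is.finite(p)) && all(p >= 0 & p <= 1),
         "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' MA summary of a DE table
#'
#' @param de A `de_table`.
#' @param fdr_cut FDR significance cut (default 0.05).
#' @return A list: `n_up` (fdr < cut and log2fc > 0), `n_down`
#'   (fdr < cut and log2fc < 0), and `ma`, the per-gene
#'   `(mean_log2cpm, log2fc, significant)` coordinates for plotting.
#' @export
ma_summary <- function(de, fdr_cut = 0.05) {
  sig <- de$fdr < fdr_cut
  list(n_up = sum(sig & de$log2fc > 0),
       n_down = sum(sig & de$log2fc < 0),
       ma = data.frame(gene = de$gene, mean_log2cpm = de$mean_log2cpm,
                       log2fc = de$log2fc,
                       significant = sig, stringsAsFactors = FALSE))
}

# order one direction of a DE table by p, then |log2fc| desc, then gene
.order_direction <- function(de, up = TRUE) {
  sub <- if (up) de[de$log2fc > 0, , drop = FALSE]
  else de[de$log2fc < 0, , drop = FALSE]
  sub[order(sub$p, -abs(sub$log2fc), sub$gene), , drop = FALSE]
}

#' Extract an up/down expression signature
#'
#' The `n` most up- and downregulated genes, sorted by p-value within
#' each direction (ties by absolute log2 fold change descending, then
#' gene symbol); directions with fewer than `n` genes are returned whole.
#' This is the list format a connectivity-query upload expects.
#'
#' @param de A `de_table`.
#' @param n Signature size per direction (default 500).
#' @return A list with character vectors `up` and `down`.
#' @export
extract_signature <- function(de, n = 500) {
  list(up = utils::head(.order_direction(de, TRUE)$gene, n),
       down = utils::head(.order_direction(de, FALSE)$gene, n))
}

#' Top upregulated genes as a derived gene set
#'
#' @param de A `de_table`.
#' @param n Set size (default 250).
#' @return A character vector of gene symbols.
#' @export
top_up_set <- function(de, n = 250) extract_signature(de, n)$up

#' Cross-dataset concordance of log2 fold changes
#'
#' Spearman correlation between the log2 fold changes of two DE tables
#' over their shared genes, plus a sliding-window trend of B along A
#' (symmetric windows of `ceil(window_frac * n)` genes, stepping one
#' gene, truncated at the ends; SE = SD / sqrt(window size)) and 2D bin
#' counts for density plotting.
#'
#' @param de_a,de_b Two `de_table`s.
#' @param window_frac Trend window as a fraction of shared genes.
#' @param n_bins Bins per axis for the density grid.
#' @return A list: `r_s`, `p`, `n`, `trend` (x, y_mean, y_se) and
#'   `bins` (x_mid, y_mid, count).
#' @export
concordance <- function(de_a, de_b, window_frac = 0.05, n_bins = 40) {
  shared <- intersect(de_a$gene, de_b$gene)
  .check(length(shared) >= 10, "need >= 10 shared genes, got %d",
         length(shared))
  x <- de_a$log2fc[match(shared, de_a$gene)]
  y <- de_b$log2fc[match(shared, de_b$gene)]
  r_s <- stats::cor(x, y, method = "spearman")
  p <- tryCatch(
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = FALSE)$p.value),
    error = function(e) NA_real_)
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  w <- ceiling(window_frac * n)
  h <- floor(w / 2)
  trend <- t(vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    c(xs[i], mean(ys[idx]),
      if (length(idx) > 1) stats::sd(ys[idx]) / sqrt(length(idx)) else 0)
  }, numeric(3)))
  brk <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  }
  xb <- brk(x); yb <- brk(y)
  ix <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1), n_bins)
  iy <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1), n_bins)
  tab <- as.data.frame(table(ix = ix, iy = iy), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  bins <- data.frame(x_mid = mids(xb)[as.integer(tab$ix)],
                     y_mid = mids(yb)[as.integer(tab$iy)],
                     count = tab$Freq)
  list(r_s = r_s, p = p, n = n,
       trend = data.frame(x = trend[, 1], y_mean = trend[, 2],
                          y_se = trend[, 3]),
       bins = bins)
}

#' Check transcriptional changes for an mRNA half-life bias
#'
#' A knockdown that merely slows transcription globally inflates apparent
#' downregulation of short-lived transcripts; this check correlates log2
#' fold changes with per-gene half-lives and summarizes the mean change
#' per half-life quartile.
#'
#' @param de A `de_table`.
#' @param half_life Named numeric vector of half-lives (hours).
#' @param limit Absolute Spearman correlation above which the bias flag
#'   is raised (default 0.3).
#' @return A list: `r_s`, `n`, `flagged`, `quartiles` (quartile,
#'   mean_log2fc, n).
#' @export
halflife_bias <- function(de, half_life, limit = 0.3) {
  shared <- intersect(de$gene, names(half_life))
  .check(length(shared) >= 50, "half-life available for < 50 genes (%d)",
         length(shared))
  lfc <- de$log2fc[match(shared, de$gene)]
  hl <- half_life[shared]
  r_s <- stats::cor(lfc, hl, method = "spearman")
  q <- stats::quantile(hl, c(0.25, 0.5, 0.75))
  quartile <- cut(hl, breaks = c(-Inf, q, Inf),
                  labels = c("Q1", "Q2", "Q3", "Q4"))
  agg <- stats::aggregate(lfc, list(quartile = quartile),
                          function(v) c(mean = mean(v), n = length(v)))
  quartiles <- data.frame(quartile = agg$quartile,
                          mean_log2fc = agg$x[, "mean"],
                          n = as.integer(agg$x[, "n"]))
  list(r_s = r_s, n = length(shared), flagged = abs(r_s) > limit,
       quartiles = quartiles)
}

#' Run the full DE stage: filter, normalize, test
#'
#' @param cm A `count_matrix`.
#' @param rpkm_min,min_samples Expression-filter parameters.
#' @return A list: `de` (a `de_table`), `factors`, `expr` (log2 CPM of
#'   the filtered genes), and the filtered `cm`.
#' @export
de_run <- function(cm, rpkm_min = 1, min_samples = 3) {
  cm <- filter_expressed(cm, rpkm_min = rpkm_min, min_samples = min_samples)
  factors <- tmm_factors(cm)
  expr <- log_cpm(cm, factors)
  de <- paired_de(expr, cm$samples)
  list(de = de, factors = factors, expr = expr, cm = cm)
}

#' Write / read a DE table as TSV
#' @param de A `de_table`.
#' @param path Path.
#' @export
write_de_tsv <- function(de, path) write_tsv(as.data.frame(de), path)

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  x <- read_tsv(path)
  .check(all(c("gene", "log2fc", "p", "fdr") %in% names(x)),
         "not a DE table: missing columns")
  class(x) <- c("de_table", "data.frame")
  x
}

#' Write a signature as a two-column TSV and plain gene lists
#'
#' @param sig A list with `up` and `down` character vectors.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Paths, invisibly.
#' @export
write_signature <- function(sig, dir, prefix = "signature") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, ".tsv"))
  write_tsv(data.frame(
    gene = c(sig$up, sig$down),
    direction = c(rep("up", length(sig$up)), rep("down", length(sig$down)))),
    p1)
  p2 <- file.path(dir, paste0(prefix, "_up.txt"))
  p3 <- file.path(dir, paste0(prefix, "_down.txt"))
  writeLines(sig$up, p2)
  writeLines(sig$down, p3)
  invisible(c(p1, p2, p3))
}
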