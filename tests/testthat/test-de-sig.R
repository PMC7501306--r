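test_that("expression filter applies the strict RPKM rule", {
  # equal library sizes (via a filler gene) so per-gene lengths can be
  # solved to give RPKM exactly 1 or 2 where intended
  counts <- rbind(
    exactly1 = c(10, 10, 10, 10),
    twice = c(20, 20, 0, 0),
    zero = c(0, 0, 0, 0),
    keep = c(20, 20, 20, 20))
  lib0 <- 50
  extra <- lib0 - colSums(counts)  # pad with a filler gene to equalize libs
  counts <- rbind(counts, filler = extra)
  len <- setNames(c(10 * 1e9 / (1 * 50), 20 * 1e9 / (2 * 50), 1000,
                    20 * 1e9 / (2 * 50), 1000), rownames(counts))
  cm <- manual_counts(counts, lengths = len, n_pairs = 2)
  kept <- filter_expressed(cm, rpkm_min = 1, min_samples = 3)
  expect_false("exactly1" %in% rownames(kept$counts))  # strict "more than"
  expect_false("twice" %in% rownames(kept$counts))
  expect_false("zero" %in% rownames(kept$counts))
  expect_true("keep" %in% rownames(kept$counts))
  cm_nolen <- cm; cm_nolen$lengths <- cm$lengths[-1]
  expect_error(filter_expressed(cm_nolen), "exactly1")
})

test_that("TMM factors are 1 for proportional libraries and match edgeR", {
  set.seed(1)
  base <- rnbinom(300, mu = 200, size = 5) + 1
  prop <- cbind(base, 2 * base, base, 2 * base)
  cmp <- manual_counts(prop)
  expect_equal(unname(tmm_factors(cmp)), rep(1, 4), tolerance = 1e-9)
  ident <- cbind(base, base)
  expect_equal(unname(tmm_factors(manual_counts(ident, n_pairs = 1))),
               c(1, 1), tolerance = 1e-9)
  expect_error(tmm_factors(manual_counts(cbind(base, 0 * base), n_pairs = 1)),
               "zero")

  skip_if_not_installed("edgeR")
  set.seed(2)
  x <- matrix(rnbinom(400 * 6, mu = exp(rnorm(400, 5, 1)), size = 3), 400, 6)
  x[sample(length(x), 50)] <- 0
  mine <- unname(tmm_factors(manual_counts(x, n_pairs = 3)))
  theirs <- unname(edgeR::calcNormFactors(x, method = "TMM"))
  expect_equal(mine, theirs, tolerance = 1e-6)
})

test_that("log-CPM handles the pseudocount and scaling identities", {
  cm <- manual_counts(matrix(c(0, 10, 0, 10), 2, 2), n_pairs = 1)
  lc <- log_cpm(cm)
  expect_equal(lc[1, 1], 0)                     # log2(0 + 1)
  # a count giving CPM exactly 1 maps to log2(2) = 1
  one <- matrix(c(1, 999999, 1, 999999), 2, 2)
  expect_equal(log_cpm(manual_counts(one, n_pairs = 1))[1, 1], 1)
  # doubling counts and library sizes leaves log-CPM unchanged
  x <- matrix(rpois(40, 50), 10, 4)
  expect_equal(log_cpm(manual_counts(x)), log_cpm(manual_counts(2 * x)),
               tolerance = 1e-12)
})

test_that("paired test returns exact nulls and handles zero variance", {
  x <- matrix(rnorm(60, 8), 10, 6,
              dimnames = list(paste0("g", 1:10), NULL))
  cm <- manual_counts(matrix(1, 10, 6))
  colnames(x) <- cm$samples$sample
  x[, cm$samples$condition == "B"] <- x[, cm$samples$condition == "A"]
  de <- paired_de(x, cm$samples)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p == 1))
  # constant nonzero differences: p capped at 0
  x2 <- x
  x2[1, cm$samples$condition == "B"] <- x2[1, cm$samples$condition == "A"] + 1
  de2 <- paired_de(x2, cm$samples)
  expect_equal(de2$p[de2$gene == "g1"], 0)
  expect_equal(de2$log2fc[de2$gene == "g1"], 1)
  expect_error(paired_de(x[, c(1, 4)], cm$samples[c(1, 4), ]), "pairs")
})

test_that("planted signed effects are recovered by the paired pipeline", {
  de_genes <- sprintf("G%05d", 1:200)
  lfc <- setNames(rep(c(1.5, -1.5), each = 100), de_genes)
  cm <- gen_counts(de_truth(de_genes = de_genes, true_lfc = lfc),
                   n_genes = 2000, n_pairs = 3, seed = 21)
  r <- de_run(cm)
  keep <- intersect(r$de$gene, de_genes)
  rho <- cor(r$de$log2fc[match(keep, r$de$gene)], cm$true_lfc[keep],
             method = "spearman")
  expect_gte(rho, 0.8)
  # estimates are unbiased: mean(estimate - truth) within 3 SE of 0
  err <- r$de$log2fc - cm$true_lfc[r$de$gene]
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
})

test_that("BH adjustment equals the textbook step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(2:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("MA summary counts strict-signed significant genes", {
  de <- structure(data.frame(
    gene = c("a", "b", "c", "d"), log2fc = c(2, -2, 0, 1),
    mean_log2cpm = 5, p = c(0.001, 0.001, 0.001, 0.9),
    fdr = c(0.01, 0.01, 0.01, 0.9)), class = c("de_table", "data.frame"))
  ms <- ma_summary(de, fdr_cut = 0.05)
  expect_equal(ms$n_up, 1)
  expect_equal(ms$n_down, 1)          # log2fc = 0 counted in neither
  expect_equal(ma_summary(de, fdr_cut = 1e-6)$n_up, 0)

  # planted 100 up / 50 down with strong effects is recovered
  de_genes <- sprintf("G%05d", 1:150)
  lfc <- setNames(c(rep(4, 100), rep(-4, 50)), de_genes)
  cm <- gen_counts(de_truth(de_genes = de_genes, true_lfc = lfc,
                            dispersion = 0.005),
                   n_genes = 2000, n_pairs = 4, seed = 9)
  r <- de_run(cm)
  ms2 <- ma_summary(r$de)
  expect_gt(ms2$n_up, 85)
  expect_lt(ms2$n_up, 120)
  expect_gt(ms2$n_down, 35)
  expect_lt(ms2$n_down, 62)
})

test_that("signature extraction follows size and deterministic tie rules", {
  set.seed(4)
  n <- 1000
  de <- structure(data.frame(
    gene = sprintf("g%04d", 1:n),
    log2fc = c(runif(600, 0.1, 3), runif(400, -3, -0.1)),
    mean_log2cpm = 5, p = runif(n), fdr = runif(n)),
    class = c("de_table", "data.frame"))
  sig <- extract_signature(de, n = 500)
  expect_length(sig$up, 500)
  expect_length(sig$down, 400)
  expect_identical(sig, extract_signature(de, n = 500))
  # ties across the boundary resolved by |lfc| then symbol
  de2 <- de
  de2$p <- rep(0.5, n)
  s1 <- extract_signature(de2, n = 10)
  ups <- de2[de2$log2fc > 0, ]
  expected <- ups$gene[order(ups$p, -abs(ups$log2fc), ups$gene)][1:10]
  expect_identical(s1$up, expected)
  # n larger than the table returns whole directions
  expect_length(extract_signature(de, n = 5000)$down, 400)
  # top-up set: right size and disjoint from downregulated genes
  top <- top_up_set(de, n = 250)
  expect_length(top, 250)
  expect_length(intersect(top, de$gene[de$log2fc < 0]), 0)
  expect_length(top_up_set(de[de$log2fc > 0, ][1:100, ], n = 250), 100)
})

test_that("concordance recovers identity, inversion and planted opposition", {
  de <- structure(data.frame(
    gene = sprintf("g%03d", 1:200), log2fc = rnorm(200),
    mean_log2cpm = 5, p = runif(200), fdr = runif(200)),
    class = c("de_table", "data.frame"))
  expect_equal(concordance(de, de)$r_s, 1)
  flip <- de; flip$log2fc <- -flip$log2fc
  expect_equal(concordance(de, flip)$r_s, -1)
  expect_error(concordance(de[1:5, ], de[1:5, ]), "10")
  cc <- concordance(de, flip, window_frac = 0.05)
  expect_equal(nrow(cc$trend), 200)
  expect_true(all(diff(cc$trend$x) >= 0))

  # planted opposed shared program: negative r_s in every seeded replicate
  signs <- vapply(1:20, function(s) {
    set.seed(s)
    shared <- rnorm(300)
    a <- structure(data.frame(gene = sprintf("g%03d", 1:300),
                              log2fc = shared + rnorm(300, sd = 0.3),
                              mean_log2cpm = 5, p = 0.5, fdr = 0.5),
                   class = c("de_table", "data.frame"))
    b <- a
    b$log2fc <- -shared + rnorm(300, sd = 0.3)
    sign(concordance(a, b)$r_s)
  }, numeric(1))
  expect_true(all(signs == -1))
})

test_that("half-life bias check flags forced confounding only", {
  set.seed(6)
  n <- 5000
  de <- structure(data.frame(
    gene = sprintf("g%05d", 1:n), log2fc = rnorm(n),
    mean_log2cpm = 5, p = runif(n), fdr = runif(n)),
    class = c("de_table", "data.frame"))
  hl <- setNames(rlnorm(n, log(5), 0.5), de$gene)
  res <- halflife_bias(de, hl)
  expect_lt(abs(res$r_s), 3 / sqrt(n))   # null: within ~3 SE of 0
  expect_false(res$flagged)
  # quartile means recombine to the global mean
  global <- sum(res$quartiles$mean_log2fc * res$quartiles$n) /
    sum(res$quartiles$n)
  expect_equal(global, mean(de$log2fc), tolerance = 1e-12)
  # forced monotone confounding is flagged
  hl2 <- setNames(exp(de$log2fc), de$gene)
  res2 <- halflife_bias(de, hl2)
  expect_gt(res2$r_s, 0.99)
  expect_true(res2$flagged)
  expect_error(halflife_bias(de, hl[1:10]), "50")
})

test_that("the pipeline is equivariant under gene permutation", {
  cm <- gen_counts(de_truth(de_genes = "G00010", true_lfc = 2),
                   n_genes = 300, n_pairs = 3, seed = 31)
  r1 <- de_run(cm)
  perm <- sample(nrow(cm$counts))
  cm2 <- cm
  cm2$counts <- cm$counts[perm, ]
  cm2$lengths <- cm$lengths[perm]
  cm2$true_lfc <- cm$true_lfc[perm]
  cm2$half_life <- cm$half_life[perm]
  r2 <- de_run(cm2)
  m1 <- r1$de[order(r1$de$gene), ]
  m2 <- r2$de[order(r2$de$gene), ]
  expect_equal(m1$log2fc, m2$log2fc, tolerance = 1e-12)
  expect_equal(m1$fdr, m2$fdr, tolerance = 1e-12)
})

test_that("type-I error is calibrated under the global null", {
  ps <- unlist(lapply(1:8, function(s) {
    cm <- gen_counts(de_truth(), n_genes = 1000, n_pairs = 3, seed = 100 + s)
    de_run(cm)$de$p
  }))
  n <- length(ps)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.005)
})
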