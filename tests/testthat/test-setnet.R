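test_that("Jaccard similarity follows the intersection/union definition", {
  expect_equal(jaccard_sim(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard_sim(letters[1:5], letters[6:10]), 0)
  expect_equal(jaccard_sim(letters[1:6], letters[4:9]), 3 / 9)
  expect_error(jaccard_sim(character(0), "a"), "empty")
})

test_that("graph construction applies both inclusive thresholds", {
  # engineered overlaps: |a|=|b|=35 with 9 shared -> J=9/61; build pairs
  mk <- function(shared, only_a, only_b) {
    list(a = c(paste0("s", seq_len(shared)), paste0("a", seq_len(only_a))),
         b = c(paste0("s", seq_len(shared)), paste0("b", seq_len(only_b))))
  }
  # J = 0.15 exactly with overlap 6: 6/40 -> union 40, each size 23
  p1 <- mk(6, 17, 17)
  expect_equal(jaccard_sim(p1$a, p1$b), 0.15)
  g1 <- build_graph(set_collection(list(A = p1$a, B = p1$b)),
                    j_min = 0.15, k_min = 5)
  expect_equal(nrow(g1$edges), 1)          # inclusive on both
  # J = 0.2, overlap 4 -> dropped by k_min
  p2 <- mk(4, 8, 8)
  expect_equal(jaccard_sim(p2$a, p2$b), 0.2)
  g2 <- build_graph(set_collection(list(A = p2$a, B = p2$b)))
  expect_equal(nrow(g2$edges), 0)
  # J just under 0.15 with big overlap -> dropped by j_min
  p3 <- mk(50, 143, 143)                   # 50/336 = 0.1488
  expect_lt(jaccard_sim(p3$a, p3$b), 0.15)
  g3 <- build_graph(set_collection(list(A = p3$a, B = p3$b)))
  expect_equal(nrow(g3$edges), 0)
  # single set: isolated node, no error
  g4 <- build_graph(set_collection(list(A = letters[1:6])))
  expect_equal(nrow(g4$nodes), 1)
  expect_equal(nrow(g4$edges), 0)
})

test_that("graph edges equal a brute-force double loop on a real collection", {
  gs <- gen_genesets(cluster_truth(4, 8), universe_size = 2000, seed = 17)
  coll <- gs$collection
  g <- build_graph(coll, j_min = 0.15, k_min = 5)
  nms <- coll$names
  expected <- 0
  for (i in seq_along(nms)[-length(nms)]) {
    for (j in seq((i + 1), length(nms))) {
      ov <- length(intersect(coll$members[[nms[i]]], coll$members[[nms[j]]]))
      jac <- ov / length(union(coll$members[[nms[i]]], coll$members[[nms[j]]]))
      if (jac >= 0.15 && ov >= 5) {
        expected <- expected + 1
        hit <- (g$edges$set_a == nms[i] & g$edges$set_b == nms[j]) |
          (g$edges$set_a == nms[j] & g$edges$set_b == nms[i])
        expect_true(any(hit))
        expect_equal(g$edges$jaccard[hit], jac)
        expect_equal(g$edges$overlap[hit], ov)
      }
    }
  }
  expect_equal(nrow(g$edges), expected)
})

test_that("Louvain resolves cliques, singletons and planted partitions", {
  # edgeless graph: every node its own community
  g0 <- toy_graph(4, matrix(numeric(0), 0, 2))
  p0 <- louvain_cluster(g0, seed = 1)
  expect_equal(length(p0$communities), 4)
  expect_setequal(unname(p0$membership), 0:3)

  # two 5-cliques joined by one edge: exactly the two cliques
  clique <- function(off) t(combn(off + 1:5, 2))
  em <- rbind(clique(0), clique(5), c(5, 6))
  g2 <- toy_graph(10, em)
  p2 <- louvain_cluster(g2, seed = 3)
  expect_equal(length(p2$communities), 2)
  expect_equal(length(unique(p2$membership[paste0("N", 1:5)])), 1)
  expect_equal(length(unique(p2$membership[paste0("N", 6:10)])), 1)
  # and its modularity matches the exhaustive optimum over all partitions
  parts <- all_partitions(10)
  nodes <- g2$nodes$name
  best <- max(vapply(parts, function(a)
    modularity_oracle(g2$edges, nodes, setNames(a, nodes)), numeric(1)))
  expect_equal(modularity_q(g2, p2), best, tolerance = 1e-12)
})

test_that("Louvain is deterministic per seed and recovers planted clusters", {
  gs <- gen_genesets(cluster_truth(4, 8), universe_size = 2000, seed = 23)
  g <- build_graph(gs$collection)
  p1 <- louvain_cluster(g, seed = 5)
  p2 <- louvain_cluster(g, seed = 5)
  expect_identical(p1$membership, p2$membership)
  skip_if_not_installed("mclust")
  truth <- gs$truth$cluster_of_set[names(p1$membership)]
  ari <- mclust::adjustedRandIndex(p1$membership, truth)
  expect_gte(ari, 0.9)
})

test_that("modularity identities hold and Louvain beats singletons", {
  # all nodes in one community -> Q = 0
  g <- toy_graph(6, t(combn(1:6, 2)))
  one <- setNames(rep(0L, 6), g$nodes$name)
  expect_equal(modularity_q(g, one), 0)
  # two disconnected equal cliques split correctly -> Q = 0.5
  g2 <- toy_graph(8, rbind(t(combn(1:4, 2)), t(combn(5:8, 2))))
  split2 <- setNames(rep(0:1, each = 4), g2$nodes$name)
  expect_equal(modularity_q(g2, split2), 0.5)
  # optimizer sanity: Q(louvain) >= Q(all singletons)
  gs <- gen_genesets(cluster_truth(3, 6), universe_size = 1500, seed = 29)
  gg <- build_graph(gs$collection)
  p <- louvain_cluster(gg, seed = 1)
  singl <- setNames(seq_len(nrow(gg$nodes)) - 1L, gg$nodes$name)
  expect_gte(modularity_q(gg, p), modularity_q(gg, singl))
  expect_error(modularity_q(gg, p$membership[-1]), "cover")
  skip_if_not_installed("igraph")
  # independent cross-check of Q on the planted graph
  ig <- igraph::graph_from_data_frame(gg$edges[, 1:2], directed = FALSE,
                                      vertices = gg$nodes$name)
  q_ig <- igraph::modularity(ig, p$membership[igraph::V(ig)$name] + 1,
                             weights = gg$edges$jaccard)
  expect_equal(modularity_q(gg, p), q_ig, tolerance = 1e-12)
})

test_that("Louvain modularity is near-optimal on all small random graphs", {
  set.seed(77)
  graphs <- list()
  for (rep in 1:25) {        # draw all graphs first: clustering reseeds RNG
    n <- sample(4:8, 1)
    prs <- t(combn(seq_len(n), 2))
    keep <- runif(nrow(prs)) < 0.45
    if (!any(keep)) next
    em <- prs[keep, , drop = FALSE]
    graphs[[length(graphs) + 1]] <- toy_graph(n, em,
                                              jaccard = runif(nrow(em), 0.2, 1))
  }
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    p <- louvain_cluster(g, seed = i)
    nodes <- g$nodes$name
    best <- max(vapply(all_partitions(length(nodes)), function(a)
      modularity_oracle(g$edges, nodes, setNames(a, nodes)), numeric(1)))
    if (best > 0) {
      expect_gte(modularity_q(g, p), 0.95 * best)
    } else {
      expect_gte(modularity_q(g, p), best - 1e-12)
    }
  }
})

test_that("tf-idf titling matches hand computation and its conventions", {
  # 4 clusters; word unique to one cluster, 2 of its 10 tokens:
  # tf-idf = 0.2 * ln 4
  g <- toy_graph(8, matrix(numeric(0), 0, 2))
  part <- louvain_cluster(g, seed = 1)
  # overwrite communities with a fixed 4-cluster layout over 8 nodes
  part$membership <- setNames(rep(0:3, each = 2L), g$nodes$name)
  part$communities <- split(names(part$membership), part$membership)
  # build names so cluster 0 has 10 tokens of which 2 are "alpha"
  part$communities[["0"]] <- c("ALPHA_BETA_GAMMA_DELTA_EPSILON",
                               "ALPHA_ZETA_ETA_THETA_IOTA")
  part$communities[["1"]] <- c("BETA_ONE_TWO", "THREE_FOUR_FIVE")
  part$communities[["2"]] <- c("BETA_SIX_SEVEN", "EIGHT_NINE_TEN")
  part$communities[["3"]] <- c("BETA_ELEVEN_TWELVE", "THIRTEEN_X_Y")
  titled <- title_clusters(part)
  sc <- titled$tfidf
  a <- sc[sc$community == "0" & sc$word == "alpha", ]
  expect_equal(a$tfidf, 0.2 * log(4), tolerance = 1e-12)
  # "beta" appears in every cluster -> idf = 0 everywhere
  expect_true(all(sc$tfidf[sc$word == "beta"] == 0))
  expect_true("alpha" %in% titled$titles[["0"]])
})

test_that("single-cluster titling falls back to word frequency", {
  g <- toy_graph(2, matrix(c(1, 2), 1, 2))
  p <- louvain_cluster(g, seed = 1)
  p$membership <- setNames(c(0L, 0L), g$nodes$name)
  p$communities <- list("0" = c("REPAIR_REPAIR_DAMAGE", "REPAIR_BREAK"))
  t1 <- title_clusters(p)
  expect_true(all(t1$tfidf$tfidf == 0))          # idf = ln 1 = 0
  expect_equal(t1$titles[["0"]][1], "repair")    # frequency fallback
})

test_that("titling is invariant to node relabeling and name case", {
  gs <- gen_genesets(cluster_truth(3, 5), universe_size = 1500, seed = 31)
  g <- build_graph(gs$collection)
  p <- title_clusters(louvain_cluster(g, seed = 2))
  # lower-case every set name: tokens are case-normalized so titles agree
  g_lc <- g
  g_lc$nodes$name <- tolower(g$nodes$name)
  names(g_lc$members) <- tolower(names(g$members))
  g_lc$edges$set_a <- tolower(g$edges$set_a)
  g_lc$edges$set_b <- tolower(g$edges$set_b)
  p_lc <- title_clusters(louvain_cluster(g_lc, seed = 2))
  expect_identical(p$titles, p_lc$titles)
  # stop words (including the six domain words) never title a cluster
  expect_false(any(c("reactome", "kegg", "dn", "up", "network", "corr") %in%
                     unlist(p$titles)))
})

test_that("multi-source clusters are annotated, single-source flagged NA", {
  gs <- gen_genesets(cluster_truth(2, 6, sources = c("hallmark", "curated")),
                     universe_size = 1000, seed = 37)
  g <- build_graph(gs$collection)
  p <- annotate_clusters(louvain_cluster(g, seed = 1))
  src <- setNames(g$nodes$source, g$nodes$name)
  for (cid in names(p$communities)) {
    expect_equal(unname(p$annotated[cid]),
                 length(unique(src[p$communities[[cid]]])) >= 2)
  }
  # force single-source: all-go collection is never annotated
  gs2 <- gen_genesets(cluster_truth(2, 4, sources = "go"),
                      universe_size = 1000, seed = 38)
  p2 <- annotate_clusters(louvain_cluster(build_graph(gs2$collection),
                                          seed = 1))
  expect_false(any(p2$annotated))
})

test_that("graph and partition writers emit well-formed tables", {
  dir <- withr::local_tempdir()
  gs <- gen_genesets(cluster_truth(2, 4), universe_size = 1000, seed = 41)
  g <- build_graph(gs$collection)
  p <- annotate_clusters(title_clusters(louvain_cluster(g, seed = 1)))
  write_edges_tsv(g, file.path(dir, "edges.tsv"))
  e <- read_tsv(file.path(dir, "edges.tsv"))
  expect_named(e, c("set_a", "set_b", "jaccard", "overlap"))
  write_clusters_tsv(p, file.path(dir, "clusters.tsv"))
  cl <- read_tsv(file.path(dir, "clusters.tsv"))
  expect_equal(nrow(cl), nrow(g$nodes))
  write_titles_tsv(p, file.path(dir, "titles.tsv"))
  ti <- read_tsv(file.path(dir, "titles.tsv"))
  expect_true(all(ti$rank >= 1 & ti$rank <= 10))
  write_graphml(g, file.path(dir, "g.graphml"))
  xml <- readLines(file.path(dir, "g.graphml"))
  expect_true(any(grepl("<graphml", xml)))
  expect_equal(sum(grepl("<node ", xml)), nrow(g$nodes))
  expect_equal(sum(grepl("<edge ", xml)), nrow(g$edges))
})
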