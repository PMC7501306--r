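# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# textbook Benjamini-Hochberg step-up: sort ascending, p_(i) * n / i,
# enforce monotonicity from the largest rank down, cap at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# one-sided Fisher p by exhaustive hypergeometric summation:
# P(X >= k) where X ~ Hypergeom(N, m, n)
fisher_oracle <- function(k, n, m, N) {
  jmax <- min(n, m)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) stats::dhyper(j, m, N - m, n), numeric(1)))
}

# all set partitions of 1..n (restricted growth strings); for exhaustive
# modularity maximization on tiny graphs
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_id) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (c in seq_len(next_id)) rec(c(assign, c), next_id)
    rec(c(assign, next_id + 1), next_id + 1)
  }
  rec(integer(0), 0)
  out
}

# brute-force modularity of a membership vector on an edge data frame
# (vectorized: Q = within-weight/m - sum_c (tot_c / 2m)^2)
modularity_oracle <- function(edges, nodes, membership, weighted = TRUE) {
  if (!nrow(edges)) return(0)
  w <- if (weighted) edges$jaccard else rep(1, nrow(edges))
  m <- sum(w)
  within <- sum(w[membership[edges$set_a] == membership[edges$set_b]]) / m
  deg <- tapply(c(w, w), c(edges$set_a, edges$set_b), sum)
  tot <- tapply(deg, membership[names(deg)], sum)
  within - sum((tot / (2 * m))^2)
}

# a small set_graph built directly from an edge list (unit Jaccard weights
# unless given), for clustering tests
toy_graph <- function(n, edges_mat, jaccard = NULL) {
  nms <- paste0("N", seq_len(n))
  members <- setNames(lapply(seq_len(n), function(i) paste0("g", i)), nms)
  if (is.null(jaccard)) jaccard <- rep(1, nrow(edges_mat))
  structure(list(
    nodes = data.frame(name = nms, direction = "up", source = "curated",
                       stringsAsFactors = FALSE),
    members = members,
    edges = data.frame(set_a = nms[edges_mat[, 1]],
                       set_b = nms[edges_mat[, 2]],
                       jaccard = jaccard,
                       overlap = rep(5L, nrow(edges_mat)),
                       stringsAsFactors = FALSE)),
    class = "set_graph")
}

# convenience: a count_matrix built from explicit components
manual_counts <- function(counts, lengths = NULL, n_pairs = ncol(counts) / 2) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
  samples <- data.frame(
    sample = c(paste0("A_", seq_len(n_pairs)), paste0("B_", seq_len(n_pairs))),
    condition = rep(c("A", "B"), each = n_pairs),
    pair = rep(paste0("p", seq_len(n_pairs)), 2),
    stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples, lengths = lengths),
            class = "count_matrix")
}
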