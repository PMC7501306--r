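#' Jaccard similarity of two gene sets
#'
#' The fraction of genes in the union of the two sets that are found in
#' both.
#'
#' @param a,b Nonempty character vectors.
#' @return A number in `[0, 1]`.
#' @export
jaccard_sim <- function(a, b) {
  .check(length(a) > 0 && length(b) > 0, "empty set")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Build a Jaccard-weighted gene-set graph
#'
#' Nodes are (FDR-screened) gene sets; all pairs are scored by Jaccard
#' similarity and an edge is kept when both the similarity and the
#' absolute overlap pass their thresholds (both comparisons inclusive).
#' Up- and downregulated results are intended to be clustered in
#' separate invocations.
#'
#' @param collection A [set_collection()] of the significant sets.
#' @param j_min Minimum Jaccard similarity (default 0.15).
#' @param k_min Minimum overlap in genes (default 5).
#' @param direction Direction label stored on the nodes.
#' @return A `set_graph`: list with `nodes` (name, direction, source),
#'   `members`, and `edges` (set_a, set_b, jaccard, overlap).
#' @export
build_graph <- function(collection, j_min = 0.15, k_min = 5,
                        direction = "up") {
  stopifnot(inherits(collection, "set_collection"))
  nms <- collection$names
  n <- length(nms)
  ea <- eb <- character(0); jj <- numeric(0); kk <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      mi <- collection$members[[nms[i]]]
      for (j in seq((i + 1), n)) {
        mj <- collection$members[[nms[j]]]
        ov <- length(intersect(mi, mj))
        if (ov < k_min) next
        jac <- ov / length(union(mi, mj))
        if (jac >= j_min) {
          ea <- c(ea, nms[i]); eb <- c(eb, nms[j])
          jj <- c(jj, jac); kk <- c(kk, ov)
        }
      }
    }
  }
  structure(list(
    nodes = data.frame(name = nms, direction = direction,
                       source = unname(collection$source[nms]),
                       stringsAsFactors = FALSE),
    members = collection$members,
    edges = data.frame(set_a = ea, set_b = eb, jaccard = jj, overlap = kk,
                       stringsAsFactors = FALSE)),
    class = "set_graph")
}

# weighted adjacency (list form) from a set_graph; optional unweighted
.adjacency <- function(graph, weighted = TRUE) {
  n <- nrow(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes$name)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), w = numeric(0))
  e <- graph$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      i <- idx[[e$set_a[r]]]; j <- idx[[e$set_b[r]]]
      w <- if (weighted) e$jaccard[r] else 1
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$w <- c(adj[[i]]$w, w)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$w <- c(adj[[j]]$w, w)
    }
  }
  adj
}

# local moving phase: greedy reassignment of nodes to the neighboring (or
# an empty) community with the best modularity gain, visiting nodes in a
# shuffled order, repeated until a full pass makes no move
.local_moving <- function(adj, self_w, resolution, comm_init) {
  n <- length(adj)
  deg <- vapply(seq_len(n), function(i) sum(adj[[i]]$w), numeric(1)) +
    2 * self_w
  two_m <- sum(deg)
  comm <- comm_init
  if (two_m == 0) return(comm)
  comm_tot <- vapply(seq_len(n), function(c) sum(deg[comm == c]), numeric(1))
  sizes <- tabulate(comm, nbins = n)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      w_to <- tapply(adj[[i]]$w, comm[adj[[i]]$nbr], sum)
      comm_tot[ci] <- comm_tot[ci] - deg[i]
      sizes[ci] <- sizes[ci] - 1L
      base <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      best_gain <- base - resolution * comm_tot[ci] * deg[i] / two_m
      best_c <- ci
      for (cn in names(w_to)) {
        c2 <- as.integer(cn)
        if (c2 == ci) next
        gain <- w_to[[cn]] - resolution * comm_tot[c2] * deg[i] / two_m
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_c <- c2 }
      }
      if (0 > best_gain + 1e-12) {        # isolate i in an empty community
        free <- which(sizes == 0L)
        if (length(free)) { best_gain <- 0; best_c <- free[1] }
      }
      comm[i] <- best_c
      comm_tot[best_c] <- comm_tot[best_c] + deg[i]
      sizes[best_c] <- sizes[best_c] + 1L
      if (best_c != ci) moved <- TRUE
    }
    if (!moved) break
  }
  comm
}

# collapse a partition into its aggregate graph (self-loops keep internal
# weight; parallel inter-community edges are summed)
.aggregate_graph <- function(adj, self_w, comm) {
  k <- max(comm)
  new_adj <- vector("list", k)
  for (c2 in seq_len(k)) new_adj[[c2]] <- list(nbr = integer(0), w = numeric(0))
  new_self <- vapply(seq_len(k), function(c2) sum(self_w[comm == c2]),
                     numeric(1))
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(adj)) {
    ci <- comm[i]
    nb <- adj[[i]]$nbr; w <- adj[[i]]$w
    for (t in seq_along(nb)) {
      cj <- comm[nb[t]]
      if (cj == ci) {
        new_self[ci] <- new_self[ci] + w[t] / 2   # each edge seen twice
      } else if (cj > ci) {
        key <- paste(ci, cj)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w[t]
      }
    }
  }
  for (key in ls(acc)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    new_adj[[ij[1]]]$nbr <- c(new_adj[[ij[1]]]$nbr, ij[2])
    new_adj[[ij[1]]]$w <- c(new_adj[[ij[1]]]$w, acc[[key]])
    new_adj[[ij[2]]]$nbr <- c(new_adj[[ij[2]]]$nbr, ij[1])
    new_adj[[ij[2]]]$w <- c(new_adj[[ij[2]]]$w, acc[[key]])
  }
  list(adj = new_adj, self = new_self)
}

#' Louvain community detection on a gene-set graph
#'
#' Standard two-phase Louvain: greedy local moving of nodes between
#' communities (visit order shuffled by `seed`) followed by aggregation
#' of communities into super-nodes, iterated until modularity stops
#' improving. Because the greedy sweep is order-dependent, the whole
#' procedure is restarted `n_restarts` times (default 10) with fresh
#' shuffles and the
#' highest-modularity partition is kept. Edges are weighted by Jaccard
#' similarity unless `weighted = FALSE`. Deterministic for a fixed seed.
#'
#' @param graph A `set_graph` from [build_graph()].
#' @param seed Integer seed for the node visit order.
#' @param resolution Resolution parameter of the modularity gain
#'   (default 1 = plain modularity).
#' @param weighted Use Jaccard edge weights.
#' @param n_restarts Shuffled restarts of the full two-phase procedure.
#' @return A `partition`: list with `membership` (named integer vector,
#'   community ids contiguous from 0), `communities` (member list),
#'   `seed`, and placeholders for titles/annotation.
#' @export
louvain_cluster <- function(graph, seed = 1, resolution = 1,
                            weighted = TRUE, n_restarts = 10) {
  stopifnot(inherits(graph, "set_graph"))
  n <- nrow(graph$nodes)
  .check(n > 0, "empty graph")
  set.seed(stream_seed(seed, "louvain"))
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(max(1, n_restarts))) {
    memb <- .louvain_once(graph, resolution, weighted)
    q <- modularity_q(graph, memb, weighted = weighted)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  communities <- split(names(best), best)
  structure(list(membership = best, communities = communities,
                 seed = seed, resolution = resolution,
                 modularity = best_q,
                 titles = NULL, tfidf = NULL, annotated = NULL,
                 graph = graph),
            class = "partition")
}

# one full Louvain run: node-level local moving, then repeated
# aggregation with local moving on the collapsed graph, with a final
# node-level refinement pass; the outer loop repeats until modularity
# stops improving. Consumes RNG state for the visit orders.
.louvain_once <- function(graph, resolution, weighted) {
  adj0 <- .adjacency(graph, weighted)
  n0 <- length(adj0)
  zero_self <- rep(0, n0)
  node_comm <- seq_len(n0)
  q_of <- function(comm) {
    modularity_q(graph, stats::setNames(comm, graph$nodes$name),
                 weighted = weighted)
  }
  q_prev <- q_of(node_comm)
  repeat {
    # phase 1 at node level (doubles as refinement on later rounds)
    node_comm <- .local_moving(adj0, zero_self, resolution, node_comm)
    node_comm <- match(node_comm, unique(node_comm))
    # phase 2: aggregate and keep optimizing the collapsed graph
    agg <- .aggregate_graph(adj0, zero_self, node_comm)
    map <- seq_along(agg$adj)
    repeat {
      comm <- .local_moving(agg$adj, agg$self, resolution, seq_along(agg$adj))
      comm <- match(comm, unique(comm))
      if (max(comm) == length(agg$adj)) break
      map <- comm[map]
      agg <- .aggregate_graph(agg$adj, agg$self, comm)
    }
    node_comm <- map[node_comm]
    q <- q_of(node_comm)
    if (q <= q_prev + 1e-12) break
    q_prev <- q
  }
  # merge-and-refine: the greedy sweep cannot make coordinated multi-node
  # moves, so tentatively merge each pair of communities, re-run local
  # moving, and accept any improvement; repeat until stable (skipped on
  # partitions too large for the quadratic pair scan to be worthwhile)
  repeat {
    k <- length(unique(node_comm))
    if (k < 2 || k > 25) break
    ids <- unique(node_comm)
    improved <- FALSE
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        cand <- node_comm
        cand[cand == ids[b]] <- ids[a]
        cand <- .local_moving(adj0, zero_self, resolution,
                              match(cand, unique(cand)))
        qc <- q_of(cand)
        if (qc > q_prev + 1e-12) {
          node_comm <- match(cand, unique(cand))
          q_prev <- qc
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  # contiguous ids from 0 in node order
  stats::setNames(match(node_comm, unique(node_comm)) - 1L,
                  graph$nodes$name)
}

#' Weighted Newman modularity of a partition
#'
#' Q = sum over communities of (within-weight / 2m - (total degree /
#' 2m)^2), computed on the Jaccard-weighted graph.
#'
#' @param graph A `set_graph`.
#' @param membership Named community vector covering every node (a
#'   `partition` is also accepted).
#' @param weighted Use Jaccard edge weights.
#' @return Modularity Q (0 for an edgeless graph).
#' @export
modularity_q <- function(graph, membership, weighted = TRUE) {
  if (inherits(membership, "partition")) membership <- membership$membership
  nodes <- graph$nodes$name
  .check(all(nodes %in% names(membership)), "membership must cover all nodes")
  e <- graph$edges
  if (!nrow(e)) return(0)
  w <- if (weighted) e$jaccard else rep(1, nrow(e))
  two_m <- 2 * sum(w)
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (r in seq_len(nrow(e))) {
    deg[e$set_a[r]] <- deg[e$set_a[r]] + w[r]
    deg[e$set_b[r]] <- deg[e$set_b[r]] + w[r]
  }
  q <- 0
  m <- sum(w)
  for (cid in unique(membership[nodes])) {
    in_c <- nodes[membership[nodes] == cid]
    within <- sum(w[e$set_a %in% in_c & e$set_b %in% in_c])
    q <- q + within / m - (sum(deg[in_c]) / two_m)^2
  }
  q
}

# fixed snapshot of common English stop words, extended by the six
# domain words stripped from gene-set names before tf-idf titling
.stop_words <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot",
  "could", "did", "do", "does", "doing", "down", "during", "each", "few",
  "for", "from", "further", "had", "has", "have", "having", "he", "her",
  "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is",
  "it", "its", "itself", "just", "me", "more", "most", "my", "myself",
  "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
  "other", "our", "ours", "out", "over", "own", "same", "she", "should",
  "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
  "then", "there", "these", "they", "this", "those", "through", "to",
  "too", "under", "until", "up", "very", "was", "we", "were", "what",
  "when", "where", "which", "while", "who", "whom", "why", "will",
  "with", "would", "you", "your", "yours",
  "reactome", "kegg", "dn", "network", "corr")
# note: "up" and "dn" are both stripped; "up" already sits in the base list

#' Title clusters by tf-idf over gene-set name words
#'
#' Set names are tokenized on runs of non-alphanumeric characters
#' (underscores split), lower-cased and stripped of stop words (a fixed
#' built-in English snapshot plus reactome, kegg, dn, up, network, corr,
#' plus any extra words supplied). Each cluster's token multiset is one
#' document: tf = word count / cluster token total, idf = ln(number of
#' clusters / number of clusters containing the word), score = tf x idf.
#' The top 10 words per cluster are emitted (ties broken by frequency,
#' then alphabetically). With a single cluster every idf is 0, so the
#' title falls back to the most frequent words.
#'
#' @param partition A `partition` from [louvain_cluster()].
#' @param stop_words Extra stop words (appended to the built-in list).
#' @param n_words Words per title (default 10).
#' @return The partition with `titles` (list of character vectors per
#'   community id) and `tfidf` (data frame community, word, n, tf, idf,
#'   tfidf) filled.
#' @export
title_clusters <- function(partition, stop_words = character(0),
                           n_words = 10) {
  stopifnot(inherits(partition, "partition"))
  stops <- c(.stop_words, tolower(stop_words))
  docs <- lapply(partition$communities, function(sets) {
    toks <- tolower(unlist(strsplit(sets, "[^A-Za-z0-9]+")))
    toks <- toks[nzchar(toks) & !(toks %in% stops)]
    toks
  })
  C <- length(docs)
  vocab <- unique(unlist(docs))
  df_count <- vapply(vocab, function(w)
    sum(vapply(docs, function(d) w %in% d, logical(1))), numeric(1))
  idf <- stats::setNames(log(C / df_count), vocab)
  rows <- list()
  titles <- list()
  for (cid in names(docs)) {
    d <- docs[[cid]]
    if (!length(d)) {
      warning(sprintf("cluster %s has no tokens after stop-wording", cid))
      titles[[cid]] <- character(0)
      next
    }
    tab <- table(d)
    tf <- as.numeric(tab) / length(d)
    sc <- tf * idf[names(tab)]
    ord <- order(-sc, -as.numeric(tab), names(tab))
    if (all(sc == 0)) ord <- order(-as.numeric(tab), names(tab))  # C == 1
    top <- utils::head(names(tab)[ord], n_words)
    titles[[cid]] <- top
    rows[[cid]] <- data.frame(community = cid, word = names(tab),
                              n = as.integer(tab), tf = tf,
                              idf = unname(idf[names(tab)]),
                              tfidf = unname(sc), stringsAsFactors = FALSE)
  }
  partition$titles <- titles
  partition$tfidf <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  partition
}

#' Flag clusters spanning more than one gene-set source
#'
#' Clusters whose member sets come from at least two distinct sources
#' are marked annotated; single-source clusters keep their scores but
#' are flagged NA.
#'
#' @param partition A `partition` (its `graph` supplies node sources).
#' @return The partition with a named logical `annotated` per community.
#' @export
annotate_clusters <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  src <- stats::setNames(partition$graph$nodes$source,
                         partition$graph$nodes$name)
  partition$annotated <- vapply(partition$communities, function(sets)
    length(unique(src[sets])) >= 2, logical(1))
  partition
}

#' Write the edge list of a set graph to TSV
#' @param graph A `set_graph`.
#' @param path Output path.
#' @export
write_edges_tsv <- function(graph, path) write_tsv(graph$edges, path)

#' Write a set graph as GraphML
#' @param graph A `set_graph`.
#' @param path Output path.
#' @export
write_graphml <- function(graph, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="jaccard" attr.type="double"/>',
    '  <key id="k" for="edge" attr.name="overlap" attr.type="int"/>',
    '  <key id="s" for="node" attr.name="source" attr.type="string"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(graph$nodes))) {
    writeLines(sprintf('    <node id="%s"><data key="s">%s</data></node>',
                       esc(graph$nodes$name[i]), esc(graph$nodes$source[i])),
               con)
  }
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="w">%.6f</data><data key="k">%d</data></edge>',
      esc(e$set_a[r]), esc(e$set_b[r]), e$jaccard[r], e$overlap[r]), con)
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}

#' Write cluster membership to TSV
#' @param partition A `partition`.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(partition, path) {
  ann <- partition$annotated
  write_tsv(data.frame(
    set = names(partition$membership),
    direction = partition$graph$nodes$direction[
      match(names(partition$membership), partition$graph$nodes$name)],
    community = unname(partition$membership),
    annotated = if (is.null(ann)) NA else
      unname(ann[as.character(partition$membership)]),
    stringsAsFactors = FALSE), path)
}

#' Write cluster titles to TSV
#' @param partition A titled `partition`.
#' @param path Output path.
#' @export
write_titles_tsv <- function(partition, path) {
  .check(!is.null(partition$titles), "run title_clusters() first")
  rows <- list()
  for (cid in names(partition$titles)) {
    words <- partition$titles[[cid]]
    if (!length(words)) next
    sc <- partition$tfidf[partition$tfidf$community == cid, ]
    rows[[cid]] <- data.frame(
      community = cid, rank = seq_along(words), word = words,
      tfidf = sc$tfidf[match(words, sc$word)], stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))), path)
}
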