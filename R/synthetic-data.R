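#' Planted truth for a synthetic siRNA screen
#'
#' Describes the ground truth behind a simulated high-content screen:
#' which genes are hits, the multiplicative effect their knockdown has on
#' the gamma-H2AX mean intensity (MI) in each cell population, and the
#' noise level of the per-cell intensity readout.
#'
#' @param hit_genes Character vector of hit gene symbols (subset of the
#'   library; validated in [gen_screen()]).
#' @param effect_gsc Multiplicative MI effect of a hit in the stem-like
#'   (GSC) population; either a scalar applied to all hits or a named
#'   vector over `hit_genes`. Must be > 0.
#' @param effect_dgc Multiplicative effect in the differentiated (DGC)
#'   population (default 1: no induction).
#' @param plate_cv Coefficient of variation of the multiplicative
#'   log-normal per-cell noise.
#' @param cells_per_well Number of cells imaged per well (>= 1).
#' @param baseline_mi Plate baseline MI in arbitrary units.
#' @param positive_effect Multiplicative effect of the positive-control
#'   wells (applies in both populations).
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(hit_genes = character(), effect_gsc = 1.4,
                         effect_dgc = 1.0, plate_cv = 0.05,
                         cells_per_well = 200, baseline_mi = 1000,
                         positive_effect = 2.0) {
  .check(all(effect_gsc > 0) && all(effect_dgc > 0) && positive_effect > 0,
         "all effects must be > 0")
  .check(cells_per_well >= 1, "cells_per_well must be >= 1")
  .check(plate_cv >= 0, "plate_cv must be >= 0")
  structure(list(hit_genes = as.character(hit_genes),
                 effect_gsc = effect_gsc, effect_dgc = effect_dgc,
                 plate_cv = plate_cv, cells_per_well = as.integer(cells_per_well),
                 baseline_mi = baseline_mi, positive_effect = positive_effect),
            class = "screen_truth")
}

# log-normal draws with mean `m` and coefficient of variation `cv`
.rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.effect_for <- function(effect, gene) {
  if (is.null(names(effect))) return(unname(effect[1]))
  if (gene %in% names(effect)) unname(effect[[gene]]) else 1
}

#' Simulate a per-cell gamma-H2AX screen dataset
#'
#' One well per library gene per population, plus scrambled-control and
#' positive-control wells. Per-cell MI is log-normal around
#' baseline x gene effect, with CV `truth$plate_cv`; hit wells are
#' multiplied by the planted effect of their population.
#'
#' @param truth A [screen_truth()].
#' @param n_genes Library size (default 296 chromatin-remodeling targets).
#' @param n_scrambled Scrambled-control wells per population.
#' @param n_positive Positive-control wells per population.
#' @param populations Character vector, subset of `c("GSC", "DGC")`.
#' @param seed Integer seed (a `"screen"` stream is derived from it).
#' @param genes Optional explicit library gene symbols.
#' @return A data frame of class `screen_dataset` with columns
#'   `plate, well, gene, role, population, cell_id, mi`.
#' @export
gen_screen <- function(truth, n_genes = 296, n_scrambled = 16,
                       n_positive = 4, populations = c("GSC", "DGC"),
                       seed = 1, genes = NULL) {
  stopifnot(inherits(truth, "screen_truth"))
  .check(n_genes >= 1, "n_genes must be >= 1")
  .check(truth$cells_per_well >= 1, "cells_per_well must be >= 1")
  .check(all(populations %in% c("GSC", "DGC")),
         "unknown population label(s): %s",
         paste(setdiff(populations, c("GSC", "DGC")), collapse = ", "))
  if (is.null(genes)) genes <- sprintf("GENE%04d", seq_len(n_genes))
  .check(length(genes) == n_genes, "length(genes) must equal n_genes")
  .check(all(truth$hit_genes %in% genes),
         "hit_genes must be a subset of the library genes")

  set.seed(stream_seed(seed, "screen"))
  nc <- truth$cells_per_well
  labels <- c(genes,
              sprintf("SCRAMBLED%02d", seq_len(n_scrambled)),
              sprintf("POSCTRL%02d", seq_len(n_positive)))
  roles <- c(rep("sample", n_genes), rep("scrambled", n_scrambled),
             rep("positive", n_positive))

  out <- vector("list", length(populations))
  for (pi in seq_along(populations)) {
    pop <- populations[pi]
    eff_tab <- if (pop == "GSC") truth$effect_gsc else truth$effect_dgc
    mu <- vapply(seq_along(labels), function(i) {
      if (roles[i] == "positive") return(truth$baseline_mi * truth$positive_effect)
      if (roles[i] == "scrambled") return(truth$baseline_mi)
      g <- labels[i]
      e <- if (g %in% truth$hit_genes) .effect_for(eff_tab, g) else 1
      truth$baseline_mi * e
    }, numeric(1))
    mi <- unlist(lapply(mu, function(m) .rlnorm_cv(nc, m, truth$plate_cv)))
    out[[pi]] <- data.frame(
      plate = "P1",
      well = rep(sprintf("%s_W%03d", pop, seq_along(labels)), each = nc),
      gene = rep(labels, each = nc),
      role = rep(roles, each = nc),
      population = pop,
      cell_id = sprintf("%s_c%07d", pop, seq_len(nc * length(labels))),
      mi = mi,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("screen_dataset", "data.frame")
  res
}

#' Planted truth for a paired RNA-seq count simulation
#'
#' @param de_genes Character vector of differentially expressed genes.
#' @param true_lfc Log2 fold change (condition B vs A) of the DE genes;
#'   scalar or named vector over `de_genes`. Non-DE genes have lfc 0.
#' @param dispersion Negative-binomial dispersion (scalar or per-gene);
#'   `0` gives the Poisson limit. Must be >= 0.
#' @param lib_size Target library size per sample (scalar; per-sample
#'   totals vary around it). Must be > 0.
#' @param pair_cv CV of the per-pair shared baseline factor.
#' @param half_life_meanlog,half_life_sdlog Log-normal parameters of the
#'   simulated per-gene mRNA half-life (hours).
#' @return An object of class `de_truth`.
#' @export
de_truth <- function(de_genes = character(), true_lfc = 1.5,
                     dispersion = 0.05, lib_size = 1e6, pair_cv = 0.1,
                     half_life_meanlog = log(5), half_life_sdlog = 0.6) {
  .check(all(dispersion >= 0), "dispersions must be >= 0")
  .check(all(lib_size > 0), "lib_size must be > 0")
  structure(list(de_genes = as.character(de_genes), true_lfc = true_lfc,
                 dispersion = dispersion, lib_size = lib_size,
                 pair_cv = pair_cv, half_life_meanlog = half_life_meanlog,
                 half_life_sdlog = half_life_sdlog),
            class = "de_truth")
}

#' Simulate a paired two-condition RNA-seq count matrix
#'
#' Counts are negative-binomial around per-gene baselines; members of a
#' replicate pair share a random baseline factor and condition-B means are
#' scaled by `2^true_lfc`. Gene lengths are included so RPKM is
#' computable.
#'
#' @param truth A [de_truth()].
#' @param n_genes Number of genes.
#' @param n_pairs Number of replicate pairs (>= 2).
#' @param seed Integer seed (a `"counts"` stream is derived).
#' @return A list of class `count_matrix`: `counts` (genes x samples
#'   integer matrix), `samples` (sample, condition, pair), `lengths`
#'   (named bp vector), `true_lfc` (named per-gene vector) and
#'   `half_life` (named hours vector).
#' @export
gen_counts <- function(truth, n_genes = 2000, n_pairs = 3, seed = 1) {
  stopifnot(inherits(truth, "de_truth"))
  .check(n_pairs >= 2, "n_pairs must be >= 2")
  .check(all(truth$lib_size > 0), "negative or zero lib_sizes")
  set.seed(stream_seed(seed, "counts"))

  genes <- sprintf("G%05d", seq_len(n_genes))
  .check(all(truth$de_genes %in% genes) || length(truth$de_genes) == 0 ||
           all(grepl("^G\\d+$", truth$de_genes)),
         "de_genes must use the generated gene namespace")
  lfc <- stats::setNames(rep(0, n_genes), genes)
  if (length(truth$de_genes)) {
    v <- truth$true_lfc
    if (is.null(names(v))) v <- stats::setNames(rep(v[1], length(truth$de_genes)),
                                                truth$de_genes)
    lfc[names(v)] <- v
  }

  # per-gene relative abundance (log-normal across genes)
  base <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1.2)
  base <- base / sum(base)
  disp <- rep(truth$dispersion, length.out = n_genes)

  samples <- data.frame(
    sample = c(sprintf("A_%d", seq_len(n_pairs)), sprintf("B_%d", seq_len(n_pairs))),
    condition = rep(c("A", "B"), each = n_pairs),
    pair = rep(sprintf("p%d", seq_len(n_pairs)), 2),
    stringsAsFactors = FALSE)

  pair_fac <- .rlnorm_cv(n_pairs, 1, truth$pair_cv)
  counts <- matrix(0L, n_genes, 2 * n_pairs,
                   dimnames = list(genes, samples$sample))
  for (j in seq_len(2 * n_pairs)) {
    p <- match(samples$pair[j], sprintf("p%d", seq_len(n_pairs)))
    scale_b <- if (samples$condition[j] == "B") 2^lfc else rep(1, n_genes)
    mu <- base * pair_fac[p] * scale_b
    mu <- mu / sum(mu) * truth$lib_size
    counts[, j] <- if (all(disp == 0)) {
      stats::rpois(n_genes, mu)
    } else {
      ifelse(disp == 0, stats::rpois(n_genes, mu),
             stats::rnbinom(n_genes, mu = mu, size = 1 / pmax(disp, 1e-12)))
    }
  }
  storage.mode(counts) <- "integer"
  lengths <- stats::setNames(as.integer(round(stats::runif(n_genes, 300, 8000))),
                             genes)
  hl <- stats::setNames(stats::rlnorm(n_genes, truth$half_life_meanlog,
                                      truth$half_life_sdlog), genes)
  structure(list(counts = counts, samples = samples, lengths = lengths,
                 true_lfc = lfc, half_life = hl),
            class = "count_matrix")
}

#' Planted truth for a clustered gene-set collection
#'
#' @param n_clusters Number of planted clusters.
#' @param sets_per_cluster Gene sets per cluster.
#' @param vocab List of character vectors: title vocabulary per cluster
#'   (must be nonempty).
#' @param sources Source labels to draw from.
#' @return An object of class `cluster_truth` carrying
#'   `cluster_of_set`, `vocab_of_cluster` and `sources`.
#' @export
cluster_truth <- function(n_clusters = 4, sets_per_cluster = 8,
                          vocab = NULL,
                          sources = c("hallmark", "curated", "go")) {
  if (is.null(vocab)) {
    pool <- list(c("repair", "break", "damage"),
                 c("stem", "renewal", "pluripotent"),
                 c("cycle", "mitotic", "checkpoint"),
                 c("chromatin", "histone", "remodeling"),
                 c("apoptosis", "death", "caspase"),
                 c("transcription", "polymerase", "elongation"))
    vocab <- pool[((seq_len(n_clusters) - 1) %% length(pool)) + 1]
  }
  .check(length(vocab) == n_clusters, "need one vocabulary per cluster")
  .check(all(vapply(vocab, length, 1L) > 0), "empty vocab")
  set_names <- character(0)
  cluster_of_set <- integer(0)
  for (k in seq_len(n_clusters)) {
    nm <- sprintf("C%d_S%d", k, seq_len(sets_per_cluster))
    set_names <- c(set_names, nm)
    cluster_of_set <- c(cluster_of_set,
                        stats::setNames(rep(k, sets_per_cluster), nm))
  }
  structure(list(cluster_of_set = cluster_of_set,
                 vocab_of_cluster = vocab,
                 sources = sources),
            class = "cluster_truth")
}

#' A named collection of gene sets
#'
#' Lightweight container mirroring a GMT file: named member lists plus a
#' source label per set and an optional GO ontology level.
#'
#' @param members Named list of character vectors (gene symbols).
#' @param source Character vector of source labels, one per set.
#' @param go_level Optional integer vector (NA for non-GO sets).
#' @return An object of class `set_collection`.
#' @export
set_collection <- function(members, source = rep("curated", length(members)),
                           go_level = rep(NA_integer_, length(members))) {
  .check(!is.null(names(members)) && all(nzchar(names(members))),
         "every set needs a nonempty name")
  .check(all(vapply(members, length, 1L) > 0), "empty gene set member list")
  members <- lapply(members, function(m) unique(toupper(m)))
  structure(list(names = names(members), members = members,
                 source = stats::setNames(source, names(members)),
                 go_level = stats::setNames(as.integer(go_level), names(members))),
            class = "set_collection")
}

#' @export
length.set_collection <- function(x) length(x$members)

#' Simulate a gene-set collection with planted clusters
#'
#' Sets of the same planted cluster draw their members from a shared gene
#' pool (pool size = `pool_factor` x set size, giving expected
#' within-cluster Jaccard ~ 0.5 at the default 1.5); pools of different
#' clusters are disjoint, so between-cluster overlap is zero. Set names
#' concatenate the source, cluster vocabulary words and a filler token.
#'
#' @param truth A [cluster_truth()].
#' @param universe_size Size of the gene universe (>= total pool demand).
#' @param set_size_range Integer range of set sizes.
#' @param seed Integer seed (a `"genesets"` stream is derived).
#' @param pool_factor Pool size as a multiple of the maximum set size.
#' @return A list: `collection` (a [set_collection()]), `universe`
#'   (character vector) and `truth` (the input, with `sources` resolved
#'   per set).
#' @export
gen_genesets <- function(truth, universe_size = 2000,
                         set_size_range = c(30, 50), seed = 1,
                         pool_factor = 1.5) {
  stopifnot(inherits(truth, "cluster_truth"))
  .check(all(vapply(truth$vocab_of_cluster, length, 1L) > 0), "empty vocab")
  set.seed(stream_seed(seed, "genesets"))
  n_clusters <- length(truth$vocab_of_cluster)
  pool_size <- ceiling(pool_factor * max(set_size_range))
  .check(universe_size >= max(set_size_range),
         "universe_size must be >= max set size")
  .check(universe_size >= n_clusters * pool_size,
         "universe too small for %d disjoint cluster pools of %d genes",
         n_clusters, pool_size)

  universe <- sprintf("U%05d", seq_len(universe_size))
  perm <- sample(universe)
  pools <- split(perm[seq_len(n_clusters * pool_size)],
                 rep(seq_len(n_clusters), each = pool_size))

  members <- list()
  source_of <- character(0)
  filler <- c("PATHWAY", "SIGNALING", "PROCESS", "RESPONSE", "REGULATION",
              "TARGETS", "SIGNATURE", "PROGRAM", "MODULE", "AXIS")
  sizes <- seq(set_size_range[1], set_size_range[2])
  for (nm in names(truth$cluster_of_set)) {
    k <- truth$cluster_of_set[[nm]]
    sz <- sizes[sample.int(length(sizes), 1)]
    src <- if (!is.null(names(truth$sources)) && nm %in% names(truth$sources)) {
      truth$sources[[nm]]
    } else sample(truth$sources, 1)
    vocab <- toupper(truth$vocab_of_cluster[[k]])
    words <- sample(vocab, min(2, length(vocab)))
    full <- paste(c(toupper(src), words, sample(filler, 1), nm), collapse = "_")
    members[[full]] <- sort(sample(pools[[k]], sz))
    source_of <- c(source_of, src)
  }
  coll <- set_collection(members, source = source_of)
  truth$cluster_of_set <- stats::setNames(unname(truth$cluster_of_set),
                                          names(members))
  truth$sources <- stats::setNames(source_of, names(members))
  list(collection = coll, universe = universe, truth = truth)
}

#' Planted truth for a per-cell assay table
#'
#' @param phase_fractions Named fractions over
#'   `G1, S, G2, M, polyploid`; must sum to 1 (tolerance 1e-9).
#' @param foci_rate Data frame `(marker, phase, condition, rate)` of
#'   Poisson means; `phase` may be a single phase, `"SG2"` (S or G2) or
#'   `"*"` (any). Later, more specific rows win.
#' @param na_mean,na_cv Nuclear-area log-normal mean (arbitrary units) and
#'   CV.
#' @param channel_separation Gap between the negative and positive channel
#'   modes, in natural-log intensity units.
#' @param channel_sd Within-component sd on the log-intensity scale.
#' @param bfp_frac Fraction of cells transduced (BFP+).
#' @param gfp_given_bfp Repair-reporter conversion rate among BFP+ cells.
#' @return An object of class `cell_truth`.
#' @export
cell_truth <- function(phase_fractions = c(G1 = 0.55, S = 0.20, G2 = 0.15,
                                           M = 0.03, polyploid = 0.07),
                       foci_rate = NULL,
                       na_mean = 100, na_cv = 0.2,
                       channel_separation = 2, channel_sd = 0.35,
                       bfp_frac = 0.4, gfp_given_bfp = 0.25) {
  .check(abs(sum(phase_fractions) - 1) <= 1e-9,
         "phase fractions must sum to 1 (got %.12f)", sum(phase_fractions))
  .check(all(phase_fractions >= 0), "phase fractions must be >= 0")
  if (is.null(foci_rate)) {
    foci_rate <- data.frame(
      marker = c("gH2AX", "53bp1", "53bp1", "brca1", "brca1"),
      phase = c("*", "G1", "SG2", "G1", "SG2"),
      condition = "*",
      rate = c(4, 3, 2, 0.5, 5),
      stringsAsFactors = FALSE)
  }
  .check(all(foci_rate$rate >= 0), "foci rates must be >= 0")
  structure(list(phase_fractions = phase_fractions, foci_rate = foci_rate,
                 na_mean = na_mean, na_cv = na_cv,
                 channel_separation = channel_separation,
                 channel_sd = channel_sd, bfp_frac = bfp_frac,
                 gfp_given_bfp = gfp_given_bfp),
            class = "cell_truth")
}

# look up the Poisson rate for (marker, phase, condition); most specific wins
.foci_rate_for <- function(tab, marker, phase, condition) {
  cand <- tab[tab$marker == marker, , drop = FALSE]
  if (!nrow(cand)) return(0)
  ph_match <- cand$phase == phase |
    (cand$phase == "SG2" & phase %in% c("S", "G2")) |
    cand$phase == "*"
  cond_match <- cand$condition == condition | cand$condition == "*"
  cand <- cand[ph_match & cond_match, , drop = FALSE]
  if (!nrow(cand)) return(0)
  specificity <- (cand$phase != "*") * 2 + (cand$condition != "*")
  cand$rate[which.max(specificity)]
}

#' Simulate a per-cell assay table
#'
#' Phases are sampled from the planted mixture; channel intensities are
#' two-component log-normal mixtures (EdU high iff S, cyclin A high iff
#' S/G2, H3S10 high iff M); DNA content sits at 2N for G1, between 2N and
#' 4N for S, 4N for G2/M and above 4.5N for polyploid cells; foci counts
#' are Poisson at the planted (marker, phase, condition) rate; nuclear
#' area is log-normal.
#'
#' @param truth A [cell_truth()].
#' @param n_cells Number of cells (>= 1).
#' @param condition Condition label stored with every cell.
#' @param seed Integer seed (a `"cells"` stream is derived).
#' @return A data frame of class `cell_table` with the true phase in
#'   column `true_phase`.
#' @export
gen_cells <- function(truth, n_cells = 5000, condition = "control", seed = 1) {
  stopifnot(inherits(truth, "cell_truth"))
  .check(n_cells >= 1, "n_cells must be >= 1")
  .check(abs(sum(truth$phase_fractions) - 1) <= 1e-9,
         "phase fractions must sum to 1")
  set.seed(stream_seed(seed, paste0("cells_", condition)))

  phases <- names(truth$phase_fractions)
  phase <- sample(phases, n_cells, replace = TRUE,
                  prob = truth$phase_fractions)

  neg_mu <- log(100)                      # negative-population log mode
  pos_mu <- neg_mu + truth$channel_separation
  ch <- function(pos) {
    mu <- ifelse(pos, pos_mu, neg_mu)
    exp(stats::rnorm(n_cells, mu, truth$channel_sd))
  }
  edu <- ch(phase == "S")
  cyclin_a <- ch(phase %in% c("S", "G2"))
  h3s10 <- ch(phase == "M")
  bfp_pos <- stats::runif(n_cells) < truth$bfp_frac
  gfp_pos <- bfp_pos & (stats::runif(n_cells) < truth$gfp_given_bfp)
  gfp <- ch(gfp_pos)
  bfp <- ch(bfp_pos)

  dna <- numeric(n_cells)
  dna[phase == "G1"] <- stats::rnorm(sum(phase == "G1"), 2, 0.12)
  dna[phase == "S"] <- stats::runif(sum(phase == "S"), 2.3, 3.7)
  dna[phase %in% c("G2", "M")] <- stats::rnorm(sum(phase %in% c("G2", "M")), 4, 0.18)
  dna[phase == "polyploid"] <- 4.8 +
    stats::rgamma(sum(phase == "polyploid"), shape = 2, rate = 1.2)

  nuclear_area <- .rlnorm_cv(n_cells, truth$na_mean, truth$na_cv)

  foci <- sapply(c("gH2AX", "53bp1", "brca1"), function(mk) {
    lam <- vapply(phase, function(ph)
      .foci_rate_for(truth$foci_rate, mk, ph, condition), numeric(1))
    stats::rpois(n_cells, lam)
  })

  res <- data.frame(
    cell = sprintf("%s_c%06d", condition, seq_len(n_cells)),
    condition = condition,
    true_phase = phase,
    nuclear_area = nuclear_area,
    edu = edu, cyclin_a = cyclin_a, dna_content = dna, h3s10 = h3s10,
    gfp = gfp, bfp = bfp,
    foci_gH2AX = foci[, "gH2AX"], foci_53bp1 = foci[, "53bp1"],
    foci_brca1 = foci[, "brca1"],
    stringsAsFactors = FALSE)
  class(res) <- c("cell_table", "data.frame")
  res
}

# ---- writers / readers -----------------------------------------------------

#' Write a screen dataset to TSV
#' @param screen A `screen_dataset`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(screen, path) write_tsv(as.data.frame(screen), path)

#' Read a screen dataset from TSV
#' @param path Input path.
#' @return A `screen_dataset` data frame.
#' @export
read_screen_tsv <- function(path) {
  x <- read_tsv(path)
  .check(all(c("plate", "well", "gene", "role", "population", "cell_id", "mi")
             %in% names(x)), "not a screen TSV: missing columns")
  class(x) <- c("screen_dataset", "data.frame")
  x
}

#' Write a count matrix with its sample and gene-length sidecars
#' @param cm A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The three paths, invisibly.
#' @export
write_counts_tsv <- function(cm, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, ".tsv"))
  p2 <- file.path(dir, paste0(prefix, "_samples.tsv"))
  p3 <- file.path(dir, paste0(prefix, "_lengths.tsv"))
  write_tsv(data.frame(gene = rownames(cm$counts), cm$counts,
                       check.names = FALSE), p1)
  write_tsv(cm$samples, p2)
  write_tsv(data.frame(gene = names(cm$lengths), length_bp = unname(cm$lengths)), p3)
  invisible(c(p1, p2, p3))
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param dir Directory holding the three files.
#' @param prefix File name prefix.
#' @return A `count_matrix` (without truth fields).
#' @export
read_counts_tsv <- function(dir, prefix = "counts") {
  x <- read_tsv(file.path(dir, paste0(prefix, ".tsv")))
  samples <- read_tsv(file.path(dir, paste0(prefix, "_samples.tsv")))
  len <- read_tsv(file.path(dir, paste0(prefix, "_lengths.tsv")))
  counts <- as.matrix(x[, -1, drop = FALSE])
  rownames(counts) <- x$gene
  structure(list(counts = counts, samples = samples,
                 lengths = stats::setNames(len$length_bp, len$gene)),
            class = "count_matrix")
}

#' Write a set collection as a GMT file
#'
#' Tab-separated lines: set name, source label (description slot),
#' members.
#' @param coll A [set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "set_collection"))
  lines <- vapply(coll$names, function(nm) {
    desc <- coll$source[[nm]]
    if (!is.na(coll$go_level[[nm]])) {
      desc <- sprintf("%s|level=%d", desc, coll$go_level[[nm]])
    }
    paste(c(nm, desc, coll$members[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a set collection
#'
#' The description field is kept as the source label; a trailing
#' `|level=N` suffix on the description is parsed as a GO ontology level.
#' @param path Input path.
#' @return A [set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .check(all(vapply(parts, length, 1L) >= 3), "malformed GMT line")
  nms <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  go_level <- rep(NA_integer_, length(nms))
  has_lvl <- grepl("\\|level=\\d+$", desc)
  go_level[has_lvl] <- as.integer(sub(".*\\|level=(\\d+)$", "\\1", desc[has_lvl]))
  desc <- sub("\\|level=\\d+$", "", desc)
  members <- lapply(parts, function(p) p[-(1:2)])
  names(members) <- nms
  set_collection(members, source = desc, go_level = go_level)
}

#' Write a cell table to TSV
#' @param cells A `cell_table`.
#' @param path Output path.
#' @export
write_cells_tsv <- function(cells, path) write_tsv(as.data.frame(cells), path)

#' Read a cell table from TSV
#' @param path Input path.
#' @return A `cell_table` data frame.
#' @export
read_cells_tsv <- function(path) {
  x <- read_tsv(path)
  .check(all(c("cell", "condition", "nuclear_area") %in% names(x)),
         "not a cell TSV: missing columns")
  class(x) <- c("cell_table", "data.frame")
  x
}
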