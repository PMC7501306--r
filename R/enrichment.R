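#' One-sided overrepresentation test for a gene list against a gene set
#'
#' Fisher's exact test with alternative "greater" on the 2x2 table
#' `[[k, n-k], [m-k, N-n-m+k]]`, where k is the overlap, n the list
#' size, m the set size (after intersecting with the universe) and N the
#' universe size. The one-sided p equals the hypergeometric upper tail.
#' The odds ratio is the sample (cross-product) odds ratio, with 0/0
#' reported as NaN and x/0 as Inf.
#'
#' @param gene_list Character vector (must be a subset of `universe`).
#' @param set A single gene set: a character vector of members, with the
#'   set's name taken from `set_name`.
#' @param universe Background gene universe.
#' @param set_name Name recorded in the result.
#' @param direction Direction label carried through (`"up"`/`"down"`).
#' @return A one-row data frame: `set, direction, k, n, m, N,
#'   odds_ratio, p`.
#' @export
overrep_test <- function(gene_list, set, universe, set_name = "set",
                         direction = "up") {
  .check(length(universe) > 0, "empty universe")
  gene_list <- unique(toupper(gene_list))
  universe <- unique(toupper(universe))
  extra <- setdiff(gene_list, universe)
  .check(length(extra) == 0, "gene list not contained in universe (%s...)",
         paste(utils::head(extra, 3), collapse = ", "))
  members <- intersect(unique(toupper(set)), universe)
  k <- length(intersect(gene_list, members))
  n <- length(gene_list)
  m <- length(members)
  N <- length(universe)
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  num <- k * (N - n - m + k)
  den <- (n - k) * (m - k)
  odds <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  data.frame(set = set_name, direction = direction, k = k, n = n, m = m,
             N = N, odds_ratio = odds, p = p, stringsAsFactors = FALSE)
}

#' Overrepresentation analysis of up/down lists against a collection
#'
#' Runs [overrep_test()] for every set and both directions, adjusting
#' p-values with Benjamini-Hochberg within each direction separately and
#' flagging significance at `fdr_cut`.
#'
#' @param up_list,down_list Disjoint gene lists (subsets of `universe`).
#' @param collection A [set_collection()].
#' @param universe Background universe.
#' @param fdr_cut FDR significance threshold (default 0.05).
#' @return A data frame of per-(set, direction) results with `fdr`,
#'   `significant` and the set's `source`.
#' @export
run_oa <- function(up_list, down_list, collection, universe,
                   fdr_cut = 0.05) {
  stopifnot(inherits(collection, "set_collection"))
  .check(length(collection) > 0, "empty collection")
  .check(length(intersect(toupper(up_list), toupper(down_list))) == 0,
         "up and down lists must be disjoint")
  run_dir <- function(lst, dir) {
    if (!length(lst)) return(NULL)
    rows <- lapply(collection$names, function(nm)
      overrep_test(lst, collection$members[[nm]], universe,
                   set_name = nm, direction = dir))
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$p)
    out
  }
  res <- rbind(run_dir(up_list, "up"), run_dir(down_list, "down"))
  res$significant <- res$fdr < fdr_cut
  res$source <- unname(collection$source[res$set])
  rownames(res) <- NULL
  res
}

# keyword rules: include / exclude substrings matched on lower-cased names
.keyword_rules <- list(
  dna_repair = list(
    include = c("repair", "homologous", "nonhomologous", "non_homologous"),
    exclude = character(0)),
  stem_cell = list(
    include = "stem_cell",
    exclude = c("hematopo", "mammary", "leukemic", "lymphoid")))

#' Curate a sub-collection by name keywords
#'
#' Substring (not word-boundary) matching on lower-cased set names.
#' Built-in rules: `dna_repair` keeps sets whose name contains repair,
#' homologous, nonhomologous or non_homologous; `stem_cell` keeps sets
#' containing stem_cell and then removes those containing hematopo,
#' mammary, leukemic or lymphoid (matched on the name, as GMT
#' description fields are inconsistently populated). A custom rule is a
#' list with `include` and optional `exclude` character vectors.
#'
#' @param collection A [set_collection()].
#' @param rule `"dna_repair"`, `"stem_cell"`, or a custom rule list.
#' @return The curated [set_collection()] (possibly empty member list).
#' @export
select_keyword_sets <- function(collection, rule = "dna_repair") {
  stopifnot(inherits(collection, "set_collection"))
  if (is.character(rule)) {
    .check(rule %in% names(.keyword_rules), "unknown rule '%s'", rule)
    rule <- .keyword_rules[[rule]]
  }
  .check(is.list(rule) && !is.null(rule$include), "rule needs $include")
  nm_lc <- tolower(collection$names)
  keep <- Reduce(`|`, lapply(rule$include, function(w)
    grepl(w, nm_lc, fixed = TRUE)))
  if (!is.null(rule$exclude) && length(rule$exclude)) {
    drop <- Reduce(`|`, lapply(rule$exclude, function(w)
      grepl(w, nm_lc, fixed = TRUE)))
    keep <- keep & !drop
  }
  .subset_collection(collection, collection$names[keep])
}

.subset_collection <- function(collection, keep_names) {
  structure(list(names = keep_names,
                 members = collection$members[keep_names],
                 source = collection$source[keep_names],
                 go_level = collection$go_level[keep_names]),
            class = "set_collection")
}

#' Keep GO sets of one ontology level
#'
#' GO-source sets are kept only when their recorded ontology level equals
#' `level` (this avoids the bulk of gene duplication across nested GO
#' terms); non-GO sets pass through unchanged. GO sets without level
#' metadata are excluded with a warning.
#'
#' @param collection A [set_collection()].
#' @param level Ontology level to keep (default 6).
#' @return The filtered [set_collection()].
#' @export
filter_go_level <- function(collection, level = 6) {
  stopifnot(inherits(collection, "set_collection"))
  is_go <- collection$source == "go"
  lvl <- collection$go_level
  no_lvl <- is_go & is.na(lvl)
  if (any(no_lvl)) {
    warning(sprintf("excluding %d GO set(s) with missing level", sum(no_lvl)))
  }
  keep <- !is_go | (!is.na(lvl) & lvl == level)
  .subset_collection(collection, collection$names[keep])
}

#' Write overrepresentation results to TSV
#' @param oa Result of [run_oa()].
#' @param path Output path.
#' @export
write_oa_tsv <- function(oa, path) write_tsv(oa, path)
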