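#' Aggregate a per-cell screen dataset into per-well summaries
#'
#' Each well is reduced to its cell count and mean gamma-H2AX MI; wells
#' with fewer than `min_cells` cells fail QC and are excluded from all
#' downstream statistics.
#'
#' @param screen A `screen_dataset` (see [gen_screen()] /
#'   [read_screen_tsv()]).
#' @param min_cells Minimum cells for a well to pass QC (default 50).
#' @return A data frame of well summaries: `plate, well, gene, role,
#'   population, n_cells, mean_mi, qc_pass`.
#' @export
summarize_wells <- function(screen, min_cells = 50) {
  .check(min_cells >= 1, "min_cells must be >= 1")
  .check(nrow(screen) > 0, "empty screen dataset")
  key <- paste(screen$plate, screen$well, sep = "\r")
  first <- !duplicated(key)
  n_cells <- as.vector(table(key)[key[first]])
  mean_mi <- as.vector(tapply(screen$mi, key, mean)[key[first]])
  out <- data.frame(plate = screen$plate[first], well = screen$well[first],
                    gene = screen$gene[first], role = screen$role[first],
                    population = screen$population[first],
                    n_cells = n_cells, mean_mi = mean_mi,
                    stringsAsFactors = FALSE)
  out$qc_pass <- out$n_cells >= min_cells
  rownames(out) <- NULL
  out[order(out$population, out$well), ]
}

#' Fold change over the scrambled-control mean
#'
#' For every qc-passing sample well, the well mean MI divided by the mean
#' of the qc-passing scrambled-control well means on the same plate and
#' population.
#'
#' @param wells Well summaries from [summarize_wells()].
#' @return A data frame `gene, population, plate, mean_mi, fc`.
#' @export
control_fold_change <- function(wells) {
  wells <- wells[wells$qc_pass, , drop = FALSE]
  out <- list()
  for (grp in split(wells, list(wells$plate, wells$population), drop = TRUE)) {
    ctrl <- grp[grp$role == "scrambled", , drop = FALSE]
    .check(nrow(ctrl) >= 1,
           "no qc-passing scrambled controls on plate %s (%s)",
           grp$plate[1], grp$population[1])
    ctrl_mean <- mean(ctrl$mean_mi)
    smp <- grp[grp$role == "sample", , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      gene = smp$gene, population = smp$population, plate = smp$plate,
      mean_mi = smp$mean_mi, fc = smp$mean_mi / ctrl_mean,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-plate z-scores of well mean MI
#'
#' z = (mean_mi - mu) / sigma, where mu and sigma are the mean and SD
#' (n - 1 denominator) of all qc-passing sample wells on the same plate
#' and population. Because hits are rare, the sample wells approximate a
#' null reference. A robust variant centers on the median and scales by
#' 1.4826 * MAD.
#'
#' @param wells Well summaries from [summarize_wells()].
#' @param robust Use median/MAD instead of mean/SD.
#' @param include_controls Also return z for control wells (scored against
#'   the same sample-well reference).
#' @return A data frame `gene, role, population, plate, mean_mi, z`.
#' @export
zscore <- function(wells, robust = FALSE, include_controls = FALSE) {
  wells <- wells[wells$qc_pass, , drop = FALSE]
  out <- list()
  for (grp in split(wells, list(wells$plate, wells$population), drop = TRUE)) {
    smp <- grp[grp$role == "sample", , drop = FALSE]
    .check(nrow(smp) >= 3,
           "need >= 3 qc-passing sample wells on plate %s (%s), got %d",
           grp$plate[1], grp$population[1], nrow(smp))
    if (robust) {
      mu <- stats::median(smp$mean_mi)
      sigma <- stats::mad(smp$mean_mi)
    } else {
      mu <- mean(smp$mean_mi)
      sigma <- stats::sd(smp$mean_mi)
    }
    scored <- if (include_controls) grp else smp
    z <- if (sigma == 0) rep(0, nrow(scored)) else (scored$mean_mi - mu) / sigma
    out[[length(out) + 1]] <- data.frame(
      gene = scored$gene, role = scored$role, population = scored$population,
      plate = scored$plate, mean_mi = scored$mean_mi, z = z,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call GSC-specific hits from per-population fold changes
#'
#' A gene is a hit when its fold change over scrambled controls is at
#' least `hit_threshold` in the stem-like population (GSC) but below it
#' in the differentiated population (DGC); the comparison is inclusive on
#' the GSC side. Genes missing either population are dropped with a
#' warning.
#'
#' @param fc Fold changes from [control_fold_change()].
#' @param z Optional z-scores from [zscore()] (reported for context).
#' @param hit_threshold Fold-change threshold (default 1.20, i.e. >= 20%
#'   induction).
#' @return A `hit_table` data frame: `gene, fc_gsc, fc_dgc, z_gsc,
#'   z_dgc, is_hit, rank` (rank is filled by [rank_hits()]).
#' @export
call_hits <- function(fc, z = NULL, hit_threshold = 1.20) {
  gsc <- fc[fc$population == "GSC", c("gene", "fc")]
  dgc <- fc[fc$population == "DGC", c("gene", "fc")]
  missing <- union(setdiff(gsc$gene, dgc$gene), setdiff(dgc$gene, gsc$gene))
  if (length(missing)) {
    warning(sprintf("excluding %d gene(s) missing one population: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  }
  tab <- merge(gsc, dgc, by = "gene", suffixes = c("_gsc", "_dgc"))
  .check(nrow(tab) > 0, "no gene present in both populations")
  if (!is.null(z)) {
    zg <- z[z$role == "sample" & z$population == "GSC", c("gene", "z")]
    zd <- z[z$role == "sample" & z$population == "DGC", c("gene", "z")]
    names(zg)[2] <- "z_gsc"; names(zd)[2] <- "z_dgc"
    tab <- merge(merge(tab, zg, by = "gene", all.x = TRUE),
                 zd, by = "gene", all.x = TRUE)
  } else {
    tab$z_gsc <- NA_real_
    tab$z_dgc <- NA_real_
  }
  tab$is_hit <- tab$fc_gsc >= hit_threshold & tab$fc_dgc < hit_threshold
  tab$rank <- NA_integer_
  rownames(tab) <- NULL
  class(tab) <- c("hit_table", "data.frame")
  tab
}

#' Rank called hits
#'
#' Hits are sorted descending by the chosen key, ties broken
#' lexicographically by gene symbol; ranks 1..n_hits are assigned to hits
#' only and the table is returned with hits first.
#'
#' @param hits A `hit_table` from [call_hits()].
#' @param by Ranking key, `"fc_gsc"` or `"z_gsc"`.
#' @return The reordered `hit_table` with `rank` filled for hits.
#' @export
rank_hits <- function(hits, by = c("fc_gsc", "z_gsc")) {
  by <- match.arg(by)
  .check(any(hits$is_hit), "no hits to rank")
  h <- hits[hits$is_hit, , drop = FALSE]
  o <- order(-h[[by]], h$gene)
  h <- h[o, , drop = FALSE]
  h$rank <- seq_len(nrow(h))
  rest <- hits[!hits$is_hit, , drop = FALSE]
  rest <- rest[order(rest$gene), , drop = FALSE]
  rest$rank <- rep(NA_integer_, nrow(rest))
  out <- rbind(h, rest)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Run the whole screen stage: summarize, fold change, z, call, rank
#'
#' @param screen A `screen_dataset`.
#' @param min_cells QC threshold for [summarize_wells()].
#' @param hit_threshold Fold-change threshold for [call_hits()].
#' @param rank_by Ranking key for [rank_hits()] (ranking is skipped when
#'   no gene is called).
#' @return A ranked `hit_table`.
#' @export
screen_call_hits <- function(screen, min_cells = 50, hit_threshold = 1.20,
                             rank_by = "fc_gsc") {
  wells <- summarize_wells(screen, min_cells = min_cells)
  fc <- control_fold_change(wells)
  z <- zscore(wells)
  hits <- call_hits(fc, z, hit_threshold = hit_threshold)
  if (any(hits$is_hit)) hits <- rank_hits(hits, by = rank_by)
  hits
}

#' Write a hit table to TSV
#' @param hits A `hit_table`.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write_tsv(as.data.frame(hits)[, c("gene", "fc_gsc", "fc_dgc", "z_gsc",
                                    "z_dgc", "is_hit", "rank")], path)
}
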