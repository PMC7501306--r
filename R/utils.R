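#' Derive a per-stage RNG stream seed from a root seed
#'
#' All generators in the package draw from streams derived from one root
#' seed by a fixed stage label, so stages are reproducible independently of
#' the order in which they run.
#'
#' @param seed Integer root seed.
#' @param label Character stage label (e.g. `"screen"`, `"counts"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  bytes <- utf8ToInt(label)
  h <- (seed %% 2147483647)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Write a data frame as tab-separated values
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a truth object (or any list) as JSON
#'
#' @param truth A list-like truth object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

# internal: stop unless all conditions hold, with a formatted message
.check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
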