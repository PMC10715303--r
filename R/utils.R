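# Shared internal helpers: rounding, TSV I/O with comment headers.

#' Round half away from zero
#'
#' Rounding used for every printed percentage in the catalog summaries:
#' ties go away from zero (2.5 -> 2.5 at 1 digit means 0.25 -> 0.3), unlike
#' base \code{round()}'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_setphen <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "setphen_error")))
}

#' Read a tab-separated table, skipping comment headers
#'
#' @param path file path.
#' @param ... passed to \code{utils::read.delim}.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, ...) {
  if (!file.exists(path)) {
    stop_setphen("input file not found: %s", path, class = "setphen_io_error")
  }
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a tab-separated table with an optional provenance header
#'
#' @param x data.frame.
#' @param path output file.
#' @param header character vector of comment lines (without the leading "#").
#' @return \code{path}, invisibly.
#' @export
write_tsv_table <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic fingerprint of an R object (polynomial rolling hash over its
# deparse, exact in double precision); used to stamp output files so reruns
# with the same config are recognizable.
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
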