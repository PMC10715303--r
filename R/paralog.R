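# Paralog annotation: map residue positions between paralogous proteins
# through a pairwise slice of an alignment and transfer variant annotations,
# excluding targets whose residue already carries the substituted identity.

#' Read an aligned FASTA file
#'
#' @param path FASTA path; "-" is the gap character. Lowercase residues are
#'   uppercased with a warning.
#' @param aligned if TRUE (default) all rows must have equal length.
#' @return named character vector of (gapped) sequences.
#' @export
read_fasta_alignment <- function(path, aligned = TRUE) {
  if (!file.exists(path)) {
    stop_setphen("alignment file not found: %s", path, class = "setphen_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    warning("lowercase residues found; uppercasing")
  }
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) < 1L) {
    stop_setphen("no FASTA records in %s", path, class = "setphen_format_error")
  }
  seqs <- toupper(as.character(aln))
  if (aligned && length(unique(nchar(seqs))) != 1L) {
    stop_setphen("ragged alignment: row lengths %s",
                 paste(unique(nchar(seqs)), collapse = ", "),
                 class = "setphen_format_error")
  }
  names(seqs) <- sub("\\s.*$", "", names(aln))
  seqs
}

#' Build a position map between two aligned sequences
#'
#' Walks the alignment columns and records, for every column where both rows
#' are non-gap, the pair of 1-based ungapped sequence coordinates.
#'
#' @param alignment named character vector of equal-length gapped sequences
#'   (e.g. from [read_fasta_alignment]), or a path to an aligned FASTA.
#' @param source_id,target_id names of the two rows.
#' @return object of class \code{alignment_map}: data.frame with columns
#'   \code{source_position}, \code{target_position}, \code{source_residue},
#'   \code{target_residue}; attributes \code{source_id}, \code{target_id} and
#'   the full ungapped sequences.
#' @export
build_position_map <- function(alignment, source_id, target_id) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    alignment <- read_fasta_alignment(alignment)
  }
  for (id in c(source_id, target_id)) {
    if (!id %in% names(alignment)) {
      stop_setphen("identifier '%s' not found in alignment (have: %s)", id,
                   paste(names(alignment), collapse = ", "),
                   class = "setphen_format_error")
    }
  }
  s <- strsplit(alignment[[source_id]], "")[[1]]
  t <- strsplit(alignment[[target_id]], "")[[1]]
  if (length(s) != length(t)) {
    stop_setphen("aligned rows have unequal lengths (%d vs %d)",
                 length(s), length(t), class = "setphen_format_error")
  }
  spos <- cumsum(s != "-")
  tpos <- cumsum(t != "-")
  keep <- s != "-" & t != "-"
  out <- data.frame(source_position = spos[keep], target_position = tpos[keep],
                    source_residue = s[keep], target_residue = t[keep],
                    stringsAsFactors = FALSE)
  attr(out, "source_id") <- source_id
  attr(out, "target_id") <- target_id
  attr(out, "source_seq") <- paste(s[s != "-"], collapse = "")
  attr(out, "target_seq") <- paste(t[t != "-"], collapse = "")
  class(out) <- c("alignment_map", "data.frame")
  out
}

#' Transfer one variant across a paralog position map
#'
#' Applies the paralog-annotation rule set: a variant maps to the equivalent
#' target residue unless (i) its source position falls in a column gapped in
#' the target (\code{UnmappedGap}), or (ii) the target residue is already the
#' variant's alternate identity (\code{ExcludedAlreadySubstituted}) -- the
#' already-glutamate exclusion. A disagreement between the recorded source
#' reference residue and the aligned sequence is reported as
#' \code{RefMismatch} (a warning status, not fatal: isoform releases differ).
#'
#' @param map an \code{alignment_map}.
#' @param variant a variant record (one row) or list with \code{ref_aa},
#'   \code{position}, \code{alt_aa}.
#' @return list with \code{status} (Mapped, ExcludedAlreadySubstituted,
#'   UnmappedGap, RefMismatch), \code{target_position}, \code{target_ref_aa}
#'   (NA when unmapped), and \code{target_variant} label when mapped.
#' @export
transfer_variant <- function(map, variant) {
  src_len <- nchar(attr(map, "source_seq"))
  pos <- as.integer(variant$position)
  if (pos < 1L || pos > src_len) {
    stop_setphen("source position %d outside sequence length %d", pos, src_len,
                 class = "setphen_argument_error")
  }
  hit <- map[map$source_position == pos, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(status = "UnmappedGap", target_position = NA_integer_,
                target_ref_aa = NA_character_, target_variant = NA_character_))
  }
  src_res <- substr(attr(map, "source_seq"), pos, pos)
  status <- if (!is.null(variant$ref_aa) && !is.na(variant$ref_aa) &&
                src_res != variant$ref_aa) "RefMismatch" else "Mapped"
  if (hit$target_residue == variant$alt_aa) status <- "ExcludedAlreadySubstituted"
  list(status = status,
       target_position = hit$target_position,
       target_ref_aa = hit$target_residue,
       target_variant = if (status == "ExcludedAlreadySubstituted") NA_character_
                        else paste0(hit$target_residue, hit$target_position,
                                    variant$alt_aa))
}

#' Transfer a whole variant table across a paralog map
#'
#' @param map an \code{alignment_map}.
#' @param variants variant records data.frame.
#' @return data.frame: one row per variant with source label, status and
#'   target annotation.
#' @export
transfer_variants <- function(map, variants) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    tr <- transfer_variant(map, v)
    data.frame(source_variant = paste0(v$ref_aa, v$position, v$alt_aa),
               status = tr$status,
               target_position = tr$target_position %||% NA_integer_,
               target_ref_aa = tr$target_ref_aa %||% NA_character_,
               target_variant = tr$target_variant %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent sequence identity of a pairwise alignment
#'
#' Identity = 100 x (identical mutually non-gap columns) / (columns where at
#' least one row is non-gap), i.e. columns gapped in exactly one row count in
#' the denominator. Rounded to one decimal.
#'
#' @param alignment named character vector of two gapped sequences (or a
#'   FASTA path).
#' @param region optional length-2 column range (alignment coordinates).
#' @return percentage, one decimal.
#' @export
percent_identity <- function(alignment, region = NULL) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    alignment <- read_fasta_alignment(alignment)
  }
  stopifnot(length(alignment) >= 2L)
  s <- strsplit(alignment[[1]], "")[[1]]
  t <- strsplit(alignment[[2]], "")[[1]]
  stopifnot(length(s) == length(t))
  idx <- seq_along(s)
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    idx <- idx[idx >= region[1] & idx <= region[2]]
    if (length(idx) == 0L) {
      stop_setphen("empty column region [%s, %s]", region[1], region[2],
                   class = "setphen_argument_error")
    }
  }
  s <- s[idx]; t <- t[idx]
  denom <- sum(s != "-" | t != "-")
  if (denom == 0L) {
    stop_setphen("region contains only gap columns", class = "setphen_argument_error")
  }
  ident <- sum(s != "-" & t != "-" & s == t)
  round_half_away(100 * ident / denom, 1)
}
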