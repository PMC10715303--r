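# Variant catalog: parse ClinVar-style missense tables, summarize the
# five-tier clinical significance distribution, filter by domain region.

#' Clinical significance classes
#'
#' The five-tier system (Benign .. Pathogenic) plus the bookkeeping classes
#' that occur in public variant tables: conflicting interpretations, no
#' assertion provided, and the joint "Pathogenic/Likely Pathogenic" label
#' which is kept as its own class rather than split.
#'
#' @export
CLINICAL_CLASSES <- c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic",
                      "Pathogenic", "Conflicting", "NotProvided", "P_or_LP")

# Free-text labels seen in the wild -> canonical class
.normalize_class <- function(x) {
  key <- tolower(trimws(x))
  key <- gsub("[ _]+", " ", key)
  map <- c("benign" = "Benign",
           "likely benign" = "LikelyBenign",
           "likelybenign" = "LikelyBenign",
           "vus" = "VUS",
           "uncertain significance" = "VUS",
           "variant of uncertain significance" = "VUS",
           "likely pathogenic" = "LikelyPathogenic",
           "likelypathogenic" = "LikelyPathogenic",
           "pathogenic" = "Pathogenic",
           "conflicting" = "Conflicting",
           "cip" = "Conflicting",
           "conflicting interpretations of pathogenicity" = "Conflicting",
           "np" = "NotProvided",
           "not provided" = "NotProvided",
           "notprovided" = "NotProvided",
           "p/lp" = "P_or_LP",
           "p or lp" = "P_or_LP",
           "p_or_lp" = "P_or_LP",
           "pathogenic/likely pathogenic" = "P_or_LP")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop_setphen("unrecognized clinical significance label: '%s'",
                 x[is.na(out)][1], class = "setphen_parse_error")
  }
  out
}

#' Parse an HGVS-style protein change
#'
#' Parses strings of the form \code{"p.Arg4763Gln"} into one-letter reference
#' and alternate residues plus the 1-based protein position. Synonymous
#' changes (reference equals alternate) are rejected: they are not missense.
#'
#' @param text protein-change string, e.g. \code{"p.Arg4763Gln"}.
#' @return list with elements \code{ref_aa}, \code{position}, \code{alt_aa}.
#' @examples
#' parse_protein_change("p.Arg4763Gln")
#' @export
parse_protein_change <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$",
                                trimws(text)))[[1]]
  if (length(m) != 4L) {
    stop_setphen("malformed protein change '%s': expected p.<Aaa><pos><Aaa>",
                 text, class = "setphen_parse_error")
  }
  ref <- aa3_to_aa1(m[2])
  alt <- aa3_to_aa1(m[4])
  pos <- as.integer(m[3])
  if (pos < 1L) {
    stop_setphen("protein position must be >= 1 in '%s'", text,
                 class = "setphen_parse_error")
  }
  if (ref == alt) {
    stop_setphen("'%s' is synonymous (ref == alt); not a missense change",
                 text, class = "setphen_not_missense")
  }
  list(ref_aa = ref, position = pos, alt_aa = alt)
}

#' Construct a variant record
#'
#' @param gene gene symbol.
#' @param ref_aa,alt_aa one-letter residues (must differ).
#' @param position protein coordinate, 1-based.
#' @param clinical_class one of [CLINICAL_CLASSES] (free-text synonyms such as
#'   "CIP" or "NP" are normalized).
#' @param genomic_location,cdna_change,condition free text, carried opaquely.
#' @return a one-row data.frame of class \code{variant_record}.
#' @export
variant_record <- function(gene, ref_aa, position, alt_aa,
                           clinical_class = "VUS",
                           genomic_location = NA_character_,
                           cdna_change = NA_character_,
                           condition = NA_character_) {
  stopifnot(position >= 1, ref_aa %in% AA_ONE, alt_aa %in% AA_ONE)
  if (ref_aa == alt_aa) {
    stop_setphen("ref_aa equals alt_aa ('%s'); not missense", ref_aa,
                 class = "setphen_not_missense")
  }
  cls <- if (clinical_class %in% CLINICAL_CLASSES) clinical_class
         else .normalize_class(clinical_class)
  out <- data.frame(gene = gene, ref_aa = ref_aa, position = as.integer(position),
                    alt_aa = alt_aa, clinical_class = cls,
                    genomic_location = genomic_location,
                    cdna_change = cdna_change, condition = condition,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_record", class(out))
  out
}

#' Read a tab-separated variant table
#'
#' Expects columns \code{gene}, \code{protein} (HGVS p. notation) and
#' \code{clinical_significance}; optional \code{grch38_location}, \code{cdna},
#' \code{condition}. "NP" is accepted as NotProvided.
#'
#' @param path TSV path.
#' @return data.frame of variant records (one row per retained missense).
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("gene", "protein", "clinical_significance")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_setphen("variant table lacks column(s): %s",
                 paste(missing, collapse = ", "), class = "setphen_parse_error")
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    pc <- parse_protein_change(tab$protein[i])
    variant_record(gene = tab$gene[i], ref_aa = pc$ref_aa,
                   position = pc$position, alt_aa = pc$alt_aa,
                   clinical_class = tab$clinical_significance[i],
                   genomic_location = tab[["grch38_location"]][i] %||% NA_character_,
                   cdna_change = tab[["cdna"]][i] %||% NA_character_,
                   condition = tab[["condition"]][i] %||% NA_character_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_record", "data.frame")
  out
}

#' Summarize the clinical-class distribution of a variant set
#'
#' Counts records per clinical class and reports percentages rounded
#' half-away-from-zero to one decimal (the convention that reproduces
#' published ClinVar-mining summaries). Percentages are only computed when
#' the total is positive.
#'
#' @param records a data.frame of variant records, or a named integer vector
#'   of per-class counts (names in [CLINICAL_CLASSES]).
#' @return object of class \code{classification_summary}: data.frame with
#'   \code{class}, \code{count}, \code{percent}, plus attribute \code{total}.
#' @export
summarize_classifications <- function(records) {
  if (is.data.frame(records)) {
    counts <- table(factor(records$clinical_class, levels = CLINICAL_CLASSES))
    counts <- stats::setNames(as.integer(counts), CLINICAL_CLASSES)
  } else {
    stopifnot(!is.null(names(records)))
    bad <- setdiff(names(records), CLINICAL_CLASSES)
    if (length(bad)) {
      stop_setphen("unknown class name(s): %s", paste(bad, collapse = ", "),
                   class = "setphen_parse_error")
    }
    counts <- stats::setNames(integer(length(CLINICAL_CLASSES)), CLINICAL_CLASSES)
    counts[names(records)] <- as.integer(records)
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_away(100 * counts / total, 1)
         else rep(NA_real_, length(counts))
  out <- data.frame(class = CLINICAL_CLASSES, count = unname(counts),
                    percent = unname(pct), stringsAsFactors = FALSE)
  attr(out, "total") <- total
  class(out) <- c("classification_summary", "data.frame")
  out
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("Clinical significance summary (%d variants)\n", attr(x, "total")))
  shown <- x[x$count > 0 | is.na(x$percent), , drop = FALSE]
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Filter variants to a protein region
#'
#' @param records variant records data.frame.
#' @param region length-2 numeric, inclusive \code{c(start, end)} protein
#'   coordinates (e.g. SET-domain boundaries; default for KMT2C is
#'   \code{c(4761, 4911)}, spanning SET plus the post-SET Zn site).
#' @return the subset of records with positions inside the region, order kept.
#' @export
filter_by_region <- function(records, region) {
  stopifnot(length(region) == 2L)
  if (region[1] > region[2]) {
    stop_setphen("inverted region [%s, %s]", region[1], region[2],
                 class = "setphen_argument_error")
  }
  records[records$position >= region[1] & records$position <= region[2], ,
          drop = FALSE]
}

#' Default SET-domain boundaries for KMT2C
#'
#' Protein coordinates covering the SET catalytic core and the C-terminal
#' post-SET Zn-binding region of KMT2C; configurable because public
#' annotations of domain limits differ by a few residues.
#' @export
KMT2C_SET_REGION <- c(4761L, 4911L)

#' Equivalent region on KMT2D (constant paralog offset of +626)
#' @export
KMT2D_SET_REGION <- c(5387L, 5537L)
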