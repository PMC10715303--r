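# Threshold classification of per-variant structural scores: folding/binding
# free-energy changes (kcal/mol) and frustration-index shifts (Z-scores).

STRUCTURAL_SCORES <- c("ddg_fold_alamut", "ddg_fold_foldx", "ddg_fold_charmm",
                       "ddg_binding_h3k4", "ddg_binding_sah")

#' Classify a folding/binding free-energy change
#'
#' A variant is Destabilizing when the free-energy change is at least
#' +threshold kcal/mol, Stabilizing when at most -threshold, otherwise
#' Neutral. The boundary is inclusive: a value exactly at the threshold is a
#' non-neutral call (the convention that reproduces published per-variant
#' effect tables, where e.g. an alanine-scan value of exactly 0.5 kcal/mol
#' is labeled destabilizing).
#'
#' @param value free-energy change, kcal/mol (positive = destabilizing).
#' @param threshold positive threshold, default 0.5 kcal/mol.
#' @return one of "Destabilizing", "Stabilizing", "Neutral".
#' @export
classify_ddg <- function(value, threshold = 0.5) {
  stopifnot(threshold > 0)
  if (!is.finite(value)) {
    stop_setphen("non-finite free-energy value", class = "setphen_argument_error")
  }
  if (value >= threshold) "Destabilizing"
  else if (value <= -threshold) "Stabilizing"
  else "Neutral"
}

#' Frustration-index shift of a mutation
#'
#' @param f_mut,f_wt frustration indices (Z-scores) of mutant and wild type.
#' @return \code{f_mut - f_wt}.
#' @export
delta_frustration <- function(f_mut, f_wt) {
  stopifnot(is.finite(f_mut), is.finite(f_wt))
  f_mut - f_wt
}

#' Classify a frustration index (or index shift)
#'
#' Z-score above +0.78: minimally frustrated (well-optimized native
#' interactions, stabilizing); strictly below -1.0: highly frustrated
#' (destabilizing); otherwise neutral.
#'
#' @param value Z-score or Z-score shift.
#' @param high_cut lower cutoff for highly frustrated (default -1.0, strict).
#' @param min_cut upper cutoff for minimally frustrated (default 0.78, strict).
#' @return one of "HighlyFrustrated", "NeutralF", "MinimallyFrustrated".
#' @export
classify_frustration <- function(value, high_cut = -1.0, min_cut = 0.78) {
  stopifnot(is.finite(value))
  if (value < high_cut) "HighlyFrustrated"
  else if (value > min_cut) "MinimallyFrustrated"
  else "NeutralF"
}

#' Per-variant structural effect calls
#'
#' Applies [classify_ddg] to the five free-energy scores and
#' [classify_frustration] to the frustration shift of one score panel, and
#' counts adverse calls (Destabilizing or HighlyFrustrated; stabilizing
#' calls are not adverse).
#'
#' @param panel one-row data.frame (or list) with the six structural scores:
#'   \code{ddg_fold_alamut}, \code{ddg_fold_foldx}, \code{ddg_fold_charmm},
#'   \code{ddg_binding_h3k4}, \code{ddg_binding_sah},
#'   \code{delta_frustration}. A missing (NA) score gives a \code{NoCall}
#'   that is excluded from the adverse count.
#' @param threshold free-energy threshold, kcal/mol.
#' @return list: \code{calls} (named character, length 6),
#'   \code{adverse_count}, \code{n_called}.
#' @export
structural_calls <- function(panel, threshold = 0.5) {
  calls <- character(0)
  for (sc in STRUCTURAL_SCORES) {
    v <- panel[[sc]]
    calls[sc] <- if (is.null(v) || is.na(v)) "NoCall" else classify_ddg(v, threshold)
  }
  df <- panel[["delta_frustration"]]
  calls["delta_frustration"] <-
    if (is.null(df) || is.na(df)) "NoCall" else classify_frustration(df)
  adverse <- sum(calls %in% c("Destabilizing", "HighlyFrustrated"))
  list(calls = calls, adverse_count = adverse,
       n_called = sum(calls != "NoCall"))
}

#' Read a per-variant structural score table
#'
#' @param path TSV with a \code{variant} column plus the six structural score
#'   columns (extra columns, e.g. as-printed audit labels, are carried).
#' @return data.frame.
#' @export
read_score_panel <- function(path) {
  tab <- read_tsv_table(path)
  need <- c("variant", STRUCTURAL_SCORES, "delta_frustration")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_setphen("score table lacks column(s): %s",
                 paste(missing, collapse = ", "), class = "setphen_format_error")
  }
  tab
}

#' Structural calls for a whole score table
#'
#' @param panels data.frame from [read_score_panel].
#' @param threshold free-energy threshold, kcal/mol.
#' @return data.frame: variant, one call column per score, adverse count.
#' @export
structural_call_table <- function(panels, threshold = 0.5) {
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    sc <- structural_calls(panels[i, ], threshold)
    cbind(data.frame(variant = panels$variant[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(sc$calls), stringsAsFactors = FALSE),
          data.frame(structural_adverse = sc$adverse_count))
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("^delta_frustration$", "delta_frustration_call",
                    names(out))
  names(out)[2:6] <- paste0(STRUCTURAL_SCORES, "_call")
  out
}
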