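# Molecular-fitness integration: combine structural effect calls (six
# scores) with dynamic-score calls (default registry of eleven) into the
# SV / DV / SDV / VUS classification.

#' Default dynamic-score registry
#'
#' Eleven dynamic scores with per-score adverse rules, completing (with the
#' six structural scores) the default 17-score molecular-fitness panel. The
#' rules are documented package defaults -- stated assumptions, editable per
#' score -- not published thresholds:
#' \itemize{
#'   \item \code{r_rmsf}: adverse if correlation < 0.9 (\code{abs_lt}).
#'   \item \code{delta_abs_rmsf}: adverse if > 0.2 Angstrom (\code{abs_gt}).
#'   \item \code{rg_shift}, \code{sasa_shift}, \code{cie_zn_shift}: adverse
#'     if the relative change versus wild type is >= 5\% (\code{rel_ge},
#'     value = variant metric, reference = wild-type metric).
#'   \item \code{ddg_mmpbsa_sah}, \code{ddg_mmpbsa_h3k4}: adverse if
#'     |variant - WT| >= 10\% of the WT magnitude (\code{rel_ge}).
#'   \item \code{hbond_D1..D4}: adverse if occupancy drops by more than 0.25
#'     versus wild type (\code{drop_gt}).
#' }
#' An \code{rmsd_shift} rule (\code{rel_ge}, 5\%) is available in the rule
#' catalog but excluded from the default registry so the default panel
#' totals 17 scores.
#'
#' @param include_rmsd include \code{rmsd_shift} (default FALSE).
#' @return data.frame: \code{score}, \code{rule} (abs_lt / abs_gt / rel_ge /
#'   drop_gt), \code{threshold}.
#' @export
default_dynamic_registry <- function(include_rmsd = FALSE) {
  reg <- data.frame(
    score = c("r_rmsf", "delta_abs_rmsf", "rg_shift", "sasa_shift",
              "ddg_mmpbsa_sah", "ddg_mmpbsa_h3k4", "cie_zn_shift",
              "hbond_D1", "hbond_D2", "hbond_D3", "hbond_D4"),
    rule = c("abs_lt", "abs_gt", "rel_ge", "rel_ge",
             "rel_ge", "rel_ge", "rel_ge",
             "drop_gt", "drop_gt", "drop_gt", "drop_gt"),
    threshold = c(0.9, 0.2, 0.05, 0.05, 0.10, 0.10, 0.05,
                  0.25, 0.25, 0.25, 0.25),
    stringsAsFactors = FALSE)
  if (include_rmsd) {
    reg <- rbind(reg, data.frame(score = "rmsd_shift", rule = "rel_ge",
                                 threshold = 0.05))
  }
  reg
}

# One dynamic score call. `value` is the variant's metric; `reference` the
# wild-type metric (needed for rel_ge and drop_gt rules).
.call_dynamic_one <- function(value, reference, rule, threshold) {
  if (is.na(value)) return("NoCall")
  adverse <- switch(rule,
    abs_lt = value < threshold,
    abs_gt = value > threshold,
    rel_ge = {
      if (is.na(reference)) return("NoCall")
      if (reference == 0) abs(value) > 0
      else abs(value - reference) / abs(reference) >= threshold
    },
    drop_gt = {
      if (is.na(reference)) return("NoCall")
      (reference - value) > threshold
    },
    stop_setphen("unknown dynamic rule '%s'", rule, class = "setphen_argument_error"))
  if (adverse) "Adverse" else "Neutral"
}

#' Call a variant's dynamic-score panel
#'
#' @param panel named list / one-row data.frame of dynamic score values for
#'   the variant (names must be registered).
#' @param reference named values of the same scores for the wild type
#'   (needed for relative-change and occupancy-drop rules; for scores whose
#'   rule is absolute, e.g. \code{r_rmsf}, it may be omitted).
#' @param registry data.frame from [default_dynamic_registry] (or edited).
#' @return list: \code{calls} (named character: Adverse / Neutral / NoCall),
#'   \code{dynamic_adverse}, \code{n_called}.
#' @export
call_dynamic <- function(panel, reference = NULL, registry = default_dynamic_registry()) {
  nm <- names(panel)
  unknown <- setdiff(nm, registry$score)
  if (length(unknown)) {
    stop_setphen("unregistered dynamic score(s): %s",
                 paste(unknown, collapse = ", "), class = "setphen_argument_error")
  }
  calls <- character(0)
  for (k in seq_len(nrow(registry))) {
    sc <- registry$score[k]
    v <- if (sc %in% nm) panel[[sc]] else NA_real_
    if (is.null(v)) v <- NA_real_
    ref <- NA_real_
    if (!is.null(reference) && sc %in% names(reference)) ref <- reference[[sc]]
    calls[sc] <- .call_dynamic_one(v, ref, registry$rule[k], registry$threshold[k])
  }
  list(calls = calls,
       dynamic_adverse = sum(calls == "Adverse"),
       n_called = sum(calls != "NoCall"))
}

#' Molecular-fitness class from the two adverse counts
#'
#' Pure function of (structural_adverse, dynamic_adverse):
#' SV if only structural calls are adverse, DV if only dynamic, SDV if both,
#' VUS if neither.
#'
#' @param structural_adverse,dynamic_adverse non-negative counts.
#' @return list of class \code{mf_call}: \code{mf_class},
#'   \code{structural_adverse}, \code{dynamic_adverse}, \code{n_adverse_total}.
#' @export
classify_mf <- function(structural_adverse, dynamic_adverse) {
  stopifnot(structural_adverse >= 0, dynamic_adverse >= 0)
  cls <- if (structural_adverse >= 1 && dynamic_adverse >= 1) "SDV"
         else if (structural_adverse >= 1) "SV"
         else if (dynamic_adverse >= 1) "DV"
         else "VUS"
  out <- list(mf_class = cls,
              structural_adverse = as.integer(structural_adverse),
              dynamic_adverse = as.integer(dynamic_adverse),
              n_adverse_total = as.integer(structural_adverse + dynamic_adverse))
  class(out) <- "mf_call"
  out
}

#' Integrative molecular-fitness report
#'
#' Joins per-variant structural score panels and dynamic panels, computes
#' the adverse counts for each, and classifies every variant. A variant
#' missing from either panel set is reported \code{Incomplete} and excluded
#' from class counts.
#'
#' @param structural data.frame of structural score panels (variant + six
#'   scores; [read_score_panel] layout).
#' @param dynamic data.frame of dynamic scores (variant + registered score
#'   columns), or NULL for a structural-only report (dynamic_adverse = 0).
#' @param wt_reference named wild-type values for relative dynamic rules.
#' @param registry dynamic registry.
#' @param threshold free-energy threshold (kcal/mol) for structural calls.
#' @return data.frame of class \code{mf_report}: variant, structural_adverse,
#'   dynamic_adverse, n_adverse_total, n_scores_total, mf_class.
#' @export
fitness_report <- function(structural, dynamic = NULL, wt_reference = NULL,
                           registry = default_dynamic_registry(),
                           threshold = 0.5) {
  if (nrow(structural) == 0L) {
    out <- data.frame(variant = character(0), structural_adverse = integer(0),
                      dynamic_adverse = integer(0), n_adverse_total = integer(0),
                      n_scores_total = integer(0), mf_class = character(0))
    class(out) <- c("mf_report", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(structural)), function(i) {
    v <- structural$variant[i]
    sc <- structural_calls(structural[i, ], threshold)
    if (is.null(dynamic)) {
      dyn_adv <- 0L; dyn_called <- 0L; complete <- TRUE
    } else {
      j <- match(v, dynamic$variant)
      if (is.na(j)) {
        dyn_adv <- NA_integer_; dyn_called <- 0L; complete <- FALSE
      } else {
        dp <- dynamic[j, intersect(names(dynamic), registry$score), drop = FALSE]
        dc <- call_dynamic(dp, wt_reference, registry)
        dyn_adv <- dc$dynamic_adverse; dyn_called <- dc$n_called; complete <- TRUE
      }
    }
    cls <- if (complete) classify_mf(sc$adverse_count, dyn_adv)$mf_class
           else "Incomplete"
    data.frame(variant = v, structural_adverse = sc$adverse_count,
               dynamic_adverse = dyn_adv,
               n_adverse_total = if (complete) sc$adverse_count + dyn_adv else NA_integer_,
               n_scores_total = sc$n_called + nrow(registry),
               mf_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mf_report", "data.frame")
  out
}

#' @export
print.mf_report <- function(x, ...) {
  counts <- table(factor(x$mf_class, levels = c("SV", "DV", "SDV", "VUS", "Incomplete")))
  cat(sprintf("Molecular-fitness report: %d variants (SV %d, DV %d, SDV %d, VUS %d, incomplete %d)\n",
              nrow(x), counts["SV"], counts["DV"], counts["SDV"], counts["VUS"],
              counts["Incomplete"]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
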