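# Predictor consensus: turn per-tool pathogenicity scores into binary
# damaging/benign calls via per-tool thresholds and summarize agreement.

#' Default pathogenicity-tool configuration
#'
#' Commonly published per-tool cutoffs for twenty missense predictors,
#' grouped as sequence/functional, ensemble, and evolutionary/conservation
#' methods. These defaults are a documented convenience -- each study should
#' confirm or override them (\code{read_tool_config}) because published
#' thresholds vary by tool version.
#'
#' @return data.frame with \code{tool}, \code{cutoff}, \code{direction}
#'   (higher_is_damaging / lower_is_damaging) and \code{category}.
#' @export
default_tool_config <- function() {
  path <- system.file("extdata", "tool_config.tsv", package = "setphen")
  cfg <- read_tsv_table(path)
  validate_tool_config(cfg)
  cfg
}

#' Read a tool configuration TSV
#' @param path TSV with columns tool, cutoff, direction, category.
#' @return validated config data.frame.
#' @export
read_tool_config <- function(path) {
  cfg <- read_tsv_table(path)
  validate_tool_config(cfg)
  cfg
}

validate_tool_config <- function(cfg) {
  need <- c("tool", "cutoff", "direction")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop_setphen("tool config lacks column(s): %s",
                 paste(missing, collapse = ", "), class = "setphen_format_error")
  }
  if (anyDuplicated(cfg$tool)) {
    stop_setphen("duplicated tool names in config", class = "setphen_format_error")
  }
  if (any(!is.finite(cfg$cutoff))) {
    stop_setphen("non-finite cutoff in tool config", class = "setphen_format_error")
  }
  ok <- cfg$direction %in% c("higher_is_damaging", "lower_is_damaging")
  if (!all(ok)) {
    stop_setphen("bad direction '%s'", cfg$direction[!ok][1],
                 class = "setphen_format_error")
  }
  invisible(cfg)
}

#' Call one tool's score as Damaging or Benign
#'
#' A score exactly at the cutoff is called Damaging (conservative tie rule
#' for screening). Missing scores give \code{"NoCall"}.
#'
#' @param score numeric score (NA allowed -> NoCall).
#' @param cutoff tool threshold.
#' @param direction \code{"higher_is_damaging"} or \code{"lower_is_damaging"}.
#' @return \code{"Damaging"}, \code{"Benign"} or \code{"NoCall"}.
#' @export
call_tool <- function(score, cutoff, direction = "higher_is_damaging") {
  direction <- match.arg(direction, c("higher_is_damaging", "lower_is_damaging"))
  if (is.na(score)) return("NoCall")
  if (!is.finite(score)) {
    stop_setphen("non-finite score", class = "setphen_argument_error")
  }
  damaging <- if (direction == "higher_is_damaging") score >= cutoff
              else score <= cutoff
  if (damaging) "Damaging" else "Benign"
}

#' Consensus over per-tool calls for one variant
#'
#' @param calls character vector of "Damaging"/"Benign"/"NoCall" values
#'   (NoCall and NA are excluded from the tool count).
#' @return list: \code{n_tools}, \code{n_damaging}, \code{fraction_damaging}
#'   (whole percent), \code{unanimous}.
#' @export
consensus <- function(calls) {
  calls <- calls[!is.na(calls) & calls != "NoCall"]
  if (length(calls) == 0L) {
    stop_setphen("no non-missing calls", class = "setphen_argument_error")
  }
  stopifnot(all(calls %in% c("Damaging", "Benign")))
  n <- length(calls)
  nd <- sum(calls == "Damaging")
  list(n_tools = n, n_damaging = nd,
       fraction_damaging = as.numeric(round_half_away(100 * nd / n, 0)),
       unanimous = nd %in% c(0L, n))
}

#' Score a variant-by-tool matrix against a tool config
#'
#' @param scores data.frame with a \code{variant} column and one numeric
#'   column per tool (NA = tool did not score the variant).
#' @param config tool config (default [default_tool_config()]).
#' @return data.frame: per-variant \code{n_tools}, \code{n_damaging},
#'   \code{fraction_damaging}, \code{unanimous}, plus per-tool call columns.
#' @export
consensus_table <- function(scores, config = default_tool_config()) {
  stopifnot("variant" %in% names(scores))
  tools <- intersect(config$tool, names(scores))
  if (length(tools) == 0L) {
    stop_setphen("no config tool matches a score column", class = "setphen_format_error")
  }
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    calls <- vapply(tools, function(tl) {
      cfg <- config[config$tool == tl, ]
      call_tool(scores[[tl]][i], cfg$cutoff, cfg$direction)
    }, character(1))
    cs <- consensus(calls)
    cbind(data.frame(variant = scores$variant[i],
                     n_tools = cs$n_tools, n_damaging = cs$n_damaging,
                     fraction_damaging = cs$fraction_damaging,
                     unanimous = cs$unanimous, stringsAsFactors = FALSE),
          as.data.frame(as.list(calls), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
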