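#' Write an evaluation report to CSV
#'
#' Collects summary-metric results and optional model comparisons into a
#' tidy CSV with the fixed column schema
#' `model, metric, landmark, estimate, se, lo, hi, p_value`, one row per
#' landmark plus one `"summary"` row per (model, metric).
#'
#' @param summaries named list of `lm_summary_metric` objects; names are
#'   the model labels.
#' @param comparisons optional named list of `lm_comparison` objects;
#'   names label the compared pair.
#' @param file destination path.
#' @return Invisibly, the assembled data frame.
#' @export
write_report <- function(summaries = list(), comparisons = list(), file) {
  rows <- list()
  for (nm in names(summaries)) {
    sm <- summaries[[nm]]
    stopifnot(inherits(sm, "lm_summary_metric"))
    rows[[length(rows) + 1L]] <- data.frame(
      model = nm, metric = sm$metric,
      landmark = c(as.character(sm$landmarks$LM), "summary"),
      estimate = c(sm$landmarks$estimate, sm$estimate),
      se = c(sm$landmarks$se, sm$se),
      lo = c(sm$landmarks$lower, sm$lower),
      hi = c(sm$landmarks$upper, sm$upper),
      p_value = NA_real_)
  }
  for (nm in names(comparisons)) {
    cm <- comparisons[[nm]]
    stopifnot(inherits(cm, "lm_comparison"))
    rows[[length(rows) + 1L]] <- data.frame(
      model = nm, metric = cm$metric,
      landmark = c(as.character(cm$landmarks$LM), "summary"),
      estimate = c(cm$landmarks$delta, cm$delta),
      se = c(cm$landmarks$se, cm$se),
      lo = c(rep(NA_real_, nrow(cm$landmarks)), cm$ci[1L]),
      hi = c(rep(NA_real_, nrow(cm$landmarks)), cm$ci[2L]),
      p_value = c(cm$landmarks$p_value, cm$p_value))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), metric = character(),
               landmark = character(), estimate = numeric(), se = numeric(),
               lo = numeric(), hi = numeric(), p_value = numeric())
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
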