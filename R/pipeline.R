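#' Extract valve findings from reports, end to end
#'
#' Runs the full pipeline — segmentation, normalization, sentence splitting,
#' rule-based mention extraction, negation/history filtering and report-level
#' resolution — and returns an object holding both the resolved findings (8
#' per report) and the underlying mention-level evidence for audit.
#'
#' @param reports a report tibble (see [read_reports()]), one row per report.
#' @param lexicon an [load_lexicon()] object.
#' @param options an [extraction_options()] list.
#' @return an object of class `valve_extraction` with elements `findings`,
#'   `mentions`, `n_reports`, `n_sentences`, `options`. Use [tidy()] for the
#'   findings tibble, [glance()] for a one-row summary, [autoplot()] for a
#'   severity distribution plot.
#' @examples
#' reports <- tibble::tibble(
#'   report_id = "r1",
#'   text = "FINDINGS:\nAortic Valve:\nsevere aortic stenosis.\nno regurgitation."
#' )
#' fit <- extract_valve_findings(reports)
#' tidy(fit)
#' @export
extract_valve_findings <- function(reports, lexicon = default_lexicon(),
                                   options = extraction_options()) {
  reports <- fill_report_columns(reports)
  sentences <- prepare_sentences(reports, lexicon)
  mentions <- extract_mentions(sentences, lexicon, options)
  findings <- resolve_findings(
    mentions[!mentions$negated & !mentions$historical, , drop = FALSE],
    report_ids = reports$report_id
  )
  structure(
    list(
      findings = findings,
      mentions = mentions,
      n_reports = nrow(reports),
      n_sentences = nrow(sentences),
      options = options
    ),
    class = "valve_extraction"
  )
}

#' @export
print.valve_extraction <- function(x, ...) {
  cat("<valve_extraction>\n")
  cat("  reports:  ", x$n_reports, "\n")
  cat("  sentences:", x$n_sentences, "\n")
  cat("  mentions: ", nrow(x$mentions),
      sprintf(" (%d negated, %d historical)",
              sum(x$mentions$negated), sum(x$mentions$historical)), "\n")
  det <- sum(!x$findings$status %in% "no_evidence")
  cat("  findings: ", nrow(x$findings), " (", det, " with evidence)\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.valve_extraction <- function(x, ...) x$findings

#' @exportS3Method
glance.valve_extraction <- function(x, ...) {
  tibble(
    n_reports = x$n_reports,
    n_sentences = x$n_sentences,
    n_mentions = nrow(x$mentions),
    n_negated = sum(x$mentions$negated),
    n_historical = sum(x$mentions$historical),
    n_findings = nrow(x$findings),
    n_detected = sum(!x$findings$status %in% "no_evidence"),
    n_prosthetic = sum(x$findings$status == "prosthetic")
  )
}

#' @exportS3Method
autoplot.valve_extraction <- function(object, ...) {
  df <- object$findings |>
    mutate(status = factor(.data$status, levels = rev(finding_statuses())))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::facet_grid(lesion ~ valve) +
    ggplot2::labs(x = "reports", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
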