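graded_statuses <- function() {
  setdiff(severity_levels(), c("prosthetic", "sclerosis"))
}

#' Resolve report-level valve findings from surviving mentions
#'
#' Collapses sentence-level mentions into one status per (valve, lesion) —
#' always exactly 8 findings per report. Any prosthetic mention makes the
#' whole valve prosthetic (a prosthetic valve is a valve-level state, reported
#' identically under both lesions). Otherwise the highest-priority severity
#' among the pair's mentions wins; ungraded mentions count as evidence and
#' yield `unknown_severity` only when no graded mention exists; no surviving
#' mentions at all means `no_evidence`. Negated and historical mentions, if
#' present in the input, are discarded first.
#'
#' @param mentions a mention tibble (see [extract_mentions()]) from one
#'   report.
#' @param report_id the report's id; inferred from `mentions` when omitted
#'   (then `mentions` must be non-empty).
#' @return a tibble of 8 rows: `report_id`, `valve`, `lesion`, `status`,
#'   `n_supporting_mentions`.
#' @export
resolve_report <- function(mentions, report_id = NULL) {
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  if (nrow(mentions) > 0) {
    ids <- unique(mentions$report_id)
    if (length(ids) > 1) {
      abort(paste0("mentions from multiple reports: ", paste(ids, collapse = ", ")),
        class = "echovhd_mixed_report_ids"
      )
    }
    if (is.null(report_id)) report_id <- ids
    if (!is.null(report_id) && length(ids) == 1 && ids != report_id) {
      abort("mentions belong to a different report_id",
        class = "echovhd_mixed_report_ids"
      )
    }
  }
  if (is.null(report_id)) abort("report_id required when mentions are empty")
  surviving <- mentions
  if ("negated" %in% names(surviving)) {
    surviving <- surviving[!surviving$negated & !surviving$historical, , drop = FALSE]
  }
  is_pros <- surviving$prosthetic |
    (!is.na(surviving$severity) & surviving$severity == "prosthetic")
  pros_valves <- unique(surviving$valve[is_pros])
  grid <- tidyr::expand_grid(valve = valves(), lesion = lesions())
  out <- purrr::pmap(grid, function(valve, lesion) {
    here <- surviving[!is.na(surviving$lesion) &
                        surviving$valve == valve & surviving$lesion == lesion, ,
                      drop = FALSE]
    if (valve %in% pros_valves) {
      status <- "prosthetic"
      # every mention that marks the valve prosthetic, or bears on this lesion
      n <- sum(surviving$valve == valve &
                 (is_pros | (!is.na(surviving$lesion) & surviving$lesion == lesion)))
    } else if (nrow(here) == 0) {
      status <- "no_evidence"
      n <- 0L
    } else {
      graded <- here$severity[here$severity != "unknown_severity"]
      status <- if (length(graded) > 0) {
        graded[which.max(severity_rank(graded))]
      } else {
        "unknown_severity"
      }
      n <- nrow(here)
    }
    tibble(report_id = report_id, valve = valve, lesion = lesion,
           status = status, n_supporting_mentions = as.integer(n))
  }) |> bind_rows()
  out
}

#' Resolve findings for a batch of reports
#'
#' @param mentions a mention tibble covering any number of reports.
#' @param report_ids all report ids in the batch; reports without mentions
#'   still get 8 `no_evidence` findings. Defaults to the ids present in
#'   `mentions`.
#' @return a findings tibble with `8 * length(report_ids)` rows.
#' @export
resolve_findings <- function(mentions, report_ids = NULL) {
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  if (is.null(report_ids)) report_ids <- unique(mentions$report_id)
  purrr::map(report_ids, function(id) {
    resolve_report(mentions[mentions$report_id == id, , drop = FALSE], id)
  }) |> bind_rows()
}

findings_columns <- function() {
  c("report_id", "valve", "lesion", "status", "n_supporting_mentions")
}

#' Write and read findings files
#'
#' One row per (report, valve, lesion) with a stable column order
#' (`report_id`, `valve`, `lesion`, `status`, `n_supporting_mentions`);
#' CSV or JSONL. Writing then reading returns the identical tibble.
#'
#' @param findings a findings tibble.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`; `read_findings()` infers from the
#'   extension when `"auto"`.
#' @return `write_findings()` returns `path` invisibly; `read_findings()`
#'   returns the findings tibble.
#' @export
write_findings <- function(findings, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  findings <- as_tibble(findings)[, findings_columns()]
  if (format == "csv") {
    readr::write_csv(findings, path, na = "")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(findings))) {
      writeLines(jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' @rdname write_findings
#' @export
read_findings <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             report_id = readr::col_character(),
                             valve = readr::col_character(),
                             lesion = readr::col_character(),
                             status = readr::col_character(),
                             n_supporting_mentions = readr::col_integer()
                           ))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- purrr::map(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      tibble(
        report_id = as.character(rec$report_id), valve = rec$valve,
        lesion = rec$lesion, status = rec$status,
        n_supporting_mentions = as.integer(rec$n_supporting_mentions %||% NA_integer_)
      )
    }) |> bind_rows()
  }
  as_tibble(out)[, findings_columns()]
}

severity_band <- function(status) {
  dplyr::case_match(
    status,
    c("trace", "trace_to_mild") ~ "trace/trace to mild",
    c("mild", "mild_to_moderate") ~ "mild/mild to moderate",
    c("moderate", "moderate_to_severe") ~ "moderate/moderate to severe",
    c("severe", "very_severe") ~ "severe/very severe",
    "unknown_severity" ~ "unknown severity",
    .default = NA_character_
  )
}

age_band <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "unknown",
    age < 18 ~ "unknown",
    age <= 49 ~ "18-49",
    age <= 64 ~ "50-64",
    age <= 79 ~ "65-79",
    TRUE ~ ">=80"
  )
}

#' Stratified severity summary of a cohort's findings
#'
#' Counts findings with detected disease (a graded or unknown-severity
#' status; prosthetic, sclerosis and no-evidence findings are not "detected
#' disease" here) per (valve, lesion, severity band), stratified by age group
#' (18-49, 50-64, 65-79, >=80), sex, and race/ethnicity, with within-stratum
#' percentages. Regurgitation has an extra trace/trace-to-mild band. Unknown
#' demographic values go to an "unknown" stratum, never dropped.
#'
#' @param findings a findings tibble.
#' @param reports the matching report tibble (for demographics).
#' @param first_report_per_patient keep only each patient's first report (by
#'   `exam_date`, then `report_id`) before summarizing.
#' @return a tibble with `stratum_type` (`age_group`/`sex`/`race_ethnicity`/
#'   `overall`), `stratum`, `valve`, `lesion`, `band`, `n`, `pct` (percentage
#'   within the stratum's detected findings for that valve and lesion).
#' @export
summarize_cohort <- function(findings, reports, first_report_per_patient = FALSE) {
  reports <- fill_report_columns(reports)
  if (first_report_per_patient) {
    keep <- reports |>
      mutate(.ord = dplyr::coalesce(.data$exam_date, "9999"),
             .pid = dplyr::coalesce(.data$patient_id, .data$report_id)) |>
      arrange(.data$.pid, .data$.ord, .data$report_id) |>
      group_by(.data$.pid) |>
      dplyr::slice(1) |>
      ungroup()
    findings <- findings[findings$report_id %in% keep$report_id, , drop = FALSE]
  }
  joined <- findings |>
    left_join(select(reports, "report_id", "age_at_exam", "sex", "race_ethnicity"),
              by = "report_id") |>
    mutate(band = severity_band(.data$status)) |>
    filter(!is.na(.data$band)) |>
    mutate(
      age_group = age_band(.data$age_at_exam),
      sex = dplyr::coalesce(.data$sex, "unknown"),
      race_ethnicity = dplyr::coalesce(.data$race_ethnicity, "unknown"),
      overall = "all"
    )
  empty <- tibble(stratum_type = character(), stratum = character(),
                  valve = character(), lesion = character(), band = character(),
                  n = integer(), pct = numeric())
  if (nrow(joined) == 0) return(empty)
  purrr::map(c("overall", "age_group", "sex", "race_ethnicity"), function(st) {
    joined |>
      mutate(stratum = .data[[st]]) |>
      count(.data$stratum, .data$valve, .data$lesion, .data$band) |>
      group_by(.data$stratum, .data$valve, .data$lesion) |>
      mutate(pct = 100 * .data$n / sum(.data$n)) |>
      ungroup() |>
      mutate(stratum_type = st, .before = 1)
  }) |> bind_rows()
}
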