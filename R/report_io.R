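#' Read echocardiography reports into a tibble
#'
#' Accepts JSONL (one JSON object per line), CSV, or a directory of UTF-8
#' `.txt` files (one report per file, `report_id` = file name stem). Only
#' `report_id` and `text` are required; demographic columns are filled with
#' `NA`/"unknown" when absent.
#'
#' @param path file or directory path.
#' @param format one of `"auto"`, `"jsonl"`, `"csv"`, `"txt_dir"`. `"auto"`
#'   infers from the extension (directory implies `txt_dir`).
#' @return a tibble with columns `report_id`, `patient_id`, `text`,
#'   `exam_date`, `age_at_exam`, `sex`, `race_ethnicity`, one row per report
#'   in file order.
#' @export
read_reports <- function(path, format = c("auto", "jsonl", "csv", "txt_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input not found: ", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "txt_dir"
    } else if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
      "jsonl"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      "csv"
    } else {
      abort("cannot infer format from extension; pass `format` explicitly")
    }
  }
  out <- switch(format,
    jsonl = read_reports_jsonl(path),
    csv = read_reports_csv(path),
    txt_dir = read_reports_txtdir(path)
  )
  out <- fill_report_columns(out)
  dup <- out$report_id[duplicated(out$report_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate report_id(s): ", paste(unique(dup), collapse = ", ")),
      class = "echovhd_duplicate_report_id"
    )
  }
  if (any(!nzchar(out$report_id) | is.na(out$report_id))) {
    abort("every report needs a non-empty report_id")
  }
  message(nrow(out), " report(s) read from ", path)
  out
}

read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) abort(paste0("malformed JSONL record at line ", i, ": ",
                                       conditionMessage(e)))
    )
    if (is.null(rec$report_id)) abort(paste0("record at line ", i, " lacks report_id"))
    tibble(
      report_id = as.character(rec$report_id),
      patient_id = as.character(rec$patient_id %||% NA_character_),
      text = as.character(rec$text %||% ""),
      exam_date = as.character(rec$exam_date %||% NA_character_),
      age_at_exam = as.numeric(rec$age_at_exam %||% NA_real_),
      sex = as.character(rec$sex %||% "unknown"),
      race_ethnicity = as.character(rec$race_ethnicity %||% "unknown")
    )
  })
  bind_rows(recs)
}

read_reports_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"report_id" %in% names(out)) abort("CSV lacks a report_id column")
  if (!"text" %in% names(out)) abort("CSV lacks a text column")
  out$report_id <- as.character(out$report_id)
  as_tibble(out)
}

read_reports_txtdir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  tibble(
    report_id = sub("\\.txt$", "", basename(files)),
    text = vapply(
      files,
      function(f) paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
      character(1), USE.NAMES = FALSE
    )
  )
}

report_columns <- function() {
  c("report_id", "patient_id", "text", "exam_date", "age_at_exam", "sex",
    "race_ethnicity")
}

fill_report_columns <- function(df) {
  df <- as_tibble(df)
  if (!"text" %in% names(df)) df$text <- ""
  df$text[is.na(df$text)] <- ""
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  if (!"exam_date" %in% names(df)) df$exam_date <- NA_character_
  if (!"age_at_exam" %in% names(df)) df$age_at_exam <- NA_real_
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  df$sex[is.na(df$sex)] <- "unknown"
  if (!"race_ethnicity" %in% names(df)) df$race_ethnicity <- "unknown"
  df$race_ethnicity[is.na(df$race_ethnicity)] <- "unknown"
  df[, report_columns()]
}

#' Write reports to JSONL
#'
#' @param reports a report tibble (see [read_reports()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  reports <- fill_report_columns(reports)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    writeLines(jsonlite::toJSON(as.list(reports[i, ]), auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
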