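#' Segment a report into sections and valve subsections
#'
#' Templated echo reports carry headers ("FINDINGS:", "IMPRESSION:", "Aortic
#' Valve:") on their own lines. A line whose text matches a header pattern
#' from the lexicon — case-insensitively, optionally followed by ":" or "-"
#' and same-line content — starts a new section at that line. Valve subsection
#' headers inside the findings/impression/summary regions attach a valve
#' context to their span. Sections partition the text exactly: every character
#' belongs to one section, and concatenating section texts in order
#' reconstructs the report.
#'
#' Only prose the extraction engine should scan is marked `included`:
#' findings/results, impression, summary/conclusion, valve subsections, and
#' any unlabeled text (including a whole report with no recognizable headers,
#' so nothing is silently dropped). The title/indication block (which carries
#' referral diagnoses), exam quality, dimensions/measurements, miscellaneous
#' and signature sections are excluded.
#'
#' @param text one report's raw text.
#' @param lexicon an [load_lexicon()] object supplying header patterns.
#' @return a tibble with columns `label`, `valve` (`NA` outside valve
#'   subsections), `char_start`, `char_end` (0-based half-open offsets into
#'   `text`), `included`. Zero rows for empty text.
#' @examples
#' lex <- default_lexicon()
#' segment_report("FINDINGS:\nAortic Valve: normal.\nIMPRESSION:\nnormal.", lex)
#' @export
segment_report <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(
      label = character(), valve = character(),
      char_start = integer(), char_end = integer(), included = logical()
    ))
  }
  n <- nchar(text)
  nl_pos <- which(strsplit(text, NULL)[[1]] == "\n") # 1-based "\n" positions
  line_starts <- c(0L, nl_pos) # 0-based start offset of each line
  line_starts <- line_starts[line_starts < n]

  sec_pat <- lexicon$section_headers
  sub_pat <- lexicon$subsection_headers

  sections <- list()
  cur_start <- 0L
  cur_label <- "unlabeled"
  cur_valve <- NA_character_
  cur_major <- "unlabeled"
  opened <- FALSE

  close_section <- function(end) {
    if (end > cur_start) {
      sections[[length(sections) + 1L]] <<- tibble(
        label = cur_label, valve = cur_valve,
        char_start = cur_start, char_end = end
      )
    }
  }

  for (ls in line_starts) {
    next_nl <- nl_pos[nl_pos > ls]
    le <- if (length(next_nl)) next_nl[1] else n # line spans [ls, le) excl. "\n"
    line <- substr(text, ls + 1L, le)
    hdr <- match_header(line, sec_pat, sub_pat)
    if (is.null(hdr)) next
    if (opened || ls > 0L) close_section(ls)
    cur_start <- ls
    opened <- TRUE
    if (hdr$kind == "section") {
      cur_label <- hdr$value
      cur_major <- hdr$value
      cur_valve <- NA_character_
    } else {
      cur_label <- cur_major
      cur_valve <- if (cur_major %in% c("findings_results", "impression", "summary_conclusion")) {
        hdr$value
      } else {
        NA_character_
      }
    }
  }
  close_section(n)
  out <- bind_rows(sections)
  out$included <- out$label %in%
    c("findings_results", "impression", "summary_conclusion", "unlabeled") |
    !is.na(out$valve)
  out
}

# match one line against header patterns; longest pattern wins; returns
# list(kind, value) or NULL
match_header <- function(line, sec_pat, sub_pat) {
  lower <- tolower(trimws(line))
  cands <- list()
  for (p in names(sec_pat)) {
    if (header_hits(lower, p)) cands[[length(cands) + 1L]] <-
        list(kind = "section", value = unname(sec_pat[[p]]), len = nchar(p))
  }
  for (p in names(sub_pat)) {
    if (header_hits(lower, p)) cands[[length(cands) + 1L]] <-
        list(kind = "subsection", value = unname(sub_pat[[p]]), len = nchar(p))
  }
  if (length(cands) == 0) return(NULL)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "len"))]]
}

# header pattern matches when the line IS the pattern, or starts with the
# pattern followed by ":" or "-" (content may follow on the same line)
header_hits <- function(lower_line, pattern) {
  esc <- stringr::str_replace_all(pattern, "([.\\\\+*?\\[\\]^$(){}=!<>|:#-])", "\\\\\\1")
  stringr::str_detect(lower_line, paste0("^", esc, "\\s*($|[:\\-])"))
}

#' @rdname segment_report
#' @param reports a report tibble from [read_reports()].
#' @return `segment_reports()` returns the row-bound segmentations with a
#'   leading `report_id` column.
#' @export
segment_reports <- function(reports, lexicon = default_lexicon()) {
  purrr::map2(reports$report_id, reports$text, function(id, txt) {
    seg <- segment_report(txt, lexicon)
    if (nrow(seg) > 0) seg$report_id <- id
    seg
  }) |>
    bind_rows() |>
    select(dplyr::any_of(c("report_id", "label", "valve", "char_start", "char_end", "included")))
}
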