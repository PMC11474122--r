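#' Valves, lesions and the severity priority scale
#'
#' The extractor grades two lesion types (stenosis, regurgitation) on each of
#' the four heart valves. Severity labels form a total order used both to pick
#' a winner when several severity phrases attach to one mention and to resolve
#' a report-level status from multiple sentences: `prosthetic` outranks
#' `very_severe`, down through `sclerosis`, with `unknown_severity` lowest.
#' `trace` and `trace_to_mild` are admissible only for regurgitation;
#' `sclerosis` only for the aortic valve's stenosis axis.
#'
#' @return `valves()` and `lesions()` return character vectors of the category
#'   labels. `severity_levels()` returns severity labels ordered from lowest to
#'   highest priority. `severity_rank()` returns the integer priority rank of a
#'   severity label (0 for `unknown_severity`, 10 for `prosthetic`).
#' @examples
#' valves()
#' severity_rank("severe") > severity_rank("moderate")
#' @export
valves <- function() c("aortic", "mitral", "tricuspid", "pulmonic")

#' @rdname valves
#' @export
lesions <- function() c("stenosis", "regurgitation")

.grade_rank <- c(
  unknown_severity = 0L, sclerosis = 1L, trace = 2L, trace_to_mild = 3L,
  mild = 4L, mild_to_moderate = 5L, moderate = 6L, moderate_to_severe = 7L,
  severe = 8L, very_severe = 9L, prosthetic = 10L
)

#' @rdname valves
#' @export
severity_levels <- function() names(.grade_rank)

#' @rdname valves
#' @param grade character vector of severity labels.
#' @export
severity_rank <- function(grade) {
  out <- unname(.grade_rank[grade])
  if (anyNA(out) && !anyNA(grade)) {
    bad <- setdiff(unique(grade), names(.grade_rank))
    abort(paste0("unknown severity grade(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Admissible severity grades for a (valve, lesion) pair
#'
#' @param valve one of [valves()].
#' @param lesion one of [lesions()].
#' @return character vector of grade labels a finding of this pair may carry
#'   (besides `prosthetic`, which is valve-level and always admissible).
#' @export
admissible_grades <- function(valve, lesion) {
  g <- severity_levels()
  if (lesion == "stenosis") g <- setdiff(g, c("trace", "trace_to_mild"))
  if (!(valve == "aortic" && lesion == "stenosis")) g <- setdiff(g, "sclerosis")
  g
}

# statuses a report-level finding can take
finding_statuses <- function() c("no_evidence", severity_levels())
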