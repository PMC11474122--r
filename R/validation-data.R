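#' Bundled validation count table
#'
#' Per-category true-positive, false-positive and false-negative counts from a
#' 200-report chart-review validation exercise of this class of rule-based
#' extractor, together with the positive predictive value, sensitivity and F1
#' as printed in that validation's report (percentages to one decimal, F1 to
#' two; undefined cells empty). Bundled as a worked example for the metric
#' arithmetic: recomputing the metrics from the count columns with
#' [metrics_from_counts()][score_against_gold] and [f1_score()] reproduces
#' every printed cell at its printed rounding.
#'
#' @return a tibble with columns `lesion`, `valve`, `category`, `tp`, `fp`,
#'   `fn`, `ppv`, `sensitivity`, `f1` (the three metric columns are the
#'   printed reference values; `NA` where undefined).
#' @examples
#' vc <- validation_counts()
#' with(vc[1, ], 100 * tp / (tp + fp)) # reproduces the printed ppv
#' @export
validation_counts <- function() {
  path <- system.file("extdata", "validation_counts.tsv", package = "echovhd")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    lesion = readr::col_character(),
                    valve = readr::col_character(),
                    category = readr::col_character(),
                    tp = readr::col_integer(),
                    fp = readr::col_integer(),
                    fn = readr::col_integer(),
                    ppv = readr::col_double(),
                    sensitivity = readr::col_double(),
                    f1 = readr::col_double()
                  ))
}

#' Recompute metrics from a count table
#'
#' Applies the PPV/sensitivity/F1 arithmetic to each (tp, fp, fn) triple of a
#' count table such as [validation_counts()].
#'
#' @param counts a tibble with `tp`, `fp`, `fn` columns.
#' @return the input with recomputed `ppv`, `sensitivity` (percent) and `f1`
#'   columns replacing any present.
#' @export
recompute_metrics <- function(counts) {
  m <- metrics_from_counts(counts$tp, counts$fp, counts$fn)
  counts$ppv <- m$ppv
  counts$sensitivity <- m$sensitivity
  counts$f1 <- m$f1
  counts
}
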