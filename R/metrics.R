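#' F1 score from PPV and sensitivity percentages
#'
#' Harmonic mean `2 * PPV * sensitivity / (PPV + sensitivity)`, rescaled to
#' the `[0, 1]` scale from percent inputs. Undefined (NA) when either input is
#' missing or both are zero.
#'
#' @param ppv positive predictive value, in percent.
#' @param sensitivity sensitivity, in percent.
#' @return F1 on `[0, 1]` (vectorized).
#' @examples
#' f1_score(96.2, 96.2)
#' f1_score(100, 66.7)
#' @export
f1_score <- function(ppv, sensitivity) {
  out <- ifelse(
    is.na(ppv) | is.na(sensitivity) | (ppv == 0 & sensitivity == 0),
    NA_real_,
    2 * ppv * sensitivity / (ppv + sensitivity) / 100
  )
  unname(out)
}

metrics_from_counts <- function(tp, fp, fn) {
  ppv <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         ppv = ppv, sensitivity = sens, f1 = f1_score(ppv, sens))
}

#' Score predicted findings against gold annotations
#'
#' For every (valve, lesion) pair, emits per-category counts and metrics for:
#' `no_evidence`, `prosthetic`, `sclerosis` (aortic stenosis only),
#' `severity_detected` (any graded or unknown-severity status on both sides,
#' regardless of whether the grades agree), and each individual grade (exact
#' match). TP counts reports where both sides carry the category, FP where
#' only the prediction does, FN where only the gold does. PPV and sensitivity
#' are percentages, undefined (NA) when their denominator is zero — shown as
#' "—" in formatted output.
#'
#' @param predicted findings tibble from the extractor.
#' @param gold findings tibble with human-adjudicated statuses; must cover
#'   the same report ids.
#' @return a tibble of class `valve_metrics`: `valve`, `lesion`, `category`,
#'   `tp`, `fp`, `fn`, `ppv`, `sensitivity`, `f1` (unrounded; see
#'   [format_metrics()] for display rounding).
#' @export
score_against_gold <- function(predicted, gold) {
  pid <- unique(predicted$report_id)
  gid <- unique(gold$report_id)
  if (!setequal(pid, gid)) {
    miss <- c(setdiff(gid, pid), setdiff(pid, gid))
    abort(paste0("predicted and gold cover different report ids: ",
                 paste(utils::head(miss, 10), collapse = ", ")),
      class = "echovhd_id_mismatch"
    )
  }
  grid <- tidyr::expand_grid(report_id = pid, valve = valves(), lesion = lesions())
  both <- grid |>
    left_join(select(predicted, "report_id", "valve", "lesion", pred = "status"),
              by = c("report_id", "valve", "lesion")) |>
    left_join(select(gold, "report_id", "valve", "lesion", gold = "status"),
              by = c("report_id", "valve", "lesion")) |>
    mutate(
      pred = dplyr::coalesce(.data$pred, "no_evidence"),
      gold = dplyr::coalesce(.data$gold, "no_evidence")
    )
  detected <- graded_statuses()
  out <- purrr::pmap(
    tidyr::expand_grid(valve = valves(), lesion = lesions()),
    function(valve, lesion) {
      d <- both[both$valve == valve & both$lesion == lesion, , drop = FALSE]
      cats <- c("no_evidence", "prosthetic",
                if (valve == "aortic" && lesion == "stenosis") "sclerosis",
                "severity_detected", detected)
      purrr::map(cats, function(cat) {
        if (cat == "severity_detected") {
          p <- d$pred %in% detected
          g <- d$gold %in% detected
        } else {
          p <- d$pred == cat
          g <- d$gold == cat
        }
        m <- metrics_from_counts(sum(p & g), sum(p & !g), sum(!p & g))
        dplyr::bind_cols(tibble(valve = valve, lesion = lesion, category = cat), m)
      }) |> bind_rows()
    }
  ) |> bind_rows()
  class(out) <- c("valve_metrics", class(out))
  out
}

#' Round metrics for display
#'
#' Percentages to one decimal, F1 to two decimals, with `NA` rendered as "—",
#' the conventional layout of validation tables.
#'
#' @param metrics a `valve_metrics` tibble.
#' @return a tibble of formatted character columns.
#' @export
format_metrics <- function(metrics) {
  fmt <- function(x, digits) ifelse(is.na(x), "—", formatC(x, format = "f", digits = digits))
  metrics |>
    as_tibble() |>
    mutate(
      ppv = fmt(.data$ppv, 1),
      sensitivity = fmt(.data$sensitivity, 1),
      f1 = fmt(.data$f1, 2)
    )
}

#' @exportS3Method
glance.valve_metrics <- function(x, ...) {
  base <- x[x$category != "severity_detected", , drop = FALSE]
  tp <- sum(base$tp)
  fp <- sum(base$fp)
  fn <- sum(base$fn)
  micro_ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  micro_sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  tibble(
    n_categories = nrow(x),
    n_populated = sum(x$tp + x$fp + x$fn > 0),
    n_perfect = sum(!is.na(x$f1) & x$f1 == 1),
    micro_ppv = micro_ppv,
    micro_sensitivity = micro_sens,
    micro_f1 = f1_score(micro_ppv, micro_sens)
  )
}

#' @exportS3Method
tidy.valve_metrics <- function(x, ...) as_tibble(x)

#' Plot per-category validation metrics
#'
#' PPV and sensitivity per category, faceted by valve and lesion; undefined
#' cells are omitted.
#'
#' @param object a `valve_metrics` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method
autoplot.valve_metrics <- function(object, ...) {
  df <- object |>
    as_tibble() |>
    tidyr::pivot_longer(c("ppv", "sensitivity"),
                        names_to = "metric", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = factor(.data$category, levels = rev(c("no_evidence", "prosthetic",
                                              "sclerosis", "severity_detected",
                                              graded_statuses()))),
    colour = .data$metric
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(lesion ~ valve) +
    ggplot2::labs(x = "percent", y = NULL, colour = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
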