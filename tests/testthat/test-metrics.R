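test_that("F1 reproduces worked examples at display rounding", {
  expect_equal(round(f1_score(96.2, 96.2), 2), 0.96)
  expect_equal(round(f1_score(100, 66.7), 2), 0.80)
  expect_equal(f1_score(100, 100), 1)
  expect_true(is.na(f1_score(0, 0)))
  expect_true(is.na(f1_score(NA, 50)))
})

test_that("F1 is symmetric and bounded by the arithmetic mean", {
  set.seed(5)
  p <- stats::runif(500, 0, 100)
  s <- stats::runif(500, 0, 100)
  expect_equal(f1_score(p, s), f1_score(s, p))
  expect_true(all(f1_score(p, s) <= (p + s) / 200 + 1e-12))
})

test_that("count arithmetic reproduces a printed validation row", {
  m <- echovhd:::metrics_from_counts(4, 1, 0)
  expect_equal(m$ppv, 80)
  expect_equal(m$sensitivity, 100)
  expect_equal(round(m$f1, 2), 0.89)
  empty <- echovhd:::metrics_from_counts(0, 0, 0)
  expect_true(is.na(empty$ppv) && is.na(empty$sensitivity) && is.na(empty$f1))
})

test_that("perfect agreement scores 100/100/1 on every populated category", {
  corpus <- generate_corpus(synth_config(n_reports = 30, seed = 8))
  met <- score_against_gold(corpus$gold, corpus$gold)
  pop <- met[met$tp + met$fp + met$fn > 0, ]
  expect_gt(nrow(pop), 0)
  expect_true(all(pop$ppv == 100 & pop$sensitivity == 100 & pop$f1 == 1))
  und <- met[met$tp + met$fp + met$fn == 0, ]
  expect_true(all(is.na(und$ppv)))
})

test_that("scoring refuses mismatched report ids and lists them", {
  g <- generate_corpus(synth_config(n_reports = 3, seed = 1))$gold
  g2 <- g
  g2$report_id <- paste0(g2$report_id, "-other")
  expect_error(score_against_gold(g, g2), class = "echovhd_id_mismatch")
})

test_that("severity-detected rows use any-grade matching", {
  gold <- resolve_findings(tibble::tibble(), "r1")
  pred <- gold
  gold$status[gold$valve == "mitral" & gold$lesion == "stenosis"] <- "moderate_to_severe"
  pred$status[pred$valve == "mitral" & pred$lesion == "stenosis"] <- "severe"
  met <- score_against_gold(pred, gold)
  ms <- met[met$valve == "mitral" & met$lesion == "stenosis", ]
  expect_equal(ms$tp[ms$category == "severity_detected"], 1L) # detected on both sides
  expect_equal(ms$fp[ms$category == "severe"], 1L)            # exact grade disagrees
  expect_equal(ms$fn[ms$category == "moderate_to_severe"], 1L)
})

test_that("counts conserve predicted and gold positives per category", {
  set.seed(6)
  ids <- sprintf("r%02d", 1:20)
  rand_findings <- function() {
    tidyr::expand_grid(report_id = ids, valve = valves(), lesion = lesions()) |>
      dplyr::rowwise() |>
      dplyr::mutate(status = sample(c("no_evidence", admissible_grades(valve, lesion)), 1),
                    n_supporting_mentions = NA_integer_) |>
      dplyr::ungroup()
  }
  pred <- rand_findings()
  gold <- rand_findings()
  met <- score_against_gold(pred, gold)
  per_grade <- met[!met$category %in% "severity_detected", ]
  for (v in valves()) {
    for (l in lesions()) {
      sub <- per_grade[per_grade$valve == v & per_grade$lesion == l, ]
      gold_sub <- gold[gold$valve == v & gold$lesion == l, ]
      pred_sub <- pred[pred$valve == v & pred$lesion == l, ]
      for (k in seq_len(nrow(sub))) {
        expect_equal(sub$tp[k] + sub$fn[k], sum(gold_sub$status == sub$category[k]))
        expect_equal(sub$tp[k] + sub$fp[k], sum(pred_sub$status == sub$category[k]))
      }
    }
  }
})

test_that("display formatting rounds like a validation table", {
  met <- tibble::tibble(valve = "pulmonic", lesion = "stenosis",
                        category = "severity_detected", tp = 25L, fp = 1L, fn = 1L,
                        ppv = 100 * 25 / 26, sensitivity = 100 * 25 / 26,
                        f1 = f1_score(100 * 25 / 26, 100 * 25 / 26))
  fmt <- format_metrics(met)
  expect_equal(fmt$ppv, "96.2")
  expect_equal(fmt$sensitivity, "96.2")
  expect_equal(fmt$f1, "0.96")
  na_fmt <- format_metrics(tibble::tibble(ppv = NA_real_, sensitivity = NA_real_,
                                          f1 = NA_real_))
  expect_true(all(na_fmt == "—"))
})
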