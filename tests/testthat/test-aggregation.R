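mk_mention <- function(report_id = "r", valve, lesion, severity,
                       prosthetic = FALSE) {
  tibble::tibble(
    report_id = report_id, sent_id = 1L, section_label = "findings_results",
    valve_context = NA_character_, valve = valve, lesion = lesion,
    matched_phrase = "x", char_start = 0L, char_end = 1L, negated = FALSE,
    historical = FALSE, prosthetic = prosthetic, severity = severity
  )
}

test_that("report resolution applies the severity priority", {
  m <- dplyr::bind_rows(
    mk_mention(valve = "aortic", lesion = "stenosis", severity = "mild"),
    mk_mention(valve = "aortic", lesion = "stenosis", severity = "severe")
  )
  f <- resolve_report(m)
  expect_equal(nrow(f), 8)
  expect_equal(f$status[f$valve == "aortic" & f$lesion == "stenosis"], "severe")
  expect_true(all(f$status[!(f$valve == "aortic" & f$lesion == "stenosis")] ==
                    "no_evidence"))
})

test_that("no mentions yields eight no-evidence findings; graded beats ungraded", {
  f <- resolve_report(mk_mention(valve = "x", lesion = "y", severity = "z")[0, ], "r9")
  expect_equal(nrow(f), 8)
  expect_true(all(f$status == "no_evidence"))
  expect_true(all(f$n_supporting_mentions == 0))

  m <- dplyr::bind_rows(
    mk_mention(valve = "mitral", lesion = "regurgitation", severity = "unknown_severity"),
    mk_mention(valve = "mitral", lesion = "regurgitation", severity = "trace")
  )
  f2 <- resolve_report(m)
  expect_equal(f2$status[f2$valve == "mitral" & f2$lesion == "regurgitation"], "trace")
  # ungraded evidence alone still counts as evidence
  f3 <- resolve_report(mk_mention(valve = "mitral", lesion = "regurgitation",
                                  severity = "unknown_severity"))
  expect_equal(f3$status[f3$valve == "mitral" & f3$lesion == "regurgitation"],
               "unknown_severity")
})

test_that("a prosthetic mention makes the whole valve prosthetic", {
  m <- dplyr::bind_rows(
    mk_mention(valve = "aortic", lesion = NA_character_, severity = "prosthetic",
               prosthetic = TRUE),
    mk_mention(valve = "aortic", lesion = "regurgitation", severity = "trace")
  )
  f <- resolve_report(m)
  ao <- f[f$valve == "aortic", ]
  expect_true(all(ao$status == "prosthetic"))
  expect_true(all(ao$n_supporting_mentions >= 1))
})

test_that("mixed report ids are refused", {
  m <- dplyr::bind_rows(
    mk_mention("r1", valve = "aortic", lesion = "stenosis", severity = "mild"),
    mk_mention("r2", valve = "aortic", lesion = "stenosis", severity = "mild")
  )
  expect_error(resolve_report(m), class = "echovhd_mixed_report_ids")
})

test_that("resolution is order-invariant and monotone in added evidence", {
  set.seed(31)
  for (i in 1:1000) {
    m <- random_mentions("r")
    if (nrow(m) == 0) next
    base <- resolve_report(m, "r")
    perm <- resolve_report(m[sample(nrow(m)), ], "r")
    expect_identical(
      dplyr::arrange(base, valve, lesion),
      dplyr::arrange(perm, valve, lesion)
    )
    # adding one more mention never lowers any resolved rank
    extra <- random_mentions("r", n = 1)
    more <- resolve_report(dplyr::bind_rows(m, extra), "r")
    expect_true(all(status_rank(dplyr::arrange(more, valve, lesion)$status) >=
                      status_rank(dplyr::arrange(base, valve, lesion)$status)))
  }
})

test_that("findings cardinality is always 8 per report", {
  set.seed(32)
  ids <- sprintf("r%03d", 1:1000)
  ments <- dplyr::bind_rows(lapply(ids[1:500], function(id) random_mentions(id)))
  f <- resolve_findings(ments, report_ids = ids)
  expect_equal(nrow(f), 8 * length(ids))
  expect_true(all(table(f$report_id) == 8L))
  expect_true(all((f$status == "no_evidence") == (f$n_supporting_mentions == 0)))
})

test_that("findings files round-trip in both formats", {
  f <- resolve_findings(random_mentions("r1"), c("r1", "r2"))
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_findings(f, path, fmt)
    expect_equal(read_findings(path), f)
  }
  expect_equal(nrow(f), 16) # 8 per report
  # empty stream gives a header-only file
  path <- withr::local_tempfile(fileext = ".csv")
  write_findings(f[0, ], path, "csv")
  expect_equal(nrow(read_findings(path)), 0)
})

test_that("cohort summaries match the generator's ground-truth tallies", {
  corpus <- generate_corpus(synth_config(n_reports = 60, seed = 13))
  smry <- summarize_cohort(corpus$gold, corpus$reports)
  overall <- smry[smry$stratum_type == "overall", ]
  truth_bands <- corpus$gold |>
    dplyr::mutate(band = echovhd:::severity_band(status)) |>
    dplyr::filter(!is.na(band)) |>
    dplyr::count(valve, lesion, band)
  joined <- dplyr::full_join(overall, truth_bands,
                             by = c("valve", "lesion", "band"))
  expect_true(all(joined$n.x == joined$n.y))
  # within-stratum percentages total 100 per (valve, lesion)
  tot <- overall |>
    dplyr::group_by(valve, lesion) |>
    dplyr::summarise(p = sum(pct), .groups = "drop")
  expect_true(all(abs(tot$p - 100) < 1e-9))
  # conservation across sex strata
  by_sex <- smry[smry$stratum_type == "sex", ]
  expect_equal(sum(by_sex$n), sum(overall$n))
})

test_that("single-finding summaries and empty inputs behave", {
  reps <- tibble::tibble(report_id = "r1", text = "", sex = "female",
                         age_at_exam = 70, race_ethnicity = "hispanic")
  f <- tibble::tibble(report_id = "r1", valve = "aortic", lesion = "stenosis",
                      status = "mild", n_supporting_mentions = 1L)
  smry <- summarize_cohort(f, reps)
  sex_row <- smry[smry$stratum_type == "sex", ]
  expect_equal(sex_row$stratum, "female")
  expect_equal(sex_row$n, 1L)
  expect_equal(sex_row$pct, 100)
  expect_equal(nrow(summarize_cohort(f[0, ], reps)), 0)
})
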