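test_that("the generator is deterministic under a fixed seed", {
  a <- generate_corpus(synth_config(n_reports = 50, seed = 7))
  b <- generate_corpus(synth_config(n_reports = 50, seed = 7))
  expect_identical(a$reports, b$reports)
  expect_identical(a$gold, b$gold)
  c2 <- generate_corpus(synth_config(n_reports = 50, seed = 8))
  expect_false(identical(a$reports$text, c2$reports$text))
})

test_that("zero prevalence gives all-no-evidence gold while distractors remain", {
  prev <- default_prevalence <- echovhd:::default_prevalence()
  prev[] <- 0
  cfg <- synth_config(n_reports = 30, seed = 3, prevalence = prev,
                      p_negated_sentence = 1, p_prosthetic = 0)
  corpus <- generate_corpus(cfg)
  expect_true(all(corpus$gold$status == "no_evidence"))
  expect_true(any(grepl("no |without evidence", corpus$reports$text)))
})

test_that("config validation rejects bad probabilities and inadmissible grades", {
  expect_error(synth_config(p_misspelling = 1.5),
               class = "echovhd_synth_config_error")
  sd <- echovhd:::default_severity_dist()
  sd$mitral.stenosis <- c(trace = 1) # trace inadmissible for stenosis
  expect_error(synth_config(severity_dist = sd),
               class = "echovhd_synth_config_error")
})

test_that("clean mode zeroes all noise probabilities and is idempotent", {
  cfg <- synth_config(p_negated_sentence = 0.5, p_history_sentence = 0.5,
                      p_misspelling = 0.5, p_ambiguous_abbrev = 0.5)
  cl <- clean_mode(cfg)
  expect_equal(cl$p_negated_sentence, 0)
  expect_equal(cl$p_history_sentence, 0)
  expect_equal(cl$p_misspelling, 0)
  expect_equal(cl$p_ambiguous_abbrev, 0)
  expect_identical(clean_mode(cl), cl)
})

test_that("gold tallies equal the sampler's draws under rare-lesion enrichment", {
  prev <- echovhd:::default_prevalence()
  prev$tricuspid.stenosis <- 0.5
  prev$pulmonic.stenosis <- 0.5
  corpus <- generate_corpus(synth_config(n_reports = 80, seed = 21,
                                         prevalence = prev, p_prosthetic = 0))
  tally <- corpus$manifest$tally
  expect_equal(sum(tally$n), nrow(corpus$gold))
  expect_equal(nrow(corpus$gold), 8 * 80)
  # enrichment visible in the gold
  ts <- corpus$gold[corpus$gold$valve == "tricuspid" &
                      corpus$gold$lesion == "stenosis", ]
  expect_gt(mean(ts$status != "no_evidence"), 0.3)
})

test_that("every distractor sentence in isolation yields no surviving mention", {
  distractors <- c(
    "no aortic stenosis.", "no regurgitation.", "without evidence of stenosis.",
    "no significant regurgitation.",
    "a prior study showed trace mitral regurgitation.",
    "previously noted mild aortic stenosis.", "history of pulmonic stenosis.",
    "peak velocity 450 ms.", "valve function preserved as before.",
    "leaflets appear unremarkable as expected."
  )
  for (d in distractors) {
    for (vc in c(NA, valves())) {
      expect_equal(nrow(surviving(sent(d, vc))), 0, info = paste(d, vc))
    }
  }
})

test_that("sampled prevalence converges to the configured rates at n = 2000", {
  corpus <- generate_corpus(synth_config(n_reports = 2000, seed = 17,
                                         p_prosthetic = 0))
  prev <- echovhd:::default_prevalence()
  for (key in names(prev)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    g <- corpus$gold[corpus$gold$valve == parts[1] & corpus$gold$lesion == parts[2], ]
    phat <- mean(g$status != "no_evidence")
    p <- prev[[key]]
    tol <- 4 * sqrt(p * (1 - p) / 2000) + 0.005
    expect_lt(abs(phat - p), tol)
  }
})

test_that("a corpus writes reports, gold and manifest to disk", {
  corpus <- generate_corpus(synth_config(n_reports = 5, seed = 2))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_equal(suppressMessages(read_reports(file.path(dir, "reports.jsonl"))),
               corpus$reports)
  expect_equal(read_findings(file.path(dir, "gold.csv")), corpus$gold)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$n_reports, 5)
})
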