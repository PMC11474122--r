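test_that("lesion term search resolves valves from phrases and context", {
  m <- sent("mild aortic stenosis and moderate mitral regurgitation")
  expect_equal(nrow(m), 2)
  expect_equal(m$valve, c("aortic", "mitral"))
  expect_equal(m$lesion, c("stenosis", "regurgitation"))
  expect_equal(m$severity, c("mild", "moderate"))

  m2 <- sent("trace regurgitation", "tricuspid")
  expect_equal(m2$valve, "tricuspid")
  expect_equal(m2$severity, "trace")

  # a bare lesion noun with no resolvable valve yields nothing
  expect_equal(nrow(sent("trace regurgitation")), 0)

  # coordinated valves before a shared lesion noun emit one mention each
  m3 <- sent("aortic or mitral stenosis")
  expect_setequal(m3$valve, c("aortic", "mitral"))
  expect_true(all(m3$lesion == "stenosis"))
})

test_that("abbreviation disambiguation follows the rule table", {
  # "ms" after a number is a millisecond, even in mitral context
  expect_equal(nrow(surviving(sent("peak velocity 450 ms", "mitral"))), 0)
  expect_equal(sent("moderate ms")$valve, "mitral")
  # "as" as a conjunction never becomes aortic stenosis
  expect_equal(nrow(sent("valve function preserved as before", "aortic")), 0)
  expect_equal(sent("mild as", "aortic")$lesion, "stenosis")
  expect_equal(sent("mild as")$valve, "aortic") # severity phrase licenses it
  expect_equal(nrow(sent("as")), 0)
  # "tr" before another lesion phrase is severity trace
  m <- sent("tr mr")
  expect_equal(m$valve, "mitral")
  expect_equal(m$severity, "trace")
  expect_equal(sent("tr", "tricuspid")$valve, "tricuspid")
  expect_equal(nrow(sent("tr")), 0)
  # congenital shorthand is ignored entirely
  expect_equal(nrow(sent("systemic av")), 0)
  expect_equal(nrow(sent("subpulmonic av")), 0)
})

test_that("negation cues negate within the window and stop at scope breakers", {
  expect_true(sent("no aortic stenosis")$negated)
  expect_true(sent("without evidence of aortic stenosis")$negated)
  m <- sent("no mitral stenosis but moderate mitral regurgitation")
  expect_equal(m$negated[m$lesion == "stenosis"], TRUE)
  expect_equal(m$negated[m$lesion == "regurgitation"], FALSE)
  expect_equal(m$severity[m$lesion == "regurgitation"], "moderate")
  # one cue negates a coordinated pair
  m2 <- sent("no aortic or mitral stenosis")
  expect_true(all(m2$negated))
  # beyond the 5-token window the cue no longer applies
  far <- sent("no thrombus is seen in the left atrium however severe mitral stenosis")
  expect_false(far$negated[far$lesion == "stenosis"])
})

test_that("history cues drop mentions but never prosthetic status", {
  expect_true(sent("a prior study showed trace mitral regurgitation")$historical)
  expect_false(sent("trace mitral regurgitation")$historical)
  m <- sent("known severe as, now status post tavr")
  lesion_m <- m[!m$prosthetic, ]
  expect_true(all(lesion_m$historical))
  pros <- m[m$prosthetic, ]
  expect_equal(nrow(pros), 1)
  expect_false(pros$historical)
  expect_equal(pros$severity, "prosthetic")
})

test_that("severity attaches by priority, first-of-list, and post-modifier rules", {
  # severity before a slash list grades only the first term by default
  m <- sent("mild as/ai/mr")
  expect_equal(m$severity[m$matched_phrase == "as"], "mild")
  expect_equal(m$severity[m$matched_phrase == "ai"], "unknown_severity")
  expect_equal(m$severity[m$matched_phrase == "mr"], "unknown_severity")
  # ... unless distribution is explicitly enabled
  md <- sent("mild as/ai/mr",
             options = extraction_options(distribute_severity_over_lists = TRUE))
  expect_true(all(md$severity == "mild"))
  # broken adjacency: "moderate to severe" cannot match, "severe" wins by rank
  expect_equal(sent("moderate to borderline severe calcific mitral stenosis")$severity,
               "severe")
  # post-modifier within three tokens
  expect_equal(sent("aortic stenosis, severe")$severity, "severe")
  expect_equal(sent("the mitral regurgitation is moderate")$severity, "moderate")
  # no severity phrase at all
  expect_equal(sent("aortic stenosis is present")$severity, "unknown_severity")
})

test_that("inadmissible severities are refused with a warning", {
  expect_warning(m <- sent("trace aortic stenosis"),
                 class = "echovhd_inadmissible_severity")
  expect_equal(m$severity, "unknown_severity")
})

test_that("prosthetic cues emit valve-level prosthetic mentions", {
  m <- sent("the aortic valve is prosthetic")
  expect_true(m$prosthetic)
  expect_equal(m$valve, "aortic")
  expect_true(is.na(m$lesion))
  m2 <- sent("aortic valve is well seated", "aortic")
  expect_equal(m2$severity, "prosthetic")
  expect_equal(sent("status post tavr")$valve, "aortic")
  expect_equal(sent("status post mvr")$valve, "mitral")
})

test_that("standalone sclerosis lands on the aortic stenosis axis only", {
  m <- sent("the aortic valve is sclerotic")
  expect_equal(m$lesion, "stenosis")
  expect_equal(m$severity, "sclerosis")
  m2 <- sent("aortic valve sclerosis is present", "aortic")
  expect_equal(m2$severity, "sclerosis")
  # graded stenosis in the same sentence outranks the sclerosis modifier
  m3 <- sent("mild aortic stenosis with sclerosis")
  expect_equal(m3$severity, "mild")
  # sclerosis of another valve is not a recognized finding
  expect_equal(nrow(sent("the mitral valve is sclerotic", "mitral")), 0)
})

test_that("sentence processing is deterministic and whitespace-insensitive", {
  set.seed(99)
  for (i in 1:50) {
    txt <- random_words(sample(2:10, 1))
    a <- suppressWarnings(sent(txt))
    b <- suppressWarnings(sent(txt))
    expect_identical(a, b)
    expect_identical(suppressWarnings(sent(paste0(txt, "   "))), a)
  }
})

test_that("no inadmissible severity ever survives on random synthetic sentences", {
  set.seed(2024)
  grades <- c("trace", "mild", "moderate", "severe", "sclerosis", "trace to mild")
  nouns <- c("aortic stenosis", "mitral regurgitation", "stenosis",
             "regurgitation", "tricuspid regurgitation", "ms", "tr", "as")
  for (i in 1:400) {
    txt <- paste(sample(c(sample(grades, 1), sample(nouns, 1), "no", "the"),
                        sample(2:4, 1), replace = TRUE), collapse = " ")
    vc <- sample(c(NA, valves()), 1)
    m <- surviving(suppressWarnings(sent(txt, vc)))
    for (k in seq_len(nrow(m))) {
      if (is.na(m$lesion[k])) next
      expect_true(
        m$severity[k] %in% c(admissible_grades(m$valve[k], m$lesion[k]), "prosthetic"),
        info = paste(txt, "|", vc)
      )
    }
  }
})
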