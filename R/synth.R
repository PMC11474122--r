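#' Configuration for the synthetic report generator
#'
#' Defaults emulate the mix seen in templated community echo reporting:
#' regurgitation common (trace/mild dominant), stenosis uncommon with mitral,
#' tricuspid and pulmonic stenosis rare, aortic sclerosis a frequent stenosis-
#' axis status, and a modest prosthetic-valve rate. All rates are
#' configurable; the defaults are a fixed study condition, not fitted to any
#' cohort.
#'
#' @param n_reports number of reports to generate.
#' @param seed RNG seed; the same seed yields a byte-identical corpus.
#' @param prevalence named list `valve.lesion` -> probability of disease.
#' @param severity_dist named list `valve.lesion` -> named probability vector
#'   over admissible grades (may include `unknown_severity`).
#' @param p_negated_sentence probability a disease-free (valve, lesion) pair
#'   renders an explicit negated sentence ("no aortic stenosis.").
#' @param p_history_sentence probability a disease-free pair renders a
#'   historical distractor ("a prior study showed mild ...").
#' @param p_misspelling probability a positive sentence carries one
#'   misspelling drawn from the lexicon's misspelling-map keys.
#' @param p_ambiguous_abbrev probability a valve subsection carries an
#'   ambiguous-abbreviation distractor ("peak velocity 450 ms.", conjunction
#'   "as").
#' @param p_prosthetic per-valve probability the valve is prosthetic.
#' @param demographics list of sampling weight vectors `age`, `sex`, `race`.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 200,
                         seed = 1L,
                         prevalence = NULL,
                         severity_dist = NULL,
                         p_negated_sentence = 0.3,
                         p_history_sentence = 0.1,
                         p_misspelling = 0,
                         p_ambiguous_abbrev = 0.15,
                         p_prosthetic = 0.04,
                         demographics = NULL) {
  prevalence <- prevalence %||% default_prevalence()
  severity_dist <- severity_dist %||% default_severity_dist()
  demographics <- demographics %||% list(
    age = c("18-49" = 0.2, "50-64" = 0.3, "65-79" = 0.35, ">=80" = 0.15),
    sex = c(female = 0.52, male = 0.48),
    race = c(
      "non-hispanic white" = 0.4, "hispanic" = 0.3, "non-hispanic black" = 0.1,
      "non-hispanic asian/pacific islander" = 0.1, "other/unknown" = 0.1
    )
  )
  probs <- c(p_negated_sentence, p_history_sentence, p_misspelling,
             p_ambiguous_abbrev, p_prosthetic, unlist(prevalence))
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]",
                                        class = "echovhd_synth_config_error")
  for (key in names(severity_dist)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    adm <- admissible_grades(parts[1], parts[2])
    bad <- setdiff(names(severity_dist[[key]]), adm)
    if (length(bad) > 0) {
      abort(paste0("severity_dist for ", key, " includes inadmissible grade(s): ",
                   paste(bad, collapse = ", ")),
        class = "echovhd_synth_config_error"
      )
    }
  }
  structure(
    list(
      n_reports = as.integer(n_reports), seed = as.integer(seed),
      prevalence = prevalence, severity_dist = severity_dist,
      p_negated_sentence = p_negated_sentence,
      p_history_sentence = p_history_sentence,
      p_misspelling = p_misspelling,
      p_ambiguous_abbrev = p_ambiguous_abbrev,
      p_prosthetic = p_prosthetic,
      demographics = demographics
    ),
    class = "synth_config"
  )
}

default_prevalence <- function() {
  list(
    aortic.stenosis = 0.18, aortic.regurgitation = 0.30,
    mitral.stenosis = 0.05, mitral.regurgitation = 0.50,
    tricuspid.stenosis = 0.02, tricuspid.regurgitation = 0.50,
    pulmonic.stenosis = 0.03, pulmonic.regurgitation = 0.30
  )
}

default_severity_dist <- function() {
  sten <- c(mild = 0.35, mild_to_moderate = 0.1, moderate = 0.25,
            moderate_to_severe = 0.08, severe = 0.13, very_severe = 0.02,
            unknown_severity = 0.07)
  reg <- c(trace = 0.3, trace_to_mild = 0.05, mild = 0.3,
           mild_to_moderate = 0.1, moderate = 0.12, moderate_to_severe = 0.05,
           severe = 0.05, very_severe = 0.01, unknown_severity = 0.02)
  list(
    aortic.stenosis = c(sclerosis = 0.3, sten * 0.7 / sum(sten)),
    aortic.regurgitation = reg,
    mitral.stenosis = sten,
    mitral.regurgitation = reg,
    tricuspid.stenosis = sten,
    tricuspid.regurgitation = reg,
    pulmonic.stenosis = sten,
    pulmonic.regurgitation = reg
  )
}

#' Noise-free variant of a generator configuration
#'
#' Zeroes every noise probability (negated and historical distractors,
#' misspellings, ambiguous-abbreviation traps) so the corpus contains only
#' clean positive findings sentences — the corpus on which extraction must
#' recover the ground truth exactly. Idempotent.
#'
#' @param config a [synth_config()].
#' @return the modified config.
#' @export
clean_mode <- function(config) {
  config$p_negated_sentence <- 0
  config$p_history_sentence <- 0
  config$p_misspelling <- 0
  config$p_ambiguous_abbrev <- 0
  config
}

# canonical rendering phrase per grade
grade_phrase <- c(
  very_severe = "very severe", severe = "severe",
  moderate_to_severe = "moderate to severe", moderate = "moderate",
  mild_to_moderate = "mild to moderate", mild = "mild",
  trace_to_mild = "trace to mild", trace = "trace"
)

lesion_noun <- c(stenosis = "stenosis", regurgitation = "regurgitation")

full_lesion_phrase <- function(valve, lesion) paste(valve, lesion_noun[[lesion]])

abbrev_for <- c(
  "aortic.stenosis" = "as", "aortic.regurgitation" = "ai",
  "mitral.stenosis" = "ms", "mitral.regurgitation" = "mr",
  "tricuspid.stenosis" = "ts", "tricuspid.regurgitation" = "tr",
  "pulmonic.stenosis" = "ps", "pulmonic.regurgitation" = "pr"
)

#' Generate a synthetic annotated corpus
#'
#' Builds templated multi-section reports (indication, measurements, findings
#' with per-valve subsections, impression, signature) from a sampled ground
#' truth, together with the exact gold findings. The gold is derived
#' analytically from the sampled truth by the same priority rules as
#' aggregation (a sampled prosthetic valve is prosthetic under both lesions)
#' — never by running the extractor, so end-to-end tests are non-circular.
#' Distractor sentences (negated findings, historical findings, millisecond
#' "ms" readings, conjunction "as") are guaranteed absent from the gold;
#' misspellings are injected only from the lexicon's curated map, so
#' normalization can undo them.
#'
#' @param config a [synth_config()].
#' @param lexicon an [load_lexicon()] object.
#' @return a list of class `echo_corpus`: `reports` (report tibble), `gold`
#'   (findings tibble) and `manifest` (config echo plus gold tallies).
#' @export
generate_corpus <- function(config, lexicon = default_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rev_map <- split(names(lexicon$misspelling_map), unname(lexicon$misspelling_map))

  reports <- vector("list", config$n_reports)
  gold <- vector("list", config$n_reports)
  for (i in seq_len(config$n_reports)) {
    r <- generate_one_report(sprintf("synth-%05d", i), config, lexicon, rev_map)
    reports[[i]] <- r$report
    gold[[i]] <- r$gold
  }
  reports <- bind_rows(reports)
  gold <- bind_rows(gold)
  if (config$n_reports == 0) {
    reports <- fill_report_columns(tibble(report_id = character(), text = character()))
    gold <- tibble(report_id = character(), valve = character(), lesion = character(),
                   status = character(), n_supporting_mentions = integer())
  }
  manifest <- list(
    config = unclass(config),
    n_reports = config$n_reports,
    tally = if (nrow(gold) > 0) count(gold, .data$valve, .data$lesion, .data$status) else gold
  )
  structure(list(reports = reports, gold = gold, manifest = manifest),
            class = "echo_corpus")
}

generate_one_report <- function(report_id, config, lexicon, rev_map) {
  dem <- config$demographics
  band <- sample(names(dem$age), 1, prob = dem$age)
  age <- switch(band,
    "18-49" = sample(18:49, 1), "50-64" = sample(50:64, 1),
    "65-79" = sample(65:79, 1), sample(80:95, 1)
  )
  sex <- sample(names(dem$sex), 1, prob = dem$sex)
  race <- sample(names(dem$race), 1, prob = dem$race)

  truth <- tidyr::expand_grid(valve = valves(), lesion = lesions())
  truth$grade <- NA_character_
  pros <- stats::setNames(stats::runif(4) < config$p_prosthetic, valves())
  for (k in seq_len(nrow(truth))) {
    key <- paste(truth$valve[k], truth$lesion[k], sep = ".")
    if (stats::runif(1) < config$prevalence[[key]]) {
      d <- config$severity_dist[[key]]
      truth$grade[k] <- sample(names(d), 1, prob = d)
    }
  }

  lines <- c(
    "INDICATION: murmur evaluation.",
    if (config$p_history_sentence > 0 && stats::runif(1) < 0.5) {
      "INDICATION NOTE: follow up of severe aortic stenosis." # excluded section
    },
    "MEASUREMENTS:",
    "aortic valve peak velocity 2.5 m/s.",
    "FINDINGS:"
  )
  for (v in valves()) {
    lines <- c(lines, paste0(stringr::str_to_title(v), " Valve:"))
    sub <- character()
    if (pros[[v]]) {
      sub <- c(sub, render_prosthetic_sentence(v))
    } else {
      for (l in lesions()) {
        g <- truth$grade[truth$valve == v & truth$lesion == l]
        if (!is.na(g)) {
          s <- render_positive_sentence(v, l, g)
          if (config$p_misspelling > 0 && stats::runif(1) < config$p_misspelling) {
            s <- inject_misspelling(s, rev_map)
          }
          sub <- c(sub, s)
        } else {
          if (config$p_negated_sentence > 0 &&
              stats::runif(1) < config$p_negated_sentence) {
            sub <- c(sub, render_negated_sentence(v, l))
          }
          if (config$p_history_sentence > 0 &&
              stats::runif(1) < config$p_history_sentence) {
            sub <- c(sub, render_history_sentence(v, l))
          }
        }
      }
    }
    if (config$p_ambiguous_abbrev > 0 &&
        stats::runif(1) < config$p_ambiguous_abbrev) {
      sub <- c(sub, sample(c(
        "peak velocity 450 ms.",
        "valve function preserved as before.",
        "leaflets appear unremarkable as expected."
      ), 1))
    }
    if (length(sub) == 0) {
      sub <- paste0("the ", v, " valve is structurally normal.")
    }
    lines <- c(lines, sub)
  }
  lines <- c(lines, "IMPRESSION:")
  imp <- character()
  for (v in valves()) {
    if (pros[[v]]) {
      if (stats::runif(1) < 0.7) imp <- c(imp, render_prosthetic_impression(v))
      next
    }
    for (l in lesions()) {
      g <- truth$grade[truth$valve == v & truth$lesion == l]
      if (!is.na(g) && g %in% names(grade_phrase) && stats::runif(1) < 0.7) {
        imp <- c(imp, paste0(grade_phrase[[g]], " ", full_lesion_phrase(v, l), "."))
      }
    }
  }
  if (length(imp) == 0) imp <- "no acute valvular abnormality summarized."
  lines <- c(lines, imp, "SIGNED BY: dr. echo.")

  gold <- tidyr::expand_grid(valve = valves(), lesion = lesions()) |>
    left_join(truth, by = c("valve", "lesion")) |>
    mutate(
      status = dplyr::case_when(
        pros[.data$valve] ~ "prosthetic",
        is.na(.data$grade) ~ "no_evidence",
        TRUE ~ .data$grade
      ),
      report_id = report_id,
      n_supporting_mentions = NA_integer_
    ) |>
    select("report_id", "valve", "lesion", "status", "n_supporting_mentions")

  report <- tibble(
    report_id = report_id, patient_id = paste0("pt-", report_id),
    text = paste(lines, collapse = "\n"),
    exam_date = NA_character_, age_at_exam = age, sex = sex,
    race_ethnicity = race
  )
  list(report = report, gold = gold)
}

render_positive_sentence <- function(valve, lesion, grade) {
  full <- full_lesion_phrase(valve, lesion)
  bare <- lesion_noun[[lesion]]
  if (grade == "sclerosis") {
    return(sample(c(
      "the aortic valve is sclerotic.",
      "aortic valve sclerosis is present."
    ), 1))
  }
  if (grade == "unknown_severity") {
    return(sample(c(
      paste0(full, " is present."),
      paste0("there is ", bare, "."),
      paste0(bare, " noted.")
    ), 1))
  }
  sev <- grade_phrase[[grade]]
  abbr <- abbrev_for[[paste(valve, lesion, sep = ".")]]
  sample(c(
    paste0(sev, " ", full, "."),
    paste0("there is ", sev, " ", bare, "."),
    paste0("the ", full, " is ", sev, "."),
    paste0(bare, " is ", sev, "."),
    paste0(sev, " ", abbr, ".")
  ), 1)
}

render_prosthetic_sentence <- function(valve) {
  post <- switch(valve,
    aortic = c("status post tavr.", "status post avr."),
    mitral = "status post mvr.",
    tricuspid = "status post tvr.",
    pulmonic = "status post pulmonic valve replacement."
  )
  sample(c(
    paste0("the ", valve, " valve is prosthetic."),
    paste0(valve, " valve prosthesis is well seated."),
    paste0("bioprosthetic ", valve, " valve in stable position."),
    post
  ), 1)
}

render_prosthetic_impression <- function(valve) {
  switch(valve,
    aortic = "status post aortic valve replacement.",
    mitral = "status post mitral valve replacement.",
    tricuspid = "status post tricuspid valve replacement.",
    pulmonic = "status post pulmonic valve replacement."
  )
}

render_negated_sentence <- function(valve, lesion) {
  full <- full_lesion_phrase(valve, lesion)
  bare <- lesion_noun[[lesion]]
  sample(c(
    paste0("no ", full, "."),
    paste0("no ", bare, "."),
    paste0("without evidence of ", bare, "."),
    paste0("no significant ", bare, ".")
  ), 1)
}

render_history_sentence <- function(valve, lesion) {
  full <- full_lesion_phrase(valve, lesion)
  sev <- if (lesion == "regurgitation") "trace" else "mild"
  sample(c(
    paste0("a prior study showed ", sev, " ", full, "."),
    paste0("previously noted ", sev, " ", full, "."),
    paste0("history of ", full, ".")
  ), 1)
}

inject_misspelling <- function(sentence, rev_map) {
  words <- strsplit(gsub("\\.$", "", sentence), " ", fixed = TRUE)[[1]]
  hit <- which(words %in% names(rev_map))
  if (length(hit) == 0) return(sentence)
  j <- if (length(hit) == 1) hit else sample(hit, 1)
  repl <- rev_map[[words[j]]]
  words[j] <- if (length(repl) == 1) repl else sample(repl, 1)
  paste0(paste(words, collapse = " "), ".")
}

#' Write a synthetic corpus to disk
#'
#' @param corpus an `echo_corpus` from [generate_corpus()].
#' @param dir output directory (created if needed); writes `reports.jsonl`,
#'   `gold.csv` and `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "echo_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reports(corpus$reports, file.path(dir, "reports.jsonl"))
  write_findings(corpus$gold, file.path(dir, "gold.csv"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.echo_corpus <- function(x, ...) {
  cat("<echo_corpus> ", nrow(x$reports), " reports, ",
      nrow(x$gold), " gold findings\n", sep = "")
  invisible(x)
}
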