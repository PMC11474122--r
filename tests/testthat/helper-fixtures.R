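# Shared fixtures and independent oracles. Loaded once per test run.

lex <- default_lexicon()

# run the sentence-level rule pipeline on raw text
sent <- function(text, valve_context = NA_character_, options = extraction_options()) {
  analyze_sentence(tokenize(tolower(text))$token, lex, valve_context, options)
}

surviving <- function(m) m[!m$negated & !m$historical, , drop = FALSE]

# --- brute-force longest-match oracle ---------------------------------------
# Enumerate every token span, keep those whose token sequence equals a phrase,
# order by start (then longer first), and keep spans greedily left to right
# without overlap. Independent of the scanning matcher.
oracle_longest_match <- function(tokens, phrases) {
  phrase_tokens <- lapply(phrases, function(p) tokenize(p)$token)
  n <- length(tokens)
  hits <- list()
  for (s in seq_len(n)) {
    for (e in seq(s, n)) {
      span <- tokens[s:e]
      for (k in seq_along(phrases)) {
        if (length(phrase_tokens[[k]]) == length(span) &&
            all(phrase_tokens[[k]] == span)) {
          hits[[length(hits) + 1]] <- list(start = s, end = e, phrase = phrases[k])
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), phrase = character()))
  }
  df <- dplyr::bind_rows(lapply(hits, tibble::as_tibble))
  df <- df[order(df$start, -(df$end - df$start)), ]
  taken <- df[0, ]
  occupied <- logical(length(tokens))
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    if (!any(occupied[idx])) {
      taken <- rbind(taken, df[i, ])
      occupied[idx] <- TRUE
    }
  }
  tibble::as_tibble(taken[order(taken$start), ])
}

# --- toy-grammar extraction oracle ------------------------------------------
# Sentences are built as <prefix> <severity> <lesion term> from known parts,
# so the expected outcome follows directly from the written rules, applied
# here by hand — never by calling the extraction code.
toy_grammar <- function() {
  prefixes <- tibble::tribble(
    ~prefix, ~kind,
    "", "none",
    "no", "negation",
    "without evidence of", "negation",
    "a prior study showed", "history",
    "known", "history"
  )
  severities <- tibble::tribble(
    ~sev, ~grade,
    "", NA_character_,
    "mild", "mild",
    "moderate to severe", "moderate_to_severe",
    "trace", "trace",
    "very severe", "very_severe"
  )
  terms <- tibble::tribble(
    ~term, ~tvalve, ~tlesion, ~tkind,
    "aortic stenosis", "aortic", "stenosis", "specific",
    "mitral regurgitation", "mitral", "regurgitation", "specific",
    "pulmonic stenosis", "pulmonic", "stenosis", "specific",
    "regurgitation", NA, "regurgitation", "generic",
    "stenosis", NA, "stenosis", "generic",
    "as", "aortic", "stenosis", "ambiguous",
    "ms", "mitral", "stenosis", "ambiguous",
    "tr", "tricuspid", "regurgitation", "ambiguous"
  )
  contexts <- c(NA, "aortic", "mitral", "tricuspid")
  grid <- tidyr::expand_grid(prefixes, severities, terms, context = contexts)
  grid$text <- trimws(paste(grid$prefix, grid$sev, grid$term))
  grid
}

# expected surviving finding for one toy-grammar sentence: a list with
# valve/lesion/severity, or NULL when no surviving mention should exist
oracle_toy_sentence <- function(prefix_kind, sev_text, sev_grade,
                                term, tvalve, tlesion, tkind, context) {
  # 1. does the term yield a mention at all?
  if (tkind == "generic") {
    if (is.na(context)) return(NULL)
    valve <- context
  } else if (tkind == "ambiguous") {
    valve <- tvalve
    accepted <- switch(term,
      as = nzchar(sev_text) || identical(context, "aortic"),
      ms = nzchar(sev_text) || identical(context, "mitral"),
      tr = identical(context, "tricuspid") || nzchar(sev_text)
    )
    if (!accepted) return(NULL)
  } else {
    valve <- tvalve
  }
  # 2. negation: cue directly precedes (gap = severity tokens <= 5)
  if (prefix_kind == "negation") return(NULL)
  # 3. history: cue anywhere before the mention
  if (prefix_kind == "history") return(NULL)
  # 4. severity: the preceding phrase if admissible, else unknown
  severity <- if (!nzchar(sev_text)) {
    "unknown_severity"
  } else if (sev_grade %in% admissible_grades(valve, tlesion)) {
    sev_grade
  } else {
    "unknown_severity"
  }
  list(valve = valve, lesion = tlesion, severity = severity)
}

# --- random generators -------------------------------------------------------
random_words <- function(n) {
  paste(sample(c("the", "valve", "aortic", "mild", "flow", "normal", "2.5",
                 "peak", "velocity", "leaflets", "stenosis", "no", "trace",
                 "regurgitation", "is", "seen", "with", "and"),
               n, replace = TRUE), collapse = " ")
}

random_report_text <- function() {
  headers <- c("FINDINGS:", "IMPRESSION:", "MEASUREMENTS:", "Aortic Valve:",
               "Mitral Valve:", "SUMMARY:", "")
  n_lines <- sample(0:8, 1)
  lines <- vapply(seq_len(n_lines), function(i) {
    if (stats::runif(1) < 0.4) sample(headers, 1) else random_words(sample(1:8, 1))
  }, character(1))
  paste(lines, collapse = "\n")
}

# resolved-status rank with no_evidence below every grade
status_rank <- function(status) {
  r <- rep(-1L, length(status))
  k <- status != "no_evidence"
  r[k] <- severity_rank(status[k])
  r
}

# random mention set for aggregation properties
random_mentions <- function(report_id = "r", n = NULL) {
  if (is.null(n)) n <- sample(0:6, 1)
  if (n == 0) {
    return(extract_mentions(prepare_sentences(
      tibble::tibble(report_id = report_id, text = "")
    )))
  }
  valve <- sample(valves(), n, replace = TRUE)
  lesion <- sample(lesions(), n, replace = TRUE)
  prosthetic <- stats::runif(n) < 0.1
  severity <- vapply(seq_len(n), function(i) {
    if (prosthetic[i]) return("prosthetic")
    sample(admissible_grades(valve[i], lesion[i]), 1)
  }, character(1))
  tibble::tibble(
    report_id = report_id, sent_id = seq_len(n), section_label = "findings_results",
    valve_context = NA_character_, valve = valve,
    lesion = ifelse(prosthetic, NA_character_, lesion),
    matched_phrase = "x", char_start = 0L, char_end = 1L,
    negated = FALSE, historical = FALSE, prosthetic = prosthetic,
    severity = severity
  )
}
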