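#' Load and validate an extraction lexicon
#'
#' The lexicon is the complete rule vocabulary the extractor matches against:
#' lesion terms per (valve, lesion) pair plus generic lesion nouns, severity
#' phrases per grade, negation and history cues, prosthetic and sclerosis
#' terms, a curated misspelling map, abbreviation disambiguation hooks, and
#' the section/subsection header patterns used for report segmentation. It
#' lives in a human-editable YAML file so sites can extend the vocabulary to
#' match their own reporting templates without code changes; the bundled
#' default covers standard valve names, abbreviations (as, ai/ar, ms, mr, ts,
#' tr, ps, pr), "insufficiency" as a regurgitation synonym, and hyphen/range
#' severity variants.
#'
#' Validation is strict: every phrase must be lowercase, no phrase may appear
#' under two severity grades, and misspelling-map keys must be disjoint from
#' the canonical vocabulary (otherwise correction would rewrite valid terms).
#' Each violation raises a distinct classed error.
#'
#' @param path path to a lexicon YAML file. `NULL` (default) loads the bundled
#'   default lexicon.
#' @return an object of class `echo_lexicon`: a list with tibbles
#'   `lesion_phrases` (`phrase`, `valve` — `NA` for generic nouns resolved
#'   from context —, `lesion`), `severity_phrases` (`phrase`, `grade`),
#'   `prosthetic_phrases` (`phrase`, `valve`), character vectors of cues, the
#'   named `misspelling_map`, and header pattern maps.
#' @examples
#' lex <- load_lexicon()
#' head(lex$lesion_phrases)
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_lexicon.yml", package = "echovhd")
  }
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path), class = "echovhd_lexicon_parse_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(paste0("lexicon file failed to parse: ", conditionMessage(e)),
        class = "echovhd_lexicon_parse_error"
      )
    }
  )
  build_lexicon(raw)
}

# construct + validate an echo_lexicon from the parsed YAML list
build_lexicon <- function(raw) {
  need <- c("lesion_terms", "severity_terms", "negation_cues", "history_cues",
            "prosthetic_terms", "section_headers", "subsection_headers")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("lexicon is missing required keys: ", paste(missing, collapse = ", ")),
      class = "echovhd_lexicon_parse_error"
    )
  }

  lesion_phrases <- purrr::imap(raw$lesion_terms, function(by_lesion, valve) {
    purrr::imap(by_lesion, function(phrases, lesion) {
      tibble(
        phrase = as.character(phrases),
        valve = if (valve == "generic") NA_character_ else valve,
        lesion = lesion
      )
    }) |> bind_rows()
  }) |> bind_rows()
  bad_valve <- setdiff(unique(stats::na.omit(lesion_phrases$valve)), valves())
  bad_lesion <- setdiff(unique(lesion_phrases$lesion), lesions())
  if (length(bad_valve) || length(bad_lesion)) {
    abort("lesion_terms keyed by unknown valve or lesion",
      class = "echovhd_lexicon_parse_error"
    )
  }

  severity_phrases <- purrr::imap(raw$severity_terms, function(phrases, grade) {
    tibble(phrase = as.character(phrases), grade = grade)
  }) |> bind_rows()
  bad_grade <- setdiff(unique(severity_phrases$grade), severity_levels())
  if (length(bad_grade)) {
    abort(paste0("unknown severity grade(s) in severity_terms: ",
                 paste(bad_grade, collapse = ", ")),
      class = "echovhd_lexicon_parse_error"
    )
  }
  dup <- severity_phrases |>
    distinct(.data$phrase, .data$grade) |>
    count(.data$phrase) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("phrase assigned to more than one severity grade: ",
                 paste(dup$phrase, collapse = ", ")),
      class = "echovhd_lexicon_duplicate_phrase"
    )
  }

  prosthetic_phrases <- purrr::imap(raw$prosthetic_terms, function(phrases, valve) {
    tibble(
      phrase = as.character(phrases),
      valve = if (valve == "generic") NA_character_ else valve
    )
  }) |> bind_rows()

  lex <- structure(list(
    lesion_phrases = lesion_phrases,
    severity_phrases = severity_phrases,
    prosthetic_phrases = prosthetic_phrases,
    negation_cues = as.character(raw$negation_cues),
    history_cues = as.character(raw$history_cues),
    sclerosis_terms = as.character(raw$sclerosis_terms %||% character()),
    ignored_phrases = as.character(raw$ignored_phrases %||% character()),
    misspelling_map = unlist(raw$misspelling_map %||% list()),
    numeric_grades = unlist(raw$numeric_grades %||% list()),
    valve_words = purrr::map(raw$valve_words %||% list(), as.character),
    ambiguous_abbrevs = unlist(raw$ambiguous_abbrevs %||% list()),
    as_conjunction_followers = as.character(raw$as_conjunction_followers %||% character()),
    section_headers = unlist(raw$section_headers),
    subsection_headers = unlist(raw$subsection_headers),
    nonbreaking_abbrevs = as.character(raw$nonbreaking_abbrevs %||% character())
  ), class = "echo_lexicon")

  validate_lexicon(lex)

  # precompiled phrase sets for the matcher (derived, not user-editable)
  lex$compiled <- list(
    lesion = compile_phrase_set(lex$lesion_phrases$phrase),
    severity = compile_phrase_set(lex$severity_phrases$phrase),
    prosthetic = compile_phrase_set(lex$prosthetic_phrases$phrase),
    negation = compile_phrase_set(lex$negation_cues),
    history = compile_phrase_set(lex$history_cues),
    sclerosis = compile_phrase_set(lex$sclerosis_terms),
    ignored = compile_phrase_set(lex$ignored_phrases)
  )
  # token -> valve lookup for backward valve resolution
  vw <- lex$valve_words
  lex$valve_word_map <- stats::setNames(
    rep(names(vw), lengths(vw)), unlist(vw)
  )
  lex
}

validate_lexicon <- function(lex) {
  all_phrases <- c(
    lex$lesion_phrases$phrase, lex$severity_phrases$phrase,
    lex$prosthetic_phrases$phrase, lex$negation_cues, lex$history_cues,
    lex$sclerosis_terms, lex$ignored_phrases
  )
  upper <- all_phrases[stringr::str_detect(all_phrases, "[A-Z]")]
  if (length(upper) > 0) {
    abort(paste0("lexicon phrases must be lowercase: ",
                 paste(unique(upper), collapse = ", ")),
      class = "echovhd_lexicon_uppercase_phrase"
    )
  }
  if (length(lex$misspelling_map) > 0) {
    canonical <- unique(unlist(lapply(all_phrases, tokenize_phrase)))
    clash <- intersect(names(lex$misspelling_map), canonical)
    if (length(clash) > 0) {
      abort(paste0("misspelling_map keys collide with canonical vocabulary: ",
                   paste(clash, collapse = ", ")),
        class = "echovhd_lexicon_misspelling_conflict"
      )
    }
  }
  full <- lex$lesion_phrases |>
    filter(!is.na(.data$valve)) |>
    distinct(.data$valve, .data$lesion)
  if (nrow(full) < length(valves()) * length(lesions())) {
    abort("lesion_terms must cover all four valves for both lesions",
      class = "echovhd_lexicon_parse_error"
    )
  }
  invisible(lex)
}

# cache the bundled lexicon per session
.lexicon_cache <- new.env(parent = emptyenv())

#' @rdname load_lexicon
#' @export
default_lexicon <- function() {
  if (is.null(.lexicon_cache$default)) {
    .lexicon_cache$default <- load_lexicon()
  }
  .lexicon_cache$default
}

#' @export
print.echo_lexicon <- function(x, ...) {
  cat("<echo_lexicon>\n")
  cat("  lesion phrases:    ", nrow(x$lesion_phrases), "\n")
  cat("  severity phrases:  ", nrow(x$severity_phrases), "\n")
  cat("  negation cues:     ", length(x$negation_cues), "\n")
  cat("  history cues:      ", length(x$history_cues), "\n")
  cat("  prosthetic phrases:", nrow(x$prosthetic_phrases), "\n")
  cat("  misspelling map:   ", length(x$misspelling_map), "entries\n")
  invisible(x)
}

# --- longest-match phrase matching -----------------------------------------

# Precompile a phrase vector: tokenized phrases grouped by first token,
# longest first, so the scan only inspects phrases that can start here.
compile_phrase_set <- function(phrases) {
  phrases <- unique(as.character(phrases))
  toks <- lapply(phrases, tokenize_phrase)
  keep <- lengths(toks) > 0
  phrases <- phrases[keep]
  toks <- toks[keep]
  if (length(phrases) == 0) {
    return(structure(list(phrase = character(), tokens = list(),
                          by_first = list()), class = "echo_phrase_set"))
  }
  ord <- order(-lengths(toks), seq_along(toks))
  phrases <- phrases[ord]
  toks <- toks[ord]
  first <- vapply(toks, `[`, character(1), 1)
  structure(
    list(phrase = phrases, tokens = toks,
         by_first = split(seq_along(phrases), first)),
    class = "echo_phrase_set"
  )
}

#' Longest-match phrase search over a token sequence
#'
#' Scans left to right; at each position the longest phrase in `phrases` whose
#' token sequence starts there wins, and matching resumes after it, so matches
#' never overlap and "moderate to severe" shadows its sub-phrases "moderate"
#' and "severe". Matches are token-boundary anchored: a phrase never matches
#' inside a longer word.
#'
#' @param tokens a character vector of lowercase tokens (or a tibble from
#'   [tokenize()], whose `token` column is used).
#' @param phrases a character vector of lowercase phrases, or a precompiled
#'   phrase set.
#' @return a tibble with columns `start`, `end` (1-based inclusive token
#'   positions) and `phrase`, in left-to-right order. Zero rows when nothing
#'   matches.
#' @examples
#' longest_match_terms(
#'   c("moderate", "to", "severe", "mitral", "regurgitation"),
#'   c("moderate", "severe", "moderate to severe")
#' )
#' @export
longest_match_terms <- function(tokens, phrases) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  set <- if (inherits(phrases, "echo_phrase_set")) phrases else compile_phrase_set(phrases)
  n <- length(tokens)
  out_start <- integer()
  out_end <- integer()
  out_phrase <- character()
  i <- 1L
  while (i <= n) {
    cand <- set$by_first[[tokens[i]]]
    hit <- 0L
    if (!is.null(cand)) {
      for (j in cand) {
        tk <- set$tokens[[j]]
        L <- length(tk)
        if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == tk)) {
          hit <- j
          break # candidates are sorted longest-first
        }
      }
    }
    if (hit > 0L) {
      L <- length(set$tokens[[hit]])
      out_start <- c(out_start, i)
      out_end <- c(out_end, i + L - 1L)
      out_phrase <- c(out_phrase, set$phrase[hit])
      i <- i + L
    } else {
      i <- i + 1L
    }
  }
  tibble(start = out_start, end = out_end, phrase = out_phrase)
}

# does any phrase in `set` end exactly at token position `end_pos`?
phrase_ends_at <- function(tokens, end_pos, set) {
  if (end_pos < 1L) return(FALSE)
  for (j in seq_along(set$phrase)) {
    tk <- set$tokens[[j]]
    L <- length(tk)
    s <- end_pos - L + 1L
    if (s >= 1L && all(tokens[s:end_pos] == tk)) return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
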