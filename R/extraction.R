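#' Extraction options
#'
#' Tunable parameters of the per-sentence rule engine.
#'
#' @param negation_window maximum number of tokens allowed between a negation
#'   cue and the lesion phrase it negates (default 5).
#' @param severity_post_window how far (in tokens) a severity phrase may trail
#'   the lesion phrase it grades ("aortic stenosis, severe"; default 3).
#' @param distribute_severity_over_lists when `TRUE`, a severity phrase that
#'   precedes a slash-coordinated list of lesion terms ("mild as/ai/mr")
#'   grades every member. The default (`FALSE`) grades only the first term,
#'   the behaviour the validation tables were produced under.
#' @param numeric_grades when `TRUE`, numeric regurgitation grades ("1+".."4+")
#'   map to severity levels via the lexicon's `numeric_grades` table; off by
#'   default.
#' @return a list of class `echovhd_options`.
#' @export
extraction_options <- function(negation_window = 5,
                               severity_post_window = 3,
                               distribute_severity_over_lists = FALSE,
                               numeric_grades = FALSE) {
  stopifnot(negation_window >= 0, severity_post_window >= 0)
  structure(
    list(
      negation_window = as.integer(negation_window),
      severity_post_window = as.integer(severity_post_window),
      distribute_severity_over_lists = isTRUE(distribute_severity_over_lists),
      numeric_grades = isTRUE(numeric_grades)
    ),
    class = "echovhd_options"
  )
}

# typed prototype of the report-level mention table
empty_mentions <- function() {
  tibble::new_tibble(list(
    report_id = character(), sent_id = integer(), section_label = character(),
    valve_context = character(), valve = character(), lesion = character(),
    matched_phrase = character(), char_start = integer(), char_end = integer(),
    negated = logical(), historical = logical(), prosthetic = logical(),
    severity = character()
  ), nrow = 0L)
}

empty_sentence_mentions <- function() {
  tibble::new_tibble(list(
    valve = character(), lesion = character(), matched_phrase = character(),
    start = integer(), end = integer(), prosthetic = logical(),
    negated = logical(), historical = logical(), severity = character()
  ), nrow = 0L)
}

#' Find lesion and prosthetic mentions in one sentence
#'
#' Step one of the rule engine: longest-match search for lesion terms. A
#' valve-specific phrase ("aortic stenosis", "mr") resolves its valve
#' directly; a generic lesion noun ("stenosis", bare "regurgitation") resolves
#' from a preceding valve-word coordination chain ("aortic or mitral
#' stenosis" yields one mention per valve) or, failing that, from the
#' enclosing subsection's valve context. A bare lesion noun with no
#' resolvable valve yields nothing. Ambiguous abbreviations ("as", "ms",
#' "tr") pass through [disambiguate_abbreviation()] before acceptance, and the
#' congenital shorthand "systemic av"/"subpulmonic av" is ignored entirely.
#' Prosthetic cues and standalone aortic sclerosis terms also emit mentions
#' here (a prosthetic mention carries `lesion = NA` — it is a valve-level
#' status).
#'
#' @param tokens a character vector of normalized tokens (or a [tokenize()]
#'   tibble).
#' @param lexicon an [load_lexicon()] object.
#' @param valve_context valve of the enclosing subsection, or `NA`.
#' @return a mention tibble (columns `valve`, `lesion`, `matched_phrase`,
#'   `start`, `end` in 1-based token positions, `prosthetic`, `negated`,
#'   `historical`, `severity`) with attribute `trace_positions`: token
#'   positions where "tr" was read as severity "trace".
#' @export
find_lesion_mentions <- function(tokens, lexicon = default_lexicon(),
                                 valve_context = NA_character_) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  out <- empty_sentence_mentions()
  trace_pos <- integer()
  if (length(tokens) == 0) {
    attr(out, "trace_positions") <- trace_pos
    return(out)
  }

  blocked <- logical(length(tokens))
  ig <- longest_match_terms(tokens, lexicon$compiled$ignored)
  for (k in seq_len(nrow(ig))) blocked[ig$start[k]:ig$end[k]] <- TRUE

  acc <- list(valve = character(), lesion = character(), phrase = character(),
              start = integer(), end = integer(), prosthetic = logical(),
              severity = character())
  add <- function(valve, lesion, phrase, start, end, prosthetic = FALSE,
                  severity = NA_character_) {
    acc$valve <<- c(acc$valve, valve)
    acc$lesion <<- c(acc$lesion, lesion)
    acc$phrase <<- c(acc$phrase, phrase)
    acc$start <<- c(acc$start, as.integer(start))
    acc$end <<- c(acc$end, as.integer(end))
    acc$prosthetic <<- c(acc$prosthetic, prosthetic)
    acc$severity <<- c(acc$severity, severity)
  }

  lm <- longest_match_terms(tokens, lexicon$compiled$lesion)
  for (k in seq_len(nrow(lm))) {
    if (any(blocked[lm$start[k]:lm$end[k]])) next
    info <- lexicon$lesion_phrases[lexicon$lesion_phrases$phrase == lm$phrase[k], ][1, ]
    if (lm$phrase[k] %in% names(lexicon$ambiguous_abbrevs)) {
      d <- disambiguate_abbreviation(lm$start[k], tokens, lexicon, valve_context)
      if (d$action == "reject") next
      if (d$action == "trace") {
        trace_pos <- c(trace_pos, lm$start[k])
        next
      }
      add(d$valve, d$lesion, lm$phrase[k], lm$start[k], lm$end[k])
    } else if (is.na(info$valve)) {
      vs <- backward_valve_scan(tokens, lm$start[k], lexicon)
      if (length(vs) == 0 && !is.na(valve_context)) vs <- valve_context
      for (v in vs) add(v, info$lesion, lm$phrase[k], lm$start[k], lm$end[k])
    } else {
      add(info$valve, info$lesion, lm$phrase[k], lm$start[k], lm$end[k])
      # "no aortic or mitral stenosis": the trailing pair matches as a phrase,
      # but valves coordinated before it share the lesion noun
      extra <- setdiff(backward_valve_scan(tokens, lm$start[k], lexicon),
                       info$valve)
      for (v in extra) add(v, info$lesion, lm$phrase[k], lm$start[k], lm$end[k])
    }
  }

  # standalone aortic sclerosis (a finding on the stenosis axis) — only when
  # the sentence has no explicit aortic stenosis mention for the term to grade
  sc <- longest_match_terms(tokens, lexicon$compiled$sclerosis)
  has_as <- any(acc$valve == "aortic" & !is.na(acc$lesion) & acc$lesion == "stenosis")
  if (!has_as) {
    for (k in seq_len(nrow(sc))) {
      if (any(blocked[sc$start[k]:sc$end[k]])) next
      vs <- backward_valve_scan(tokens, sc$start[k], lexicon)
      if (length(vs) == 0 && !is.na(valve_context)) vs <- valve_context
      if ("aortic" %in% vs) {
        add("aortic", "stenosis", sc$phrase[k], sc$start[k], sc$end[k],
            severity = "sclerosis")
        break
      }
    }
  }

  pm <- longest_match_terms(tokens, lexicon$compiled$prosthetic)
  for (k in seq_len(nrow(pm))) {
    if (any(blocked[pm$start[k]:pm$end[k]])) next
    info <- lexicon$prosthetic_phrases[lexicon$prosthetic_phrases$phrase == pm$phrase[k], ][1, ]
    v <- info$valve
    if (is.na(v)) {
      vs <- backward_valve_scan(tokens, pm$start[k], lexicon)
      if (length(vs) == 1) v <- vs
    }
    if (is.na(v)) {
      ahead <- tokens[seq(pm$end[k] + 1L, length.out = min(2L, length(tokens) - pm$end[k]))]
      hit <- ahead[ahead %in% names(lexicon$valve_word_map)]
      if (length(hit) > 0) v <- unname(lexicon$valve_word_map[hit[1]])
    }
    if (is.na(v) && !is.na(valve_context)) v <- valve_context
    if (is.na(v)) {
      inplay <- unique(lexicon$valve_word_map[tokens[tokens %in% names(lexicon$valve_word_map)]])
      if (length(inplay) == 1) v <- unname(inplay)
    }
    if (is.na(v)) next
    add(v, NA_character_, pm$phrase[k], pm$start[k], pm$end[k],
        prosthetic = TRUE, severity = "prosthetic")
  }

  out <- tibble::new_tibble(list(
    valve = acc$valve, lesion = acc$lesion, matched_phrase = acc$phrase,
    start = acc$start, end = acc$end, prosthetic = acc$prosthetic,
    negated = logical(length(acc$valve)), historical = logical(length(acc$valve)),
    severity = acc$severity
  ), nrow = length(acc$valve))
  attr(out, "trace_positions") <- trace_pos
  out
}

# collect valve words in the coordination chain immediately before `start`,
# looking through connectors and copular filler ("aortic or mitral", "aortic
# valve is"), up to 8 tokens back
backward_valve_scan <- function(tokens, start, lexicon) {
  connectors <- c("or", "and", ",", "/", "valve", "valves", "is", "are",
                  "appears", "appear", "leaflet", "leaflets", "the")
  found <- character()
  i <- start - 1L
  while (i >= 1L && start - i <= 8L) {
    t <- tokens[i]
    if (t %in% names(lexicon$valve_word_map)) {
      found <- c(unname(lexicon$valve_word_map[t]), found)
    } else if (!(t %in% connectors)) {
      break
    }
    i <- i - 1L
  }
  unique(found)
}

#' Disambiguate "as", "ms" and "tr"
#'
#' Deterministic rule table for the three abbreviations whose surface form has
#' a competing non-lesion reading: "as" (aortic stenosis vs the conjunction),
#' "ms" (mitral stenosis vs millisecond) and "tr" (tricuspid regurgitation vs
#' severity trace).
#'
#' * "as": rejected when the next token marks conjunction use (determiner,
#'   verb, "well", "before", ...); otherwise accepted as (aortic, stenosis)
#'   when immediately preceded by a severity phrase or a
#'   sclerosis/prosthetic cue, or when the valve context is aortic.
#' * "ms": rejected when the previous token is numeric (a millisecond
#'   measurement); otherwise accepted as (mitral, stenosis) when preceded by a
#'   severity phrase or in mitral context.
#' * "tr": read as (tricuspid, regurgitation) in tricuspid context or adjacent
#'   to tricuspid terms; read as severity "trace" when it immediately precedes
#'   another lesion phrase ("tr mr"); accepted as tricuspid regurgitation when
#'   a severity phrase immediately precedes it; otherwise rejected.
#'
#' @param index 1-based token position of the abbreviation.
#' @param tokens character vector of sentence tokens.
#' @param lexicon an [load_lexicon()] object.
#' @param valve_context valve of the enclosing subsection, or `NA`.
#' @return a list with `action` (`"accept"`, `"reject"` or `"trace"`) and, for
#'   accepted readings, `valve` and `lesion`.
#' @export
disambiguate_abbreviation <- function(index, tokens, lexicon = default_lexicon(),
                                      valve_context = NA_character_) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  tok <- tokens[index]
  rule <- lexicon$ambiguous_abbrevs[[tok]]
  if (is.null(rule)) abort(paste0("token is not an ambiguous abbreviation: ", tok))
  nxt <- if (index < length(tokens)) tokens[index + 1L] else ""
  prev <- if (index > 1L) tokens[index - 1L] else ""
  sev_before <- phrase_ends_at(tokens, index - 1L, lexicon$compiled$severity)
  reject <- list(action = "reject")

  if (rule == "as_rule") {
    if (nxt %in% lexicon$as_conjunction_followers) return(reject)
    cue_before <- phrase_ends_at(tokens, index - 1L, lexicon$compiled$sclerosis) ||
      phrase_ends_at(tokens, index - 1L, lexicon$compiled$prosthetic)
    if (sev_before || cue_before || identical(valve_context, "aortic")) {
      return(list(action = "accept", valve = "aortic", lesion = "stenosis"))
    }
    return(reject)
  }
  if (rule == "ms_rule") {
    if (is_numeric_token(prev)) return(reject) # millisecond measurement
    if (sev_before || identical(valve_context, "mitral")) {
      return(list(action = "accept", valve = "mitral", lesion = "stenosis"))
    }
    return(reject)
  }
  if (rule == "tr_rule") {
    near <- tokens[max(1L, index - 3L):min(length(tokens), index + 3L)]
    if (identical(valve_context, "tricuspid") || "tricuspid" %in% near) {
      return(list(action = "accept", valve = "tricuspid", lesion = "regurgitation"))
    }
    if (index < length(tokens) &&
        phrase_starts_at(tokens, index + 1L, lexicon$compiled$lesion)) {
      return(list(action = "trace"))
    }
    if (sev_before) {
      return(list(action = "accept", valve = "tricuspid", lesion = "regurgitation"))
    }
    return(reject)
  }
  reject
}

# does any phrase in `set` start exactly at token position `pos`?
phrase_starts_at <- function(tokens, pos, set) {
  cand <- set$by_first[[tokens[pos]]]
  if (is.null(cand)) return(FALSE)
  n <- length(tokens)
  for (j in cand) {
    tk <- set$tokens[[j]]
    L <- length(tk)
    if (pos + L - 1L <= n && all(tokens[pos:(pos + L - 1L)] == tk)) return(TRUE)
  }
  FALSE
}

#' Mark negated mentions
#'
#' A mention is negated when a negation cue precedes it in the same sentence
#' with at most `window` intervening tokens and no scope breaker ("but",
#' "however", ",") in between. Coordinated lesions share one cue: in "no
#' aortic or mitral stenosis" both resolved mentions sit inside the cue's
#' scope.
#'
#' @param mentions a mention tibble from [find_lesion_mentions()].
#' @param tokens the sentence's token vector.
#' @param lexicon an [load_lexicon()] object.
#' @param window maximum intervening tokens (default 5).
#' @return `mentions` with `negated` filled in.
#' @export
apply_negation <- function(mentions, tokens, lexicon = default_lexicon(), window = 5) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  if (nrow(mentions) == 0) return(mentions)
  cues <- longest_match_terms(tokens, lexicon$compiled$negation)
  breakers <- c("but", "however", ",")
  mentions$negated <- vapply(seq_len(nrow(mentions)), function(i) {
    m_start <- mentions$start[i]
    for (k in seq_len(nrow(cues))) {
      ce <- cues$end[k]
      if (ce >= m_start) next
      gap <- m_start - ce - 1L
      if (gap > window) next
      between <- if (gap > 0) tokens[(ce + 1L):(m_start - 1L)] else character()
      if (!any(between %in% breakers)) return(TRUE)
    }
    FALSE
  }, logical(1))
  mentions
}

#' Mark historical mentions
#'
#' A mention is historical when a history cue ("prior study", "previously",
#' "history of", "known") occurs anywhere before it in the same sentence.
#' Historical mentions describe an earlier exam and are dropped downstream.
#' Prosthetic mentions are exempt: "known severe as, now status post tavr"
#' drops the graded stenosis mention but keeps the prosthetic status —
#' prosthetic cues describe the valve as it stands.
#'
#' @inheritParams apply_negation
#' @return `mentions` with `historical` filled in.
#' @export
apply_history_filter <- function(mentions, tokens, lexicon = default_lexicon()) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  if (nrow(mentions) == 0) return(mentions)
  cues <- longest_match_terms(tokens, lexicon$compiled$history)
  if (nrow(cues) == 0) return(mentions)
  first_cue_end <- min(cues$end)
  mentions$historical <- !mentions$prosthetic & !mentions$negated &
    mentions$start > first_cue_end
  mentions
}

#' Attach severity grades to surviving mentions
#'
#' Severity phrases are found by longest match (so "moderate to severe" never
#' splits into "moderate" and "severe") and attached left to right: each
#' phrase grades its nearest unclaimed mention, preferring a mention it
#' precedes (pre-modifier order) and falling back to a mention it trails by at
#' most `severity_post_window` tokens ("aortic stenosis, severe"). A phrase
#' with no unclaimed mention still contributes to the nearest mention, so in
#' "moderate to borderline severe calcific mitral stenosis" both "moderate"
#' and "severe" attach and the higher-priority "severe" wins. A phrase before
#' a slash list ("mild as/ai/mr") grades only the first term unless
#' `distribute_severity_over_lists` is set. Grades inadmissible for the lesion
#' (trace on a stenosis; sclerosis off the aortic stenosis axis) are discarded
#' with a warning. A mention with no surviving candidate keeps its preset
#' grade (standalone sclerosis) or becomes `unknown_severity`.
#'
#' @inheritParams apply_negation
#' @param options an [extraction_options()] list.
#' @return `mentions` with `severity` filled in.
#' @export
assign_severity <- function(mentions, tokens, lexicon = default_lexicon(),
                            options = extraction_options()) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  if (nrow(mentions) == 0) return(mentions)
  trace_pos <- attr(mentions, "trace_positions") %||% integer()

  sev <- longest_match_terms(tokens, lexicon$compiled$severity)
  if (nrow(sev) > 0) {
    grades <- lexicon$severity_phrases$grade[
      match(sev$phrase, lexicon$severity_phrases$phrase)
    ]
    sev$grade <- grades
  } else {
    sev$grade <- character()
  }
  if (length(trace_pos) > 0) {
    sev <- bind_rows(sev, tibble(
      start = trace_pos, end = trace_pos, phrase = "tr", grade = "trace"
    ))
  }
  if (options$numeric_grades && length(lexicon$numeric_grades) > 0) {
    hits <- which(tokens %in% names(lexicon$numeric_grades))
    if (length(hits) > 0) {
      sev <- bind_rows(sev, tibble(
        start = hits, end = hits, phrase = tokens[hits],
        grade = unname(lexicon$numeric_grades[tokens[hits]])
      ))
    }
  }
  # a severity word inside a mention span is that mention's own surface form
  # (standalone sclerosis), not a modifier
  if (nrow(sev) > 0 && nrow(mentions) > 0) {
    inside <- vapply(seq_len(nrow(sev)), function(k) {
      any(sev$start[k] >= mentions$start & sev$end[k] <= mentions$end)
    }, logical(1))
    sev <- sev[!inside, , drop = FALSE]
  }
  sev <- sev[order(sev$start), , drop = FALSE]

  eligible <- which(!mentions$negated & !mentions$historical & !mentions$prosthetic)
  candidates <- vector("list", nrow(mentions))
  claimed <- logical(nrow(mentions))

  pick_forward <- function(idx_set, s_end) {
    ahead <- idx_set[mentions$start[idx_set] > s_end]
    if (length(ahead) == 0) return(NA_integer_)
    ahead[which.min(mentions$start[ahead])]
  }
  pick_backward <- function(idx_set, s_start) {
    behind <- idx_set[mentions$end[idx_set] < s_start &
                        (s_start - mentions$end[idx_set] - 1L) <= options$severity_post_window]
    if (length(behind) == 0) return(NA_integer_)
    behind[which.max(mentions$end[behind])]
  }

  for (k in seq_len(nrow(sev))) {
    un <- eligible[!claimed[eligible]]
    target <- pick_forward(un, sev$end[k])
    claim <- TRUE
    if (is.na(target)) target <- pick_backward(un, sev$start[k])
    if (is.na(target)) {
      # all mentions claimed: still contribute to the nearest one
      target <- pick_forward(eligible, sev$end[k])
      if (is.na(target)) target <- pick_backward(eligible, sev$start[k])
      claim <- FALSE
    }
    if (is.na(target)) next
    targets <- target
    if (options$distribute_severity_over_lists && claim) {
      targets <- slash_list_members(mentions, target, tokens, eligible)
    }
    for (m in targets) {
      candidates[[m]] <- c(candidates[[m]], sev$grade[k])
      if (claim) claimed[m] <- TRUE
    }
  }

  for (m in eligible) {
    cand <- candidates[[m]]
    if (length(cand) > 0) {
      ok <- cand %in% admissible_grades(mentions$valve[m], mentions$lesion[m])
      if (any(!ok)) {
        warn(paste0(
          "severity '", paste(unique(cand[!ok]), collapse = "', '"),
          "' is not admissible for ", mentions$valve[m], " ",
          mentions$lesion[m], "; ignored"
        ), class = "echovhd_inadmissible_severity")
      }
      cand <- cand[ok]
    }
    mentions$severity[m] <- if (length(cand) > 0) {
      cand[which.max(severity_rank(cand))]
    } else if (!is.na(mentions$severity[m])) {
      mentions$severity[m] # preset (standalone sclerosis)
    } else {
      "unknown_severity"
    }
  }
  mentions
}

# mentions forming a slash-coordinated run starting at `first` (as/ai/mr)
slash_list_members <- function(mentions, first, tokens, eligible) {
  members <- first
  cur <- first
  repeat {
    sep <- mentions$end[cur] + 1L
    if (sep >= length(tokens) || tokens[sep] != "/") break
    nxt <- eligible[mentions$start[eligible] == sep + 1L]
    if (length(nxt) == 0) break
    members <- c(members, nxt[1])
    cur <- nxt[1]
  }
  members
}

#' Run the full sentence-level rule pipeline
#'
#' Fixed order: find mentions (with abbreviation disambiguation), negation,
#' history, severity. Mentions dropped by a filter stay in the output with
#' their `negated`/`historical` flag set; they are excluded from aggregation.
#'
#' @param tokens character vector of normalized sentence tokens.
#' @inheritParams find_lesion_mentions
#' @param options an [extraction_options()] list.
#' @return a sentence-level mention tibble.
#' @export
analyze_sentence <- function(tokens, lexicon = default_lexicon(),
                             valve_context = NA_character_,
                             options = extraction_options()) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  m <- find_lesion_mentions(tokens, lexicon, valve_context)
  m <- apply_negation(m, tokens, lexicon, options$negation_window)
  m <- apply_history_filter(m, tokens, lexicon)
  m <- assign_severity(m, tokens, lexicon, options)
  m
}

#' Extract mentions from prepared sentences
#'
#' Applies [analyze_sentence()] to every row of a [prepare_sentences()] tibble
#' and maps token positions back to report character offsets.
#'
#' @param sentences a tibble from [prepare_sentences()].
#' @param lexicon an [load_lexicon()] object.
#' @param options an [extraction_options()] list.
#' @return a tibble with one row per mention: `report_id`, `sent_id`,
#'   `section_label`, `valve_context`, `valve`, `lesion`, `matched_phrase`,
#'   `char_start`, `char_end`, `negated`, `historical`, `prosthetic`,
#'   `severity`.
#' @export
extract_mentions <- function(sentences, lexicon = default_lexicon(),
                             options = extraction_options()) {
  n_sent <- nrow(sentences)
  per <- vector("list", n_sent)
  reps <- integer(n_sent)
  for (i in seq_len(n_sent)) {
    tk <- sentences$tokens[[i]]
    m <- analyze_sentence(tk$token, lexicon, sentences$valve_context[i], options)
    reps[i] <- nrow(m)
    if (nrow(m) > 0) {
      m$char_start <- tk$char_start[m$start]
      m$char_end <- tk$char_end[m$end]
      per[[i]] <- m
    }
  }
  keep <- reps > 0
  idx <- rep(which(keep), reps[keep])
  if (length(idx) == 0) return(empty_mentions())
  ms <- bind_rows(per[keep])
  tibble::new_tibble(list(
    report_id = sentences$report_id[idx],
    sent_id = sentences$sent_id[idx],
    section_label = sentences$section_label[idx],
    valve_context = sentences$valve_context[idx],
    valve = ms$valve,
    lesion = ms$lesion,
    matched_phrase = ms$matched_phrase,
    char_start = ms$char_start,
    char_end = ms$char_end,
    negated = ms$negated,
    historical = ms$historical,
    prosthetic = ms$prosthetic,
    severity = ms$severity
  ), nrow = length(idx))
}
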