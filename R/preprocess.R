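#' Normalize report text
#'
#' Lowercases the text, tokenizes it, and replaces every whole-word occurrence
#' of a misspelling-map key by its canonical form. Because replacement is
#' token-wise, every normalized token keeps its original character
#' coordinates, giving a lossless offset map back into the raw report.
#' Normalization is idempotent: misspelling-map keys are disjoint from the
#' canonical vocabulary, so a second pass changes nothing.
#'
#' @param text a single string.
#' @param lexicon an [load_lexicon()] object (supplies the misspelling map).
#' @return a list with `text` (the normalized string) and `tokens`, a tibble
#'   with columns `token` (corrected form), `raw` (original lowercase form),
#'   `char_start`/`char_end` (0-based half-open offsets into the original
#'   text) and `norm_start`/`norm_end` (offsets into the normalized string).
#' @examples
#' normalize_text("Severe Aortic Stenosis", default_lexicon())$text
#' @export
normalize_text <- function(text, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text)) text <- ""
  lower <- tolower(text)
  toks <- tokenize(lower)
  map <- lexicon$misspelling_map
  corrected <- toks$token
  if (length(map) > 0 && nrow(toks) > 0) {
    hit <- corrected %in% names(map)
    corrected[hit] <- unname(map[corrected[hit]])
  }
  # splice corrected tokens back between the verbatim inter-token gaps
  pieces <- character(0)
  norm_start <- integer(nrow(toks))
  norm_end <- integer(nrow(toks))
  pos <- 0L
  prev_end <- 0L
  for (i in seq_len(nrow(toks))) {
    gap <- substr(lower, prev_end + 1L, toks$char_start[i])
    pieces <- c(pieces, gap, corrected[i])
    pos <- pos + nchar(gap)
    norm_start[i] <- pos
    pos <- pos + nchar(corrected[i])
    norm_end[i] <- pos
    prev_end <- toks$char_end[i]
  }
  pieces <- c(pieces, substr(lower, prev_end + 1L, nchar(lower)))
  out_tokens <- toks
  out_tokens$raw <- toks$token
  out_tokens$token <- corrected
  out_tokens$norm_start <- norm_start
  out_tokens$norm_end <- norm_end
  list(
    text = paste(pieces, collapse = ""),
    tokens = out_tokens[, c("token", "raw", "char_start", "char_end",
                            "norm_start", "norm_end")]
  )
}

#' Split section text into sentences
#'
#' Boundaries fall at ".", ";" and newline, except periods inside decimal
#' numbers ("2.5") and after known non-breaking abbreviations ("dr."). The
#' returned spans partition the input: concatenating them in order
#' reconstructs the text exactly. Spans containing no word tokens (pure
#' whitespace/punctuation) are flagged so downstream steps can skip them
#' without losing characters.
#'
#' @param text a section's (normalized) text.
#' @param lexicon an [load_lexicon()] object (supplies non-breaking
#'   abbreviations).
#' @return a tibble with columns `char_start`, `char_end` (0-based half-open
#'   offsets into `text`), `text` (the span) and `has_tokens`.
#' @examples
#' split_sentences("peak velocity 2.5 m/s; mild ai", default_lexicon())
#' @export
split_sentences <- function(text, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble(char_start = integer(), char_end = integer(),
                  text = character(), has_tokens = logical())
  if (is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, NULL)[[1]]
  cand <- which(chars %in% c(".", ";", "\n"))
  keep <- vapply(cand, function(p) {
    if (chars[p] != ".") return(TRUE)
    prev <- if (p > 1) chars[p - 1] else ""
    nxt <- if (p < length(chars)) chars[p + 1] else ""
    if (grepl("[0-9]", prev) && grepl("[0-9]", nxt)) return(FALSE) # decimal
    # word right before the period
    w_end <- p - 1L
    w_start <- w_end
    while (w_start >= 1 && grepl("[a-z]", chars[w_start], ignore.case = TRUE)) {
      w_start <- w_start - 1L
    }
    word <- if (w_end > w_start) {
      tolower(paste(chars[(w_start + 1L):w_end], collapse = ""))
    } else {
      ""
    }
    !(word %in% lexicon$nonbreaking_abbrevs)
  }, logical(1))
  bounds <- cand[keep]
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, length(chars))
  ok <- starts <= ends
  starts <- starts[ok]
  ends <- ends[ok]
  spans <- stringr::str_sub(text, starts, ends)
  tibble(
    char_start = starts - 1L,
    char_end = ends,
    text = spans,
    has_tokens = stringr::str_detect(spans, "[a-z0-9]")
  )
}

#' Prepare tokenized sentences for extraction
#'
#' Runs the per-report front half of the pipeline: segmentation, normalization
#' of each included section, sentence splitting, and token assignment. Each
#' sentence carries the valve context of its enclosing subsection (if any) and
#' character offsets into the original report.
#'
#' @param reports a report tibble from [read_reports()].
#' @param lexicon an [load_lexicon()] object.
#' @return a tibble with one row per retained (token-bearing) sentence:
#'   `report_id`, `sent_id`, `section_label`, `valve_context`, `char_start`,
#'   `char_end`, `text`, and `tokens` (list column of token tibbles with
#'   report-level offsets).
#' @export
prepare_sentences <- function(reports, lexicon = default_lexicon()) {
  acc <- list()
  for (r in seq_len(nrow(reports))) {
    id <- reports$report_id[r]
    txt <- reports$text[r]
    secs <- segment_report(txt, lexicon)
    secs <- secs[secs$included, , drop = FALSE]
    if (nrow(secs) == 0) next
    lab <- character(); vc <- character(); cs <- integer(); ce <- integer()
    stx <- character(); tkl <- list()
    for (j in seq_len(nrow(secs))) {
      sec_start <- secs$char_start[j]
      sec_text <- substr(txt, sec_start + 1L, secs$char_end[j])
      norm <- normalize_text(sec_text, lexicon)
      sents <- split_sentences(norm$text, lexicon)
      sents <- sents[sents$has_tokens, , drop = FALSE]
      toks <- norm$tokens
      for (i in seq_len(nrow(sents))) {
        sel <- toks$norm_start >= sents$char_start[i] &
          toks$norm_end <= sents$char_end[i]
        tk <- toks[sel, , drop = FALSE]
        if (nrow(tk) == 0) next
        lab <- c(lab, secs$label[j])
        vc <- c(vc, secs$valve[j])
        cs <- c(cs, sec_start + min(tk$char_start))
        ce <- c(ce, sec_start + max(tk$char_end))
        stx <- c(stx, trimws(sents$text[i]))
        tkl[[length(tkl) + 1L]] <- tibble::new_tibble(list(
          token = tk$token,
          char_start = sec_start + tk$char_start,
          char_end = sec_start + tk$char_end
        ), nrow = nrow(tk))
      }
    }
    n <- length(lab)
    if (n == 0) next
    acc[[length(acc) + 1L]] <- tibble::new_tibble(list(
      report_id = rep(id, n), sent_id = seq_len(n), section_label = lab,
      valve_context = vc, char_start = cs, char_end = ce, text = stx,
      tokens = tkl
    ), nrow = n)
  }
  if (length(acc) == 0) {
    return(tibble(
      report_id = character(), sent_id = integer(), section_label = character(),
      valve_context = character(), char_start = integer(), char_end = integer(),
      text = character(), tokens = list()
    ))
  }
  bind_rows(acc)
}

#' Mine misspelling candidates from a corpus
#'
#' Offline, human-in-the-loop tooling: for each canonical single-token term,
#' ranks corpus tokens by a character edit-distance similarity ratio and emits
#' the top candidates for manual review. Nothing enters the runtime
#' misspelling map without explicit acceptance; the output is advisory only.
#' Ranking is deterministic (similarity, then corpus frequency, then
#' alphabetical).
#'
#' @param reports a report tibble; its `text` column is the corpus.
#' @param canonical_terms character vector of canonical terms; multi-token
#'   phrases are skipped (their component words can be passed individually).
#' @param top_k maximum candidates per term (default 100).
#' @param path optional CSV path for the review file.
#' @return a tibble with columns `term`, `candidate`, `score` (in `[0, 1]`),
#'   `freq` (corpus frequency) and `status` (always `"candidate"`).
#' @export
mine_misspellings <- function(reports, canonical_terms, top_k = 100, path = NULL) {
  if (nrow(reports) == 0) abort("corpus is empty")
  if (!is.numeric(top_k) || top_k < 1) abort("top_k must be >= 1")
  all_tokens <- unlist(lapply(tolower(reports$text), function(t) tokenize(t)$token))
  all_tokens <- all_tokens[grepl("^[a-z]+$", all_tokens)]
  if (length(all_tokens) == 0) abort("corpus is empty")
  freq <- table(all_tokens)
  vocab <- names(freq)
  canonical_terms <- tolower(canonical_terms)
  single <- canonical_terms[!grepl("\\s", canonical_terms)]
  out <- purrr::map(single, function(term) {
    if (!term %in% vocab) return(NULL) # term absent from corpus vocabulary
    cands <- setdiff(vocab, term)
    if (length(cands) == 0) return(NULL)
    d <- drop(utils::adist(term, cands))
    score <- 1 - d / pmax(nchar(term), nchar(cands))
    res <- tibble(
      term = term, candidate = cands, score = score,
      freq = as.integer(freq[cands]), status = "candidate"
    ) |>
      arrange(desc(.data$score), desc(.data$freq), .data$candidate)
    utils::head(res, top_k)
  }) |> bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(term = character(), candidate = character(), score = numeric(),
                  freq = integer(), status = character())
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
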