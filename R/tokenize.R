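# Tokenization shared by matching, sentence splitting and the misspelling
# miner. Hyphens and underscores act as plain separators so hyphenated
# severity ranges ("mild-to-moderate") collapse onto their spelled-out phrase
# variants; "/" is kept as a token because slash lists ("mild as/ai/mr") and
# units ("m/s") carry meaning for disambiguation.

.token_pattern <- "[0-9]+\\.[0-9]+|[0-9]+\\+|[0-9]+|[a-z]+|[^\\sa-z0-9_-]"

#' Tokenize normalized report text
#'
#' Splits lowercase text into word, number and punctuation tokens, keeping
#' character offsets into the input. Decimal numbers ("2.5") and numeric
#' regurgitation grades ("2+") stay single tokens; hyphens are separators.
#'
#' @param text a single lowercase string.
#' @return a tibble with columns `token`, `char_start`, `char_end` (0-based,
#'   half-open offsets into `text`). Zero rows for empty input.
#' @examples
#' tokenize("peak velocity 2.5 m/s")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), char_start = integer(), char_end = integer()))
  }
  loc <- stringr::str_locate_all(text, .token_pattern)[[1]]
  if (nrow(loc) == 0) {
    return(tibble(token = character(), char_start = integer(), char_end = integer()))
  }
  tibble(
    token = stringr::str_sub(text, loc[, 1], loc[, 2]),
    char_start = as.integer(loc[, 1] - 1L),
    char_end = as.integer(loc[, 2])
  )
}

# tokenize a lexicon phrase into its token sequence (character vector)
tokenize_phrase <- function(phrase) tokenize(phrase)$token

is_numeric_token <- function(token) {
  grepl("^[0-9]+(\\.[0-9]+)?$", token)
}
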