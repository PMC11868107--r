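#' Read a wordlist file
#'
#' Reads a UTF-8 plain-text wordlist (one word per line), for use as the
#' reference of the "dictionary" lexicality criterion. Entries are trimmed,
#' case-folded, NFC-normalised and de-duplicated; blank lines are dropped.
#'
#' @param path Path to the wordlist file.
#' @return A character vector of unique lowercase words.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) stop_config("read_wordlist(): file not found: %s", path)
  words <- readr::read_lines(path)
  words <- stringr::str_trim(words)
  words <- words[nzchar(words)]
  words <- unique(nfc(stringr::str_to_lower(words)))
  if (length(words) == 0L) stop_config("read_wordlist(): %s holds no words", path)
  if (any(stringr::str_detect(words, "\\s"))) {
    stop_config("read_wordlist(): entries must not contain whitespace")
  }
  words
}

#' Read a frequency lexicon
#'
#' Reads a CSV with columns `word` and `log10_frq` (log10 lexical frequency,
#' as in Spanish lexical databases), for use as the reference of the
#' "database" lexicality criterion. Words are case-folded and
#' NFC-normalised; duplicated words or non-finite frequencies are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `word` and `log10_frq`.
#' @export
read_frequency_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop_config("read_frequency_lexicon(): file not found: %s", path)
  }
  lex <- readr::read_csv(path, col_types = readr::cols(
    word = readr::col_character(), log10_frq = readr::col_double()))
  validate_frequency_lexicon(lex, path)
}

validate_frequency_lexicon <- function(lex, what = "frequency lexicon") {
  if (!all(c("word", "log10_frq") %in% names(lex))) {
    stop_config("%s must have columns `word` and `log10_frq`", what)
  }
  lex <- tibble::as_tibble(lex)
  lex$word <- nfc(stringr::str_to_lower(lex$word))
  if (anyDuplicated(lex$word) > 0L) {
    stop_config("%s: duplicated word(s): %s", what,
                paste(utils::head(unique(lex$word[duplicated(lex$word)]), 5L),
                      collapse = ", "))
  }
  if (!all(is.finite(lex$log10_frq))) {
    stop_config("%s: frequencies must be finite", what)
  }
  if (nrow(lex) == 0L) stop_config("%s is empty", what)
  lex[c("word", "log10_frq")]
}

#' Check whether responses are real words
#'
#' Adds a binary `lexicality` column to an attempt table. Two criteria are
#' supported. Under `"dictionary"`, a response is lexical (1) iff it appears
#' in the supplied wordlist; the target item plays no role. Under
#' `"database"`, a response is lexical iff it appears in the frequency
#' lexicon *and* its log10 frequency is strictly higher than the target
#' item's; in any other scenario it is scored as a non-lexical production
#' (0). Lookups are case-folded and NFC-normalised. Blank responses are
#' never lexical and are annotated in `lexicality_note`, as is the
#' (surprising but possible) case of an item that is itself absent from the
#' frequency lexicon — its frequency is then treated as lower than any
#' listed response's, so that real-word responses are not silently excluded.
#'
#' @param data Attempt table.
#' @param item_col,response_col Names of the target and response columns.
#' @param criterion `"dictionary"` or `"database"`.
#' @param wordlist Character vector of words (see [read_wordlist()]);
#'   required for the dictionary criterion.
#' @param freq_lexicon Data frame with columns `word` and `log10_frq` (see
#'   [read_frequency_lexicon()]); required for the database criterion.
#' @return The input tibble with `lexicality` (integer 0/1) and
#'   `lexicality_note` columns appended.
#' @export
check_lexicality <- function(data, item_col = "item",
                             response_col = "response",
                             criterion = c("dictionary", "database"),
                             wordlist = NULL, freq_lexicon = NULL) {
  criterion <- rlang::arg_match(criterion)
  check_cols(data, c(item_col, response_col), "check_lexicality()")
  out <- tibble::as_tibble(data)
  responses <- nfc(stringr::str_to_lower(as.character(out[[response_col]])))
  items <- nfc(stringr::str_to_lower(as.character(out[[item_col]])))
  blank <- is_blank(responses)
  note <- rep(NA_character_, nrow(out))
  note[blank] <- "no response"

  if (criterion == "dictionary") {
    if (is.null(wordlist) || length(wordlist) == 0L) {
      stop_config("check_lexicality(): the dictionary criterion needs a non-empty `wordlist`")
    }
    wordlist <- nfc(stringr::str_to_lower(wordlist))
    lex <- as.integer(!blank & responses %in% wordlist)
  } else {
    if (is.null(freq_lexicon) || nrow(freq_lexicon) == 0L) {
      stop_config("check_lexicality(): the database criterion needs a non-empty `freq_lexicon`")
    }
    freq_lexicon <- validate_frequency_lexicon(freq_lexicon)
    f <- stats::setNames(freq_lexicon$log10_frq, freq_lexicon$word)
    resp_f <- unname(f[responses])
    item_f <- unname(f[items])
    item_missing <- is.na(item_f)
    item_f[item_missing] <- -Inf
    note[item_missing & !blank] <-
      "item not in frequency lexicon; treated as lowest frequency"
    lex <- as.integer(!blank & !is.na(resp_f) & resp_f > item_f)
  }
  out$lexicality <- lex
  out$lexicality_note <- note
  out
}
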