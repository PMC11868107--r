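# Internal helpers shared across modules.

# Split a string into Unicode code points. The code point is the unit of
# comparison everywhere: IPA affricates written as two code points (e.g. d + ʒ)
# count as two characters, and combining diacritics are left as read.
chr_vec <- function(x) {
  if (is.na(x)) return(character(0))
  strsplit(x, "", fixed = FALSE)[[1]]
}

# Blank = NA, empty, or whitespace-only.
is_blank <- function(x) {
  is.na(x) | !nzchar(trimws(x))
}

nfc <- function(x) stringi::stri_trans_nfc(x)

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "girasol_config_error")
}

stop_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "girasol_data_error")
}

check_cols <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_config("%s: column(s) not found in data: %s",
                where, paste(missing, collapse = ", "))
  }
  invisible(data)
}

#' Strip stress and syllable marks from broad phonemic transcriptions
#'
#' Removes the IPA primary (\code{ˈ}) and secondary (\code{ˌ}) stress
#' marks and the syllable separator (\code{.}) from a character vector, as is
#' conventionally done before scoring broad transcriptions. Scoring functions
#' never strip these silently; apply this explicitly when working with
#' phonemic columns.
#'
#' @param x Character vector of IPA strings.
#' @return Character vector with stress and syllable marks removed.
#' @examples
#' strip_transcription_marks("dɪˈvɛl.əp.mənt")
#' @export
strip_transcription_marks <- function(x) {
  stringr::str_remove_all(x, "[ˈˌ.]")
}
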