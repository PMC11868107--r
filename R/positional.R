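#' Explode match strings into per-position accuracy records
#'
#' Unrolls each attempt's target-length-adjusted binary match string (the
#' `adj_strict_match_pos` column of [get_formal_similarity()]) into one row
#' per target position, for fine-grained positional-accuracy analysis (e.g.
#' serial-position effects in phonological encoding). Every input column is
#' retained as an identifier; four columns are added: `position` (1-based
#' index within the target string), `element_in_item` and
#' `element_in_response` (the characters at that position; the latter is the
#' empty string where the response is shorter than the target), and
#' `correct_pos` (1 if the response character matches the target character at
#' that position).
#'
#' @param data Table carrying items, responses and match strings (typically
#'   the output of [get_formal_similarity()]).
#' @param item_col,response_col Names of the target and response columns.
#' @param match_col Name of the column holding binary match strings whose
#'   length equals the target's length.
#' @return A tibble with one row per target position per input row.
#' @examples
#' tibble::tibble(item = "mangrove", response = "mango") |>
#'   get_formal_similarity() |>
#'   positional_accuracy()
#' @export
positional_accuracy <- function(data, item_col = "item",
                                response_col = "response",
                                match_col = "adj_strict_match_pos") {
  check_cols(data, c(item_col, response_col, match_col),
             "positional_accuracy()")
  out <- tibble::as_tibble(data)
  items <- as.character(out[[item_col]])
  responses <- as.character(out[[response_col]])
  matches <- as.character(out[[match_col]])
  bad <- which(stringr::str_length(matches) != stringr::str_length(items))
  if (length(bad) > 0L) {
    stop_data(
      "positional_accuracy(): match string length != item length in row(s) %s",
      paste(utils::head(bad, 5L), collapse = ", "))
  }
  expanded <- purrr::pmap(list(items, responses, matches), function(it, re, ma) {
    a <- chr_vec(it)
    b <- if (is.na(re)) character(0) else chr_vec(re)
    n <- length(a)
    resp_el <- character(n)
    k <- min(n, length(b))
    if (k > 0L) resp_el[seq_len(k)] <- b[seq_len(k)]
    tibble::tibble(
      position = seq_len(n),
      element_in_item = a,
      element_in_response = resp_el,
      correct_pos = as.integer(chr_vec(ma))
    )
  })
  out$.pos <- expanded
  tidyr::unnest(out, ".pos")
}

#' Summarise positional accuracy by group
#'
#' Aggregates a per-position table (from [positional_accuracy()]) into the
#' proportion of correctly produced elements per group — the tabular data
#' behind positional-accuracy profiles (accuracy by within-word position,
#' task, session, ...). Include `"position"` in `by` to profile across
#' positions.
#'
#' @param data Output of [positional_accuracy()].
#' @param by Character vector of grouping columns (e.g.
#'   \code{c("task", "position")}).
#' @return A tibble with one row per group: `n` scored positions,
#'   `n_correct`, and `proportion` correct. Groups with no rows after
#'   filtering are simply absent.
#' @export
positional_summary <- function(data, by = "position") {
  check_cols(data, c(by, "correct_pos"), "positional_summary()")
  if (nrow(data) == 0L) {
    stop_data("positional_summary(): empty input")
  }
  out <- dplyr::group_by(tibble::as_tibble(data),
                         dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    out,
    n = dplyr::n(),
    n_correct = sum(.data$correct_pos),
    proportion = .data$n_correct / .data$n,
    .groups = "drop"
  )
  out
}
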