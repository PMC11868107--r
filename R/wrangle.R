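#' Split multi-attempt response cells into one column per attempt
#'
#' Assessment transcripts often hold several successive attempts at a target
#' word in a single response cell (e.g. \code{"talablo, talabro, taladro"}),
#' as happens with conduites d'approche. This function splits such cells on a
#' literal delimiter into columns \code{attempt_1 ... attempt_K}, where K is
#' the largest attempt count in the table. Attempts are trimmed of leading and
#' trailing whitespace; interior spaces are preserved (they will raise a
#' warning flag downstream in [get_formal_similarity()]). All other columns
#' are carried through unchanged; the original response column is replaced by
#' the attempt columns.
#'
#' @param data A data frame with one row per stimulus presentation.
#' @param col_name Name of the column holding the raw response cell.
#' @param separate_with Literal delimiter between attempts (not a regular
#'   expression), default \code{", "}.
#' @return A tibble with columns \code{attempt_1 ... attempt_K} in place of
#'   \code{col_name}. Positions beyond a cell's attempt count are \code{NA};
#'   a blank attempt produced by the split itself (e.g. \code{"a, , b"}) is
#'   kept as an empty string so [get_attempts()] can drop it explicitly.
#' @seealso [get_attempts()] to pivot the attempt columns into long format.
#' @examples
#' df <- tibble::tibble(item = "taladro",
#'                      response = "talablo, talabro, taladro")
#' separate_responses(df, col_name = "response", separate_with = ", ")
#' @export
separate_responses <- function(data, col_name = "response",
                               separate_with = ", ") {
  if (!is.character(separate_with) || length(separate_with) != 1L ||
      !nzchar(separate_with)) {
    stop_config("separate_responses(): `separate_with` must be a non-empty string")
  }
  check_cols(data, col_name, "separate_responses()")
  cells <- as.character(data[[col_name]])
  parts <- stringr::str_split(cells, stringr::fixed(separate_with))
  parts <- purrr::map(parts, stringr::str_trim)
  # NA cells behave like empty cells: one blank attempt
  parts[is.na(cells)] <- list("")
  k <- max(lengths(parts), 1L)
  wide <- purrr::map(seq_len(k), function(i) {
    purrr::map_chr(parts, function(p) if (length(p) >= i) p[i] else NA_character_)
  })
  names(wide) <- paste0("attempt_", seq_len(k))
  out <- tibble::as_tibble(data)
  pos <- match(col_name, names(out))
  before <- out[seq_len(pos - 1L)]
  after <- if (pos < ncol(out)) out[(pos + 1L):ncol(out)] else NULL
  dplyr::bind_cols(before, tibble::as_tibble(wide), after)
}

#' Pivot attempt columns into a long table of single attempts
#'
#' Takes the output of [separate_responses()] and reshapes it so that each
#' attempt occupies its own row, restoring a single \code{response} column and
#' adding repetition metadata: \code{RA} is 1 when the source cell held more
#' than one (non-blank) attempt — the multi-attempt, conduite-d'approche case
#' — and 0 for single responses; \code{attempt} numbers the attempts 1..k in
#' their original left-to-right order. When \code{drop_blank_spaces} is
#' \code{TRUE}, blank attempts are removed before numbering, so attempt
#' indices count only the retained attempts.
#'
#' @param data Output of [separate_responses()] (columns matching
#'   \code{attempt_<n>} must be present).
#' @param drop_blank_spaces Drop rows whose attempt is empty or
#'   whitespace-only (recommended; blank rows are an artefact of the split).
#' @return A tibble of single attempts with columns \code{response},
#'   \code{RA} and \code{attempt} appended after the passthrough columns.
#' @examples
#' tibble::tibble(item = "taladro", response = "talablo, taladro") |>
#'   separate_responses() |>
#'   get_attempts()
#' @export
get_attempts <- function(data, drop_blank_spaces = TRUE) {
  attempt_cols <- grep("^attempt_[0-9]+$", names(data), value = TRUE)
  if (length(attempt_cols) == 0L) {
    stop_data(paste0("get_attempts(): no attempt_<n> columns found; ",
                     "run separate_responses() first"))
  }
  attempt_cols <- attempt_cols[order(as.integer(sub("^attempt_", "", attempt_cols)))]
  out <- tibble::as_tibble(data)
  out$.cell <- seq_len(nrow(out))
  long <- tidyr::pivot_longer(out, cols = dplyr::all_of(attempt_cols),
                              names_to = ".slot", values_to = "response")
  long$.slot <- as.integer(sub("^attempt_", "", long$.slot))
  long <- dplyr::arrange(long, .data$.cell, .data$.slot)
  # NA slots are padding, never attempts; blank strings are real (empty)
  # attempts that drop_blank_spaces removes
  long <- dplyr::filter(long, !is.na(.data$response))
  if (drop_blank_spaces) {
    long <- dplyr::filter(long, nzchar(stringr::str_trim(.data$response)))
  }
  long <- dplyr::group_by(long, .data$.cell)
  long <- dplyr::mutate(
    long,
    RA = as.integer(sum(nzchar(stringr::str_trim(.data$response))) > 1L),
    attempt = dplyr::row_number()
  )
  long <- dplyr::ungroup(long)
  dplyr::select(long, -".cell", -".slot")
}
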