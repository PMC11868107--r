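#' Compute the formal-similarity index battery for an attempt table
#'
#' Scores every (target, response) pair in a long-format attempt table with
#' the full battery of formal indexes: string lengths (`targetL`,
#' `responseL`), the shared-character proportion `p_shared_char` (see
#' [shared_char_proportion()]), the positionwise match percentage
#' `p_shared_char_in_pos` with its binary match strings `strict_match_pos`
#' and `adj_strict_match_pos`, the character-count difference
#' `diff_char_num` (target minus response), the Levenshtein (`Ld`),
#' unrestricted Damerau-Levenshtein (`DLd`) and Jaro-Winkler (`JWd`)
#' distances, the proportion of correct characters `pcc`, the longest common
#' substring `lcs`, the alignment trace `similarity_str`, the shared-initial
#' flag `shared1char`, and a `comment_warning` set when a response contains
#' spaces or commas (which could indicate repeated attempts left unsplit).
#'
#' When `attempt_col` and `group_cols` are supplied, the across-attempt
#' change `approach_diff` is also computed: within each group (the
#' `group_cols` identifiers plus the target item) attempts are ordered by
#' attempt number and `approach_diff` is the difference in `pcc` between an
#' attempt and its predecessor (`NA` for the first attempt of each group).
#' Group on every identifier that distinguishes assessments (participant,
#' item, task, date), otherwise attempts from different presentations would
#' be compared. When the two parameters are omitted the battery is computed
#' without `approach_diff`.
#'
#' Scoring is case-sensitive and works on Unicode code points, so it applies
#' equally to orthographic and broad phonemic (IPA) columns; strip stress and
#' syllable marks first with [strip_transcription_marks()] when scoring
#' transcriptions.
#'
#' @param data Long-format attempt table (e.g. from [get_attempts()]).
#' @param item_col,response_col Names of the target and response columns.
#' @param attempt_col Optional name of the attempt-number column; requires
#'   `group_cols`.
#' @param group_cols Optional character vector of identifier columns defining
#'   the attempt groups for `approach_diff`.
#' @return The input tibble with the index columns appended.
#' @examples
#' tibble::tibble(item = "mangrove", response = "mango") |>
#'   get_formal_similarity()
#' @export
get_formal_similarity <- function(data, item_col = "item",
                                  response_col = "response",
                                  attempt_col = NULL, group_cols = NULL) {
  check_cols(data, c(item_col, response_col), "get_formal_similarity()")
  if (!is.null(attempt_col) && is.null(group_cols)) {
    stop_config(paste0("get_formal_similarity(): `attempt_col` requires ",
                       "`group_cols` to identify which attempts belong together"))
  }
  if (!is.null(attempt_col)) {
    check_cols(data, c(attempt_col, group_cols), "get_formal_similarity()")
  }
  out <- tibble::as_tibble(data)
  items <- as.character(out[[item_col]])
  responses <- as.character(out[[response_col]])
  if (any(is_blank(items))) {
    stop_data("get_formal_similarity(): blank target item in row(s) %s",
              paste(utils::head(which(is_blank(items)), 5L), collapse = ", "))
  }

  idx <- purrr::map2(items, responses, score_pair)
  idx <- dplyr::bind_rows(idx)
  if (nrow(out) == 0L) idx <- score_pair("x", "x")[0, ]
  out <- dplyr::bind_cols(out, idx)

  if (!is.null(attempt_col)) {
    keys <- out[c(group_cols, item_col, attempt_col)]
    if (anyDuplicated(keys) > 0L) {
      dup <- keys[duplicated(keys), , drop = FALSE]
      stop_data(
        "get_formal_similarity(): duplicate (group, attempt) keys, e.g.: %s",
        paste(utils::capture.output(print(utils::head(dup, 3L)))[-1],
              collapse = " | "))
    }
    out$.row <- seq_len(nrow(out))
    # attempt numbers may arrive as text from read_table(); order numerically
    att_key <- suppressWarnings(as.numeric(out[[attempt_col]]))
    out$.att <- if (anyNA(att_key)) out[[attempt_col]] else att_key
    out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(c(group_cols, item_col))))
    out <- dplyr::arrange(out, .data$.att, .by_group = TRUE)
    out <- dplyr::mutate(out, approach_diff = .data$pcc - dplyr::lag(.data$pcc))
    out <- dplyr::ungroup(out)
    out <- dplyr::arrange(out, .data$.row)
    out <- dplyr::select(out, -".row", -".att")
  }
  out
}

# Battery for one (target, response) pair; blank responses yield degenerate
# values (distances = target length, pcc = 0, empty match strings stay all-0)
# rather than errors, since a blank attempt is a legitimate no-response row.
score_pair <- function(item, response) {
  blank <- is_blank(response)
  resp <- if (blank) "" else response
  a_len <- stringr::str_length(item)
  r_len <- if (blank) 0L else stringr::str_length(resp)
  pm <- positional_match(item, resp)
  ed <- edit_distances(item, resp)
  tibble::tibble(
    targetL = a_len,
    responseL = r_len,
    p_shared_char = if (blank) NA_real_ else shared_char_proportion(item, resp),
    p_shared_char_in_pos = pm$p_shared_char_in_pos,
    diff_char_num = a_len - r_len,
    Ld = ed$Ld,
    DLd = ed$DLd,
    JWd = ed$JWd,
    pcc = max(0, 1 - ed$DLd / a_len),
    lcs = lcs_substring(item, resp),
    similarity_str = similarity_trace(item, resp),
    shared1char = !blank &&
      stringr::str_sub(item, 1L, 1L) == stringr::str_sub(resp, 1L, 1L),
    strict_match_pos = pm$strict_match_pos,
    adj_strict_match_pos = pm$adj_strict_match_pos,
    comment_warning = if (!blank && stringr::str_detect(resp, "[ ,]")) {
      "response contains spaces or commas, could indicate RAs"
    } else {
      NA_character_
    }
  )
}
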