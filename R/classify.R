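#' Classify a single attempt
#'
#' Applies the error taxonomy's decision tree to one attempt, given the
#' evidence computed by the earlier pipeline stages. The tree is:
#'
#' 1. blank/missing response: *no response*;
#' 2. the attempt was annotated as successful (`accessed = 1`) or equals the
#'    target: correct, no error category;
#' 3. nonword responses (`lexicality = 0`): *nonword* (phonemic) when the
#'    shared-character proportion reaches `formal_threshold`, otherwise
#'    *neologism*;
#' 4. real-word responses (`lexicality = 1`): formally related means sharing
#'    at least `formal_threshold` percent of characters **or** the initial
#'    character; semantically related means a present cosine at or above
#'    `cosine_limit_value`. Both: *mixed*; only formal: *formal*; only
#'    semantic: *semantic*; neither: *unrelated*.
#'
#' Ties at the thresholds count as related ("at least 50%", so `>=`). A
#' missing cosine (e.g. out-of-vocabulary response) counts as not
#' semantically related; [classify_errors()] records this in a note column.
#'
#' @param item,response Target and response strings.
#' @param accessed 1 if the response was annotated as a successful
#'   production, 0 otherwise (NA allowed: falls back to string equality).
#' @param lexicality 1 if the response is a real word, 0 otherwise.
#' @param p_shared_char Shared-character percentage in \[0, 100\].
#' @param shared1char Logical, identical first character.
#' @param w2v_cos Embedding cosine similarity, or NA.
#' @param cosine_limit_value Semantic-relatedness threshold on the cosine,
#'   default 0.46 (tuned for stores whose cosines live in \[0, 1\]; adjust
#'   for models on \[-1, 1\]).
#' @param formal_threshold Formal-relatedness threshold on
#'   `p_shared_char`, in percent; default 50.
#' @return A named integer vector over the seven categories
#'   (`no_response`, `nonword`, `neologism`, `formal`, `unrelated`,
#'   `semantic`, `mixed`).
#' @export
classify_attempt <- function(item, response, accessed, lexicality,
                             p_shared_char, shared1char, w2v_cos,
                             cosine_limit_value = 0.46,
                             formal_threshold = 50) {
  cats <- stats::setNames(integer(7), error_categories())
  if (is_blank(response)) {
    cats[["no_response"]] <- 1L
    return(cats)
  }
  correct <- (!is.na(accessed) && accessed == 1) ||
    (!is.na(item) && response == item)
  if (correct) return(cats)
  if (is.na(lexicality)) return(cats)  # unclassifiable; flagged upstream
  formally <- (!is.na(p_shared_char) && p_shared_char >= formal_threshold)
  if (lexicality == 0) {
    if (formally) cats[["nonword"]] <- 1L else cats[["neologism"]] <- 1L
    return(cats)
  }
  formally <- formally || isTRUE(shared1char)
  semantically <- !is.na(w2v_cos) && w2v_cos >= cosine_limit_value
  if (formally && semantically) {
    cats[["mixed"]] <- 1L
  } else if (formally) {
    cats[["formal"]] <- 1L
  } else if (semantically) {
    cats[["semantic"]] <- 1L
  } else {
    cats[["unrelated"]] <- 1L
  }
  cats
}

error_categories <- function() {
  c("no_response", "nonword", "neologism", "formal", "unrelated",
    "semantic", "mixed")
}

#' Classify production errors, optionally handling repeated attempts
#'
#' Applies [classify_attempt()] row by row to a fully scored attempt table
#' (after [get_formal_similarity()], [check_lexicality()] and
#' [get_semantic_similarity()]; the function refuses to run if a stage was
#' skipped). Seven binary category columns are appended, plus
#' `check_comment`, which is `"required"` when an erroneous attempt received
#' zero or multiple categories and therefore needs manual review, and
#' `"is only considered as RA"` for attempts inside repeated-attempt cells
#' left unclassified because `also_classify_RAs = FALSE`. Correct attempts
#' (`accessed = 1` or response equal to the item) get all-zero categories.
#' `classification_note` records audit information such as a cosine missing
#' because the response is out of the embedding vocabulary.
#'
#' @param data Scored attempt table.
#' @param access_col Column with the correctness annotation (1 = target
#'   produced).
#' @param RA_col Column with the repeated-attempt flag (1 = the source cell
#'   held several attempts).
#' @param item_col,response_col Names of the target and response columns.
#' @param also_classify_RAs Classify attempts inside repeated-attempt cells
#'   too (default); if `FALSE`, rows with `RA = 1` are left unclassified.
#' @param cosine_limit_value,formal_threshold See [classify_attempt()].
#' @return The input tibble with the category columns, `check_comment` and
#'   `classification_note` appended.
#' @export
classify_errors <- function(data, access_col = "accessed", RA_col = "RA",
                            item_col = "item", response_col = "response",
                            also_classify_RAs = TRUE,
                            cosine_limit_value = 0.46,
                            formal_threshold = 50) {
  check_cols(data, c(access_col, RA_col, item_col, response_col),
             "classify_errors()")
  check_pipeline_cols(data)
  check_thresholds(cosine_limit_value, formal_threshold)
  classify_core(data, access_col, item_col, response_col,
                RA_col = RA_col, also_classify_RAs = also_classify_RAs,
                cosine_limit_value = cosine_limit_value,
                formal_threshold = formal_threshold)
}

#' Classify production errors of single responses
#'
#' The repeated-attempt-free variant of [classify_errors()], for tables of
#' one response per stimulus: no `RA` column is consulted and every row is
#' classified. On rows without repeated attempts it yields exactly the
#' categories [classify_errors()] assigns with `also_classify_RAs = TRUE`.
#'
#' @inheritParams classify_errors
#' @return The input tibble with the category columns, `check_comment` and
#'   `classification_note` appended.
#' @export
classify_errors_regular <- function(data, access_col = "accessed",
                                    item_col = "item",
                                    response_col = "response",
                                    cosine_limit_value = 0.46,
                                    formal_threshold = 50) {
  check_cols(data, c(access_col, item_col, response_col),
             "classify_errors_regular()")
  check_pipeline_cols(data)
  check_thresholds(cosine_limit_value, formal_threshold)
  classify_core(data, access_col, item_col, response_col,
                RA_col = NULL, also_classify_RAs = TRUE,
                cosine_limit_value = cosine_limit_value,
                formal_threshold = formal_threshold)
}

check_pipeline_cols <- function(data) {
  stages <- c(
    p_shared_char = "get_formal_similarity()",
    shared1char = "get_formal_similarity()",
    lexicality = "check_lexicality()",
    w2v_cos = "get_semantic_similarity()"
  )
  missing <- setdiff(names(stages), names(data))
  if (length(missing) > 0L) {
    stop_config(
      "classification needs column(s) %s: run %s first",
      paste(missing, collapse = ", "),
      paste(unique(stages[missing]), collapse = ", then "))
  }
}

check_thresholds <- function(cosine_limit_value, formal_threshold) {
  if (!is.numeric(formal_threshold) || formal_threshold <= 0 ||
      formal_threshold > 100) {
    stop_config("`formal_threshold` must be in (0, 100]")
  }
  if (!is.numeric(cosine_limit_value) || cosine_limit_value < -1 ||
      cosine_limit_value > 1) {
    stop_config("`cosine_limit_value` must be within the cosine range [-1, 1]")
  }
}

classify_core <- function(data, access_col, item_col, response_col, RA_col,
                          also_classify_RAs, cosine_limit_value,
                          formal_threshold) {
  out <- tibble::as_tibble(data)
  n <- nrow(out)
  items <- as.character(out[[item_col]])
  responses <- as.character(out[[response_col]])
  accessed <- suppressWarnings(as.numeric(out[[access_col]]))
  lexicality <- suppressWarnings(as.numeric(out[["lexicality"]]))
  psc <- suppressWarnings(as.numeric(out[["p_shared_char"]]))
  s1c <- as.logical(out[["shared1char"]])
  w2v <- suppressWarnings(as.numeric(out[["w2v_cos"]]))
  ra <- if (is.null(RA_col)) rep(0, n) else suppressWarnings(as.numeric(out[[RA_col]]))

  cats <- matrix(0L, nrow = n, ncol = 7L,
                 dimnames = list(NULL, error_categories()))
  comment <- character(n)
  note <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!also_classify_RAs && !is.na(ra[i]) && ra[i] == 1) {
      comment[i] <- "is only considered as RA"
      next
    }
    ci <- classify_attempt(items[i], responses[i], accessed[i], lexicality[i],
                           psc[i], s1c[i], w2v[i],
                           cosine_limit_value = cosine_limit_value,
                           formal_threshold = formal_threshold)
    cats[i, ] <- ci
    correct <- (!is.na(accessed[i]) && accessed[i] == 1) ||
      (!is.na(items[i]) && !is.na(responses[i]) && responses[i] == items[i])
    erroneous <- !correct
    if (erroneous && sum(ci) != 1L) comment[i] <- "required"
    if (erroneous && !is_blank(responses[i]) &&
        !is.na(lexicality[i]) && lexicality[i] == 1 && is.na(w2v[i])) {
      note[i] <- "cosine missing (out of vocabulary): treated as not semantically related"
    }
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(cats))
  out$check_comment <- comment
  out$classification_note <- note
  out
}
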