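#' Read an assessment table
#'
#' Reads a UTF-8 CSV or TSV with a header row into a tibble of character
#' columns (types are applied by the downstream stages, which coerce what
#' they need). The delimiter is auto-detected from the extension
#' (`.tsv`/`.tab` = tab, otherwise comma) and can be overridden. All cells
#' are NFC-normalised so that composed and decomposed Unicode spellings of
#' the same transcription compare equal.
#'
#' @param path Path to the file.
#' @param delim Optional delimiter override (e.g. `";"`).
#' @return A tibble of character columns.
#' @export
read_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_config("read_table(): file not found: %s", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  header <- strsplit(readr::read_lines(path, n_max = 1L), delim, fixed = TRUE)[[1]]
  header <- gsub("^\"|\"$", "", header)
  if (anyDuplicated(header) > 0L) {
    stop_config("read_table(): duplicated header column(s) in %s: %s", path,
                paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  out <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  dplyr::mutate(out, dplyr::across(dplyr::where(is.character), nfc))
}

#' Write a table as CSV or TSV
#'
#' @param data A data frame.
#' @param path Output path; `.tsv`/`.tab` extensions select tab delimiting.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' Configure the analysis pipeline
#'
#' Collects and validates everything [run_pipeline()] needs: column
#' bindings, the attempt delimiter, lexicality criterion and resources,
#' thresholds, and which stages to run. Resources may be given as loaded
#' objects (`wordlist`, `freq_lexicon`, `embeddings`) or as file paths
#' (`wordlist_path`, `freq_lexicon_path`, `embeddings_path`), in which case
#' they are loaded when the pipeline runs.
#'
#' @param response_col,item_col,attempt_col,access_col,RA_col Column
#'   bindings in the input table (the attempt column is created by the
#'   wrangle stage).
#' @param group_cols Identifier columns grouping attempts of one
#'   presentation.
#' @param separate_with Literal attempt delimiter.
#' @param drop_blank_spaces Drop blank attempts while wrangling.
#' @param stages Stages to run, a prefix of
#'   `c("wrangle", "formal", "lexicality", "semantics", "classify")`.
#' @param criterion Lexicality criterion, `"dictionary"` or `"database"`.
#' @param wordlist,wordlist_path Wordlist resource.
#' @param freq_lexicon,freq_lexicon_path Frequency-lexicon resource.
#' @param embeddings,embeddings_path Embedding resource.
#' @param embeddings_format Format for `embeddings_path`.
#' @param cosine_limit_value,formal_threshold Classifier thresholds.
#' @param also_classify_RAs Classify attempts inside repeated-attempt
#'   cells.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(response_col = "response", item_col = "item",
                            attempt_col = "attempt",
                            access_col = "accessed", RA_col = "RA",
                            group_cols = c("ID", "item_ID"),
                            separate_with = ", ", drop_blank_spaces = TRUE,
                            stages = c("wrangle", "formal", "lexicality",
                                       "semantics", "classify"),
                            criterion = c("dictionary", "database"),
                            wordlist = NULL, wordlist_path = NULL,
                            freq_lexicon = NULL, freq_lexicon_path = NULL,
                            embeddings = NULL, embeddings_path = NULL,
                            embeddings_format = "word2vec-text",
                            cosine_limit_value = 0.46, formal_threshold = 50,
                            also_classify_RAs = TRUE) {
  all_stages <- c("wrangle", "formal", "lexicality", "semantics", "classify")
  stages <- unique(match.arg(stages, all_stages, several.ok = TRUE))
  # stages must be contiguous in pipeline order (a stage cannot run without
  # the columns its predecessor produces); the start may be later than
  # wrangle when the input table is already in the right shape
  pos <- sort(match(stages, all_stages))
  stages <- all_stages[seq(min(pos), max(pos))]
  criterion <- rlang::arg_match(criterion)
  bound <- c(response_col, item_col, attempt_col, access_col, RA_col)
  if (anyDuplicated(bound) > 0L) {
    stop_config("pipeline_config(): bound column names must be distinct")
  }
  check_thresholds(cosine_limit_value, formal_threshold)
  structure(list(
    response_col = response_col, item_col = item_col,
    attempt_col = attempt_col, access_col = access_col, RA_col = RA_col,
    group_cols = group_cols, separate_with = separate_with,
    drop_blank_spaces = isTRUE(drop_blank_spaces), stages = stages,
    criterion = criterion,
    wordlist = wordlist, wordlist_path = wordlist_path,
    freq_lexicon = freq_lexicon, freq_lexicon_path = freq_lexicon_path,
    embeddings = embeddings, embeddings_path = embeddings_path,
    embeddings_format = embeddings_format,
    cosine_limit_value = cosine_limit_value,
    formal_threshold = formal_threshold,
    also_classify_RAs = isTRUE(also_classify_RAs)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — wrangle (split and pivot multi-attempt
#' cells), formal similarity, lexicality check, semantic similarity, error
#' classification — on a raw response table. Running the pipeline is
#' equivalent to composing the stage functions by hand: each stage is a pure
#' function of its input and the configuration.
#'
#' @param data Raw response table (one row per stimulus presentation), e.g.
#'   from [read_table()].
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages (row counts and flag
#'   tallies).
#' @return The table after the last configured stage.
#' @export
run_pipeline <- function(data, config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- tibble::as_tibble(data)
  stages <- config$stages

  if ("wrangle" %in% stages) {
    out <- separate_responses(out, col_name = config$response_col,
                              separate_with = config$separate_with)
    out <- get_attempts(out, drop_blank_spaces = config$drop_blank_spaces)
    say("wrangle: %d attempts from %d cells (%d within repeated attempts)",
        nrow(out), nrow(data), sum(out$RA == 1))
  }
  if ("formal" %in% stages) {
    out <- get_formal_similarity(out, item_col = config$item_col,
                                 response_col = config$response_col,
                                 attempt_col = config$attempt_col,
                                 group_cols = config$group_cols)
    say("formal: %d rows scored, %d comment warnings",
        nrow(out), sum(!is.na(out$comment_warning)))
  }
  if ("lexicality" %in% stages) {
    res <- load_lexicality_resource(config)
    out <- check_lexicality(out, item_col = config$item_col,
                            response_col = config$response_col,
                            criterion = config$criterion,
                            wordlist = res$wordlist,
                            freq_lexicon = res$freq_lexicon)
    say("lexicality (%s): %d lexical / %d rows",
        config$criterion, sum(out$lexicality == 1), nrow(out))
  }
  if ("semantics" %in% stages) {
    model <- load_embedding_resource(config)
    out <- get_semantic_similarity(out, item_col = config$item_col,
                                   response_col = config$response_col,
                                   model = model)
    say("semantics: %d cosines, %d missing",
        sum(!is.na(out$w2v_cos)), sum(is.na(out$w2v_cos)))
  }
  if ("classify" %in% stages) {
    out <- classify_errors(out, access_col = config$access_col,
                           RA_col = config$RA_col,
                           item_col = config$item_col,
                           response_col = config$response_col,
                           also_classify_RAs = config$also_classify_RAs,
                           cosine_limit_value = config$cosine_limit_value,
                           formal_threshold = config$formal_threshold)
    say("classify: %d rows, %d flagged for review",
        nrow(out), sum(out$check_comment == "required"))
  }
  out
}

load_lexicality_resource <- function(config) {
  if (config$criterion == "dictionary") {
    wl <- config$wordlist
    if (is.null(wl) && !is.null(config$wordlist_path)) {
      wl <- read_wordlist(config$wordlist_path)
    }
    if (is.null(wl)) {
      stop_config("lexicality stage: the dictionary criterion needs `wordlist` or `wordlist_path`")
    }
    list(wordlist = wl, freq_lexicon = NULL)
  } else {
    fl <- config$freq_lexicon
    if (is.null(fl) && !is.null(config$freq_lexicon_path)) {
      fl <- read_frequency_lexicon(config$freq_lexicon_path)
    }
    if (is.null(fl)) {
      stop_config("lexicality stage: the database criterion needs `freq_lexicon` or `freq_lexicon_path`")
    }
    list(wordlist = NULL, freq_lexicon = fl)
  }
}

load_embedding_resource <- function(config) {
  model <- config$embeddings
  if (is.null(model) && !is.null(config$embeddings_path)) {
    model <- read_embeddings(config$embeddings_path,
                             format = config$embeddings_format)
  }
  if (is.null(model)) {
    stop_config("semantics stage: an embedding store is required (`embeddings` or `embeddings_path`)")
  }
  model
}
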