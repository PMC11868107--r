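#' Read a word-embedding table
#'
#' Loads word vectors in word2vec format into an embedding store. The text
#' format is a header line `"<vocab_size> <dimension>"` followed by one
#' space-separated row per word; the binary format is the same header line
#' followed by `<word> <dimension x float32>` records. Vocabulary lookups by
#' the similarity functions are case-folded and NFC-normalised.
#'
#' @param path Path to the embedding file.
#' @param format `"word2vec-text"` or `"word2vec-binary"`.
#' @param normalize Scale every vector to unit length on load (cosine
#'   similarity is scale-invariant, so this only matters if vectors are used
#'   directly).
#' @return An object of class `embedding_store`: a list with `dim` (vector
#'   dimension) and `vectors` (a words-by-dim numeric matrix with the
#'   vocabulary as row names).
#' @export
read_embeddings <- function(path, format = c("word2vec-text", "word2vec-binary"),
                            normalize = FALSE) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) stop_config("read_embeddings(): file not found: %s", path)
  if (format == "word2vec-text") {
    store <- read_w2v_text(path)
  } else {
    store <- read_w2v_binary(path)
  }
  if (normalize) {
    norms <- sqrt(rowSums(store$vectors^2))
    if (any(norms == 0)) {
      stop_config("read_embeddings(): zero vector cannot be normalised (word %s)",
                  rownames(store$vectors)[which(norms == 0)[1]])
    }
    store$vectors <- store$vectors / norms
  }
  store
}

read_w2v_text <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) stop_config("read_embeddings(): %s is empty", path)
  header <- strsplit(stringr::str_trim(lines[1]), "\\s+")[[1]]
  vocab <- suppressWarnings(as.integer(header[1]))
  dim <- suppressWarnings(as.integer(header[2]))
  if (length(header) != 2L || is.na(vocab) || is.na(dim) || dim <= 0L || vocab <= 0L) {
    stop_config("read_embeddings(): malformed header at line 1 of %s", path)
  }
  body <- lines[-1]
  body <- body[nzchar(stringr::str_trim(body))]
  if (length(body) != vocab) {
    stop_config("read_embeddings(): header of %s declares %d words but %d rows found",
                path, vocab, length(body))
  }
  words <- character(vocab)
  mat <- matrix(NA_real_, vocab, dim)
  for (i in seq_len(vocab)) {
    parts <- strsplit(stringr::str_trim(body[i]), "\\s+")[[1]]
    if (length(parts) != dim + 1L) {
      stop_config("read_embeddings(): line %d of %s has %d values, expected %d",
                  i + 1L, path, length(parts) - 1L, dim)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) {
      stop_config("read_embeddings(): non-numeric value at line %d of %s",
                  i + 1L, path)
    }
    words[i] <- parts[1]
    mat[i, ] <- vals
  }
  new_embedding_store(mat, words)
}

read_w2v_binary <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw == as.raw(0x0A))[1]
  if (is.na(nl)) stop_config("read_embeddings(): malformed header in %s", path)
  header <- strsplit(rawToChar(raw[seq_len(nl - 1L)]), "\\s+")[[1]]
  vocab <- suppressWarnings(as.integer(header[1]))
  dim <- suppressWarnings(as.integer(header[2]))
  if (length(header) != 2L || is.na(vocab) || is.na(dim) || dim <= 0L || vocab <= 0L) {
    stop_config("read_embeddings(): malformed header in %s", path)
  }
  pos <- nl + 1L
  words <- character(vocab)
  mat <- matrix(NA_real_, vocab, dim)
  n_raw <- length(raw)
  for (i in seq_len(vocab)) {
    # word runs to the next space
    start <- pos
    while (pos <= n_raw && raw[pos] != as.raw(0x20)) pos <- pos + 1L
    if (pos > n_raw) stop_config("read_embeddings(): truncated record %d in %s", i, path)
    words[i] <- rawToChar(raw[start:(pos - 1L)])
    pos <- pos + 1L
    end <- pos + 4L * dim - 1L
    if (end > n_raw) stop_config("read_embeddings(): truncated vector %d in %s", i, path)
    mat[i, ] <- readBin(raw[pos:end], "numeric", n = dim, size = 4L, endian = "little")
    pos <- end + 1L
    while (pos <= n_raw && raw[pos] == as.raw(0x0A)) pos <- pos + 1L
  }
  new_embedding_store(mat, words)
}

new_embedding_store <- function(mat, words) {
  if (anyDuplicated(words) > 0L) {
    stop_config("embedding store: duplicated word(s): %s",
                paste(utils::head(unique(words[duplicated(words)]), 5L),
                      collapse = ", "))
  }
  rownames(mat) <- words
  structure(list(dim = ncol(mat), vectors = mat), class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store: %d words, dimension %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Write an embedding store to a word2vec file
#'
#' The counterpart of [read_embeddings()]; mainly useful for materialising
#' the toy stores built by [make_toy_embeddings()] as fixture files.
#'
#' @param store An `embedding_store`.
#' @param path Output path.
#' @param format `"word2vec-text"` or `"word2vec-binary"`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(store, path,
                             format = c("word2vec-text", "word2vec-binary")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(store, "embedding_store"))
  words <- rownames(store$vectors)
  if (format == "word2vec-text") {
    rows <- apply(store$vectors, 1L, function(v) {
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")
    })
    readr::write_lines(
      c(paste(length(words), store$dim), paste(words, rows)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste(length(words), store$dim), con, eos = NULL)
    writeBin(charToRaw("\n"), con)
    for (i in seq_along(words)) {
      writeChar(paste0(words[i], " "), con, eos = NULL)
      writeBin(store$vectors[i, ], con, size = 4L, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  }
  invisible(path)
}

#' Cosine similarity between two words in an embedding store
#'
#' Looks both words up (case-folded, NFC-normalised) and returns the cosine
#' of their vectors, or `NA` when either word is missing, blank, or out of
#' vocabulary.
#'
#' @param store An `embedding_store`.
#' @param word1,word2 Words to compare.
#' @return A number in \[-1, 1\] (in \[0, 1\] for stores with non-negative
#'   geometry), or `NA`.
#' @export
embedding_cosine <- function(store, word1, word2) {
  stopifnot(inherits(store, "embedding_store"))
  if (is_blank(word1) || is_blank(word2)) return(NA_real_)
  vocab <- rownames(store$vectors)
  k1 <- match(nfc(stringr::str_to_lower(word1)), vocab)
  k2 <- match(nfc(stringr::str_to_lower(word2)), vocab)
  if (is.na(k1) || is.na(k2)) return(NA_real_)
  u <- store$vectors[k1, ]
  v <- store$vectors[k2, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Score target-response semantic similarity by embedding cosine
#'
#' Adds a `w2v_cos` column holding the cosine similarity between the target
#' and response word vectors. The cosine is `NA` when the item or response
#' is missing/blank or out of the store's vocabulary; `w2v_note` records
#' which. Downstream, [classify_errors()] treats a missing cosine as "not
#' semantically related".
#'
#' @param data Attempt table.
#' @param item_col,response_col Names of the target and response columns.
#' @param model An `embedding_store` from [read_embeddings()] or
#'   [make_toy_embeddings()].
#' @return The input tibble with `w2v_cos` and `w2v_note` appended.
#' @export
get_semantic_similarity <- function(data, item_col = "item",
                                    response_col = "response", model) {
  check_cols(data, c(item_col, response_col), "get_semantic_similarity()")
  if (!inherits(model, "embedding_store")) {
    stop_config("get_semantic_similarity(): `model` must be an embedding_store")
  }
  out <- tibble::as_tibble(data)
  items <- as.character(out[[item_col]])
  responses <- as.character(out[[response_col]])
  vocab <- rownames(model$vectors)
  key <- function(x) nfc(stringr::str_to_lower(x))
  out$w2v_cos <- purrr::map2_dbl(items, responses,
                                 function(a, b) embedding_cosine(model, a, b))
  oov_item <- !is_blank(items) & !(key(items) %in% vocab)
  oov_resp <- !is_blank(responses) & !(key(responses) %in% vocab)
  note <- rep(NA_character_, nrow(out))
  note[oov_resp] <- "response not in embedding vocabulary"
  note[oov_item] <- "item not in embedding vocabulary"
  note[oov_item & oov_resp] <- "item and response not in embedding vocabulary"
  note[is_blank(items) | is_blank(responses)] <- "missing item or response"
  note[!is.na(out$w2v_cos)] <- NA_character_
  out$w2v_note <- note
  out
}
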