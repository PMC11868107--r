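# Synthetic resources: toy lexicons, embedding stores with prescribed
# cosines, and simulated multi-attempt response tables with exact ground
# truth. Everything here is deterministic under a seed; the analysis stages
# themselves never draw random numbers.

# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a toy wordlist and frequency lexicon
#'
#' Deterministic stand-ins for the dictionary wordlist and the frequency
#' database used by [check_lexicality()]. When `frequencies` is omitted,
#' log10 frequencies are drawn uniformly on \[0.5, 3\] (the typical range of
#' log10 counts-per-million in lexical databases) under the given seed.
#'
#' @param words Character vector of words (no duplicates).
#' @param frequencies Optional numeric vector of log10 frequencies, one per
#'   word.
#' @param seed RNG seed for the default frequencies.
#' @return A list with `wordlist` (lowercase character vector) and
#'   `lexicon` (tibble with `word`, `log10_frq`).
#' @export
make_toy_lexicon <- function(words, frequencies = NULL, seed = 1L) {
  if (length(words) == 0L) stop_config("make_toy_lexicon(): `words` is empty")
  words_lc <- nfc(stringr::str_to_lower(words))
  if (anyDuplicated(words_lc) > 0L) {
    stop_config("make_toy_lexicon(): duplicated word(s): %s",
                paste(unique(words_lc[duplicated(words_lc)]), collapse = ", "))
  }
  if (is.null(frequencies)) {
    frequencies <- with_local_seed(seed, stats::runif(length(words_lc), 0.5, 3))
  }
  if (length(frequencies) != length(words_lc)) {
    stop_config("make_toy_lexicon(): `frequencies` must match `words` in length")
  }
  list(
    wordlist = words_lc,
    lexicon = tibble::tibble(word = words_lc, log10_frq = frequencies)
  )
}

#' Build an embedding store with prescribed pairwise cosines
#'
#' Constructs unit vectors for groups of words such that any two distinct
#' words in the same cluster have cosine exactly `within_cos` and any two
#' words from different clusters have cosine exactly `between_cos`. The
#' construction is geometric, not sampled: every word gets
#' \eqn{\sqrt{b}\,u + \sqrt{w-b}\,c_g + \sqrt{1-w}\,e_i} over orthonormal
#' axes (a global axis, one axis per cluster, one axis per word), so the
#' cosines are exact up to floating-point rounding. This makes it easy to
#' place word pairs deliberately above or below a semantic threshold such
#' as the classifier's default 0.46.
#'
#' @param clusters List of character vectors, one per cluster.
#' @param within_cos Target cosine within a cluster, in (0, 1\].
#' @param between_cos Target cosine across clusters, in \[0, `within_cos`).
#' @return An `embedding_store` whose cosines lie in \[0, 1\].
#' @examples
#' st <- make_toy_embeddings(list(c("table", "chair"), c("truck", "boat")))
#' embedding_cosine(st, "table", "chair") # 0.8
#' @export
make_toy_embeddings <- function(clusters, within_cos = 0.8, between_cos = 0.1) {
  words <- unlist(clusters, use.names = FALSE)
  if (length(words) == 0L) stop_config("make_toy_embeddings(): no words given")
  words_lc <- nfc(stringr::str_to_lower(words))
  if (anyDuplicated(words_lc) > 0L) {
    stop_config("make_toy_embeddings(): duplicated word(s) across clusters: %s",
                paste(unique(words_lc[duplicated(words_lc)]), collapse = ", "))
  }
  if (!(between_cos >= 0 && between_cos < within_cos && within_cos <= 1)) {
    stop_config(paste0("make_toy_embeddings(): need ",
                       "0 <= between_cos < within_cos <= 1 (got %s, %s)"),
                format(between_cos), format(within_cos))
  }
  g <- length(clusters)
  w <- length(words_lc)
  dim <- 1L + g + w
  alpha <- sqrt(between_cos)
  beta <- sqrt(within_cos - between_cos)
  gamma <- sqrt(1 - within_cos)
  mat <- matrix(0, nrow = w, ncol = dim)
  idx <- 0L
  for (gi in seq_len(g)) {
    for (word in clusters[[gi]]) {
      idx <- idx + 1L
      mat[idx, 1L] <- alpha
      mat[idx, 1L + gi] <- beta
      mat[idx, 1L + g + idx] <- gamma
    }
  }
  new_embedding_store(mat, words_lc)
}

#' Specify a response simulation
#'
#' Bundles and validates the parameters of [simulate_responses()].
#'
#' @param n_items Number of stimulus presentations to simulate.
#' @param attempts_per_item Either a single integer (fixed number of
#'   attempts for multi-attempt cells) or `list(dist = "geometric",
#'   prob = p)` for 1 + geometric attempts. Only items drawn as phonological
#'   nonword errors produce multi-attempt (conduite d'approche) cells;
#'   other categories yield single attempts.
#' @param error_mix Named proportions over the seven outcome categories
#'   (`no_response`, `nonword`, `neologism`, `formal`, `unrelated`,
#'   `semantic`, `mixed`); must sum to 1.
#' @param edit_rates Named probabilities over the corruption operations
#'   (`substitute`, `delete`, `insert`, `transpose`); must sum to 1.
#' @param cosine_limit_value,formal_threshold Thresholds the constructed
#'   responses are required to satisfy (matching the classifier defaults).
#' @param cda_monotone Require the realised proportion of correct
#'   characters to be non-decreasing across the attempts of a conduite
#'   d'approche (self-correction); set `FALSE` for negative controls.
#' @param max_retries Rejection-sampling cap per constructed response.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_items = 100L,
                            attempts_per_item = 3L,
                            error_mix = c(no_response = 0.05, nonword = 0.3,
                                          neologism = 0.1, formal = 0.15,
                                          unrelated = 0.1, semantic = 0.2,
                                          mixed = 0.1),
                            edit_rates = c(substitute = 0.5, delete = 0.2,
                                           insert = 0.2, transpose = 0.1),
                            cosine_limit_value = 0.46,
                            formal_threshold = 50,
                            cda_monotone = TRUE,
                            max_retries = 1000L,
                            seed = 1L) {
  if (!setequal(names(error_mix), error_categories())) {
    stop_config("simulation_spec(): `error_mix` must name exactly: %s",
                paste(error_categories(), collapse = ", "))
  }
  error_mix <- error_mix[error_categories()]
  if (any(error_mix < 0) || any(error_mix > 1) ||
      abs(sum(error_mix) - 1) > 1e-8) {
    stop_config("simulation_spec(): `error_mix` must be proportions summing to 1")
  }
  if (!setequal(names(edit_rates),
                c("substitute", "delete", "insert", "transpose"))) {
    stop_config("simulation_spec(): `edit_rates` must name substitute, delete, insert, transpose")
  }
  if (any(edit_rates < 0) || abs(sum(edit_rates) - 1) > 1e-8) {
    stop_config("simulation_spec(): `edit_rates` must be probabilities summing to 1")
  }
  if (is.numeric(attempts_per_item) && length(attempts_per_item) == 1L) {
    if (attempts_per_item < 1) {
      stop_config("simulation_spec(): `attempts_per_item` must be >= 1")
    }
  } else if (!(is.list(attempts_per_item) &&
               identical(attempts_per_item$dist, "geometric") &&
               is.numeric(attempts_per_item$prob) &&
               attempts_per_item$prob > 0 && attempts_per_item$prob <= 1)) {
    stop_config(paste0("simulation_spec(): `attempts_per_item` must be a ",
                       "single integer or list(dist = \"geometric\", prob = p)"))
  }
  check_thresholds(cosine_limit_value, formal_threshold)
  structure(list(n_items = as.integer(n_items),
                 attempts_per_item = attempts_per_item,
                 error_mix = error_mix, edit_rates = edit_rates,
                 cosine_limit_value = cosine_limit_value,
                 formal_threshold = formal_threshold,
                 cda_monotone = isTRUE(cda_monotone),
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a multi-attempt response table with known ground truth
#'
#' Generates stimulus presentations whose responses are *constructed* to
#' satisfy a drawn error category's defining inequalities, verified with the
#' package's own scorers during rejection sampling, so the ground truth is
#' exact. Real-word errors (formal, unrelated, semantic, mixed) are sampled
#' from the lexicon under the required formal-similarity and embedding-
#' cosine constraints; nonword errors are corruptions of the target via
#' seeded edit operations; neologisms are random strings sharing less than
#' the formal threshold of characters with the target. Items drawn as
#' phonological nonword errors may produce conduite-d'approche cells: several
#' attempts joined by `", "`, with (by default) non-decreasing proportion of
#' correct characters across attempts, emulating self-correction.
#'
#' @param spec A [simulation_spec()].
#' @param lexicon A list with `wordlist` and `lexicon`, as returned by
#'   [make_toy_lexicon()]; items are drawn from its wordlist.
#' @param embeddings An `embedding_store` covering the lexicon words.
#' @return A list with `responses` — a raw table of one row per presentation
#'   (columns `ID`, `task`, `item_ID`, `item`, `response`, `accessed`) —
#'   and `truth` — one row per attempt (`item_ID`, `attempt`, `response`,
#'   `category`, `pcc`).
#' @export
simulate_responses <- function(spec, lexicon, embeddings) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!inherits(embeddings, "embedding_store")) {
    stop_config("simulate_responses(): `embeddings` must be an embedding_store")
  }
  if (is.null(lexicon$wordlist) || length(lexicon$wordlist) == 0L) {
    stop_config("simulate_responses(): `lexicon` must come from make_toy_lexicon()")
  }
  with_local_seed(spec$seed, simulate_responses_impl(spec, lexicon, embeddings))
}

simulate_responses_impl <- function(spec, lexicon, embeddings) {
  wl <- lexicon$wordlist
  categories <- sample(error_categories(), spec$n_items, replace = TRUE,
                       prob = spec$error_mix)
  items <- sample(wl, spec$n_items, replace = TRUE)
  resp_rows <- vector("list", spec$n_items)
  truth_rows <- vector("list", spec$n_items)
  for (i in seq_len(spec$n_items)) {
    attempts <- build_attempts(categories[i], items[i], spec, wl, embeddings)
    cell <- paste(attempts, collapse = ", ")
    resp_rows[[i]] <- tibble::tibble(
      ID = "S01", task = "naming", item_ID = i, item = items[i],
      response = cell,
      accessed = as.integer(cell == items[i])
    )
    truth_rows[[i]] <- tibble::tibble(
      item_ID = i, attempt = seq_along(attempts), response = attempts,
      category = categories[i],
      pcc = purrr::map_dbl(attempts, function(r) {
        if (is_blank(r)) 0 else pcc(items[i], r)
      })
    )
  }
  list(responses = dplyr::bind_rows(resp_rows),
       truth = dplyr::bind_rows(truth_rows))
}

draw_n_attempts <- function(spec) {
  a <- spec$attempts_per_item
  if (is.numeric(a)) as.integer(a) else 1L + stats::rgeom(1L, a$prob)
}

build_attempts <- function(category, item, spec, wordlist, embeddings) {
  thr <- spec$formal_threshold
  climit <- spec$cosine_limit_value
  formally_related <- function(w) {
    shared_char_proportion(item, w) >= thr ||
      stringr::str_sub(w, 1L, 1L) == stringr::str_sub(item, 1L, 1L)
  }
  cos_to_item <- function(w) embedding_cosine(embeddings, item, w)
  pick_word <- function(keep) {
    cand <- wordlist[wordlist != item]
    cand <- cand[purrr::map_lgl(cand, keep)]
    if (length(cand) == 0L) {
      rlang::abort(
        sprintf(paste0("simulate_responses(): no lexicon word satisfies the ",
                       "'%s' constraints for item '%s'; extend the lexicon or ",
                       "embedding clusters"), category, item),
        class = "girasol_simulation_error")
    }
    sample(cand, 1L)
  }
  switch(
    category,
    no_response = "",
    formal = pick_word(function(w) {
      formally_related(w) && !is.na(cos_to_item(w)) && cos_to_item(w) < climit
    }),
    unrelated = pick_word(function(w) {
      !formally_related(w) && !is.na(cos_to_item(w)) && cos_to_item(w) < climit
    }),
    semantic = pick_word(function(w) {
      !formally_related(w) && !is.na(cos_to_item(w)) && cos_to_item(w) >= climit
    }),
    mixed = pick_word(function(w) {
      formally_related(w) && !is.na(cos_to_item(w)) && cos_to_item(w) >= climit
    }),
    neologism = make_neologism(item, spec, wordlist),
    nonword = make_nonword_cda(item, spec, wordlist)
  )
}

# A nonword sharing < formal_threshold percent of characters with the item.
make_neologism <- function(item, spec, wordlist) {
  alphabet <- letters
  len <- max(3L, stringr::str_length(item))
  for (try in seq_len(spec$max_retries)) {
    cand <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    if (!(cand %in% wordlist) && cand != item &&
        shared_char_proportion(item, cand) < spec$formal_threshold) {
      return(cand)
    }
  }
  rlang::abort("simulate_responses(): neologism construction exceeded max_retries; change parameters",
               class = "girasol_simulation_error")
}

# Apply n_edits random edit operations to a word.
corrupt_word <- function(word, n_edits, edit_rates) {
  chars <- chr_vec(word)
  alphabet <- letters
  ops <- names(edit_rates)
  for (e in seq_len(n_edits)) {
    op <- sample(ops, 1L, prob = edit_rates)
    n <- length(chars)
    if (op == "delete" && n <= 2L) op <- "substitute"
    if (op == "transpose" && n < 2L) op <- "substitute"
    if (op == "substitute") {
      i <- sample.int(n, 1L)
      chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
    } else if (op == "delete") {
      chars <- chars[-sample.int(n, 1L)]
    } else if (op == "insert") {
      i <- sample.int(n + 1L, 1L)
      chars <- append(chars, sample(alphabet, 1L), after = i - 1L)
    } else {
      i <- sample.int(n - 1L, 1L)
      chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
    }
  }
  paste(chars, collapse = "")
}

# One nonword attempt: a corruption of the item that stays formally related
# (shared-character proportion at or above the threshold) and non-lexical.
make_nonword_attempt <- function(item, n_edits, spec, wordlist) {
  for (try in seq_len(spec$max_retries)) {
    cand <- corrupt_word(item, n_edits, spec$edit_rates)
    if (!(cand %in% wordlist) && cand != item && nzchar(cand) &&
        shared_char_proportion(item, cand) >= spec$formal_threshold) {
      return(cand)
    }
  }
  rlang::abort("simulate_responses(): nonword construction exceeded max_retries; change parameters",
               class = "girasol_simulation_error")
}

# A conduite d'approche: k nonword attempts whose edit load decreases, so the
# expected proportion of correct characters rises towards the target.
make_nonword_cda <- function(item, spec, wordlist) {
  k <- draw_n_attempts(spec)
  edit_loads <- rev(seq_len(k))  # k edits down to 1
  for (try in seq_len(spec$max_retries)) {
    attempts <- purrr::map_chr(edit_loads, function(e) {
      make_nonword_attempt(item, e, spec, wordlist)
    })
    traj <- purrr::map_dbl(attempts, function(r) pcc(item, r))
    if (!spec$cda_monotone || k == 1L || all(diff(traj) >= 0)) {
      return(attempts)
    }
  }
  rlang::abort("simulate_responses(): monotone CdA construction exceeded max_retries; change parameters",
               class = "girasol_simulation_error")
}
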