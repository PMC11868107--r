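# Shared fixtures (built in code) and independent oracles.

# --- taxonomy exemplar resources -------------------------------------------
# A lexicon holding exactly the real words of the classic exemplars, and an
# embedding store placing chair (vs table) and furnace (vs furniture) above
# the default 0.46 cosine threshold, and truck and sneaker (vs table) below.
exemplar_resources <- function() {
  clusters <- list(
    c("table", "chair", "furniture", "furnace"),
    c("truck", "sneaker")
  )
  list(
    wordlist = unlist(clusters),
    embeddings = make_toy_embeddings(clusters, within_cos = 0.8,
                                     between_cos = 0.1)
  )
}

# --- simulation resources ---------------------------------------------------
# Two semantic clusters of nonsense CV words designed so that every word has
# at least one candidate of each real-word error type: a same-cluster
# same-initial partner (mixed), a same-cluster different-initial partner with
# under-threshold character overlap (semantic), a cross-cluster same-initial
# partner (formal), and a cross-cluster different-initial partner with
# under-threshold overlap (unrelated).
sim_resources <- function(seed = 1L) {
  clusters <- list(
    c("bafica", "bafima", "dosulo", "dosuto"),
    c("bejuge", "bejune", "darepa", "dareta")
  )
  lex <- make_toy_lexicon(unlist(clusters), seed = seed)
  emb <- make_toy_embeddings(clusters, within_cos = 0.8, between_cos = 0.1)
  list(lexicon = lex, embeddings = emb)
}

# Long attempt table from a simulation's ground truth (one row per attempt).
truth_long <- function(sim) {
  truth <- sim$truth
  names(truth)[names(truth) == "pcc"] <- "pcc_truth"
  items <- sim$responses[c("item_ID", "item")]
  out <- merge(truth, items, by = "item_ID", sort = FALSE)
  out <- out[order(out$item_ID, out$attempt), ]
  counts <- table(out$item_ID)
  out$RA <- as.integer(counts[as.character(out$item_ID)] > 1L)
  out$accessed <- as.integer(!is.na(out$response) & out$response == out$item)
  tibble::as_tibble(out)
}

# Run the scoring + classification stages on a long attempt table.
classify_long <- function(long, res,
                          cosine_limit_value = 0.46, formal_threshold = 50) {
  long |>
    get_formal_similarity(item_col = "item", response_col = "response",
                          attempt_col = "attempt",
                          group_cols = "item_ID") |>
    check_lexicality(item_col = "item", response_col = "response",
                     criterion = "dictionary",
                     wordlist = res$lexicon$wordlist) |>
    get_semantic_similarity(item_col = "item", response_col = "response",
                            model = res$embeddings) |>
    classify_errors(access_col = "accessed", RA_col = "RA",
                    item_col = "item", response_col = "response",
                    also_classify_RAs = TRUE,
                    cosine_limit_value = cosine_limit_value,
                    formal_threshold = formal_threshold)
}

error_category_cols <- c("no_response", "nonword", "neologism", "formal",
                         "unrelated", "semantic", "mixed")

recovered_category <- function(classified) {
  apply(classified[error_category_cols], 1L, function(r) {
    hit <- which(r == 1L)
    if (length(hit) == 1L) error_category_cols[hit] else NA_character_
  })
}

# --- independent oracles ----------------------------------------------------

split_chars <- function(x) strsplit(x, "")[[1]]

# Is s a subsequence of t?
is_subsequence <- function(s, t) {
  if (length(s) == 0L) return(TRUE)
  j <- 1L
  for (ch in t) {
    if (ch == s[j]) {
      j <- j + 1L
      if (j > length(s)) return(TRUE)
    }
  }
  FALSE
}

# Brute-force LCS length: enumerate all subsequences of the shorter string.
oracle_lcs_length <- function(a, b) {
  x <- split_chars(a); y <- split_chars(b)
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  n <- length(x)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    sel <- x[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(sel) > best && is_subsequence(sel, y)) best <- length(sel)
  }
  best
}

# Unrestricted Damerau-Levenshtein via the prefix recursion
#   d(i, j) = min(deletion, insertion, substitution,
#                 min over crossing matches k < i, l < j with
#                 a[k] == b[j], b[l] == a[i]:
#                 d(k-1, l-1) + (i-k-1) + 1 + (j-l-1))
# memoised over prefix pairs; an implementation independent of the
# alphabet-indexed dynamic programme used by the package.
oracle_dld <- function(a, b) {
  x <- split_chars(a); y <- split_chars(b)
  n <- length(x); m <- length(y)
  memo <- array(NA_integer_, dim = c(n + 1L, m + 1L))
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    if (i == 0L) { memo[i + 1L, j + 1L] <<- j; return(j) }
    if (j == 0L) { memo[i + 1L, j + 1L] <<- i; return(i) }
    best <- min(rec(i - 1L, j) + 1L,
                rec(i, j - 1L) + 1L,
                rec(i - 1L, j - 1L) + (x[i] != y[j]))
    for (k in seq_len(i - 1L)) {
      if (x[k] != y[j]) next
      for (l in seq_len(j - 1L)) {
        if (y[l] != x[i]) next
        best <- min(best, rec(k - 1L, l - 1L) + (i - k - 1L) + 1L + (j - l - 1L))
      }
    }
    memo[i + 1L, j + 1L] <<- best
    best
  }
  rec(n, m)
}

# Seeded sample of string pairs over a small alphabet.
random_string_pairs <- function(n_pairs, alphabet = c("a", "b", "c"),
                                max_len = 5L, seed = 42L) {
  set.seed(seed)
  rand_str <- function() {
    len <- sample(0:max_len, 1L)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }
  data.frame(a = replicate(n_pairs, rand_str()),
             b = replicate(n_pairs, rand_str()),
             stringsAsFactors = FALSE)
}
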