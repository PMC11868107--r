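#' @title Formal-similarity primitives between a target and a response string
#' @description
#' These functions score a single (target, response) pair of strings. They are
#' the building blocks used by [get_formal_similarity()] to score whole
#' assessment tables; they operate on Unicode code points, so broad phonemic
#' (IPA) transcriptions are handled like orthographic text (an affricate
#' written as two code points counts as two characters). Comparisons are
#' case-sensitive; fold case on read if needed.
#' @name string-metrics
NULL

# ---- internal scalar engines (character vectors in, numbers out) ----------

# Levenshtein distance, classic DP.
ld_impl <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j] + cost, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Unrestricted Damerau-Levenshtein distance (full variant: a transposed pair
# may be edited again), computed with the alphabet-indexed dynamic programme.
# With unit costs this recurrence is exact.
dld_impl <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  inf <- n + m
  # d has an extra sentinel row/column: d[i + 2, j + 2] holds the distance
  # between the first i characters of a and the first j characters of b.
  d <- matrix(0L, n + 2L, m + 2L)
  d[1L, ] <- inf
  d[, 1L] <- inf
  d[2L, 2L:(m + 2L)] <- 0:m
  d[2L:(n + 2L), 2L] <- 0:n
  alphabet <- unique(c(a, b))
  da <- stats::setNames(integer(length(alphabet)), alphabet)
  for (i in seq_len(n)) {
    db <- 0L
    for (j in seq_len(m)) {
      k <- da[[b[j]]]
      l <- db
      if (a[i] == b[j]) {
        cost <- 0L
        db <- j
      } else {
        cost <- 1L
      }
      d[i + 2L, j + 2L] <- min(
        d[i + 1L, j + 1L] + cost,                       # match / substitution
        d[i + 2L, j + 1L] + 1L,                         # insertion
        d[i + 1L, j + 2L] + 1L,                         # deletion
        d[k + 1L, l + 1L] + (i - k - 1L) + 1L + (j - l - 1L)  # transposition
      )
    }
    da[[a[i]]] <- i
  }
  d[n + 2L, m + 2L]
}

# Jaro similarity; standard matching-window definition.
jaro_impl <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L && m == 0L) return(1)
  if (n == 0L || m == 0L) return(0)
  window <- max(floor(max(n, m) / 2) - 1L, 0L)
  a_match <- logical(n); b_match <- logical(m)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window)
    hi <- min(m, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!b_match[j] && a[i] == b[j]) {
        a_match[i] <- TRUE
        b_match[j] <- TRUE
        break
      }
    }
  }
  mt <- sum(a_match)
  if (mt == 0L) return(0)
  # transpositions: half the number of out-of-order matched pairs
  t <- sum(a[a_match] != b[b_match]) / 2
  (mt / n + mt / m + (mt - t) / mt) / 3
}

jw_distance_impl <- function(a, b, prefix_scale = 0.1, max_prefix = 4L) {
  j <- jaro_impl(a, b)
  l <- 0L
  while (l < min(length(a), length(b), max_prefix) && a[l + 1L] == b[l + 1L]) {
    l <- l + 1L
  }
  1 - (j + l * prefix_scale * (1 - j))
}

# Suffix-distance table for the Levenshtein backtrace:
# D[i + 1, j + 1] = Ld(a[i+1..n], b[j+1..m]).
ld_suffix_table <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[n + 1L, ] <- m:0
  D[, m + 1L] <- n:0
  if (n > 0L && m > 0L) {
    for (i in n:1) {
      for (j in m:1) {
        cost <- if (a[i] == b[j]) 0L else 1L
        D[i, j] <- min(D[i + 1L, j + 1L] + cost,
                       D[i + 1L, j] + 1L,
                       D[i, j + 1L] + 1L)
      }
    }
  }
  D
}

# ---- exported operations ---------------------------------------------------

#' Proportion of shared characters between two strings
#'
#' Computes the shared-character proportion
#' \deqn{100 \cdot \frac{2\,SL}{NL_t + NL_r}}{100 * 2*SL / (NLt + NLr)}
#' where \eqn{SL} is the size of the multiset intersection of the two strings'
#' characters (order-independent: each character counts as many times as it
#' occurs in both strings) and \eqn{NL_t}, \eqn{NL_r} are the string lengths.
#' This is the proportion of shared letters (psl) on orthographic strings, or
#' of shared phonemes (psp) on broad phonemic transcriptions after
#' [strip_transcription_marks()].
#'
#' @param target,response Non-empty strings.
#' @return A percentage in \[0, 100\]; symmetric in its arguments.
#' @examples
#' shared_char_proportion("development", "intelligence") # 52.17
#' shared_char_proportion("rhino", "hippo")              # 60
#' @export
shared_char_proportion <- function(target, response) {
  if (is_blank(target) || is_blank(response)) {
    stop_data("shared_char_proportion() is undefined for empty strings")
  }
  a <- chr_vec(target)
  b <- chr_vec(response)
  ta <- table(a)
  tb <- table(b)
  shared_chars <- intersect(names(ta), names(tb))
  sl <- sum(pmin(ta[shared_chars], tb[shared_chars]))
  2 * sl / (length(a) + length(b)) * 100
}

#' Positionwise character matches between target and response
#'
#' Builds the binary match strings used for positional-accuracy analysis:
#' position \eqn{i} holds 1 iff both strings are at least \eqn{i} characters
#' long and carry the identical character there. The strict string spans
#' \code{max(targetL, responseL)} positions; the adjusted string is truncated
#' or padded to exactly the target's length, which is the reference unit for
#' the percentage.
#'
#' @param target Non-empty target string.
#' @param response Response string (may be empty: all positions are 0).
#' @return A list with components \code{strict_match_pos},
#'   \code{adj_strict_match_pos} (binary strings) and
#'   \code{p_shared_char_in_pos} (percent of target positions matched).
#' @examples
#' positional_match("mangrove", "mango")
#' @export
positional_match <- function(target, response) {
  if (is_blank(target)) {
    stop_data("positional_match() requires a non-empty target")
  }
  a <- chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  n <- length(a); m <- length(b)
  len <- max(n, m)
  hits <- integer(len)
  k <- min(n, m)
  if (k > 0L) hits[seq_len(k)] <- as.integer(a[seq_len(k)] == b[seq_len(k)])
  adj <- hits[seq_len(n)]
  adj[is.na(adj)] <- 0L  # defensive; cannot trigger since len >= n
  list(
    strict_match_pos = paste(hits, collapse = ""),
    adj_strict_match_pos = paste(adj, collapse = ""),
    p_shared_char_in_pos = 100 * sum(adj) / n
  )
}

#' Edit distances between target and response
#'
#' Computes the Levenshtein distance (insertions, deletions, substitutions),
#' the unrestricted Damerau-Levenshtein distance (additionally adjacent
#' transpositions, with no restriction against editing a transposed pair
#' again) and the Jaro-Winkler distance (1 minus the Jaro-Winkler similarity,
#' prefix scaling 0.1 over at most 4 characters, no boost threshold).
#'
#' @param target,response Strings; empty strings are allowed (the distance to
#'   an empty string is the other string's length; the Jaro-Winkler distance
#'   of two empty strings is 0, of an empty vs a non-empty string 1).
#' @return A list with integer components \code{Ld}, \code{DLd} and numeric
#'   \code{JWd}.
#' @examples
#' edit_distances("mangrove", "mango") # DLd = 3
#' edit_distances("ab", "ba")          # Ld = 2, DLd = 1
#' @export
edit_distances <- function(target, response) {
  a <- if (is.na(target)) character(0) else chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  list(
    Ld = as.integer(ld_impl(a, b)),
    DLd = as.integer(dld_impl(a, b)),
    JWd = jw_distance_impl(a, b)
  )
}

#' Longest common subsequence of two strings
#'
#' Returns one maximal-length common subsequence. Among equal-length ties the
#' backtrace is deterministic: the subsequence whose matched target indices
#' are lexicographically smallest (leftmost in the target) is returned.
#'
#' @param target,response Strings (possibly empty).
#' @return The longest common subsequence as a single string.
#' @examples
#' lcs_string("mangrove", "mango") # "mang"
#' @export
lcs_string <- function(target, response) {
  a <- if (is.na(target)) character(0) else chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return("")
  # L[i, j] = LCS length of a[i..n] vs b[j..m]
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1) {
    for (j in m:1) {
      L[i, j] <- if (a[i] == b[j]) L[i + 1L, j + 1L] + 1L
                 else max(L[i + 1L, j], L[i, j + 1L])
    }
  }
  out <- character(0)
  i <- 1L; j <- 1L
  while (i <= n && j <= m && L[i, j] > 0L) {
    if (a[i] == b[j] && L[i, j] == L[i + 1L, j + 1L] + 1L) {
      out <- c(out, a[i])
      i <- i + 1L; j <- j + 1L
    } else if (L[i, j + 1L] == L[i, j]) {
      # skipping the response character keeps the current target character
      # available, which yields the leftmost-in-target tie-break
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Longest common substring of two strings
#'
#' Returns the longest *contiguous* run of characters common to both strings
#' (leftmost in the target among equal-length ties). This is the variant
#' reported in the `lcs` column of [get_formal_similarity()]: for clinical
#' scoring the preserved contiguous fragment of the target (e.g. \code{"mang"}
#' for mangrove vs mango) is usually the quantity of interest, whereas
#' [lcs_string()] may splice in characters matched far apart.
#'
#' @param target,response Strings (possibly empty).
#' @return The longest common substring as a single string.
#' @examples
#' lcs_substring("mangrove", "mango") # "mang"
#' @export
lcs_substring <- function(target, response) {
  a <- if (is.na(target)) character(0) else chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return("")
  # L[i, j] = length of the common suffix of a[1..i] and b[1..j]
  prev <- integer(m + 1L)
  best_len <- 0L
  best_end <- 0L
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      if (a[i] == b[j]) {
        cur[j + 1L] <- prev[j] + 1L
        if (cur[j + 1L] > best_len) {
          best_len <- cur[j + 1L]
          best_end <- i
        }
      }
    }
    prev <- cur
  }
  if (best_len == 0L) return("")
  paste(a[(best_end - best_len + 1L):best_end], collapse = "")
}

#' Alignment trace between target and response
#'
#' Backtraces the Levenshtein dynamic programme into one symbol per edit-script
#' step: \code{M} (match), \code{S} (substitution), \code{D} (deletion of a
#' target character), \code{I} (insertion of a response character). At equal
#' cost, the tie-break priority is M > S > D > I, so the trace is
#' deterministic. The number of M + S + D symbols equals the target length and
#' M + S + I the response length; the number of non-M symbols equals the
#' Levenshtein distance.
#'
#' @param target,response Strings (possibly empty).
#' @return A trace string over the alphabet \{M, D, S, I\}.
#' @examples
#' similarity_trace("mangrove", "mango")
#' similarity_trace("abc", "abc") # "MMM"
#' @export
similarity_trace <- function(target, response) {
  a <- if (is.na(target)) character(0) else chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  n <- length(a); m <- length(b)
  D <- ld_suffix_table(a, b)
  out <- character(0)
  i <- 1L; j <- 1L
  while (i <= n || j <= m) {
    if (i <= n && j <= m && a[i] == b[j] && D[i, j] == D[i + 1L, j + 1L]) {
      out <- c(out, "M"); i <- i + 1L; j <- j + 1L
    } else if (i <= n && j <= m && D[i, j] == D[i + 1L, j + 1L] + 1L) {
      out <- c(out, "S"); i <- i + 1L; j <- j + 1L
    } else if (i <= n && D[i, j] == D[i + 1L, j] + 1L) {
      out <- c(out, "D"); i <- i + 1L
    } else {
      out <- c(out, "I"); j <- j + 1L
    }
  }
  paste(out, collapse = "")
}

#' Proportion of correct characters
#'
#' One minus the unrestricted Damerau-Levenshtein distance divided by the
#' target length, floored at 0 so the index stays in \[0, 1\]. On phonemic
#' transcriptions this is the proportion of correct phonemes; on orthographic
#' strings, of correct letters.
#'
#' @param target Non-empty target string.
#' @param response Response string (may be empty: pcc is 0).
#' @return A proportion in \[0, 1\]; 1 iff the strings are identical.
#' @examples
#' pcc("mangrove", "mango") # 1 - 3/8
#' @export
pcc <- function(target, response) {
  if (is_blank(target)) {
    stop_data("pcc() requires a non-empty target")
  }
  a <- chr_vec(target)
  b <- if (is.na(response)) character(0) else chr_vec(response)
  max(0, 1 - dld_impl(a, b) / length(a))
}
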