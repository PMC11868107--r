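test_that("shared-character proportion reproduces the worked examples", {
  expect_equal(round(shared_char_proportion("development", "intelligence"), 2),
               52.17)
  expect_equal(shared_char_proportion("rhino", "hippo"), 60)
  # broad phonemic transcriptions, after explicit stress/syllable stripping
  psp <- shared_char_proportion(
    strip_transcription_marks("dɪˈvɛl.əp.mənt"),
    strip_transcription_marks("ɪnˈtɛl.ɪ.dʒəns"))
  expect_equal(round(psp, 2), 63.64)
  psp2 <- shared_char_proportion(
    strip_transcription_marks("ˈraɪnoʊ"),
    strip_transcription_marks("ˈhɪpoʊ"))
  expect_equal(round(psp2, 2), 54.55)
  expect_equal(shared_char_proportion("ab", "ab"), 100)
  expect_equal(shared_char_proportion("ab", "cd"), 0)
})

test_that("shared-character proportion counts multiset overlap and is symmetric", {
  # repeated letters count once per occurrence in both strings
  expect_equal(shared_char_proportion("aab", "abb"), 2 * 2 / 6 * 100)
  pairs <- random_string_pairs(40, max_len = 5L, seed = 7L)
  pairs <- pairs[nzchar(pairs$a) & nzchar(pairs$b), ]
  for (i in seq_len(nrow(pairs))) {
    expect_equal(shared_char_proportion(pairs$a[i], pairs$b[i]),
                 shared_char_proportion(pairs$b[i], pairs$a[i]))
  }
  expect_error(shared_char_proportion("", "abc"), class = "girasol_data_error")
})

test_that("positional match strings follow the target-length convention", {
  pm <- positional_match("mangrove", "mango")
  expect_equal(pm$adj_strict_match_pos, "11110000")
  expect_equal(pm$p_shared_char_in_pos, 50)

  expect_equal(positional_match("abc", "abc")$adj_strict_match_pos, "111")
  expect_equal(positional_match("abc", "abc")$p_shared_char_in_pos, 100)

  # response longer than target: strict spans the longer string, the
  # adjusted string exactly the target
  pm2 <- positional_match("ab", "abcd")
  expect_equal(pm2$strict_match_pos, "1100")
  expect_equal(pm2$adj_strict_match_pos, "11")
  expect_equal(pm2$p_shared_char_in_pos, 100)

  expect_error(positional_match("", "x"), class = "girasol_data_error")
})

test_that("edit distances match the worked examples and conventions", {
  expect_equal(edit_distances("mangrove", "mango")$DLd, 3L)
  ed <- edit_distances("ab", "ba")
  expect_equal(ed$Ld, 2L)
  expect_equal(ed$DLd, 1L)
  ed0 <- edit_distances("abc", "")
  expect_equal(ed0$Ld, 3L)
  expect_equal(ed0$DLd, 3L)
  expect_equal(ed0$JWd, 1)
  expect_equal(edit_distances("abc", "abc")$JWd, 0)
  # standard Jaro-Winkler hand evaluation: jaro = 17/18, prefix 3
  expect_equal(edit_distances("martha", "marhta")$JWd,
               1 - (17 / 18 + 3 * 0.1 * (1 - 17 / 18)),
               tolerance = 1e-12)
  # unrestricted variant: a transposed pair may be edited again
  expect_equal(edit_distances("ca", "abc")$DLd, 2L)
  expect_equal(edit_distances("ca", "abc")$Ld, 3L)
})

test_that("longest common subsequence uses the leftmost backtrace", {
  expect_equal(lcs_string("abc", "abc"), "abc")
  expect_equal(lcs_string("abcd", "acbd"), "abd")
  expect_equal(lcs_string("mangrove", "mango"), "mango")
  expect_equal(lcs_string("", "abc"), "")
})

test_that("longest common substring reproduces the contiguous worked example", {
  expect_equal(lcs_substring("mangrove", "mango"), "mang")
  expect_equal(lcs_substring("abcd", "acbd"), "a")
  expect_equal(lcs_substring("xyz", "abc"), "")
})

test_that("alignment traces are minimal and account for both strings", {
  tr <- similarity_trace("mangrove", "mango")
  counts <- table(factor(split_chars(tr), levels = c("M", "D", "S", "I")))
  expect_equal(sum(counts[c("M", "S", "D")]), 8)
  expect_equal(sum(counts[c("M", "S", "I")]), 5)
  expect_equal(sum(counts[c("S", "D", "I")]),
               edit_distances("mangrove", "mango")$Ld)
  expect_equal(similarity_trace("abc", "abc"), "MMM")
  expect_equal(similarity_trace("a", "b"), "S")
})

test_that("pcc is one minus normalised distance, floored at zero", {
  expect_equal(pcc("mangrove", "mango"), 1 - 3 / 8)
  expect_equal(pcc("abc", "abc"), 1)
  expect_equal(pcc("ab", "wxyz"), 0)
  expect_error(pcc("", "x"), class = "girasol_data_error")
})

test_that("appending the correct next target character never decreases pcc", {
  words <- c("taladro", "mangrove", "bamete", "abcab")
  for (w in words) {
    n <- nchar(w)
    vals <- vapply(seq_len(n), function(k) pcc(w, substr(w, 1, k)), numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("distances and subsequence lengths agree with independent oracles", {
  pairs <- random_string_pairs(120, max_len = 5L, seed = 11L)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    ed <- edit_distances(a, b)
    expect_equal(ed$Ld, drop(utils::adist(a, b)), info = paste(a, b))
    expect_equal(ed$DLd, oracle_dld(a, b), info = paste(a, b))
    expect_lte(ed$DLd, ed$Ld)
    expect_equal(nchar(lcs_string(a, b)), oracle_lcs_length(a, b),
                 info = paste(a, b))
    # symmetry
    ed_rev <- edit_distances(b, a)
    expect_equal(ed$Ld, ed_rev$Ld)
    expect_equal(ed$DLd, ed_rev$DLd)
    expect_equal(ed$JWd, ed_rev$JWd)
    # lcs is a subsequence of both strings
    expect_true(is_subsequence(split_chars(lcs_string(a, b)), split_chars(a)))
    expect_true(is_subsequence(split_chars(lcs_string(a, b)), split_chars(b)))
    # the trace consumes both strings at cost Ld
    tr <- split_chars(similarity_trace(a, b))
    expect_equal(sum(tr %in% c("M", "S", "D")), nchar(a))
    expect_equal(sum(tr %in% c("M", "S", "I")), nchar(b))
    expect_equal(sum(tr != "M"), ed$Ld)
  }
})
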