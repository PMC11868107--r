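# A fully scored one-row table for classifier tests.
scored_row <- function(item, response, accessed = 0, RA = 0, wordlist,
                       embeddings) {
  tibble::tibble(item = item, response = response,
                 accessed = accessed, RA = RA, attempt = 1L, id = 1L) |>
    get_formal_similarity() |>
    check_lexicality(criterion = "dictionary", wordlist = wordlist) |>
    get_semantic_similarity(model = embeddings)
}

test_that("the canonical exemplars land in their categories", {
  res <- exemplar_resources()
  cases <- tibble::tibble(
    response = c("tagle", "timos", "truck", "chair", "sneaker", ""),
    item = "table",
    expected = c("nonword", "neologism", "formal", "semantic",
                 "unrelated", "no_response"))
  cases <- rbind(cases,
                 tibble::tibble(response = "furnace", item = "furniture",
                                expected = "mixed"))
  for (i in seq_len(nrow(cases))) {
    out <- scored_row(cases$item[i], cases$response[i],
                      wordlist = res$wordlist,
                      embeddings = res$embeddings) |>
      classify_errors()
    got <- recovered_category(out)
    expect_equal(got, cases$expected[i],
                 info = paste(cases$item[i], "->", cases$response[i]))
    expect_equal(out$check_comment, "")
  }
})

test_that("accessed responses and literal matches are never error-coded", {
  res <- exemplar_resources()
  # annotated as accessed even though the string differs (dialectal variant)
  out <- scored_row("table", "chair", accessed = 1,
                    wordlist = res$wordlist, embeddings = res$embeddings) |>
    classify_errors()
  expect_true(all(out[error_category_cols] == 0))
  expect_equal(out$check_comment, "")
  # equality implies correct even with accessed = 0
  out2 <- scored_row("table", "table", accessed = 0,
                     wordlist = res$wordlist, embeddings = res$embeddings) |>
    classify_errors()
  expect_true(all(out2[error_category_cols] == 0))
})

test_that("repeated attempts can be excluded from classification", {
  res <- exemplar_resources()
  out <- scored_row("table", "truck", RA = 1,
                    wordlist = res$wordlist, embeddings = res$embeddings) |>
    classify_errors(also_classify_RAs = FALSE)
  expect_true(all(out[error_category_cols] == 0))
  expect_equal(out$check_comment, "is only considered as RA")
  # with the flag on, the same row is classified
  out2 <- scored_row("table", "truck", RA = 1,
                     wordlist = res$wordlist, embeddings = res$embeddings) |>
    classify_errors(also_classify_RAs = TRUE)
  expect_equal(recovered_category(out2), "formal")
})

test_that("unclassifiable rows are flagged as required", {
  res <- exemplar_resources()
  row <- scored_row("table", "truck",
                    wordlist = res$wordlist, embeddings = res$embeddings)
  row$lexicality <- NA_integer_
  out <- classify_errors(row)
  expect_true(all(out[error_category_cols] == 0))
  expect_equal(out$check_comment, "required")
})

test_that("out-of-vocabulary real words are unclassified semantically, with a note", {
  res <- exemplar_resources()
  wordlist <- c(res$wordlist, "iguana")  # real word, no embedding vector
  out <- scored_row("table", "iguana", wordlist = wordlist,
                    embeddings = res$embeddings) |>
    classify_errors()
  # not semantically related by convention; iguana shares no formal relation
  expect_equal(recovered_category(out), "unrelated")
  expect_match(out$classification_note, "out of vocabulary")
  expect_equal(out$check_comment, "")
})

test_that("the pipeline order is enforced by name", {
  df <- tibble::tibble(item = "a", response = "b", accessed = 0, RA = 0)
  expect_error(classify_errors(df), "get_formal_similarity")
  scored <- get_formal_similarity(df)
  expect_error(classify_errors(scored), "check_lexicality")
})

test_that("the regular classifier matches the RA-aware one on single responses", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 40, attempts_per_item = 1, seed = 11)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  long <- truth_long(sim)
  scored <- long |>
    get_formal_similarity(attempt_col = "attempt", group_cols = "item_ID") |>
    check_lexicality(criterion = "dictionary",
                     wordlist = res$lexicon$wordlist) |>
    get_semantic_similarity(model = res$embeddings)
  a <- classify_errors(scored, also_classify_RAs = TRUE)
  b <- classify_errors_regular(scored)
  keep <- a$RA == 0
  expect_equal(as.data.frame(a[keep, error_category_cols]),
               as.data.frame(b[keep, error_category_cols]))
})

test_that("every erroneous attempt gets exactly one category or a flag", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 60, attempts_per_item = 2, seed = 2)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  out <- classify_long(truth_long(sim), res)
  erroneous <- out$accessed != 1
  n_cats <- rowSums(out[error_category_cols])
  expect_true(all(n_cats[erroneous] == 1 |
                    out$check_comment[erroneous] == "required"))
  expect_true(all(n_cats[!erroneous] == 0))
})

test_that("raising the cosine threshold only demotes semantic relatedness", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 50, attempts_per_item = 1, seed = 3)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  long <- truth_long(sim)
  lo <- classify_long(long, res, cosine_limit_value = 0.3)
  hi <- classify_long(long, res, cosine_limit_value = 0.9)
  from_lo <- recovered_category(lo)
  from_hi <- recovered_category(hi)
  legal <- c("mixed->formal", "semantic->unrelated")
  moved <- which(from_lo != from_hi)
  expect_true(all(paste0(from_lo[moved], "->", from_hi[moved]) %in% legal))
})
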