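test_that("toy lexicons are deterministic and validated", {
  lex <- make_toy_lexicon(c("mesa", "silla", "taladro"),
                          frequencies = c(1, 2, 3))
  expect_equal(lex$wordlist, c("mesa", "silla", "taladro"))
  expect_equal(lex$lexicon$log10_frq, c(1, 2, 3))
  expect_error(make_toy_lexicon(c("mesa", "Mesa")),
               class = "girasol_config_error")
  # default frequencies are reproducible from the seed
  a <- make_toy_lexicon(c("a", "b"), seed = 4)
  b <- make_toy_lexicon(c("a", "b"), seed = 4)
  expect_identical(a, b)
})

test_that("toy embeddings hit the prescribed cosines exactly", {
  st <- make_toy_embeddings(list(c("cat", "dog", "cow"), c("saw", "axe")),
                            within_cos = 0.8, between_cos = 0.1)
  expect_equal(embedding_cosine(st, "cat", "dog"), 0.8, tolerance = 1e-6)
  expect_equal(embedding_cosine(st, "dog", "cow"), 0.8, tolerance = 1e-6)
  expect_equal(embedding_cosine(st, "cat", "axe"), 0.1, tolerance = 1e-6)
  expect_equal(embedding_cosine(st, "saw", "axe"), 0.8, tolerance = 1e-6)
  expect_equal(embedding_cosine(st, "cat", "cat"), 1)
  # all vectors are unit length
  expect_equal(unname(sqrt(rowSums(st$vectors^2))), rep(1, 5))
})

test_that("degenerate and infeasible cosine requests are handled", {
  one <- make_toy_embeddings(list(c("a", "b")), within_cos = 1,
                             between_cos = 0)
  expect_equal(unname(one$vectors["a", ]), unname(one$vectors["b", ]))
  expect_error(make_toy_embeddings(list("a", "b"), within_cos = 0.3,
                                   between_cos = 0.5),
               class = "girasol_config_error")
  expect_error(make_toy_embeddings(list(c("a", "a"))),
               class = "girasol_config_error")
})

test_that("simulations are byte-identical under a fixed seed", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 25, seed = 99)
  s1 <- simulate_responses(spec, res$lexicon, res$embeddings)
  s2 <- simulate_responses(spec, res$lexicon, res$embeddings)
  expect_identical(s1, s2)
})

test_that("every generated response satisfies its category's inequalities", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 80, attempts_per_item = 3, seed = 7)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  long <- truth_long(sim)
  wl <- res$lexicon$wordlist
  for (i in seq_len(nrow(long))) {
    item <- long$item[i]; r <- long$response[i]; cat <- long$category[i]
    if (cat == "no_response") {
      expect_equal(r, "")
      next
    }
    psc <- shared_char_proportion(item, r)
    s1c <- substr(r, 1, 1) == substr(item, 1, 1)
    cos <- embedding_cosine(res$embeddings, item, r)
    lexical <- r %in% wl
    switch(cat,
      nonword = expect_true(!lexical && psc >= 50),
      neologism = expect_true(!lexical && psc < 50),
      formal = expect_true(lexical && (psc >= 50 || s1c) && cos < 0.46),
      unrelated = expect_true(lexical && psc < 50 && !s1c && cos < 0.46),
      semantic = expect_true(lexical && psc < 50 && !s1c && cos >= 0.46),
      mixed = expect_true(lexical && (psc >= 50 || s1c) && cos >= 0.46))
  }
})

test_that("conduite d'approche trajectories rise monotonically by default", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 40, attempts_per_item = 4,
                          error_mix = c(no_response = 0, nonword = 1,
                                        neologism = 0, formal = 0,
                                        unrelated = 0, semantic = 0, mixed = 0),
                          seed = 13)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  diffs <- tapply(sim$truth$pcc, sim$truth$item_ID, diff)
  expect_true(all(unlist(diffs) >= 0))
  # multi-attempt cells join attempts with the standard delimiter
  multi <- sim$responses$response[1]
  expect_equal(length(strsplit(multi, ", ", fixed = TRUE)[[1]]), 4L)
})

test_that("a pure no-response mix yields empty cells", {
  res <- sim_resources()
  spec <- simulation_spec(n_items = 10,
                          error_mix = c(no_response = 1, nonword = 0,
                                        neologism = 0, formal = 0,
                                        unrelated = 0, semantic = 0, mixed = 0),
                          seed = 1)
  sim <- simulate_responses(spec, res$lexicon, res$embeddings)
  expect_true(all(sim$responses$response == ""))
  expect_true(all(sim$truth$category == "no_response"))
})

test_that("infeasible constructions raise a simulation error", {
  # a single-cluster store leaves no under-threshold words for the
  # 'unrelated' category
  lex <- make_toy_lexicon(c("bamete", "bamelo"))
  emb <- make_toy_embeddings(list(c("bamete", "bamelo")),
                             within_cos = 0.8, between_cos = 0.1)
  spec <- simulation_spec(n_items = 5,
                          error_mix = c(no_response = 0, nonword = 0,
                                        neologism = 0, formal = 0,
                                        unrelated = 1, semantic = 0, mixed = 0),
                          seed = 1)
  expect_error(simulate_responses(spec, lex, emb),
               class = "girasol_simulation_error")
})

test_that("simulation specs are validated", {
  expect_error(simulation_spec(error_mix = c(no_response = 1)),
               class = "girasol_config_error")
  expect_error(simulation_spec(edit_rates = c(substitute = 2, delete = 0,
                                              insert = 0, transpose = -1)),
               class = "girasol_config_error")
  expect_error(simulation_spec(attempts_per_item = 0),
               class = "girasol_config_error")
  expect_error(simulation_spec(attempts_per_item = list(dist = "poisson")),
               class = "girasol_config_error")
})
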