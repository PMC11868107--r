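# girasol

Scoring and classification of single-word production errors in aphasia and
related disorders, for clinicians and psycholinguists who work with
transcribed naming, repetition, reading or spelling data — including data
with **repeated attempts** (conduites d'approche), where a participant
produces several successive approximations to one target
("*talablo, talabro, taladro*" for *taladro*).

The package covers the full workflow:

1. **Wrangle** multi-attempt response cells into a long table of single
   attempts with repetition metadata (`separate_responses()`,
   `get_attempts()`).
2. **Score** each target–response pair with a battery of formal-similarity
   indexes (`get_formal_similarity()`), and explode per-position accuracy
   (`positional_accuracy()`, `positional_summary()`).
3. **Classify** each attempt into the standard error taxonomy — no
   response, phonemic nonword, neologism, formal, unrelated, semantic,
   mixed — from lexicality, formal and semantic evidence
   (`check_lexicality()`, `get_semantic_similarity()`,
   `classify_errors()`).

## The indexes

For a target $t$ (length $NL_t$) and response $r$ (length $NL_r$), the
central quantities are:

- proportion of shared letters/phonemes
  $\mathrm{psl} = \frac{2\,SL}{NL_t + NL_r}\times 100$, with $SL$ the
  multiset intersection of characters — e.g. 52.17% for
  *development*/*intelligence*, 60% for *rhino*/*hippo*;
- positionwise hits adjusted to the target's length — `11110000` (50%) for
  *mangrove*/*mango*;
- Levenshtein, unrestricted Damerau–Levenshtein and Jaro–Winkler distances,
  and the proportion of correct characters
  $\mathrm{pcc} = 1 - DLd/NL_t$;
- longest common substring/subsequence and a deterministic M/D/S/I
  alignment trace;
- `approach_diff`, the change in pcc between consecutive attempts of one
  presentation — the quantity of interest when asking whether production
  quality improves across a conduite d'approche.

Strings are compared code point by code point, so broad IPA transcriptions
work exactly like orthography (strip stress/syllable marks first with
`strip_transcription_marks()`). Semantic relatedness is the cosine between
word2vec-style embedding vectors (`read_embeddings()`), thresholded at 0.46
by default for models with cosines in [0, 1].

## Worked example

```r
library(girasol)
library(tibble)

raw <- tibble(
  ID = "P01", task = "naming", item_ID = 1:3,
  item     = c("taladro", "peine", "mesa"),
  response = c("talablo, talabro, taladro", "pente", "silla"),
  accessed = 0)

wordlist <- c("taladro", "peine", "mesa", "silla", "pinza", "martillo")
store <- make_toy_embeddings(
  list(c("mesa", "silla"), c("taladro", "martillo", "pinza"), c("peine")),
  within_cos = 0.8, between_cos = 0.1)

raw |>
  separate_responses(col_name = "response", separate_with = ", ") |>
  get_attempts(drop_blank_spaces = TRUE) |>
  get_formal_similarity(item_col = "item", response_col = "response",
                        attempt_col = "attempt",
                        group_cols = c("ID", "item_ID")) |>
  check_lexicality(criterion = "dictionary", wordlist = wordlist) |>
  get_semantic_similarity(model = store) |>
  classify_errors()
```

The key columns of the result:

```
  item    response    RA attempt p_shared_char   DLd   pcc approach_diff lexicality w2v_cos nonword semantic
1 taladro talablo      1       1          71.4     2 0.714        NA              0    NA         1        0
2 taladro talabro      1       2          85.7     1 0.857         0.143          0    NA         1        0
3 taladro taladro      1       3         100       0 1             0.143          1     1         0        0
4 peine   pente        0       1          80       2 0.6          NA              0    NA         1        0
5 mesa    silla        0       1          44.4     4 0            NA              1     0.8       0        1
```

Reading it: the conduite d'approche for *taladro* improves by 0.143 pcc per
attempt until the target is reached (the final attempt equals the item, so
no error is coded); *talablo* and *talabro* are nonwords sharing ≥ 50% of
the target's characters, hence phonemic nonword errors, as is *pente* for
*peine*; *silla* for *mesa* is a real word, formally unrelated (44.4%
shared, different initial) but with embedding cosine 0.8 above the 0.46
threshold — a semantic error.

The same pipeline runs in one call via `run_pipeline(raw, pipeline_config(...))`,
or from a shell via the `girasol` script.

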