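---
title: "Scoring and classifying single-word production errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying single-word production errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girasol)
library(tibble)
```

## The problem

In aphasia and related disorders (conduction aphasia, apraxia of speech,
stuttering, developmental language disorders), single-word production is
assessed by comparing what a person said or wrote against a target word.
Coding those responses by hand — is *tagle* a phonologically related nonword
or a neologism? how close is attempt three to the target compared with
attempt two? — is slow and unreliable, particularly when a single stimulus
draws several successive attempts, as in a *conduite d'approche* (CdA):
"*talablo, talabro, talabro, taladro, taladro*" for *taladro*.

girasol automates this workflow in three steps, each a pure function of a
table and its configuration:

1. **wrangle** — split multi-attempt response cells and pivot to one row per
   attempt, with repetition metadata (`RA`, `attempt`);
2. **score** — compute formal-similarity indexes between target and response
   strings, plus per-position accuracy;
3. **classify** — combine lexicality, formal similarity and embedding-based
   semantic similarity into the standard seven-way error taxonomy
   (no response, phonemic nonword, neologism, formal, unrelated, semantic,
   mixed).

## Units of comparison

All scoring operates on **Unicode code points**, case-sensitively. This
choice matters for broad phonemic (IPA) transcriptions: an affricate written
as two code points (d + ʒ) counts as two characters. That convention is what
makes the shared-phoneme computation below come out at 63.64% rather than
some other figure, and it extends unchanged to orthographic text. Inputs read
through `read_table()` are NFC-normalised so composed and decomposed accents
compare equal; a fold-to-lowercase step, if wanted, belongs at read time.

Stress marks (ˈ ˌ) and syllable separators (.) in transcriptions are removed
by an explicit call to `strip_transcription_marks()` — scoring functions
never strip anything silently, so what you score is exactly what you see.

A note on one transcription: the shared-phoneme proportion of
*development*/*intelligence* equals 63.64% only for the full transcription
/ɪnˈtɛl.ɪ.dʒəns/ (11 code points after mark removal). A variant sometimes
printed without the initial vowel, /nˈtɛl.ɪ.dʒəns/, cannot produce that
figure; we treat it as a typo and use the full form.

## The formal index battery

For a target $t$ of length $NL_t$ and response $r$ of length $NL_r$,
`get_formal_similarity()` computes:

* **p_shared_char** — the proportion of shared characters,
  $\mathrm{psl} = \frac{2\,SL}{NL_t + NL_r} \times 100$, where $SL$ is the
  *multiset* intersection size of the two strings' characters
  (order-independent; a letter occurring twice in both strings counts
  twice). On orthography this is the proportion of shared letters (psl), on
  transcriptions the proportion of shared phonemes (psp).

```{r psl}
shared_char_proportion("development", "intelligence")
shared_char_proportion(strip_transcription_marks("dɪˈvɛl.əp.mənt"),
                       strip_transcription_marks("ɪnˈtɛl.ɪ.dʒəns"))
```

* **strict_match_pos / adj_strict_match_pos / p_shared_char_in_pos** —
  position-by-position hits: position $i$ is 1 iff both strings carry the
  identical character there. The strict string spans
  $\max(NL_t, NL_r)$ positions; the adjusted string exactly $NL_t$, and the
  percentage of 1s in it (denominator $NL_t$) is the positional accuracy.
  The target is the reference unit throughout; this keeps the adjusted
  string, the percentage and the per-position explosion mutually consistent.

* **Ld, DLd, JWd** — Levenshtein; unrestricted Damerau–Levenshtein; and
  Jaro–Winkler distance with the standard parameters (prefix scaling 0.1,
  maximum prefix 4, no boost threshold). We implement the *unrestricted*
  (full) Damerau–Levenshtein variant, in which a transposed pair may be
  edited again, because transposition is a first-class edit operation on a
  par with the other three, with no adjacency-reuse restriction: e.g.
  `edit_distances("ca", "abc")$DLd` is `r edit_distances("ca", "abc")$DLd`,
  while the restricted (optimal string alignment) variant would give 3.
  Both distances are validated in the test suite against brute-force
  oracles over a small alphabet.

* **pcc** — proportion of correct characters, $1 - DLd/NL_t$, floored at 0.
  The denominator is the *target* length, consistent with the target being
  the reference unit everywhere else; the floor keeps the index in $[0,1]$
  when a response is much longer than its target. (Definitions of pcc vary
  in their denominator; if a different convention is needed the raw `DLd`
  and `targetL` columns are there to recompute it.)

* **lcs** — the longest *contiguous* stretch of characters common to both
  strings (`lcs_substring()`): for *mangrove*/*mango* this is the preserved
  fragment "mang". The classical longest common *subsequence* is available
  as `lcs_string()`; it may splice characters matched far apart ("mango"
  for the same pair, because the later *o* also matches), which is usually
  not what a clinician means by the preserved portion of a production. Both
  backtraces are deterministic (leftmost in the target among ties).

* **similarity_str** — a Levenshtein alignment trace over
  {M, D, S, I}; tie-break priority M > S > D > I at equal cost, which makes
  the trace reproducible run to run.

* **approach_diff** — within each group (the `group_cols` identifiers plus
  the target item), attempts are ordered by attempt number and
  `approach_diff` is $\Delta$pcc between consecutive attempts. Grouping by
  every identifier that distinguishes presentations (participant, item,
  task, date) is essential: otherwise attempt 2 of one assessment would be
  compared with attempt 1 of another. Duplicate (group, attempt) keys are a
  data-integrity error, not silently averaged. The telescoping identity
  $\sum_{k\ge 2} \Delta\mathrm{pcc}_k = \mathrm{pcc}_{last} -
  \mathrm{pcc}_{first}$ is checked in the tests to $10^{-12}$.

Blank responses are legitimate rows (a no-response trial), so the battery
scores them degenerately (distances equal the target length, pcc 0, all-zero
match strings, `p_shared_char` missing) rather than erroring; the
standalone scalar functions, by contrast, reject empty inputs loudly.

## Lexicality

`check_lexicality()` implements two criteria. The **dictionary** criterion
is plain wordlist membership, independent of the target. The **database**
criterion declares a response lexical only when it appears in a frequency
lexicon *and* has strictly higher log10 frequency than the target item; any
other scenario is non-lexical. The database rule makes lexicality depend on
the target — the same response can be lexical for a low-frequency target
and non-lexical for a high-frequency one. That is surprising but it is the
rule as defined, so we implement it as stated and surface the judgement in
the output for supervision. One genuinely open corner is a target that is
itself absent from the lexicon: we treat its frequency as lower than any
listed response's (so real-word responses are not silently discarded) and
record the fact in `lexicality_note`.

## Semantic similarity

`read_embeddings()` loads word vectors in word2vec text or binary format;
`get_semantic_similarity()` adds the cosine between target and response
vectors (`w2v_cos`). Cosines are missing when either word is blank or out of
vocabulary — missingness is a value here, not an error, and the classifier
treats a missing cosine as "not semantically related" while recording the
fact in an audit note. Lookups are case-folded; no subword fallback is
attempted.

The classifier's default semantic threshold is **0.46**, appropriate for
embedding models whose cosines live in $[0, 1]$; thresholds in the
literature range up to 0.55, and around 0.50 is a reasonably safe choice.
The parameter should be recalibrated per model and language — models trained
on different corpora distribute their cosines differently, and models on
$[-1, 1]$ need a correspondingly adjusted value. It is a named argument
everywhere it is used.

## The classifier

`classify_errors()` applies, per attempt:

1. blank response → **no response**;
2. `accessed = 1`, or response equal to the target → correct, no category.
   The annotation wins over string comparison, so accepted dialectal
   variants marked correct are never error-coded;
3. nonwords: **nonword** (phonemic) if `p_shared_char` ≥ 50%, else
   **neologism**;
4. real words: *formally related* = shares ≥ 50% of characters **or** the
   initial character; *semantically related* = cosine present and ≥ the
   threshold. Both → **mixed** (evaluated first, so it cannot double-fire
   with its components); only formal → **formal**; only semantic →
   **semantic**; neither → **unrelated**.

Ties at either threshold count as related ("at least 50%"). Every erroneous
attempt therefore receives exactly one category by construction; if
evidence is contradictory or missing (e.g. `lexicality` is NA), no category
fires and `check_comment` is set to `"required"` for manual review. With
`also_classify_RAs = FALSE`, attempts inside multi-attempt cells are left
unclassified with the comment `"is only considered as RA"`.
`classify_errors_regular()` is the same tree without any repeated-attempt
logic, for conventionally shaped one-response tables.

```{r classify}
wordlist <- c("table", "chair", "truck", "sneaker", "furniture", "furnace")
store <- make_toy_embeddings(
  list(c("table", "chair", "furniture", "furnace"), c("truck", "sneaker")),
  within_cos = 0.8, between_cos = 0.1)

tibble(item = "table", response = c("tagle", "truck", "chair"),
       accessed = 0, RA = 0) |>
  get_formal_similarity() |>
  check_lexicality(criterion = "dictionary", wordlist = wordlist) |>
  get_semantic_similarity(model = store) |>
  classify_errors()
```

## Synthetic data: what it emulates, and what it does not

The package generates every resource its tests need.

`make_toy_embeddings()` builds unit vectors over orthonormal axes (one
global, one per cluster, one per word) so that within-cluster cosines equal
one prescribed value and cross-cluster cosines another, exactly. That turns
the semantic threshold into something testable: place a pair at 0.8 and it
must classify as related, at 0.1 it must not.

`simulate_responses()` draws a category per item from `error_mix` and
*constructs* a response satisfying that category's defining inequalities,
verified during rejection sampling with the package's own scorers — so
ground truth is exact rather than post-hoc labelled. Multi-attempt cells
are produced for the phonological nonword category only, where conduites
d'approche occur clinically; their attempts are corruptions of the target
with a decreasing number of edit operations, and by default the realised
pcc trajectory is required to be non-decreasing (self-correction), with a
flag to disable this for negative controls. The default error mixture
(5% no response, 30% nonword, 10% neologism, 15% formal, 10% unrelated,
20% semantic, 10% mixed) follows the broad ordering seen in anomia error
corpora, where phonological and semantic errors dominate; it is a test-bed
composition, not an empirical claim.

What the simulation deliberately does **not** emulate: Spanish (or any)
phonotactics — nonsense words only need to satisfy the scoring definitions;
realistic word-frequency distributions; embedding noise (real cosines are
not two-valued); transcription errors or annotation disagreements. A
perfect round-trip (the classifier recovering 100% of generating
categories, which the acceptance tests require) therefore demonstrates the
internal consistency of scorer + classifier under controlled evidence, not
classification accuracy on clinical data, where supervision of the output
remains essential.

## Numerical and scale choices

* All analysis stages are deterministic; randomness is confined to the
  generators and driven by explicit integer seeds (`simulation_spec(seed=)`),
  giving byte-identical outputs across runs and platforms.
* Toy embedding cosines are exact up to floating-point rounding; tests
  compare them at $10^{-6}$.
* The oracle-equivalence tests compare `Ld`, `DLd` and subsequence lengths
  against independent brute-force implementations on a seeded sample of
  3,000 string pairs over the alphabet {a, b, c} with lengths up to 5 —
  large enough to exercise every edit interaction (including
  transposition-then-edit cases that separate the unrestricted from the
  restricted Damerau–Levenshtein) while keeping the suite fast.
* The classifier round-trip runs on roughly 500 simulated attempts
  (320 items, CdAs of 3 attempts), which covers every category and both RA
  values many times over.
* Rejection sampling is capped (default 1,000 retries) and fails loudly
  with a suggestion to change parameters, never silently relaxing a
  constraint.

## Known limitations

* Lexicality and semantics are only as good as the supplied wordlist,
  frequency lexicon and embedding model; the package ships none and makes
  their influence explicit through configuration.
* The formal criterion operates on whatever representation the user scores
  (orthographic or phonemic); the column passed decides, and mixing the two
  within one analysis is the user's responsibility.
* No weighted or feature-based phonological distances, no syllable-aware
  alignment, and no categories beyond the seven (perseverations and
  circumlocutions are out of scope).
* Automatic phonemic transcription is out of scope; transcriptions are
  inputs.
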