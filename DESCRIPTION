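Package: girasol
Title: Multi-Attempt Response Wrangling and Production-Error Analysis for
    Aphasia Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spoken and written single-word production in
    aphasia and related disorders. Converts assessment tables whose response
    cells hold several successive attempts (conduites d'approche) into long
    format with repetition metadata; computes a battery of formal-similarity
    indexes between target and response strings (shared-character proportions,
    Levenshtein, unrestricted Damerau-Levenshtein and Jaro-Winkler distances,
    longest common subsequence, alignment traces, positionwise match strings
    and across-attempt change in the proportion of correct characters);
    explodes match strings into per-position accuracy records; checks response
    lexicality against a wordlist or a frequency lexicon; scores semantic
    relatedness by cosine similarity over word embeddings; and classifies
    errors into the standard psycholinguistic taxonomy (no response, phonemic
    nonword, neologism, formal, unrelated, semantic, mixed). Includes a
    synthetic-data generator that builds toy lexicons, embedding stores with
    prescribed cosines, and simulated multi-attempt response tables with known
    ground-truth categories.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
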