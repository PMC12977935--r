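Package: dmckit
Title: Diagnostic Molecular Combinations for DNA Barcode-Based Species Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives, verifies and evaluates diagnostic molecular combinations
    (DMCs): minimal sets of (alignment position, nucleotide) pairs that jointly
    distinguish a query taxon from every other sequence in a barcode reference
    library. Candidate combinations are assembled by weighted random sampling of
    alignment sites scored by a Jaccard-style uniqueness index, filtered by a
    minimum number of exclusive character states, refined towards shorter
    combinations, and summarised as a majority-consensus DMC per taxon. DMCs can
    be tested against aligned sequences, against unaligned sequences via
    semi-global pairwise alignment to the training reference, or alignment-free
    via a sliding window, and scored with per-species confusion matrices and
    classification metrics (recall, precision, specificity, balanced accuracy,
    F1) with missing-data exclusion. A synthetic barcode-library generator with
    planted diagnostic sites makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
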