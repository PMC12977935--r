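---
title: "Deriving and validating diagnostic molecular combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating diagnostic molecular combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A molecular diagnosis for a species description must be *state-specific*
(cite concrete sites and their nucleotides) and *contrastive* (demonstrate
that the cited combination occurs in no other known species). dmckit works
with **diagnostic molecular combinations (DMCs)**: ordered sets of
(alignment position, nucleotide) pairs, written `[25: A; 69: G]`, that
jointly separate one *query taxon* from every other sequence — the
*background* — in a reference barcode library. Positions are 1-based columns
of the training alignment, anchored to a designated reference sequence (the
first training sequence of the taxon, a stand-in for a holotype barcode).

Single diagnostic sites are often absent, and a single site is fragile:
one newly sampled haplotype can invalidate it. The search therefore
targets combinations, with two user-controlled safeguards:

* `min_len` — a minimum number of cited sites;
* `exclusive` — a minimum number of **exclusive character states**: every
  background sequence must differ from the combination at at least
  `exclusive` of its sites. This is the number of extra nucleotide matches
  that would be needed to break the diagnosis, analogous to Bremer support
  for a clade. Since a combination with `exclusive = k` cannot have fewer
  than `k` sites, the effective minimum length is
  `max(min_len, exclusive)`; the package raises `min_len` automatically.

## The search

For a query taxon, only *eligible* columns can be cited: at least one query
sequence has a non-missing state there, and all non-missing query states
are identical and unambiguous. Each eligible column `j` gets a
Jaccard-style uniqueness weight

$$w_j = d_j / B_j,$$

where `B_j` counts background sequences with informative data at `j` and
`d_j` those whose state differs from the query state. `w_j = 1` means the
column alone separates the taxon from every informative background
sequence. Two readings of the underlying Jaccard idea are defensible; the
default counts differing *sequences* (above), and a state-set variant
(`weight_method = "state_set"`, one minus the Jaccard similarity of the
query and background state sets) is available for comparison.

Candidate combinations are built by **weighted random sampling**: sites are
drawn one at a time without replacement with probability proportional to
`w`, and growth stops at the first length `>= max(min_len, exclusive)`
whose exclusivity reaches `exclusive`. Sampling from *all* positive-weight
sites, rather than a top-ranked cut-off, avoids systematically ignoring
informative sites that tie just below a threshold. A draw that fails to
qualify by `max_len` sites (default 15, a cap that prevents runaway growth
on recalcitrant taxa) is rejected. `iter` draws are attempted (default
50000).

Because growth stops at the first qualifying prefix, every sampled
candidate has exclusivity exactly `exclusive` whenever
`min_len <= exclusive`; candidates only overshoot when the first
length-eligible prefix already exceeds the threshold.

**Refinement** (`ref_strength` in [0, 1]) searches each retained optimal
candidate for shorter sub-combinations that still qualify. For candidates
with `2^L <= 4096` all proper subsets of allowed size are enumerated
exactly; longer candidates get `max(1, round(ref_strength * L))`
randomized backward-elimination passes (shuffle the site order, try
deleting each site, keep a deletion if the reduction still qualifies).
`ref_strength = 0` disables refinement. Refinement is applied to the
`top_k` ranked pool members rather than every distinct candidate, which
bounds the work without affecting the retained pool in practice.

**Consensus.** Distinct qualifying candidates are ranked by exclusivity
(descending), then length (ascending), then the lexicographically smallest
position vector — the last tie-break makes seeded runs fully
deterministic. The `top_k` (default 100) best form the optimal pool. Sites
occurring in at least `majority_threshold` (default 0.5) of pool members
seed the majority-consensus DMC; if it does not yet qualify, the
next-most-frequent sites are added greedily (ties towards lower columns)
until it does. If no augmentation qualifies, the top-ranked candidate is
reported instead and the row is flagged `ok_fallback`. One optimal
candidate distinct from the consensus is always reported as the
alternative DMC, and both are re-verified against the length and
exclusivity contracts before output.

**Reproducibility.** One root seed drives everything; each taxon gets an
independent RNG stream derived from a stable hash of its label, so adding
a query taxon never perturbs the results for the others.

## Scoring rules and degenerate inputs

* Missing data are `N`, `?` and (by default) `-`. With `gaps_new = TRUE`
  a gap is a fifth ordinary state for background comparisons — a gapped
  background sequence can then *differ* at a site — but a column whose
  query state is a gap is never citable (a DMC cites nucleotides).
* In **exclusivity scoring**, a missing background state never counts as
  differing (it cannot demonstrate a difference), and an ambiguity code
  counts as differing only when its expansion excludes the DMC state. This
  is deliberately dual to match semantics below, so that exclusivity
  `>= k` guarantees at least `k` mismatches for every background sequence.
  The aggressive alternative (count missing as differing) is available as
  `missing_differs = TRUE`.
* In **site weighting**, an ambiguity code counts as differing unless it
  expands to exactly the query state; background columns with no
  informative data get weight 0.
* A taxon with no sequences yields status `no_query_sequences`; a taxon
  whose eligible columns all have weight 0, or for which no draw ever
  qualifies, yields `no_dmc_found`. Neither aborts the run.
* Exclusivity of an empty site list is 0; exclusivity is undefined (an
  error) without background sequences.

## Verification

Three modes test a DMC table against sequences, all reporting per
(sequence, DMC) pair the counts `n_match`, `n_mismatch`, `n_missing`
(which always sum to the DMC length) and a binary decision
`n_mismatch <= tolerance`. A fully missing profile is never a match. In
test sequences, `N`, `?`, `-` are missing, and an IUPAC ambiguity code
counts as a match when its expansion contains the DMC state
(`ambiguity_matches = FALSE` reverts to strict equality). The two
tolerances used in practice are 0 and 1.

* `identify_aligned()` — test sequences share the training coordinate
  system; states are read off directly.
* `identify_unaligned_global()` — each test sequence is aligned to the
  DMC taxon's degapped reference with a semi-global Needleman–Wunsch
  variant (reference global, test overhangs free; match +2, mismatch −1,
  gap opening 10, gap extension 0.5 — all exposed). Aligning to the single
  designated reference, rather than a profile of the whole training
  alignment, keeps the position map well defined and cheap. DMC columns
  are projected through the reference's own gap pattern; sites that land
  on gaps are missing.
* `identify_sliding()` — alignment-free: DMC sites are projected to
  degapped reference coordinates to form a rigid spacing pattern that is
  slid across the test sequence; the window with the fewest mismatches
  wins (ties towards the smallest start). Indels *inside* the footprint
  are not absorbed — this is the method's stated limitation, and sequences
  shorter than the footprint are reported all-missing and unmatched.

On exact ungapped copies of the training sequences all three modes agree,
provided DMCs are long enough that a short motif cannot recur by chance
elsewhere in a sequence; this is one practical reason to prefer
`exclusive = 4` with `min_len = 10` as a starting configuration over
minimal two-site combinations.

## Evaluation

`evaluate_dmcs()` builds one confusion matrix per DMC. A test sequence with
missing data at any of a DMC's sites is excluded from *that DMC's* matrix
only (the sites, and hence the exclusion, are species-specific; the same
sequence can be counted for another DMC). Among the rest: TP = conspecific
and matched, FN = conspecific and unmatched, FP = heterospecific and
matched, TN = heterospecific and unmatched, so
`TP + FP + TN + FN + n_excluded` always equals the number of test
sequences. True labels come from sequence ids via the same delimited-prefix
convention used in training; ids matching no query taxon are
heterospecific for every DMC.

The metrics are the printed formulas:
Recall `TP/(TP+FN)`, Precision `TP/(TP+FP)`, Specificity `TN/(TN+FP)`,
**Accuracy `(Recall + Specificity)/2`** — the balanced form, *not*
`(TP+TN)/total`; the name collides with the conventional definition, so
this is worth repeating — and F1 `2PR/(P+R)`. Any metric with a zero
denominator is undefined and serialised as `NA`, never 0, so averages are
not silently deflated. For taxa without conspecific test sequences only
specificity is reported, since TP and FN cannot be determined. F1 is
insensitive to adding true negatives, which is why it is the preferred
summary when a few common species dominate a test set; balanced accuracy
moves only through specificity.

## The synthetic generator

`generate_training_alignment()` emulates a species-structured barcode
library at desk scale: one random ancestral sequence, per-species
substitution at `background_divergence` (default 0.1), within-species
substitution at `intraspecific_rate`, undetermined cells at
`missing_rate`, and column-coherent gap events at `gap_rate` (all members
of randomly chosen species share each gap column, mimicking shared indel
events; planted columns are never gapped). The default width of 313
columns matches a typical COI minibarcode. Each species additionally
receives `planted_sites_per_species` disjoint columns at which it is fixed
for a state no other species carries, so before noise the planted set is
diagnostic with exclusivity equal to its size — exact ground truth,
deterministic from the seed. Note that between-species divergence *also*
creates fully exclusive columns (private substitutions), so planted sites
are a guaranteed qualifying set, not the only one.

`generate_test_set()` degaps training sequences and applies flanks,
truncations, substitutions and 1-bp indels at stated rates; ids extend the
source id so the prefix convention recovers true labels. A `protect`
argument shields stated positions from edits, which the test suite uses to
verify that indels away from the DMC footprint leave identification
decisions unchanged.

What the generator does *not* emulate: phylogenetic correlation among
species (a two-level substitution model is used deliberately — the search
makes no tree assumptions), codon structure, alignment error, chimeras and
contamination. Passing tests therefore demonstrate algorithmic
correctness under the stated statistical structure, not performance on any
particular empirical library.

## Problem sizes and numerical choices

The validation suite runs on libraries of 4–8 species, 3–5 sequences per
species and 40–120 columns: large enough that exhaustive enumeration of
all combinations up to four sites is feasible as an independent oracle,
small enough that fifty instances and twenty 50000-iteration searches run
in minutes. The brute-force oracle certifies the minimal qualifying
length, every reported exclusivity, and the planted ground truth; the
search is required to recover a minimal-length qualifying DMC in at least
95% of seeded runs on instances where the oracle finds one within four
sites.

Open choices resolved here (the source descriptions leave them
unspecified): the pool size retained for consensus (`top_k = 100`), the
majority cut-off (0.5), refinement as subset enumeration below
`2^L <= 4096` and backward elimination above, gap-as-fifth-state as the
meaning of `gaps_new`, pairwise (not profile) alignment in the global
mode, and a rigid-offset scan as the sliding window. All are exposed as
parameters or documented flags so they can be varied.

## Known limitations

* The sliding window does not absorb indels inside the DMC footprint;
  use the global mode for indel-rich test sets.
* Gap-placement ambiguity next to a diagnostic site can shift the position
  map when an indel occurs immediately adjacent to the footprint.
* Short DMCs (2–3 sites) match unrelated sequences by chance in the
  alignment-free mode; prefer longer combinations when test sets are
  unaligned and unlabelled.
* Exclusivity is conservative under heavy missing data: a background
  sequence with no data at the DMC sites caps exclusivity at 0, which
  blocks otherwise valid combinations (this is intentional; see
  `missing_differs`).
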