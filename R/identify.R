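# DMC verification against test sequences: aligned lookup, semi-global
# pairwise alignment to the training reference, and an alignment-free
# sliding-window scan.

#' Read unaligned sequences from FASTA
#'
#' Like [read_alignment()] but without the equal-length requirement; used
#' for test sets that are not aligned to the training coordinate system.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of normalised (uppercase, U->T)
#'   sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Classify observed states against a DMC's states
#'
#' Per-site classification: a state is *missing* when it is `N`, `?` or
#' `-`; a *match* when it equals the DMC state or is an IUPAC ambiguity code
#' whose expansion contains it (when `ambiguity_matches` is on, the
#' default); otherwise a *mismatch*. The sequence matches the DMC when its
#' non-missing mismatches do not exceed `tolerance`.
#'
#' @param sites DMC sites: a tibble with columns `position`, `state`.
#' @param states Character vector of observed states, one per DMC site.
#' @param tolerance Maximum number of mismatches still counted as a match.
#' @param ambiguity_matches Treat compatible ambiguity codes as matches.
#' @return A list with `n_sites`, `n_match`, `n_mismatch`, `n_missing`,
#'   `matched`.
#' @export
match_profile <- function(sites, states, tolerance = 0,
                          ambiguity_matches = TRUE) {
  n <- nrow(sites)
  if (length(states) != n) {
    stop("expected ", n, " states, got ", length(states))
  }
  states[is.na(states)] <- "N"
  miss <- states %in% MISSING_STATES
  if (ambiguity_matches) {
    hit <- !miss & state_could_match(states, sites$state)
  } else {
    hit <- !miss & states == sites$state
  }
  n_missing <- sum(miss)
  n_match <- sum(hit)
  n_mismatch <- n - n_match - n_missing
  # a fully uninformative profile (all sites missing) never counts as a match
  list(n_sites = n, n_match = n_match, n_mismatch = n_mismatch,
       n_missing = n_missing,
       matched = n_mismatch <= tolerance && n_missing < n)
}

# Extract the testable DMCs (one per ok row) from a dmc_table.
table_dmcs <- function(dmcs, which = c("consensus", "alternative")) {
  which <- match.arg(which)
  col <- paste0(which, "_dmc")
  ok <- !is.na(dmcs[[col]])
  purrr::map(which(ok), function(i) {
    list(taxon = dmcs$taxon[i],
         sites = parse_dmc_string(dmcs[[col]][i]),
         reference_id = dmcs$reference_id[i])
  })
}

as_match_report <- function(rows, mode, tolerance) {
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sequence_id = character(), taxon = character(),
                          n_sites = integer(), n_match = integer(),
                          n_mismatch = integer(), n_missing = integer(),
                          matched = logical(), offset = integer())
  }
  attr(out, "mode") <- mode
  attr(out, "tolerance") <- tolerance
  class(out) <- c("dmc_match_report", class(tibble::as_tibble(out)))
  out
}

outcome_row <- function(sequence_id, taxon, prof, offset = NA_integer_) {
  tibble::tibble(sequence_id = sequence_id, taxon = taxon,
                 n_sites = prof$n_sites, n_match = prof$n_match,
                 n_mismatch = prof$n_mismatch, n_missing = prof$n_missing,
                 matched = prof$matched, offset = as.integer(offset))
}

#' Test DMCs against aligned sequences
#'
#' Every test sequence shares the training alignment's coordinate system;
#' the states at each DMC's columns are read off directly and classified
#' with [match_profile()]. The report covers the full cross product of test
#' sequences and DMCs.
#'
#' @param dmcs A `dmc_table` (see [find_dmcs()], [read_dmc_table()]).
#' @param test_aln A `dmc_alignment` of test sequences, aligned to the
#'   training coordinates.
#' @param tolerance Mismatch tolerance (default 0; the companion setting in
#'   practice is 1).
#' @param which Test the `"consensus"` (default) or `"alternative"` DMCs.
#' @param ambiguity_matches See [match_profile()].
#' @return A `dmc_match_report` tibble with one row per (sequence, DMC)
#'   pair and columns `sequence_id`, `taxon`, `n_sites`, `n_match`,
#'   `n_mismatch`, `n_missing`, `matched`, `offset`.
#' @export
identify_aligned <- function(dmcs, test_aln, tolerance = 0,
                             which = "consensus", ambiguity_matches = TRUE) {
  stopifnot(inherits(test_aln, "dmc_alignment"))
  dl <- table_dmcs(dmcs, which)
  m <- alignment_matrix(test_aln)
  rows <- purrr::map(dl, function(d) {
    if (max(d$sites$position) > test_aln$n_sites) {
      stop(sprintf("DMC for '%s' cites position %d beyond the %d test columns",
                   d$taxon, max(d$sites$position), test_aln$n_sites))
    }
    purrr::map(rownames(m), function(id) {
      prof <- match_profile(d$sites, m[id, d$sites$position], tolerance,
                            ambiguity_matches)
      outcome_row(id, d$taxon, prof)
    })
  })
  as_match_report(purrr::flatten(rows), "aligned", tolerance)
}

# --- semi-global position mapping ------------------------------------------

default_scoring <- function() {
  list(match = 2, mismatch = -1, gap_opening = 10, gap_extension = 0.5)
}

#' Map reference positions onto an unaligned test sequence
#'
#' Aligns the (degapped) reference sequence to a test sequence with a
#' semi-global Needleman-Wunsch variant — the reference is aligned globally,
#' the test sequence's overhanging ends are free — and records, for every
#' reference position, the aligned test position, or `NA` when the position
#' falls on a gap.
#'
#' @param test_seq Test sequence (plain character string).
#' @param reference_seq Degapped reference sequence.
#' @param scoring List with `match`, `mismatch`, `gap_opening`,
#'   `gap_extension` (defaults 2, -1, 10, 0.5; penalties are magnitudes).
#' @return An integer vector of length `nchar(reference_seq)`; element `i`
#'   is the 1-based test position aligned to reference position `i`, or
#'   `NA`.
#' @export
build_position_map <- function(test_seq, reference_seq,
                               scoring = default_scoring()) {
  if (!nzchar(test_seq) || !nzchar(reference_seq)) {
    stop("cannot align empty sequences")
  }
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  clean <- function(s) gsub("[?]", "N", gsub("-", "", s, fixed = TRUE))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(clean(reference_seq)),
    subject = Biostrings::DNAString(clean(test_seq)),
    type = "global-local", substitutionMatrix = sub_mat,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  s_off <- Biostrings::start(Biostrings::subject(pa)) - 1L
  n_ref <- nchar(clean(reference_seq))
  map <- rep(NA_integer_, n_ref)
  ppos <- 0L
  spos <- s_off
  for (k in seq_along(p_chars)) {
    p_gap <- p_chars[k] == "-"
    s_gap <- s_chars[k] == "-"
    if (!s_gap) spos <- spos + 1L
    if (!p_gap) {
      ppos <- ppos + 1L
      if (!s_gap) map[ppos] <- spos
    }
  }
  map
}

# Per training-alignment column: the degapped position within the reference
# sequence, or NA where the reference itself has a gap.
reference_column_map <- function(ref_gapped) {
  chars <- strsplit(ref_gapped, "")[[1]]
  is_base <- chars != "-"
  out <- cumsum(is_base)
  out[!is_base] <- NA_integer_
  as.integer(out)
}

get_reference <- function(training_aln, d) {
  ref_id <- d$reference_id
  if (is.na(ref_id) || !ref_id %in% names(training_aln$seq)) {
    stop("reference sequence '", ref_id %||% "<missing>",
         "' for taxon '", d$taxon, "' not found in the training alignment")
  }
  training_aln$seq[[ref_id]]
}

#' Test DMCs against unaligned sequences via pairwise alignment
#'
#' For every (test sequence, DMC) pair, the test sequence is aligned to the
#' DMC taxon's designated reference sequence with [build_position_map()];
#' the DMC's alignment columns are projected through the reference's gap
#' pattern onto the test sequence, mapped states are extracted (unmapped
#' sites are missing) and classified with [match_profile()].
#'
#' @inheritParams identify_aligned
#' @param test_seqs Named character vector of unaligned test sequences
#'   (see [read_sequences()]).
#' @param training_aln The training `dmc_alignment` the DMCs were derived
#'   from (provides reference sequences and the coordinate system).
#' @param scoring Alignment scoring; see [build_position_map()].
#' @return A `dmc_match_report` (mode `"global_aligned"`).
#' @export
identify_unaligned_global <- function(dmcs, test_seqs, training_aln,
                                      tolerance = 0, which = "consensus",
                                      ambiguity_matches = TRUE,
                                      scoring = default_scoring()) {
  stopifnot(inherits(training_aln, "dmc_alignment"))
  dl <- table_dmcs(dmcs, which)
  rows <- purrr::map(dl, function(d) {
    ref_gapped <- get_reference(training_aln, d)
    ref_degap <- gsub("-", "", ref_gapped, fixed = TRUE)
    col_map <- reference_column_map(ref_gapped)
    ref_pos <- col_map[d$sites$position]
    purrr::map(names(test_seqs), function(id) {
      test <- gsub("-", "", test_seqs[[id]], fixed = TRUE)
      map <- build_position_map(test, ref_degap, scoring)
      test_pos <- ifelse(is.na(ref_pos), NA_integer_, map[ref_pos])
      chars <- strsplit(test, "")[[1]]
      states <- ifelse(is.na(test_pos), "N", chars[test_pos])
      prof <- match_profile(d$sites, states, tolerance, ambiguity_matches)
      outcome_row(id, d$taxon, prof)
    })
  })
  as_match_report(purrr::flatten(rows), "global_aligned", tolerance)
}

#' Test DMCs against raw sequences with a sliding window
#'
#' Alignment-free verification: the DMC's sites are projected to degapped
#' reference coordinates to obtain a rigid spacing pattern, which is slid
#' across each test sequence. The window minimising the mismatch count
#' (ties resolved towards the smallest start) is reported; the sequence
#' matches when that window's mismatches are within `tolerance`. Sequences
#' shorter than the DMC footprint are reported all-missing and unmatched.
#'
#' @inheritParams identify_unaligned_global
#' @return A `dmc_match_report` (mode `"sliding"`) whose `offset` column
#'   holds the best window's 1-based start.
#' @export
identify_sliding <- function(dmcs, test_seqs, training_aln, tolerance = 0,
                             which = "consensus", ambiguity_matches = TRUE) {
  stopifnot(inherits(training_aln, "dmc_alignment"))
  dl <- table_dmcs(dmcs, which)
  rows <- purrr::map(dl, function(d) {
    ref_gapped <- get_reference(training_aln, d)
    col_map <- reference_column_map(ref_gapped)
    ref_pos <- col_map[d$sites$position]
    if (anyNA(ref_pos)) {
      stop(sprintf(
        "DMC for '%s' cites a column where its reference sequence has a gap; cannot project to unaligned coordinates",
        d$taxon))
    }
    delta <- ref_pos - ref_pos[1]
    span <- max(delta) + 1L
    purrr::map(names(test_seqs), function(id) {
      test <- gsub("-", "", test_seqs[[id]], fixed = TRUE)
      chars <- strsplit(test, "")[[1]]
      n <- length(chars)
      if (n < span) {
        prof <- list(n_sites = nrow(d$sites), n_match = 0L, n_mismatch = 0L,
                     n_missing = nrow(d$sites), matched = FALSE)
        return(outcome_row(id, d$taxon, prof))
      }
      best <- NULL
      for (s in seq_len(n - span + 1L)) {
        prof <- match_profile(d$sites, chars[s + delta], tolerance,
                              ambiguity_matches)
        if (is.null(best) || prof$n_mismatch < best$prof$n_mismatch) {
          best <- list(prof = prof, s = s)
        }
      }
      outcome_row(id, d$taxon, best$prof, best$s)
    })
  })
  as_match_report(purrr::flatten(rows), "sliding", tolerance)
}
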