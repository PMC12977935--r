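# Shared fixtures and independent brute-force oracles. The oracles use only
# direct string manipulation and exhaustive loops, never the code paths they
# check.

# Build a dmc_alignment through the public FASTA interface.
make_alignment <- function(seqs, queries = NULL) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  aln <- read_alignment(path)
  if (!is.null(queries)) aln <- assign_taxa(aln, queries)
  aln
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Brute-force exclusivity: for every background sequence, count the DMC
# sites where its state is non-missing and demonstrably different (its
# expansion excludes the DMC state); return the minimum.
oracle_exclusivity <- function(aln, taxon, sites, gaps_new = FALSE) {
  bg <- aln$taxa$seq_id[aln$taxa$taxon != taxon]
  stopifnot(length(bg) > 0)
  if (nrow(sites) == 0) return(0L)
  miss <- if (gaps_new) c("N", "?") else c("N", "?", "-")
  per_seq <- vapply(bg, function(id) {
    chars <- strsplit(aln$seq[[id]], "")[[1]]
    n_diff <- 0L
    for (k in seq_len(nrow(sites))) {
      st <- chars[sites$position[k]]
      if (st %in% miss) next
      expansion <- ORACLE_IUPAC[[st]]
      if (is.null(expansion)) expansion <- character()  # "-" under gaps_new
      if (!(sites$state[k] %in% expansion)) n_diff <- n_diff + 1L
    }
    n_diff
  }, integer(1))
  min(per_seq)
}

# Exhaustively enumerate all site combinations up to `max_size` over the
# taxon's fixed-state columns and return the minimum qualifying length
# (NA when nothing up to max_size qualifies).
oracle_min_qualifying_length <- function(aln, taxon, exclusive, min_len = 1,
                                         max_size = 4, gaps_new = FALSE) {
  elig <- site_eligibility(aln, taxon, gaps_new)
  pos <- elig$position[elig$eligible]
  states <- elig$state[elig$eligible]
  eff <- max(min_len, exclusive)
  for (size in seq(eff, max_size)) {
    if (size > length(pos)) break
    combos <- utils::combn(seq_along(pos), size, simplify = FALSE)
    for (cb in combos) {
      sites <- tibble::tibble(position = pos[cb], state = states[cb])
      if (oracle_exclusivity(aln, taxon, sites, gaps_new) >= exclusive) {
        return(size)
      }
    }
  }
  NA_integer_
}

# A small fully hand-checkable two-species alignment used across tests.
toy_alignment <- function() {
  make_alignment(c(
    Aus_bus_01 = "ACGTACGTAC",
    Aus_bus_02 = "ACGTACGTAC",
    Aus_cus_01 = "TCGTACGTGC",
    Aus_cus_02 = "TCGTACGTGC",
    Dus_eus_01 = "ACGAACGTAA",
    Dus_eus_02 = "ACGAACTTAA"
  ), queries = c("Aus_bus", "Aus_cus", "Dus_eus"))
}
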