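# Synthetic species-structured barcode libraries with planted diagnostic
# sites, and matched unaligned test sets. Ground truth is exact by
# construction, so every other module is testable without external data.

#' Specification for a synthetic barcode library
#'
#' The generator emulates a species-structured barcode library: an ancestral
#' random sequence diverges between species, varies within species, and each
#' species receives a set of planted sites at which it is fixed for a state
#' no other species carries there (so the planted set is diagnostic with
#' exclusivity equal to its size, before noise).
#'
#' @param n_species Number of species.
#' @param seqs_per_species Sequences per species (scalar or length-2 range).
#' @param n_sites Alignment width in columns (default 313, a typical COI
#'   minibarcode length).
#' @param planted_sites_per_species Number of planted diagnostic sites per
#'   species (default 2); planted sites are disjoint across species.
#' @param intraspecific_rate Per-site substitution probability within a
#'   species (default 0).
#' @param missing_rate Per-cell probability of an undetermined state `N`
#'   (default 0).
#' @param gap_rate Fraction of columns hit by shared gap events (default 0).
#' @param background_divergence Per-site substitution probability between
#'   the ancestral sequence and each species (default 0.1).
#' @param seed Random seed; generation is fully deterministic given the
#'   spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_species = 8, seqs_per_species = 5, n_sites = 313,
                       planted_sites_per_species = 2, intraspecific_rate = 0,
                       missing_rate = 0, gap_rate = 0,
                       background_divergence = 0.1, seed = 1) {
  stopifnot(n_species >= 2, all(seqs_per_species >= 1), n_sites >= 1,
            planted_sites_per_species >= 0,
            intraspecific_rate >= 0, intraspecific_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            gap_rate >= 0, gap_rate < 1,
            background_divergence > 0, background_divergence <= 1)
  if (planted_sites_per_species * n_species > n_sites) {
    stop("planted sites (", planted_sites_per_species * n_species,
         ") exceed alignment columns (", n_sites, ")")
  }
  structure(list(
    n_species = as.integer(n_species),
    seqs_per_species = as.integer(seqs_per_species),
    n_sites = as.integer(n_sites),
    planted_sites_per_species = as.integer(planted_sites_per_species),
    intraspecific_rate = intraspecific_rate,
    missing_rate = missing_rate,
    gap_rate = gap_rate,
    background_divergence = background_divergence,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES, x), 1), character(1),
         USE.NAMES = FALSE)
}

#' Generate a training alignment with planted diagnostic sites
#'
#' Species consensus sequences are derived from one ancestral random
#' sequence by per-site substitution at `background_divergence`; planted
#' sites are then overwritten so each species is fixed for a state no other
#' species carries there. Individual sequences add within-species variation
#' (`intraspecific_rate`), undetermined cells (`missing_rate`) and
#' column-coherent gap events (`gap_rate`). Sequence ids follow
#' `Genus<g>_species<s>_<counter>` so [assign_taxa()] resolves them.
#'
#' @param spec A [synth_spec()].
#' @return A list with `alignment` (a `dmc_alignment`, taxa assigned),
#'   `truth` (a list with `taxon` — species labels — and `sites` — a tibble
#'   of planted `taxon`, `position`, `state`) and `spec`.
#' @export
generate_training_alignment <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_species
    L <- spec$n_sites
    genus <- ((seq_len(ns) - 1L) %/% 4L) + 1L
    species <- sprintf("Genus%d_species%d", genus, seq_len(ns))
    per <- if (length(spec$seqs_per_species) == 2) {
      sample(spec$seqs_per_species[1]:spec$seqs_per_species[2], ns,
             replace = TRUE)
    } else rep(spec$seqs_per_species, ns)

    ancestral <- sample(BASES, L, replace = TRUE)
    consensus <- matrix(rep(ancestral, each = ns), nrow = ns)
    for (s in seq_len(ns)) {
      hit <- which(stats::runif(L) < spec$background_divergence)
      if (length(hit) > 0) consensus[s, hit] <- other_base(consensus[s, hit])
    }

    # plant disjoint diagnostic sites: species s fixed for a state no other
    # species carries at that column
    n_planted <- spec$planted_sites_per_species * ns
    planted_pos <- if (n_planted > 0) sample(L, n_planted) else integer()
    truth_sites <- tibble::tibble(taxon = character(), position = integer(),
                                  state = character())
    if (spec$planted_sites_per_species > 0) {
      assign_split <- split(planted_pos,
                            rep(seq_len(ns), each = spec$planted_sites_per_species))
      for (s in seq_len(ns)) {
        for (p in assign_split[[s]]) {
          x <- sample(BASES, 1)
          consensus[s, p] <- x
          clash <- setdiff(which(consensus[, p] == x), s)
          if (length(clash) > 0) consensus[clash, p] <- other_base(rep(x, length(clash)))
          truth_sites <- dplyr::bind_rows(
            truth_sites,
            tibble::tibble(taxon = species[s], position = p, state = x))
        }
      }
    }

    # individual sequences: intraspecific substitutions, then missing data
    seq_mat <- NULL
    ids <- character()
    for (s in seq_len(ns)) {
      for (k in seq_len(per[s])) {
        row <- consensus[s, ]
        hit <- which(stats::runif(L) < spec$intraspecific_rate)
        if (length(hit) > 0) row[hit] <- other_base(row[hit])
        hit <- which(stats::runif(L) < spec$missing_rate)
        if (length(hit) > 0) row[hit] <- "N"
        seq_mat <- rbind(seq_mat, row)
        ids <- c(ids, sprintf("%s_%03d", species[s], k))
      }
    }

    # column-coherent gap events shared by all members of affected species
    if (spec$gap_rate > 0) {
      candidates <- setdiff(seq_len(L), planted_pos)
      n_gap_cols <- min(length(candidates), round(spec$gap_rate * L))
      gap_cols <- sample(candidates, n_gap_cols)
      sp_of_row <- rep(seq_len(ns), times = per)
      for (p in gap_cols) {
        affected <- which(stats::runif(ns) < 0.5)
        if (length(affected) == 0) affected <- sample(ns, 1)
        seq_mat[sp_of_row %in% affected, p] <- "-"
      }
    }

    seqs <- stats::setNames(apply(seq_mat, 1, paste, collapse = ""), ids)
    aln <- assign_taxa(new_alignment(seqs), species)
    truth_sites <- dplyr::arrange(truth_sites, .data$taxon, .data$position)
    list(alignment = aln,
         truth = list(taxon = species, sites = truth_sites),
         spec = spec)
  })
}

#' Generate an unaligned test set from a training alignment
#'
#' Produces degapped copies of the training sequences with optional random
#' flanking bases, end truncations, substitutions and indels, emulating the
#' heterogeneous unaligned barcodes of public repositories. Ids extend the
#' source id (`<source>_t<k>`) so the same prefix convention recovers the
#' true labels.
#'
#' @param aln Training `dmc_alignment`.
#' @param n_copies Copies per training sequence (default 1).
#' @param subst_rate Per-site substitution probability (default 0).
#' @param indel_rate Per-site probability of a 1-bp insertion or deletion
#'   (default 0).
#' @param truncation Length-2 range; each end is truncated by an amount
#'   drawn uniformly from it (default `c(0, 0)`).
#' @param flank Length-2 range of random-base flank lengths added at each
#'   end (default `c(0, 0)`).
#' @param protect Optional integer positions (degapped coordinates of the
#'   source sequence) shielded from substitutions, indels and truncation.
#' @param seed Random seed.
#' @return A list with `seqs` (named character vector) and `truth` (named
#'   vector mapping test id to source taxon label).
#' @export
generate_test_set <- function(aln, n_copies = 1, subst_rate = 0,
                              indel_rate = 0, truncation = c(0, 0),
                              flank = c(0, 0), protect = integer(),
                              seed = 1) {
  stopifnot(inherits(aln, "dmc_alignment"), length(truncation) == 2,
            length(flank) == 2)
  taxon_of <- stats::setNames(aln$taxa$taxon, aln$taxa$seq_id)
  with_seed(seed, {
    out <- character()
    labels <- character()
    for (id in names(aln$seq)) {
      base_seq <- gsub("-", "", aln$seq[[id]], fixed = TRUE)
      n <- nchar(base_seq)
      for (k in seq_len(n_copies)) {
        chars <- strsplit(base_seq, "")[[1]]
        editable <- setdiff(seq_len(n), protect)
        # substitutions
        hit <- editable[stats::runif(length(editable)) < subst_rate]
        if (length(hit) > 0) chars[hit] <- other_base(chars[hit])
        # truncation, capped so protected sites survive
        lo_max <- if (length(protect)) min(protect) - 1L else n - 1L
        hi_max <- if (length(protect)) n - max(protect) else n - 1L
        lo <- min(sample(truncation[1]:truncation[2], 1), max(lo_max, 0))
        hi <- min(sample(truncation[1]:truncation[2], 1), max(hi_max, 0))
        if (lo + hi >= n) stop("truncation longer than sequence '", id, "'")
        kept <- chars[(lo + 1):(n - hi)]
        kept_pos <- (lo + 1):(n - hi)
        # 1-bp indels at non-protected positions
        if (indel_rate > 0) {
          res <- character()
          for (i in seq_along(kept)) {
            p <- kept_pos[i]
            if (!(p %in% protect) && stats::runif(1) < indel_rate) {
              if (stats::runif(1) < 0.5) {
                next  # deletion
              } else {
                res <- c(res, sample(BASES, 1), kept[i])  # insertion before
              }
            } else {
              res <- c(res, kept[i])
            }
          }
          kept <- res
        }
        fl_lo <- sample(flank[1]:flank[2], 1)
        fl_hi <- sample(flank[1]:flank[2], 1)
        full <- c(if (fl_lo > 0) sample(BASES, fl_lo, replace = TRUE),
                  kept,
                  if (fl_hi > 0) sample(BASES, fl_hi, replace = TRUE))
        tid <- sprintf("%s_t%d", id, k)
        out[tid] <- paste(full, collapse = "")
        labels[tid] <- unname(taxon_of[id])
      }
    }
    list(seqs = out, truth = labels)
  })
}

#' Write unaligned sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
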