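# Reading and writing the external formats: FASTA alignments, query-taxon
# lists, DMC tables, and the bracketed DMC notation "[25: A; 69: G]".

#' Read a multiple sequence alignment from FASTA
#'
#' Reads a nucleotide alignment in FASTA format. Residues are uppercased and
#' `U` is normalised to `T` so RNA-deposited barcodes work transparently.
#' All records must have identical length; positions are 1-based alignment
#' columns throughout the package.
#'
#' @param path Path to a FASTA file with at least two records.
#' @return An object of class `dmc_alignment`: a list with elements
#'   `seq` (named character vector of residue strings), `n_sites`
#'   (alignment width) and `taxa` (a tibble with columns `seq_id`, `taxon`;
#'   taxa are `"BACKGROUND"` until [assign_taxa()] is called).
#' @seealso [assign_taxa()], [write_alignment()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  seqs <- as.character(set)
  names(seqs) <- ids
  new_alignment(seqs)
}

new_alignment <- function(seqs, taxa = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- ids[lens != lens[[1]]]
    stop("alignment rows have unequal lengths (offending ids: ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  n_sites <- lens[[1]]
  if (n_sites < 1) stop("alignment has zero columns")
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad_chars <- setdiff(chars, ALLOWED_ALPHABET)
  if (length(bad_chars) > 0) {
    first_bad <- regexpr(paste0("[", paste(bad_chars, collapse = ""), "]"), seqs)
    hit <- which(first_bad > 0)[1]
    stop(sprintf(
      "invalid residue character(s) %s (first in '%s' at position %d)",
      paste(shQuote(bad_chars), collapse = ", "), ids[hit], first_bad[hit]))
  }
  if (is.null(taxa)) {
    taxa <- tibble::tibble(seq_id = ids, taxon = BACKGROUND_LABEL)
  }
  structure(
    list(seq = seqs, n_sites = unname(n_sites), taxa = taxa),
    class = "dmc_alignment"
  )
}

#' @export
print.dmc_alignment <- function(x, ...) {
  n_assigned <- sum(x$taxa$taxon != BACKGROUND_LABEL)
  cat(sprintf("<dmc_alignment> %d sequences x %d sites (%d assigned to query taxa)\n",
              length(x$seq), x$n_sites, n_assigned))
  invisible(x)
}

#' @export
length.dmc_alignment <- function(x) length(x$seq)

#' Write an alignment back to FASTA
#'
#' @param aln A `dmc_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dmc_alignment"))
  set <- Biostrings::BStringSet(aln$seq)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Character matrix view (rows = sequences, columns = alignment sites).
alignment_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, ""), use.names = FALSE),
              nrow = length(aln$seq), ncol = aln$n_sites, byrow = TRUE)
  rownames(m) <- names(aln$seq)
  m
}

#' Read a query-taxon list from CSV
#'
#' One taxon label per row, first column. A header row is auto-detected when
#' the first cell is literally `taxon` or `query` (case-insensitive). Entries
#' may be species-level labels (`Genus_species`) or higher-level prefixes
#' (`Genus`). Duplicates are dropped with a warning; order is preserved.
#'
#' @param path Path to the CSV file.
#' @return A character vector of query taxon labels.
#' @export
read_query_list <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    blank.lines.skip = TRUE, strip.white = TRUE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) stop("query list is empty: ", path)
  queries <- trimws(raw[[1]])
  if (tolower(queries[1]) %in% c("taxon", "query")) queries <- queries[-1]
  queries <- queries[nzchar(queries)]
  if (length(queries) == 0) stop("query list contains no taxa: ", path)
  if (anyDuplicated(queries)) {
    warning("duplicate query taxa dropped: ",
            paste(unique(queries[duplicated(queries)]), collapse = ", "))
    queries <- unique(queries)
  }
  queries
}

#' Assign sequences to query taxa by delimited prefix match
#'
#' A sequence id belongs to query `q` when the id equals `q` or starts with
#' `q` followed by a separator character. When several queries match (e.g. a
#' genus and one of its species), the longest match wins. Unmatched ids are
#' labelled `"BACKGROUND"`.
#'
#' @param aln A `dmc_alignment`.
#' @param queries Character vector of query taxon labels (see
#'   [read_query_list()]).
#' @param sep Separator characters marking an id boundary. Default `"_"`
#'   and `"|"`.
#' @return The alignment with its `taxa` table populated.
#' @export
assign_taxa <- function(aln, queries, sep = c("_", "|")) {
  stopifnot(inherits(aln, "dmc_alignment"))
  queries <- as.character(queries)
  if (length(queries) == 0) stop("no query taxa supplied")
  ids <- names(aln$seq)
  assigned <- vapply(ids, function(id) {
    hits <- queries[vapply(queries, function(q) {
      id == q || any(startsWith(id, paste0(q, sep)))
    }, logical(1))]
    if (length(hits) == 0) return(BACKGROUND_LABEL)
    lens <- nchar(hits)
    best <- hits[lens == max(lens)]
    if (length(best) > 1) {
      stop(sprintf("sequence '%s' matches multiple queries of equal length: %s",
                   id, paste(best, collapse = ", ")))
    }
    best
  }, character(1), USE.NAMES = FALSE)
  aln$taxa <- tibble::tibble(seq_id = ids, taxon = assigned)
  aln
}

taxon_members <- function(aln, taxon) {
  aln$taxa$seq_id[aln$taxa$taxon == taxon]
}

#' Parse and format the bracketed DMC notation
#'
#' A DMC is printed as `"[25: A; 69: G]"`: semicolon-separated
#' `position: state` pairs, 1-based alignment columns, states in `A,C,G,T`.
#' `parse_dmc_string()` and `format_dmc_string()` are mutual inverses on
#' canonical strings.
#'
#' @param text A DMC string.
#' @return For `parse_dmc_string()`, a tibble with integer `position` and
#'   character `state`; for `format_dmc_string()`, a single string.
#' @examples
#' parse_dmc_string("[25: A; 69: G]")
#' format_dmc_string(tibble::tibble(position = c(25L, 69L), state = c("A", "G")))
#' @export
parse_dmc_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- trimws(text)
  if (!grepl("^\\[.*\\]$", s)) stop("DMC string must be bracketed: ", text)
  body <- trimws(substr(s, 2, nchar(s) - 1))
  if (!nzchar(body)) {
    return(tibble::tibble(position = integer(), state = character()))
  }
  tokens <- trimws(strsplit(body, ";", fixed = TRUE)[[1]])
  pairs <- lapply(seq_along(tokens), function(i) {
    m <- regmatches(tokens[i],
                    regexec("^([0-9]+)\\s*:\\s*([A-Za-z])$", tokens[i]))[[1]]
    if (length(m) != 3) {
      stop(sprintf("malformed DMC token %d: '%s'", i, tokens[i]))
    }
    state <- toupper(m[3])
    if (!state %in% BASES) {
      stop(sprintf("non-nucleotide state in DMC token %d: '%s'", i, tokens[i]))
    }
    list(position = as.integer(m[2]), state = state)
  })
  pos <- vapply(pairs, `[[`, integer(1), "position")
  if (anyDuplicated(pos)) {
    stop("duplicate position in DMC string: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  }
  tibble::tibble(position = pos,
                 state = vapply(pairs, `[[`, character(1), "state"))
}

#' @rdname parse_dmc_string
#' @param sites A tibble (or data frame) with columns `position` and `state`.
#' @export
format_dmc_string <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0) return("[]")
  paste0("[", paste(sprintf("%d: %s", sites$position, sites$state),
                    collapse = "; "), "]")
}

dmc_table_columns <- c(
  "taxon", "consensus_dmc", "consensus_length", "consensus_exclusivity",
  "alternative_dmc", "alternative_exclusivity", "n_optimal_candidates",
  "status", "reference_id"
)

#' Write and read DMC tables as CSV
#'
#' The on-disk schema has columns `taxon`, `consensus_dmc` (bracket
#' notation), `consensus_length`, `consensus_exclusivity`,
#' `alternative_dmc`, `alternative_exclusivity`, `n_optimal_candidates`,
#' `status` and `reference_id`. Rows with `status != "ok"` carry empty DMC
#' cells. `read_dmc_table()` is the exact inverse of `write_dmc_table()`.
#'
#' @param table A `dmc_table` as returned by [find_dmcs()].
#' @param path CSV file path.
#' @return `write_dmc_table()` returns `path` invisibly; `read_dmc_table()`
#'   returns a `dmc_table` tibble.
#' @export
write_dmc_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(table)[, dmc_table_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_dmc_table
#' @export
read_dmc_table <- function(path) {
  if (!file.exists(path)) stop("DMC table not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  needed <- setdiff(dmc_table_columns, "reference_id")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("DMC table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"reference_id" %in% names(raw)) raw$reference_id <- NA_character_
  tab <- tibble::tibble(
    taxon = raw$taxon,
    consensus_dmc = ifelse(nzchar(raw$consensus_dmc), raw$consensus_dmc, NA),
    consensus_length = suppressWarnings(as.integer(raw$consensus_length)),
    consensus_exclusivity = suppressWarnings(as.integer(raw$consensus_exclusivity)),
    alternative_dmc = ifelse(nzchar(raw$alternative_dmc), raw$alternative_dmc, NA),
    alternative_exclusivity = suppressWarnings(as.integer(raw$alternative_exclusivity)),
    n_optimal_candidates = suppressWarnings(as.integer(raw$n_optimal_candidates)),
    status = raw$status,
    reference_id = ifelse(nzchar(raw$reference_id) & !is.na(raw$reference_id),
                          raw$reference_id, NA_character_)
  )
  # validate every DMC string on ingest
  for (col in c("consensus_dmc", "alternative_dmc")) {
    ok <- is.na(tab[[col]])
    for (i in which(!ok)) parse_dmc_string(tab[[col]][i])
  }
  as_dmc_table(tab)
}

as_dmc_table <- function(x) {
  class(x) <- c("dmc_table", class(tibble::as_tibble(x)))
  x
}
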