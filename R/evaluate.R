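# Per-species confusion matrices and classification metrics from a match
# report, with the missing-data exclusion rule, plus the DMC state-matrix
# export used for visual comparison.

normalize_truth <- function(truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("seq_id", "taxon") %in% names(truth)))
    stats::setNames(truth$taxon, truth$seq_id)
  } else if (!is.null(names(truth))) {
    truth
  } else {
    stop("truth must be a named vector or a data frame with seq_id, taxon")
  }
}

#' Derive true taxon labels from sequence ids
#'
#' Applies the same delimited-prefix convention as [assign_taxa()]: an id
#' belongs to the longest query label that prefixes it at a separator
#' boundary, and unmatched ids are `"BACKGROUND"` (heterospecific for every
#' DMC).
#'
#' @param ids Character vector of sequence ids.
#' @param queries Query taxon labels.
#' @param sep Separator characters; see [assign_taxa()].
#' @return A named character vector mapping id to taxon label.
#' @export
truth_from_ids <- function(ids, queries, sep = c("_", "|")) {
  labels <- vapply(ids, function(id) {
    hits <- queries[vapply(queries, function(q) {
      id == q || any(startsWith(id, paste0(q, sep)))
    }, logical(1))]
    if (length(hits) == 0) return(BACKGROUND_LABEL)
    hits[which.max(nchar(hits))]
  }, character(1), USE.NAMES = FALSE)
  stats::setNames(labels, ids)
}

#' Per-taxon confusion counts with missing-data exclusion
#'
#' For each DMC's taxon, test sequences with missing data at any of that
#' DMC's sites are excluded from its confusion matrix (exclusion is
#' per-DMC: a sequence can be excluded for one species and counted for
#' another). Among the rest: TP = conspecific and matched, FN = conspecific
#' and unmatched, FP = heterospecific and matched, TN = heterospecific and
#' unmatched.
#'
#' @param report A `dmc_match_report`.
#' @param truth Mapping from sequence id to true taxon label: a named
#'   character vector or a data frame with columns `seq_id`, `taxon` (see
#'   [truth_from_ids()]).
#' @return A tibble with one row per DMC taxon: `taxon`, `TP`, `FP`, `TN`,
#'   `FN`, `n_excluded`, `has_conspecifics`.
#' @export
confusion_counts <- function(report, truth) {
  truth <- normalize_truth(truth)
  orphans <- setdiff(unique(report$sequence_id), names(truth))
  if (length(orphans) > 0) {
    stop("test sequences missing from truth labels: ",
         paste(utils::head(orphans, 5), collapse = ", "))
  }
  report |>
    dplyr::mutate(
      true_taxon = unname(truth[.data$sequence_id]),
      conspecific = .data$true_taxon == .data$taxon,
      excluded = .data$n_missing > 0
    ) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      TP = sum(!.data$excluded & .data$conspecific & .data$matched),
      FP = sum(!.data$excluded & !.data$conspecific & .data$matched),
      TN = sum(!.data$excluded & !.data$conspecific & !.data$matched),
      FN = sum(!.data$excluded & .data$conspecific & !.data$matched),
      n_excluded = sum(.data$excluded),
      has_conspecifics = any(.data$conspecific),
      .groups = "drop"
    )
}

#' Classification metrics from confusion counts
#'
#' Recall = TP/(TP+FN); Precision = TP/(TP+FP); Specificity = TN/(TN+FP);
#' Accuracy = (Recall + Specificity)/2 — the balanced form, *not*
#' (TP+TN)/total; F1 = 2PR/(P+R). A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0. For taxa without conspecific
#' test sequences only specificity is reported, since true positives and
#' false negatives cannot be determined.
#'
#' @param counts A tibble of confusion counts (see [confusion_counts()]).
#' @return The input with columns `recall`, `precision`, `specificity`,
#'   `accuracy`, `f1` appended.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- counts |>
    dplyr::mutate(
      recall = safe_div(.data$TP, .data$TP + .data$FN),
      precision = safe_div(.data$TP, .data$TP + .data$FP),
      specificity = safe_div(.data$TN, .data$TN + .data$FP),
      accuracy = (.data$recall + .data$specificity) / 2,
      f1 = ifelse(
        !is.na(.data$precision) & !is.na(.data$recall) &
          (.data$precision + .data$recall) > 0,
        2 * .data$precision * .data$recall / (.data$precision + .data$recall),
        NA_real_)
    )
  # specificity-only rule for taxa without conspecific test sequences
  no_con <- !out$has_conspecifics
  out$recall[no_con] <- NA_real_
  out$precision[no_con] <- NA_real_
  out$accuracy[no_con] <- NA_real_
  out$f1[no_con] <- NA_real_
  out
}

#' Evaluate DMCs: confusion counts plus metrics per taxon
#'
#' Convenience pipeline: [confusion_counts()] followed by
#' [classification_metrics()]. Deterministic and invariant to test-set
#' ordering.
#'
#' @inheritParams confusion_counts
#' @return A `dmc_metrics` tibble with columns `taxon`, `TP`, `FP`, `TN`,
#'   `FN`, `n_excluded`, `recall`, `precision`, `specificity`, `accuracy`,
#'   `f1`, `has_conspecifics`.
#' @export
evaluate_dmcs <- function(report, truth) {
  out <- classification_metrics(confusion_counts(report, truth)) |>
    dplyr::select("taxon", "TP", "FP", "TN", "FN", "n_excluded",
                  "recall", "precision", "specificity", "accuracy", "f1",
                  "has_conspecifics")
  attr(out, "mode") <- attr(report, "mode")
  attr(out, "tolerance") <- attr(report, "tolerance")
  class(out) <- c("dmc_metrics", class(tibble::as_tibble(out)))
  out
}

#' Write a match report or metrics table to CSV
#'
#' @param x A `dmc_match_report` or `dmc_metrics` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Per-taxon character-state matrix at a DMC's sites
#'
#' For each taxon in the alignment and each DMC position, reports the fixed
#' state when the taxon is monomorphic there, or the set of observed states
#' in `{A,G}` notation. The query taxon's row always equals the DMC states.
#' Missing states are ignored unless a taxon has nothing else at a column.
#'
#' @param aln A `dmc_alignment` with taxa assigned.
#' @param sites DMC sites (tibble with `position`, `state`), e.g. from
#'   [parse_dmc_string()].
#' @param taxon The DMC's query taxon (placed first in the output).
#' @return A `dmc_state_matrix` tibble: one row per taxon, one column per
#'   DMC position (named `pos_<position>`).
#' @export
dmc_state_matrix <- function(aln, sites, taxon = NULL) {
  stopifnot(inherits(aln, "dmc_alignment"))
  if (any(sites$position > aln$n_sites)) {
    stop("DMC position out of range: ",
         max(sites$position), " > ", aln$n_sites)
  }
  m <- alignment_matrix(aln)
  taxa <- unique(aln$taxa$taxon)
  if (!is.null(taxon)) taxa <- c(taxon, setdiff(taxa, taxon))
  rows <- purrr::map(taxa, function(tx) {
    ids <- aln$taxa$seq_id[aln$taxa$taxon == tx]
    cells <- vapply(sites$position, function(p) {
      obs <- m[ids, p]
      inf <- sort(unique(obs[!obs %in% MISSING_STATES]))
      if (length(inf) == 0) "?" else if (length(inf) == 1) inf
      else paste0("{", paste(inf, collapse = ","), "}")
    }, character(1))
    tibble::as_tibble(stats::setNames(as.list(cells),
                                      paste0("pos_", sites$position))) |>
      dplyr::mutate(taxon = tx, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sites") <- sites
  attr(out, "query_taxon") <- taxon
  class(out) <- c("dmc_state_matrix", class(tibble::as_tibble(out)))
  out
}
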