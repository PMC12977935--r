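# broom-style tidy()/glance() methods for the package's result tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DMC table into one row per diagnostic site
#'
#' @param x A `dmc_table` from [find_dmcs()] or [read_dmc_table()].
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `kind` (`consensus` or
#'   `alternative`), `position`, `state`, `exclusivity`.
#' @method tidy dmc_table
#' @export
tidy.dmc_table <- function(x, ...) {
  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    purrr::map(c("consensus", "alternative"), function(kind) {
      str <- x[[paste0(kind, "_dmc")]][i]
      if (is.na(str)) return(NULL)
      sites <- parse_dmc_string(str)
      excl <- x[[paste0(kind, "_exclusivity")]][i]
      dplyr::mutate(sites, taxon = x$taxon[i], kind = .env$kind,
                    exclusivity = excl, .before = 1)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Summarise a DMC table in one row
#'
#' @param x A `dmc_table`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of queries, successful searches and
#'   fallbacks, and consensus length/exclusivity summaries.
#' @method glance dmc_table
#' @export
glance.dmc_table <- function(x, ...) {
  ok <- x$status %in% c("ok", "ok_fallback")
  tibble::tibble(
    n_queries = nrow(x),
    n_ok = sum(ok),
    n_fallback = sum(x$status == "ok_fallback"),
    n_no_dmc = sum(x$status == "no_dmc_found"),
    n_no_sequences = sum(x$status == "no_query_sequences"),
    mean_length = mean(x$consensus_length[ok]),
    mean_exclusivity = mean(x$consensus_exclusivity[ok])
  )
}

#' Summarise a match report in one row
#'
#' @param x A `dmc_match_report`.
#' @param ... Unused.
#' @return A one-row tibble with the mode, tolerance, pair counts, match
#'   rate and the number of fully uninformative (all-missing) pairs.
#' @method glance dmc_match_report
#' @export
glance.dmc_match_report <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode") %||% NA_character_,
    tolerance = attr(x, "tolerance") %||% NA_integer_,
    n_pairs = nrow(x),
    n_matched = sum(x$matched),
    match_rate = mean(x$matched),
    n_uninformative = sum(x$n_missing == x$n_sites)
  )
}

#' Summarise an evaluation table in one row
#'
#' @param x A `dmc_metrics` table from [evaluate_dmcs()].
#' @param ... Unused.
#' @return A one-row tibble of macro-averaged metrics (undefined values
#'   excluded from the averages, never counted as zero).
#' @method glance dmc_metrics
#' @export
glance.dmc_metrics <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x),
    n_with_conspecifics = sum(x$has_conspecifics),
    mean_recall = mean(x$recall, na.rm = TRUE),
    mean_precision = mean(x$precision, na.rm = TRUE),
    mean_specificity = mean(x$specificity, na.rm = TRUE),
    mean_accuracy = mean(x$accuracy, na.rm = TRUE),
    mean_f1 = mean(x$f1, na.rm = TRUE)
  )
}
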