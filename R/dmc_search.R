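# Core DMC search: site weighting, weighted-random-sampling candidate
# construction, exclusivity scoring, refinement, and majority-consensus
# summarisation.

#' Search parameters for the DMC search
#'
#' @param iter Number of candidate combinations to evaluate (default 50000).
#' @param min_len Minimum DMC length in sites (default 2). Automatically
#'   raised to `exclusive` when `exclusive > min_len`, so the minimum number
#'   of exclusive states indirectly controls the minimum length.
#' @param exclusive Minimum number of exclusive character states: every
#'   background sequence must differ from the DMC at at least this many of
#'   its sites (default 2). Analogous to Bremer support — the number of extra
#'   matches needed to break the diagnosis.
#' @param ref_strength Refinement strength in `[0, 1]` (default 0.33):
#'   controls how intensively sub-combinations of optimal candidates are
#'   tested in search of shorter valid DMCs. `0` disables refinement.
#' @param max_len Cap on candidate growth (default 15); candidates that do
#'   not qualify by this length are rejected.
#' @param gaps_new If `TRUE`, alignment gaps (`-`) are treated as a fifth
#'   ordinary character state in background comparisons; if `FALSE` (default)
#'   gaps are missing data.
#' @param top_k Number of top-ranked qualifying candidates retained as the
#'   optimal pool for consensus building (default 100).
#' @param majority_threshold Site-inclusion frequency needed for a site to
#'   seed the majority-consensus DMC (default 0.5).
#' @param seed Root random seed; per-taxon streams are derived from it so
#'   results for one taxon do not depend on which other taxa are queried.
#' @param weight_method `"sequence"` (default): a site's weight is the
#'   fraction of informative background sequences whose state differs from
#'   the query state. `"state_set"`: one minus the Jaccard similarity of the
#'   query and background state sets at the site.
#' @param missing_differs If `TRUE`, missing background states count as
#'   differing in exclusivity scoring. Default `FALSE` (conservative: a
#'   missing state cannot demonstrate a difference).
#' @return A list of class `dmc_search_params`.
#' @export
dmc_search_params <- function(iter = 50000, min_len = 2, exclusive = 2,
                              ref_strength = 0.33, max_len = 15,
                              gaps_new = FALSE, top_k = 100,
                              majority_threshold = 0.5, seed = 1,
                              weight_method = c("sequence", "state_set"),
                              missing_differs = FALSE) {
  weight_method <- match.arg(weight_method)
  stopifnot(iter >= 1, min_len >= 1, exclusive >= 1,
            ref_strength >= 0, ref_strength <= 1,
            max_len >= 1, top_k >= 1,
            majority_threshold > 0, majority_threshold <= 1)
  eff_min_len <- max(min_len, exclusive)
  if (eff_min_len > max_len) {
    stop("effective minimum length (max(min_len, exclusive) = ", eff_min_len,
         ") exceeds max_len (", max_len, ")")
  }
  structure(list(
    iter = as.integer(iter), min_len = as.integer(min_len),
    exclusive = as.integer(exclusive), ref_strength = ref_strength,
    max_len = as.integer(max_len), gaps_new = isTRUE(gaps_new),
    top_k = as.integer(top_k), majority_threshold = majority_threshold,
    seed = as.integer(seed), weight_method = weight_method,
    missing_differs = isTRUE(missing_differs),
    eff_min_len = as.integer(eff_min_len)
  ), class = "dmc_search_params")
}

# --- eligibility ------------------------------------------------------------

#' Site eligibility and fixed query state per alignment column
#'
#' A column can contribute a DMC site only when at least one query sequence
#' has a non-missing state there and all non-missing query states are
#' identical and unambiguous. Under `gaps_new`, `-` is an ordinary state for
#' comparison purposes but a column fixed for `-` in the query is still
#' ineligible (a DMC cites nucleotides).
#'
#' @param aln A `dmc_alignment` with taxa assigned.
#' @param taxon Query taxon label.
#' @param gaps_new Gap policy; see [dmc_search_params()].
#' @return A tibble with one row per column: `position`, `eligible`,
#'   `state` (the shared query state, `NA` when ineligible).
#' @export
site_eligibility <- function(aln, taxon, gaps_new = FALSE) {
  members <- taxon_members(aln, taxon)
  if (length(members) == 0) {
    stop("no sequences assigned to query taxon '", taxon, "'")
  }
  m <- alignment_matrix(aln)[members, , drop = FALSE]
  res <- apply(m, 2, function(col) {
    obs <- col[!is_missing_state(col, gaps_new)]
    if (length(obs) == 0) return(NA_character_)
    u <- unique(obs)
    # under gaps_new a column fixed for "-" fails the `u %in% BASES` test:
    # gaps are a comparison state but never a citable DMC site
    if (length(u) == 1 && u %in% BASES) u else NA_character_
  })
  tibble::tibble(
    position = seq_len(aln$n_sites),
    eligible = !is.na(res),
    state = unname(res)
  )
}

# --- weights ----------------------------------------------------------------

#' Jaccard-style site uniqueness weights
#'
#' Scores each alignment column by how strongly the query taxon's fixed
#' state there separates it from the background. Under the default
#' `"sequence"` method the weight is `d/B`: the fraction of background
#' sequences with informative data at the column whose state differs from
#' the query state (an ambiguity code counts as differing unless it expands
#' to exactly the query state). Under `"state_set"` the weight is one minus
#' the Jaccard similarity between the query and background state sets.
#' Ineligible columns and columns without informative background data get
#' weight 0.
#'
#' @inheritParams site_eligibility
#' @param method Weighting variant; see [dmc_search_params()].
#' @return A tibble with columns `position`, `eligible`, `state`, `weight`.
#' @export
site_weights <- function(aln, taxon, gaps_new = FALSE,
                         method = c("sequence", "state_set")) {
  method <- match.arg(method)
  elig <- site_eligibility(aln, taxon, gaps_new)
  bg_ids <- aln$taxa$seq_id[aln$taxa$taxon != taxon]
  m <- alignment_matrix(aln)[bg_ids, , drop = FALSE]
  w <- numeric(aln$n_sites)
  for (j in which(elig$eligible)) {
    q <- elig$state[j]
    col <- m[, j]
    informative <- col[!is_missing_state(col, gaps_new)]
    if (length(informative) == 0) next
    if (method == "sequence") {
      expansions <- IUPAC_EXPANSION[informative]
      differs <- vapply(expansions, function(e) !identical(e, q), logical(1))
      # gaps under gaps_new are a fifth state: always differ from a base
      differs[informative == "-"] <- TRUE
      w[j] <- sum(differs) / length(informative)
    } else {
      bg_set <- unique(unlist(IUPAC_EXPANSION[setdiff(informative, "-")],
                              use.names = FALSE))
      if ("-" %in% informative) bg_set <- union(bg_set, "-")
      w[j] <- 1 - length(intersect(q, bg_set)) / length(union(q, bg_set))
    }
  }
  elig$weight <- w
  elig
}

# --- exclusivity ------------------------------------------------------------

# 0/1 matrix of demonstrable differences: rows = background sequences,
# columns = DMC sites. Entry 1 iff the background state is non-missing and
# its IUPAC expansion does not contain the DMC state (so the sequence cannot
# carry the diagnostic state there). Exclusivity of a site set is the minimum
# row sum over this matrix.
background_diff_matrix <- function(aln, taxon, positions, states,
                                   gaps_new = FALSE, missing_differs = FALSE) {
  bg_ids <- aln$taxa$seq_id[aln$taxa$taxon != taxon]
  if (length(bg_ids) == 0) {
    stop("exclusivity is undefined without background sequences")
  }
  m <- alignment_matrix(aln)[bg_ids, positions, drop = FALSE]
  D <- matrix(0L, nrow = length(bg_ids), ncol = length(positions))
  for (k in seq_along(positions)) {
    col <- m[, k]
    miss <- is_missing_state(col, gaps_new)
    could <- state_could_match(col, rep(states[k], length(col)))
    could[col == "-"] <- FALSE  # a gap never carries a base (gaps_new case)
    D[, k] <- as.integer(ifelse(miss, as.integer(missing_differs), !could))
  }
  rownames(D) <- bg_ids
  D
}

#' Exclusivity score of a site/state combination
#'
#' The minimum, over all background sequences, of the number of DMC sites at
#' which that sequence demonstrably differs from the DMC state — i.e. the
#' number of extra nucleotide matches a background sequence would need to
#' break the diagnosis. Missing background states do not count as differing
#' (conservative), nor do ambiguity codes whose expansion contains the DMC
#' state.
#'
#' @inheritParams site_eligibility
#' @param sites A tibble with columns `position` and `state` (as returned by
#'   [parse_dmc_string()]).
#' @param missing_differs Count missing background states as differing
#'   (default `FALSE`).
#' @return A non-negative integer. An empty site list scores 0.
#' @export
exclusivity_score <- function(sites, aln, taxon, gaps_new = FALSE,
                              missing_differs = FALSE) {
  if (is.null(sites) || nrow(sites) == 0) return(0L)
  D <- background_diff_matrix(aln, taxon, sites$position, sites$state,
                              gaps_new, missing_differs)
  as.integer(min(rowSums(D)))
}

# --- search context ---------------------------------------------------------

# Precomputed per-taxon state shared by sampling, refinement and consensus:
# eligible columns, their query states, sampling weights, and the background
# difference matrix over all eligible columns.
search_context <- function(aln, taxon, params) {
  wtab <- site_weights(aln, taxon, params$gaps_new, params$weight_method)
  elig_pos <- wtab$position[wtab$eligible]
  if (length(elig_pos) == 0) return(NULL)
  states <- wtab$state[wtab$eligible]
  D <- background_diff_matrix(aln, taxon, elig_pos, states,
                              params$gaps_new, params$missing_differs)
  w <- wtab$weight[wtab$eligible]
  list(
    positions = elig_pos,                 # alignment columns, by eligible index
    states = stats::setNames(states, elig_pos),
    weights = w,                          # by eligible index
    D = D,                                # background x eligible index
    pool_idx = which(w > 0),
    pool_w = w[w > 0]
  )
}

ctx_exclusivity <- function(ctx, idx) {
  if (length(idx) == 0) return(0L)
  as.integer(min(rowSums(ctx$D[, idx, drop = FALSE])))
}

ctx_sites <- function(ctx, idx) {
  pos <- sort(ctx$positions[idx])
  tibble::tibble(position = pos, state = unname(ctx$states[as.character(pos)]))
}

# One weighted-random-sampling draw: a permutation of positive-weight columns
# drawn sequentially with probability proportional to weight, grown until the
# first prefix of length >= eff_min_len reaches the exclusivity threshold.
# Returns eligible-column indices or NULL on rejection.
draw_candidate <- function(ctx, params) {
  pool_idx <- ctx$pool_idx
  if (length(pool_idx) == 0) {
    stop("degenerate search: no column separates the query from the background")
  }
  k <- min(params$max_len, length(pool_idx))
  perm <- if (length(pool_idx) == 1) pool_idx else
    pool_idx[sample.int(length(pool_idx), size = k, prob = ctx$pool_w)]
  D <- ctx$D
  eff <- params$eff_min_len
  excl <- params$exclusive
  d <- numeric(nrow(D))
  for (L in seq_len(k)) {
    d <- d + D[, perm[L]]
    if (L >= eff && min(d) >= excl) return(perm[seq_len(L)])
  }
  NULL
}

#' Draw one candidate DMC by weighted random sampling
#'
#' Sites are drawn one at a time without replacement with probability
#' proportional to their uniqueness weight; growth stops at the first length
#' `>= max(min_len, exclusive)` whose exclusivity reaches `exclusive`, and
#' the draw is rejected if no prefix qualifies by `max_len` sites. Uses the
#' current RNG state.
#'
#' @inheritParams site_eligibility
#' @param params A [dmc_search_params()] object.
#' @return A tibble of sites (`position`, `state`) with attribute
#'   `exclusivity`, or `NULL` when the draw is rejected.
#' @export
sample_candidate <- function(aln, taxon, params = dmc_search_params()) {
  ctx <- search_context(aln, taxon, params)
  if (is.null(ctx)) stop("no eligible columns for taxon '", taxon, "'")
  idx <- draw_candidate(ctx, params)
  if (is.null(idx)) return(NULL)
  out <- ctx_sites(ctx, idx)
  attr(out, "exclusivity") <- ctx_exclusivity(ctx, idx)
  out
}

# --- refinement -------------------------------------------------------------

refine_indices <- function(idx, ctx, params) {
  L <- length(idx)
  if (params$ref_strength == 0 || L <= params$eff_min_len) return(list())
  found <- new.env(parent = emptyenv())
  qualifies <- function(sub) {
    length(sub) >= params$eff_min_len && ctx_exclusivity(ctx, sub) >= params$exclusive
  }
  record <- function(sub) {
    assign(paste(sort(sub), collapse = ","), sort(sub), envir = found)
  }
  if (2^L <= 4096) {
    # exhaustive: every qualifying proper subset of allowed size
    for (size in params$eff_min_len:(L - 1)) {
      combos <- utils::combn(idx, size, simplify = FALSE)
      for (sub in combos) if (qualifies(sub)) record(sub)
    }
  } else {
    r <- max(1L, round(params$ref_strength * L))
    for (pass in seq_len(r)) {
      cur <- idx
      for (site in sample(idx)) {
        if (length(cur) <= params$eff_min_len) break
        if (!site %in% cur) next
        trial <- setdiff(cur, site)
        if (qualifies(trial)) {
          cur <- trial
          record(cur)
        }
      }
    }
  }
  unname(as.list(found))
}

#' Refine a qualifying DMC towards shorter sub-combinations
#'
#' Tests sub-combinations of a qualifying candidate and returns the distinct
#' shorter combinations that still meet the length and exclusivity
#' constraints. For short candidates (`2^L <= 4096`) all proper subsets of
#' allowed size are enumerated; for longer ones, `max(1, round(ref_strength
#' * L))` randomized backward-elimination passes are run. `ref_strength = 0`
#' returns nothing.
#'
#' @inheritParams exclusivity_score
#' @param params A [dmc_search_params()] object.
#' @return A list of site tibbles (possibly empty), each qualifying.
#' @export
refine_dmc <- function(sites, aln, taxon, params = dmc_search_params()) {
  ctx <- search_context(aln, taxon, params)
  idx <- match(sites$position, ctx$positions)
  if (anyNA(idx)) stop("DMC contains positions that are not eligible columns")
  subs <- refine_indices(idx, ctx, params)
  lapply(subs, function(s) ctx_sites(ctx, s))
}

# --- pool ranking and consensus --------------------------------------------

# Rank candidates by exclusivity (desc), length (asc), then lexicographically
# smallest position vector; fully deterministic.
rank_pool <- function(pool) {
  lex <- vapply(pool$idx_sorted_pos, function(p)
    paste(sprintf("%06d", p), collapse = ","), character(1))
  pool[order(-pool$exclusivity, pool$length, lex), , drop = FALSE]
}

make_pool <- function(cand_env, ctx) {
  keys <- ls(cand_env)
  if (length(keys) == 0) {
    return(tibble::tibble(idx = list(), idx_sorted_pos = list(),
                          exclusivity = integer(), length = integer()))
  }
  idx_list <- lapply(keys, function(k) get(k, envir = cand_env)$idx)
  excl <- vapply(keys, function(k) get(k, envir = cand_env)$excl, integer(1))
  tibble::tibble(
    idx = idx_list,
    idx_sorted_pos = lapply(idx_list, function(i) sort(ctx$positions[i])),
    exclusivity = unname(excl),
    length = lengths(idx_list)
  )
}

#' Build the majority-consensus and alternative DMC from a candidate pool
#'
#' The `top_k` candidates (ranked by exclusivity, then brevity, then
#' position order) form the optimal pool. Sites present in at least
#' `majority_threshold` of pool members seed the consensus; next-most
#' frequent sites (ties broken towards lower columns) are added greedily
#' until the consensus meets the length and exclusivity constraints. If no
#' augmentation qualifies, the top-ranked candidate is returned instead and
#' the fallback is flagged. The alternative DMC is the highest-ranked pool
#' member distinct from the consensus.
#'
#' @param pool A list of qualifying site tibbles (`position`, `state`).
#' @inheritParams site_eligibility
#' @param params A [dmc_search_params()] object.
#' @return A list with elements `consensus`, `alternative` (site tibbles with
#'   attribute `exclusivity`), `n_optimal`, `fallback` (logical), or `NULL`
#'   when the pool is empty.
#' @export
consensus_dmc <- function(pool, aln, taxon, params = dmc_search_params()) {
  ctx <- search_context(aln, taxon, params)
  if (length(pool) == 0) return(NULL)
  cand_env <- new.env(parent = emptyenv())
  for (sites in pool) {
    idx <- match(sites$position, ctx$positions)
    if (anyNA(idx)) stop("pool member contains ineligible positions")
    key <- paste(sort(idx), collapse = ",")
    if (!exists(key, envir = cand_env)) {
      assign(key, list(idx = idx, excl = ctx_exclusivity(ctx, idx)),
             envir = cand_env)
    }
  }
  ptab <- rank_pool(make_pool(cand_env, ctx))
  consensus_from_pool(ptab, ctx, params)
}

consensus_from_pool <- function(ptab, ctx, params) {
  if (nrow(ptab) == 0) return(NULL)
  optimal <- utils::head(ptab, params$top_k)
  all_idx <- sort(unique(unlist(optimal$idx)))
  freq <- vapply(all_idx, function(i)
    mean(vapply(optimal$idx, function(s) i %in% s, logical(1))), numeric(1))
  # order sites by frequency desc, then lower alignment column first
  ord <- order(-freq, ctx$positions[all_idx])
  ordered_idx <- all_idx[ord]
  ordered_freq <- freq[ord]
  start_n <- sum(ordered_freq >= params$majority_threshold)
  fallback <- FALSE
  consensus_idx <- NULL
  for (n in max(start_n, 1):length(ordered_idx)) {
    cand <- ordered_idx[seq_len(n)]
    if (length(cand) >= params$eff_min_len &&
        ctx_exclusivity(ctx, cand) >= params$exclusive) {
      consensus_idx <- cand
      break
    }
  }
  if (is.null(consensus_idx)) {
    consensus_idx <- optimal$idx[[1]]
    fallback <- TRUE
  }
  cons_key <- paste(sort(consensus_idx), collapse = ",")
  alt_idx <- NULL
  for (i in seq_len(nrow(optimal))) {
    if (paste(sort(optimal$idx[[i]]), collapse = ",") != cons_key) {
      alt_idx <- optimal$idx[[i]]
      break
    }
  }
  if (is.null(alt_idx)) alt_idx <- optimal$idx[[1]]
  cons <- ctx_sites(ctx, consensus_idx)
  attr(cons, "exclusivity") <- ctx_exclusivity(ctx, consensus_idx)
  alt <- ctx_sites(ctx, alt_idx)
  attr(alt, "exclusivity") <- ctx_exclusivity(ctx, alt_idx)
  list(consensus = cons, alternative = alt,
       n_optimal = nrow(optimal), fallback = fallback)
}

# --- top-level search -------------------------------------------------------

#' Find diagnostic molecular combinations for a set of query taxa
#'
#' For each query taxon: score alignment columns by uniqueness, run `iter`
#' weighted-random-sampling construction attempts, refine the retained
#' optimal candidates towards shorter combinations, and summarise the pool
#' as a majority-consensus DMC plus one optimal alternative. Both reported
#' DMCs are re-verified against the length and exclusivity constraints
#' before output. The whole run is reproducible from `params$seed`;
#' per-taxon RNG streams are independent.
#'
#' @param aln A `dmc_alignment` (taxa are assigned from `queries` if not
#'   already).
#' @param queries Character vector of query taxon labels.
#' @param params A [dmc_search_params()] object.
#' @return A `dmc_table` tibble with one row per query taxon and columns
#'   `taxon`, `consensus_dmc`, `consensus_length`, `consensus_exclusivity`,
#'   `alternative_dmc`, `alternative_exclusivity`, `n_optimal_candidates`,
#'   `status` (`ok`, `ok_fallback`, `no_dmc_found` or `no_query_sequences`)
#'   and `reference_id` (the taxon's designated reference sequence, used by
#'   the unaligned identification modes).
#' @examples
#' \donttest{
#' spec <- synth_spec(n_species = 4, seqs_per_species = 3, n_sites = 60,
#'                    seed = 7)
#' synth <- generate_training_alignment(spec)
#' tab <- find_dmcs(synth$alignment, synth$truth$taxon,
#'                  dmc_search_params(iter = 500, seed = 7))
#' tab
#' }
#' @export
find_dmcs <- function(aln, queries, params = dmc_search_params()) {
  stopifnot(inherits(aln, "dmc_alignment"))
  queries <- as.character(queries)
  if (!any(aln$taxa$taxon %in% queries)) {
    aln <- assign_taxa(aln, queries)
  }
  rows <- lapply(queries, function(taxon) {
    search_one_taxon(aln, taxon, params)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  as_dmc_table(out)
}

empty_row <- function(taxon, status, ref_id = NA_character_) {
  tibble::tibble(
    taxon = taxon, consensus_dmc = NA_character_,
    consensus_length = NA_integer_, consensus_exclusivity = NA_integer_,
    alternative_dmc = NA_character_, alternative_exclusivity = NA_integer_,
    n_optimal_candidates = 0L, status = status, reference_id = ref_id
  )
}

search_one_taxon <- function(aln, taxon, params) {
  members <- taxon_members(aln, taxon)
  if (length(members) == 0) return(empty_row(taxon, "no_query_sequences"))
  ref_id <- members[[1]]
  ctx <- tryCatch(search_context(aln, taxon, params), error = identity)
  if (inherits(ctx, "error")) stop(ctx)
  if (is.null(ctx) || all(ctx$weights <= 0)) {
    return(empty_row(taxon, "no_dmc_found", ref_id))
  }
  res <- with_seed(derive_seed(params$seed, taxon), {
    cand_env <- new.env(parent = emptyenv())
    for (i in seq_len(params$iter)) {
      idx <- draw_candidate(ctx, params)
      if (is.null(idx)) next
      key <- paste(sort(idx), collapse = ",")
      if (!exists(key, envir = cand_env)) {
        assign(key, list(idx = idx, excl = ctx_exclusivity(ctx, idx)),
               envir = cand_env)
      }
    }
    ptab <- rank_pool(make_pool(cand_env, ctx))
    if (nrow(ptab) == 0) {
      NULL
    } else {
      # refine the retained optimal candidates; fold reductions into the pool
      if (params$ref_strength > 0) {
        for (idx in utils::head(ptab, params$top_k)$idx) {
          for (sub in refine_indices(idx, ctx, params)) {
            key <- paste(sub, collapse = ",")
            if (!exists(key, envir = cand_env)) {
              assign(key, list(idx = sub, excl = ctx_exclusivity(ctx, sub)),
                     envir = cand_env)
            }
          }
        }
        ptab <- rank_pool(make_pool(cand_env, ctx))
      }
      consensus_from_pool(ptab, ctx, params)
    }
  })
  if (is.null(res)) return(empty_row(taxon, "no_dmc_found", ref_id))
  cons_excl <- attr(res$consensus, "exclusivity")
  alt_excl <- attr(res$alternative, "exclusivity")
  # final re-verification of the output contracts
  stopifnot(nrow(res$consensus) >= params$eff_min_len,
            cons_excl >= params$exclusive,
            nrow(res$alternative) >= params$eff_min_len,
            alt_excl >= params$exclusive)
  tibble::tibble(
    taxon = taxon,
    consensus_dmc = format_dmc_string(res$consensus),
    consensus_length = nrow(res$consensus),
    consensus_exclusivity = cons_excl,
    alternative_dmc = format_dmc_string(res$alternative),
    alternative_exclusivity = alt_excl,
    n_optimal_candidates = res$n_optimal,
    status = if (res$fallback) "ok_fallback" else "ok",
    reference_id = ref_id
  )
}
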