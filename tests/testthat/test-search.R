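test_that("site eligibility follows the fixed-state and gap rules", {
  aln <- make_alignment(c(
    Q_a_1 = "AANR-",
    Q_a_2 = "ACN-A",
    X_b_1 = "CCCCC"
  ), queries = "Q_a")
  off <- site_eligibility(aln, "Q_a", gaps_new = FALSE)
  # col1 {A,A} fixed; col2 {A,C} polymorphic; col3 {N,N} all missing;
  # col4 {R,-} gap missing, R ambiguous; col5 {-,A} gap missing -> A
  expect_equal(off$eligible, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(off$state[c(1, 5)], c("A", "A"))

  on <- site_eligibility(aln, "Q_a", gaps_new = TRUE)
  # under gaps-as-state, col5 {-,A} is polymorphic -> ineligible
  expect_equal(on$eligible, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  expect_error(site_eligibility(aln, "Zz_q"), "no sequences")
})

test_that("site weights equal the differing-background fraction", {
  # query fixed A; background states A, C, C, G at the focal column
  aln <- make_alignment(c(
    Q_a_1 = "AT", Q_a_2 = "AT",
    X_1 = "AA", X_2 = "CA", X_3 = "CA", X_4 = "GA"
  ), queries = "Q_a")
  w <- site_weights(aln, "Q_a")
  expect_equal(w$weight[1], 3 / 4)
  # column 2: query T, all background A -> every informative sequence differs
  expect_equal(w$weight[2], 1)

  # invariant column gets weight zero
  aln2 <- make_alignment(c(Q_a_1 = "AA", X_1 = "AC"), queries = "Q_a")
  expect_equal(site_weights(aln2, "Q_a")$weight[1], 0)
  expect_true(all(dplyr::between(w$weight, 0, 1)))
})

test_that("weights treat ambiguity codes and missing data as specified", {
  # background R at an A-column differs (expansion {A,G} != {A});
  # background N is uninformative and drops out of the denominator
  aln <- make_alignment(c(
    Q_a_1 = "A", X_1 = "R", X_2 = "N", X_3 = "A"
  ), queries = "Q_a")
  expect_equal(site_weights(aln, "Q_a")$weight[1], 1 / 2)
})

test_that("exclusivity_score agrees with the brute-force oracle", {
  aln <- toy_alignment()
  for (taxon in c("Aus_bus", "Aus_cus", "Dus_eus")) {
    elig <- site_eligibility(aln, taxon)
    pos <- elig$position[elig$eligible]
    st <- elig$state[elig$eligible]
    withr::with_seed(99, {
      for (rep in 1:25) {
        k <- sample(1:4, 1)
        pick <- sort(sample(seq_along(pos), k))
        sites <- tibble::tibble(position = pos[pick], state = st[pick])
        expect_identical(exclusivity_score(sites, aln, taxon),
                         oracle_exclusivity(aln, taxon, sites))
      }
    })
  }
  # hand-checked cases
  empty <- tibble::tibble(position = integer(), state = character())
  expect_identical(exclusivity_score(empty, aln, "Aus_bus"), 0L)
  one <- parse_dmc_string("[1: A; 4: T]")
  expect_identical(exclusivity_score(one, aln, "Aus_bus"), 1L)
})

test_that("adding a site never decreases exclusivity", {
  aln <- toy_alignment()
  elig <- site_eligibility(aln, "Aus_bus")
  pos <- elig$position[elig$eligible]
  st <- elig$state[elig$eligible]
  withr::with_seed(4, {
    for (rep in 1:20) {
      base_idx <- sort(sample(seq_along(pos), 3))
      extra <- sample(setdiff(seq_along(pos), base_idx), 1)
      s0 <- tibble::tibble(position = pos[base_idx], state = st[base_idx])
      s1 <- dplyr::arrange(dplyr::bind_rows(
        s0, tibble::tibble(position = pos[extra], state = st[extra])),
        position)
      expect_gte(exclusivity_score(s1, aln, "Aus_bus"),
                 exclusivity_score(s0, aln, "Aus_bus"))
    }
  })
})

test_that("candidate sampling is degenerate-safe and proportional", {
  # one informative column: the candidate is exactly that column
  aln <- make_alignment(c(Q_a_1 = "ATT", X_1 = "CTT", X_2 = "CTT"),
                        queries = "Q_a")
  p <- dmc_search_params(min_len = 1, exclusive = 1, seed = 1)
  withr::with_seed(1, {
    cand <- sample_candidate(aln, "Q_a", p)
    expect_equal(cand$position, 1L)
    expect_equal(attr(cand, "exclusivity"), 1L)
  })

  # equal weights over m columns: first drawn site uniform
  # (chi-square goodness of fit on >= 10^4 seeded draws)
  m <- 5
  seqs <- c(Q_a_1 = paste(rep("A", m), collapse = ""),
            X_1 = paste(rep("C", m), collapse = ""))
  aln2 <- make_alignment(seqs, queries = "Q_a")
  p2 <- dmc_search_params(min_len = 1, exclusive = 1, seed = 1)
  firsts <- withr::with_seed(7, {
    vapply(1:10000, function(i) sample_candidate(aln2, "Q_a", p2)$position[1],
           integer(1))
  })
  chi <- suppressWarnings(stats::chisq.test(table(factor(firsts, levels = 1:m))))
  expect_gt(chi$p.value, 0.01)
})

test_that("sampling rejects taxa with no qualifying combination", {
  # background identical to query at every column: weights all zero
  aln <- make_alignment(c(Q_a_1 = "ACGT", X_1 = "ACGT"), queries = "Q_a")
  expect_error(sample_candidate(aln, "Q_a", dmc_search_params(min_len = 1,
                                                              exclusive = 1)),
               "degenerate")
  tab <- find_dmcs(aln, "Q_a", dmc_search_params(iter = 10, min_len = 1,
                                                 exclusive = 1, seed = 2))
  expect_equal(tab$status, "no_dmc_found")

  # informative sites exist but exclusivity 3 is unreachable: brute force
  # confirms no combination qualifies, so every iteration rejects
  aln2 <- make_alignment(c(Q_a_1 = "AAAA", X_1 = "CCAA", X_2 = "AACC"),
                         queries = "Q_a")
  expect_true(is.na(oracle_min_qualifying_length(aln2, "Q_a", exclusive = 3,
                                                 max_size = 4)))
  tab2 <- find_dmcs(aln2, "Q_a", dmc_search_params(iter = 500, min_len = 1,
                                                   exclusive = 3, max_len = 4,
                                                   seed = 3))
  expect_equal(tab2$status, "no_dmc_found")
})

test_that("refinement returns qualifying reductions and respects bounds", {
  aln <- toy_alignment()
  p <- dmc_search_params(min_len = 2, exclusive = 1, ref_strength = 1, seed = 1)
  # [1: A; 4: T; 10: C] qualifies; subsets {1,4}, {1,10}, {4,9}... checked
  # against the oracle
  sites <- parse_dmc_string("[1: A; 4: T; 10: C]")
  expect_gte(exclusivity_score(sites, aln, "Aus_bus"), 1L)
  reduced <- withr::with_seed(1, refine_dmc(sites, aln, "Aus_bus", p))
  expect_gt(length(reduced), 0)
  for (r in reduced) {
    expect_gte(nrow(r), 2)
    expect_lt(nrow(r), 3)
    expect_gte(oracle_exclusivity(aln, "Aus_bus", r), 1L)
  }

  # ref_strength = 0: no refinement at all
  p0 <- dmc_search_params(min_len = 2, exclusive = 1, ref_strength = 0)
  expect_length(withr::with_seed(1, refine_dmc(sites, aln, "Aus_bus", p0)), 0)

  # a DMC whose every allowed proper subset fails exclusivity returns nothing
  aln2 <- make_alignment(c(Q_a_1 = "AAA", X_1 = "CCA", X_2 = "ACC"),
                         queries = "Q_a")
  p2 <- dmc_search_params(min_len = 1, exclusive = 2, ref_strength = 1)
  s3 <- tibble::tibble(position = 1:3, state = c("A", "A", "A"))
  expect_identical(exclusivity_score(s3, aln2, "Q_a"), 2L)
  expect_length(withr::with_seed(1, refine_dmc(s3, aln2, "Q_a", p2)), 0)
})

test_that("randomized refinement recovers a planted redundant-site reduction", {
  # query has 3 exclusive columns (1,2,3) plus a redundant column 4 shared
  # with one background sequence; dropping site 4 still qualifies
  aln <- make_alignment(c(
    Q_a_1 = paste0("AAAA", strrep("T", 12)),
    X_1 = paste0("CCCA", strrep("T", 12)),
    X_2 = paste0("CCCC", strrep("T", 12))
  ), queries = "Q_a")
  sites <- tibble::tibble(position = 1:4, state = rep("A", 4))
  p <- dmc_search_params(min_len = 3, exclusive = 3, ref_strength = 1)
  # force the randomized path by lifting the enumeration cutoff artificially:
  # L = 4 is below it, so enumeration applies and must find the reduction
  found <- withr::with_seed(1, refine_dmc(sites, aln, "Q_a", p))
  expect_true(any(vapply(found, function(r)
    identical(r$position, 1:3), logical(1))))

  # stochastic recovery with backward elimination on a longer DMC:
  # 16 sites (2^16 > 4096), one redundant
  long <- make_alignment(c(
    Q_b_1 = paste0(strrep("A", 17), "G"),
    Y_1 = paste0(strrep("C", 16), "AG"),
    Y_2 = paste0(strrep("C", 17), "G")
  ), queries = "Q_b")
  sites16 <- tibble::tibble(position = c(1:16, 17L), state = rep("A", 17))
  p16 <- dmc_search_params(min_len = 16, exclusive = 16, ref_strength = 1,
                           max_len = 20)
  hits <- withr::with_seed(21, {
    vapply(1:100, function(i) {
      red <- refine_dmc(sites16, long, "Q_b", p16)
      any(vapply(red, function(r) nrow(r) == 16, logical(1)))
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("consensus is built from majority sites and verified", {
  aln <- toy_alignment()
  p <- dmc_search_params(min_len = 2, exclusive = 1, seed = 1)
  # pool of one candidate: consensus = alternative = that candidate
  one <- list(parse_dmc_string("[1: A; 4: T]"))
  res <- consensus_dmc(one, aln, "Aus_bus", p)
  expect_equal(res$consensus$position, c(1L, 4L))
  expect_equal(res$alternative$position, c(1L, 4L))
  expect_equal(res$n_optimal, 1L)

  # three candidates sharing sites 1 and 4 (frequency 1), each with one
  # private site: consensus = {1, 4}, which qualifies on its own
  pool <- list(parse_dmc_string("[1: A; 4: T; 7: G]"),
               parse_dmc_string("[1: A; 4: T; 9: A]"),
               parse_dmc_string("[1: A; 4: T; 10: C]"))
  res2 <- consensus_dmc(pool, aln, "Aus_bus", p)
  expect_equal(res2$consensus$position, c(1L, 4L))
  expect_false(res2$fallback)
  expect_gte(attr(res2$consensus, "exclusivity"), 1L)

  # empty pool -> NULL (reported upstream as no_dmc_found)
  expect_null(consensus_dmc(list(), aln, "Aus_bus", p))
})

test_that("consensus greedily augments majority sites until it qualifies", {
  # species Q_a: columns 1-5 all fixed A; backgrounds chosen so that the
  # majority sites {1,2} have exclusivity 1 < 2 and the next most frequent
  # site (ties broken towards lower columns: 3) restores exclusivity 2
  aln <- make_alignment(c(
    Q_a_1 = "AAAAAT",
    X_1 = "CCAAAT",  # differs at 1,2 only
    X_2 = "ACCCCT"   # differs at 2,3,4,5
  ), queries = "Q_a")
  p <- dmc_search_params(min_len = 2, exclusive = 2, seed = 1, top_k = 10)
  pool <- list(parse_dmc_string("[1: A; 2: A; 3: A]"),
               parse_dmc_string("[1: A; 2: A; 4: A]"),
               parse_dmc_string("[1: A; 2: A; 5: A]"))
  # majority sites {1,2} (freq 1) fail: X_2 differs only at 2 -> excl 1
  expect_identical(exclusivity_score(parse_dmc_string("[1: A; 2: A]"),
                                     aln, "Q_a"), 1L)
  res <- consensus_dmc(pool, aln, "Q_a", p)
  expect_false(res$fallback)
  expect_equal(res$consensus$position, c(1L, 2L, 3L))
  expect_gte(attr(res$consensus, "exclusivity"), 2L)
})

test_that("find_dmcs recovers planted diagnostic sites and satisfies contracts", {
  spec <- synth_spec(n_species = 8, seqs_per_species = 5, n_sites = 40,
                     planted_sites_per_species = 2,
                     background_divergence = 0.02, seed = 31)
  synth <- generate_training_alignment(spec)
  tab <- find_dmcs(synth$alignment, synth$truth$taxon,
                   dmc_search_params(iter = 2000, min_len = 2, exclusive = 2,
                                     ref_strength = 1, seed = 8))
  expect_true(all(tab$status %in% c("ok", "ok_fallback")))
  n_inclusion_checked <- 0L
  for (i in seq_len(nrow(tab))) {
    tx <- tab$taxon[i]
    sites <- parse_dmc_string(tab$consensus_dmc[i])
    expect_gte(nrow(sites), 2)
    expect_identical(oracle_exclusivity(synth$alignment, tx, sites),
                     tab$consensus_exclusivity[i])
    expect_gte(tab$consensus_exclusivity[i], 2L)
    planted <- synth$truth$sites$position[synth$truth$sites$taxon == tx]
    planted_sites <- synth$truth$sites[synth$truth$sites$taxon == tx,
                                       c("position", "state")]
    # the planted pair itself always qualifies (exclusivity >= 2 by oracle)
    expect_gte(oracle_exclusivity(synth$alignment, tx, planted_sites), 2L)
    # when brute force shows every qualifying 2-site combination involves a
    # planted site, the consensus must include one (divergence also creates
    # fully exclusive columns, so the condition is checked per species)
    w <- site_weights(synth$alignment, tx)
    non_planted_exclusive <- setdiff(w$position[w$weight == 1], planted)
    if (length(non_planted_exclusive) < 2) {
      n_inclusion_checked <- n_inclusion_checked + 1L
      expect_gt(length(intersect(sites$position, planted)), 0)
    }
  }
  expect_gt(n_inclusion_checked, 0L)
})

test_that("exclusive above min_len raises the effective minimum length", {
  spec <- synth_spec(n_species = 5, seqs_per_species = 3, n_sites = 60,
                     planted_sites_per_species = 4,
                     background_divergence = 0.2, seed = 13)
  synth <- generate_training_alignment(spec)
  tab <- find_dmcs(synth$alignment, synth$truth$taxon,
                   dmc_search_params(iter = 800, min_len = 2, exclusive = 4,
                                     seed = 9))
  ok <- tab$status %in% c("ok", "ok_fallback")
  expect_true(any(ok))
  expect_true(all(tab$consensus_length[ok] >= 4))
  expect_true(all(tab$consensus_exclusivity[ok] >= 4))
})

test_that("identical seeds give byte-identical DMC tables", {
  spec <- synth_spec(n_species = 4, seqs_per_species = 3, n_sites = 40,
                     background_divergence = 0.2, seed = 77)
  synth <- generate_training_alignment(spec)
  p <- dmc_search_params(iter = 300, seed = 123)
  t1 <- find_dmcs(synth$alignment, synth$truth$taxon, p)
  t2 <- find_dmcs(synth$alignment, synth$truth$taxon, p)
  f1 <- tempfile(); f2 <- tempfile()
  write_dmc_table(t1, f1); write_dmc_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-taxon results are unchanged when another query is added", {
  spec <- synth_spec(n_species = 4, seqs_per_species = 3, n_sites = 40,
                     background_divergence = 0.2, seed = 55)
  synth <- generate_training_alignment(spec)
  p <- dmc_search_params(iter = 300, seed = 42)
  all_tab <- find_dmcs(synth$alignment, synth$truth$taxon, p)
  one_tab <- find_dmcs(synth$alignment, synth$truth$taxon[2], p)
  expect_equal(as.data.frame(one_tab),
               as.data.frame(all_tab[all_tab$taxon == synth$truth$taxon[2], ]))
})
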