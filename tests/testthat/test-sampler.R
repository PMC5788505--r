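# Monte Carlo machinery: schedule, acceptance, moves, runs, ensembles.

test_that("the annealing schedule is exact at its endpoints and monotone", {
  expect_identical(anneal_temperature(0), 0.4)
  expect_identical(anneal_temperature(1), 0.3 * 0.2 + 0.1)
  expect_equal(anneal_temperature(0.5), 0.2341641, tolerance = 1e-6)
  grid <- anneal_temperature(seq(0, 1, by = 0.01))
  expect_true(all(diff(grid) < 0))
  expect_error(anneal_temperature(1.5), "\\[0, 1\\]")
})

test_that("improving or equal-scoring proposals are always accepted", {
  set.seed(1)
  for (i in 1:50) {
    old <- rnorm(1)
    expect_true(metropolis_accept(old, old + abs(rnorm(1)), 0.01))
    expect_true(metropolis_accept(old, old, 1e-9)) # D = 0 => p = 1
  }
})

test_that("proposed moves stay valid and differ at one or two positions", {
  p <- default_problem(1L, include_anchor = TRUE)
  cand <- p$candidates
  set.seed(42)
  cur <- p$planted
  for (i in 1:200) {
    nxt <- propose_move(cur, cand)
    expect_true(validate_pathway(nxt, cand)$valid)
    ndiff <- sum(as.character(nxt) != as.character(cur))
    expect_true(ndiff %in% c(1L, 2L))
    # type preservation: ligand positions still hold metabolites
    lig <- as.character(nxt)[seq(1, length(nxt), by = 2)]
    expect_true(all(lig %in% cand$metabolites))
    cur <- nxt
  }
})

test_that("swap is the only move on pools exactly the pathway size", {
  p <- generate_problem(synthetic_config(K = 3L, include_decoys = FALSE, seed = 5L),
                        verify_ceiling = 0)
  set.seed(9)
  start <- p$planted
  ids <- sort(as.character(start))
  for (i in 1:50) {
    nxt <- propose_move(start, p$candidates)
    expect_identical(sort(as.character(nxt)), ids) # same components, rearranged
    expect_identical(sum(as.character(nxt) != as.character(start)), 2L)
  }
})

test_that("random pathway draws are reproducible and respect constraints", {
  p <- default_problem(1L, include_anchor = TRUE)
  sc <- pathmapr:::problem_scorer(p)
  d1 <- random_score_distribution(p$candidates, sc, n = 300L, seed = 7L)
  d2 <- random_score_distribution(p$candidates, sc, n = 300L, seed = 7L)
  expect_identical(d1$scores, d2$scores)
  set.seed(1)
  for (q in random_pathways(p$candidates, 50L)) {
    expect_true(validate_pathway(q, p$candidates)$valid)
  }
})

test_that("the random-model spread estimate agrees with the exhaustive population", {
  oracle <- tiny_oracle(1L)
  sc <- pathmapr:::problem_scorer(oracle$problem)
  est <- random_score_distribution(oracle$problem$candidates, sc,
                                   n = 10000L, seed = 3L)
  truth <- pathmapr:::pop_sd(oracle$totals)
  expect_lt(abs(est$sd - truth) / truth, 0.05)
})

test_that("runs are deterministic in their seed and record the start state", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  r1 <- run_mc(p$candidates, sc, n_steps = 500L, seed = 13L)
  r2 <- run_mc(p$candidates, sc, n_steps = 500L, seed = 13L)
  expect_identical(
    vapply(r1, function(x) x$key, ""),
    vapply(r2, function(x) x$key, "")
  )
  expect_identical(vapply(r1, function(x) x$total, 0),
                   vapply(r2, function(x) x$total, 0))
  r0 <- run_mc(p$candidates, sc, n_steps = 0L, seed = 13L)
  expect_length(r0, 1L) # exactly the start model
})

test_that("every recorded model is valid and its stored score is fresh", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  recs <- run_mc(p$candidates, sc, n_steps = 2000L, seed = 21L)
  expect_gt(length(recs), 1L)
  for (m in recs[seq_len(min(50, length(recs)))]) {
    expect_true(validate_pathway(m$pathway, p$candidates)$valid)
    fresh <- score_pathway(m$pathway, sc)
    expect_equal(m$total, fresh$total, tolerance = 1e-12)
    expect_equal(m$terms, fresh$terms, tolerance = 1e-12)
  }
})

test_that("a tiny instance is fully explored within ten thousand steps", {
  lib <- lib3()
  cand <- candidate_sets(protein_table(c("E1", "E2")), lib, K = 2L)
  set.seed(2)
  rest <- restraint_set(lib, docking = list(
    E1 = stats::setNames(rnorm(3), lib$id),
    E2 = stats::setNames(rnorm(3), lib$id)
  ))
  sc <- pathway_scorer(cand, rest)
  recs <- run_mc(cand, sc, n_steps = 10000L, seed = 3L)
  expect_identical(length(recs), 12L) # all 2! * 3! pathways visited
})

test_that("the ensemble cutoff follows the stated rule and deduplicates runs", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  cfg <- sampler_config(n_steps = 1000L, n_runs = 3L, n_random_models = 200L,
                        cutoff_sd = 2.0, seed = 5L)
  e <- run_ensemble(p$candidates, sc, config = cfg)
  expect_equal(e$cutoff, e$best - 2.0 * e$random_sd, tolerance = 1e-12)
  expect_true(all(vapply(e$models, function(m) m$total, 0) >= e$cutoff))
  expect_identical(anyDuplicated(vapply(e$all_models, function(m) m$key, "")), 0L)
  cfg15 <- sampler_config(n_steps = 1000L, n_runs = 3L, n_random_models = 200L,
                          cutoff_sd = 1.5, seed = 5L)
  e15 <- run_ensemble(p$candidates, sc, config = cfg15)
  expect_equal(e15$cutoff, e15$best - 1.5 * e15$random_sd, tolerance = 1e-12)
  expect_gte(length(e$models), length(e15$models)) # stricter cutoff, smaller set
})
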