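# Shared fixtures, built in code and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

get_fixture <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- make()
  .fx[[name]]
}

# three simple metabolites used by hand-built scoring fixtures
lib3 <- function() {
  metabolite_library(c("m1", "m2", "m3"), c("CCO", "CC=O", "CCC"))
}

# small planted instance: 4 proteins x 6 metabolites, K = 3 (8640 pathways)
tiny_problem <- function(seed = 1L) {
  get_fixture(paste0("tiny", seed), function() {
    generate_problem(
      synthetic_config(K = 3L, n_decoy_proteins = 1L, n_decoy_metabolites = 2L,
                       seed = seed),
      verify_ceiling = 0
    )
  })
}

# reference study conditions: K = 4, 3 decoy proteins, 8 decoy metabolites
default_problem <- function(seed = 1L, ...) {
  get_fixture(paste0("default", seed, paste(c(...), collapse = "")), function() {
    generate_problem(synthetic_config(K = 4L, seed = seed, ...), verify_ceiling = 0)
  })
}

# exhaustive scores of a small instance under a scorer
exhaustive_scores <- function(problem, scorer = NULL) {
  scorer <- scorer %||% pathmapr:::problem_scorer(problem)
  total_fn <- pathmapr:::make_total_fn(scorer)
  all_p <- enumerate_pathways(problem$candidates)
  list(
    pathways = all_p,
    keys = vapply(all_p, canonical_key, ""),
    totals = vapply(all_p, function(q) {
      i <- pathmapr:::pathway_indices(scorer, q)
      total_fn(i$lig, i$pro)
    }, 0)
  )
}

# exhaustive oracle for the small planted instance, under full and
# docking-only scoring, cached per seed (used by several test files)
tiny_oracle <- function(seed = 1L) {
  get_fixture(paste0("oracle", seed), function() {
    p <- tiny_problem(seed)
    full <- exhaustive_scores(p)
    dock_only <- restrict_restraints(p, "docking")
    dsc <- pathway_scorer(dock_only$candidates, dock_only$restraints)
    dock <- exhaustive_scores(p, dsc)
    pk <- canonical_key(p$planted)
    i <- match(pk, full$keys)
    list(
      problem = p, planted_key = pk,
      keys = full$keys, totals = full$totals,
      argmax_key = full$keys[which.max(full$totals)],
      full_rank = 1L + sum(full$totals > full$totals[i]),
      dock_rank = 1L + sum(dock$totals > dock$totals[i])
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
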