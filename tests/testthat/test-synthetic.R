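# Planted-problem generator: determinism, coherence, planted optimality.

test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(K = 3L, seed = 99L)
  p1 <- generate_problem(cfg, verify_ceiling = 0)
  p2 <- generate_problem(cfg, verify_ceiling = 0)
  expect_identical(p1$candidates$metabolites, p2$candidates$metabolites)
  expect_identical(p1$restraints$docking, p2$restraints$docking)
  expect_identical(p1$restraints$sea, p2$restraints$sea)
  expect_identical(as.character(p1$planted), as.character(p2$planted))
  p3 <- generate_problem(synthetic_config(K = 3L, seed = 100L), verify_ceiling = 0)
  expect_false(identical(p1$restraints$docking, p3$restraints$docking))
})

test_that("the planted pathway is valid and its chemistry is exact", {
  p <- tiny_problem(1L)
  expect_true(validate_pathway(p$planted, p$candidates)$valid)
  # each curated transform maps its substrate exactly onto its product
  lib <- p$restraints$library
  nodes <- as.character(p$planted)
  for (i in seq(2, length(nodes) - 1, by = 2)) {
    sub <- lib$smiles[match(nodes[i - 1], lib$id)]
    prod <- lib$smiles[match(nodes[i + 1], lib$id)]
    prods <- unlist(lapply(p$restraints$transforms[[nodes[i]]],
                           function(s) apply_transformation(sub, s)))
    expect_true(chem_fingerprint(prod)$smiles %in%
                  vapply(prods, function(x) chem_fingerprint(x)$smiles, ""))
  }
})

test_that("the planted pathway is the exhaustive optimum on small instances", {
  for (s in 1:3) {
    p <- generate_problem(
      synthetic_config(K = 3L, n_decoy_proteins = 1L, n_decoy_metabolites = 2L,
                       seed = s)
    )
    expect_true(p$verified)
  }
})

test_that("anchored problems fix the transporter and restrict its ligand", {
  p <- default_problem(2L, include_anchor = TRUE)
  cand <- p$candidates
  expect_identical(cand$constraints[["protein:1"]], "sbp")
  nodes <- as.character(p$planted)
  expect_identical(nodes[2L], "sbp")
  expect_true(nodes[1L] %in% cand$constraints[["ligand:1"]])
  expect_identical(cand$proteins$kind[match("sbp", cand$proteins$id)],
                   "transporter_sbp")
})

test_that("dummy candidates carry no transforms and no docking table", {
  p <- default_problem(3L, include_dummy = TRUE)
  expect_true("dummy" %in% p$candidates$proteins$id)
  expect_false("dummy" %in% names(p$restraints$docking))
  expect_null(p$restraints$transforms[["dummy"]])
})

test_that("infeasible chain lengths are refused with a clear message", {
  expect_error(synthetic_config(K = 7L), "at most 5")
  expect_error(synthetic_config(K = 1L))
})
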