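# Restraint terms: elementary operations, hand-built fixtures, and
# dual-route checks against independent recomputation.

test_that("z-score normalization handles the degenerate-spread guard", {
  pop <- c(1, 2, 3)
  expect_equal(zscore(2, mean(pop), pathmapr:::pop_sd(pop)), 0)
  expect_equal(zscore(mean(pop) + pathmapr:::pop_sd(pop), mean(pop),
                      pathmapr:::pop_sd(pop)), 1)
  expect_warning(z0 <- zscore(5, 5, 0), "zero spread")
  expect_equal(z0, 0)
})

test_that("SEA pair scores cap the log-evalue weight at 50", {
  # a strongly significant pair: -log10(9.5e-63) ~ 62, capped
  expect_equal(sea_sab(9.5e-63, 50, 50), 50)
  expect_equal(sea_sab(1.0, 50, 50), 0)
  expect_equal(sea_sab(1e-25, 50, 40), 20) # 25 * (40/50)
  expect_error(sea_sab(0), "positive")
  # cap and symmetry in the confidence weights over random inputs
  set.seed(11)
  ev <- 10^stats::runif(50, -80, 1)
  expect_true(all(sea_sab(ev, 50, 50) <= 50))
  expect_equal(sea_sab(ev, 30, 45), sea_sab(ev, 45, 30))
})

test_that("docking tables carry their own population statistics", {
  tab <- docking_table(c(a = 1, b = 2, c = 3))
  expect_equal(tab$mean, 2)
  expect_equal(tab$sd, pathmapr:::pop_sd(c(1, 2, 3)))
  z <- docking_zscores(tab)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(pathmapr:::pop_sd(z), 1, tolerance = 1e-12)
})

test_that("the docking term is the negated mean pair Z, omitting unscored pairs", {
  cand <- candidate_sets(protein_table(c("E1", "E2")), lib3(), K = 1L)
  rest <- restraint_set(lib3(), docking = list(E1 = c(m1 = -1, m2 = 1)))
  sc <- pathway_scorer(cand, rest)
  # z-scores of the two-entry table are exactly {-1, +1}
  expect_equal(score_docking(c("m1", "E1", "m2"), sc), 0)
  expect_equal(score_docking(c("m1", "E1", "m3"), sc), 1) # single scored pair, z = -1
  expect_equal(score_docking(c("m3", "E1", "m2"), sc), -1)
  # no scored pair at all: term absent, not zero
  expect_true(is.na(score_docking(c("m1", "E2", "m2"), sc)))
  expect_equal(score_pathway(c("m1", "E2", "m2"), sc)$total, 0)
})

test_that("the SEA term z-scores pair scores against the all-pair population", {
  lib <- lib3()
  cand <- candidate_sets(protein_table(c("A", "B", "C")), lib, K = 2L)
  sea <- data.frame(
    a = c("A", "A", "B", "A", "B", "C"),
    b = c("B", "C", "C", "A", "B", "C"),
    evalue = c(1.0, 1e-10, 1e-20, 1e-50, 1e-50, 1e-50)
  )
  sc <- pathway_scorer(cand, restraint_set(lib, sea = sea))
  # S_AB population is {0, 10, 20}: mean 10, population sd 8.164966
  expect_equal(score_sea(c("m1", "B", "m2", "C", "m3"), sc), 1.2247449,
               tolerance = 1e-6)
  expect_equal(score_sea(c("m1", "A", "m2", "C", "m3"), sc), 0)
  expect_equal(score_sea(c("m1", "A", "m2", "B", "m3"), sc), -1.2247449,
               tolerance = 1e-6)
})

test_that("the gene-cluster overlap is the pair-set intersection over the larger set", {
  lib <- lib3()
  cand <- candidate_sets(protein_table(c("A", "B", "C", "D")), lib, K = 2L)
  sc <- pathway_scorer(cand, restraint_set(lib, gene_cluster = c("A", "B", "C")))
  expect_equal(sc$gc$value(c("A", "B", "D")), 1 / 3) # shared pairs: {A-B}
  expect_equal(sc$gc$value(c("A", "B", "C")), 1)
  expect_equal(sc$gc$value(c("D")), 0)
})

test_that("transformation triads match an independent chem-level recomputation", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  cand_ids <- p$candidates$metabolites
  lib <- p$restraints$library
  smiles_of <- function(id) lib$smiles[match(id, lib$id)]
  sub <- as.character(p$planted)[1L]   # glycerol
  enz <- as.character(p$planted)[2L]   # its oxidase
  prods <- unlist(lapply(p$restraints$transforms[[enz]],
                         function(s) apply_transformation(smiles_of(sub), s)))
  tc <- vapply(cand_ids, function(m) {
    max(vapply(prods, function(pr) max_stereo_tanimoto(pr, smiles_of(m)), 0))
  }, 0)
  for (target in cand_ids[c(2L, 4L)]) {
    expected <- pathmapr:::quiet_z(tc[[target]], mean(tc), pathmapr:::pop_sd(tc))
    got <- score_transformations(c(sub, enz, target), sc)
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("endpoint and screening terms match fingerprint-level recomputation", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  lib <- p$restraints$library
  fps <- chem_fingerprint(stats::setNames(lib$smiles, lib$id))
  cand_ids <- p$candidates$metabolites
  # endpoint: max TC vs central, z-scored against all candidate x central pairs
  tcmat <- sapply(p$restraints$central, function(cen) {
    vapply(cand_ids, function(m) tanimoto(fps[[m]], fps[[cen]]), 0)
  })
  for (m in cand_ids[c(1L, 3L)]) {
    expected <- pathmapr:::quiet_z(max(tcmat[m, ]), mean(tcmat),
                                   pathmapr:::pop_sd(tcmat))
    nodes <- as.character(p$planted)
    nodes[length(nodes)] <- m
    nodes[seq(1, length(nodes) - 2, by = 2)] <- setdiff(cand_ids, m)[1:3]
    expect_equal(score_endpoint(nodes, sc), expected, tolerance = 1e-10)
  }
  # screening hits: per-candidate max-over-hits TC population
  screened <- names(p$restraints$hts)[1L]
  hits <- p$restraints$hts[[screened]]
  tch <- vapply(cand_ids, function(m) {
    max(vapply(hits, function(h) tanimoto(fps[[m]], fps[[h]]), 0))
  }, 0)
  pos <- match(screened, as.character(p$planted))
  sub <- as.character(p$planted)[pos - 1L]
  expect_equal(score_hts(p$planted, sc),
               pathmapr:::quiet_z(tch[[sub]], mean(tch), pathmapr:::pop_sd(tch)),
               tolerance = 1e-10)
  # homology: TC to the reference substrate, z-scored over candidates
  annotated <- names(p$restraints$homology)[1L]
  ref_fp <- chem_fingerprint(p$restraints$homology[[annotated]])
  tcr <- vapply(cand_ids, function(m) tanimoto(fps[[m]], ref_fp), 0)
  pos <- match(annotated, as.character(p$planted))
  sub <- as.character(p$planted)[pos - 1L]
  expect_equal(score_homology(p$planted, sc),
               pathmapr:::quiet_z(tcr[[sub]], mean(tcr), pathmapr:::pop_sd(tcr)),
               tolerance = 1e-10)
})

test_that("scoring is pure: identical pathway, identical breakdown", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  s1 <- score_pathway(p$planted, sc)
  s2 <- score_pathway(p$planted, sc)
  expect_identical(s1$terms, s2$terms)
  expect_identical(s1$total, s2$total)
})

test_that("ablating a restraint removes exactly its term from the total", {
  p <- tiny_problem(1L)
  s_full <- score_pathway(p$planted, p)
  p_noend <- ablate(p, "endpoint")
  s_noend <- score_pathway(p$planted, p_noend)
  expect_true(is.na(s_noend$terms["z_cm"]))
  expect_false(is.na(s_full$terms["z_cm"]))
  expect_equal(s_noend$total, s_full$total - s_full$terms[["z_cm"]],
               tolerance = 1e-12)
  # dropping everything but docking reduces the score to the docking term
  p_dock <- restrict_restraints(p, "docking")
  s_dock <- score_pathway(p$planted, p_dock)
  expect_equal(s_dock$total, s_dock$terms[["z_vs"]])
  expect_equal(s_dock$terms[["z_vs"]], s_full$terms[["z_vs"]])
  expect_error(ablate(p, "astrology"), "unknown restraint")
  expect_error(ablate(p_noend, "endpoint"), "not present")
})
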