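# Cheminformatics primitives: fingerprints, Tanimoto, SMIRKS application,
# stereoisomer-aware comparison.

test_that("fingerprints are deterministic and canonicalization-invariant", {
  a <- chem_fingerprint("CCO")
  b <- chem_fingerprint("CCO")
  expect_identical(a$bits, b$bits)
  # same molecule written in a different atom order
  c <- chem_fingerprint("OCC")
  expect_identical(a$bits, c$bits)
  expect_gt(length(a$bits), 0L)
})

test_that("chirality is encoded: enantiomers get different fingerprints", {
  r <- chem_fingerprint("F[C@H](Cl)Br")
  s <- chem_fingerprint("F[C@@H](Cl)Br")
  expect_false(identical(r$bits, s$bits))
  expect_equal(tanimoto(r, r), 1.0)
  expect_lt(tanimoto(r, s), 1.0)
})

test_that("unparseable SMILES are rejected naming the record", {
  expect_error(chem_fingerprint(c(good = "CCO", broken = "not-a-smiles")), "broken")
})

test_that("tanimoto follows the set arithmetic and its conventions", {
  params <- fp_params()
  mk <- function(bits) pathmapr:::new_chem_fp(bits, params)
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5) # 2 shared / 4 union
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1.0)
  expect_equal(tanimoto(mk(integer()), mk(integer())), 0.0) # empty: no evidence
  # symmetry and bounds over random bit sets
  set.seed(7)
  for (i in 1:25) {
    a <- mk(sample.int(64, sample.int(10, 1)))
    b <- mk(sample.int(64, sample.int(10, 1)))
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0)
    expect_lte(tanimoto(a, b), 1)
  }
})

test_that("fingerprints with different parameters refuse to compare", {
  a <- pathmapr:::new_chem_fp(1:3, fp_params())
  b <- pathmapr:::new_chem_fp(1:3, list(radius = 3L, nbits = 2048L, chiral = TRUE))
  expect_error(tanimoto(a, b), "parameters differ")
})

test_that("SMIRKS application enumerates, canonicalizes, and deduplicates sites", {
  ox <- "[CH2:1][OH:2]>>[CH:1]=[O:2]"
  expect_identical(apply_transformation("CCO", ox), "CC=O")
  expect_identical(apply_transformation("CC(C)=O", ox), character()) # no motif match
  # glycerol's two symmetric primary alcohols give one unique product
  expect_identical(apply_transformation("OCC(O)CO", ox), "O=CC(O)CO")
  expect_error(apply_transformation("CCO", ">>not-smirks<<"), "SMIRKS")
})

test_that("transformation products are invariant to SMILES writing order", {
  ox <- "[CH2:1][OH:2]>>[CH:1]=[O:2]"
  expect_identical(
    apply_transformation("OCC(O)CO", ox),
    apply_transformation("C(O)(CO)CO", ox)
  )
})

test_that("stereo-aware maximum Tanimoto reduces, dominates, and caps", {
  # no undefined centers: reduces to the plain coefficient
  a <- chem_fingerprint("CCO"); b <- chem_fingerprint("CC=O")
  expect_equal(max_stereo_tanimoto("CCO", "CC=O"), tanimoto(a, b))
  # unspecified-stereo form of a defined molecule: one isomer matches exactly
  expect_equal(max_stereo_tanimoto("CC(O)C(=O)O", "C[C@H](O)C(=O)O"), 1.0)
  # stereo maximum never falls below the unexpanded comparison
  pairs <- list(c("CC(O)C(=O)O", "C[C@@H](O)C(=O)O"),
                c("OCC(O)C(O)CO", "OC[C@H](O)[C@H](O)CO"))
  for (pr in pairs) {
    plain <- tanimoto(chem_fingerprint(pr[1]), chem_fingerprint(pr[2]))
    expect_gte(max_stereo_tanimoto(pr[1], pr[2]), plain)
  }
  # enumeration cap: 5 undefined centers would give 32 assignments, 16 evaluated
  expect_identical(n_stereoisomers("CC(O)C(O)C(O)C(O)C(O)CO"), 16L)
  expect_identical(n_stereoisomers("CCO"), 1L)
})

test_that("similarity statistics use the population standard deviation", {
  s <- similarity_stats(c(1.0, 0.5, 0.0))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0.4082483, tolerance = 1e-6)
  fp <- chem_fingerprint("CCO")
  s2 <- similarity_stats(list(fp, fp, fp), fp)
  expect_equal(s2$mean, 1.0)
  expect_equal(s2$sd, 0.0)
  expect_equal(similarity_stats(0.7)$sd, 0.0) # single-member population
  expect_error(similarity_stats(numeric()), "empty")
})
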