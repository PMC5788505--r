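# Pathway representation: validation, canonical keys, exhaustive enumeration.

cand_small <- function() {
  candidate_sets(
    proteins = protein_table(c("E1", "E2")),
    metabolites = c("M1", "M2", "M3"),
    K = c(1L, 2L)
  )
}

test_that("validation enforces alternation, uniqueness, membership, constraints", {
  cand <- cand_small()
  expect_true(validate_pathway(c("M1", "E1", "M2"), cand)$valid)

  v <- validate_pathway(c("M1", "E1", "M1"), cand)
  expect_false(v$valid)
  expect_match(v$violations, "metabolite repeated", all = FALSE)

  v <- validate_pathway(c("M1", "E1", "M2", "E1", "M3"), cand)
  expect_false(v$valid)
  expect_match(v$violations, "protein repeated", all = FALSE)

  v <- validate_pathway(c("M1", "E9", "M2"), cand)
  expect_false(v$valid)
  expect_match(v$violations, "unknown protein", all = FALSE)

  v <- validate_pathway(c("M1", "E1"), cand)
  expect_false(v$valid)

  cand_anchored <- candidate_sets(
    proteins = protein_table(c("E_sbp", "E2")),
    metabolites = c("M1", "M2", "M3"),
    K = 1L,
    constraints = list("protein:1" = "E_sbp")
  )
  v <- validate_pathway(c("M1", "E2", "M2"), cand_anchored)
  expect_false(v$valid)
  expect_match(v$violations, "constraint at protein:1", all = FALSE)
  expect_true(validate_pathway(c("M1", "E_sbp", "M2"), cand_anchored)$valid)
})

test_that("constraints outside the candidate pools are rejected at construction", {
  expect_error(
    candidate_sets(protein_table(c("E1", "E2")), c("M1", "M2"), K = 1L,
                   constraints = list("protein:1" = "E9")),
    "outside the candidate pool"
  )
  expect_error(
    candidate_sets(protein_table(c("E1", "E2")), c("M1", "M2"), K = 1L,
                   constraints = list(anywhere = "E1")),
    "protein:1"
  )
})

test_that("canonical keys are deterministic and order-sensitive", {
  expect_identical(canonical_key(c("M1", "E1", "M2")), "M1|E1|M2")
  expect_false(canonical_key(c("M1", "E1", "M2")) == canonical_key(c("M2", "E1", "M1")))
  expect_identical(canonical_key(pathway(c("M1", "E1", "M2"))),
                   canonical_key(pathway(c("M1", "E1", "M2"))))
})

test_that("enumeration matches the closed-form count and yields valid, distinct models", {
  cand <- cand_small()
  all2 <- enumerate_pathways(cand, K = 2L)
  expect_length(all2, 12L) # 2! * 3!/(3-3)! = 2 * 6
  expect_identical(n_pathways(2, 3, 2), 12)
  keys <- vapply(all2, canonical_key, "")
  expect_identical(anyDuplicated(keys), 0L)
  for (p in all2) expect_true(validate_pathway(p, cand)$valid)

  all1 <- enumerate_pathways(cand, K = 1L)
  expect_length(all1, 2L * 3L * 2L) # E choices x ordered ligand pairs

  cand_min <- candidate_sets(protein_table("E1"), c("M1", "M2"), K = 1L)
  expect_length(enumerate_pathways(cand_min), 2L)

  cand_con <- candidate_sets(protein_table("E1"), c("M1", "M2"), K = 1L,
                             constraints = list("ligand:1" = "M1"))
  expect_length(enumerate_pathways(cand_con), 1L)
})

test_that("the enumeration ceiling guards intractable instances", {
  cand <- candidate_sets(protein_table(paste0("E", 1:10)),
                         paste0("M", 1:20), K = 6L)
  expect_error(enumerate_pathways(cand), "ceiling")
})
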