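# Stage-4 analysis: Hamming clustering, edge frequencies, convergence,
# union-network export.

mk_model <- function(nodes, total = 0) {
  structure(list(pathway = nodes, key = canonical_key(nodes),
                 terms = c(z_vs = total), total = total),
            class = "scored_pathway")
}

test_that("the Hamming distance is the mismatch fraction over all nodes", {
  a <- paste0("n", 1:11)
  b <- a; b[4] <- "x"
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 1 / 11, tolerance = 1e-9)
  expect_equal(hamming_distance(a, paste0("z", 1:11)), 1)
  expect_equal(hamming_distance(a, paste0("n", 1:7)), 1) # cross-length
})

test_that("near-identical models share a cluster, distant ones do not", {
  a <- c("m1", "p1", "m2", "p2", "m3")
  b <- c("m1", "p1", "m4", "p2", "m3") # 1 of 5 differs: distance 0.2
  c3 <- c("m9", "p9", "m8", "p8", "m3") # 4 of 5 differ from both
  cl <- cluster_models(list(mk_model(a, 3), mk_model(b, 2), mk_model(c3, 1)))
  expect_identical(cl$n_clusters, 2L)
  expect_identical(cl$assignments[[canonical_key(a)]],
                   cl$assignments[[canonical_key(b)]])
  expect_false(cl$assignments[[canonical_key(a)]] ==
                 cl$assignments[[canonical_key(c3)]])
  # representative of the {a, b} cluster is the higher-scoring member
  expect_identical(unname(cl$representatives[[cl$assignments[[canonical_key(a)]]]]),
                   canonical_key(a))
  # mutually maximally distant models each get their own cluster
  far <- list(mk_model(c("a1", "b1", "c1")), mk_model(c("a2", "b2", "c2")),
              mk_model(c("a3", "b3", "c3")))
  expect_identical(cluster_models(far)$n_clusters, 3L)
  expect_identical(cluster_models(far[1])$n_clusters, 1L)
})

test_that("cluster counts hit the unique-model and single-cluster limits", {
  set.seed(4)
  models <- lapply(1:12, function(i) {
    mk_model(c(sample(paste0("m", 1:6), 3), sample(paste0("p", 1:4), 2))[c(1, 4, 2, 5, 3)])
  })
  keys <- vapply(models, function(m) m$key, "")
  models <- models[!duplicated(keys)]
  expect_identical(cluster_models(models, cutoff = 0)$n_clusters, length(models))
  expect_identical(cluster_models(models, cutoff = 1.0)$n_clusters, 1L)
})

test_that("edge frequencies count models containing each enzyme-ligand edge", {
  m1 <- mk_model(c("s", "E1", "x", "E2", "t"))
  m2 <- mk_model(c("s", "E1", "y", "E2", "t"))
  ef <- edge_frequencies(list(m1, m2))
  shared <- ef[ef$protein == "E1" & ef$ligand == "s", ]
  expect_equal(shared$frequency, 1.0)
  expect_equal(shared$rank, 1)
  half <- ef[ef$protein == "E1" & ef$ligand == "x", ]
  expect_equal(half$frequency, 0.5)
  expect_equal(half$rank, 2)
  # per-model edge multiset is recoverable: frequencies x model count
  expect_equal(sum(ef$frequency * 2), 2 * 4) # 2K edges per model, K = 2
})

test_that("the convergence curve is monotone and ends at one", {
  assignments <- stats::setNames(c(1L, 1L, 2L, 3L), c("k1", "k2", "k3", "k4"))
  cl <- structure(list(assignments = assignments, n_clusters = 3L),
                  class = "cluster_result")
  cc <- convergence_curve(list(c("k1"), c("k2"), c("k3", "k4")), cl)
  expect_equal(cc$fraction, c(1 / 3, 1 / 3, 1))
  expect_true(all(diff(cc$fraction) >= 0))
  # all runs finding the same models: flat at 1
  cc2 <- convergence_curve(list(c("k1", "k3", "k4"), c("k1", "k3", "k4")), cl)
  expect_equal(cc2$fraction, c(1, 1))
})

test_that("the union network is the union of the model graphs", {
  m1 <- mk_model(c("s", "E1", "x", "E2", "t"), 2)
  doc1 <- import_netimp(export_netimp(list(m1)))
  expect_length(doc1$nodes, 5L)
  expect_length(doc1$edges, 4L)
  # a second model differing in one interior ligand adds 1 node and 2 edges
  m2 <- mk_model(c("s", "E1", "y", "E2", "t"), 1)
  doc2 <- import_netimp(export_netimp(list(m1, m2)))
  expect_length(doc2$nodes, 6L)
  expect_length(doc2$edges, 6L)
  expect_length(doc2$models, 2L)
})

test_that("export -> import -> export is byte-identical", {
  p <- tiny_problem(1L)
  sc <- pathmapr:::problem_scorer(p)
  recs <- run_mc(p$candidates, sc, n_steps = 2000L, seed = 8L)
  txt1 <- as.character(export_netimp(recs[seq_len(min(30, length(recs)))]))
  txt2 <- as.character(export_netimp(import_netimp(txt1)))
  expect_identical(txt1, txt2)
})
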