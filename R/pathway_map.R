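## The user-facing fitter: compile restraints, sample, analyze.

#' Map a metabolic pathway from heterogeneous restraints
#'
#' Runs the full pipeline for one or more pathway lengths: compiles the
#' restraints into a scorer, performs independent Monte Carlo
#' simulated-annealing runs, keeps the unique good-scoring models
#' (score at or above `best - cutoff_sd * SD(random models)`), clusters
#' them by Hamming distance at 0.2, tabulates enzyme-ligand edge
#' frequencies, and records the sampling convergence curve. Models from
#' all lengths are ranked together by raw composite score; clustering
#' assigns cross-length pairs distance 1 so per-length sub-ensembles stay
#' separate.
#'
#' @param cand A [candidate_sets()]; or a `planted_problem`, in which case
#'   `rest` may be omitted.
#' @param rest A [restraint_set()].
#' @param lengths Integer vector of pathway lengths to model independently
#'   (default: the lengths declared in the candidate set).
#' @param config A [sampler_config()].
#' @param cluster_cutoff Hamming cut distance (default 0.2).
#' @return Object of class `pathway_map`: list with `models` (good-scoring,
#'   sorted by decreasing score), `ensembles` (per-length
#'   `good_scoring_set`s, named by K), `clusters`, `edge_frequencies`,
#'   `convergence`, `config`.
#' @examples
#' \dontrun{
#' prob <- generate_problem(synthetic_config(K = 3, seed = 1))
#' fit <- pathway_map(prob, config = sampler_config(n_steps = 2000, n_runs = 4,
#'                                                  n_random_models = 500))
#' summary(fit)
#' }
#' @export
pathway_map <- function(cand, rest = NULL, lengths = NULL,
                        config = sampler_config(), cluster_cutoff = 0.2) {
  if (inherits(cand, "planted_problem")) {
    problem <- cand
    cand <- problem$candidates
    rest <- rest %||% problem$restraints
    scorer <- problem_scorer(problem)
  } else {
    scorer <- if (inherits(rest, "pathway_scorer")) rest else pathway_scorer(cand, rest)
  }
  lengths <- as.integer(lengths %||% cand$K)
  ensembles <- lapply(lengths, function(K) {
    run_ensemble(cand, scorer, config = config, K = K)
  })
  names(ensembles) <- as.character(lengths)
  models <- do.call(c, lapply(ensembles, function(e) e$models))
  totals <- vapply(models, function(m) m$total, 0)
  keys <- vapply(models, function(m) m$key, "")
  models <- models[order(-totals, keys)]
  clusters <- cluster_models(models, cutoff = cluster_cutoff)
  per_run_keys <- if (length(lengths) == 1L) {
    ensembles[[1L]]$per_run_keys
  } else {
    # run r pools the models that the r-th run of every length found
    lapply(seq_len(config$n_runs), function(r) {
      unlist(lapply(ensembles, function(e) e$per_run_keys[[r]]), use.names = FALSE)
    })
  }
  convergence <- if (config$n_runs >= 2L) {
    convergence_curve(per_run_keys, clusters)
  } else {
    data.frame(n_runs = 1L, fraction = 1)
  }
  structure(
    list(models = models, ensembles = ensembles, clusters = clusters,
         edge_frequencies = edge_frequencies(models),
         convergence = convergence, config = config,
         cluster_cutoff = cluster_cutoff, lengths = lengths),
    class = "pathway_map"
  )
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("Integrative pathway map\n")
  cat("  lengths modeled: K = ", paste(x$lengths, collapse = ", "), "\n", sep = "")
  for (K in names(x$ensembles)) {
    e <- x$ensembles[[K]]
    cat(sprintf("  K=%s: %d good-scoring / %d unique sampled (best %.3f, cutoff %.3f)\n",
                K, length(e$models), length(e$all_models), e$best, e$cutoff))
  }
  cat("  clusters (Hamming cut ", x$cluster_cutoff, "): ",
      x$clusters$n_clusters, "\n", sep = "")
  if (length(x$models)) {
    cat("  top model: ", paste(x$models[[1L]]$pathway, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.pathway_map <- function(object, n_top = 5L, ...) {
  top <- utils::head(object$models, n_top)
  tab <- do.call(rbind, lapply(top, function(m) {
    data.frame(total = m$total, cluster = unname(object$clusters$assignments[m$key]),
               model = paste(m$pathway, collapse = " -> "),
               stringsAsFactors = FALSE)
  }))
  out <- list(
    top_models = tab,
    n_models = length(object$models),
    n_clusters = object$clusters$n_clusters,
    best_breakdown = if (length(object$models)) object$models[[1L]]$terms,
    convergence_tail = utils::tail(object$convergence, 3L)
  )
  class(out) <- "summary.pathway_map"
  out
}

#' @export
print.summary.pathway_map <- function(x, ...) {
  cat("Good-scoring models: ", x$n_models, " in ", x$n_clusters, " clusters\n",
      sep = "")
  cat("\nTop models:\n")
  print(x$top_models, row.names = FALSE)
  if (!is.null(x$best_breakdown)) {
    t <- x$best_breakdown[!is.na(x$best_breakdown)]
    cat("\nBest model restraint breakdown:\n")
    print(round(t, 4))
  }
  cat("\nConvergence (fraction of clusters found):\n")
  print(x$convergence_tail, row.names = FALSE)
  invisible(x)
}

#' @param x A `pathway_map`.
#' @param which Panels to draw: score distribution and/or convergence.
#' @param ... Passed to the base plotting calls.
#' @rdname pathway_map
#' @export
plot.pathway_map <- function(x, which = c("scores", "convergence"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1L, length(which)))
  on.exit(graphics::par(op))
  if ("scores" %in% which) {
    e <- x$ensembles[[1L]]
    totals <- vapply(e$all_models, function(m) m$total, 0)
    graphics::hist(totals, breaks = 30, main = "Unique sampled models",
                   xlab = "composite score", col = "grey85", border = "white")
    graphics::abline(v = e$cutoff, col = "firebrick", lwd = 2)
    graphics::abline(v = e$best, col = "steelblue", lwd = 2, lty = 2)
    graphics::legend("topleft", legend = c("cutoff", "best"), bty = "n",
                     col = c("firebrick", "steelblue"), lwd = 2, lty = c(1, 2))
  }
  if ("convergence" %in% which) {
    graphics::plot(x$convergence$n_runs, x$convergence$fraction, type = "s",
                   ylim = c(0, 1), xlab = "independent runs",
                   ylab = "fraction of clusters found", main = "Sampling convergence")
  }
  invisible(x)
}

#' Rank of a pathway among sampled models
#'
#' Rank (1 = best) of a reference pathway by composite score among the
#' unique sampled models pooled with the reference itself, so an unsampled
#' reference still has a defined rank.
#'
#' @param fit A `pathway_map` or `good_scoring_set`.
#' @param p Reference pathway.
#' @param scorer Scorer used for the reference score when `fit` does not
#'   contain it.
#' @return Integer rank.
#' @export
pathway_rank <- function(fit, p, scorer) {
  models <- if (inherits(fit, "pathway_map")) {
    unlist(lapply(fit$ensembles, function(e) e$all_models), recursive = FALSE)
  } else {
    fit$all_models
  }
  key <- canonical_key(p)
  totals <- vapply(models, function(m) m$total, 0)
  keys <- vapply(models, function(m) m$key, "")
  ref_total <- if (key %in% keys) {
    totals[match(key, keys)]
  } else {
    score_pathway(p, scorer)$total
  }
  1L + sum(totals[keys != key] > ref_total)
}
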