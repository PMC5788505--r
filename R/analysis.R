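## Ensemble analysis: Hamming clustering, edge-frequency ranking,
## convergence diagnostics, union-network JSON export.

model_nodes <- function(x) {
  if (inherits(x, "scored_pathway")) x$pathway else as.character(x)
}

model_total <- function(x) {
  if (inherits(x, "scored_pathway")) x$total else NA_real_
}

#' Normalized Hamming distance between pathway models
#'
#' Fraction of node positions (proteins and ligands alike) at which the
#' two models differ. Models of different lengths are assigned distance 1
#' so per-length sub-ensembles cluster separately.
#'
#' @param a,b Pathways (or `scored_pathway` objects).
#' @return Numeric in `[0, 1]`.
#' @export
hamming_distance <- function(a, b) {
  a <- model_nodes(a); b <- model_nodes(b)
  if (length(a) != length(b)) return(1.0)
  sum(a != b) / length(a)
}

#' Cluster good-scoring models by Hamming distance
#'
#' Agglomerative hierarchical clustering (average linkage) of the models'
#' pairwise normalized Hamming distances, cut at the given distance.
#' Deterministic for a fixed input order. Each cluster's representative is
#' its best-scoring member (ties broken by lexicographic canonical key).
#'
#' @param models List of pathways or `scored_pathway` objects.
#' @param cutoff Cut distance (default 0.2).
#' @param linkage `stats::hclust` agglomeration method (default "average").
#' @return Object of class `cluster_result`: `assignments` (named integer,
#'   model key -> cluster id), `representatives` (model key per cluster),
#'   `n_clusters`, `cutoff`, `linkage`.
#' @export
cluster_models <- function(models, cutoff = 0.2, linkage = "average") {
  stopifnot(length(models) >= 1L)
  keys <- vapply(models, function(m) canonical_key(model_nodes(m)), "")
  n <- length(models)
  if (n == 1L) {
    assign <- stats::setNames(1L, keys)
    return(structure(
      list(assignments = assign, representatives = stats::setNames(keys, 1L),
           n_clusters = 1L, cutoff = cutoff, linkage = linkage),
      class = "cluster_result"
    ))
  }
  nodes <- lapply(models, model_nodes)
  lens <- lengths(nodes)
  d <- matrix(1, n, n) # cross-length pairs sit at distance 1
  diag(d) <- 0
  for (len in unique(lens)) {
    g <- which(lens == len)
    if (length(g) < 2L) next
    M <- do.call(rbind, nodes[g])
    mism <- matrix(0, length(g), length(g))
    for (j in seq_len(len)) mism <- mism + outer(M[, j], M[, j], "!=")
    d[g, g] <- mism / len
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  cl <- stats::cutree(hc, h = cutoff)
  totals <- vapply(models, model_total, 0)
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    o <- order(-totals[members], keys[members])
    keys[members[o[1L]]]
  }, "")
  structure(
    list(assignments = stats::setNames(as.integer(cl), keys),
         representatives = stats::setNames(reps, sort(unique(cl))),
         n_clusters = length(reps), cutoff = cutoff, linkage = linkage),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result: ", x$n_clusters, " clusters of ",
      length(x$assignments), " models (", x$linkage, " linkage, cut ",
      x$cutoff, ")>\n", sep = "")
  invisible(x)
}

#' Enzyme-ligand edge frequencies over an ensemble
#'
#' For every (protein, adjacent ligand) edge occurring in any model, the
#' fraction of models containing it, with dense descending ranks per
#' protein (ties share a rank). The ligand preceding a protein position is
#' its substrate, the following one its product.
#'
#' @param models Non-empty list of pathways or `scored_pathway` objects.
#' @return Data frame `edge_frequency_table` with columns `protein`,
#'   `ligand`, `role`, `frequency`, `rank`.
#' @export
edge_frequencies <- function(models) {
  stopifnot(length(models) >= 1L)
  rows <- list()
  for (m in models) {
    nodes <- model_nodes(m)
    K <- (length(nodes) - 1L) %/% 2L
    lig <- nodes[seq(1L, length(nodes), by = 2L)]
    pro <- nodes[seq(2L, length(nodes) - 1L, by = 2L)]
    rows[[length(rows) + 1L]] <- data.frame(
      protein = rep(pro, 2L),
      ligand = c(lig[seq_len(K)], lig[seq_len(K) + 1L]),
      role = rep(c("substrate", "product"), each = K),
      stringsAsFactors = FALSE
    )
  }
  all_edges <- do.call(rbind, rows)
  key <- paste(all_edges$protein, all_edges$ligand, all_edges$role, sep = "\r")
  counts <- table(key)
  uniq <- all_edges[!duplicated(key), , drop = FALSE]
  uniq$frequency <- as.numeric(counts[paste(uniq$protein, uniq$ligand, uniq$role, sep = "\r")]) /
    length(models)
  uniq <- uniq[order(uniq$protein, -uniq$frequency, uniq$role, uniq$ligand), , drop = FALSE]
  uniq$rank <- stats::ave(-uniq$frequency, uniq$protein, FUN = function(v) {
    match(v, sort(unique(v))) # dense ranks, ties share
  })
  rownames(uniq) <- NULL
  class(uniq) <- c("edge_frequency_table", "data.frame")
  uniq
}

#' Sampling convergence curve
#'
#' Fraction of the final cluster set discovered after the first r runs,
#' for r = 1..R; a plateau indicates converged sampling.
#'
#' @param per_run_keys List (one element per run) of canonical keys sampled
#'   in that run, e.g. `good_scoring_set$per_run_keys`.
#' @param clusters A [cluster_models()] result on the good-scoring set.
#' @return Data frame with columns `n_runs`, `fraction`.
#' @export
convergence_curve <- function(per_run_keys, clusters) {
  stopifnot(length(per_run_keys) >= 2L)
  assign <- clusters$assignments
  total <- clusters$n_clusters
  seen <- integer(0)
  frac <- numeric(length(per_run_keys))
  for (r in seq_along(per_run_keys)) {
    keys <- intersect(per_run_keys[[r]], names(assign))
    seen <- union(seen, unname(assign[keys]))
    frac[r] <- length(seen) / total
  }
  data.frame(n_runs = seq_along(per_run_keys), fraction = frac)
}

## ---- union-network JSON export ------------------------------------------

#' Export an ensemble as a union-network JSON document
#'
#' Builds the union of all models' graphs: a node list (id, type), an edge
#' list with per-model membership, and the model list with per-restraint
#' score breakdowns and cluster assignments (`"format": "netimp/1"`). The
#' document round-trips losslessly through [import_netimp()].
#'
#' @param models Non-empty list of `scored_pathway` objects (e.g.
#'   `good_scoring_set$models`), or a `netimp_document` from
#'   [import_netimp()], or a `pathway_map` fit.
#' @param clusters Optional [cluster_models()] result (computed on the
#'   spot when omitted).
#' @param path Optional file path; when given the JSON text is written
#'   there (and returned invisibly).
#' @return JSON text (class `json`), invisibly when `path` is given.
#' @export
export_netimp <- function(models, clusters = NULL, path = NULL) {
  if (inherits(models, "netimp_document")) {
    doc <- unclass(models)
  } else {
    if (inherits(models, "pathway_map")) {
      clusters <- clusters %||% models$clusters
      models <- models$models
    }
    stopifnot(length(models) >= 1L)
    if (is.null(clusters)) clusters <- cluster_models(models)
    keys <- vapply(models, function(m) m$key, "")
    o <- order(-vapply(models, function(m) m$total, 0), keys)
    models <- models[o]; keys <- keys[o]
    nodes <- list(); edges <- list()
    for (i in seq_along(models)) {
      nd <- models[[i]]$pathway
      n <- length(nd)
      typ <- rep(c("ligand", "protein"), length.out = n)
      for (j in seq_len(n)) {
        nodes[[nd[j]]] <- list(id = nd[j], type = typ[j])
      }
      for (j in seq_len(n - 1L)) {
        ek <- paste(nd[j], nd[j + 1L], sep = "\r")
        if (is.null(edges[[ek]])) {
          edges[[ek]] <- list(source = nd[j], target = nd[j + 1L], models = list())
        }
        edges[[ek]]$models <- c(edges[[ek]]$models, list(keys[i]))
      }
    }
    nodes <- nodes[order(names(nodes))]
    edges <- edges[order(names(edges))]
    doc <- list(
      format = "netimp/1",
      parameters = list(cluster_cutoff = clusters$cutoff, linkage = clusters$linkage),
      nodes = unname(nodes),
      edges = unname(edges),
      models = lapply(seq_along(models), function(i) {
        m <- models[[i]]
        terms <- m$terms[!is.na(m$terms)]
        list(
          key = m$key,
          nodes = as.list(m$pathway),
          total = m$total,
          scores = as.list(terms),
          cluster = unname(clusters$assignments[m$key])
        )
      })
    )
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Import a union-network JSON document
#'
#' @param path File path or JSON text.
#' @return Object of class `netimp_document` mirroring the export schema;
#'   re-exporting it reproduces the input byte for byte.
#' @export
import_netimp <- function(path) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!identical(doc$format, "netimp/1")) stop("not a netimp/1 document")
  structure(doc, class = "netimp_document")
}

#' @export
print.netimp_document <- function(x, ...) {
  cat("<netimp/1 document: ", length(x$nodes), " nodes, ", length(x$edges),
      " edges, ", length(x$models), " models>\n", sep = "")
  invisible(x)
}
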