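## Stage-2 candidate metabolite set: top docking hits per screen, expanded
## one round through the proteins' chemical transformations.

#' Build the candidate metabolite set
#'
#' The smallest library subset expected to contain all pathway
#' metabolites: the union of (a) the `top_n` best-scoring metabolites of
#' each docking screen and (b) every library metabolite whose Tanimoto
#' coefficient to any transformation product of a metabolite in (a)
#' exceeds `tc_cutoff` (strictly). Substrates matching no transform motif
#' contribute no products; expansion is single-round. Product comparisons
#' use the stereo-aware maximum (products of generic transforms routinely
#' carry undefined stereocenters).
#'
#' @param docking Named list: protein id -> named numeric vector of raw
#'   docking scores (lower = better) or [docking_table()].
#' @param transforms Named list: protein id -> character vector of SMIRKS
#'   (may be `NULL` or empty: no expansion).
#' @param library A [metabolite_library()] (the reference library, e.g.
#'   KEGG-like).
#' @param top_n Docking hits kept per screen (default 1000).
#' @param tc_cutoff Similarity threshold for transformation products
#'   (default 0.75, strict).
#' @param params Fingerprint parameters.
#' @return List with `ids` (character, sorted) and `provenance` (data
#'   frame: id, source `"docking"`/`"transform"`, parent).
#' @export
build_candidate_metabolites <- function(docking, transforms, library,
                                        top_n = 1000L, tc_cutoff = 0.75,
                                        params = fp_params()) {
  stopifnot(length(docking) >= 1L, top_n >= 1L, tc_cutoff > 0, tc_cutoff <= 1)
  docking <- lapply(docking, function(d) {
    if (inherits(d, "docking_table")) d$scores else d
  })
  ## (a) top-n per screen, ascending score, ties by id for determinism
  prov <- list()
  top_ids <- character()
  for (pid in names(docking)) {
    sc <- docking[[pid]]
    sc <- sc[names(sc) %in% library$id]
    o <- order(sc, names(sc))
    take <- names(sc)[o][seq_len(min(top_n, length(sc)))]
    top_ids <- union(top_ids, take)
    prov[[length(prov) + 1L]] <- data.frame(
      id = take, source = "docking", parent = pid, stringsAsFactors = FALSE
    )
  }
  ## (b) one transformation round over the union, matched into the library
  smirks_all <- unique(unlist(transforms, use.names = FALSE))
  if (length(smirks_all)) {
    smiles_map <- as.list(stats::setNames(library$smiles, library$id))
    prof <- chem_backend_cached(c(
      list(op = "profile", smiles = smiles_map, smirks = as.list(smirks_all)),
      params, list(max_isomers = 16L)
    ))
    bits <- lapply(prof$bits, function(b) as.integer(unlist(b)))
    for (pid in names(transforms)) {
      smk <- transforms[[pid]]
      if (length(smk) == 0L) next
      for (s in match(smk, smirks_all)) {
        per_sub <- prof$products[[s]]
        for (sub in top_ids) {
          prods <- per_sub[[sub]]
          if (length(prods) == 0L) next
          for (pr in prods) {
            pr_sbits <- lapply(pr$b, function(b) as.integer(unlist(b)))
            for (mid in library$id) {
              if (max_tc_vs(pr_sbits, bits[[mid]]) > tc_cutoff) {
                prov[[length(prov) + 1L]] <- data.frame(
                  id = mid, source = "transform", parent = sub,
                  stringsAsFactors = FALSE
                )
              }
            }
          }
        }
      }
    }
  }
  prov <- do.call(rbind, prov)
  prov <- prov[!duplicated(prov[c("id", "source", "parent")]), , drop = FALSE]
  rownames(prov) <- NULL
  list(ids = sort(unique(prov$id)), provenance = prov)
}

#' Write a candidate build to disk
#'
#' One metabolite id per line plus a provenance TSV.
#'
#' @param build Result of [build_candidate_metabolites()].
#' @param ids_path,provenance_path Output paths.
#' @export
write_candidates <- function(build, ids_path, provenance_path) {
  writeLines(build$ids, ids_path)
  write_tsv(build$provenance, provenance_path)
  invisible(NULL)
}
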