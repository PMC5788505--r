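## Pathway representation: a linear graph of alternating ligand and protein
## nodes, plus the candidate pools and positional constraints that bound the
## sampling space.

#' Metabolite library
#'
#' @param id Character vector of unique metabolite identifiers.
#' @param smiles Character vector of SMILES strings, parallel to `id`.
#' @return A `metabolite_library`: data frame with columns `id`, `smiles`.
#' @export
metabolite_library <- function(id, smiles) {
  stopifnot(is.character(id), is.character(smiles), length(id) == length(smiles))
  if (anyDuplicated(id)) stop("duplicate metabolite ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  structure(
    data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE),
    class = c("metabolite_library", "data.frame")
  )
}

#' Protein candidate table
#'
#' @param id Character vector of protein identifiers.
#' @param kind One of `"enzyme"`, `"transporter_sbp"`, `"dummy"` per protein.
#' @param family Free-text family label.
#' @return A `protein_table` data frame.
#' @export
protein_table <- function(id, kind = "enzyme", family = "") {
  kind <- rep_len(kind, length(id))
  family <- rep_len(family, length(id))
  ok <- kind %in% c("enzyme", "transporter_sbp", "dummy")
  if (!all(ok)) stop("unknown protein kind: ", paste(kind[!ok], collapse = ", "))
  if (anyDuplicated(id)) stop("duplicate protein ids")
  structure(
    data.frame(id = id, kind = kind, family = family, stringsAsFactors = FALSE),
    class = c("protein_table", "data.frame")
  )
}

#' Candidate pools and positional constraints
#'
#' Defines the sampling space: the protein and metabolite candidate pools,
#' the pathway length K (number of protein positions; a pathway has K+1
#' ligand positions), and optional anchors restricting single positions to
#' subsets of the pools (e.g. a transporter solute-binding protein fixed at
#' the pathway start with its ligand restricted to screening hits).
#'
#' Constraints are a named list; names have the form `"protein:<i>"` or
#' `"ligand:<i>"` (1-based position among positions of that type), values
#' are character vectors of allowed ids.
#'
#' @param proteins A [protein_table()] (or data frame with columns
#'   `id`, `kind`, `family`).
#' @param metabolites A [metabolite_library()] or character vector of ids.
#' @param K Integer pathway length(s). Several lengths may be given; most
#'   operations use `K[1]` unless asked otherwise.
#' @param constraints Named list of positional constraints (see Details).
#' @return Object of class `candidate_sets`.
#' @export
candidate_sets <- function(proteins, metabolites, K, constraints = list()) {
  if (is.character(proteins)) proteins <- protein_table(proteins)
  met_ids <- if (is.data.frame(metabolites)) metabolites$id else as.character(metabolites)
  K <- as.integer(K)
  stopifnot(all(K >= 1), length(met_ids) >= max(K) + 1L, nrow(proteins) >= max(K))
  if (length(constraints)) {
    if (is.null(names(constraints)) || any(!grepl("^(protein|ligand):[0-9]+$", names(constraints))))
      stop("constraint names must look like 'protein:1' or 'ligand:2'")
    for (nm in names(constraints)) {
      allowed <- constraints[[nm]]
      pool <- if (startsWith(nm, "protein")) proteins$id else met_ids
      if (!all(allowed %in% pool))
        stop("constraint ", nm, " allows ids outside the candidate pool: ",
             paste(setdiff(allowed, pool), collapse = ", "))
    }
  }
  structure(
    list(
      proteins = proteins,
      metabolites = met_ids,
      library = if (is.data.frame(metabolites)) metabolites else NULL,
      K = K,
      constraints = constraints
    ),
    class = "candidate_sets"
  )
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("<candidate_sets: ", nrow(x$proteins), " proteins, ",
      length(x$metabolites), " metabolites, K = ",
      paste(x$K, collapse = "/"),
      if (length(x$constraints)) paste0(", ", length(x$constraints), " constraints"),
      ">\n", sep = "")
  invisible(x)
}

#' Construct a pathway model
#'
#' A pathway is an ordered node sequence alternating ligand and protein
#' positions, beginning and ending with a ligand: `[m1, p1, m2, p2, ..., mK+1]`.
#'
#' @param nodes Character vector of node ids (odd positions ligands, even
#'   positions proteins), length `2K + 1`.
#' @return Character vector of class `pathway`.
#' @export
pathway <- function(nodes) {
  nodes <- as.character(nodes)
  if (length(nodes) < 3L || length(nodes) %% 2L == 0L)
    stop("a pathway has 2K+1 nodes (K >= 1)")
  structure(nodes, class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", paste(unclass(x), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

pathway_ligands <- function(p) unclass(p)[seq(1L, length(p), by = 2L)]
pathway_proteins <- function(p) unclass(p)[seq(2L, length(p), by = 2L)]

#' Validate a pathway against candidate pools and constraints
#'
#' Checks strict ligand/protein alternation, uniqueness of every id, pool
#' membership, and positional constraints. Validation never raises: the
#' result carries a list of named violations.
#'
#' @param p A [pathway()] (or bare character vector of nodes).
#' @param cand A [candidate_sets()].
#' @return List with `valid` (logical) and `violations` (character vector).
#' @export
validate_pathway <- function(p, cand) {
  p <- as.character(p)
  v <- character()
  if (length(p) < 3L || length(p) %% 2L == 0L) {
    v <- c(v, "alternation: a pathway has 2K+1 nodes")
    return(list(valid = FALSE, violations = v))
  }
  lig <- p[seq(1L, length(p), by = 2L)]
  pro <- p[seq(2L, length(p), by = 2L)]
  K <- length(pro)
  if (!(K %in% cand$K)) v <- c(v, sprintf("length: K=%d not among declared lengths", K))
  if (anyDuplicated(lig)) v <- c(v, "metabolite repeated")
  if (anyDuplicated(pro)) v <- c(v, "protein repeated")
  if (!all(lig %in% cand$metabolites))
    v <- c(v, paste0("unknown metabolite: ",
                     paste(setdiff(lig, cand$metabolites), collapse = ", ")))
  if (!all(pro %in% cand$proteins$id))
    v <- c(v, paste0("unknown protein: ",
                     paste(setdiff(pro, cand$proteins$id), collapse = ", ")))
  for (nm in names(cand$constraints)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    idx <- as.integer(parts[2L])
    node <- if (parts[1L] == "protein") {
      if (idx <= K) pro[idx] else NA_character_
    } else {
      if (idx <= K + 1L) lig[idx] else NA_character_
    }
    if (!is.na(node) && !(node %in% cand$constraints[[nm]]))
      v <- c(v, paste0("constraint at ", nm))
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Canonical key of a pathway
#'
#' Deterministic string identifying a node sequence; two pathways share a
#' key iff their node sequences are identical. Used to define "unique
#' sampled models".
#'
#' @param p A [pathway()] or character vector of nodes.
#' @return Character scalar, nodes joined by `"|"`.
#' @export
canonical_key <- function(p) paste(as.character(p), collapse = "|")

## all ordered selections of k elements from x; small-instance tool only
perm_k <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(matrix(character(), nrow = 1L, ncol = 0L))
  if (k > n) return(matrix(character(), nrow = 0L, ncol = k))
  rec <- function(chosen, rest) {
    if (length(chosen) == k) return(list(chosen))
    out <- list()
    for (i in seq_along(rest)) {
      out <- c(out, rec(c(chosen, rest[i]), rest[-i]))
    }
    out
  }
  do.call(rbind, rec(character(), x))
}

#' Count of unconstrained pathways
#'
#' `P!/(P-K)! * L!/(L-K-1)!` ordered protein and ligand selections.
#'
#' @param n_proteins,n_metabolites Pool sizes.
#' @param K Pathway length.
#' @return Numeric count.
#' @export
n_pathways <- function(n_proteins, n_metabolites, K) {
  prod(seq(n_proteins, by = -1, length.out = K)) *
    prod(seq(n_metabolites, by = -1, length.out = K + 1))
}

#' Exhaustively enumerate all valid pathways
#'
#' Brute-force oracle for small instances, used to verify the Monte Carlo
#' sampler. Guarded by a count ceiling on the unconstrained permutation
#' count.
#'
#' @param cand A [candidate_sets()].
#' @param K Pathway length (default `cand$K[1]`).
#' @param ceiling Maximum tolerated unconstrained count (default `1e7`).
#' @return List of `pathway` objects, each passing [validate_pathway()].
#' @export
enumerate_pathways <- function(cand, K = cand$K[1L], ceiling = 1e7) {
  P <- nrow(cand$proteins)
  L <- length(cand$metabolites)
  total <- n_pathways(P, L, K)
  if (total > ceiling) {
    stop(sprintf("instance too large to enumerate: %g pathways exceeds ceiling %g",
                 total, ceiling))
  }
  pro_perm <- perm_k(cand$proteins$id, K)
  lig_perm <- perm_k(cand$metabolites, K + 1L)
  cand1 <- cand
  cand1$K <- K
  out <- vector("list", nrow(pro_perm) * nrow(lig_perm))
  n <- 0L
  for (i in seq_len(nrow(pro_perm))) {
    for (j in seq_len(nrow(lig_perm))) {
      nodes <- character(2L * K + 1L)
      nodes[seq(1L, 2L * K + 1L, by = 2L)] <- lig_perm[j, ]
      nodes[seq(2L, 2L * K, by = 2L)] <- pro_perm[i, ]
      if (validate_pathway(nodes, cand1)$valid) {
        n <- n + 1L
        out[[n]] <- pathway(nodes)
      }
    }
  }
  out[seq_len(n)]
}
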