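## Restraint data: every information source consumed by the scoring
## function, with its normalization statistics.

#' Z-score with a degenerate-spread guard
#'
#' `(x - mean)/sd`; when the population spread is (numerically) zero the
#' score is defined as 0 with a warning, so uninformative populations drop
#' out instead of producing infinities.
#'
#' @param x Numeric value(s).
#' @param mean,sd Population statistics.
#' @return Numeric, same length as `x`.
#' @export
zscore <- function(x, mean, sd) {
  if (is.na(sd) || sd < 1e-12) {
    warning("zero spread in normalization population; z-score set to 0")
    return(rep(0, length(x)))
  }
  (x - mean) / sd
}

#' SEA pair score S_AB
#'
#' Converts a ligand-set similarity E-value for proteins A and B into the
#' pair score `S_AB = w_AB * F_AB`, with `w_AB = min(-log10 evalue, 50)`
#' and `F_AB = min(w_AA, w_BB)/50` modeling confidence through the
#' self-similarity terms.
#'
#' @param evalue E-value for the pair (must be > 0).
#' @param w_AA,w_BB Capped self-similarity weights in `[0, 50]`.
#' @return Numeric scalar.
#' @export
sea_sab <- function(evalue, w_AA = 50, w_BB = 50) {
  if (any(evalue <= 0)) stop("E-values must be positive")
  w_ab <- pmin(-log10(evalue), 50)
  w_ab * pmin(w_AA, w_BB) / 50
}

#' Docking score table for one protein
#'
#' Raw docking scores (lower = more favorable) for a protein against a
#' metabolite set, with the per-protein population mean/sd used to convert
#' raw scores into Z-scores.
#'
#' @param scores Named numeric vector: metabolite id -> raw docking score.
#' @return A `docking_table`: list with `scores`, `mean`, `sd`.
#' @export
docking_table <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  structure(
    list(scores = scores, mean = mean(scores), sd = pop_sd(scores)),
    class = "docking_table"
  )
}

#' Per-protein docking Z-scores
#'
#' @param tab A [docking_table()].
#' @return Named numeric vector of Z-scores over the table's metabolites.
#' @export
docking_zscores <- function(tab) {
  stopifnot(inherits(tab, "docking_table"))
  zscore(tab$scores, tab$mean, tab$sd)
}

#' Assemble a restraint set
#'
#' Any component may be absent (`NULL`); the corresponding scoring term is
#' then simply omitted for every pathway. Normalization statistics are
#' computed once, at compile time, so scoring is pure.
#'
#' @param library A [metabolite_library()] covering every id referenced by
#'   the other components (candidates, central metabolites, screening hits).
#' @param docking Named list: protein id -> named numeric vector of raw
#'   docking scores (or [docking_table()]).
#' @param sea Data frame with columns `a`, `b`, `evalue` (self pairs `A,A`
#'   supply the confidence weights; missing self pairs default to the
#'   maximal weight 50 with a warning at compile time).
#' @param transforms Named list: protein id -> character vector of SMIRKS.
#' @param central Character vector of central-metabolism metabolite ids.
#' @param hts Named list: screened protein id -> character vector of hit
#'   metabolite ids.
#' @param homology Named list: protein id -> reference substrate SMILES.
#' @param gene_cluster Character vector of clustered protein ids, or a
#'   two-column matrix/data frame of protein pairs.
#' @return Object of class `restraint_set`.
#' @export
restraint_set <- function(library,
                          docking = NULL,
                          sea = NULL,
                          transforms = NULL,
                          central = NULL,
                          hts = NULL,
                          homology = NULL,
                          gene_cluster = NULL) {
  stopifnot(inherits(library, "metabolite_library"))
  if (!is.null(docking)) {
    docking <- lapply(docking, function(d) if (inherits(d, "docking_table")) d else docking_table(d))
  }
  if (!is.null(sea)) {
    sea <- as.data.frame(sea)
    stopifnot(all(c("a", "b", "evalue") %in% names(sea)))
    if (any(sea$evalue <= 0)) stop("SEA E-values must be positive")
  }
  if (!is.null(central) && !all(central %in% library$id))
    stop("central metabolites missing from library: ",
         paste(setdiff(central, library$id), collapse = ", "))
  if (!is.null(gene_cluster)) {
    gene_cluster <- if (is.null(dim(gene_cluster))) {
      ids <- as.character(gene_cluster)
      if (length(ids) < 2) stop("gene cluster needs at least 2 proteins")
      t(utils::combn(sort(ids), 2L))
    } else {
      as.matrix(gene_cluster)
    }
  }
  structure(
    list(
      library = library, docking = docking, sea = sea, transforms = transforms,
      central = central, hts = hts, homology = homology, gene_cluster = gene_cluster
    ),
    class = "restraint_set"
  )
}

#' @export
print.restraint_set <- function(x, ...) {
  present <- c(
    docking = !is.null(x$docking), transforms = !is.null(x$transforms),
    sea = !is.null(x$sea), endpoint = !is.null(x$central),
    hts = !is.null(x$hts), homology = !is.null(x$homology),
    gene_cluster = !is.null(x$gene_cluster)
  )
  cat("<restraint_set: ", nrow(x$library), " library metabolites; components: ",
      paste(names(present)[present], collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Restraint component names
#'
#' @return Character vector of the recognized restraint component names.
#' @export
restraint_names <- function() {
  c("docking", "transforms", "sea", "endpoint", "hts", "homology", "gene_cluster")
}

#' Remove one restraint component
#'
#' Returns a copy of the restraint set (or planted problem) with the named
#' component removed; all other components untouched. Scoring a pathway
#' against the ablated set yields the original total minus the dropped term.
#'
#' @param x A `restraint_set` or `planted_problem`.
#' @param drop One of [restraint_names()].
#' @return Same class as `x`.
#' @export
ablate <- function(x, drop) {
  stopifnot(length(drop) == 1L)
  if (!drop %in% restraint_names()) stop("unknown restraint name: ", drop)
  if (inherits(x, "planted_problem")) {
    x$restraints <- ablate(x$restraints, drop)
    return(x)
  }
  stopifnot(inherits(x, "restraint_set"))
  field <- switch(drop, endpoint = "central", drop)
  if (is.null(x[[field]])) stop("restraint not present: ", drop)
  x[field] <- list(NULL)
  x
}

#' Keep only some restraint components
#'
#' @param x A `restraint_set` or `planted_problem`.
#' @param keep Character vector of component names to retain.
#' @return Same class as `x`.
#' @export
restrict_restraints <- function(x, keep) {
  stopifnot(all(keep %in% restraint_names()))
  if (inherits(x, "planted_problem")) {
    x$restraints <- restrict_restraints(x$restraints, keep)
    return(x)
  }
  for (nm in restraint_names()) {
    field <- switch(nm, endpoint = "central", nm)
    if (!nm %in% keep) x[field] <- list(NULL)
  }
  x
}
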