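## Cheminformatics primitives: Morgan fingerprints, Tanimoto similarity,
## SMIRKS transformation application, stereoisomer-aware comparison.
## RDKit does the chemistry; similarity arithmetic is done here on bit sets.

#' Default fingerprint parameters
#'
#' Morgan (circular) fingerprints of radius 2 folded to 2048 bits with
#' chirality encoded — the community-standard parameterization for
#' metabolite comparison. Chirality matters here because sugar-acid
#' interconversions differ only in stereochemistry.
#'
#' @return A list with elements `radius`, `nbits`, `chiral`.
#' @export
fp_params <- function() list(radius = 2L, nbits = 2048L, chiral = TRUE)

new_chem_fp <- function(bits, params, smiles = NULL) {
  structure(
    list(
      bits = as.integer(bits),
      nbits = as.integer(params$nbits),
      radius = as.integer(params$radius),
      chiral = isTRUE(params$chiral),
      smiles = smiles
    ),
    class = "chem_fp"
  )
}

#' @export
print.chem_fp <- function(x, ...) {
  cat(
    "<Morgan fingerprint: ", length(x$bits), " bits on / ", x$nbits,
    ", radius ", x$radius, if (x$chiral) ", chiral" else "", ">\n",
    sep = ""
  )
  invisible(x)
}

#' Compute Morgan fingerprints
#'
#' @param smiles Character vector of SMILES strings.
#' @param params Fingerprint parameters, see [fp_params()].
#' @return A single `chem_fp` for one SMILES, otherwise a list of them
#'   (named after `names(smiles)` when present). Unparseable records are a
#'   load-time error naming the offending entry.
#' @export
chem_fingerprint <- function(smiles, params = fp_params()) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  resp <- chem_backend(c(list(op = "fingerprints", smiles = as.list(unname(smiles))), params))
  bad <- unlist(resp$bad)
  if (length(bad)) {
    lab <- if (!is.null(names(smiles))) names(smiles)[bad] else smiles[bad]
    stop("unparseable SMILES: ", paste(lab, collapse = ", "))
  }
  fps <- lapply(seq_along(smiles), function(i) {
    new_chem_fp(unlist(resp$bits[[i]]), params, smiles = resp$canonical[[i]])
  })
  names(fps) <- names(smiles)
  if (length(fps) == 1L) fps[[1L]] else fps
}

check_fp_pair <- function(a, b) {
  if (!inherits(a, "chem_fp") || !inherits(b, "chem_fp")) {
    stop("tanimoto() expects two 'chem_fp' objects")
  }
  if (a$nbits != b$nbits || a$radius != b$radius || a$chiral != b$chiral) {
    stop("fingerprint parameters differ; only like-parameterized fingerprints compare")
  }
  invisible(TRUE)
}

tanimoto_bits <- function(a, b) {
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0L) return(0) # two empty fingerprints: no evidence of similarity
  ni / nu
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|A intersect B| / |A union B|`, in `[0, 1]`. Two empty fingerprints
#' score 0 by convention.
#'
#' @param a,b `chem_fp` objects with matching parameters.
#' @return Numeric scalar in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  check_fp_pair(a, b)
  tanimoto_bits(a$bits, b$bits)
}

#' Apply a SMIRKS reaction transform to a molecule
#'
#' Applies the generic reaction at every matching site of the substrate and
#' returns the distinct canonical product SMILES. An empty result means the
#' substrate does not match the reaction's substrate motif.
#'
#' @param smiles Substrate SMILES (single string).
#' @param smirks SMIRKS reaction string (single string).
#' @return Character vector of canonical product SMILES (possibly empty).
#' @export
apply_transformation <- function(smiles, smirks) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            is.character(smirks), length(smirks) == 1L)
  resp <- chem_backend(list(op = "transform", smirks = list(smirks), smiles = list(smiles)))
  if (length(resp$bad_smirks)) stop("unparseable SMIRKS: ", smirks)
  if (length(resp$bad_smiles)) stop("unparseable SMILES: ", smiles)
  as.character(unlist(resp$products[[1L]][[1L]], use.names = FALSE))
}

#' Stereo-aware maximum Tanimoto coefficient
#'
#' When molecule `a` has undefined stereocenters, up to 16 distinct
#' stereoisomer assignments are enumerated and the maximum Tanimoto
#' coefficient against `b` is returned; with no undefined centers this
#' reduces to the plain coefficient.
#'
#' @param a,b SMILES strings.
#' @param params Fingerprint parameters.
#' @param max_isomers Enumeration cap (default 16).
#' @return Numeric scalar in `[0, 1]`.
#' @export
max_stereo_tanimoto <- function(a, b, params = fp_params(), max_isomers = 16L) {
  stopifnot(is.character(a), is.character(b))
  resp <- chem_backend(c(
    list(op = "stereo_bits", smiles = as.list(c(a, b)), max_isomers = max_isomers),
    params
  ))
  if (length(resp$bad)) stop("unparseable SMILES: ", c(a, b)[unlist(resp$bad)])
  b_bits <- unlist(resp$bits[[2L]][[1L]])
  max(vapply(resp$bits[[1L]], function(iso) tanimoto_bits(unlist(iso), b_bits), 0))
}

#' Count stereoisomer assignments that would be evaluated
#'
#' @inheritParams max_stereo_tanimoto
#' @param smiles SMILES string.
#' @return Integer: number of distinct assignments, capped at `max_isomers`.
#' @export
n_stereoisomers <- function(smiles, max_isomers = 16L) {
  resp <- chem_backend(list(op = "n_stereoisomers", smiles = as.list(smiles),
                            max_isomers = max_isomers))
  n <- unlist(resp$n)
  if (any(is.na(n))) stop("unparseable SMILES")
  n
}

#' Mean and population standard deviation of a similarity population
#'
#' Summarizes a reference population of Tanimoto coefficients; these
#' statistics normalize the knowledge-based restraint terms. Accepts either
#' a numeric vector of precomputed coefficients, or a list of query
#' fingerprints plus a reference (single fingerprint, or a list in which
#' case each query contributes its maximum coefficient over the reference
#' set).
#'
#' @param query Numeric vector of Tanimoto coefficients, or list of
#'   `chem_fp` objects.
#' @param reference Optional `chem_fp` or list of `chem_fp`.
#' @return Object of class `similarity_stats`: list with `mean` and `sd`
#'   (population, ddof = 0).
#' @export
similarity_stats <- function(query, reference = NULL) {
  if (is.numeric(query)) {
    tc <- query
  } else {
    stopifnot(is.list(query), length(query) >= 1, !is.null(reference))
    refs <- if (inherits(reference, "chem_fp")) list(reference) else reference
    tc <- vapply(query, function(q) {
      max(vapply(refs, function(r) tanimoto(q, r), 0))
    }, 0)
  }
  if (length(tc) == 0) stop("empty similarity population")
  structure(
    list(mean = mean(tc), sd = pop_sd(tc)),
    class = "similarity_stats"
  )
}

#' @export
print.similarity_stats <- function(x, ...) {
  cat(sprintf("<similarity population: mean %.4f, sd %.4f>\n", x$mean, x$sd))
  invisible(x)
}

## population (ddof = 0) standard deviation
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
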