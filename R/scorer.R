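## Compiled scoring of pathway models. All normalization populations are
## evaluated once per (candidate set, restraint set) pair and frozen into
## lookup tables, so scoring is a pure function of the node sequence and
## fast enough for millions of Monte Carlo evaluations.

quiet_z <- function(x, m, s) {
  if (is.na(s) || s < 1e-12) {
    x[!is.na(x)] <- 0 # degenerate population: uninformative, preserves absences
    return(x)
  }
  (x - m) / s
}

## max Tanimoto of a list of stereo-enumerated bit sets against one bit set
max_tc_vs <- function(sbits, bits) {
  best <- 0
  for (b in sbits) {
    tc <- tanimoto_bits(b, bits)
    if (tc > best) best <- tc
  }
  best
}

#' Compile a pathway scorer
#'
#' Precomputes every restraint lookup table: per-protein docking Z-scores,
#' transformation Tanimoto matrices (maximum over each protein's SMIRKS,
#' their products, and up to 16 stereoisomer assignments per product,
#' Z-scored per substrate against all candidate metabolites), SEA pair
#' Z-scores, and the endpoint / screening-hit / homology / gene-cluster
#' normalizations.
#'
#' @param cand A [candidate_sets()].
#' @param rest A [restraint_set()].
#' @param params Fingerprint parameters, see [fp_params()].
#' @param gc_max_exhaustive Enumerate gene-cluster subset populations
#'   exhaustively up to this many subsets, else sample.
#' @param gc_samples,gc_seed Sample size and seed for large subset spaces.
#' @return Object of class `pathway_scorer`.
#' @export
pathway_scorer <- function(cand, rest, params = fp_params(),
                           gc_max_exhaustive = 2^20, gc_samples = 1e5,
                           gc_seed = 1L) {
  stopifnot(inherits(cand, "candidate_sets"), inherits(rest, "restraint_set"))
  lib <- rest$library
  mids <- cand$metabolites
  if (!all(mids %in% lib$id))
    stop("candidate metabolites missing from library: ",
         paste(setdiff(mids, lib$id), collapse = ", "))
  pids <- cand$proteins$id
  kinds <- cand$proteins$kind
  P <- length(pids); L <- length(mids)
  is_dummy <- kinds == "dummy"
  if (any(is_dummy) && !is.null(rest$docking) &&
      any(pids[is_dummy] %in% names(rest$docking)))
    stop("dummy proteins cannot carry docking tables")

  ## ---- chemistry profile (one backend call, cached) --------------------
  need_ids <- unique(c(mids, rest$central, unlist(rest$hts)))
  need_ids <- need_ids[need_ids %in% lib$id]
  smiles_map <- as.list(stats::setNames(lib$smiles[match(need_ids, lib$id)], need_ids))
  ref_ids <- character()
  if (!is.null(rest$homology)) {
    ref_ids <- paste0(".ref.", names(rest$homology))
    for (i in seq_along(rest$homology)) smiles_map[[ref_ids[i]]] <- rest$homology[[i]]
  }
  smirks_all <- unique(unlist(rest$transforms, use.names = FALSE))
  prof <- chem_backend_cached(c(
    list(op = "profile", smiles = smiles_map, smirks = as.list(smirks_all)),
    params, list(max_isomers = 16L)
  ))
  bits <- lapply(prof$bits, function(b) as.integer(unlist(b)))
  sbits <- lapply(prof$sbits, function(ss) lapply(ss, function(b) as.integer(unlist(b))))

  ## ---- docking ---------------------------------------------------------
  zdock <- matrix(NA_real_, P, L, dimnames = list(pids, mids))
  if (!is.null(rest$docking)) {
    for (pid in names(rest$docking)) {
      if (!pid %in% pids) next
      tab <- rest$docking[[pid]]
      z <- quiet_z(tab$scores, tab$mean, tab$sd)
      hit <- intersect(names(z), mids)
      zdock[pid, hit] <- z[hit]
    }
  }

  ## ---- chemical transformations ---------------------------------------
  ## direct rule (dummy / transform-less proteins): stereo-max TC of the
  ## substrate itself against every candidate
  tc_direct <- matrix(0, L, L, dimnames = list(mids, mids))
  for (i in seq_len(L)) {
    si <- sbits[[mids[i]]]
    for (j in seq_len(L)) tc_direct[i, j] <- max_tc_vs(si, bits[[mids[j]]])
  }
  zct_direct <- t(apply(tc_direct, 1L, function(r) quiet_z(r, mean(r), pop_sd(r))))

  ct_enabled <- !is.null(rest$transforms)
  zct <- vector("list", P)
  if (ct_enabled) {
    ## per unique SMIRKS: stereo-max TC of each product of substrate i vs candidate j
    tc_by_smirks <- lapply(seq_along(smirks_all), function(s) {
      m <- matrix(0, L, L, dimnames = list(mids, mids))
      per_sub <- prof$products[[s]]
      for (i in seq_len(L)) {
        prods <- per_sub[[mids[i]]]
        if (length(prods) == 0L) next
        for (j in seq_len(L)) {
          bj <- bits[[mids[j]]]
          best <- 0
          for (pr in prods) {
            tc <- max_tc_vs(lapply(pr$b, function(b) as.integer(unlist(b))), bj)
            if (tc > best) best <- tc
          }
          m[i, j] <- best
        }
      }
      m
    })
    for (p in seq_len(P)) {
      smk <- rest$transforms[[pids[p]]]
      if (is_dummy[p] || is.null(smk) || length(smk) == 0L) {
        zct[[p]] <- zct_direct
      } else {
        idx <- match(smk, smirks_all)
        tc_p <- tc_by_smirks[[idx[1L]]]
        for (s in idx[-1L]) tc_p <- pmax(tc_p, tc_by_smirks[[s]])
        zct[[p]] <- t(apply(tc_p, 1L, function(r) quiet_z(r, mean(r), pop_sd(r))))
      }
    }
  }

  ## ---- SEA -------------------------------------------------------------
  zsea <- matrix(NA_real_, P, P, dimnames = list(pids, pids))
  if (!is.null(rest$sea)) {
    ev <- matrix(NA_real_, P, P, dimnames = list(pids, pids))
    for (r in seq_len(nrow(rest$sea))) {
      a <- rest$sea$a[r]; b <- rest$sea$b[r]
      if (a %in% pids && b %in% pids) ev[a, b] <- ev[b, a] <- rest$sea$evalue[r]
    }
    w_self <- pmin(-log10(diag(ev)), 50)
    if (any(is.na(w_self) & !is_dummy)) {
      warning("missing SEA self E-values for: ",
              paste(pids[is.na(w_self) & !is_dummy], collapse = ", "),
              "; self-weight defaults to 50")
      w_self[is.na(w_self)] <- 50
    }
    sab <- matrix(NA_real_, P, P, dimnames = list(pids, pids))
    for (a in seq_len(P)) {
      for (b in seq_len(P)) {
        if (a == b || is_dummy[a] || is_dummy[b] || is.na(ev[a, b])) next
        sab[a, b] <- sea_sab(ev[a, b], w_self[a], w_self[b])
      }
    }
    pop <- sab[upper.tri(sab)]
    pop <- pop[!is.na(pop)]
    if (length(pop)) {
      zsea <- quiet_z(sab, mean(pop), pop_sd(pop))
      dimnames(zsea) <- list(pids, pids)
    }
  }

  ## ---- endpoint (central metabolism) ----------------------------------
  zcm <- NULL
  if (!is.null(rest$central)) {
    cen_bits <- lapply(rest$central, function(id) bits[[id]])
    tc_max <- vapply(mids, function(m) {
      max(vapply(cen_bits, function(cb) tanimoto_bits(bits[[m]], cb), 0))
    }, 0)
    pop <- unlist(lapply(mids, function(m) {
      vapply(cen_bits, function(cb) tanimoto_bits(bits[[m]], cb), 0)
    }))
    zcm <- quiet_z(tc_max, mean(pop), pop_sd(pop))
    names(zcm) <- mids
  }

  ## ---- screening hits / homology (per-protein substrate profiles) -----
  profile_term <- function(target_bits_list) {
    tc <- vapply(mids, function(m) {
      max(vapply(target_bits_list, function(tb) tanimoto_bits(bits[[m]], tb), 0))
    }, 0)
    quiet_z(tc, mean(tc), pop_sd(tc))
  }
  zhts <- NULL
  if (!is.null(rest$hts)) {
    keep <- intersect(names(rest$hts), pids)
    if (length(keep))
      zhts <- lapply(stats::setNames(keep, keep), function(pid) {
        profile_term(lapply(rest$hts[[pid]], function(id) bits[[id]]))
      })
  }
  zhs <- NULL
  if (!is.null(rest$homology)) {
    keep <- intersect(names(rest$homology), pids)
    if (length(keep))
      zhs <- lapply(stats::setNames(keep, keep), function(pid) {
        profile_term(list(bits[[paste0(".ref.", pid)]]))
      })
  }

  ## ---- gene cluster ----------------------------------------------------
  gc <- NULL
  if (!is.null(rest$gene_cluster)) {
    cl_pairs <- apply(rest$gene_cluster, 1L, function(r) paste(sort(r), collapse = "|"))
    cl_pairs <- unique(cl_pairs)
    real <- pids[!is_dummy]
    gc_value <- function(members) {
      if (length(members) < 2L) return(0)
      pp <- utils::combn(sort(members), 2L, FUN = paste, collapse = "|")
      length(intersect(pp, cl_pairs)) / max(length(cl_pairs), length(pp))
    }
    sizes <- 3:length(real)
    counts <- vapply(sizes, function(k) choose(length(real), k), 0)
    if (sum(counts) <= gc_max_exhaustive) {
      pop <- unlist(lapply(sizes, function(k) {
        utils::combn(real, k, FUN = gc_value)
      }))
    } else {
      pop <- with_preserved_seed(gc_seed, {
        vapply(seq_len(gc_samples), function(i) {
          k <- sizes[sample.int(length(sizes), 1L)]
          gc_value(real[sample.int(length(real), k)])
        }, 0)
      })
    }
    gc <- list(pairs = cl_pairs, mean = mean(pop), sd = pop_sd(pop),
               value = gc_value)
  }

  structure(
    list(
      mids = mids, pids = pids, is_dummy = is_dummy, K = cand$K,
      cand = cand, params = params,
      zdock = zdock, ct_enabled = ct_enabled, zct = zct,
      zct_direct = zct_direct,
      sea_enabled = !is.null(rest$sea), zsea = zsea,
      zcm = zcm, zhts = zhts, zhs = zhs, gc = gc
    ),
    class = "pathway_scorer"
  )
}

#' @export
print.pathway_scorer <- function(x, ...) {
  terms <- c(
    z_vs = any(!is.na(x$zdock)), z_ct = x$ct_enabled, z_sea = x$sea_enabled,
    z_cm = !is.null(x$zcm), z_hts = !is.null(x$zhts), z_hs = !is.null(x$zhs),
    z_gc = !is.null(x$gc)
  )
  cat("<pathway_scorer: ", length(x$pids), " proteins x ", length(x$mids),
      " metabolites; active terms: ", paste(names(terms)[terms], collapse = " + "),
      ">\n", sep = "")
  invisible(x)
}

## indices of a character pathway in scorer space
pathway_indices <- function(sc, p) {
  p <- as.character(p)
  n <- length(p)
  lig <- match(p[seq(1L, n, by = 2L)], sc$mids)
  pro <- match(p[seq(2L, n - 1L, by = 2L)], sc$pids)
  if (anyNA(lig) || anyNA(pro)) stop("pathway contains ids outside the candidate pools")
  list(lig = lig, pro = pro)
}

## full per-term breakdown from index vectors; NA marks an absent term
scorer_breakdown <- function(sc, lig, pro) {
  K <- length(pro)
  terms <- c(z_vs = NA_real_, z_ct = NA_real_, z_sea = NA_real_, z_cm = NA_real_,
             z_hts = NA_real_, z_hs = NA_real_, z_gc = NA_real_)
  ## virtual screening: substrate-enzyme and product-enzyme pairs
  zv <- c(sc$zdock[cbind(pro, lig[seq_len(K)])],
          sc$zdock[cbind(pro, lig[seq_len(K) + 1L])])
  zv <- zv[!is.na(zv)]
  if (length(zv)) terms["z_vs"] <- -mean(zv)
  ## chemical transformations: one triad per protein position
  if (sc$ct_enabled) {
    zt <- numeric(K)
    for (i in seq_len(K)) zt[i] <- sc$zct[[pro[i]]][lig[i], lig[i + 1L]]
    terms["z_ct"] <- mean(zt)
  }
  ## SEA: consecutive non-dummy protein pairs
  if (sc$sea_enabled && K >= 2L) {
    zs <- sc$zsea[cbind(pro[-K], pro[-1L])]
    zs <- zs[!is.na(zs)]
    if (length(zs)) terms["z_sea"] <- mean(zs)
  }
  ## endpoint
  if (!is.null(sc$zcm)) terms["z_cm"] <- sc$zcm[lig[K + 1L]]
  ## screening hits: substrate of each screened protein present in the model
  if (!is.null(sc$zhts)) {
    v <- numeric()
    for (pid in names(sc$zhts)) {
      pos <- match(match(pid, sc$pids), pro)
      if (!is.na(pos)) v <- c(v, sc$zhts[[pid]][lig[pos]])
    }
    if (length(v)) terms["z_hts"] <- mean(v)
  }
  ## homology
  if (!is.null(sc$zhs)) {
    v <- numeric()
    for (pid in names(sc$zhs)) {
      pos <- match(match(pid, sc$pids), pro)
      if (!is.na(pos)) v <- c(v, sc$zhs[[pid]][lig[pos]])
    }
    if (length(v)) terms["z_hs"] <- mean(v)
  }
  ## gene cluster
  if (!is.null(sc$gc)) {
    members <- sc$pids[pro[!sc$is_dummy[pro]]]
    terms["z_gc"] <- quiet_z(sc$gc$value(members), sc$gc$mean, sc$gc$sd)
  }
  terms
}

## fast total (same arithmetic as scorer_breakdown, minimal allocation)
scorer_total <- function(sc, lig, pro) {
  terms <- scorer_breakdown(sc, lig, pro)
  sum(terms, na.rm = TRUE)
}

#' Score a pathway model against all restraints
#'
#' The composite score is the sum of the per-restraint Z-score terms;
#' terms whose information is unavailable (or not applicable to this
#' pathway) are omitted. A dummy node contributes no score except through
#' the chemical transformation term.
#'
#' @param p A [pathway()] or character node vector.
#' @param scorer A [pathway_scorer()]; alternatively a `planted_problem`,
#'   whose scorer is compiled (and memoized) on first use.
#' @return Object of class `scored_pathway`: list with `pathway`, `key`,
#'   `terms` (named numeric; `NA` = absent) and `total`.
#' @export
score_pathway <- function(p, scorer) {
  scorer <- as_scorer(scorer)
  idx <- pathway_indices(scorer, p)
  terms <- scorer_breakdown(scorer, idx$lig, idx$pro)
  structure(
    list(pathway = as.character(p), key = canonical_key(p),
         terms = terms, total = sum(terms, na.rm = TRUE)),
    class = "scored_pathway"
  )
}

#' @export
print.scored_pathway <- function(x, ...) {
  cat("<scored_pathway> total = ", format(x$total, digits = 4), "\n  ",
      paste(x$pathway, collapse = " -> "), "\n", sep = "")
  t <- x$terms[!is.na(x$terms)]
  cat("  ", paste(sprintf("%s=%.3f", names(t), t), collapse = "  "), "\n", sep = "")
  invisible(x)
}

as_scorer <- function(x) {
  if (inherits(x, "pathway_scorer")) return(x)
  if (inherits(x, "planted_problem")) return(problem_scorer(x))
  stop("expected a 'pathway_scorer' or 'planted_problem'")
}

one_term <- function(p, scorer, term) {
  scorer <- as_scorer(scorer)
  idx <- pathway_indices(scorer, p)
  unname(scorer_breakdown(scorer, idx$lig, idx$pro)[term])
}

#' Individual restraint terms
#'
#' Each returns the single named Z-score term for a pathway (`NA` when the
#' term is absent): `score_docking` the negated mean docking Z over scored
#' enzyme-ligand pairs, `score_transformations` the mean triad
#' transformation Z, `score_sea` the mean consecutive-pair SEA Z,
#' `score_endpoint` the central-metabolism endpoint Z of the final ligand,
#' `score_hts` the screening-hit Z of the screened protein's substrate,
#' `score_homology` the reference-substrate homology Z, and
#' `score_gene_cluster` the genome-context Z.
#'
#' @param p A [pathway()] or character node vector.
#' @param scorer A [pathway_scorer()] or `planted_problem`.
#' @return Numeric scalar (possibly `NA`).
#' @name restraint_terms
NULL

#' @rdname restraint_terms
#' @export
score_docking <- function(p, scorer) one_term(p, scorer, "z_vs")

#' @rdname restraint_terms
#' @export
score_transformations <- function(p, scorer) one_term(p, scorer, "z_ct")

#' @rdname restraint_terms
#' @export
score_sea <- function(p, scorer) one_term(p, scorer, "z_sea")

#' @rdname restraint_terms
#' @export
score_endpoint <- function(p, scorer) one_term(p, scorer, "z_cm")

#' @rdname restraint_terms
#' @export
score_hts <- function(p, scorer) one_term(p, scorer, "z_hts")

#' @rdname restraint_terms
#' @export
score_homology <- function(p, scorer) one_term(p, scorer, "z_hs")

#' @rdname restraint_terms
#' @export
score_gene_cluster <- function(p, scorer) one_term(p, scorer, "z_gc")
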