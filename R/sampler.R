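## Metropolis Monte Carlo simulated annealing over pathway models.

#' Annealing temperature schedule
#'
#' `T(N) = 0.3 * 0.2^N + 0.1` where `N` is the MC step number normalized by
#' the total number of steps; strictly decreasing from `T(0) = 0.4` to
#' `T(1) = 0.16`.
#'
#' @param step_fraction Numeric in `[0, 1]`.
#' @return Temperature(s).
#' @export
anneal_temperature <- function(step_fraction) {
  if (any(step_fraction < 0 | step_fraction > 1)) {
    stop("step fraction must lie in [0, 1]")
  }
  0.3 * 0.2^step_fraction + 0.1
}

#' Metropolis acceptance
#'
#' An improving (or equal-scoring) proposal is always accepted without
#' consuming a random draw; otherwise acceptance has probability
#' `exp(-D/T)` with `D = old - new > 0` under score maximization, decided
#' by one uniform(0,1) draw compared against the acceptance probability.
#'
#' @param old_score,new_score Composite pathway scores.
#' @param temperature Positive temperature.
#' @return Logical.
#' @export
metropolis_accept <- function(old_score, new_score, temperature) {
  stopifnot(temperature > 0)
  if (new_score >= old_score) return(TRUE)
  stats::runif(1L) < exp(-(old_score - new_score) / temperature)
}

## ---- internal index-space machinery ------------------------------------

## constraint lookup tables in index space: element [[pos]] is an integer
## vector of allowed candidate indices, or NULL for unconstrained
constraint_tables <- function(cand, K) {
  allowed_lig <- vector("list", K + 1L)
  allowed_pro <- vector("list", K)
  for (nm in names(cand$constraints)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    idx <- as.integer(parts[2L])
    if (parts[1L] == "protein") {
      if (idx <= K) allowed_pro[[idx]] <- match(cand$constraints[[nm]], cand$proteins$id)
    } else {
      if (idx <= K + 1L) allowed_lig[[idx]] <- match(cand$constraints[[nm]], cand$metabolites)
    }
  }
  list(lig = allowed_lig, pro = allowed_pro)
}

ok_at <- function(tables, what, pos, id) {
  allowed <- tables[[what]][[pos]]
  is.null(allowed) || id %in% allowed
}

## uniform random valid pathway (constraint-aware, rejection on collisions)
random_pathway_idx <- function(P, L, K, tables, max_tries = 10000L) {
  cl <- which(!vapply(tables$lig, is.null, TRUE))
  cp <- which(!vapply(tables$pro, is.null, TRUE))
  draw_from <- function(v) v[sample.int(length(v), 1L)]
  for (t in seq_len(max_tries)) {
    lig <- integer(K + 1L); pro <- integer(K)
    for (i in cl) lig[i] <- draw_from(tables$lig[[i]])
    for (i in cp) pro[i] <- draw_from(tables$pro[[i]])
    if (anyDuplicated(lig[cl]) || anyDuplicated(pro[cp])) next
    free_l <- setdiff(seq_len(L), lig[cl])
    free_p <- setdiff(seq_len(P), pro[cp])
    open_l <- if (length(cl)) seq_len(K + 1L)[-cl] else seq_len(K + 1L)
    open_p <- if (length(cp)) seq_len(K)[-cp] else seq_len(K)
    lig[open_l] <- free_l[sample.int(length(free_l), length(open_l))]
    pro[open_p] <- free_p[sample.int(length(free_p), length(open_p))]
    ok <- all(vapply(seq_len(K + 1L), function(i) ok_at(tables, "lig", i, lig[i]), TRUE)) &&
      all(vapply(seq_len(K), function(i) ok_at(tables, "pro", i, pro[i]), TRUE))
    if (ok) return(list(lig = lig, pro = pro))
  }
  stop("could not draw a valid random pathway (over-constrained instance?)")
}

## one MC move in index space; returns NULL if the drawn move is illegal
try_move_idx <- function(lig, pro, P, L, tables) {
  K <- length(pro)
  can_replace_l <- L > K + 1L
  can_replace_p <- P > K
  can_swap_l <- K + 1L >= 2L
  can_swap_p <- K >= 2L
  kinds <- c(
    if (can_swap_l) "swap_l", if (can_swap_p) "swap_p",
    if (can_replace_l) "rep_l", if (can_replace_p) "rep_p"
  )
  swap_ok <- any(c(can_swap_l, can_swap_p))
  rep_ok <- any(c(can_replace_l, can_replace_p))
  # move class uniform between swap and replace when both are available
  cls <- if (swap_ok && rep_ok) {
    if (stats::runif(1L) < 0.5) "swap" else "replace"
  } else if (swap_ok) "swap" else if (rep_ok) "replace" else {
    stop("no legal move exists")
  }
  if (cls == "swap") {
    types <- c(if (can_swap_l) "l", if (can_swap_p) "p")
    ty <- types[sample.int(length(types), 1L)]
    if (ty == "l") {
      ij <- sample.int(K + 1L, 2L)
      a <- ij[1L]; b <- ij[2L]
      if (!ok_at(tables, "lig", a, lig[b]) || !ok_at(tables, "lig", b, lig[a])) return(NULL)
      lig[c(a, b)] <- lig[c(b, a)]
    } else {
      ij <- sample.int(K, 2L)
      a <- ij[1L]; b <- ij[2L]
      if (!ok_at(tables, "pro", a, pro[b]) || !ok_at(tables, "pro", b, pro[a])) return(NULL)
      pro[c(a, b)] <- pro[c(b, a)]
    }
  } else {
    types <- c(if (can_replace_l) "l", if (can_replace_p) "p")
    ty <- types[sample.int(length(types), 1L)]
    if (ty == "l") {
      pos <- sample.int(K + 1L, 1L)
      unused <- setdiff(seq_len(L), lig)
      id <- unused[sample.int(length(unused), 1L)]
      if (!ok_at(tables, "lig", pos, id)) return(NULL)
      lig[pos] <- id
    } else {
      pos <- sample.int(K, 1L)
      unused <- setdiff(seq_len(P), pro)
      id <- unused[sample.int(length(unused), 1L)]
      if (!ok_at(tables, "pro", pos, id)) return(NULL)
      pro[pos] <- id
    }
  }
  list(lig = lig, pro = pro)
}

propose_move_idx <- function(lig, pro, P, L, tables, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    mv <- try_move_idx(lig, pro, P, L, tables)
    if (!is.null(mv)) return(mv)
  }
  stop("no legal move found after ", max_tries, " attempts (over-constrained instance?)")
}

## ---- exported sampling operations --------------------------------------

#' Propose one Monte Carlo move
#'
#' Either swaps two components of the same type within the pathway, or
#' replaces a component with an unused candidate of the same type; the
#' result is always a valid pathway respecting positional constraints.
#' Uses (and advances) R's random number stream.
#'
#' @param p A [pathway()].
#' @param cand A [candidate_sets()].
#' @return A new `pathway` differing from `p` at one (replace) or two
#'   (swap) positions.
#' @export
propose_move <- function(p, cand) {
  p <- as.character(p)
  K <- (length(p) - 1L) %/% 2L
  tables <- constraint_tables(cand, K)
  lig <- match(p[seq(1L, length(p), by = 2L)], cand$metabolites)
  pro <- match(p[seq(2L, length(p) - 1L, by = 2L)], cand$proteins$id)
  mv <- propose_move_idx(lig, pro, nrow(cand$proteins), length(cand$metabolites), tables)
  nodes <- character(length(p))
  nodes[seq(1L, length(p), by = 2L)] <- cand$metabolites[mv$lig]
  nodes[seq(2L, length(p) - 1L, by = 2L)] <- cand$proteins$id[mv$pro]
  pathway(nodes)
}

#' Draw uniformly random valid pathways
#'
#' @param cand A [candidate_sets()].
#' @param n Number of pathways.
#' @param K Pathway length (default `cand$K[1]`).
#' @return List of `pathway` objects.
#' @export
random_pathways <- function(cand, n, K = cand$K[1L]) {
  tables <- constraint_tables(cand, K)
  P <- nrow(cand$proteins); L <- length(cand$metabolites)
  lapply(seq_len(n), function(i) {
    s <- random_pathway_idx(P, L, K, tables)
    nodes <- character(2L * K + 1L)
    nodes[seq(1L, 2L * K + 1L, by = 2L)] <- cand$metabolites[s$lig]
    nodes[seq(2L, 2L * K, by = 2L)] <- cand$proteins$id[s$pro]
    pathway(nodes)
  })
}

#' Score distribution of random pathway models
#'
#' Used to set the good-scoring cutoff: the cutoff is the best sampled
#' score minus `cutoff_sd` standard deviations of this distribution.
#'
#' @param cand A [candidate_sets()].
#' @param scorer A [pathway_scorer()] (or `planted_problem`).
#' @param n Number of random models (reference-scale default 10000).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @param K Pathway length.
#' @return List with `mean`, `sd` (population) and the score vector.
#' @export
random_score_distribution <- function(cand, scorer, n = 10000L, seed = 1L,
                                      K = cand$K[1L]) {
  stopifnot(n >= 2L)
  scorer <- as_scorer(scorer)
  total_fn <- make_total_fn(scorer)
  tables <- constraint_tables(cand, K)
  P <- nrow(cand$proteins); L <- length(cand$metabolites)
  scores <- with_preserved_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- random_pathway_idx(P, L, K, tables)
      total_fn(s$lig, s$pro)
    }, 0)
  })
  sd <- pop_sd(scores)
  if (sd < 1e-12) warning("random-model score spread is zero; cutoff degenerates to the best score")
  list(mean = mean(scores), sd = sd, scores = scores)
}

## fast composite-score closure over the compiled lookup tables
make_total_fn <- function(sc) {
  P <- length(sc$pids)
  L <- length(sc$mids)
  zdock <- sc$zdock
  ct <- sc$ct_enabled
  zct_arr <- NULL
  if (ct) {
    zct_arr <- array(NA_real_, c(L, L, P))
    for (p in seq_len(P)) zct_arr[, , p] <- sc$zct[[p]]
  }
  sea <- sc$sea_enabled
  zsea <- sc$zsea
  zcm <- sc$zcm
  hts_p <- if (!is.null(sc$zhts)) match(names(sc$zhts), sc$pids) else integer()
  hts_v <- unname(sc$zhts)
  hs_p <- if (!is.null(sc$zhs)) match(names(sc$zhs), sc$pids) else integer()
  hs_v <- unname(sc$zhs)
  gc <- sc$gc
  is_dummy <- sc$is_dummy
  pids <- sc$pids
  LL <- L * L

  function(lig, pro) {
    K <- length(pro)
    total <- 0
    i1 <- seq_len(K)
    zv <- zdock[(lig[i1] - 1L) * P + pro]
    zv <- c(zv, zdock[(lig[i1 + 1L] - 1L) * P + pro])
    zv <- zv[!is.na(zv)]
    if (length(zv)) total <- total - sum(zv) / length(zv)
    if (ct) {
      total <- total + sum(zct_arr[(pro - 1L) * LL + (lig[i1 + 1L] - 1L) * L + lig[i1]]) / K
    }
    if (sea && K >= 2L) {
      zs <- zsea[(pro[-1L] - 1L) * P + pro[-K]]
      zs <- zs[!is.na(zs)]
      if (length(zs)) total <- total + sum(zs) / length(zs)
    }
    if (!is.null(zcm)) total <- total + zcm[lig[K + 1L]]
    if (length(hts_p)) {
      v <- 0; nv <- 0L
      for (j in seq_along(hts_p)) {
        pos <- match(hts_p[j], pro)
        if (!is.na(pos)) { v <- v + hts_v[[j]][lig[pos]]; nv <- nv + 1L }
      }
      if (nv) total <- total + v / nv
    }
    if (length(hs_p)) {
      v <- 0; nv <- 0L
      for (j in seq_along(hs_p)) {
        pos <- match(hs_p[j], pro)
        if (!is.na(pos)) { v <- v + hs_v[[j]][lig[pos]]; nv <- nv + 1L }
      }
      if (nv) total <- total + v / nv
    }
    if (!is.null(gc)) {
      total <- total + quiet_z(gc$value(pids[pro[!is_dummy[pro]]]), gc$mean, gc$sd)
    }
    unname(total)
  }
}

#' One Monte Carlo simulated-annealing run
#'
#' Starts from a uniformly random valid pathway and executes `n_steps`
#' proposals with annealed Metropolis acceptance; every accepted state
#' (including the start) is recorded once, keyed by its canonical key.
#'
#' @param cand A [candidate_sets()].
#' @param scorer A [pathway_scorer()] or `planted_problem`.
#' @param n_steps Number of MC steps (reference-scale default 5e6).
#' @param seed Integer run seed; identical seeds give bitwise-identical
#'   visited sets. The caller's RNG stream is left untouched.
#' @param K Pathway length.
#' @return List of records, in first-visit order; each has `nodes`, `key`,
#'   `total`, `terms`.
#' @export
run_mc <- function(cand, scorer, n_steps = 5e6, seed = 1L, K = cand$K[1L]) {
  scorer <- as_scorer(scorer)
  total_fn <- make_total_fn(scorer)
  tables <- constraint_tables(cand, K)
  P <- nrow(cand$proteins); L <- length(cand$metabolites)
  with_preserved_seed(seed, {
    state <- random_pathway_idx(P, L, K, tables)
    cur_total <- total_fn(state$lig, state$pro)
    seen <- new.env(parent = emptyenv(), size = 1024L)
    order_keys <- character(256L)
    n_rec <- 0L
    record <- function(s, tot) {
      key <- paste(c(s$lig, s$pro), collapse = ",")
      if (is.null(seen[[key]])) {
        n_rec <<- n_rec + 1L
        if (n_rec > length(order_keys)) order_keys <<- c(order_keys, character(length(order_keys)))
        order_keys[n_rec] <<- key
        seen[[key]] <- list(lig = s$lig, pro = s$pro, total = tot)
      }
    }
    record(state, cur_total)
    if (n_steps >= 1L) {
      for (step in seq_len(n_steps)) {
        temp <- 0.3 * 0.2^(step / n_steps) + 0.1
        mv <- propose_move_idx(state$lig, state$pro, P, L, tables)
        new_total <- total_fn(mv$lig, mv$pro)
        accept <- if (new_total >= cur_total) TRUE else
          stats::runif(1L) < exp(-(cur_total - new_total) / temp)
        if (accept) {
          state <- mv
          cur_total <- new_total
          record(state, new_total)
        }
      }
    }
    lapply(order_keys[seq_len(n_rec)], function(k) {
      rec <- seen[[k]]
      nodes <- character(2L * K + 1L)
      nodes[seq(1L, 2L * K + 1L, by = 2L)] <- scorer$mids[rec$lig]
      nodes[seq(2L, 2L * K, by = 2L)] <- scorer$pids[rec$pro]
      structure(
        list(pathway = nodes, key = canonical_key(nodes),
             terms = scorer_breakdown(scorer, rec$lig, rec$pro),
             total = rec$total),
        class = "scored_pathway"
      )
    })
  })
}

#' Sampler configuration
#'
#' Reference-scale defaults: 5,000,000 steps per run, 1000 independent runs,
#' good-score cutoff 2 standard deviations (of the random-model score
#' distribution) below the best sampled score, 10,000 random models. All
#' are configurable downward for small instances.
#'
#' @param n_steps,n_runs MC steps per run and number of independent runs.
#' @param cutoff_sd Cutoff stringency in random-model standard deviations
#'   (2.0 default; 1.5 for long pathways keeps ensemble sizes comparable).
#' @param n_random_models Random models used to estimate the score spread.
#' @param seed Master seed; per-run seeds are `seed + run index`.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_steps = 5e6, n_runs = 1000L, cutoff_sd = 2.0,
                           n_random_models = 10000L, seed = 1L) {
  stopifnot(n_steps >= 0, n_runs >= 1, cutoff_sd > 0, n_random_models >= 2)
  structure(
    list(n_steps = n_steps, n_runs = as.integer(n_runs), cutoff_sd = cutoff_sd,
         n_random_models = as.integer(n_random_models), seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Run the full sampling stage
#'
#' Performs `n_runs` independent annealing runs (per-run seeds derived from
#' the master seed), merges the unique sampled models, estimates the
#' random-model score spread, and keeps the good-scoring set: unique models
#' with score at or above `best - cutoff_sd * sd_random`.
#'
#' @param cand A [candidate_sets()].
#' @param scorer A [pathway_scorer()], [restraint_set()] (compiled against
#'   `cand`), or `planted_problem`.
#' @param config A [sampler_config()].
#' @param K Pathway length.
#' @return Object of class `good_scoring_set`: list with `models` (sorted
#'   by decreasing score), `all_models`, `best`, `cutoff`, `random_mean`,
#'   `random_sd`, `per_run_keys`, `config`.
#' @export
run_ensemble <- function(cand, scorer, config = sampler_config(), K = cand$K[1L]) {
  if (inherits(scorer, "restraint_set")) scorer <- pathway_scorer(cand, scorer)
  scorer <- as_scorer(scorer)
  rnd <- random_score_distribution(cand, scorer, n = config$n_random_models,
                                   seed = config$seed, K = K)
  merged <- new.env(parent = emptyenv())
  order_keys <- character()
  per_run_keys <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    recs <- run_mc(cand, scorer, n_steps = config$n_steps,
                   seed = config$seed + r, K = K)
    keys <- vapply(recs, function(x) x$key, "")
    per_run_keys[[r]] <- keys
    fresh <- !vapply(keys, function(k) !is.null(merged[[k]]), TRUE)
    for (i in which(fresh)) merged[[keys[i]]] <- recs[[i]]
    order_keys <- c(order_keys, keys[fresh])
  }
  all_models <- lapply(order_keys, function(k) merged[[k]])
  totals <- vapply(all_models, function(x) x$total, 0)
  best <- max(totals)
  cutoff <- best - config$cutoff_sd * rnd$sd
  good <- all_models[totals >= cutoff]
  good_tot <- vapply(good, function(x) x$total, 0)
  good_key <- vapply(good, function(x) x$key, "")
  good <- good[order(-good_tot, good_key)]
  structure(
    list(models = good, all_models = all_models, best = best, cutoff = cutoff,
         random_mean = rnd$mean, random_sd = rnd$sd,
         per_run_keys = per_run_keys, config = config, K = K),
    class = "good_scoring_set"
  )
}

#' @export
print.good_scoring_set <- function(x, ...) {
  cat("<good_scoring_set: ", length(x$models), " good-scoring of ",
      length(x$all_models), " unique sampled models; best ",
      format(x$best, digits = 4), ", cutoff ", format(x$cutoff, digits = 4),
      " (", x$config$cutoff_sd, " SD of random models)>\n", sep = "")
  invisible(x)
}
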