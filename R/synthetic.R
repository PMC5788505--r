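## Planted-pathway synthetic problems: a chemically coherent reaction chain
## plus decoys, with every restraint input emitted in the package's own
## file formats, so the full stack is testable without docking runs.

#' Curated reaction chain used by the generator
#'
#' A five-step catabolic chain of real small molecules connected by exact
#' generic transformations (oxidations, a phosphorylation, a
#' dephosphorylation): glycerol, D-glyceraldehyde (written without stereo
#' assignments), glycerate, 3-phospho-glycerate, phosphohydroxypyruvate,
#' hydroxypyruvate. Each SMIRKS maps its substrate exactly onto the next
#' chain compound.
#'
#' @return List with data frames `compounds` (id, smiles), `reactions`
#'   (smirks, label), `decoys` (id, smiles), `central` (id, smiles) and
#'   `anchor` (id, smiles), plus `decoy_smirks`.
#' @export
synthetic_chemistry <- function() {
  compounds <- data.frame(
    id = c("glycerol", "glyceraldehyde", "glycerate", "glycerate-3P",
           "hydroxypyruvate-3P", "hydroxypyruvate"),
    smiles = c("OCC(O)CO", "O=CC(O)CO", "O=C(O)C(O)CO", "O=C(O)C(O)COP(=O)(O)O",
               "O=C(O)C(=O)COP(=O)(O)O", "O=C(O)C(=O)CO"),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    smirks = c(
      "[CH2:1][OH:2]>>[CH:1]=[O:2]",
      "[CH:1]=[O:2]>>[C:1](=[O:2])O",
      "[CH2:1][OH:2]>>[CH2:1][O:2]P(=O)(O)O",
      "[CH1:1][OH:2]>>[C:1]=[O:2]",
      "[C:1][O:2]P(=O)(O)O>>[C:1][O:2]"
    ),
    label = c("primary-alcohol dehydrogenase", "aldehyde dehydrogenase",
              "carbohydrate kinase", "secondary-alcohol dehydrogenase",
              "phosphatase"),
    stringsAsFactors = FALSE
  )
  decoys <- data.frame(
    id = c("ethanol", "butanol", "phenol", "alanine", "glycine", "acetone",
           "propionate", "ethanolamine", "cyclohexanol", "ethyl-acetate",
           "toluene", "urea", "ethanethiol", "ethylene-glycol", "lactate",
           "glycolaldehyde", "glycolate"),
    smiles = c("CCO", "CCCCO", "Oc1ccccc1", "CC(N)C(=O)O", "NCC(=O)O",
               "CC(C)=O", "CCC(=O)O", "NCCO", "OC1CCCCC1", "CCOC(C)=O",
               "Cc1ccccc1", "NC(N)=O", "CCS", "OCCO", "CC(O)C(=O)O",
               "OCC=O", "OCC(=O)O"),
    stringsAsFactors = FALSE
  )
  central <- data.frame(
    id = c("pyruvate", "acetate", "oxaloacetate", "succinate"),
    smiles = c("CC(=O)C(=O)O", "CC(=O)O", "O=C(O)CC(=O)C(=O)O", "O=C(O)CCC(=O)O"),
    stringsAsFactors = FALSE
  )
  anchor <- data.frame(
    id = "propanediol", smiles = "CC(O)CO", stringsAsFactors = FALSE
  )
  decoy_smirks <- c(
    "[C:1](=[O:2])O>>[C:1](=[O:2])OC",  # esterification
    "[CH2:1][OH:2]>>[CH2:1][O:2]C",     # O-methylation
    "[CH:1]=[O:2]>>[CH2:1][OH:2]"       # aldehyde reduction
  )
  list(compounds = compounds, reactions = reactions, decoys = decoys,
       central = central, anchor = anchor, decoy_smirks = decoy_smirks)
}

#' Synthetic problem configuration
#'
#' Defaults are the generator's reference study conditions: a length-4
#' planted pathway among 3 decoy proteins and 8 decoy metabolites, true
#' enzyme-ligand docking pairs favored by 1.5 population standard
#' deviations over unit Gaussian noise, adjacent true protein pairs with
#' ligand-set E-values of 1e-20 against a near-1 background, and exact
#' transformations. Setting a signal to zero makes the corresponding true
#' values exactly exchangeable with background.
#'
#' @param K Pathway length (number of protein positions), 2..5 (2..6 with
#'   an anchor transporter).
#' @param n_decoy_proteins,n_decoy_metabolites Pool padding (ignored when
#'   `include_decoys = FALSE`).
#' @param docking_signal Mean docking Z-advantage of true pairs.
#' @param docking_noise Docking score noise SD.
#' @param sea_signal E-value exponent gap of adjacent-true pairs.
#' @param transform_fidelity Per-step probability that a true triad's
#'   transform maps its substrate exactly onto its product; an infidelity
#'   step plants a random decoy product and a random transform.
#' @param include_anchor Fix a transporter solute-binding protein at the
#'   pathway start, constrain its ligand to the screening hits.
#' @param include_dummy Add a dummy (unknown-enzyme) protein candidate.
#' @param include_decoys Pad the pools with decoy proteins and metabolites.
#' @param restraints Which restraint components to emit, see
#'   [restraint_names()]; `gene_cluster` is off by default.
#' @param seed Integer seed; fixed seed gives a byte-identical problem.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(K = 4L,
                             n_decoy_proteins = 3L,
                             n_decoy_metabolites = 8L,
                             docking_signal = 1.5,
                             docking_noise = 1.0,
                             sea_signal = 20,
                             transform_fidelity = 1.0,
                             include_anchor = FALSE,
                             include_dummy = FALSE,
                             include_decoys = TRUE,
                             restraints = setdiff(restraint_names(), "gene_cluster"),
                             seed = 1L) {
  K <- as.integer(K)
  stopifnot(K >= 2L, docking_noise >= 0, transform_fidelity >= 0,
            transform_fidelity <= 1, all(restraints %in% restraint_names()))
  n_steps <- if (include_anchor) K - 1L else K
  if (n_steps > 5L)
    stop("curated chemistry supports at most 5 enzymatic steps (K = ",
         if (include_anchor) "6 with" else "5 without", " an anchor)")
  if (!include_decoys) {
    n_decoy_proteins <- 0L
    n_decoy_metabolites <- 0L
  }
  structure(
    list(K = K, n_decoy_proteins = as.integer(n_decoy_proteins),
         n_decoy_metabolites = as.integer(n_decoy_metabolites),
         docking_signal = docking_signal, docking_noise = docking_noise,
         sea_signal = sea_signal, transform_fidelity = transform_fidelity,
         include_anchor = include_anchor, include_dummy = include_dummy,
         include_decoys = include_decoys, restraints = restraints,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a planted-pathway problem
#'
#' Emits a complete problem — candidate pools, every restraint input, and
#' the planted true pathway — deterministically from the seed. With the
#' default signal settings the planted pathway is constructed to be the
#' global score optimum; on instances small enough to enumerate this is
#' verified exhaustively at generation time (`$verified`).
#'
#' @param config A [synthetic_config()].
#' @param verify_ceiling Verify the planted optimum by exhaustive
#'   enumeration when the unconstrained pathway count is at most this
#'   (set 0 to skip).
#' @return Object of class `planted_problem`: list with `candidates`
#'   ([candidate_sets()]), `restraints` ([restraint_set()]), `planted`
#'   ([pathway()]), `config`, `verified`.
#' @export
generate_problem <- function(config = synthetic_config(), verify_ceiling = 2e4) {
  stopifnot(inherits(config, "synthetic_config"))
  chem <- synthetic_chemistry()
  K <- config$K
  n_steps <- if (config$include_anchor) K - 1L else K

  with_preserved_seed(config$seed, {
    ## ---- planted chain (ligands + per-step transforms) -----------------
    motif_pool <- c(chem$reactions$smirks, chem$decoy_smirks)
    decoy_pool <- chem$decoys
    lig_ids <- character(n_steps + 1L)
    lig_ids[1L] <- chem$compounds$id[1L]
    trans <- character(n_steps)
    labels <- character(n_steps)
    used_decoys <- character()
    for (i in seq_len(n_steps)) {
      if (stats::runif(1L) < config$transform_fidelity) {
        lig_ids[i + 1L] <- chem$compounds$id[i + 1L]
        trans[i] <- chem$reactions$smirks[i]
        labels[i] <- chem$reactions$label[i]
      } else {
        pick <- setdiff(decoy_pool$id, c(lig_ids, used_decoys))
        lig_ids[i + 1L] <- pick[sample.int(length(pick), 1L)]
        used_decoys <- c(used_decoys, lig_ids[i + 1L])
        trans[i] <- motif_pool[sample.int(length(motif_pool), 1L)]
        labels[i] <- "uncharacterized"
      }
    }
    if (config$include_anchor) lig_ids <- c(chem$anchor$id, lig_ids)

    ## ---- proteins -------------------------------------------------------
    enz_ids <- paste0("enz", seq_len(n_steps))
    pro_ids <- enz_ids
    pro_kind <- rep("enzyme", n_steps)
    pro_family <- labels
    transforms <- stats::setNames(as.list(trans), enz_ids)
    if (config$include_anchor) {
      pro_ids <- c("sbp", pro_ids)
      pro_kind <- c("transporter_sbp", pro_kind)
      pro_family <- c("TRAP solute-binding protein", pro_family)
    }
    planted_pro <- pro_ids
    if (config$n_decoy_proteins > 0L) {
      dec_ids <- paste0("dec", seq_len(config$n_decoy_proteins))
      pro_ids <- c(pro_ids, dec_ids)
      pro_kind <- c(pro_kind, rep("enzyme", length(dec_ids)))
      pro_family <- c(pro_family, rep("decoy family", length(dec_ids)))
      for (d in dec_ids) {
        transforms[[d]] <- motif_pool[sample.int(length(motif_pool), 1L)]
      }
    }
    if (config$include_dummy) {
      pro_ids <- c(pro_ids, "dummy")
      pro_kind <- c(pro_kind, "dummy")
      pro_family <- c(pro_family, "unknown protein")
    }

    ## ---- metabolite pools ----------------------------------------------
    free_decoys <- setdiff(decoy_pool$id, lig_ids)
    n_dec <- min(config$n_decoy_metabolites, length(free_decoys))
    dec_met <- if (n_dec > 0L) {
      free_decoys[sample.int(length(free_decoys), n_dec)]
    } else character()
    cand_met <- c(lig_ids, dec_met)
    all_cpds <- rbind(chem$compounds, chem$decoys, chem$central, chem$anchor)
    central_ids <- if ("endpoint" %in% config$restraints) {
      unique(c(lig_ids[length(lig_ids)], chem$central$id))
    } else NULL
    lib_ids <- unique(c(cand_met, central_ids))
    lib <- metabolite_library(
      id = lib_ids,
      smiles = all_cpds$smiles[match(lib_ids, all_cpds$id)]
    )

    ## ---- candidate sets + anchor constraints ----------------------------
    constraints <- list()
    hts_hits <- NULL
    if ("hts" %in% config$restraints || config$include_anchor) {
      other <- c(dec_met, setdiff(cand_met, lig_ids[1L]))[1L]
      hts_hits <- c(lig_ids[1L], other)
    }
    if (config$include_anchor) {
      constraints <- list("protein:1" = "sbp", "ligand:1" = hts_hits)
    }
    cand <- candidate_sets(
      proteins = protein_table(pro_ids, pro_kind, pro_family),
      metabolites = lib[match(cand_met, lib$id), , drop = FALSE],
      K = K,
      constraints = constraints
    )

    ## ---- restraint data --------------------------------------------------
    L <- length(cand_met)
    docking <- NULL
    if ("docking" %in% config$restraints) {
      docking <- list()
      for (p in seq_along(pro_ids)) {
        if (pro_kind[p] == "dummy") next
        raw <- stats::rnorm(L, sd = max(config$docking_noise, 1e-6))
        names(raw) <- cand_met
        pos <- match(pro_ids[p], planted_pro)
        if (!is.na(pos)) {
          adj <- c(lig_ids[pos], lig_ids[pos + 1L])
          raw[adj] <- raw[adj] - config$docking_signal * config$docking_noise
        }
        docking[[pro_ids[p]]] <- raw
      }
    }
    sea <- NULL
    if ("sea" %in% config$restraints) {
      real <- pro_ids[pro_kind != "dummy"]
      pairs <- t(utils::combn(real, 2L))
      ev <- stats::runif(nrow(pairs), 0.3, 1)
      for (r in seq_len(nrow(pairs))) {
        ia <- match(pairs[r, 1L], planted_pro)
        ib <- match(pairs[r, 2L], planted_pro)
        if (!is.na(ia) && !is.na(ib) && abs(ia - ib) == 1L) {
          ev[r] <- ev[r] * 10^(-config$sea_signal)
        }
      }
      sea <- data.frame(
        a = c(pairs[, 1L], real), b = c(pairs[, 2L], real),
        evalue = c(ev, rep(1e-50, length(real))),
        stringsAsFactors = FALSE
      )
    }
    hts <- NULL
    if ("hts" %in% config$restraints) {
      hts <- stats::setNames(list(hts_hits), planted_pro[1L])
    }
    homology <- NULL
    if ("homology" %in% config$restraints && length(planted_pro) >= 2L) {
      ref_sub <- lig_ids[2L] # substrate of the second planted protein
      homology <- stats::setNames(
        list(lib$smiles[match(ref_sub, lib$id)]), planted_pro[2L]
      )
    }
    gene_cluster <- if ("gene_cluster" %in% config$restraints) planted_pro else NULL

    rest <- restraint_set(
      library = lib,
      docking = docking,
      sea = sea,
      transforms = if ("transforms" %in% config$restraints) transforms else NULL,
      central = central_ids,
      hts = hts,
      homology = homology,
      gene_cluster = gene_cluster
    )

    planted_nodes <- character(2L * K + 1L)
    planted_nodes[seq(1L, 2L * K + 1L, by = 2L)] <- lig_ids
    planted_nodes[seq(2L, 2L * K, by = 2L)] <- planted_pro
    problem <- structure(
      list(candidates = cand, restraints = rest, planted = pathway(planted_nodes),
           config = config, verified = NA),
      class = "planted_problem"
    )
    attr(problem, "scorer_env") <- new.env(parent = emptyenv())

    ## ---- optional exhaustive verification of the planted optimum ---------
    if (verify_ceiling > 0 &&
        n_pathways(length(pro_ids), L, K) <= verify_ceiling) {
      sc <- problem_scorer(problem)
      total_fn <- make_total_fn(sc)
      planted_total <- score_pathway(problem$planted, sc)$total
      all_p <- enumerate_pathways(cand, K)
      best <- -Inf; best_key <- ""
      for (p in all_p) {
        idx <- pathway_indices(sc, p)
        tot <- total_fn(idx$lig, idx$pro)
        if (tot > best) { best <- tot; best_key <- canonical_key(p) }
      }
      problem$verified <- identical(best_key, canonical_key(problem$planted)) &&
        abs(best - planted_total) < 1e-9
      if (!problem$verified) {
        warning("planted pathway is not the exhaustive optimum for seed ",
                config$seed)
      }
    }
    problem
  })
}

#' @export
print.planted_problem <- function(x, ...) {
  cat("<planted_problem (seed ", x$config$seed, ")>\n", sep = "")
  print(x$candidates)
  print(x$restraints)
  cat("planted: ", paste(unclass(x$planted), collapse = " -> "), "\n", sep = "")
  if (!is.na(x$verified)) {
    cat("planted optimum verified by enumeration: ", x$verified, "\n", sep = "")
  }
  invisible(x)
}
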