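## Plain-text input/output: SMILES files, TSV restraint tables, YAML
## manifests. A written problem directory doubles as format documentation.

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

#' Read a SMILES file
#'
#' One record per line: `SMILES<whitespace>id`. Blank lines and `#`
#' comments are ignored; malformed lines are an error naming the line.
#'
#' @param path File path.
#' @return A [metabolite_library()].
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- keep[vapply(parts, length, 0L) < 2L]
  if (length(bad)) stop("malformed SMILES line ", paste(bad, collapse = ", "),
                        " in ", path)
  metabolite_library(
    id = vapply(parts, `[[`, "", 2L),
    smiles = vapply(parts, `[[`, "", 1L)
  )
}

#' Write a SMILES file
#'
#' @param library A [metabolite_library()].
#' @param path File path.
#' @export
write_smiles <- function(library, path) {
  writeLines(paste(library$smiles, library$id), path)
}

#' Write a planted problem to a directory
#'
#' Emits every input in the package's exchange formats: `library.smi`,
#' `candidates.txt`, `proteins.tsv`, `transforms.tsv`, `docking/<id>.tsv`,
#' `sea.tsv`, `central.txt`, `hits_<id>.txt`, `homology.tsv`,
#' `gene_cluster.tsv`, a `manifest.yaml` tying them together, and the
#' ground truth in `truth.txt` (not referenced by the manifest).
#'
#' @param problem A `planted_problem`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "planted_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cand <- problem$candidates
  rest <- problem$restraints
  write_smiles(rest$library, file.path(dir, "library.smi"))
  writeLines(cand$metabolites, file.path(dir, "candidates.txt"))
  write_tsv(as.data.frame(cand$proteins), file.path(dir, "proteins.tsv"))
  manifest <- list(
    format = "pathmap-problem/1",
    library = "library.smi",
    candidates = "candidates.txt",
    proteins = "proteins.tsv",
    K = as.integer(cand$K),
    constraints = lapply(cand$constraints, as.list)
  )
  if (!is.null(rest$transforms)) {
    rows <- do.call(rbind, lapply(names(rest$transforms), function(pid) {
      data.frame(protein = pid, smirks = rest$transforms[[pid]],
                 label = "", stringsAsFactors = FALSE)
    }))
    write_tsv(rows, file.path(dir, "transforms.tsv"))
    manifest$transforms <- "transforms.tsv"
  }
  if (!is.null(rest$docking)) {
    dir.create(file.path(dir, "docking"), showWarnings = FALSE)
    for (pid in names(rest$docking)) {
      tab <- rest$docking[[pid]]
      df <- data.frame(metabolite = names(tab$scores),
                       score = fmt_num(unname(tab$scores)),
                       stringsAsFactors = FALSE)
      write_tsv(df, file.path(dir, "docking", paste0(pid, ".tsv")))
    }
    manifest$docking <- "docking"
  }
  if (!is.null(rest$sea)) {
    df <- rest$sea
    df$evalue <- fmt_num(df$evalue)
    write_tsv(df, file.path(dir, "sea.tsv"))
    manifest$sea <- "sea.tsv"
  }
  if (!is.null(rest$central)) {
    writeLines(rest$central, file.path(dir, "central.txt"))
    manifest$central <- "central.txt"
  }
  if (!is.null(rest$hts)) {
    manifest$hts <- list()
    for (pid in names(rest$hts)) {
      fn <- paste0("hits_", pid, ".txt")
      writeLines(rest$hts[[pid]], file.path(dir, fn))
      manifest$hts[[pid]] <- fn
    }
  }
  if (!is.null(rest$homology)) {
    df <- data.frame(protein = names(rest$homology),
                     reference_smiles = unlist(rest$homology),
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, "homology.tsv"))
    manifest$homology <- "homology.tsv"
  }
  if (!is.null(rest$gene_cluster)) {
    write_tsv(data.frame(a = rest$gene_cluster[, 1L], b = rest$gene_cluster[, 2L],
                         stringsAsFactors = FALSE),
              file.path(dir, "gene_cluster.tsv"))
    manifest$gene_cluster <- "gene_cluster.tsv"
  }
  manifest$seed <- problem$config$seed
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (!is.null(problem$planted)) {
    writeLines(as.character(problem$planted), file.path(dir, "truth.txt"))
  }
  invisible(dir)
}

#' Read a problem directory
#'
#' Reconstructs candidate sets and restraints from a `manifest.yaml` (as
#' written by [write_problem()] or assembled by hand). The planted truth is
#' attached when a `truth.txt` sits next to the manifest.
#'
#' @param path Problem directory or manifest file path.
#' @return A `planted_problem` (with `planted = NULL` when no truth file).
#' @export
read_problem <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.yaml") else path
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  man <- yaml::read_yaml(manifest_path)
  rel <- function(p) file.path(dir, p)
  lib <- read_smiles(rel(man$library))
  cand_met <- readLines(rel(man$candidates), warn = FALSE)
  prot <- read_tsv(rel(man$proteins))
  constraints <- lapply(man$constraints, function(x) unlist(x))
  cand <- candidate_sets(
    proteins = protein_table(prot$id, prot$kind, prot$family),
    metabolites = lib[match(cand_met, lib$id), , drop = FALSE],
    K = man$K,
    constraints = constraints
  )
  transforms <- NULL
  if (!is.null(man$transforms)) {
    tr <- read_tsv(rel(man$transforms))
    transforms <- lapply(split(tr$smirks, tr$protein), as.character)
  }
  docking <- NULL
  if (!is.null(man$docking)) {
    files <- sort(list.files(rel(man$docking), pattern = "\\.tsv$", full.names = TRUE))
    docking <- lapply(files, function(f) {
      df <- read_tsv(f)
      stats::setNames(as.numeric(df$score), df$metabolite)
    })
    names(docking) <- sub("\\.tsv$", "", basename(files))
  }
  sea <- if (!is.null(man$sea)) {
    df <- read_tsv(rel(man$sea))
    df$evalue <- as.numeric(df$evalue)
    df
  }
  central <- if (!is.null(man$central)) readLines(rel(man$central), warn = FALSE)
  hts <- if (!is.null(man$hts)) {
    lapply(man$hts, function(fn) readLines(rel(fn), warn = FALSE))
  }
  homology <- if (!is.null(man$homology)) {
    df <- read_tsv(rel(man$homology))
    stats::setNames(as.list(df$reference_smiles), df$protein)
  }
  gene_cluster <- if (!is.null(man$gene_cluster)) {
    as.matrix(read_tsv(rel(man$gene_cluster)))
  }
  rest <- restraint_set(
    library = lib, docking = docking, sea = sea, transforms = transforms,
    central = central, hts = hts, homology = homology,
    gene_cluster = gene_cluster
  )
  planted <- NULL
  truth <- file.path(dir, "truth.txt")
  if (file.exists(truth)) planted <- pathway(readLines(truth, warn = FALSE))
  cfg <- list(K = man$K, seed = man$seed %||% 1L)
  problem <- structure(
    list(candidates = cand, restraints = rest, planted = planted,
         config = cfg, verified = NA),
    class = "planted_problem"
  )
  attr(problem, "scorer_env") <- new.env(parent = emptyenv())
  problem
}

#' Write ensemble outputs
#'
#' Writes the good-scoring set (JSON lines: one model per line with key,
#' nodes, total, per-term breakdown), cluster assignments and edge
#' frequencies as TSV, the convergence curve, and the union-network JSON.
#'
#' @param fit A `pathway_map` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(fit, dir) {
  stopifnot(inherits(fit, "pathway_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "models.jsonl"), "w")
  for (m in fit$models) {
    terms <- m$terms[!is.na(m$terms)]
    writeLines(jsonlite::toJSON(
      list(key = m$key, nodes = as.list(m$pathway), total = m$total,
           scores = as.list(terms)),
      auto_unbox = TRUE, digits = NA
    ), con)
  }
  close(con)
  cl <- fit$clusters
  write_tsv(
    data.frame(key = names(cl$assignments), cluster = unname(cl$assignments),
               stringsAsFactors = FALSE),
    file.path(dir, "clusters.tsv")
  )
  write_tsv(as.data.frame(fit$edge_frequencies), file.path(dir, "edges.tsv"))
  write_tsv(fit$convergence, file.path(dir, "convergence.tsv"))
  export_netimp(fit, path = file.path(dir, "netimp.json"))
  invisible(dir)
}
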