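## small shared helpers

## run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## scorer memoized on the problem object's environment
problem_scorer <- function(problem) {
  stopifnot(inherits(problem, "planted_problem"))
  env <- attr(problem, "scorer_env")
  if (is.null(env)) {
    # problems built by generate_problem() carry a cache environment; a
    # problem reconstructed by hand just compiles on the spot
    return(pathway_scorer(problem$candidates, problem$restraints))
  }
  key <- paste(class(problem$restraints), length(problem$candidates$metabolites),
               paste(restraints_present(problem$restraints), collapse = ","))
  if (is.null(env$scorer) || !identical(env$key, key)) {
    env$scorer <- pathway_scorer(problem$candidates, problem$restraints)
    env$key <- key
  }
  env$scorer
}

restraints_present <- function(rest) {
  nm <- restraint_names()
  fields <- ifelse(nm == "endpoint", "central", nm)
  nm[!vapply(fields, function(f) is.null(rest[[f]]), TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
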