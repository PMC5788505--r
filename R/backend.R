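## Bridge to the bundled RDKit helper. One subprocess call per request; all
## callers batch their work so a whole problem needs only a handful of calls.

.pathmapr <- new.env(parent = emptyenv())

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "pathmapr")
  if (!nzchar(path) || !file.exists(path)) {
    # during in-source test runs (pkgload) inst/ may be uninstalled
    path <- file.path("inst", "python", "chem_backend.py")
  }
  if (!file.exists(path)) stop("chem_backend.py not found")
  path
}

python_binary <- function() {
  bin <- getOption("pathmapr.python", "")
  if (!nzchar(bin)) bin <- Sys.getenv("PATHMAPR_PYTHON", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no python interpreter found; set options(pathmapr.python=)")
  bin
}

#' @noRd
chem_backend <- function(req) {
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  out <- suppressWarnings(system2(
    python_binary(), shQuote(backend_script()),
    input = payload, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (exit ", status, ")")
  }
  resp <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) stop("chemistry backend error: ", resp$error)
  resp
}

## Memoise backend calls within a session: synthetic problems share one
## metabolite pool and SMIRKS alphabet, so repeated generation is free.
chem_backend_cached <- function(req) {
  key <- paste(
    req$op,
    paste(deparse(req, control = "all"), collapse = ""),
    collapse = "|"
  )
  key <- paste0("k", format(sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) %% 2^26)),
                "_", nchar(key))
  hit <- .pathmapr$cache[[key]]
  if (!is.null(hit) && identical(hit$req, req)) return(hit$resp)
  resp <- chem_backend(req)
  if (is.null(.pathmapr$cache)) .pathmapr$cache <- list()
  .pathmapr$cache[[key]] <- list(req = req, resp = resp)
  resp
}
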