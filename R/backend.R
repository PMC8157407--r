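# Bridge to the bundled Python chemistry/learner backend.
#
# Every call writes a JSON job file, runs `python backend.py <cmd> in out`
# and reads the JSON result.  Calls are batched by design: callers pass
# vectors of SMILES / lists of jobs, never loop over single molecules.
# Atom indices crossing this boundary are 0-based; all exported R
# functions use 1-based indices.

backend_script <- function() {
  path <- system.file("python", "backend.py", package = "interpbench")
  if (!nzchar(path) || !file.exists(path)) {
    stop("backend.py not found; is interpbench installed correctly?")
  }
  path
}

backend_python <- function() {
  Sys.getenv("INTERPBENCH_PYTHON", "python")
}

#' Call the Python backend
#'
#' Low-level bridge used by all chemistry and model-fitting functions.
#' Not intended for direct use.
#'
#' @param command backend command name.
#' @param payload list serialized to JSON for the backend.
#' @return parsed JSON result as a list.
#' @keywords internal
py_backend <- function(command, payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(system2(
    backend_python(), c(backend_script(), command, fin, fout),
    stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) {
    stop("python backend failed (command '", command, "', status ", status,
         "); check that python with rdkit/scikit-learn is available")
  }
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  if (!is.null(res$error)) {
    stop("python backend error in '", command, "': ", res$error)
  }
  if (status != 0) {
    stop("python backend exited with status ", status,
         " for command '", command, "'")
  }
  res
}
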