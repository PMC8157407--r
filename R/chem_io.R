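# Molecule records, dataset tables, file I/O and the fixture pool generator.

#' Molecule record
#'
#' A standardized molecule with a frozen, reproducible heavy-atom indexing.
#' Atoms are indexed 1..A in the order they appear in the stored canonical
#' SMILES; this order is identical across conformers and across re-parsing
#' with the same RDKit version, and every per-atom quantity in the package
#' (ground truth, contributions, masks) refers to it.  Hydrogens are
#' implicit: all per-atom quantities are defined over heavy atoms only.
#'
#' @param mol_id identifier string.
#' @param parsed one parsed-molecule entry from the backend.
#' @return object of class `mol_record` with fields `mol_id`, `smiles`,
#'   `atoms` (data.frame: symbol, z, aromatic, in_ring, n_h), `bonds`
#'   (data.frame: a, b, order, ring; 1-based endpoint indices), `n_heavy`,
#'   `mw` and `conformers` (list of A x 3 coordinate matrices in Angstrom,
#'   or NULL).
#' @keywords internal
new_mol_record <- function(mol_id, parsed) {
  atoms <- do.call(rbind, lapply(parsed$atoms, function(a) {
    data.frame(symbol = a$symbol, z = a$z, aromatic = a$aromatic,
               in_ring = a$in_ring, n_h = a$n_h,
               stringsAsFactors = FALSE)
  }))
  if (length(parsed$bonds) > 0) {
    bonds <- do.call(rbind, lapply(parsed$bonds, function(b) {
      data.frame(a = b$a + 1L, b = b$b + 1L, order = b$order, ring = b$ring)
    }))
  } else {
    bonds <- data.frame(a = integer(), b = integer(),
                        order = numeric(), ring = logical())
  }
  conformers <- NULL
  if (!is.null(parsed$conformers)) {
    conformers <- lapply(parsed$conformers, function(cf) {
      m <- do.call(rbind, lapply(cf, unlist))
      colnames(m) <- c("x", "y", "z")
      m
    })
  }
  structure(list(mol_id = mol_id, smiles = parsed$smiles, atoms = atoms,
                 bonds = bonds, n_heavy = parsed$n_heavy, mw = parsed$mw,
                 conformers = conformers),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat("<mol_record>", x$mol_id, x$smiles, "\n ", x$n_heavy, "heavy atoms,",
      sprintf("MW %.1f", x$mw),
      if (!is.null(x$conformers)) sprintf(", %d conformer(s)",
                                          length(x$conformers)) else "",
      "\n")
  invisible(x)
}

#' Parse SMILES into molecule records
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers (default `mol1`, `mol2`, ...).
#' @param quiet suppress the skip warning.
#' @return list of [new_mol_record()] objects; unparsable entries are
#'   skipped with a warning recording their count (attribute `n_skipped`).
#' @export
parse_smiles <- function(smiles, ids = NULL, quiet = FALSE) {
  stopifnot(length(smiles) >= 1)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  res <- py_backend("parse", list(smiles = as.list(as.character(smiles))))
  ok <- vapply(res$mols, function(m) isTRUE(m$ok), logical(1))
  if (!quiet && any(!ok)) {
    warning(sum(!ok), " unparsable SMILES skipped (",
            paste(utils::head(smiles[!ok], 5), collapse = ", "), ")")
  }
  records <- Map(new_mol_record, ids[ok], res$mols[ok])
  attr(records, "n_skipped") <- sum(!ok)
  records
}

#' Read molecules from a file
#'
#' Supports whitespace-separated `.smi` (SMILES plus optional id), CSV with
#' a named SMILES column, and SDF V2000 (first conformer retained).
#' Unparsable entries are skipped with a warning; zero parsable molecules
#' is an error naming the file.
#'
#' @param path file path.
#' @param format one of `"smi"`, `"csv"`, `"sdf"`; default guessed from the
#'   extension.
#' @param smiles_col,id_col CSV column names.
#' @return list of `mol_record` objects (attribute `n_skipped`).
#' @export
read_molecules <- function(path, format = c("auto", "smi", "csv", "sdf"),
                           smiles_col = "smiles", id_col = "mol_id") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smi", csv = "csv", sdf = "sdf",
                     stop("cannot guess format of ", path))
  }
  if (format == "sdf") {
    res <- py_backend("parse_sdf", list(path = normalizePath(path)))
    ok <- vapply(res$mols, function(m) isTRUE(m$ok), logical(1))
    if (!any(ok)) stop("no parsable molecules in ", path)
    if (any(!ok)) warning(sum(!ok), " unparsable SDF records skipped")
    ids <- vapply(seq_along(res$mols), function(i) {
      nm <- res$mols[[i]]$name
      if (is.null(nm) || !nzchar(nm)) paste0("sdf", i) else nm
    }, character(1))
    records <- Map(new_mol_record, ids[ok], res$mols[ok])
    attr(records, "n_skipped") <- sum(!ok)
    return(records)
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty file: ", path)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("smi", i)
    }, character(1))
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_col %in% names(tab)) {
      stop("CSV ", path, " has no column '", smiles_col, "'")
    }
    if (nrow(tab) == 0) stop("empty file: ", path)
    smiles <- tab[[smiles_col]]
    ids <- if (id_col %in% names(tab)) as.character(tab[[id_col]]) else
      paste0("csv", seq_len(nrow(tab)))
  }
  records <- parse_smiles(smiles, ids)
  if (length(records) == 0) stop("no parsable molecules in ", path)
  records
}

#' Standardize a molecule pool
#'
#' Reduces each molecule to its largest fragment, neutralizes charges,
#' removes duplicates (by canonical SMILES of the standardized structure)
#' and drops molecules with molecular weight above `mw_max`.  Idempotent;
#' output order follows input order of the first occurrence.
#'
#' @param records list of `mol_record`.
#' @param mw_max molecular weight cutoff in g/mol (default 500).
#' @return filtered list of `mol_record`.
#' @export
standardize_pool <- function(records, mw_max = 500) {
  stopifnot(length(records) >= 1)
  res <- py_backend("standardize", list(
    smiles = unname(lapply(records, `[[`, "smiles"))))
  ok <- vapply(res$mols, function(m) isTRUE(m$ok), logical(1))
  smiles <- vapply(res$mols, function(m)
    if (isTRUE(m$ok)) m$smiles else NA_character_, character(1))
  mw <- vapply(res$mols, function(m)
    if (isTRUE(m$ok)) m$mw else NA_real_, numeric(1))
  keep <- ok & mw <= mw_max & !duplicated(smiles)
  if (!any(keep)) stop("all molecules removed by standardization/filters")
  # re-parse kept structures so records carry the standardized graph
  out <- parse_smiles(smiles[keep],
                      ids = vapply(records[keep], `[[`, character(1),
                                   "mol_id"),
                      quiet = TRUE)
  attr(out, "n_skipped") <- NULL
  out
}

# ---------------------------------------------------------------------------
# Fixture pool generator: a ChEMBL-like stand-in assembled from a fixed
# grammar of chain-concatenable drug-like building blocks.  Each block is a
# SMILES snippet that stays valid when blocks are concatenated into a chain
# (rings close internally; first/last atoms keep a free valence).

fixture_blocks <- function() {
  data.frame(
    smiles = c("C", "CC", "CCC", "CCCC",
               "c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "C1CCOC1",
               "C(C)", "C(F)", "C(Cl)", "C(Br)",
               "O", "N", "S", "C(O)", "C(N)",
               "C(=O)", "C(=O)O", "C(=O)N", "NC(=O)", "C(=O)NC"),
    general        = c(4, 4, 3, 2, 3, 2, 1, 1, 1, 2, 1, 1, 0.5,
                       2, 2, 1, 1.5, 1.5, 1, 1, 1.5, 1.5, 1),
    amide_rich     = c(4, 4, 3, 2, 2, 1.5, 1, 1, 1, 2, 0.5, 0.5, 0.2,
                       1, 1.5, 0.5, 1, 1, 0.5, 0.5, 4, 4, 3),
    donor_acceptor_rich = c(3, 4, 4, 4, 2, 2, 1, 1, 1, 1.5, 0.5, 0.5, 0.2,
                            3, 3, 0.5, 2.5, 2.5, 1, 1, 1, 1, 0.5),
    stringsAsFactors = FALSE)
}

#' Generate a deterministic fixture pool of drug-like molecules
#'
#' Stand-in for a ChEMBL-like source pool: molecules are assembled from a
#' fixed grammar of drug-like building blocks (rings, chains, N/O groups,
#' amide linkers, H-bond donors/acceptors), parsed, standardized,
#' deduplicated and filtered to MW <= 500.  A pure function of
#' `(n, seed, profile)`.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param profile block-weight profile: `"general"`, `"amide_rich"` or
#'   `"donor_acceptor_rich"`.
#' @return list of `n` `mol_record` objects with ids `fx000001`, ...
#' @export
generate_fixture_pool <- function(n, seed,
                                  profile = c("general", "amide_rich",
                                              "donor_acceptor_rich")) {
  stopifnot(n >= 1)
  profile <- match.arg(profile)
  blocks <- fixture_blocks()
  w <- blocks[[profile]]
  rng <- local_rng(seed)
  accepted <- character(0)
  round <- 0L
  while (length(accepted) < n && round < 50L) {
    round <- round + 1L
    batch <- max(2L * (n - length(accepted)), 20L)
    cand <- vapply(seq_len(batch), function(i) {
      nb <- rng$int(2L, 8L)
      paste(blocks$smiles[rng$weighted(length(w), nb, w)], collapse = "")
    }, character(1))
    res <- py_backend("standardize", list(smiles = as.list(cand)))
    for (m in res$mols) {
      if (isTRUE(m$ok) && m$mw <= 500 && !(m$smiles %in% accepted)) {
        accepted <- c(accepted, m$smiles)
        if (length(accepted) == n) break
      }
    }
  }
  if (length(accepted) < n) {
    stop("fixture generator could not produce ", n, " unique molecules")
  }
  parse_smiles(accepted, ids = sprintf("fx%06d", seq_len(n)), quiet = TRUE)
}

# Small self-contained RNG (Lehmer / MINSTD) so fixture generation never
# touches the global .Random.seed and is reproducible across R versions.
local_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(
    unif = nxt,
    int = function(lo, hi) lo + floor(nxt() * (hi - lo + 1)),
    weighted = function(nitem, k, w) {
      cw <- cumsum(w) / sum(w)
      vapply(seq_len(k), function(i) findInterval(nxt(), cw) + 1L,
             integer(1))
    })
}

# ---------------------------------------------------------------------------
# Dataset tables

#' Dataset table
#'
#' Molecules plus activities, task type and train/test split assignment.
#'
#' @param records named list of `mol_record` (names = mol_id).
#' @param activity named vector (numeric for regression, `"active"` /
#'   `"inactive"` for classification), names = mol_id.
#' @param task `"regression"` or `"classification"`.
#' @param split optional named character vector (`"train"` / `"test"`).
#' @return object of class `mol_dataset`.
#' @export
mol_dataset <- function(records, activity, task, split = NULL) {
  ids <- vapply(records, `[[`, character(1), "mol_id")
  names(records) <- ids
  stopifnot(!anyDuplicated(ids), all(ids %in% names(activity)))
  activity <- activity[ids]
  if (!is.null(split)) {
    stopifnot(all(ids %in% names(split)),
              all(split %in% c("train", "test")))
    split <- split[ids]
  }
  structure(list(records = records, activity = activity,
                 task = task, split = split),
            class = "mol_dataset")
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat("<mol_dataset>", length(x$records), "molecules,", x$task, "task\n")
  if (!is.null(x$split)) {
    cat("  split:", sum(x$split == "train"), "train /",
        sum(x$split == "test"), "test\n")
  }
  invisible(x)
}

#' Write / read a dataset as CSV
#'
#' Columns `mol_id, smiles, activity, split`; reading re-parses the stored
#' canonical SMILES, reproducing activities, splits and SMILES exactly.
#'
#' @param ds a `mol_dataset`.
#' @param path CSV file path.
#' @return `write_dataset`: the path, invisibly; `read_dataset`: a
#'   `mol_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mol_dataset"))
  tab <- data.frame(
    mol_id = names(ds$records),
    smiles = vapply(ds$records, `[[`, character(1), "smiles"),
    activity = unname(ds$activity),
    split = if (is.null(ds$split)) NA_character_ else unname(ds$split),
    stringsAsFactors = FALSE)
  attr(tab, "task") <- ds$task
  utils::write.csv(cbind(tab, task = ds$task), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  task <- tab$task[1]
  records <- parse_smiles(tab$smiles, ids = tab$mol_id, quiet = TRUE)
  activity <- if (task == "regression") as.numeric(tab$activity) else
    as.character(tab$activity)
  names(activity) <- tab$mol_id
  split <- NULL
  if (!all(is.na(tab$split))) {
    split <- stats::setNames(tab$split, tab$mol_id)
  }
  mol_dataset(records, activity, task, split)
}

#' Write / read ground truth as JSON-lines
#'
#' One JSON object per molecule: `mol_id` and the per-heavy-atom expected
#' contribution vector.
#'
#' @param truths list of `atom_truth`.
#' @param path output file.
#' @export
write_truths <- function(truths, path) {
  lines <- vapply(truths, function(tr) {
    jsonlite::toJSON(list(mol_id = tr$mol_id, expected = tr$expected),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truths
#' @export
read_truths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    new_atom_truth(obj$mol_id, as.numeric(obj$expected))
  })
  names(out) <- vapply(out, `[[`, character(1), "mol_id")
  out
}
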