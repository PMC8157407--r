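# Ground-truth assignment: activities and per-atom expected contributions
# for the six benchmark labeling rules (atom counts, amide groups, and the
# two-point 3D pharmacophore).

#' Atom truth
#'
#' Per-heavy-atom expected contributions for one molecule; the benchmark
#' "ground truth" that calculated contributions are scored against.
#'
#' @param mol_id identifier.
#' @param expected numeric vector, one value per heavy atom (1-based atom
#'   order of the molecule record).
#' @return object of class `atom_truth` with `expected`, `positive`
#'   (indices with expected > 0) and `negative` (indices with expected < 0).
#' @export
new_atom_truth <- function(mol_id, expected) {
  structure(list(mol_id = mol_id, expected = as.numeric(expected),
                 positive = which(expected > 0),
                 negative = which(expected < 0)),
            class = "atom_truth")
}

#' Label a molecule by atom counts
#'
#' The three simple additive tasks: activity is the nitrogen count (`N`),
#' nitrogen minus oxygen count (`N_minus_O`), or half the combined N+O
#' count (`N_plus_O`).  For `N_plus_O` only molecules with strictly equal
#' nitrogen and oxygen counts are eligible (the task is built around two
#' perfectly correlated patterns); others get activity `NA`.
#'
#' Expected contributions: `N` task — N atoms 1, others 0; `N_minus_O` —
#' N atoms 1, O atoms -1, others 0; `N_plus_O` — every N and O atom 0.5.
#'
#' @param record a `mol_record`.
#' @param task `"N"`, `"N_minus_O"` or `"N_plus_O"`.
#' @return list with `activity` (number, or `NA` if ineligible) and
#'   `truth` (an `atom_truth`).
#' @export
label_atom_count <- function(record, task = c("N", "N_minus_O", "N_plus_O")) {
  task <- match.arg(task)
  sym <- record$atoms$symbol
  is_n <- sym == "N"
  is_o <- sym == "O"
  expected <- numeric(record$n_heavy)
  if (task == "N") {
    expected[is_n] <- 1
    activity <- sum(is_n)
  } else if (task == "N_minus_O") {
    expected[is_n] <- 1
    expected[is_o] <- -1
    activity <- sum(is_n) - sum(is_o)
  } else {
    if (sum(is_n) != sum(is_o)) {
      return(list(activity = NA_real_,
                  truth = new_atom_truth(record$mol_id,
                                         numeric(record$n_heavy))))
    }
    expected[is_n | is_o] <- 0.5
    activity <- (sum(is_n) + sum(is_o)) / 2
  }
  list(activity = activity, truth = new_atom_truth(record$mol_id, expected))
}

AMIDE_SMARTS <- "NC=O"

# batched SMARTS matching over a record list; returns per record a list of
# 1-based atom-index sets (unique unordered sets)
match_pool <- function(records, smarts) {
  res <- py_backend("match", list(
    smiles = unname(lapply(records, `[[`, "smiles")),
    smarts = as.list(smarts)))
  lapply(res$matches, function(per_mol) {
    lapply(per_mol, function(per_pat) {
      lapply(per_pat, function(m) vapply(m, as.integer, integer(1)) + 1L)
    })
  })
}

#' Label a molecule by amide groups
#'
#' Matches of the SMARTS pattern `NC=O` are enumerated over unique atom
#' index sets.  Regression activity is the number of matches;
#' classification activity is `"active"` iff at least one match.  Every
#' atom belonging to any match has expected contribution 1 (removing it
#' destroys the pattern), all others 0; overlapping matches (imides) share
#' atoms but each still counts as a match.
#'
#' @param record a `mol_record`.
#' @param mode `"regression"` or `"classification"`.
#' @param matches optional precomputed list of 1-based atom-index sets
#'   (used by the batched pool labeler).
#' @return list with `activity`, `n_matches` and `truth`.
#' @export
label_amide <- function(record, mode = c("regression", "classification"),
                        matches = NULL) {
  mode <- match.arg(mode)
  if (is.null(matches)) {
    matches <- match_pool(list(record), AMIDE_SMARTS)[[1]][[1]]
  }
  covered <- sort(unique(unlist(matches)))
  expected <- numeric(record$n_heavy)
  expected[covered] <- 1
  n <- length(matches)
  activity <- if (mode == "regression") n else
    if (n > 0) "active" else "inactive"
  list(activity = activity, n_matches = n,
       truth = new_atom_truth(record$mol_id, expected))
}

# ---------------------------------------------------------------------------
# Pharmacophore task

hbond_definitions <- function() {
  path <- system.file("extdata", "hbond_smarts.tsv", package = "interpbench")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(role = vapply(parts, `[`, character(1), 1),
             smarts = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Assign H-bond donor and acceptor atoms
#'
#' Applies the fixed SMARTS definition table shipped in
#' `extdata/hbond_smarts.tsv` (donors: N-H / O-H; acceptors: N/O excluding
#' amide N, nitro oxygens and pyrrole-type aromatic N).  The first atom of
#' each SMARTS hit is the feature atom.
#'
#' @param record a `mol_record`.
#' @param matches optional precomputed matches (batched path).
#' @return list with integer vectors `donors` and `acceptors` (1-based).
#' @export
assign_pharmacophore_features <- function(record, matches = NULL) {
  defs <- hbond_definitions()
  if (is.null(matches)) {
    matches <- match_pool(list(record), defs$smarts)[[1]]
  }
  pick <- function(role) {
    idx <- which(defs$role == role)
    sort(unique(unlist(lapply(matches[idx], function(hits)
      vapply(hits, `[`, integer(1), 1)))))
  }
  list(donors = pick("donor"), acceptors = pick("acceptor"))
}

#' Generate 3D conformers
#'
#' Distance-geometry embedding (ETKDG, experimental-torsion terms), up to
#' `max_conf` conformers per molecule, heavy-atom coordinates only, no
#' energy minimization.  Deterministic for a fixed seed.  Molecules that
#' fail embedding are returned with `embed_failed = TRUE` instead of
#' raising an error, and should be excluded from the pharmacophore pool.
#'
#' @param records list of `mol_record` (or a single record).
#' @param max_conf maximum conformers per molecule (default 25).
#' @param seed integer seed.
#' @return list of `mol_record` with `conformers` filled in.
#' @export
generate_conformers <- function(records, max_conf = 25, seed = 1) {
  single <- inherits(records, "mol_record")
  if (single) records <- list(records)
  res <- py_backend("conformers", list(
    smiles = unname(lapply(records, `[[`, "smiles")),
    max_conf = max_conf, seed = seed))
  out <- Map(function(rec, m) {
    if (!isTRUE(m$ok)) {
      rec$embed_failed <- TRUE
      return(rec)
    }
    rec$conformers <- lapply(m$conformers, function(cf) {
      mat <- do.call(rbind, lapply(cf, unlist))
      colnames(mat) <- c("x", "y", "z")
      mat
    })
    rec
  }, records, res$mols)
  if (single) out[[1]] else out
}

#' Label a molecule against the two-point pharmacophore
#'
#' Collects, over all conformers, every (donor, acceptor) atom pair whose
#' Euclidean heavy-atom distance lies in `[d_min, d_max]`; pairs are
#' unordered and a self-pair (donor atom = acceptor atom) is disallowed.
#' The molecule is `active` iff the union over conformers is exactly one
#' pair (the same two atoms wherever the pattern occurs), `inactive` iff
#' the union is empty, and `excluded` (ambiguous) otherwise.  For actives
#' the two pharmacophore atoms get expected contribution 1.
#'
#' @param record a `mol_record` with at least one conformer.
#' @param d_min,d_max distance window in Angstrom (defaults 9 and 10).
#' @param features optional precomputed donor/acceptor assignment.
#' @return list with `donors`, `acceptors`, `matching_pairs` (2-column
#'   matrix of atom indices), `label`, `activity` and `truth` (`NA`
#'   activity and all-zero truth for excluded molecules).
#' @export
label_pharmacophore <- function(record, d_min = 9, d_max = 10,
                                features = NULL) {
  stopifnot(!is.null(record$conformers), length(record$conformers) >= 1)
  if (is.null(features)) features <- assign_pharmacophore_features(record)
  pairs <- matrix(integer(0), ncol = 2)
  if (length(features$donors) && length(features$acceptors)) {
    cand <- expand.grid(d = features$donors, a = features$acceptors)
    cand <- cand[cand$d != cand$a, , drop = FALSE]
    if (nrow(cand)) {
      hit <- rep(FALSE, nrow(cand))
      for (cf in record$conformers) {
        dd <- sqrt(rowSums((cf[cand$d, , drop = FALSE] -
                            cf[cand$a, , drop = FALSE])^2))
        hit <- hit | (dd >= d_min & dd <= d_max)
      }
      mp <- cbind(pmin(cand$d, cand$a), pmax(cand$d, cand$a))[hit, ,
                                                              drop = FALSE]
      pairs <- unique(mp)
    }
  }
  label <- if (nrow(pairs) == 1) "active" else
    if (nrow(pairs) == 0) "inactive" else "excluded"
  expected <- numeric(record$n_heavy)
  if (label == "active") expected[pairs[1, ]] <- 1
  activity <- switch(label, active = "active", inactive = "inactive",
                     excluded = NA_character_)
  list(donors = features$donors, acceptors = features$acceptors,
       matching_pairs = pairs, label = label, activity = activity,
       truth = new_atom_truth(record$mol_id, expected))
}

#' Label a molecule pool for one benchmark task
#'
#' Batched labeling front end: applies the task's rule to every record and
#' returns parallel activity/truth containers.  For the pharmacophore task
#' conformers must already be present (see [generate_conformers()]);
#' molecules with failed embedding or an ambiguous (excluded) label get
#' activity `NA`.
#'
#' @param records list of `mol_record`.
#' @param task one of `"N"`, `"N_minus_O"`, `"N_plus_O"`, `"amide_reg"`,
#'   `"amide_class"`, `"pharmacophore"`.
#' @param d_min,d_max pharmacophore distance window.
#' @return list with `activity` (named vector; `NA` = ineligible),
#'   `truths` (named list of `atom_truth`) and `n_matches` (amide tasks).
#' @export
label_pool <- function(records, task, d_min = 9, d_max = 10) {
  ids <- vapply(records, `[[`, character(1), "mol_id")
  if (task %in% c("N", "N_minus_O", "N_plus_O")) {
    labs <- lapply(records, label_atom_count, task = task)
    activity <- vapply(labs, function(l) l$activity, numeric(1))
    truths <- lapply(labs, `[[`, "truth")
    n_matches <- NULL
  } else if (task %in% c("amide_reg", "amide_class")) {
    mode <- if (task == "amide_reg") "regression" else "classification"
    all_matches <- match_pool(records, AMIDE_SMARTS)
    labs <- Map(function(rec, m) label_amide(rec, mode, matches = m[[1]]),
                records, all_matches)
    activity <- if (mode == "regression") {
      vapply(labs, function(l) l$activity, numeric(1))
    } else {
      vapply(labs, function(l) l$activity, character(1))
    }
    truths <- lapply(labs, `[[`, "truth")
    n_matches <- vapply(labs, `[[`, integer(1), "n_matches")
    names(n_matches) <- ids
  } else if (task == "pharmacophore") {
    defs <- hbond_definitions()
    all_matches <- match_pool(records, defs$smarts)
    labs <- Map(function(rec, m) {
      if (isTRUE(rec$embed_failed) || is.null(rec$conformers)) {
        return(list(activity = NA_character_,
                    truth = new_atom_truth(rec$mol_id,
                                           numeric(rec$n_heavy))))
      }
      feats <- assign_pharmacophore_features(rec, matches = m)
      label_pharmacophore(rec, d_min, d_max, features = feats)
    }, records, all_matches)
    activity <- vapply(labs, function(l) l$activity, character(1))
    truths <- lapply(labs, `[[`, "truth")
    n_matches <- NULL
  } else {
    stop("unknown task: ", task)
  }
  names(activity) <- ids
  names(truths) <- ids
  list(activity = activity, truths = truths, n_matches = n_matches)
}

benchmark_tasks <- function() {
  c("N", "N_minus_O", "N_plus_O", "amide_reg", "amide_class",
    "pharmacophore")
}

task_type <- function(task) {
  if (task %in% c("N", "N_minus_O", "N_plus_O", "amide_reg"))
    "regression" else "classification"
}
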