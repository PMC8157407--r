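# Structural interpretation by virtual removal: atoms or connected
# fragments are replaced by dummy atoms and the contribution of the
# removed part is the difference between the prediction for the whole
# molecule and for the remainder.  Works against any predictor exposing
# the masked-prediction contract.

#' Contribution vector
#'
#' Calculated per-atom or per-fragment contributions for one molecule.
#'
#' @param mol_id identifier.
#' @param level `"atom"` or `"fragment"`.
#' @param targets list of 1-based atom-index sets (singletons at atom
#'   level, enumerating every heavy atom exactly once).
#' @param contributions numeric vector aligned to `targets` (`NA` =
#'   prediction failed for that masked form).
#' @param base_prediction full-molecule prediction (active-class
#'   probability for classification).
#' @return object of class `contrib_vector`.
#' @export
new_contrib_vector <- function(mol_id, level, targets, contributions,
                               base_prediction) {
  stopifnot(length(targets) == length(contributions))
  structure(list(mol_id = mol_id, level = level, targets = targets,
                 contributions = as.numeric(contributions),
                 base_prediction = base_prediction),
            class = "contrib_vector")
}

#' @export
print.contrib_vector <- function(x, ...) {
  cat("<contrib_vector>", x$mol_id, x$level, "level,",
      length(x$targets), "targets, base prediction",
      sprintf("%.4f", x$base_prediction), "\n")
  invisible(x)
}

#' Virtually remove atoms from a molecule
#'
#' Marks the given heavy atoms as dummy atoms (atomic number 0) with all
#' bonds preserved; every other atom keeps its index, and the heavy-atom
#' count is unchanged.  Descriptors computed from the masked record
#' produce dummy-atom feature keys that are absent from any dummy-free
#' training vocabulary, so models ignore the removed part.
#'
#' @param record a `mol_record`.
#' @param atoms non-empty vector of 1-based atom indices; masking all
#'   heavy atoms is an error.
#' @return the masked `mol_record` (field `mask` records the indices).
#' @export
mask_atoms <- function(record, atoms) {
  stopifnot(inherits(record, "mol_record"), length(atoms) >= 1)
  atoms <- sort(unique(as.integer(atoms)))
  if (any(atoms < 1 | atoms > record$n_heavy)) {
    stop("mask indices out of range 1..", record$n_heavy)
  }
  mask <- sort(union(record$mask, atoms))
  if (length(mask) >= record$n_heavy) stop("cannot mask all heavy atoms")
  record$atoms$symbol[mask] <- "*"
  record$atoms$z[mask] <- 0L
  record$mask <- mask
  record
}

# prediction front end for the generic masked-prediction contract:
# a predictor is either a predictor_handle or a function
# (record, masked_atom_indices) -> number
masked_predictions <- function(predictor, records, masks) {
  if (inherits(predictor, "predictor_handle")) {
    return(predict_model(predictor, records, masks = masks))
  }
  stopifnot(is.function(predictor))
  vapply(seq_along(records), function(i) {
    val <- tryCatch(predictor(records[[i]],
                              if (is.null(masks[[i]])) integer(0) else
                                masks[[i]]),
                    error = function(e) NA_real_)
    as.numeric(val)
  }, numeric(1))
}

#' Atom contributions by virtual removal
#'
#' `contribution(a) = predict(full) - predict(mask(a))` for every heavy
#' atom `a`.  For classification models the prediction is the
#' active-class probability, so contributions lie in `[-1, 1]`.
#'
#' @param record a `mol_record`.
#' @param predictor a `predictor_handle`, or any function
#'   `(record, masked_atom_indices) -> number` satisfying the masked
#'   prediction contract (row-removal schemes for graph models plug in
#'   here).
#' @return a `contrib_vector` at atom level; failed masked predictions
#'   are `NA` with a warning.
#' @export
atom_contributions <- function(record, predictor) {
  a <- record$n_heavy
  jobs_rec <- rep(list(record), a + 1L)
  jobs_mask <- c(list(NULL), as.list(seq_len(a)))
  pred <- masked_predictions(predictor, jobs_rec, jobs_mask)
  base <- pred[1]
  contrib <- base - pred[-1]
  if (anyNA(contrib)) {
    warning(sum(is.na(contrib)), " masked prediction(s) failed for ",
            record$mol_id)
  }
  new_contrib_vector(record$mol_id, "atom", as.list(seq_len(a)), contrib,
                     base)
}

#' Enumerate fragments by acyclic-bond breaking
#'
#' All connected fragments obtainable by deleting 1..`max_bonds` eligible
#' bonds — acyclic single bonds between heavy atoms (never ring, double,
#' triple or aromatic bonds) — subject to the size limits: at most
#' `max_atoms` atoms and at most `max_frac` of the molecule's heavy atoms
#' (evaluated exactly, so size 2 is allowed for a 5-atom molecule).
#' Duplicate atom sets are collapsed.  Ring systems small enough to pass
#' the size limits are legitimate fragments (rings are kept intact).
#'
#' @param record a `mol_record`.
#' @param max_bonds maximum broken bonds (default 3).
#' @param max_atoms maximum fragment size (default 7).
#' @param max_frac maximum fragment fraction of heavy atoms (default 0.4).
#' @return list of fragments, each a list with `atoms` (sorted 1-based
#'   indices) and `n_broken_bonds`; empty when no bond is eligible.
#' @export
enumerate_fragments <- function(record, max_bonds = 3, max_atoms = 7,
                                max_frac = 0.4) {
  a <- record$n_heavy
  bonds <- record$bonds
  eligible <- bonds$order == 1 & !bonds$ring
  # size cap: |S| <= max_frac * A in exact arithmetic (max_frac rational)
  cap <- min(max_atoms, floor(max_frac * a + 1e-9))
  if (cap < 1 || !any(eligible)) return(list())

  nbr <- vector("list", a)
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds$a[k]]] <- c(nbr[[bonds$a[k]]], bonds$b[k])
    nbr[[bonds$b[k]]] <- c(nbr[[bonds$b[k]]], bonds$a[k])
  }
  # bond lookup: key i*N+j -> eligible?
  key <- function(i, j) pmin(i, j) * (a + 1L) + pmax(i, j)
  elig_keys <- key(bonds$a[eligible], bonds$b[eligible])
  all_keys <- key(bonds$a, bonds$b)

  out <- list()
  emit <- function(sub) {
    # boundary bonds: one endpoint inside, one outside
    inside <- logical(a)
    inside[sub] <- TRUE
    cross <- xor(inside[bonds$a], inside[bonds$b])
    nb <- sum(cross)
    if (nb < 1 || nb > max_bonds) return()
    if (!all(all_keys[cross] %in% elig_keys)) return()
    out[[length(out) + 1L]] <<- list(atoms = sort(sub),
                                     n_broken_bonds = nb)
  }
  # ESU (Wernicke) enumeration of connected subgraphs up to size `cap`
  extend <- function(sub, ext, v) {
    emit(sub)
    if (length(sub) == cap) return()
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      new_nbr <- setdiff(nbr[[w]], c(sub, unlist(nbr[sub])))
      ext2 <- union(ext, new_nbr[new_nbr > v])
      extend(c(sub, w), ext2, v)
    }
  }
  for (v in seq_len(a)) {
    extend(v, nbr[[v]][nbr[[v]] > v], v)
  }
  out
}

#' Fragment contributions by virtual removal
#'
#' @param record a `mol_record`.
#' @param predictor as in [atom_contributions()].
#' @param fragments list from [enumerate_fragments()] (default: enumerate
#'   with its defaults).
#' @return a `contrib_vector` at fragment level (empty when the molecule
#'   has no eligible fragments).
#' @export
fragment_contributions <- function(record, predictor,
                                   fragments = enumerate_fragments(record)) {
  if (length(fragments) == 0) {
    return(new_contrib_vector(record$mol_id, "fragment", list(),
                              numeric(0), NA_real_))
  }
  targets <- lapply(fragments, `[[`, "atoms")
  jobs_rec <- rep(list(record), length(targets) + 1L)
  jobs_mask <- c(list(NULL), targets)
  pred <- masked_predictions(predictor, jobs_rec, jobs_mask)
  new_contrib_vector(record$mol_id, "fragment", targets,
                     pred[1] - pred[-1], pred[1])
}

#' Interpret a dataset
#'
#' Computes contribution vectors for many molecules, batching all masked
#' predictions into single backend calls when the predictor is a trained
#' model handle.  By default only the training split is interpreted —
#' interpretation performance is evaluated where prediction error is
#' smallest.
#'
#' @param ds a `mol_dataset`.
#' @param predictor a `predictor_handle` or masked-prediction function.
#' @param level `"atom"` or `"fragment"`.
#' @param on which split to interpret (`"train"`, `"test"`, `"all"`).
#' @param ... passed to [enumerate_fragments()] at fragment level.
#' @return named list of `contrib_vector`.
#' @export
interpret_dataset <- function(ds, predictor, level = c("atom", "fragment"),
                              on = "train", ...) {
  level <- match.arg(level)
  stopifnot(inherits(ds, "mol_dataset"))
  ids <- names(ds$records)
  if (!is.null(ds$split) && on != "all") ids <- ids[ds$split == on]
  records <- ds$records[ids]

  if (!inherits(predictor, "predictor_handle")) {
    out <- lapply(records, function(rec) {
      if (level == "atom") atom_contributions(rec, predictor) else
        fragment_contributions(rec, predictor,
                               enumerate_fragments(rec, ...))
    })
    names(out) <- ids
    return(out)
  }

  # batched path: one featurize + one predict call for everything
  jobs_rec <- list()
  jobs_mask <- list()
  slot <- vector("list", length(records))  # per molecule: job indices
  targets_by_mol <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    targets <- if (level == "atom") as.list(seq_len(rec$n_heavy)) else
      lapply(enumerate_fragments(rec, ...), `[[`, "atoms")
    targets_by_mol[[i]] <- targets
    base_j <- length(jobs_rec) + 1L
    jobs_rec <- c(jobs_rec, rep(list(rec), length(targets) + 1L))
    jobs_mask <- c(jobs_mask, c(list(NULL), targets))
    slot[[i]] <- base_j
  }
  pred <- masked_predictions(predictor, jobs_rec, jobs_mask)
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    targets <- targets_by_mol[[i]]
    j0 <- slot[[i]]
    base <- pred[j0]
    contrib <- base - pred[j0 + seq_along(targets)]
    out[[i]] <- new_contrib_vector(records[[i]]$mol_id, level, targets,
                                   contrib, base)
  }
  names(out) <- ids
  out
}
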