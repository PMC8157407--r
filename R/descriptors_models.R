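# Fingerprint featurization (masking-aware) and the conventional model
# harness (RF / PLS / GBM / SVM via the scikit-learn backend, 1-NN
# baseline in R).

#' Fingerprint specification
#'
#' The four fingerprint families: atom pairs at topological distances 1-30
#' (`AP`), Morgan circular substructures of radius 2 (`MG2`), all linear
#' subpaths of 2-4 atoms (`RDK`) and topological torsions of 4 atoms
#' (`TT`).  Counted fingerprints are kept unfolded (sparse keyed counts)
#' so out-of-vocabulary dummy-atom features can be dropped exactly; binary
#' fingerprints are folded to `nbits` bits (default 2048), accepting
#' possible hash collisions between dummy features and real bits.
#'
#' @param family `"AP"`, `"MG2"`, `"RDK"` or `"TT"`.
#' @param counted logical; `FALSE` for the folded binary form.
#' @param nbits folded length for binary fingerprints.
#' @return object of class `fp_spec`.
#' @export
fingerprint_spec <- function(family = c("AP", "MG2", "RDK", "TT"),
                             counted = TRUE, nbits = 2048) {
  family <- match.arg(family)
  structure(list(family = family, counted = counted,
                 nbits = as.integer(nbits)),
            class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("<fp_spec>", x$family, if (x$counted) "counted (unfolded)" else
    sprintf("binary (%d bits)", x$nbits), "\n")
  invisible(x)
}

#' Featurize one molecule
#'
#' Returns the feature mapping for a single molecule (keyed counts for
#' counted fingerprints, on-bit indicator for binary).  When a vocabulary
#' is supplied, keys absent from it are returned in the `"oov"` attribute
#' and excluded from the mapping — the mechanism by which models ignore
#' dummy-atom descriptors that never occurred in training.
#'
#' @param record a `mol_record`.
#' @param spec a [fingerprint_spec()].
#' @param vocabulary optional character vector of training feature keys.
#' @param mask optional 1-based atom indices to replace by dummy atoms
#'   before featurization.
#' @return named numeric vector of features (attribute `oov`: dropped
#'   keys).
#' @export
featurize <- function(record, spec, vocabulary = NULL, mask = NULL) {
  stopifnot(inherits(record, "mol_record"), inherits(spec, "fp_spec"))
  mask <- sort(union(record$mask, mask))
  res <- py_backend("featurize", list(
    smiles = list(record$smiles),
    masks = if (length(mask) == 0) NULL else
      list(as.list(as.integer(mask) - 1L)),
    family = spec$family, counted = spec$counted, nbits = spec$nbits,
    as_mapping = TRUE))
  f <- unlist(res$features[[1]])
  if (is.null(f)) f <- stats::setNames(numeric(0), character(0))
  oov <- character(0)
  if (!is.null(vocabulary)) {
    oov <- setdiff(names(f), vocabulary)
    f <- f[names(f) %in% vocabulary]
  }
  attr(f, "oov") <- oov
  f
}

#' Featurize a batch of (molecule, mask) jobs into a sparse matrix
#'
#' @param records list of `mol_record` (may repeat).
#' @param spec a [fingerprint_spec()].
#' @param masks optional list (parallel to `records`) of 1-based atom index
#'   vectors; `NULL` entries mean no masking.
#' @param vocabulary optional feature-key universe; if omitted (training
#'   mode) the union of observed keys is used and returned.
#' @return list with `X` (dgCMatrix, rows = jobs, columns = vocabulary),
#'   `vocab` and `n_oov_dropped` per job.
#' @export
featurize_matrix <- function(records, spec, masks = NULL,
                             vocabulary = NULL) {
  stopifnot(inherits(spec, "fp_spec"))
  mtx <- tempfile(fileext = ".mtx")
  on.exit(unlink(mtx), add = TRUE)
  payload <- list(
    smiles = unname(lapply(records, `[[`, "smiles")),
    family = spec$family, counted = spec$counted, nbits = spec$nbits,
    mtx = mtx)
  # merge explicit masks with masks frozen on the records by mask_atoms()
  masks_eff <- lapply(seq_along(records), function(i) {
    sort(union(records[[i]]$mask,
               if (is.null(masks)) NULL else masks[[i]]))
  })
  if (any(lengths(masks_eff) > 0)) {
    payload$masks <- lapply(masks_eff, function(m)
      if (length(m) == 0) list() else as.list(as.integer(m) - 1L))
  }
  if (!is.null(vocabulary)) payload$vocab <- as.list(vocabulary)
  res <- py_backend("featurize", payload)
  X <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  vocab <- vapply(res$vocab, as.character, character(1))
  colnames(X) <- vocab
  list(X = X, vocab = vocab,
       n_oov_dropped = vapply(res$n_oov_dropped, as.integer, integer(1)))
}

#' Default hyperparameter grids
#'
#' Documented defaults; the grid is searched by five-fold cross-validation
#' (RMSE for regression, balanced accuracy for classification).
#'
#' @param algorithm `"RF"`, `"GBM"`, `"SVM"` or `"PLS"`.
#' @return list of parameter lists.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    RF = list(list(n_estimators = 250L), list(n_estimators = 500L)),
    GBM = list(list(n_estimators = 100L, max_depth = 3L,
                    learning_rate = 0.1),
               list(n_estimators = 300L, max_depth = 3L,
                    learning_rate = 0.1)),
    SVM = list(list(C = 1), list(C = 10), list(C = 100)),
    PLS = list(list(n_components = 2L), list(n_components = 8L),
               list(n_components = 16L), list(n_components = 32L)),
    stop("no default grid for algorithm: ", algorithm))
}

# internal: fit on a prepared matrix (also used with oracle feature sets)
fit_matrix <- function(X, y, task, algorithm, grid, cv_folds = 5,
                       seed = 1) {
  if (algorithm == "PLS") {
    cap <- min(ncol(X), nrow(X) - 1L)
    grid <- grid[vapply(grid, function(g)
      g$n_components <= cap, logical(1))]
    if (length(grid) == 0) grid <- list(list(n_components = cap))
  }
  mtx <- tempfile(fileext = ".mtx")
  model_out <- tempfile(fileext = ".joblib")
  on.exit(unlink(mtx), add = TRUE)
  Matrix::writeMM(methods::as(X, "TsparseMatrix"), mtx)
  res <- py_backend("fit", list(
    mtx = mtx, y = as.list(unname(y)), task = task, algorithm = algorithm,
    grid = grid, cv_folds = cv_folds, seed = seed, model_out = model_out))
  list(model_path = model_out,
       best_params = res$best_params,
       cv_table = res$cv_table,
       train_pred = vapply(res$train_pred, as.numeric, numeric(1)))
}

#' Train a QSAR model
#'
#' Featurizes the training split, freezes the training feature vocabulary,
#' selects hyperparameters by `cv_folds`-fold cross-validation over the
#' grid and refits on the full training split.  Classification models
#' predict the active-class probability.
#'
#' @param ds a `mol_dataset` (its `train` split is used when present).
#' @param spec a [fingerprint_spec()].
#' @param algorithm `"RF"`, `"PLS"` (regression only), `"GBM"` or `"SVM"`.
#' @param grid parameter grid (default [default_grid()]).
#' @param cv_folds folds for the grid search (default 5).
#' @param seed integer seed passed to all randomized learners.
#' @return object of class `predictor_handle`.
#' @export
train_model <- function(ds, spec, algorithm, grid = default_grid(algorithm),
                        cv_folds = 5, seed = 1) {
  stopifnot(inherits(ds, "mol_dataset"))
  ids <- if (is.null(ds$split)) names(ds$records) else
    names(ds$records)[ds$split == "train"]
  if (length(ids) < 2 * cv_folds) {
    stop("need at least ", 2 * cv_folds, " training molecules")
  }
  y <- ds$activity[ids]
  if (ds$task == "regression" && stats::sd(as.numeric(y)) == 0) {
    stop("degenerate labels: zero variance")
  }
  if (ds$task == "classification" && length(unique(y)) < 2) {
    stop("degenerate labels: single class")
  }
  fm <- featurize_matrix(ds$records[ids], spec)
  fit <- fit_matrix(fm$X, y, ds$task, algorithm, grid, cv_folds, seed)
  structure(list(algorithm = algorithm, task = ds$task, spec = spec,
                 vocab = fm$vocab, model_path = fit$model_path,
                 best_params = fit$best_params, cv_table = fit$cv_table,
                 train_ids = ids,
                 train_pred = stats::setNames(fit$train_pred, ids),
                 seed = seed),
            class = "predictor_handle")
}

#' @export
print.predictor_handle <- function(x, ...) {
  cat("<predictor_handle>", x$algorithm, x$task, "on", x$spec$family,
      if (x$spec$counted) "counted" else "binary", "fingerprints;",
      length(x$vocab), "features,", length(x$train_ids),
      "training molecules\n")
  invisible(x)
}

#' Predict with a trained model
#'
#' Molecules are vectorized against the model's frozen training
#' vocabulary (out-of-vocabulary keys, e.g. dummy-atom features of masked
#' molecules, are dropped).  Classification returns the active-class
#' probability in `[0, 1]`.
#'
#' @param handle a `predictor_handle`.
#' @param records list of `mol_record`.
#' @param masks optional list of 1-based atom index vectors to mask.
#' @return numeric vector of predictions.
#' @export
predict_model <- function(handle, records, masks = NULL) {
  stopifnot(inherits(handle, "predictor_handle"))
  fm <- featurize_matrix(records, handle$spec, masks = masks,
                         vocabulary = handle$vocab)
  predict_matrix(handle, fm$X)
}

predict_matrix <- function(handle, X) {
  mtx <- tempfile(fileext = ".mtx")
  on.exit(unlink(mtx), add = TRUE)
  Matrix::writeMM(methods::as(X, "TsparseMatrix"), mtx)
  res <- py_backend("predict", list(model = handle$model_path, mtx = mtx))
  vapply(res$pred, as.numeric, numeric(1))
}

#' Save / load a trained model
#'
#' Writes the fitted backend state plus spec, vocabulary and grid record
#' into a directory; reloading reproduces predictions bit-for-bit.
#'
#' @param handle a `predictor_handle`.
#' @param path directory to create.
#' @export
save_model <- function(handle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  file.copy(handle$model_path, file.path(path, "model.joblib"),
            overwrite = TRUE)
  meta <- handle
  meta$model_path <- NULL
  meta$spec <- unclass(meta$spec)
  jsonlite::write_json(unclass(meta), file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  handle <- list(
    algorithm = meta$algorithm, task = meta$task,
    spec = structure(list(family = meta$spec$family,
                          counted = meta$spec$counted,
                          nbits = as.integer(meta$spec$nbits)),
                     class = "fp_spec"),
    vocab = as.character(meta$vocab),
    model_path = file.path(path, "model.joblib"),
    best_params = meta$best_params, cv_table = meta$cv_table,
    train_ids = meta$train_ids,
    train_pred = stats::setNames(as.numeric(meta$train_pred),
                                 names(meta$train_pred)),
    seed = meta$seed)
  structure(handle, class = "predictor_handle")
}

#' 1-nearest-neighbor modelability baseline
#'
#' Nearest neighbor in the chosen descriptor space — Tanimoto similarity
#' for binary fingerprints, Dice on counts (2 * sum(min) / (sum + sum))
#' for counted ones.  Good 1-NN performance flags a trivially modelable
#' (biased) dataset.
#'
#' @param ds a `mol_dataset` with a train/test split.
#' @param spec a [fingerprint_spec()].
#' @return list with `pred` (named test predictions), `neighbor` ids and
#'   `scores` (the [predictive_scores()] of the test predictions).
#' @export
baseline_1nn <- function(ds, spec) {
  stopifnot(inherits(ds, "mol_dataset"), !is.null(ds$split))
  tr_ids <- names(ds$records)[ds$split == "train"]
  te_ids <- names(ds$records)[ds$split == "test"]
  fm <- featurize_matrix(ds$records[c(tr_ids, te_ids)], spec)
  Xtr <- fm$X[seq_along(tr_ids), , drop = FALSE]
  Xte <- fm$X[length(tr_ids) + seq_along(te_ids), , drop = FALSE]
  sums_tr <- Matrix::rowSums(Xtr)
  nn <- integer(length(te_ids))
  for (i in seq_along(te_ids)) {
    x <- Xte[i, ]
    if (spec$counted) {
      # Dice on counts: 2 sum(min) / (sum_a + sum_b)
      mins <- Matrix::rowSums(pmin_matrix(Xtr, x))
      sim <- 2 * mins / (sums_tr + sum(x))
    } else {
      inter <- as.numeric(Xtr %*% x)
      sim <- inter / (sums_tr + sum(x) - inter)
    }
    sim[!is.finite(sim)] <- 0
    nn[i] <- which.max(sim)
  }
  pred_act <- ds$activity[tr_ids][nn]
  if (ds$task == "regression") {
    pred <- as.numeric(pred_act)
    scores <- predictive_scores(prediction_set(
      as.numeric(ds$activity[te_ids]), pred, "regression"))
  } else {
    pred <- as.character(pred_act)
    scores <- predictive_scores(prediction_set(
      as.character(ds$activity[te_ids]), pred, "classification"))
  }
  list(pred = stats::setNames(pred, te_ids),
       neighbor = stats::setNames(tr_ids[nn], te_ids),
       scores = scores)
}

# row-wise pmin of a sparse matrix against a dense vector
pmin_matrix <- function(M, x) {
  Mt <- methods::as(M, "TsparseMatrix")
  vals <- pmin(Mt@x, x[Mt@j + 1L])
  Matrix::sparseMatrix(i = Mt@i + 1L, j = Mt@j + 1L, x = vals,
                       dims = dim(M))
}
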