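# Sampling labeled pools into benchmark datasets: normal-shaped activity
# distributions for regression, balanced classes for classification, 70/30
# splits, and the correlation bias audit.

#' Sampling plan
#'
#' @param task benchmark task name (see [benchmark_tasks()]).
#' @param target_size dataset size (>= 10).
#' @param target_mean,target_sd desired activity mean / sd (regression
#'   only; defaults: pool median and half the interquartile range).
#' @param seed integer seed.
#' @return object of class `sampling_plan`.
#' @export
sampling_plan <- function(task, target_size, target_mean = NULL,
                          target_sd = NULL, seed = 1) {
  stopifnot(target_size >= 10)
  if (!is.null(target_sd)) stopifnot(target_sd > 0)
  structure(list(task = task, target_size = as.integer(target_size),
                 target_mean = target_mean, target_sd = target_sd,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# Freedman-Diaconis histogram density of activities, with fallbacks for
# tiny/degenerate spreads
fd_density <- function(a) {
  iqr <- stats::IQR(a)
  h <- if (iqr > 0) 2 * iqr / length(a)^(1 / 3) else
    (max(a) - min(a)) / max(1, ceiling(sqrt(length(a))))
  if (h <= 0) stop("degenerate pool: single activity value")
  breaks <- seq(min(a) - h / 2, max(a) + h, by = h)
  bin <- findInterval(a, breaks)
  tab <- tabulate(bin, nbins = length(breaks))
  tab[bin] / length(a)
}

#' Sample a regression dataset with normal-shaped activities
#'
#' Each pool member gets a sampling weight proportional to the normal
#' density at its activity divided by the empirical (histogram) density of
#' its activity bin, so the drawn activities resemble a normal
#' distribution even when the pool is skewed.  Drawn without replacement.
#'
#' @param pool a `mol_dataset` (regression activities, `NA` = ineligible)
#'   or list of records plus `activity`.
#' @param plan a [sampling_plan()].
#' @return a `mol_dataset` of `plan$target_size` molecules.
#' @export
sample_regression <- function(pool, plan) {
  stopifnot(inherits(pool, "mol_dataset"), inherits(plan, "sampling_plan"))
  keep <- !is.na(pool$activity)
  records <- pool$records[keep]
  a <- as.numeric(pool$activity[keep])
  n <- length(a)
  if (n < plan$target_size) {
    stop("pool too small: ", n, " eligible molecules < target ",
         plan$target_size)
  }
  if (length(unique(a)) == 1) stop("degenerate pool: single activity value")
  mu <- if (is.null(plan$target_mean)) stats::median(a) else plan$target_mean
  sigma <- if (is.null(plan$target_sd)) max(stats::IQR(a) / 2, 0.5) else
    plan$target_sd
  w <- stats::dnorm((a - mu) / sigma) / fd_density(a)
  w[!is.finite(w) | w <= 0] <- min(w[w > 0 & is.finite(w)])
  if (n == plan$target_size) {
    idx <- seq_len(n)
  } else {
    idx <- with_seed(plan$seed, sample.int(n, plan$target_size,
                                           prob = w / sum(w)))
  }
  ds <- mol_dataset(records[idx], pool$activity[keep][idx], "regression")
  attr(ds, "weights") <- w
  ds
}

#' Sample a balanced classification dataset
#'
#' Draws exactly `floor(target_size / 2)` actives and the same number of
#' inactives uniformly at random.  Molecules with `NA` activity (e.g.
#' pharmacophore-excluded) must be removed beforehand and are ignored.
#'
#' @inheritParams sample_regression
#' @return a balanced `mol_dataset`.
#' @export
sample_classification <- function(pool, plan) {
  stopifnot(inherits(pool, "mol_dataset"), inherits(plan, "sampling_plan"))
  keep <- !is.na(pool$activity)
  act <- as.character(pool$activity[keep])
  records <- pool$records[keep]
  per_class <- plan$target_size %/% 2L
  n_act <- sum(act == "active")
  n_inact <- sum(act == "inactive")
  if (n_act < per_class || n_inact < per_class) {
    stop("insufficient class members: ", n_act, " active / ", n_inact,
         " inactive available, ", per_class, " of each required")
  }
  idx <- with_seed(plan$seed, {
    c(sample(which(act == "active"), per_class),
      sample(which(act == "inactive"), per_class))
  })
  mol_dataset(records[idx], pool$activity[keep][idx], "classification")
}

#' Split a dataset 70/30 into training and test sets
#'
#' Random assignment with `|train| = round(train_frac * n)`;
#' classification splits are stratified by class so the designed balance
#' is preserved in both halves.
#'
#' @param ds a `mol_dataset`.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return the dataset with its `split` field assigned.
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1) {
  stopifnot(inherits(ds, "mol_dataset"), length(ds$records) > 0)
  n <- length(ds$records)
  split <- rep("test", n)
  if (ds$task == "classification") {
    with_seed(seed, {
      for (cl in unique(as.character(ds$activity))) {
        idx <- which(as.character(ds$activity) == cl)
        ntr <- round(train_frac * length(idx))
        split[sample(idx, ntr)] <- "train"
      }
    })
  } else {
    ntr <- round(train_frac * n)
    split[with_seed(seed, sample.int(n, ntr))] <- "train"
  }
  ds$split <- stats::setNames(split, names(ds$records))
  ds
}

AUDIT_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I")

element_counts <- function(records, elements = AUDIT_ELEMENTS) {
  out <- t(vapply(records, function(rec) {
    vapply(elements, function(e) sum(rec$atoms$symbol == e), numeric(1))
  }, numeric(length(elements))))
  colnames(out) <- elements
  out
}

#' Audit a dataset for element-correlation bias
#'
#' Pearson correlation between the task's true-pattern count per molecule
#' (number of atoms with positive expected contribution, or amide match
#' count if supplied) and the per-molecule counts of common elements.
#' Correlations with zero-variance columns are reported as `NA`, never an
#' error.
#'
#' @param ds a `mol_dataset`.
#' @param truths named list of `atom_truth` covering the dataset.
#' @param pattern_count optional named vector overriding the pattern count
#'   (e.g. amide match counts).
#' @param threshold flag correlations with `|r|` above this (default 0.3).
#' @return object of class `bias_audit`: data.frame with element, r, and
#'   flagged; plus the pattern count used.
#' @export
audit_bias <- function(ds, truths, pattern_count = NULL, threshold = 0.3) {
  ids <- names(ds$records)
  if (is.null(pattern_count)) {
    pattern_count <- vapply(ids, function(id)
      length(truths[[id]]$positive) + length(truths[[id]]$negative),
      numeric(1))
  } else {
    pattern_count <- as.numeric(pattern_count[ids])
  }
  elems <- element_counts(ds$records)
  r <- vapply(colnames(elems), function(e) {
    x <- elems[, e]
    if (stats::sd(x) == 0 || stats::sd(pattern_count) == 0) {
      return(NA_real_)
    }
    stats::cor(pattern_count, x)
  }, numeric(1))
  tab <- data.frame(element = colnames(elems), r = unname(r),
                    flagged = !is.na(r) & abs(r) > threshold)
  structure(list(correlations = tab, pattern_count = pattern_count,
                 threshold = threshold),
            class = "bias_audit")
}

#' @export
print.bias_audit <- function(x, ...) {
  cat("<bias_audit> max |r| =",
      sprintf("%.3f", suppressWarnings(max(abs(x$correlations$r),
                                           na.rm = TRUE))), "\n")
  print(x$correlations)
  invisible(x)
}

#' Repeat regression sampling and keep the least-biased draw
#'
#' Mirrors the dataset-design procedure of repeating the sampling with
#' different seeds and keeping the dataset with the lowest observed
#' element correlations.
#'
#' @inheritParams sample_regression
#' @param truths named list of `atom_truth` for the pool.
#' @param n_trials number of seeds tried (derived from `plan$seed`).
#' @return the selected `mol_dataset`, with attributes `audit` (its
#'   [audit_bias()] result) and `trial_max_r` (max |r| per trial).
#' @export
sample_regression_min_bias <- function(pool, plan, truths, n_trials = 5) {
  trials <- lapply(seq_len(n_trials), function(k) {
    p <- plan
    p$seed <- plan$seed + (k - 1L) * 1000L
    ds <- sample_regression(pool, p)
    audit <- audit_bias(ds, truths)
    max_r <- suppressWarnings(max(abs(audit$correlations$r), na.rm = TRUE))
    list(ds = ds, audit = audit, max_r = max_r)
  })
  max_rs <- vapply(trials, `[[`, numeric(1), "max_r")
  best <- trials[[which.min(max_rs)]]
  ds <- best$ds
  attr(ds, "audit") <- best$audit
  attr(ds, "trial_max_r") <- max_rs
  ds
}

# evaluate `expr` under a private RNG state; global .Random.seed restored
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
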