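# Predictive-performance and interpretation-quality metrics.
#
# Interpretation metrics are per-molecule ranking scores against the
# ground-truth expected contributions: AUC+/AUC- (label-rewritten ranking
# AUC with midrank tie handling), top-n / bottom-n, per-molecule
# contribution RMSE, top-k percentages and the fragment top-2 score.

#' Prediction set
#'
#' @param y_obs observed values (numeric, or `"active"`/`"inactive"`).
#' @param y_pred predictions: numbers for regression; labels or
#'   active-class probabilities for classification.
#' @param task `"regression"` or `"classification"`.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(y_obs, y_pred,
                           task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 1)
  structure(list(y_obs = y_obs, y_pred = y_pred, task = task),
            class = "prediction_set")
}

#' Predictive scores
#'
#' Regression: `Q2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`
#' and `RMSE = sqrt(mean((pred - obs)^2))`.  Classification (active =
#' positive class): sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`
#' and balanced accuracy (their mean); probability predictions are
#' thresholded at 0.5.
#'
#' @param p a [prediction_set()].
#' @return named list of scores (plus `confusion` for classification).
#'   `Q2` is `NA` when the observed values have zero variance.
#' @export
predictive_scores <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  if (p$task == "regression") {
    obs <- as.numeric(p$y_obs)
    pred <- as.numeric(p$y_pred)
    ss_res <- sum((pred - obs)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    q2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
    return(list(Q2 = q2, RMSE = sqrt(mean((pred - obs)^2))))
  }
  obs <- as.character(p$y_obs)
  pred <- if (is.numeric(p$y_pred)) {
    ifelse(p$y_pred >= 0.5, "active", "inactive")
  } else {
    as.character(p$y_pred)
  }
  tp <- sum(pred == "active" & obs == "active")
  fn <- sum(pred != "active" & obs == "active")
  tn <- sum(pred == "inactive" & obs == "inactive")
  fp <- sum(pred != "inactive" & obs == "inactive")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       confusion = c(TP = tp, TN = tn, FP = fp, FN = fn))
}

# midrank ranking AUC of scores against binary labels
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-molecule ranking AUC of contributions
#'
#' For `sign = "positive"` all atoms with expected contribution > 0 are
#' labeled 1 and every other atom (including negative ones) 0; the AUC
#' measures how high positive atoms rank by calculated contribution.  For
#' `sign = "negative"` atoms with expected < 0 are labeled 1, all others
#' 0, and contributions are ranked ascending (most negative on top).
#' Ties contribute 0.5 (midrank).  `NA` when the molecule has no atoms of
#' the requested sign.
#'
#' @param contrib an atom-level `contrib_vector`.
#' @param truth the molecule's `atom_truth`.
#' @param sign `"positive"` or `"negative"`.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
molecule_auc <- function(contrib, truth, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(contrib$level == "atom",
            length(contrib$contributions) == length(truth$expected))
  labels <- as.integer(if (sign == "positive") truth$expected > 0 else
    truth$expected < 0)
  scores <- if (sign == "positive") contrib$contributions else
    -contrib$contributions
  if (anyNA(scores)) return(NA_real_)
  rank_auc(scores, labels)
}

#' Dataset-level mean AUC
#'
#' Unweighted mean of [molecule_auc()] over molecules for which it is
#' defined; molecules without atoms of the requested sign are excluded
#' and counted.
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @param sign `"positive"` or `"negative"`.
#' @return list with `mean_auc` (`NA` if no molecule qualifies) and
#'   `n_excluded`.
#' @export
dataset_auc <- function(contribs, truths, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  aucs <- vapply(names(contribs), function(id)
    molecule_auc(contribs[[id]], truths[[id]], sign), numeric(1))
  list(mean_auc = if (all(is.na(aucs))) NA_real_ else
    mean(aucs, na.rm = TRUE),
    n_excluded = sum(is.na(aucs)))
}

# deterministic atom ranking: contribution (desc for top / asc for
# bottom), atom index ascending as tie break
ranked_atoms <- function(contrib, bottom = FALSE) {
  x <- if (bottom) contrib$contributions else -contrib$contributions
  order(x, seq_along(x))
}

# number of true atoms among the first k ranked atoms; tie_mode
# "expected" replaces the index tie break by the expected count over
# random tie orders (hypergeometric mean within the tied block)
count_in_top <- function(contrib, true_idx, k, bottom = FALSE,
                         tie_mode = "index") {
  a <- length(contrib$contributions)
  k <- min(k, a)
  if (k == 0 || length(true_idx) == 0) return(0)
  if (tie_mode == "index") {
    sel <- ranked_atoms(contrib, bottom)[seq_len(k)]
    return(sum(sel %in% true_idx))
  }
  x <- if (bottom) contrib$contributions else -contrib$contributions
  ord <- order(x)
  thresh <- x[ord[k]]
  strict <- which(x < thresh)
  tied <- which(x == thresh)
  slots <- k - length(strict)
  sum(strict %in% true_idx) +
    slots * sum(tied %in% true_idx) / length(tied)
}

#' Top-n / bottom-n score
#'
#' `score = sum(m_i) / sum(n_i)` where `n_i` is the number of true
#' positive atoms of molecule i (negative, for `direction = "bottom"`)
#' and `m_i` how many of them appear among its `n_i` highest-ranked
#' (lowest, for bottom) calculated contributions.  Molecules with
#' `n_i = 0` contribute nothing.  Ties are broken deterministically by
#' atom index (`tie_mode = "expected"` instead averages over random tie
#' orders).
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @param direction `"top"` (positive atoms) or `"bottom"` (negative).
#' @param tie_mode `"index"` or `"expected"`.
#' @return score in `[0, 1]`, or `NA` when no molecule has true atoms.
#' @export
top_n_score <- function(contribs, truths, direction = c("top", "bottom"),
                        tie_mode = c("index", "expected")) {
  direction <- match.arg(direction)
  tie_mode <- match.arg(tie_mode)
  bottom <- direction == "bottom"
  m_sum <- 0
  n_sum <- 0
  for (id in names(contribs)) {
    truth <- truths[[id]]
    true_idx <- if (bottom) truth$negative else truth$positive
    n_i <- length(true_idx)
    if (n_i == 0) next
    if (anyNA(contribs[[id]]$contributions)) next
    m_sum <- m_sum + count_in_top(contribs[[id]], true_idx, n_i, bottom,
                                  tie_mode)
    n_sum <- n_sum + n_i
  }
  if (n_sum == 0) return(NA_real_)
  m_sum / n_sum
}

#' Contribution RMSE
#'
#' Per-molecule root mean square error of calculated vs expected
#' contributions over all heavy atoms, and its unweighted mean over all
#' molecules (pattern-free molecules included — their expected vector is
#' all zero).
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @return list with `per_molecule` (named vector) and `mean`.
#' @export
contribution_rmse <- function(contribs, truths) {
  per <- vapply(names(contribs), function(id) {
    ct <- contribs[[id]]
    tr <- truths[[id]]
    if (length(ct$contributions) != length(tr$expected)) {
      stop("contribution/truth length mismatch for ", id)
    }
    sqrt(mean((ct$contributions - tr$expected)^2))
  }, numeric(1))
  list(per_molecule = per, mean = mean(per))
}

#' Percentage of true atoms found in the top k
#'
#' For each molecule with at least one positive atom, the fraction of its
#' positive atoms among the `k` highest-ranked contributions (all atoms
#' when `k` exceeds the heavy-atom count); averaged and expressed as a
#' percentage.
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @param k number of top atoms considered (2, 3 or 5 in the reports).
#' @param tie_mode see [top_n_score()].
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
topk_percentage <- function(contribs, truths, k,
                            tie_mode = c("index", "expected")) {
  tie_mode <- match.arg(tie_mode)
  fracs <- c()
  for (id in names(contribs)) {
    true_idx <- truths[[id]]$positive
    if (length(true_idx) == 0) next
    if (anyNA(contribs[[id]]$contributions)) next
    m <- count_in_top(contribs[[id]], true_idx, k, FALSE, tie_mode)
    fracs <- c(fracs, m / length(true_idx))
  }
  if (length(fracs) == 0) return(NA_real_)
  100 * mean(fracs)
}

#' Fragment top-2 score
#'
#' For molecules with exactly two true (positive) atoms: the two
#' highest-contribution fragments are selected and the molecule scores 1
#' if their atom union covers both true centers, 0.5 if one, 0 if none;
#' scores are averaged.  Molecules with fewer than two fragments are
#' scored with whatever fragments they have; molecules without exactly
#' two positive atoms are skipped and counted.
#'
#' @param frag_contribs named list of fragment-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @return list with `score` and `n_skipped`.
#' @export
fragment_top2 <- function(frag_contribs, truths) {
  scores <- c()
  n_skipped <- 0
  for (id in names(frag_contribs)) {
    ct <- frag_contribs[[id]]
    true_idx <- truths[[id]]$positive
    if (length(true_idx) != 2) {
      n_skipped <- n_skipped + 1
      next
    }
    if (length(ct$targets) == 0) {
      scores <- c(scores, 0)
      next
    }
    ord <- order(-ct$contributions,
                 vapply(ct$targets, min, numeric(1)))
    sel <- ord[seq_len(min(2, length(ord)))]
    covered <- unique(unlist(ct$targets[sel]))
    scores <- c(scores, sum(true_idx %in% covered) / 2)
  }
  list(score = if (length(scores)) mean(scores) else NA_real_,
       n_skipped = n_skipped)
}

#' Interpretation metrics stratified by true-pattern count
#'
#' Mean AUC+, top-n and mean contribution RMSE within each subset of
#' molecules having exactly `c` true patterns (c = 0..`max_count`), plus
#' an `"All"` row reproducing the unstratified metrics.
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @param counts named integer vector of true-pattern counts per molecule
#'   (e.g. amide match counts).
#' @param max_count largest stratified count (default 6).
#' @return data.frame with columns count, n_molecules, mean_auc_pos,
#'   top_n, mean_rmse (`NA` for empty/undefined cells).
#' @export
breakdown_by_pattern_count <- function(contribs, truths, counts,
                                       max_count = 6) {
  counts <- counts[names(contribs)]
  one_row <- function(ids, label) {
    if (length(ids) == 0) {
      return(data.frame(count = label, n_molecules = 0,
                        mean_auc_pos = NA_real_, top_n = NA_real_,
                        mean_rmse = NA_real_))
    }
    cc <- contribs[ids]
    tt <- truths[ids]
    data.frame(count = label, n_molecules = length(ids),
               mean_auc_pos = dataset_auc(cc, tt, "positive")$mean_auc,
               top_n = top_n_score(cc, tt, "top"),
               mean_rmse = contribution_rmse(cc, tt)$mean)
  }
  rows <- list(one_row(names(contribs), "All"))
  for (cval in 0:max_count) {
    ids <- names(contribs)[!is.na(counts) & counts == cval]
    rows[[length(rows) + 1L]] <- one_row(ids, as.character(cval))
  }
  do.call(rbind, rows)
}

#' Dataset-level interpretation report
#'
#' Aggregates all interpretation-quality metrics for one dataset/model
#' pair: mean AUC+/AUC- (with exclusion counts), top-n and bottom-n,
#' mean contribution RMSE, and top-k percentages for k = 2, 3, 5.
#'
#' @param contribs named list of atom-level `contrib_vector`.
#' @param truths named list of `atom_truth`.
#' @param frag_contribs optional fragment-level contributions for the
#'   fragment top-2 score.
#' @return object of class `interpretation_report` (a list of metric
#'   values).
#' @export
interpretation_report <- function(contribs, truths, frag_contribs = NULL) {
  pos <- dataset_auc(contribs, truths, "positive")
  neg <- dataset_auc(contribs, truths, "negative")
  rep <- list(
    n_molecules = length(contribs),
    mean_auc_pos = pos$mean_auc, n_excluded_auc_pos = pos$n_excluded,
    mean_auc_neg = neg$mean_auc, n_excluded_auc_neg = neg$n_excluded,
    top_n = top_n_score(contribs, truths, "top"),
    bottom_n = top_n_score(contribs, truths, "bottom"),
    mean_rmse = contribution_rmse(contribs, truths)$mean,
    topk_pct = stats::setNames(
      vapply(c(2, 3, 5), function(k)
        topk_percentage(contribs, truths, k), numeric(1)),
      c("top2", "top3", "top5")))
  if (!is.null(frag_contribs)) {
    ft <- fragment_top2(frag_contribs, truths)
    rep$fragment_top2 <- ft$score
    rep$fragment_top2_n_skipped <- ft$n_skipped
  }
  structure(rep, class = "interpretation_report")
}

#' @export
print.interpretation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("<interpretation_report>", x$n_molecules, "molecules\n")
  cat("  mean AUC+ :", fmt(x$mean_auc_pos),
      sprintf("(%d excluded)", x$n_excluded_auc_pos), "\n")
  cat("  mean AUC- :", fmt(x$mean_auc_neg),
      sprintf("(%d excluded)", x$n_excluded_auc_neg), "\n")
  cat("  top-n     :", fmt(x$top_n), "  bottom-n :", fmt(x$bottom_n), "\n")
  cat("  mean RMSE :", fmt(x$mean_rmse), "\n")
  cat("  top-k %   :", paste(names(x$topk_pct),
                             vapply(x$topk_pct, fmt, character(1)),
                             sep = "=", collapse = "  "), "\n")
  if (!is.null(x$fragment_top2)) {
    cat("  fragment top-2 :", fmt(x$fragment_top2), "\n")
  }
  invisible(x)
}
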