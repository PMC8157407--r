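# Interpretation-quality and predictive metrics against closed forms and
# independent brute-force oracles.

test_that("predictive_scores matches hand-computed regression values", {
  # perfect prediction
  p <- prediction_set(c(1, 2, 3), c(1, 2, 3), "regression")
  s <- predictive_scores(p)
  expect_equal(s$Q2, 1)
  expect_equal(s$RMSE, 0)

  # hand-made 6-point table: obs mean = 3.5
  obs <- c(1, 2, 3, 4, 5, 6)
  pred <- c(1.5, 1.5, 3.5, 3.5, 5.5, 5.5)
  s <- predictive_scores(prediction_set(obs, pred, "regression"))
  ss_res <- sum((pred - obs)^2)              # 6 * 0.25 = 1.5
  expect_equal(s$RMSE, sqrt(ss_res / 6))
  expect_equal(s$Q2, 1 - ss_res / sum((obs - 3.5)^2))

  # zero-variance observations: Q2 undefined, not an error
  s <- predictive_scores(prediction_set(c(2, 2, 2), c(1, 2, 3),
                                        "regression"))
  expect_true(is.na(s$Q2))
})

test_that("predictive_scores classification follows the confusion counts", {
  obs <- c("active", "active", "inactive", "inactive", "inactive",
           "inactive")
  pred <- c("active", "active", "active", "inactive", "inactive",
            "inactive")
  s <- predictive_scores(prediction_set(obs, pred, "classification"))
  expect_equal(s$sensitivity, 1.0)
  expect_equal(s$specificity, 0.75)
  expect_equal(s$balanced_accuracy, 0.875)
  expect_equal(unname(s$confusion), c(2, 3, 1, 0))  # TP TN FP FN

  # sensitivity 1, specificity 0.5 -> balanced accuracy 0.75
  s <- predictive_scores(prediction_set(
    c("active", "inactive", "inactive"),
    c("active", "active", "inactive"), "classification"))
  expect_equal(s$balanced_accuracy, 0.75)

  # probability predictions threshold at 0.5
  s <- predictive_scores(prediction_set(
    c("active", "inactive"), c(0.9, 0.2), "classification"))
  expect_equal(s$balanced_accuracy, 1.0)
})

test_that("molecule_auc handles the worked examples and sign rewriting", {
  # perfect ranking of positives
  expect_equal(molecule_auc(make_contrib(c(0.9, 0.1, 0.8)),
                            make_truth(c(1, 0, 1))), 1.0)
  # inverted ranking
  expect_equal(molecule_auc(make_contrib(c(0.1, 0.9)),
                            make_truth(c(1, 0))), 0.0)
  # no atoms of the requested sign -> undefined
  expect_true(is.na(molecule_auc(make_contrib(c(0.1, 0.9)),
                                 make_truth(c(0, 0)))))
  # AUC-: negative atoms labeled 1, ranked ascending
  ct <- make_contrib(c(-0.9, 0.5, -0.1))
  tr <- make_truth(c(-1, 0, 0))
  expect_equal(molecule_auc(ct, tr, "negative"), 1.0)
  # AUC+ on a mixed-sign truth sets negative labels to 0
  ct <- make_contrib(c(0.9, -0.8, 0.1))
  tr <- make_truth(c(1, -1, 0))
  expect_equal(molecule_auc(ct, tr, "positive"), 1.0)
})

test_that("molecule_auc and top_n_score match brute-force oracles on 1000
           random instances", {
  set.seed(42)
  for (rep in 1:1000) {
    a <- sample(3:20, 1)
    # coarse grid of values forces plenty of ties
    contrib <- sample(seq(-1, 1, by = 0.25), a, replace = TRUE)
    expected <- sample(c(-1, 0, 1), a, replace = TRUE)
    ct <- make_contrib(contrib)
    tr <- make_truth(expected)
    expect_identical(molecule_auc(ct, tr, "positive"),
                     oracle_auc(contrib, as.integer(expected > 0)))
    expect_identical(molecule_auc(ct, tr, "negative"),
                     oracle_auc(-contrib, as.integer(expected < 0)))
  }
  # top-n over random multi-molecule datasets (tie break: atom index)
  for (rep in 1:200) {
    nmol <- sample(1:5, 1)
    contribs <- list()
    truths <- list()
    cvec <- list()
    tvec <- list()
    for (i in seq_len(nmol)) {
      a <- sample(2:15, 1)
      x <- sample(seq(0, 1, by = 0.2), a, replace = TRUE)
      e <- sample(c(0, 1), a, replace = TRUE)
      id <- paste0("m", i)
      contribs[[id]] <- make_contrib(x, id)
      truths[[id]] <- make_truth(e, id)
      cvec[[i]] <- x
      tvec[[i]] <- which(e > 0)
    }
    expect_identical(top_n_score(contribs, truths),
                     oracle_top_n(cvec, tvec))
  }
})

test_that("top_n_score implements the sum(m)/sum(n) pooling", {
  # the worked example: two positive atoms, one retrieved in top 2
  ct <- make_contrib(c(0.9, 0.05, 0.5, 0.2))
  tr <- make_truth(c(1, 1, 0, 0))
  expect_equal(top_n_score(list(m = ct), list(m = tr)), 0.5)
  # perfect contributions give 1
  ct2 <- make_contrib(c(1, 1, 0, 0))
  expect_equal(top_n_score(list(m = ct2), list(m = tr)), 1.0)
  # pooling, not averaging: m=(1,2), n=(2,2) -> 3/4 (average would be .75
  # here too, so use asymmetric n): n=(2,1), m=(1,1) -> 2/3
  ct3 <- make_contrib(c(0.9, 0.1), "m2")
  tr3 <- make_truth(c(1, 0), "m2")
  expect_equal(top_n_score(list(m = ct, m2 = ct3),
                           list(m = tr, m2 = tr3)), 2 / 3)
  # bottom-n ranks ascending against negative atoms
  ctn <- make_contrib(c(-0.9, 0.3, -0.2))
  trn <- make_truth(c(-1, 0, -1))
  expect_equal(top_n_score(list(m = ctn), list(m = trn), "bottom"), 1.0)
  # no true atoms anywhere -> undefined
  expect_true(is.na(top_n_score(list(m = ct), list(m = make_truth(c(0, 0, 0, 0))))))
})

test_that("tie handling: deterministic index tie-break and expected mode", {
  # two tied atoms straddling the cutoff; true atom has the higher index
  ct <- make_contrib(c(0.5, 0.5, 0.1))
  tr <- make_truth(c(0, 1, 0))   # n_i = 1, top-1 by index tie-break = atom 1
  expect_equal(top_n_score(list(m = ct), list(m = tr)), 0.0)
  # expected-value mode: one slot, one of two tied atoms is true -> 0.5
  expect_equal(top_n_score(list(m = ct), list(m = tr),
                           tie_mode = "expected"), 0.5)
})

test_that("contribution_rmse averages per-molecule RMSE over all molecules", {
  ct1 <- make_contrib(c(0, 0), "a")
  tr1 <- make_truth(c(1, 1), "a")
  ct2 <- make_contrib(c(0.5, 0.5, 0.5), "b")
  tr2 <- make_truth(c(0, 0, 0), "b")
  r <- contribution_rmse(list(a = ct1, b = ct2), list(a = tr1, b = tr2))
  expect_equal(unname(r$per_molecule), c(1.0, 0.5))
  expect_equal(r$mean, 0.75)
  # pattern-free molecules are included (no exclusion for RMSE)
  expect_equal(contribution_rmse(list(b = ct2), list(b = tr2))$mean, 0.5)
  # exact match -> 0
  expect_equal(contribution_rmse(list(a = make_contrib(c(1, 1), "a")),
                                 list(a = tr1))$mean, 0)
  # length mismatch is fatal
  expect_error(contribution_rmse(list(a = make_contrib(c(1, 1, 1), "a")),
                                 list(a = tr1)), "mismatch")
})

test_that("topk_percentage matches a brute-force count and is monotone in k", {
  set.seed(7)
  for (rep in 1:50) {
    a <- sample(4:15, 1)
    x <- sample(seq(0, 1, by = 0.1), a, replace = TRUE)
    e <- numeric(a)
    e[sample(a, 2)] <- 1
    ct <- list(m = make_contrib(x))
    tr <- list(m = make_truth(e))
    pcts <- vapply(c(2, 3, 5), function(k)
      topk_percentage(ct, tr, k), numeric(1))
    expect_true(all(diff(pcts) >= -1e-12))
    # brute force at k = 3
    ord <- order(-x, seq_along(x))
    m <- sum(ord[seq_len(min(3, a))] %in% which(e > 0))
    expect_equal(pcts[2], 100 * m / 2)
  }
  # both true centers in top 2 -> 100% for the molecule
  ct <- list(m = make_contrib(c(0.9, 0.8, 0.1, 0)))
  tr <- list(m = make_truth(c(1, 1, 0, 0)))
  expect_equal(topk_percentage(ct, tr, 2), 100)
  # k beyond the atom count uses all atoms (fraction 1)
  expect_equal(topk_percentage(ct, tr, 5), 100)
})

test_that("top-2 percentage equals top-n x 100 when every molecule has
           exactly 2 positive atoms", {
  set.seed(11)
  contribs <- list()
  truths <- list()
  for (i in 1:30) {
    a <- sample(5:12, 1)
    e <- numeric(a)
    e[sample(a, 2)] <- 1
    id <- paste0("m", i)
    contribs[[id]] <- make_contrib(stats::runif(a), id)
    truths[[id]] <- make_truth(e, id)
  }
  expect_equal(topk_percentage(contribs, truths, 2),
               100 * top_n_score(contribs, truths))
})

test_that("dataset_auc averages defined molecules and counts exclusions", {
  ct1 <- make_contrib(c(0.9, 0.1), "a")
  tr1 <- make_truth(c(1, 0), "a")          # AUC 1
  ct2 <- make_contrib(c(0.4, 0.6), "b")
  tr2 <- make_truth(c(1, 0), "b")          # AUC 0
  ct3 <- make_contrib(c(0.5, 0.5), "c")
  tr3 <- make_truth(c(0, 0), "c")          # no positives -> excluded
  r <- dataset_auc(list(a = ct1, b = ct2, c = ct3),
                   list(a = tr1, b = tr2, c = tr3))
  expect_equal(r$mean_auc, 0.5)
  expect_equal(r$n_excluded, 1)
  # single molecule
  r1 <- dataset_auc(list(a = ct1), list(a = tr1))
  expect_equal(r1$mean_auc, 1.0)
  # all undefined
  r0 <- dataset_auc(list(c = ct3), list(c = tr3))
  expect_true(is.na(r0$mean_auc))
  expect_equal(r0$n_excluded, 1)
})

test_that("fragment_top2 scores 1 / 0.5 / 0 by covered true centers", {
  tr <- list(m = make_truth(c(1, 0, 0, 0, 1), "m"))
  frag <- function(contribs, targets) {
    list(m = new_contrib_vector("m", "fragment", targets, contribs, 0.9))
  }
  # two top fragments jointly cover both centers
  f <- frag(c(0.8, 0.7, 0.1), list(c(1, 2), c(4, 5), 3))
  expect_equal(fragment_top2(f, tr)$score, 1)
  # cover exactly one
  f <- frag(c(0.8, 0.7, 0.1), list(c(1, 2), c(3, 4), c(4, 5)))
  expect_equal(fragment_top2(f, tr)$score, 0.5)
  # cover none
  f <- frag(c(0.8, 0.7, 0.1), list(c(2, 3), c(3, 4), c(1, 5)))
  expect_equal(fragment_top2(f, tr)$score, 0)
  # fewer than 2 fragments: scored with what is available
  f <- frag(0.5, list(c(1, 5)))
  expect_equal(fragment_top2(f, tr)$score, 1)
  # molecules without exactly two positive atoms are skipped
  r <- fragment_top2(frag(c(0.8), list(c(1, 2))),
                     list(m = make_truth(c(1, 0, 0, 0, 0), "m")))
  expect_true(is.na(r$score))
  expect_equal(r$n_skipped, 1)
})

test_that("breakdown_by_pattern_count stratifies and reproduces global rows", {
  set.seed(3)
  contribs <- list()
  truths <- list()
  counts <- c()
  for (i in 1:20) {
    a <- 8
    cnt <- sample(1:2, 1)
    e <- numeric(a)
    e[sample(a, 3 * cnt)] <- 1
    id <- paste0("m", i)
    contribs[[id]] <- make_contrib(stats::runif(a), id)
    truths[[id]] <- make_truth(e, id)
    counts[id] <- cnt
  }
  bd <- breakdown_by_pattern_count(contribs, truths, counts, max_count = 3)
  all_row <- bd[bd$count == "All", ]
  expect_equal(all_row$mean_auc_pos,
               dataset_auc(contribs, truths)$mean_auc)
  expect_equal(all_row$top_n, top_n_score(contribs, truths))
  expect_equal(all_row$mean_rmse, contribution_rmse(contribs, truths)$mean)
  # empty subset -> NA row
  expect_true(is.na(bd$top_n[bd$count == "3"]))
  # single-count dataset: populated row equals global metrics
  one <- names(counts)[counts == 1]
  bd1 <- breakdown_by_pattern_count(contribs[one], truths[one],
                                    counts[one], max_count = 2)
  expect_equal(bd1$top_n[bd1$count == "1"],
               bd1$top_n[bd1$count == "All"])
})

test_that("interpretation_report aggregates all metrics coherently", {
  ct <- list(a = make_contrib(c(0.9, 0.1, -0.5), "a"),
             b = make_contrib(c(0.2, 0.8, 0.1), "b"))
  tr <- list(a = make_truth(c(1, 0, -1), "a"),
             b = make_truth(c(0, 1, 0), "b"))
  rep <- interpretation_report(ct, tr)
  expect_s3_class(rep, "interpretation_report")
  expect_equal(rep$mean_auc_pos, 1.0)
  expect_equal(rep$top_n, 1.0)
  expect_equal(rep$n_excluded_auc_neg, 1)  # molecule b has no negatives
  expect_true(all(rep$topk_pct >= 0 & rep$topk_pct <= 100))
  expect_output(print(rep), "mean AUC")
})
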