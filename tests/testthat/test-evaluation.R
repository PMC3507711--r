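test_that("exact divisibility deals one of each class per fold", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(0, 100))),
    list(name = "cls", kind = "nominal", labels = c("a", "b", "c")))
  d <- patient_table(tibble::tibble(x = 1:30,
    cls = rep(c("a", "b", "c"), each = 10)), sch)
  plan <- make_stratified_folds(d, n_folds = 10, seed = 1)
  per <- table(plan$fold, d$cls[match(plan$.row_id, d$.row_id)])
  expect_true(all(per == 1))
})

test_that("the 399/551/149 cohort stratifies within one row per fold", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(0, 2000))),
    list(name = "cls", kind = "nominal", labels = c("low", "medium", "high")))
  d <- patient_table(tibble::tibble(x = seq_len(1099),
    cls = rep(c("low", "medium", "high"), c(399, 551, 149))), sch)
  plan <- make_stratified_folds(d, n_folds = 10, repeats = 3, seed = 2)
  for (r in 1:3) {
    pr <- plan[plan$repeat_id == r, ]
    per <- table(pr$fold, d$cls[match(pr$.row_id, d$.row_id)])
    expect_true(all(per[, "low"] %in% 39:40))
    expect_true(all(per[, "medium"] %in% 55:56))
    expect_true(all(per[, "high"] %in% 14:15))
    # folds partition the rows
    expect_setequal(pr$.row_id, d$.row_id)
  }
  # same seed, same plan
  plan2 <- make_stratified_folds(d, n_folds = 10, repeats = 3, seed = 2)
  expect_identical(as.data.frame(plan), as.data.frame(plan2))
  # a class smaller than n_folds is rejected
  small <- patient_table(tibble::tibble(x = 1:12,
    cls = c(rep("low", 5), rep("medium", 4), rep("high", 3))), sch)
  expect_error(make_stratified_folds(small, n_folds = 5),
    class = "pcatree_cv_error")
})

test_that("Table 2/3-style multiclass metrics follow the cell formulas", {
  m <- matrix(1:9, 3, 3, byrow = TRUE,
    dimnames = list(c("low", "medium", "high"), c("low", "medium", "high")))
  mm <- multiclass_metrics(m)
  expect_equal(mm$per_class$sensitivity[1], 1 / 12)  # a/(a+d+g)
  expect_equal(mm$per_class$precision[1], 1 / 6)     # a/(a+b+c)
  expect_equal(mm$accuracy, (1 + 5 + 9) / 45)

  perfect <- diag(c(5, 7, 9))
  colnames(perfect) <- rownames(perfect) <- c("low", "medium", "high")
  mp <- multiclass_metrics(perfect)
  expect_true(all(mp$per_class$sensitivity == 1))
  expect_true(all(mp$per_class$precision == 1))
  expect_equal(mp$accuracy, 1)

  # label permutation permutes the metrics consistently
  perm <- c(2, 3, 1)
  mper <- multiclass_metrics(m[perm, perm])
  expect_equal(mper$per_class$sensitivity,
    mm$per_class$sensitivity[perm])
  expect_equal(mper$per_class$precision, mm$per_class$precision[perm])
})

test_that("binary metrics follow the Table 6 formulas including degeneracies", {
  m <- matrix(c(10, 10, 10, 10), 2, 2,
    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  bm <- binary_metrics(m, positive = "pos")
  expect_equal(bm$TPR, 0.5)
  expect_equal(bm$precision, 0.5)
  expect_equal(bm$f_score, 0.5)  # harmonic mean of equals

  z <- matrix(c(0, 0, 5, 15), 2, 2, byrow = TRUE,
    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  bz <- binary_metrics(z, positive = "pos")
  expect_equal(bz$TP, 0L)
  expect_equal(bz$f_score, 0)
  expect_true(bz$f_score_undefined || bz$f_score == 0)

  # direct formula evaluation at the printed-table operating point
  tpr <- 0.415; prec <- 0.275
  expect_equal(2 * tpr * prec / (tpr + prec), 0.3308, tolerance = 5e-5)
})

test_that("metric functions agree with spreadsheet-style recomputation", {
  set.seed(19)
  for (i in 1:300) {
    m <- matrix(rpois(9, 8), 3, 3,
      dimnames = list(c("l", "m", "h"), c("l", "m", "h")))
    mm <- multiclass_metrics(m)
    for (j in 1:3) {
      den_s <- sum(m[, j]); den_p <- sum(m[j, ])
      expect_equal(mm$per_class$sensitivity[j],
        if (den_s == 0) 0 else m[j, j] / den_s)
      expect_equal(mm$per_class$precision[j],
        if (den_p == 0) 0 else m[j, j] / den_p)
    }
    expect_equal(mm$accuracy, sum(diag(m)) / sum(m))
  }
  for (i in 1:300) {
    b <- matrix(rpois(4, 6), 2, 2,
      dimnames = list(c("pos", "neg"), c("pos", "neg")))
    bm <- binary_metrics(b, positive = "pos")
    TP <- b[1, 1]; FP <- b[1, 2]; FN <- b[2, 1]; TN <- b[2, 2]
    tpr <- if (TP + FN == 0) 0 else TP / (TP + FN)
    fpr <- if (FP + TN == 0) 0 else FP / (FP + TN)
    prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
    f <- if (tpr + prec == 0) 0 else 2 * tpr * prec / (tpr + prec)
    expect_equal(bm$TPR, tpr); expect_equal(bm$FPR, fpr)
    expect_equal(bm$precision, prec); expect_equal(bm$f_score, f)
  }
})

test_that("a constant-majority predictor shows why accuracy misleads at 81:19", {
  d <- gen_scenario2d("sparse", 81, 19, seed = 12)
  plan <- make_stratified_folds(d, n_folds = 5, seed = 3)
  cv <- run_cv(d, list(learner = constant_learner("majority")), plan, seed = 1)
  per <- tidy(cv, positive = "minority")
  expect_equal(mean(per$accuracy), 0.81, tolerance = 0.02)
  expect_equal(mean(per$TPR), 0)
  expect_equal(mean(per$f_score), 0)
})

test_that("repeated CV returns one result per repeat x fold and never leaks", {
  d <- gen_scenario2d("sparse", 60, 20, seed = 8)
  plan <- make_stratified_folds(d, n_folds = 4, repeats = 3, seed = 5)
  cv <- run_cv(d, list(
    learner = learner_tree(),
    cleaning = list(k = 3, minority_label = "minority"),
    sampling = "under"), plan, seed = 2)
  expect_equal(nrow(cv$folds), 12L)
  # leakage audit: no test row id ever appears in its training table
  for (i in seq_len(nrow(cv$folds))) {
    expect_length(intersect(cv$folds$train_ids[[i]], cv$folds$test_ids[[i]]), 0L)
  }
  # pooled counts cover every row once per repeat
  expect_equal(sum(cv$pooled), nrow(d) * 3)
  # test folds keep the original distribution: per-fold column sums match plan
  cm1 <- cv$folds$confusion[[1]]
  expect_equal(sum(cm1), cv$folds$n_test[[1]])
})

test_that("in-pipeline discretization fits on training folds only", {
  coh <- gen_pca_cohort(n_patients = 200, seed = 33)
  dz0 <- fit_equal_deviation_intervals(coh$total_dose_72h, 3)
  strat <- apply_discretization(dz0, coh$total_dose_72h)
  plan <- make_stratified_folds(coh, n_folds = 4, seed = 7, class = strat)
  cv <- run_cv(coh, list(
    discretize = list(K = 3),
    learner = learner_tree()), plan, seed = 3)
  expect_equal(nrow(cv$folds), 4L)
  expect_equal(sort(cv$labels), sort(c("low", "medium", "high")))
  for (i in 1:4) {
    expect_length(intersect(cv$folds$train_ids[[i]], cv$folds$test_ids[[i]]), 0L)
  }
  # continuous target without a discretizer stage is refused
  expect_error(run_cv(coh, list(learner = learner_tree()), plan),
    class = "pcatree_cv_error")
})

test_that("paired t-tests match closed forms and the Bonferroni cap", {
  same <- paired_t_bonferroni(c(1, 2, 3), list(x = c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p_adjusted, 1)

  tt <- paired_t_bonferroni(c(1, 2, 3, 4, 5), list(z = rep(0, 5)))
  expect_equal(tt$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$t, 4.2426, tolerance = 1e-4)
  expect_equal(tt$df, 4)

  # seven comparisons at raw p = 0.2 cap at 1
  set.seed(2)
  base <- rnorm(10)
  others <- replicate(7, base + rnorm(10, 0, 1), simplify = FALSE)
  res <- paired_t_bonferroni(base, others)
  expect_true(all(res$p_adjusted <= 1))
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 7))

  # degenerate exact win
  win <- paired_t_bonferroni(c(2, 2, 2), list(w = c(1, 1, 1)))
  expect_equal(win$p_value, 0)
  expect_true(is.infinite(win$t))
})
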