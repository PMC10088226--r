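test_that("metrics match hand-computed one-vs-rest values", {
  cm <- confusion_matrix(c(rep(0, 4), rep(1, 6)),
                         c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1))
  # counts [[3,1],[2,4]]
  rep_ <- metrics_report(cm)
  expect_equal(rep_$accuracy, 0.7)
  expect_equal(rep_$per_class$sensitivity, c(3 / 4, 4 / 6))
  expect_equal(rep_$sensitivity, mean(c(3 / 4, 4 / 6)))
  expect_equal(rep_$per_class$precision, c(3 / 5, 4 / 5))
  expect_equal(rep_$f_score,
               2 * rep_$precision * rep_$sensitivity /
                 (rep_$precision + rep_$sensitivity))
})

test_that("perfect and single-class predictions hit the metric extremes", {
  y <- rep(0:2, each = 4)
  perfect <- metrics_report(confusion_matrix(y, y))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f_score, 1)

  all0 <- metrics_report(confusion_matrix(rep(0:1, 5), rep(0L, 10), 2))
  expect_equal(all0$per_class$specificity[1], 0)  # predicted class has SPC 0
})

test_that("metrics agree with a brute-force recount on random labelings", {
  set.seed(53)
  for (i in 1:100) {
    C <- sample(2:5, 1)
    n <- sample(20:60, 1)
    yt <- c(seq_len(C) - 1L, sample(0:(C - 1), n - C, replace = TRUE))
    yp <- sample(0:(C - 1), n, replace = TRUE)
    got <- metrics_report(confusion_matrix(yt, yp, C))
    want <- recount_metrics(yt, yp, C)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("a perfect scorer yields ROC AUC exactly 1", {
  y <- rep(0:2, each = 10)
  scores <- matrix(0, 30, 3)
  scores[cbind(seq_len(30), y + 1L)] <- 1
  roc <- multiclass_curves(scores, y, "ROC")
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$points$x[1], 0)
  expect_equal(roc$points$y[1], 0)
  expect_equal(tail(roc$points$x, 1), 1)
  expect_equal(tail(roc$points$y, 1), 1)
})

test_that("label-independent scores give chance-level AUCs", {
  set.seed(59)
  n <- 1000
  y <- rep(0:1, each = n / 2)
  scores <- matrix(runif(2 * n), n, 2)
  roc <- multiclass_curves(scores, y, "ROC")
  expect_gt(roc$auc, 0.45)
  expect_lt(roc$auc, 0.55)
  pr <- multiclass_curves(scores, y, "PR")
  expect_lt(abs(pr$auc - 0.5), 0.05)  # prevalence of each class is 0.5

  # unbalanced prevalence
  y2 <- c(rep(0L, 800), rep(1L, 200))
  s2 <- cbind(runif(n), runif(n))
  pr_un <- multiclass_curves(s2, y2, "PR")
  # macro over the two one-vs-rest prevalences 0.8 and 0.2
  expect_lt(abs(pr_un$auc - 0.5), 0.05)
})

test_that("absent classes are skipped with a warning", {
  y <- rep(0L, 10)
  y[1:5] <- 1L
  scores <- matrix(runif(30), 10, 3)
  expect_warning(multiclass_curves(scores, y, "ROC"), "absent")
})

test_that("wilcoxon exact p-values match enumeration landmarks", {
  out <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, 0.1)
  expect_equal(out$method, "exact")
  swapped <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$p_value, out$p_value)

  tied <- wilcoxon_rank_sum(c(2, 2, 2, 2), c(2, 2, 2, 2))
  expect_equal(tied$p_value, 1.0)
})

test_that("exact mode agrees with the reference distribution for n = 4 + 4", {
  # all ways of splitting ranks 1..8 into two groups of four
  splits <- combn(8, 4)
  for (i in seq_len(ncol(splits))) {
    a <- splits[, i]
    b <- setdiff(1:8, a)
    got <- wilcoxon_rank_sum(a, b)
    want <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p_value, want, info = paste(a, collapse = ","))
  }
})

test_that("run-set summaries reproduce boxplot statistics", {
  mk <- function(f, trace) structure(
    list(best = candidate_solution(1:3, f), trace = trace,
         objective_calls = 10L, seed = 1L), class = "search_result")
  runs <- lapply(seq(0.1, 0.9, by = 0.1), function(f) mk(f, c(f / 2, f)))
  s <- run_set_summary(runs)
  expect_equal(s$median, 0.5)
  expect_equal(s$mean_trace, c(0.25, 0.5))
  expect_false(is.unsorted(s$mean_trace))

  same <- run_set_summary(lapply(1:5, function(i) mk(0.7, c(0.6, 0.7))))
  expect_equal(same$q1, same$q3)
  expect_length(same$outliers, 0)
  expect_error(run_set_summary(list(mk(0.5, c(1, 2)), mk(0.5, 1))), "unequal")
})

test_that("cross-validated runs predict each sample exactly once, deterministically", {
  gen <- tiny_table(n = 50, d = 8, informative = 3, class_sep = 5,
                    missing_rate = 0.03, seed = 61)
  cfg <- trader_config(3, pop_size = 8, iterations = 3, n_groups = 2)
  run <- cross_validated_run(gen$table, cfg, ensemble_size = 2, seed = 19)
  expect_equal(sort(run$predictions$sample), 1:50)
  expect_equal(run$metrics$confusion$N, 50L)
  expect_setequal(run$predictions$fold, 1:5)
  run2 <- cross_validated_run(gen$table, cfg, ensemble_size = 2, seed = 19)
  expect_identical(run$predictions$predicted, run2$predictions$predicted)
  expect_identical(run$metrics$accuracy, run2$metrics$accuracy)
  # selection sees only training rows: every per-fold subset was chosen from
  # a table of 40 training samples; accuracy on near-separable data is high
  expect_gte(run$metrics$accuracy, 0.8)
})

test_that("optimizer comparison runs at matched budgets", {
  gen <- tiny_table(n = 40, d = 8, informative = 3, class_sep = 5, seed = 67)
  tab <- min_max_normalize(gen$table)$table
  cmp <- compare_optimizers(tab, trader_config(3, pop_size = 6, iterations = 2,
                                               n_groups = 2),
                            n_runs = 4, seed = 3)
  expect_equal(cmp$budget, 6 + 2 * ceiling(0.3 * 6))
  for (r in cmp$trader$runs) expect_equal(r$objective_calls, cmp$budget)
  for (r in cmp$baseline$runs) expect_equal(r$objective_calls, cmp$budget)
  expect_true(cmp$wilcoxon$p_value >= 0 && cmp$wilcoxon$p_value <= 1)
})
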