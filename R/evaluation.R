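#' Mean-based multiclass metrics from a confusion matrix
#'
#' One-vs-rest metrics per class: precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` (each 0 when its denominator is 0),
#' averaged unweighted over classes (macro). Accuracy is the pooled
#' `sum_i TP_i / N`; the F-score is the harmonic mean of the macro precision
#' and macro sensitivity.
#'
#' @param cm a [confusion_matrix()].
#' @param average `"macro"` (default) or `"micro"` for the per-class
#'   averaging of precision/sensitivity/specificity.
#' @return object of class `metrics_report`: `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f_score`, `per_class` (data.frame),
#'   `confusion`.
#' @export
metrics_report <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (cm$N == 0L) stop("empty confusion matrix")
  counts <- cm$counts
  C <- nrow(counts)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- cm$N - tp - fp - fn
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  per_class <- data.frame(
    class = seq_len(C) - 1L,
    precision = safe_div(tp, tp + fp),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp))
  if (average == "macro") {
    pre <- mean(per_class$precision)
    sen <- mean(per_class$sensitivity)
    spc <- mean(per_class$specificity)
  } else {
    pre <- safe_div(sum(tp), sum(tp + fp))
    sen <- safe_div(sum(tp), sum(tp + fn))
    spc <- safe_div(sum(tn), sum(tn + fp))
  }
  f <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  structure(list(accuracy = multiclass_accuracy(cm), precision = pre,
                 sensitivity = sen, specificity = spc, f_score = f,
                 per_class = per_class, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  PRE %.4f  SEN %.4f  SPC %.4f  F %.4f  (N = %d)\n",
              x$accuracy, x$precision, x$sensitivity, x$specificity,
              x$f_score, x$confusion$N))
  invisible(x)
}

# One-vs-rest ROC points for a binary indicator and a score vector.
# Returns (FPR, TPR) from (0,0) to (1,1) over descending score thresholds.
roc_points <- function(pos, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]; score <- score[ord]
  P <- sum(pos); Ng <- sum(!pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(score, fromLast = TRUE)  # one point per threshold
  data.frame(x = c(0, fp[last] / Ng, 1), y = c(0, tp[last] / P, 1))
}

# One-vs-rest precision-recall points, anchored at recall 0 with the
# precision of the highest threshold.
pr_points <- function(pos, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]; score <- score[ord]
  P <- sum(pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(score, fromLast = TRUE)
  rec <- tp[last] / P
  prec <- tp[last] / (tp[last] + fp[last])
  data.frame(x = c(0, rec), y = c(prec[1], prec))
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Reduce a curve to unique x keeping the largest y (upper envelope), so
# linear interpolation onto a shared grid is well defined.
upper_envelope <- function(pts) {
  agg <- stats::aggregate(y ~ x, data = pts, FUN = max)
  agg[order(agg$x), ]
}

#' Multiclass ROC / precision-recall curves (one-vs-rest, macro average)
#'
#' Builds a one-vs-rest curve per class from a per-class score matrix, then
#' macro-averages: each class curve is interpolated onto the shared grid of
#' all observed x values and the mean y is taken. AUC is the trapezoidal area
#' of the macro curve. For a voting ensemble the score of class i is its vote
#' share (see [vote_scores()]).
#'
#' @param scores numeric matrix, samples x C, finite.
#' @param y_true integer labels in `0..C-1`.
#' @param kind `"ROC"` or `"PR"`.
#' @return object of class `curve_set`: `kind`, `points` (data.frame `x`,
#'   `y`; for ROC x is the false-positive rate and y the true-positive rate,
#'   for PR x is recall and y precision), `auc`, and `per_class` (list of
#'   per-class point sets with their AUCs).
#' @export
multiclass_curves <- function(scores, y_true, kind = c("ROC", "PR")) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (nrow(scores) != length(y_true)) stop("scores rows must match labels")
  C <- ncol(scores)
  per_class <- list()
  for (cls in seq_len(C) - 1L) {
    pos <- y_true == cls
    if (!any(pos)) {
      warning("class ", cls, " absent from y_true; skipped in macro average")
      next
    }
    pts <- if (kind == "ROC") roc_points(pos, scores[, cls + 1L])
           else pr_points(pos, scores[, cls + 1L])
    per_class[[paste0("class", cls)]] <-
      list(points = pts, auc = trapezoid_auc(pts$x, pts$y))
  }
  if (!length(per_class)) stop("no class present in y_true")
  envs <- lapply(per_class, function(p) upper_envelope(p$points))
  grid <- sort(unique(unlist(lapply(envs, `[[`, "x"))))
  ys <- vapply(envs, function(e)
    stats::approx(e$x, e$y, xout = grid, rule = 2, ties = "ordered")$y,
    numeric(length(grid)))
  macro_y <- if (is.matrix(ys)) rowMeans(ys) else ys
  pts <- data.frame(x = grid, y = macro_y)
  if (kind == "ROC" && (pts$x[1] != 0 || pts$y[1] != 0))
    pts <- rbind(data.frame(x = 0, y = 0), pts)  # zero-width start anchor
  structure(list(kind = kind, points = pts,
                 auc = trapezoid_auc(pts$x, pts$y),
                 per_class = per_class),
            class = "curve_set")
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two run sets
#'
#' Two-sided test that two sets of final scores come from the same
#' distribution. Uses exact enumeration of the null rank-sum distribution
#' when `max(length(a), length(b)) <= 10` and there are no ties, and the
#' normal approximation with midranks and tie correction otherwise (p = 1
#' when the tie-corrected variance vanishes, e.g. all values identical).
#'
#' @param a,b non-empty numeric score vectors (e.g. final fitness of repeated
#'   optimizer runs).
#' @return list with `statistic` (the Mann-Whitney U of `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))  # midranks
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (max(n1, n2) <= 10 && !has_ties) {
    sums <- utils::combn(n, n1, FUN = sum)
    p_low <- mean(sums <= W)
    p_high <- mean(sums >= W)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(a, b))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Convergence / stability summary of repeated runs
#'
#' Boxplot statistics of the final fitness across repeated searches plus the
#' element-wise mean convergence trace; the raw material of stability
#' boxplots and mean convergence curves.
#'
#' @param results non-empty list of `search_result` objects with equal trace
#'   lengths.
#' @return object of class `run_set_summary`: `final_scores`, `median`, `q1`,
#'   `q3`, `whiskers` (length 2), `outliers`, `mean_trace`.
#' @export
run_set_summary <- function(results) {
  if (!length(results)) stop("need at least one result")
  lens <- vapply(results, function(r) length(r$trace), integer(1))
  if (length(unique(lens)) != 1L) stop("traces have unequal lengths")
  finals <- vapply(results, function(r) r$best$fitness, numeric(1))
  bs <- grDevices::boxplot.stats(finals)
  traces <- do.call(cbind, lapply(results, `[[`, "trace"))
  structure(list(final_scores = finals,
                 median = bs$stats[3], q1 = bs$stats[2], q3 = bs$stats[4],
                 whiskers = c(bs$stats[1], bs$stats[5]),
                 outliers = bs$out,
                 mean_trace = rowMeans(traces)),
            class = "run_set_summary")
}

#' Compare two optimizers at matched objective budgets
#'
#' Runs Trader and the random-search baseline `n_runs` times each at an
#' identical objective-call budget, summarizes both run sets, and tests the
#' final-score difference with [wilcoxon_rank_sum()].
#'
#' @param table a preprocessed [data_table].
#' @param config a [trader_config()]; the baseline budget is set to Trader's
#'   exact call count.
#' @param n_runs repeated runs per optimizer.
#' @param objective_cfg an [objective_config()].
#' @param seed master seed; run seeds are derived from it.
#' @return list with `trader` and `baseline` (`run_set_summary` each, plus
#'   run lists), `wilcoxon`, and `budget`.
#' @export
compare_optimizers <- function(table, config, n_runs = 10L,
                               objective_cfg = objective_config(),
                               seed = 1L) {
  objective <- make_objective(table, objective_cfg)
  m <- ceiling(config$change_fraction * config$pop_size)
  budget <- config$pop_size + config$iterations * m
  trader_runs <- lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "trader_run", i)
    trader_search(table, cfg, objective = objective)
  })
  base_runs <- lapply(seq_len(n_runs), function(i)
    random_search_baseline(table, budget = budget, k = config$k,
                           seed = derive_seed(seed, "baseline_run", i),
                           objective = objective))
  tf <- vapply(trader_runs, function(r) r$best$fitness, numeric(1))
  bf <- vapply(base_runs, function(r) r$best$fitness, numeric(1))
  list(trader = list(summary = run_set_summary(trader_runs),
                     runs = trader_runs),
       baseline = list(summary = run_set_summary(base_runs),
                       runs = base_runs),
       wilcoxon = wilcoxon_rank_sum(tf, bf),
       budget = budget)
}

#' Cross-validated end-to-end run
#'
#' The full pipeline under outer stratified k-fold cross-validation. Per
#' fold: imputation and normalization statistics are fit on the training
#' part only; `ensemble_size` Trader searches with derived seeds select
#' feature subsets on the training part; an ensemble is trained and the
#' held-out part predicted. Held-out predictions are pooled over folds into
#' one confusion matrix and one vote-share score matrix, from which the
#' metrics report and ROC/PR curves are computed. Fully determined by `seed`.
#'
#' With `leak_compat = TRUE` the preprocessing and feature selection are done
#' once on the full dataset before splitting (the historically common but
#' leak-prone protocol); members are still trained per fold on training rows
#' only.
#'
#' @param table a [data_table] (may contain missing cells).
#' @param config a [trader_config()].
#' @param objective_cfg an [objective_config()].
#' @param ensemble_size number of Trader runs / ensemble members per fold.
#' @param outer_folds number of outer folds (default 5).
#' @param seed master seed.
#' @param leak_compat logical; see above.
#' @return list with `metrics` (a `metrics_report`), `roc` and `pr`
#'   (`curve_set`s), `predictions` (data.frame: `sample`, `fold`, `truth`,
#'   `predicted`), `scores` (pooled vote-share matrix), `fold_details`
#'   (selected subsets per fold).
#' @export
cross_validated_run <- function(table, config,
                                objective_cfg = objective_config(),
                                ensemble_size = 5L, outer_folds = 5L,
                                seed = 1L, leak_compat = FALSE) {
  folds <- stratified_folds(table$labels, outer_folds,
                            derive_seed(seed, "outer_folds"))
  n <- n_samples(table)
  pred <- integer(n); fold_of <- integer(n)
  scores <- matrix(NA_real_, n, table$class_count)
  fold_details <- list()

  if (leak_compat) {
    prep_full <- preprocess_table(table)
    full_results <- run_member_searches(prep_full$table, config,
                                        objective_cfg, ensemble_size, seed)
  }

  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (leak_compat) {
      train_tab <- subset_rows(prep_full$table, train_idx)
      test_vals <- prep_full$table$values[test_idx, , drop = FALSE]
      results <- full_results
    } else {
      train_tab <- subset_rows(table, train_idx)
      prep <- preprocess_table(train_tab)
      train_tab <- prep$table
      test_vals <- fill_with_column_means(table, test_idx, train_tab)
      test_vals <- normalize_matrix(test_vals, prep$ranges)
      results <- run_member_searches(train_tab, config, objective_cfg,
                                     ensemble_size,
                                     derive_seed(seed, "fold", f))
    }
    ens <- build_ensemble(train_tab, results, objective_cfg)
    pred[test_idx] <- vote_predict(ens, test_vals)
    scores[test_idx, ] <- vote_scores(ens, test_vals)
    fold_details[[f]] <- list(
      fold = f, test_size = length(test_idx),
      subsets = lapply(results, function(r) sort(r$best$indices)),
      member_fitness = vapply(results, function(r) r$best$fitness, numeric(1)))
  }

  cm <- confusion_matrix(table$labels, pred, table$class_count)
  list(metrics = metrics_report(cm),
       roc = multiclass_curves(scores, table$labels, "ROC"),
       pr = multiclass_curves(scores, table$labels, "PR"),
       predictions = data.frame(sample = seq_len(n),
                                fold = fold_index_of(folds, n),
                                truth = table$labels, predicted = pred),
       scores = scores,
       fold_details = fold_details)
}

run_member_searches <- function(train_tab, config, objective_cfg,
                                ensemble_size, seed) {
  objective <- make_objective(train_tab, objective_cfg)
  lapply(seq_len(ensemble_size), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "member", r)
    trader_search(train_tab, cfg, objective = objective)
  })
}

fold_index_of <- function(folds, n) {
  out <- integer(n)
  for (f in seq_along(folds)) out[folds[[f]]] <- f
  out
}

# Test rows may carry missing cells: fill them with training-column means
# (training-only statistics; no held-out information is used).
fill_with_column_means <- function(table, test_idx, train_tab) {
  vals <- table$values[test_idx, , drop = FALSE]
  mask <- table$missing_mask[test_idx, , drop = FALSE]
  if (any(mask)) {
    means <- colMeans(train_tab$values)
    for (j in which(colSums(mask) > 0L))
      vals[mask[, j], j] <- means[j]
  }
  vals
}

normalize_matrix <- function(vals, ranges) {
  span <- ranges$max - ranges$min
  vals <- sweep(vals, 2, ranges$min, "-")
  vals <- sweep(vals, 2, ifelse(span == 0, 1, span), "/")
  vals[, span == 0] <- 0
  vals
}
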