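# Shared fixtures: tiny generated tables and deterministic stub objectives.

tiny_table <- function(n = 40, d = 8, informative = 3, classes = 2,
                       class_sep = 4, missing_rate = 0, seed = 42) {
  generate_dataset(synthetic_spec(
    n_samples = n, n_features = d, n_informative = informative,
    class_count = classes, class_sep = class_sep, noise_sd = 1,
    missing_rate = missing_rate, seed = seed))
}

# Deterministic subset objective with a known optimum: fitness is the
# normalized sum of per-feature weights, maximized by the top-k weighted
# features. Lets search tests run without any SVM fitting.
weighted_objective <- function(n_feat, k) {
  w <- seq_len(n_feat) / n_feat
  top <- sum(sort(w, decreasing = TRUE)[seq_len(k)])
  function(indices) sum(w[indices]) / top
}

# Pseudo-random but deterministic objective (hash of the sorted subset).
hash_objective <- function(n_feat) {
  function(indices) {
    h <- sum(sort(indices) * seq_along(indices) * 2654435761) %% 104729
    h / 104729
  }
}

# Independent per-class recount of precision/sensitivity/specificity from
# label vectors; the brute-force oracle for metrics_report.
recount_metrics <- function(y_true, y_pred, C) {
  per <- t(vapply(0:(C - 1), function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    tn <- sum(y_true != cls & y_pred != cls)
    c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
      specificity = if (tn + fp == 0) 0 else tn / (tn + fp))
  }, numeric(3)))
  list(accuracy = mean(y_true == y_pred),
       precision = mean(per[, "precision"]),
       sensitivity = mean(per[, "sensitivity"]),
       specificity = mean(per[, "specificity"]))
}

# Stub ensemble member predicting fixed labels regardless of input.
fixed_member <- function(labels) {
  force(labels)
  function(newdata) labels[seq_len(nrow(newdata))]
}

expect_valid_solution <- function(cs, n_feat, k) {
  expect_s3_class(cs, "candidate_solution")
  expect_length(cs$indices, k)
  expect_false(anyDuplicated(cs$indices) > 0)
  expect_true(all(cs$indices >= 1 & cs$indices <= n_feat))
}
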