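#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred integer labels in `0..C-1`, equal length.
#' @param n_classes number of classes C; defaults to `max(label) + 1`.
#' @return object of class `confusion_matrix`: list with `counts`
#'   (C x C integer matrix, rows = true class, columns = predicted class) and
#'   `N` (total samples).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) == 0L) stop("empty label vectors")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(n_classes)) n_classes <- max(c(y_true, y_pred)) + 1L
  n_classes <- as.integer(n_classes)
  if (any(y_true < 0 | y_true >= n_classes) ||
      any(y_pred < 0 | y_pred >= n_classes))
    stop("label out of range 0..C-1")
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true))
    counts[y_true[i] + 1L, y_pred[i] + 1L] <-
      counts[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  structure(list(counts = counts, N = length(y_true)),
            class = "confusion_matrix")
}

#' Mean-based multiclass accuracy
#'
#' Accuracy of a pooled confusion matrix over all classes:
#' `sum_i TP_i / N`, i.e. the trace of the matrix divided by the total sample
#' count. For two classes this reduces to `(TP + TN) / N`.
#'
#' @param cm a [confusion_matrix()].
#' @return accuracy in `[0, 1]`.
#' @export
multiclass_accuracy <- function(cm) {
  if (cm$N == 0L) stop("empty confusion matrix")
  sum(diag(cm$counts)) / cm$N
}

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` folds with per-class counts differing by
#' at most one across folds. Deterministic for a given seed.
#'
#' @param labels integer labels in `0..C-1`.
#' @param k number of folds; must not exceed the smallest class count.
#' @param seed integer seed.
#' @return list of `k` integer index vectors (1-based rows), pairwise disjoint,
#'   whose union is all samples.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  cls_sizes <- table(labels)
  if (k > min(cls_sizes))
    stop("k = ", k, " exceeds the smallest class count (", min(cls_sizes), ")")
  folds <- vector("list", k)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      bins <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[bins == f])
    }
  })
  lapply(folds, sort)
}

#' Objective (fitness) configuration
#'
#' Settings for the SVM wrapped as the feature-subset fitness function.
#' Defaults: RBF kernel, cost 1, kernel width by the "scale" heuristic
#' `1 / (d * var(X))`, 5 inner folds.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost SVM regularization parameter, > 0.
#' @param gamma RBF kernel width; `NULL` (default) uses the scale heuristic.
#' @param inner_folds folds of the internal cross-validation (>= 2).
#'   `inner_folds = 1` is a leak-prone compatibility mode scoring
#'   resubstitution accuracy (train and evaluate on all rows).
#' @param seed seed controlling the internal fold split.
#' @return an `objective_config` list.
#' @export
objective_config <- function(kernel = c("rbf", "linear"), cost = 1,
                             gamma = NULL, inner_folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, inner_folds >= 1)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "objective_config")
}

svm_gamma <- function(config, X) {
  if (!is.null(config$gamma)) return(config$gamma)
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v == 0) 1 / ncol(X) else 1 / (ncol(X) * v)
}

fit_svm <- function(X, y, config, class_count) {
  e1071::svm(X, factor(y, levels = 0:(class_count - 1L)),
             kernel = if (config$kernel == "rbf") "radial" else "linear",
             cost = config$cost, gamma = svm_gamma(config, X),
             scale = FALSE)
}

#' SVM accuracy of a feature subset
#'
#' The wrapper fitness: restricts the table to the subset's columns, runs an
#' internal stratified k-fold cross-validation of the configured SVM, pools
#' all held-out predictions into one confusion matrix, and returns the
#' mean-based multiclass accuracy. Deterministic given the config seed and
#' invariant to the order of indices in the subset.
#'
#' @param table a preprocessed [data_table] (no missing cells).
#' @param subset a [candidate_solution()] or an integer vector of 1-based
#'   feature indices.
#' @param config an [objective_config()].
#' @return accuracy in `[0, 1]`.
#' @export
svm_fitness <- function(table, subset, config = objective_config()) {
  idx <- if (inherits(subset, "candidate_solution")) subset$indices else subset
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("empty feature subset")
  if (any(idx < 1L | idx > n_features(table)))
    stop("subset index out of range")
  if (any(table$missing_mask)) stop("table has missing cells; preprocess first")
  X <- table$values[, idx, drop = FALSE]
  y <- table$labels
  if (config$inner_folds == 1L) {
    fit <- fit_svm(X, y, config, table$class_count)
    pred <- as.integer(as.character(stats::predict(fit, X)))
    return(multiclass_accuracy(confusion_matrix(y, pred, table$class_count)))
  }
  folds <- stratified_folds(y, config$inner_folds, config$seed)
  yt <- integer(0); yp <- integer(0)
  for (f in folds) {
    fit <- fit_svm(X[-f, , drop = FALSE], y[-f], config, table$class_count)
    pred <- stats::predict(fit, X[f, , drop = FALSE])
    yt <- c(yt, y[f])
    yp <- c(yp, as.integer(as.character(pred)))
  }
  multiclass_accuracy(confusion_matrix(yt, yp, table$class_count))
}

#' Build a memoized objective function
#'
#' Returns `function(indices) -> fitness` closing over the table and config,
#' with a cache keyed by the sorted subset so repeated subsets are not
#' re-fitted. The search loop counts every evaluation request as an objective
#' call, cache hit or not, preserving budget parity across optimizers.
#'
#' @inheritParams svm_fitness
#' @return a function mapping an index vector to its fitness.
#' @export
make_objective <- function(table, config = objective_config()) {
  cache <- new.env(parent = emptyenv())
  function(indices) {
    key <- paste(sort(as.integer(indices)), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- svm_fitness(table, indices, config)
    cache[[key]] <- val
    val
  }
}

# Evaluate a block of code without disturbing the caller's RNG stream.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Deterministic sub-seed derivation: mixes a global seed with a stream tag and
# counter so independent components (population, folds, generator, runs) get
# reproducible, distinct streams. Result always in [0, 2^31).
derive_seed <- function(seed, tag, counter = 0L) {
  h <- sum(utf8ToInt(as.character(tag))) %% 2147483647
  x <- (as.double(seed) %% 2147483647)
  x <- (x * 69069 + h + 1) %% 2147483647
  x <- (x * 69069 + as.double(counter) * 9973 + 1) %% 2147483647
  as.integer(x)
}
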