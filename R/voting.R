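#' Build a voting ensemble from search results
#'
#' Trains one SVM per search result on the full training data restricted to
#' that result's best feature subset. Member diversity comes from the
#' independent stochastic searches (typically Trader runs with distinct seeds,
#' optionally mixed with random-search baselines).
#'
#' @param table a preprocessed training [data_table].
#' @param search_results non-empty list of `search_result` objects.
#' @param objective_cfg an [objective_config()] giving the member SVM
#'   settings.
#' @param tie_policy `"fitness_weighted"` (default: tied classes compared by
#'   the summed fitness of their voters, residual ties to the lowest class
#'   index) or `"lowest_index"`.
#' @param source_tags optional character vector naming each member.
#' @return object of class `ensemble_model`: `members` (each with `subset`,
#'   `model`, `member_fitness`, `source_tag`), `class_count`, `tie_policy`.
#' @export
build_ensemble <- function(table, search_results,
                           objective_cfg = objective_config(),
                           tie_policy = c("fitness_weighted", "lowest_index"),
                           source_tags = NULL) {
  tie_policy <- match.arg(tie_policy)
  if (!length(search_results)) stop("need at least one search result")
  if (is.null(source_tags))
    source_tags <- paste0("run", seq_along(search_results))
  members <- lapply(seq_along(search_results), function(i) {
    res <- search_results[[i]]
    idx <- sort(res$best$indices)
    model <- fit_svm(table$values[, idx, drop = FALSE], table$labels,
                     objective_cfg, table$class_count)
    list(subset = candidate_solution(idx, res$best$fitness),
         model = model, member_fitness = res$best$fitness,
         source_tag = source_tags[i])
  })
  structure(list(members = members, class_count = table$class_count,
                 tie_policy = tie_policy),
            class = "ensemble_model")
}

#' Build an ensemble from explicit prediction functions
#'
#' Constructs an `ensemble_model` whose members are arbitrary
#' `function(newdata) -> integer labels` — used for stub members in
#' simulations and tests of the voting arithmetic itself.
#'
#' @param predict_fns list of prediction functions.
#' @param class_count number of classes C.
#' @param member_fitness numeric vector of member fitnesses (default all 1).
#' @param tie_policy as in [build_ensemble()].
#' @return an `ensemble_model`.
#' @export
stub_ensemble <- function(predict_fns, class_count,
                          member_fitness = rep(1, length(predict_fns)),
                          tie_policy = c("fitness_weighted", "lowest_index")) {
  tie_policy <- match.arg(tie_policy)
  members <- lapply(seq_along(predict_fns), function(i)
    list(subset = NULL, model = predict_fns[[i]],
         member_fitness = member_fitness[i],
         source_tag = paste0("stub", i)))
  structure(list(members = members, class_count = as.integer(class_count),
                 tie_policy = tie_policy),
            class = "ensemble_model")
}

member_predict <- function(member, newdata) {
  if (is.function(member$model)) return(as.integer(member$model(newdata)))
  idx <- member$subset$indices
  if (ncol(newdata) < max(idx))
    stop("sample dimensionality below the member's feature indices")
  p <- stats::predict(member$model, newdata[, idx, drop = FALSE])
  as.integer(as.character(p))
}

#' Per-class vote counts
#'
#' For each sample, the number of ensemble members predicting each class.
#' Row sums always equal the member count.
#'
#' @param ensemble an `ensemble_model`.
#' @param newdata numeric matrix with full feature dimensionality (each member
#'   restricts to its own subset internally), or a single sample vector.
#' @return integer matrix, samples x C.
#' @export
vote_counts <- function(ensemble, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  C <- ensemble$class_count
  counts <- matrix(0L, nrow(newdata), C)
  for (member in ensemble$members) {
    pred <- member_predict(member, newdata)
    if (any(pred < 0L | pred >= C)) stop("member predicted an out-of-range class")
    for (i in seq_along(pred))
      counts[i, pred[i] + 1L] <- counts[i, pred[i] + 1L] + 1L
  }
  counts
}

#' Majority-vote prediction
#'
#' Returns the class with the most member votes for each sample. Under the
#' `fitness_weighted` tie policy, tied classes are compared by the summed
#' fitness of the members that voted for them; any residual tie goes to the
#' lowest class index.
#'
#' @inheritParams vote_counts
#' @return integer vector of predicted labels in `0..C-1`.
#' @export
vote_predict <- function(ensemble, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  counts <- vote_counts(ensemble, newdata)
  weights <- NULL
  if (ensemble$tie_policy == "fitness_weighted") {
    C <- ensemble$class_count
    weights <- matrix(0, nrow(newdata), C)
    for (member in ensemble$members) {
      pred <- member_predict(member, newdata)
      for (i in seq_along(pred))
        weights[i, pred[i] + 1L] <- weights[i, pred[i] + 1L] +
          member$member_fitness
    }
  }
  vapply(seq_len(nrow(counts)), function(i) {
    cand <- which(counts[i, ] == max(counts[i, ]))
    if (length(cand) > 1L && !is.null(weights)) {
      w <- weights[i, cand]
      cand <- cand[w == max(w)]
    }
    cand[1] - 1L
  }, integer(1))
}

#' Vote-share score matrix
#'
#' Class scores for curve construction: the fraction of members voting each
#' class, `F_p_i / member count`. Rows sum to 1.
#'
#' @inheritParams vote_counts
#' @return numeric matrix, samples x C.
#' @export
vote_scores <- function(ensemble, newdata) {
  vote_counts(ensemble, newdata) / length(ensemble$members)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d members, %d classes, tie policy %s\n",
              length(x$members), x$class_count, x$tie_policy))
  invisible(x)
}
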