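#' Pearson correlation over jointly observed positions
#'
#' Computes the ordinary Pearson correlation between two vectors, restricted
#' to positions where both values are observed. Used to rank candidate donor
#' samples during imputation.
#'
#' @param x,y numeric vectors of equal length; may contain `NA`.
#' @param shared_mask optional logical vector marking the positions to use;
#'   defaults to positions where both `x` and `y` are non-`NA`.
#' @return the correlation in `[-1, 1]`, or `NA_real_` when it is undefined
#'   (fewer than 3 shared positions, or zero variance in either vector).
#' @export
pearson_correlation <- function(x, y, shared_mask = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(shared_mask)) shared_mask <- !is.na(x) & !is.na(y)
  xs <- x[shared_mask]; ys <- y[shared_mask]
  if (length(xs) < 3L) return(NA_real_)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Fill missing cells by correlated-neighbor interpolation
#'
#' For each sample with missing cells, donor samples are ranked by Pearson
#' correlation with the target over jointly observed features. Donors must be
#' fully observed; if no fully observed donor correlates above `min_corr`, the
#' requirement is relaxed to donors observed in the target's missing columns
#' (recorded as `relaxed` in the report). The `max_neighbors` best donors with
#' correlation strictly above `min_corr` are kept (fewer is allowed, minimum
#' one), and each missing cell is filled with the correlation-weighted mean of
#' the donors' values in that column (weights `r_i / sum(r)`). When no donor
#' qualifies the cell falls back to the column mean over observed values.
#'
#' @param table a [data_table]; no sample may be entirely missing.
#' @param max_neighbors maximum donors per sample (default 10).
#' @param min_corr donor correlation threshold, exclusive (default 0.5).
#' @return a list with `table` (all cells observed, `missing_mask` all-false)
#'   and `report`, a data.frame with one row per filled cell: `sample`,
#'   `feature` (1-based), `value`, `n_neighbors`, `fallback`, `relaxed`.
#' @export
impute_missing <- function(table, max_neighbors = 10L, min_corr = 0.5) {
  vals <- table$values
  mask <- table$missing_mask
  n <- nrow(vals)
  if (!any(mask)) {
    return(list(table = table,
                report = empty_imputation_report()))
  }
  if (any(rowSums(mask) == ncol(vals)))
    stop("a sample is entirely missing; cannot impute")
  col_means <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[!mask[, j], j]
    if (!length(v)) stop("column ", j, " has no observed values")
    mean(v)
  }, numeric(1))

  complete_rows <- which(rowSums(mask) == 0L)
  rep_rows <- list()
  out <- vals
  for (s in which(rowSums(mask) > 0L)) {
    miss_cols <- which(mask[s, ])
    pick <- choose_neighbors(vals, mask, s, miss_cols, complete_rows,
                             max_neighbors, min_corr)
    for (j in miss_cols) {
      if (length(pick$rows)) {
        w <- pick$r / sum(pick$r)
        val <- sum(w * vals[pick$rows, j])
        fallback <- FALSE
      } else {
        val <- col_means[j]
        fallback <- TRUE
      }
      out[s, j] <- val
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        sample = s, feature = j, value = val,
        n_neighbors = length(pick$rows), fallback = fallback,
        relaxed = pick$relaxed)
    }
  }
  report <- do.call(rbind, rep_rows)
  new_tab <- data_table(out, table$labels,
                        feature_names = table$feature_names,
                        missing_mask = matrix(FALSE, n, ncol(vals)),
                        label_levels = table$label_levels)
  list(table = new_tab, report = report)
}

empty_imputation_report <- function() {
  data.frame(sample = integer(0), feature = integer(0), value = numeric(0),
             n_neighbors = integer(0), fallback = logical(0),
             relaxed = logical(0))
}

# Rank donor rows for sample s: fully observed donors first; relax to rows
# observed in s's missing columns only when the strict pool yields none.
choose_neighbors <- function(vals, mask, s, miss_cols, complete_rows,
                             max_neighbors, min_corr) {
  rank_pool <- function(pool) {
    if (!length(pool)) return(list(rows = integer(0), r = numeric(0)))
    r <- vapply(pool, function(t) {
      sm <- !mask[s, ] & !mask[t, ]
      v <- pearson_correlation(vals[s, ], vals[t, ], sm)
      if (is.na(v)) -Inf else v
    }, numeric(1))
    keep <- which(r > min_corr)
    keep <- keep[order(r[keep], decreasing = TRUE)]
    keep <- keep[seq_len(min(length(keep), max_neighbors))]
    list(rows = pool[keep], r = r[keep])
  }
  strict <- rank_pool(setdiff(complete_rows, s))
  if (length(strict$rows))
    return(c(strict, list(relaxed = FALSE)))
  pool <- setdiff(which(rowSums(mask[, miss_cols, drop = FALSE]) == 0L), s)
  relaxed <- rank_pool(setdiff(pool, complete_rows))
  c(relaxed, list(relaxed = length(relaxed$rows) > 0))
}

#' Min-max normalization to [0, 1]
#'
#' Rescales every feature column to `[0, 1]` by
#' `(x - min_j) / (max_j - min_j)` using the column minimum and maximum.
#' Constant columns map to 0 everywhere. The per-column `(min, max)` record is
#' returned so held-out data can be transformed with training statistics via
#' [apply_min_max()].
#'
#' @param table a [data_table] with no missing cells (run [impute_missing()]
#'   first).
#' @return list with `table` (normalized) and `ranges`, a data.frame with
#'   columns `feature`, `min`, `max`.
#' @export
min_max_normalize <- function(table) {
  if (any(table$missing_mask))
    stop("missing cells present; impute before normalizing")
  mins <- apply(table$values, 2, min)
  maxs <- apply(table$values, 2, max)
  ranges <- data.frame(feature = table$feature_names, min = mins, max = maxs,
                       row.names = NULL)
  list(table = apply_min_max(table, ranges), ranges = ranges)
}

#' Apply stored min-max statistics
#'
#' Transforms a table with a `(min, max)` record fit elsewhere (typically the
#' training fold). Values outside the training range map outside `[0, 1]`;
#' columns whose stored range is degenerate map to 0.
#'
#' @param table a [data_table] with no missing cells.
#' @param ranges data.frame from [min_max_normalize()].
#' @return the transformed [data_table].
#' @export
apply_min_max <- function(table, ranges) {
  if (any(table$missing_mask))
    stop("missing cells present; impute before normalizing")
  if (nrow(ranges) != ncol(table$values))
    stop("ranges do not match the table's features")
  span <- ranges$max - ranges$min
  vals <- sweep(table$values, 2, ranges$min, "-")
  vals <- sweep(vals, 2, ifelse(span == 0, 1, span), "/")
  vals[, span == 0] <- 0
  data_table(vals, table$labels, feature_names = table$feature_names,
             missing_mask = table$missing_mask,
             label_levels = table$label_levels)
}

#' Impute then normalize in one step
#'
#' Convenience wrapper running [impute_missing()] followed by
#' [min_max_normalize()].
#'
#' @inheritParams impute_missing
#' @return list with `table`, `report`, `ranges`.
#' @export
preprocess_table <- function(table, max_neighbors = 10L, min_corr = 0.5) {
  imp <- impute_missing(table, max_neighbors, min_corr)
  nrm <- min_max_normalize(imp$table)
  list(table = nrm$table, report = imp$report, ranges = nrm$ranges)
}
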