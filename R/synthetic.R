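#' Synthetic dataset specification
#'
#' Parameters of the generator that emulates UCI-style clinical/biological
#' classification tables: a handful of informative columns carrying
#' class-dependent Gaussian signal, the rest noise (a fraction of the noise
#' columns binarized), balanced labels, and optional missing cells.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_features total number of feature columns.
#' @param n_informative number of informative columns (<= `n_features`).
#' @param class_count number of classes C (>= 2).
#' @param class_sep minimum pairwise distance between class centroids in the
#'   informative subspace (signal strength; 0 = no signal).
#' @param noise_sd standard deviation of the Gaussian noise added to
#'   informative columns.
#' @param binary_fraction fraction of the non-informative columns thresholded
#'   to \{0, 1\}.
#' @param missing_rate fraction of cells flagged missing, in `[0, 1)`; cells
#'   are placed so that no row or column becomes entirely missing.
#' @param seed integer seed; generation is fully determined by it.
#' @param name optional preset name.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, n_features, n_informative,
                           class_count = 2L, class_sep = 3, noise_sd = 1,
                           binary_fraction = 0, missing_rate = 0,
                           seed = 1L, name = NULL) {
  stopifnot(n_samples >= 2, n_features >= 1,
            n_informative >= 1, n_informative <= n_features,
            class_count >= 2, class_sep >= 0, noise_sd >= 0,
            binary_fraction >= 0, binary_fraction <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_count = as.integer(class_count),
                 class_sep = class_sep, noise_sd = noise_sd,
                 binary_fraction = binary_fraction,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 name = name),
            class = "synthetic_spec")
}

#' Generate a synthetic classification table
#'
#' Class centroids are drawn at random in the informative subspace and
#' rescaled so their minimum pairwise distance equals `class_sep`; informative
#' cells are the centroid coordinate of the sample's class plus
#' `N(0, noise_sd^2)` noise; the remaining columns are standard Gaussian
#' noise, a `binary_fraction` of them thresholded at 0 to \{0, 1\}. Labels are
#' balanced up to the remainder; informative column positions are shuffled and
#' returned as ground truth. Missing cells are placed uniformly at
#' `missing_rate`, never emptying a row or column.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [data_table]) and `informative` (sorted
#'   1-based indices of the informative columns).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; d <- spec$n_features
  di <- spec$n_informative; C <- spec$class_count
  out <- with_preserved_rng({
    set.seed(spec$seed)
    labels <- rep(seq_len(C) - 1L, length.out = n)

    centroids <- matrix(stats::rnorm(C * di), C, di)
    if (spec$class_sep > 0) {
      dmin <- min(stats::dist(centroids))
      if (dmin == 0) stop("degenerate centroid draw; change the seed")
      centroids <- centroids * (spec$class_sep / dmin)
    } else {
      centroids[] <- 0
    }

    vals <- matrix(stats::rnorm(n * d), n, d)
    info_cols <- sort(sample.int(d, di))
    vals[, info_cols] <- centroids[labels + 1L, , drop = FALSE] +
      stats::rnorm(n * di, sd = spec$noise_sd)

    noise_cols <- setdiff(seq_len(d), info_cols)
    n_bin <- round(spec$binary_fraction * length(noise_cols))
    if (n_bin > 0) {
      bin_cols <- noise_cols[seq_len(n_bin)]
      vals[, bin_cols] <- (vals[, bin_cols] > 0) + 0
    }

    mask <- matrix(FALSE, n, d)
    target <- round(spec$missing_rate * n * d)
    if (target > 0) {
      cells <- sample.int(n * d)
      row_obs <- rep(d, n); col_obs <- rep(n, d)
      placed <- 0L
      for (cell in cells) {
        if (placed >= target) break
        i <- ((cell - 1L) %% n) + 1L
        j <- ((cell - 1L) %/% n) + 1L
        if (row_obs[i] > 1L && col_obs[j] > 1L) {
          mask[i, j] <- TRUE
          row_obs[i] <- row_obs[i] - 1L
          col_obs[j] <- col_obs[j] - 1L
          placed <- placed + 1L
        }
      }
    }
    vals[mask] <- NA_real_
    list(vals = vals, labels = labels, mask = mask, info_cols = info_cols)
  })
  table <- data_table(out$vals, out$labels, missing_mask = out$mask)
  list(table = table, informative = out$info_cols)
}

#' Benchmark-shaped generator presets
#'
#' One [synthetic_spec()] per benchmark dataset shape commonly used for this
#' kind of method: 13 presets spanning 32-900 samples, 6-20,531 features and
#' 2-16 classes, with missing cells where the corresponding benchmark has
#' them. The informative-column count matches the subset size the method
#' typically selects on that shape.
#'
#' @param class_sep,noise_sd signal parameters shared by all presets.
#' @param seed base seed; each preset derives its own.
#' @return named list of 13 `synthetic_spec` objects.
#' @export
table1_presets <- function(class_sep = 3, noise_sd = 1, seed = 1L) {
  rows <- list(
    #        name        n    d      C  inf  mixed  missing
    list("LIV",        345L,     6L,  2L,  4L, TRUE,  FALSE),
    list("PID",        768L,     8L,  2L,  4L, FALSE, FALSE),
    list("SHD",        270L,    13L,  2L,  5L, TRUE,  FALSE),
    list("CHD2",       303L,    13L,  2L,  5L, TRUE,  FALSE),
    list("CHD5",       303L,    13L,  5L,  5L, TRUE,  FALSE),
    list("HEP",        150L,    19L,  2L,  6L, TRUE,  TRUE),
    list("PAR",        197L,    22L,  2L,  6L, FALSE, TRUE),
    list("WDBC",       569L,    31L,  2L,  6L, FALSE, FALSE),
    list("LUNG",        32L,    56L,  3L,  8L, TRUE,  TRUE),
    list("ARRYTM",     452L,   279L, 16L,  9L, FALSE, TRUE),
    list("PARKINSON",  756L,   754L,  2L, 10L, TRUE,  FALSE),
    list("ARCENE",     900L, 10000L,  2L, 10L, FALSE, FALSE),
    list("GENEEXPR",   801L, 20531L,  5L, 15L, FALSE, FALSE))
  specs <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    synthetic_spec(n_samples = r[[2]], n_features = r[[3]],
                   n_informative = r[[5]], class_count = r[[4]],
                   class_sep = class_sep, noise_sd = noise_sd,
                   binary_fraction = if (r[[6]]) 0.3 else 0,
                   missing_rate = if (r[[7]]) 0.02 else 0,
                   seed = derive_seed(seed, "preset", i), name = r[[1]])
  })
  names(specs) <- vapply(rows, `[[`, character(1), 1)
  specs
}
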