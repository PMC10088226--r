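#' Candidate feature subset
#'
#' The search encoding: a fixed-length vector of `k` distinct 1-based feature
#' indices plus an optional fitness. Indices are kept 1-based internally so the
#' retailing operator's multiplicative perturbation can move a variable off any
#' value; they are converted to 0-based only at file boundaries.
#'
#' @param indices integer vector of distinct feature indices in
#'   `1..n_features`.
#' @param fitness fitness in `[0, 1]`, or `NA` when not yet evaluated.
#' @return object of class `candidate_solution`.
#' @export
candidate_solution <- function(indices, fitness = NA_real_) {
  indices <- as.integer(indices)
  if (length(indices) < 1L) stop("a candidate solution needs >= 1 index")
  if (anyDuplicated(indices)) stop("candidate indices must be distinct")
  if (any(indices < 1L)) stop("candidate indices must be >= 1")
  structure(list(indices = indices, fitness = fitness),
            class = "candidate_solution")
}

#' Trader search configuration
#'
#' Defaults follow the protocol used throughout: population 100, 50
#' iterations, 30% of the population modified per iteration, 5 trader groups,
#' equal chance of retailing vs distributing on slave solutions.
#'
#' @param k subset size (number of features each solution selects).
#' @param pop_size population size.
#' @param iterations number of search iterations.
#' @param change_fraction fraction of the population modified per iteration,
#'   in `(0, 1]`.
#' @param n_groups number of trader groups the population is split into.
#' @param seed integer seed; all search randomness derives from it.
#' @param operator_mix probability a modified slave undergoes retailing (vs
#'   distributing).
#' @return a `trader_config` list.
#' @export
trader_config <- function(k, pop_size = 100L, iterations = 50L,
                          change_fraction = 0.3, n_groups = 5L, seed = 1L,
                          operator_mix = 0.5) {
  stopifnot(k >= 1, pop_size >= 1, iterations >= 0,
            change_fraction > 0, change_fraction <= 1,
            n_groups >= 1, n_groups <= pop_size,
            operator_mix >= 0, operator_mix <= 1)
  structure(list(k = as.integer(k), pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 change_fraction = change_fraction,
                 n_groups = as.integer(n_groups), seed = as.integer(seed),
                 operator_mix = operator_mix),
            class = "trader_config")
}

#' Random initial population
#'
#' Draws `pop_size` candidate solutions, each a uniform random `k`-subset of
#' `1..n_features` without replacement, fitness unset. Consumes the current
#' RNG stream; [trader_search()] seeds it.
#'
#' @param pop_size number of solutions.
#' @param k subset size.
#' @param n_features number of available features.
#' @return list of [candidate_solution()].
#' @export
init_population <- function(pop_size, k, n_features) {
  if (k > n_features) stop("k exceeds the number of features")
  lapply(seq_len(pop_size), function(i)
    candidate_solution(sample.int(n_features, k)))
}

#' Random partition of the population into trader groups
#'
#' Splits population positions into `n_groups` non-empty groups with sizes as
#' equal as possible (difference at most 1). Each group's master is its
#' best-fitness member (ties broken by lowest position) and its finance is the
#' sum of member fitnesses.
#'
#' @param population list of evaluated [candidate_solution()] (fitness set).
#' @param n_groups number of groups.
#' @return list of groups, each a list with `member_ids`, `master_id`,
#'   `finance`.
#' @export
partition_groups <- function(population, n_groups) {
  n <- length(population)
  if (n_groups > n) stop("more groups than population members")
  fitness <- vapply(population, `[[`, numeric(1), "fitness")
  if (anyNA(fitness)) stop("all members must be evaluated before grouping")
  ids <- sample.int(n)
  sizes <- rep(n %/% n_groups, n_groups)
  if (n %% n_groups) sizes[seq_len(n %% n_groups)] <- sizes[seq_len(n %% n_groups)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_len(n_groups), function(g) {
    members <- sort(ids[starts[g]:stops[g]])
    refresh_group(members, fitness)
  })
}

refresh_group <- function(members, fitness) {
  f <- fitness[members]
  list(member_ids = members,
       master_id = members[which.max(f)],  # which.max takes the lowest id on ties
       finance = sum(f))
}

# Shared repair: clamp raw values into [1, n_features], then replace
# duplicates with uniform draws from the unused indices, keeping k constant.
repair_indices <- function(raw, n_feat) {
  v <- pmin.int(pmax.int(as.integer(raw), 1L), n_feat)
  dup <- duplicated(v)
  if (any(dup)) {
    unused <- setdiff(seq_len(n_feat), v[!dup])
    v[dup] <- if (length(unused) == 1L) unused else
      sample(unused, sum(dup))
  }
  v
}

# Non-empty random position set: each position independently with probability
# 1/k, one position forced when none is drawn.
random_positions <- function(k) {
  s <- which(stats::runif(k) < 1 / k)
  if (!length(s)) s <- sample.int(k, 1L)
  s
}

#' Retailing operator (minor perturbation of a slave)
#'
#' Picks a random non-empty set of positions; each chosen variable `V_j`
#' becomes `V_j + sign * delta` with `sign` uniform in \{-1, +1\} and `delta`
#' a uniform integer in `[0, V_j]`, followed by repair (clamp into range,
#' replace duplicates). The input is untouched; the returned solution has
#' fitness unset.
#'
#' @param scs a slave [candidate_solution()].
#' @param n_feat number of features (index upper bound).
#' @return a new [candidate_solution()].
#' @export
retailing <- function(scs, n_feat) {
  v <- scs$indices
  for (j in random_positions(length(v))) {
    sign <- if (stats::runif(1) < 0.5) -1L else 1L
    delta <- sample.int(v[j] + 1L, 1L) - 1L
    v[j] <- v[j] + sign * delta
  }
  candidate_solution(repair_indices(v, n_feat))
}

#' Distributing operator (copy master values into a slave)
#'
#' Picks a random non-empty set of positions and overwrites the slave's
#' variables at those positions with the group master's values, then repairs.
#'
#' @param scs a slave [candidate_solution()].
#' @param mcs the group's master [candidate_solution()]; same length.
#' @param n_feat number of features.
#' @return a new [candidate_solution()].
#' @export
distributing <- function(scs, mcs, n_feat) {
  if (length(scs$indices) != length(mcs$indices))
    stop("slave and master must have equal subset size")
  v <- scs$indices
  s <- random_positions(length(v))
  v[s] <- mcs$indices[s]
  candidate_solution(repair_indices(v, n_feat))
}

#' Importing-exporting operator (exchange between group masters)
#'
#' One exporter master is chosen uniformly; equally sized random non-empty
#' position sets `S` (importer) and `M` (exporter) are drawn and the
#' importer's variables at `S` receive the exporter's values at `M`, paired in
#' drawn order, then repaired. The global-best archive is maintained by the
#' search loop, so a destructive exchange can never lose the best solution.
#'
#' @param importer_mcs the importing master [candidate_solution()].
#' @param exporter_mcs_list non-empty list of other masters.
#' @param n_feat number of features.
#' @return a new [candidate_solution()].
#' @export
import_export <- function(importer_mcs, exporter_mcs_list, n_feat) {
  if (!length(exporter_mcs_list)) stop("need at least one exporter")
  exp <- exporter_mcs_list[[sample.int(length(exporter_mcs_list), 1L)]]
  v <- importer_mcs$indices
  k_imp <- length(v); k_exp <- length(exp$indices)
  s <- random_positions(k_imp)
  if (length(s) > k_exp) s <- s[seq_len(k_exp)]
  m <- sample.int(k_exp, length(s))
  v[s] <- exp$indices[m]
  candidate_solution(repair_indices(v, n_feat))
}

#' Trader feature-subset search
#'
#' Population-based wrapper feature selection. The initial population is
#' evaluated (one objective call each), randomly partitioned into trader
#' groups, and each group's best member becomes its master. Per iteration a
#' `change_fraction` share of the population is drawn uniformly; selected
#' slaves undergo retailing or distributing against their group master,
#' selected masters undergo importing-exporting against the other masters.
#' Modified candidates are evaluated and accepted only when not worse than the
#' member they replace, masters and finances are re-derived, and the
#' best-so-far fitness is appended to the trace. The objective-call count is
#' exactly `pop_size + iterations * ceiling(change_fraction * pop_size)`.
#'
#' @param table a preprocessed [data_table]; ignored when `objective` is
#'   supplied together with `n_feat`.
#' @param config a [trader_config()].
#' @param objective_cfg an [objective_config()] used to build the default SVM
#'   objective.
#' @param objective optional `function(indices) -> fitness in [0, 1]`
#'   overriding the SVM objective (used for oracles and stubs).
#' @param n_feat number of features; defaults to `n_features(table)`.
#' @return object of class `search_result`: list with `best`
#'   (a [candidate_solution()]), `trace` (length `iterations + 1`, best-so-far
#'   fitness, non-decreasing), `objective_calls`, `seed`, and `groups` (final
#'   group structure).
#' @export
trader_search <- function(table = NULL, config,
                          objective_cfg = objective_config(),
                          objective = NULL, n_feat = NULL) {
  if (is.null(n_feat)) {
    if (is.null(table)) stop("supply `table` or `n_feat`")
    n_feat <- n_features(table)
  }
  if (config$k > n_feat) stop("k exceeds the number of features")
  if (is.null(objective)) objective <- make_objective(table, objective_cfg)

  calls <- 0L
  evaluate <- function(cs) {
    calls <<- calls + 1L
    cs$fitness <- objective(cs$indices)
    cs
  }

  with_preserved_rng({
    set.seed(config$seed)
    pop <- init_population(config$pop_size, config$k, n_feat)
    pop <- lapply(pop, evaluate)
    fitness <- vapply(pop, `[[`, numeric(1), "fitness")
    groups <- partition_groups(pop, config$n_groups)
    group_of <- integer(config$pop_size)
    for (g in seq_along(groups)) group_of[groups[[g]]$member_ids] <- g

    best_id <- which.max(fitness)
    best <- pop[[best_id]]
    trace <- best$fitness
    m <- as.integer(ceiling(config$change_fraction * config$pop_size))

    for (it in seq_len(config$iterations)) {
      selected <- sample.int(config$pop_size, m)
      masters <- vapply(groups, `[[`, integer(1), "master_id")
      proposals <- lapply(selected, function(id) {
        g <- group_of[id]
        if (id == groups[[g]]$master_id) {
          exporters <- pop[setdiff(masters, id)]
          if (length(exporters))
            import_export(pop[[id]], exporters, n_feat)
          else
            retailing(pop[[id]], n_feat)
        } else if (stats::runif(1) < config$operator_mix) {
          retailing(pop[[id]], n_feat)
        } else {
          distributing(pop[[id]], pop[[groups[[g]]$master_id]], n_feat)
        }
      })
      proposals <- lapply(proposals, function(cs) {
        tryCatch(evaluate(cs),
                 error = function(e) stop("objective failed at iteration ", it,
                                          ": ", conditionMessage(e)))
      })
      for (i in seq_along(selected)) {
        id <- selected[i]
        if (proposals[[i]]$fitness >= fitness[id]) {
          pop[[id]] <- proposals[[i]]
          fitness[id] <- proposals[[i]]$fitness
        }
      }
      groups <- lapply(groups, function(g) refresh_group(g$member_ids, fitness))
      it_best <- which.max(fitness)
      if (fitness[it_best] > best$fitness) best <- pop[[it_best]]
      trace <- c(trace, best$fitness)
    }
  })

  structure(list(best = best, trace = trace, objective_calls = calls,
                 seed = config$seed, groups = groups),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: best fitness %.4f with %d features, %d objective calls\n",
              x$best$fitness, length(x$best$indices), x$objective_calls))
  invisible(x)
}

#' Budget-matched random-search baseline
#'
#' Evaluates `budget` uniform random `k`-subsets and keeps the best; the
#' comparison partner for Trader at an identical number of objective calls.
#'
#' @param table a preprocessed [data_table] (or `NULL` with `n_feat` set).
#' @param budget number of objective calls, >= 1.
#' @param k subset size.
#' @param seed integer seed.
#' @param objective_cfg an [objective_config()].
#' @param objective optional objective override as in [trader_search()].
#' @param n_feat number of features; defaults to `n_features(table)`.
#' @return a `search_result` with `objective_calls = budget` and a
#'   length-`budget` best-so-far trace.
#' @export
random_search_baseline <- function(table = NULL, budget, k, seed = 1L,
                                   objective_cfg = objective_config(),
                                   objective = NULL, n_feat = NULL) {
  stopifnot(budget >= 1)
  if (is.null(n_feat)) n_feat <- n_features(table)
  if (k > n_feat) stop("k exceeds the number of features")
  if (is.null(objective)) objective <- make_objective(table, objective_cfg)
  best <- NULL
  trace <- numeric(budget)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (b in seq_len(budget)) {
      cs <- candidate_solution(sample.int(n_feat, k))
      cs$fitness <- objective(cs$indices)
      if (is.null(best) || cs$fitness > best$fitness) best <- cs
      trace[b] <- best$fitness
    }
  })
  structure(list(best = best, trace = trace,
                 objective_calls = as.integer(budget),
                 seed = as.integer(seed), groups = NULL),
            class = "search_result")
}

#' Sweep the subset size k
#'
#' Runs [trader_search()] for each `k` in a range and returns every result
#' plus the best overall (largest fitness; smaller `k` wins ties).
#'
#' @param table a preprocessed [data_table].
#' @param k_range integer vector of subset sizes to try.
#' @param ... passed to [trader_config()] (everything but `k`).
#' @param objective_cfg an [objective_config()].
#' @return list with `results` (one `search_result` per k, named) and
#'   `best_k`.
#' @export
sweep_k <- function(table, k_range, ..., objective_cfg = objective_config()) {
  results <- lapply(k_range, function(k)
    trader_search(table, trader_config(k = k, ...),
                  objective_cfg = objective_cfg))
  names(results) <- paste0("k", k_range)
  fit <- vapply(results, function(r) r$best$fitness, numeric(1))
  list(results = results, best_k = k_range[which.max(fit)])
}
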