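test_that("vote counts tally member predictions and conserve the total", {
  ens <- stub_ensemble(list(fixed_member(c(0L, 1L)),
                            fixed_member(c(0L, 1L)),
                            fixed_member(c(1L, 1L))), class_count = 2)
  X <- matrix(0, 2, 3)
  counts <- vote_counts(ens, X)
  expect_equal(counts, matrix(c(2L, 1L, 0L, 3L), 2, 2, byrow = TRUE))
  expect_equal(rowSums(counts), c(3, 3))
  expect_equal(vote_predict(ens, X), c(0L, 1L))
})

test_that("fitness-weighted tie policy favors the better member's class", {
  ens <- stub_ensemble(list(fixed_member(0L), fixed_member(1L)),
                       class_count = 2, member_fitness = c(0.6, 0.9))
  expect_equal(vote_predict(ens, matrix(0, 1, 2)), 1L)
  ens2 <- stub_ensemble(list(fixed_member(0L), fixed_member(1L)),
                        class_count = 2, member_fitness = c(0.9, 0.6))
  expect_equal(vote_predict(ens2, matrix(0, 1, 2)), 0L)
  # equal fitness: residual tie goes to the lowest class index
  ens3 <- stub_ensemble(list(fixed_member(0L), fixed_member(1L)),
                        class_count = 2)
  expect_equal(vote_predict(ens3, matrix(0, 1, 2)), 0L)
})

test_that("prediction equals a brute-force recount argmax on random stubs", {
  set.seed(41)
  for (rep in 1:10) {
    C <- sample(2:4, 1)
    n <- 20
    m <- sample(3:7, 1)
    votes <- replicate(m, sample(0:(C - 1), n, replace = TRUE),
                       simplify = FALSE)
    ens <- stub_ensemble(lapply(votes, fixed_member), class_count = C,
                         tie_policy = "lowest_index")
    pred <- vote_predict(ens, matrix(0, n, 1))
    for (i in seq_len(n)) {
      recount <- tabulate(vapply(votes, `[[`, integer(1), i) + 1L, C)
      expect_equal(pred[i], which.max(recount) - 1L)
    }
  }
})

test_that("member permutation leaves predictions unchanged", {
  set.seed(43)
  votes <- replicate(5, sample(0:2, 30, replace = TRUE), simplify = FALSE)
  fits <- runif(5)
  ens <- stub_ensemble(lapply(votes, fixed_member), 3, member_fitness = fits)
  perm <- c(3, 1, 5, 2, 4)
  ens_p <- stub_ensemble(lapply(votes[perm], fixed_member), 3,
                         member_fitness = fits[perm])
  X <- matrix(0, 30, 1)
  expect_equal(vote_predict(ens, X), vote_predict(ens_p, X))
  expect_equal(vote_counts(ens, X), vote_counts(ens_p, X))
})

test_that("ensembles of trained SVM members restrict features internally", {
  gen <- tiny_table(n = 60, d = 8, informative = 3, class_sep = 5, seed = 47)
  tab <- min_max_normalize(gen$table)$table
  obj <- make_objective(tab)
  runs <- lapply(1:3, function(i)
    trader_search(tab, trader_config(3, pop_size = 10, iterations = 5, seed = i),
                  objective = obj))
  ens <- build_ensemble(tab, runs)
  expect_length(ens$members, 3)
  expect_equal(ens$class_count, tab$class_count)
  pred <- vote_predict(ens, tab$values)
  expect_true(all(pred %in% 0:(tab$class_count - 1)))
  expect_gte(mean(pred == tab$labels), 0.8)
  # single-member ensemble predicts exactly like its model
  ens1 <- build_ensemble(tab, runs[1])
  counts1 <- vote_counts(ens1, tab$values)
  expect_equal(rowSums(counts1), rep(1, 60))
  expect_error(build_ensemble(tab, list()), "at least one")
})

test_that("vote shares form a score matrix with unit row sums", {
  ens <- stub_ensemble(list(fixed_member(c(0L, 1L, 2L)),
                            fixed_member(c(0L, 0L, 2L))), class_count = 3)
  s <- vote_scores(ens, matrix(0, 3, 1))
  expect_equal(rowSums(s), rep(1, 3))
  expect_equal(s[1, ], c(1, 0, 0))
})
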