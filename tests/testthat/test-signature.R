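# Small feature sets built in code: `sep` gives disjoint per-male clusters,
# `null_features` shares one distribution across labels.
sep_features <- function(n_males = 2, calls = 6, gap = 50, seed = 1) {
  set.seed(seed)
  data.frame(
    male_id = rep(sprintf("M%02d", seq_len(n_males)), each = calls),
    pulse_rate_hz = rep(seq_len(n_males) * gap, each = calls) +
      rnorm(n_males * calls, 0, 0.1),
    centroid_hz = rep(seq_len(n_males) * gap * 10, each = calls) +
      rnorm(n_males * calls, 0, 1))
}

null_features <- function(n_males = 8, calls = 6, p = 5, seed = 1) {
  set.seed(seed)
  n <- n_males * calls
  out <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(out) <- paste0("f", seq_len(p))
  out$male_id <- rep(sprintf("M%02d", seq_len(n_males)), each = calls)
  out
}

test_that("disjoint clusters classify perfectly and chance follows label count", {
  res <- crossval_dfa(sep_features(), n_iterations = 20, seed = 4)
  expect_equal(res$mean_correct, 100)
  expect_equal(res$chance, 50)
  expect_equal(crossval_dfa(null_features(16, calls = 4), n_iterations = 2,
                            seed = 1)$chance, 100 / 16)
})

test_that("random labels classify at chance within Monte-Carlo error", {
  res <- crossval_dfa(null_features(8, calls = 8), n_iterations = 100,
                      seed = 9)
  # 8 labels: chance 12.5%; s.e. of the mean over iterations is small but
  # iterations share the data, so allow a generous band
  expect_lt(abs(res$mean_correct - 12.5), 6)
})

test_that("confusion matrix is row-stochastic and consistent with the effect size", {
  colony <- simulate_colony(6, seed = 21, jitter = 0.05)
  fm <- simulate_feature_matrix(colony$signatures, 8, seed = 22)
  res <- crossval_dfa(fm, n_iterations = 50, seed = 23)
  expect_equal(unname(rowSums(res$confusion)), rep(1, 6), tolerance = 1e-9)
  # equal per-class call counts: mean correct = mean of the diagonal
  expect_equal(res$mean_correct, 100 * mean(diag(res$confusion)),
               tolerance = 0.1)
})

test_that("pDFA is deterministic under a seed and scale-invariant", {
  fm <- null_features(4, calls = 6)
  r1 <- crossval_dfa(fm, n_iterations = 10, seed = 5)
  r2 <- crossval_dfa(fm, n_iterations = 10, seed = 5)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$confusion, r2$confusion)

  fm_scaled <- fm
  fm_scaled$f1 <- fm_scaled$f1 * 1000
  fm_scaled$f2 <- fm_scaled$f2 / 1000
  r3 <- crossval_dfa(fm_scaled, n_iterations = 10, seed = 5)
  expect_equal(r1$mean_correct, r3$mean_correct, tolerance = 1e-6)
})

test_that("the pooled-covariance classifier agrees with an independent LDA", {
  skip_if_not_installed("MASS")
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c("a", "b", "c"), each = n / 3)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "c", 2] <- X[y == "c", 2] + 2
  fit <- rivalcall:::lda_pooled_fit(X, y)
  mine <- rivalcall:::lda_pooled_predict(fit, X)
  ref <- as.character(predict(MASS::lda(X, grouping = y), X)$class)
  expect_gt(mean(mine == ref), 0.98)
})

test_that("permutation p-values respect the +1 bound and perfect separation", {
  # large enough validation sets that no permuted labelling classifies
  # perfectly, so the +1-corrected minimum is attained
  fm <- sep_features(n_males = 4, calls = 9)
  p <- pdfa_pvalue(fm, n_permutations = 99, n_iterations = 5, seed = 2)
  expect_equal(as.numeric(p), 1 / 100)
  expect_lte(as.numeric(p), 1)

  expect_error(pdfa_pvalue(fm, n_permutations = 0, seed = 1),
               "n_permutations")
})

test_that("pdfa wrapper returns one complete reproducible result", {
  fm <- null_features(4, calls = 6, seed = 3)
  r1 <- pdfa(fm, n_iterations = 5, n_permutations = 19, seed = 7)
  r2 <- pdfa(fm, n_iterations = 5, n_permutations = 19, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$mean_correct, r2$mean_correct)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("DFA input contracts are enforced", {
  fm <- null_features(2, calls = 3)
  fm$f1[1] <- NA
  expect_error(crossval_dfa(fm), "missing")
  expect_error(crossval_dfa(null_features(1, calls = 6)), "2 labels")
  expect_error(crossval_dfa(null_features(3, calls = 2)), "3 calls")
})

test_that("duplicated calls give zero within-distances", {
  base <- data.frame(male_id = rep(c("A", "B"), each = 4),
                     pulse_rate_hz = rep(c(1.2, 2.4), each = 4),
                     centroid_hz = rep(c(1600, 1800), each = 4),
                     year = rep(c(1, 2), 4))
  st <- stability_distances(base, grouping = "year")
  expect_true(all(st$distances$within == 0))
  expect_equal(st$per_individual$within_mean, c(0, 0))
})

test_that("constructed separation yields within < between for every male", {
  colony <- simulate_colony(10, seed = 31, jitter = 0.03)
  y1 <- simulate_feature_matrix(colony$signatures, 5, seed = 32, year = 1)
  # year 2 drifted: signatures shifted by far more than the jitter
  drift <- colony$signatures
  drift$pulse_rate <- drift$pulse_rate * 1.6
  y2 <- simulate_feature_matrix(drift, 5, seed = 33, year = 2)
  st <- stability_distances(rbind(y1, y2), grouping = "year")
  expect_true(all(st$per_individual$within_mean <
                    st$per_individual$between_mean))
  expect_lt(st$test$p_value, 0.05)
})

test_that("stable signatures across years show no significant drift", {
  colony <- simulate_colony(10, seed = 41, jitter = 0.05)
  y1 <- simulate_feature_matrix(colony$signatures, 6, seed = 42, year = 1)
  y2 <- simulate_feature_matrix(colony$signatures, 6, seed = 43, year = 2)
  st <- stability_distances(rbind(y1, y2), grouping = "year")
  expect_gt(st$test$p_value, 0.05)
  # between-individual distances dwarf within-individual ones
  expect_gt(mean(st$distances$between_individuals),
            mean(st$distances$within))
})

test_that("individuals lacking two calls per level are excluded with notice", {
  colony <- simulate_colony(4, seed = 51)
  y1 <- simulate_feature_matrix(colony$signatures, c(5, 5, 5, 1), seed = 52,
                                year = 1)
  y2 <- simulate_feature_matrix(colony$signatures, 5, seed = 53, year = 2)
  expect_message(st <- stability_distances(rbind(y1, y2), grouping = "year"),
                 "excluded")
  expect_equal(nrow(st$per_individual), 3L)
})
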