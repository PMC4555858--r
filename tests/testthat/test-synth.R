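test_that("season simulation respects the logistic win model", {
  # overwhelming strength difference: the strong male wins everything
  cfg <- colony_config(n_males = 2, strength = c(0, 10), steepness = 10,
                       n_interactions = 50, seed = 3)
  led <- simulate_season(cfg)
  expect_equal(nrow(led), 50L)
  expect_true(all(led$winner_id == "M02"))

  # empty season
  cfg0 <- colony_config(2, c(0, 0), n_interactions = 0, seed = 3)
  expect_equal(nrow(simulate_season(cfg0)), 0L)

  expect_error(colony_config(1, 0, 10, seed = 1), "n_males")
  expect_error(colony_config(3, 0, 10, steepness = 0, seed = 1), "steepness")
})

test_that("equal-strength males win at the fair-coin rate", {
  cfg <- colony_config(n_males = 20, strength = rep(0, 20),
                       n_interactions = 2000, seed = 17)
  led <- simulate_season(cfg)
  for (m in sprintf("M%02d", 1:20)) {
    n_m <- sum(led$winner_id == m | led$loser_id == m)
    wins <- sum(led$winner_id == m)
    se <- sqrt(0.25 / n_m)
    expect_lt(abs(wins / n_m - 0.5), 3 * se)
  }
})

test_that("empirical win rates match the logistic prediction", {
  for (d in c(0.3, 1)) {
    cfg <- colony_config(2, c(0, d), steepness = 1, n_interactions = 1e4,
                         seed = 23 + round(10 * d))
    led <- simulate_season(cfg)
    p_hat <- mean(led$winner_id == "M02")
    p <- plogis(d)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 1e4))
  }
})

test_that("season simulation is bit-reproducible under a fixed seed", {
  cfg <- colony_config(6, rnorm(6), 200, seed = 99)
  expect_identical(simulate_season(cfg), simulate_season(cfg))
})

test_that("call synthesis is deterministic at zero jitter and validates targets", {
  sig <- call_signature("X", 1.5, 6, 1400, 500, jitter = 0)
  w1 <- simulate_call(sig, sample_rate = 16000, seed = 5)
  w2 <- simulate_call(sig, sample_rate = 16000, seed = 5)
  expect_identical(w1$samples, w2$samples)

  expect_error(call_signature("X", 1.5, 6, 500, 700), "below")
  expect_error(call_signature("X", 1.5, 2, 1400, 500), "n_pulses")
  expect_error(call_signature("X", 1.5, 6, 1400, 500, jitter = 1), "jitter")
  expect_error(simulate_call(call_signature("X", 1.5, 6, 5000, 4500),
                             sample_rate = 8000, seed = 1), "Nyquist")
})

test_that("zero-jitter synthesis round-trips its signature targets", {
  sig <- call_signature("X", 2.1, 8, 1650, 520, jitter = 0)
  w <- simulate_call(sig, seed = 8)
  ft <- extract_features(w)
  expect_equal(ft$n_pulses, 8L)
  expect_equal(ft$pulse_rate_hz, 2.1, tolerance = 0.01 / 2.1)
  bin <- 48000 / 4096
  expect_lt(abs(ft$q25_hz - 520), bin)
  expect_lt(abs(ft$centroid_hz - 1650), bin)
})

test_that("the observed group-mean Q25 is reachable as a synthesis target", {
  sig <- call_signature("X", 1.7, 10, 1700, 643, jitter = 0)
  ft <- extract_features(simulate_call(sig, seed = 12))
  expect_lt(abs(ft$q25_hz - 643), 48000 / 4096)
})

test_that("paired response vectors carry the configured effect", {
  r0 <- simulate_responses(condition_effect = 0, n_trials = 10, noise_sd = 1,
                           seed = 2)
  d <- r0$latency_vocalize[r0$condition == "B"] -
    r0$latency_vocalize[r0$condition == "A"]
  expect_lt(abs(mean(d)), 3 * sqrt(2) / sqrt(10))

  # huge effect, vanishing noise: all pairs ordered identically
  r1 <- simulate_responses(condition_effect = 20, n_trials = 10,
                           noise_sd = 1e-9, seed = 2)
  d1 <- r1$latency_posture[r1$condition == "B"] -
    r1$latency_posture[r1$condition == "A"]
  expect_true(all(d1 > 0))

  expect_error(simulate_responses(0, 10, noise_sd = -1, seed = 1),
               "non-negative")

  # latencies are censored at the 90 s window and flagged
  r2 <- simulate_responses(condition_effect = 100, n_trials = 20,
                           noise_sd = 1, seed = 4)
  b <- r2[r2$condition == "B", ]
  expect_true(all(b$latency_vocalize <= 90))
  expect_true(all(b$truncated))
})

test_that("feature-level generator hits targets exactly at zero jitter", {
  colony <- simulate_colony(4, seed = 6, jitter = 0)
  fm <- simulate_feature_matrix(colony$signatures, 3, seed = 7)
  for (m in seq_len(4)) {
    s <- colony$signatures[m, ]
    rows <- fm[fm$male_id == s$male_id, ]
    expect_equal(rows$pulse_rate_hz, rep(s$pulse_rate, 3))
    expect_equal(rows$centroid_hz, rep(s$centroid_target, 3))
    expect_true(all(rows$q25_hz <= rows$q50_hz & rows$q50_hz <= rows$q75_hz))
  }
  expect_identical(fm, simulate_feature_matrix(colony$signatures, 3, seed = 7))
})

test_that("paired Wilcoxon power through the generator matches a direct oracle", {
  # effect sized for ~80% power at n = 10 (shift of ~1.05 s.d. of the
  # paired difference)
  effect <- 1.05 * sqrt(2)
  n_rep <- 300
  oracle <- mean(vapply(seq_len(n_rep), function(i) {
    set.seed(1e5 + i)
    a <- rnorm(10); b <- rnorm(10) + effect
    wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value < 0.05
  }, logical(1)))
  pkg <- mean(vapply(seq_len(n_rep), function(i) {
    r <- simulate_responses(condition_effect = c(0, 0, effect, 0, 0, 0),
                            n_trials = 10, noise_sd = 1, seed = 2e5 + i)
    compare_conditions(r$latency_vocalize[r$condition == "A"],
                       r$latency_vocalize[r$condition == "B"])$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(pkg - oracle), 0.05)
})
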