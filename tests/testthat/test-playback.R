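test_that("stimulus specs enforce kind-specific fields and repetitions", {
  expect_equal(stimulus_spec("natural_series")$repetitions, 3L)
  expect_equal(stimulus_spec("mod_q25", target_q25 = 536)$repetitions, 2L)
  expect_error(stimulus_spec("natural_series", target_q25 = 500), "relevant")
  expect_error(stimulus_spec("mod_pulse_rate"), "relevant")
  expect_error(stimulus_spec("mod_pulse_rate", target_pulse_rate = 3,
                             repetitions = 4), "2 or 3")
  expect_error(stimulus_spec("mod_q25", target_q25 = 536, gap = 0), "gap")
})

test_that("pulse-rate modification preserves count and pulse waveforms", {
  w <- medium_call()
  slow <- modify_pulse_rate(w, 1)
  ft <- extract_features(slow)
  expect_equal(ft$n_pulses, 14L)
  expect_equal(ft$pulse_rate_hz, 1, tolerance = 0.01)

  # the first pulse's samples are carried verbatim
  env <- envelope(w)
  on1 <- round(detect_pulses(env)[1] * w$sample_rate)
  seg <- w$samples[(on1 + 1):(on1 + 500)]
  env_s <- envelope(slow)
  on1s <- round(detect_pulses(env_s)[1] * slow$sample_rate)
  seg_s <- slow$samples[(on1s + 1):(on1s + 500)]
  expect_equal(seg_s, seg)

  # identity target: measured features essentially unchanged
  same <- modify_pulse_rate(w, extract_features(w)$pulse_rate_hz)
  expect_equal(extract_features(same)$pulse_rate_hz,
               extract_features(w)$pulse_rate_hz, tolerance = 1e-3)

  expect_error(modify_pulse_rate(w, 50), "overlap")
})

test_that("pulse-count modification hits the target and keeps the rate", {
  w <- medium_call()
  rate0 <- extract_features(w)$pulse_rate_hz

  up <- extract_features(modify_pulse_count(w, 21))
  expect_equal(up$n_pulses, 21L)
  expect_lt(abs(up$pulse_rate_hz - rate0) / rate0, 0.02)

  down <- modify_pulse_count(w, 7)
  fd <- extract_features(down)
  expect_equal(fd$n_pulses, 7L)
  expect_lt(abs(fd$pulse_rate_hz - rate0) / rate0, 0.02)

  # same count: bitwise identity
  expect_identical(modify_pulse_count(w, 14)$samples, w$samples)

  # 14 -> 7 -> 14 restores the count, not the waveform (lossy)
  back <- modify_pulse_count(down, 14)
  expect_equal(extract_features(back)$n_pulses, 14L)
  expect_false(length(back$samples) == length(w$samples) &&
                 all(back$samples == w$samples))

  expect_error(modify_pulse_count(w, 0), "target")
})

test_that("spectral tilt lands Q25 on target without disturbing timing", {
  w <- medium_call()
  f0 <- extract_features(w)
  bin <- w$sample_rate / 4096

  hi <- shift_q25(w, 804)
  fh <- extract_features(hi)
  expect_lt(abs(fh$q25_hz - 804), bin)
  expect_equal(fh$n_pulses, f0$n_pulses)
  expect_lt(abs(fh$pulse_rate_hz - f0$pulse_rate_hz) / f0$pulse_rate_hz, 0.01)
  expect_lt(abs(fh$duration_s - f0$duration_s) / f0$duration_s, 0.01)

  # identity target: spectrum unchanged within tolerance
  same <- shift_q25(w, f0$q25_hz)
  expect_lt(abs(extract_features(same)$q25_hz - f0$q25_hz), bin)

  expect_error(shift_q25(w, -5), "Nyquist")
  expect_error(shift_q25(w, 30000), "Nyquist")
})

test_that("series are composed sample-exactly and rendered at level", {
  fs <- 16000
  mk <- function(seed, n = 5) {
    simulate_call(call_signature("S", 1.7, n, 1500, 500, jitter = 0),
                  sample_rate = fs, seed = seed, max_iter = 1)
  }
  calls <- list(mk(1), mk(2, 6), mk(3, 7))
  sp <- stimulus_spec("natural_series")
  s <- build_series(calls, sp)
  expect_equal(length(s$samples),
               sum(vapply(calls, function(w) length(w$samples), numeric(1))) +
                 2L * round(3 * fs))
  expect_equal(peak_level(s), 116, tolerance = 0.01)

  # modified kinds repeat a single call twice
  s2 <- build_series(calls[1], stimulus_spec("mod_pulse_rate",
                                             target_pulse_rate = 1.2))
  mod <- modify_pulse_rate(calls[[1]], 1.2)
  expect_equal(length(s2$samples), 2L * length(mod$samples) + round(3 * fs))

  expect_error(build_series(calls[1:2], sp), "3 distinct")
  expect_error(build_series(calls, stimulus_spec("mod_q25",
                                                 target_q25 = 536)),
               "1 call")
})

test_that("response PCA retains eigenvalue>1 blocks with exact variance split", {
  set.seed(71)
  n <- 40
  a <- rnorm(n)
  b <- as.numeric(residuals(lm(rnorm(n) ~ a)))  # exactly uncorrelated with a
  # two perfectly correlated blocks of sizes 4 and 2
  resp <- data.frame(latency_orient = a, latency_posture = a,
                     latency_vocalize = a, latency_move = a,
                     n_calls = b, distance_moved = b)
  pc <- response_pca(resp)
  expect_equal(pc$n_retained, 2L)
  expect_equal(sort(unname(pc$variance_explained), decreasing = TRUE),
               c(400 / 6, 200 / 6), tolerance = 1e-6)
  # orthogonal rotation preserves the loading cross-product
  expect_equal(sum(pc$variance_explained), 100,
               tolerance = 1e-9)
})

test_that("varimax rotation conserves retained variance exactly", {
  set.seed(72)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  resp <- data.frame(
    latency_orient = 0.8 * f1 + 0.3 * rnorm(n),
    latency_posture = 0.9 * f1 + 0.3 * rnorm(n),
    latency_vocalize = 0.7 * f1 + 0.4 * rnorm(n),
    n_calls = -0.8 * f1 + 0.3 * rnorm(n),
    latency_move = 0.9 * f2 + 0.3 * rnorm(n),
    distance_moved = -0.8 * f2 + 0.4 * rnorm(n))
  Z <- scale(as.matrix(resp))
  eg <- eigen(cor(as.matrix(resp)))
  k <- sum(eg$values > 1)
  pc <- response_pca(resp)
  expect_equal(pc$n_retained, k)
  expect_equal(sum(pc$variance_explained) / 100 * ncol(resp),
               sum(eg$values[seq_len(k)]), tolerance = 1e-9)
  # scores are uncorrelated with unit variance
  expect_equal(unname(diag(cov(pc$scores))), rep(1, k), tolerance = 1e-9)
})

test_that("a planted dominant factor is recovered up to sign", {
  set.seed(73)
  n <- 80
  weights <- c(0.15, 0.7, 0.9, -0.9, 0.8, -0.75)
  f <- rnorm(n)
  resp <- as.data.frame(sapply(seq_along(weights), function(j) {
    weights[j] * f + 0.3 * rnorm(n)
  }))
  names(resp) <- c("latency_orient", "latency_posture", "latency_vocalize",
                   "n_calls", "latency_move", "distance_moved")
  pc <- response_pca(resp)
  r <- cor(pc$loadings[, 1], weights)
  expect_gt(abs(r), 0.95)
  # sign convention: latencies load positively on each component
  expect_gt(sum(pc$loadings[grep("latency", rownames(pc$loadings)), 1]), 0)
})

test_that("constant measures are dropped with a notice", {
  set.seed(74)
  resp <- data.frame(latency_orient = rnorm(20), latency_posture = rnorm(20),
                     n_calls = rep(3, 20), distance_moved = rnorm(20))
  expect_message(pc <- response_pca(resp), "n_calls")
  expect_false("n_calls" %in% rownames(pc$loadings))
})

test_that("paired Wilcoxon comparisons match full enumeration for n <= 12", {
  # all-positive distinct differences at n = 10: the textbook minimum
  b <- c(2.1, 3.7, 1.4, 5.9, 4.2, 6.8, 0.3, 7.5, 8.1, 2.9)
  a <- b + seq(0.5, 5, by = 0.5)
  expect_equal(compare_conditions(a, b)$p_value, 2 / 1024)

  expect_equal(compare_conditions(a, a)$p_value, 1)
  expect_message(compare_conditions(a, a), "zero")

  set.seed(75)
  for (n in 5:12) {
    x <- rnorm(n); y <- rnorm(n)
    got <- compare_conditions(x, y)$p_value
    want <- enumerate_signed_rank(x - y)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the distance-trend permutation test behaves at its edges", {
  d <- c(40, 30, 20, 10)
  flat <- data.frame(male_id = rep(sprintf("m%d", 1:5), each = 4),
                     distance = rep(d, 5), score = rep(0.7, 20))
  res <- alpha_distance_test(flat, n_permutations = 200, seed = 1)
  expect_equal(res$p_value, 1)

  # p can never undercut 1/(n_perm + 1)
  expect_gte(res$p_value, 1 / 201)

  # strong close-range effect: scores drop sharply at 10 m
  set.seed(76)
  eff <- do.call(rbind, lapply(1:5, function(m) {
    data.frame(male_id = sprintf("m%d", m), distance = d,
               score = c(0.5, 0.4, 0.3, -2) + rnorm(4, 0, 0.1))
  }))
  res2 <- alpha_distance_test(eff, n_permutations = 500, seed = 2)
  expect_lt(res2$p_value, 0.05)

  # incomplete blocks are excluded with a notice
  expect_message(
    res3 <- alpha_distance_test(rbind(eff, data.frame(male_id = "m9",
                                                      distance = 40,
                                                      score = 1)),
                                n_permutations = 100, seed = 3),
    "m9")
  expect_equal(res3$n_males, 5L)
})
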