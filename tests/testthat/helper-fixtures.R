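# Shared fixtures and independent oracles, all built in code.

# A ledger of n decided contests with explicit flags, defaults quiet.
make_ledger <- function(winner, loser, date = seq_along(winner),
                        winner_vocalized = TRUE, loser_vocalized = FALSE,
                        contact = "none", decided = TRUE) {
  interaction_records(data.frame(
    date = date, winner_id = winner, loser_id = loser,
    winner_vocalized = winner_vocalized, loser_vocalized = loser_vocalized,
    contact = contact, decided = decided, stringsAsFactors = FALSE))
}

# Deterministic envelope fixture: hann-shaped pulses of width `width_s`
# starting every `spacing_s`, as a call_envelope object.
make_envelope <- function(n_pulses, spacing_s, width_s, fs = 8000,
                          tail_s = 0.2) {
  n <- round(((n_pulses - 1) * spacing_s + width_s + tail_s) * fs)
  env <- numeric(n)
  nw <- round(width_s * fs)
  pulse <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  for (i in seq_len(n_pulses)) {
    at <- round((i - 1) * spacing_s * fs) + 1L
    env[at:(at + nw - 1L)] <- pmax(env[at:(at + nw - 1L)], pulse)
  }
  structure(list(env = env, sample_rate = fs, degenerate = FALSE),
            class = "call_envelope")
}

# Multi-tone waveform whose energy sits on exact analysis-bin frequencies
# (multiples of fs/1024 so the tones are periodic in 1024-, 4096- and
# 8192-point windows); returns the waveform and its exact line spectrum.
make_multitone <- function(seed, fs = 8192, dur = 2) {
  set.seed(seed)
  k <- sample(5:12, 1)
  freqs <- sort(sample(seq(2, 400, by = 2), k)) * fs / 1024
  amps <- runif(k, 0.2, 1)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rowSums(vapply(seq_len(k),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  list(wave = call_waveform(x / max(abs(x)), fs),
       freqs = freqs, power = amps^2)
}

# Brute-force cumulative-spectrum oracle: direct DFT of the full signal,
# cumulative energy sum, quartiles read off the cumulative curve.
oracle_quartiles <- function(x, fs) {
  n <- length(x)
  P <- (Mod(stats::fft(x))^2)[seq_len(n %/% 2 + 1)]
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  cum <- cumsum(P) / sum(P)
  list(q25 = f[which(cum >= 0.25)[1]],
       q50 = f[which(cum >= 0.50)[1]],
       q75 = f[which(cum >= 0.75)[1]],
       centroid = sum(f * P) / sum(P))
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of all
# 2^n sign assignments (no ties/zeros assumed).
enumerate_signed_rank <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# A jitter-free medium-male call (1.7 Hz, 14 pulses), cached per session.
medium_call <- local({
  cache <- NULL
  function(fs = 48000) {
    if (is.null(cache)) {
      sig <- call_signature("BASE", pulse_rate = 1.7, n_pulses = 14,
                            centroid_target = 1700, q25_target = 643,
                            jitter = 0)
      cache <<- simulate_call(sig, sample_rate = fs, seed = 20151)
    }
    cache
  }
})
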