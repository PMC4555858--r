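# Playback stimulus construction (natural series and size-cue-modified
# calls) and behavioural response scoring.

# Locate pulse chunks on a call: onset/offset sample indices from the
# smoothed envelope, plus a symmetric pad of context samples so each pulse
# (including its sub-threshold attack/decay) is carried verbatim.
pulse_chunks <- function(wave, threshold = 0.15, min_gap = 0.05,
                         smooth_pts = 41L) {
  env <- envelope(wave, smooth_pts = smooth_pts)
  fs <- wave$sample_rate
  onsets_t <- detect_pulses(env, threshold = threshold, min_gap = min_gap)
  if (!length(onsets_t)) stop("no detectable pulses", call. = FALSE)
  onset_idx <- round(onsets_t * fs) + 1L
  n <- length(onset_idx)
  above <- env$env >= threshold
  len <- length(above)
  offset_idx <- integer(n)
  for (i in seq_len(n)) {
    to <- if (i < n) onset_idx[i + 1L] - 1L else len
    reg <- onset_idx[i]:to
    offset_idx[i] <- reg[max(which(above[reg]))]
  }
  gaps <- if (n > 1L) onset_idx[-1L] - offset_idx[-n] else round(0.05 * fs)
  pad <- max(1L, min(round(0.025 * fs), floor(min(gaps) / 2) - 1L))
  list(onset_idx = onset_idx, offset_idx = offset_idx, pad = pad,
       env = env, fs = fs,
       duration = (offset_idx[n] - onset_idx[1L]) / fs)
}

# Rebuild a call by placing the original pulse chunks at new onset sample
# positions over a silent canvas.
place_chunks <- function(wave, ch, new_onset_idx) {
  fs <- wave$sample_rate
  n <- length(new_onset_idx)
  starts <- new_onset_idx - (ch$onset_idx[seq_len(n)] -
                               pmax(ch$onset_idx[seq_len(n)] - ch$pad, 1L))
  lens <- pmin(ch$offset_idx[seq_len(n)] + ch$pad, length(wave$samples)) -
    pmax(ch$onset_idx[seq_len(n)] - ch$pad, 1L) + 1L
  if (n > 1L && any(starts[-1L] <= starts[-n] + lens[-n])) {
    stop("infeasible target: pulses would overlap", call. = FALSE)
  }
  out <- numeric(max(starts + lens - 1L) + ch$pad)
  for (i in seq_len(n)) {
    src_from <- pmax(ch$onset_idx[i] - ch$pad, 1L)
    src_to <- pmin(ch$offset_idx[i] + ch$pad, length(wave$samples))
    seg <- wave$samples[src_from:src_to]
    out[starts[i]:(starts[i] + length(seg) - 1L)] <- seg
  }
  call_waveform(out, fs, calibration = wave$calibration,
                male_id = wave$male_id, year = wave$year,
                context = wave$context)
}

#' Change a call's pulse rate by rescaling the inter-pulse silences
#'
#' Each pulse waveform is preserved verbatim; the silences between pulses
#' are rescaled uniformly so that the re-measured pulse rate (pulses per
#' measured envelope duration) equals `target`. The pulse count is
#' unchanged.
#'
#' @param call a [call_waveform()] with detectable pulses.
#' @param target desired pulse rate, Hz.
#' @param threshold,min_gap,smooth_pts pulse-detection settings.
#' @return the modified [call_waveform()].
#' @export
modify_pulse_rate <- function(call, target, threshold = 0.15,
                              min_gap = 0.05, smooth_pts = 41L) {
  check_scalar_number(target, "target")
  if (target <= 0) stop("`target` must be > 0", call. = FALSE)
  ch <- pulse_chunks(call, threshold, min_gap, smooth_pts)
  n <- length(ch$onset_idx)
  if (n < 2L) stop("need >= 2 pulses to rescale inter-pulse intervals",
                   call. = FALSE)
  tail_w <- ch$offset_idx[n] - ch$onset_idx[n]      # samples
  span_new <- round(n / target * ch$fs) - tail_w    # onset span, samples
  if (span_new <= 0) stop("infeasible target: pulses would overlap",
                          call. = FALSE)
  rel <- ch$onset_idx - ch$onset_idx[1L]
  new_onsets <- ch$onset_idx[1L] + round(rel * span_new / rel[n])
  place_chunks(call, ch, new_onsets)
}

#' Change a call's pulse count, preserving its pulse rate
#'
#' Pulses are deleted from the end of the call, or appended by repeating
#' the final pulse at the prevailing (final) inter-pulse interval, until
#' the count equals `target`; the gaps are then rescaled so the re-measured
#' pulse rate (pulses / measured duration) is restored — under this
#' package's rate convention, changing the count at a fixed interval alone
#' would shift the measured rate. When `target` equals the current count
#' the call is returned bitwise unchanged.
#'
#' @param call a [call_waveform()] with at least one detectable pulse.
#' @param target desired pulse count (>= 1).
#' @inheritParams modify_pulse_rate
#' @return the modified [call_waveform()].
#' @export
modify_pulse_count <- function(call, target, threshold = 0.15,
                               min_gap = 0.05, smooth_pts = 41L) {
  target <- check_count(target, "target")
  if (target < 1L) stop("`target` must be >= 1", call. = FALSE)
  ch <- pulse_chunks(call, threshold, min_gap, smooth_pts)
  n <- length(ch$onset_idx)
  if (target == n) return(call)
  rate0 <- n / ch$duration
  if (target < n) {
    keep <- seq_len(target)
    ch2 <- ch
    ch2$onset_idx <- ch$onset_idx[keep]
    ch2$offset_idx <- ch$offset_idx[keep]
    out <- place_chunks(call, ch2, ch$onset_idx[keep])
  } else {
    if (n < 2L) stop("need >= 2 pulses to infer the prevailing interval",
                     call. = FALSE)
    delta <- ch$onset_idx[n] - ch$onset_idx[n - 1L]
    extra <- target - n
    ch2 <- ch
    ch2$onset_idx <- c(ch$onset_idx, rep(ch$onset_idx[n], extra))
    ch2$offset_idx <- c(ch$offset_idx, rep(ch$offset_idx[n], extra))
    new_onsets <- c(ch$onset_idx, ch$onset_idx[n] + delta * seq_len(extra))
    out <- place_chunks(call, ch2, new_onsets)
  }
  if (target >= 2L) out <- modify_pulse_rate(out, rate0, threshold, min_gap,
                                             smooth_pts)
  out
}

#' Shift a call's first spectral energy quartile by spectral tilt
#'
#' Reshapes the spectral envelope with a smooth zero-phase power-law tilt
#' `H(f) = ((f + f0)/f0)^a`, tuning the exponent `a` in a closed loop
#' until the re-measured Q25 is within one FFT bin of `target`. Because
#' the tilt is smooth and zero-phase, the temporal structure (pulse count,
#' duration, rate) is essentially unchanged. Pitch-synchronous resynthesis
#' is deliberately not used: these calls are pulsatile broadband noise and
#' carry no pitch to synchronize to.
#'
#' @param call a [call_waveform()].
#' @param target desired Q25, Hz (inside (0, Nyquist)).
#' @param nfft spectral analysis segment length.
#' @param f0 tilt knee frequency, Hz (default 200; smaller values steepen
#'   the low-frequency action of the tilt).
#' @inheritParams modify_pulse_rate
#' @return the modified [call_waveform()].
#' @export
shift_q25 <- function(call, target, nfft = 4096L, f0 = 200,
                      threshold = 0.15, min_gap = 0.05, smooth_pts = 41L) {
  check_scalar_number(target, "target")
  nyq <- call$sample_rate / 2
  if (target <= 0 || target >= nyq) {
    stop("`target` must lie inside (0, Nyquist)", call. = FALSE)
  }
  bin <- call$sample_rate / nfft
  peak0 <- max(abs(call$samples))
  measure <- function(a) {
    w <- apply_tilt(call, a, f0, peak0)
    list(wave = w,
         q25 = extract_features(w, threshold = threshold, min_gap = min_gap,
                                smooth_pts = smooth_pts,
                                nfft = nfft)$q25_hz)
  }
  lo <- -14; hi <- 14
  m0 <- measure(0)
  if (abs(m0$q25 - target) <= 0.55 * bin) return(m0$wave)
  f_lo <- measure(lo)$q25 - target
  f_hi <- measure(hi)$q25 - target
  if (sign(f_lo) == sign(f_hi)) {
    stop("target Q25 outside the attainable range for this call",
         call. = FALSE)
  }
  best <- m0
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    m <- measure(mid)
    err <- m$q25 - target
    if (abs(err) < abs(best$q25 - target)) best <- m
    if (abs(err) <= 0.55 * bin) return(m$wave)
    if (sign(err) == sign(f_lo)) { lo <- mid; f_lo <- err } else hi <- mid
  }
  best$wave
}

apply_tilt <- function(call, a, f0, peak0) {
  if (a == 0) return(call)
  x <- call$samples
  n <- length(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (seq_len(nfft) - 1) * call$sample_rate / nfft
  f <- pmin(f, call$sample_rate - f)
  H <- ((f + f0) / f0)^(a / 2)   # amplitude tilt; power tilt exponent a
  y <- Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
  y <- y / max(abs(y)) * peak0
  call_waveform(y, call$sample_rate, calibration = call$calibration,
                male_id = call$male_id, year = call$year,
                context = call$context)
}

#' Specification for one playback stimulus series
#'
#' @param kind `"natural_series"` (three different natural calls) or one of
#'   the modified kinds `"mod_pulse_rate"`, `"mod_pulse_count"`,
#'   `"mod_q25"` (two repetitions of a single modified call; fewer
#'   repetitions limit habituation when each male hears many variants).
#' @param target_pulse_rate,target_n_pulses,target_q25 the manipulation
#'   target; exactly the field relevant to `kind` must be set.
#' @param repetitions renditions per series; defaults to 3 for natural
#'   series and 2 for modified kinds; must be 2 or 3.
#' @param gap silence between renditions, s (default 3).
#' @param level rendered peak level, dB re 20 uPa at 1 m (default 116).
#' @return list of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(kind = c("natural_series", "mod_pulse_rate",
                                   "mod_pulse_count", "mod_q25"),
                          target_pulse_rate = NULL, target_n_pulses = NULL,
                          target_q25 = NULL, repetitions = NULL,
                          gap = 3, level = 116) {
  kind <- match.arg(kind)
  repetitions <- repetitions %||% if (kind == "natural_series") 3L else 2L
  if (!repetitions %in% c(2L, 3L)) {
    stop("`repetitions` must be 2 or 3", call. = FALSE)
  }
  if (gap <= 0) stop("`gap` must be > 0", call. = FALSE)
  set <- c(rate = !is.null(target_pulse_rate),
           count = !is.null(target_n_pulses),
           q25 = !is.null(target_q25))
  need <- switch(kind, natural_series = c(FALSE, FALSE, FALSE),
                 mod_pulse_rate = c(TRUE, FALSE, FALSE),
                 mod_pulse_count = c(FALSE, TRUE, FALSE),
                 mod_q25 = c(FALSE, FALSE, TRUE))
  if (!all(set == need)) {
    stop("exactly the target field relevant to `kind` must be set",
         call. = FALSE)
  }
  structure(list(kind = kind, target_pulse_rate = target_pulse_rate,
                 target_n_pulses = target_n_pulses, target_q25 = target_q25,
                 repetitions = as.integer(repetitions), gap = gap,
                 level = level),
            class = "stimulus_spec")
}

#' Build a calibrated playback series from calls and a stimulus spec
#'
#' Natural series concatenate three different calls; modified kinds apply
#' the requested manipulation to a single call and repeat it. Renditions
#' are separated by exactly `gap` seconds of silence (sample-exact), and
#' the output is peak-normalized with its calibration set so that the
#' rendered level at 1 m equals `spec$level` dB peak re 20 uPa (the
#' calibration maps digital full scale to pascals at 1 m).
#'
#' @param calls list of [call_waveform()]s sharing one sample rate: 3
#'   distinct calls for a natural series, 1 call for modified kinds.
#' @param spec a [stimulus_spec()].
#' @return a calibrated [call_waveform()] of the full series.
#' @export
build_series <- function(calls, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (inherits(calls, "call_waveform")) calls <- list(calls)
  if (!length(calls)) stop("`calls` must be non-empty", call. = FALSE)
  fs <- calls[[1]]$sample_rate
  if (any(vapply(calls, function(w) w$sample_rate, numeric(1)) != fs)) {
    stop("all calls must share one sample rate", call. = FALSE)
  }
  if (spec$kind == "natural_series") {
    if (length(calls) != 3L) {
      stop("natural series requires exactly 3 distinct calls", call. = FALSE)
    }
    renditions <- calls
  } else {
    if (length(calls) != 1L) {
      stop("modified series requires exactly 1 call", call. = FALSE)
    }
    mod <- switch(spec$kind,
      mod_pulse_rate = modify_pulse_rate(calls[[1]], spec$target_pulse_rate),
      mod_pulse_count = modify_pulse_count(calls[[1]], spec$target_n_pulses),
      mod_q25 = shift_q25(calls[[1]], spec$target_q25))
    renditions <- rep(list(mod), spec$repetitions)
  }
  gap_samples <- numeric(round(spec$gap * fs))
  pieces <- list()
  for (i in seq_along(renditions)) {
    pieces[[length(pieces) + 1L]] <- renditions[[i]]$samples
    if (i < length(renditions)) pieces[[length(pieces) + 1L]] <- gap_samples
  }
  out <- unlist(pieces, use.names = FALSE)
  out <- out / max(abs(out))
  calibration <- 20e-6 * 10^(spec$level / 20)
  call_waveform(out, fs, calibration = calibration)
}

#' Collapse six behavioural response measures into rotated PC scores
#'
#' PCA on the correlation matrix of the (standardized) measures; components
#' with eigenvalue greater than 1 are retained and varimax-rotated.
#' Constant measures are dropped with a notice. Each component's sign is
#' fixed so that latency measures load positively — a strong aggressive
#' reaction (short latencies, approach, calling) therefore yields negative
#' scores, the convention used throughout the playback analyses.
#'
#' @param responses data frame of response trials; non-measure columns
#'   (`trial`, `condition`, `truncated`) are ignored if present.
#' @return object of class `"pc_scores"`: `loadings` (measures x retained
#'   components), `variance_explained` (% per rotated component),
#'   `scores` (trials x components), `n_retained`, `eigenvalues`,
#'   `dropped`.
#' @export
response_pca <- function(responses) {
  df <- as.data.frame(responses)
  df <- df[, setdiff(names(df), c("trial", "condition", "truncated", "male_id",
                                  "distance")), drop = FALSE]
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  sds <- vapply(df, stats::sd, numeric(1))
  dropped <- names(df)[sds == 0]
  if (length(dropped)) {
    message("constant measure(s) dropped: ", paste(dropped, collapse = ", "))
    df <- df[, sds > 0, drop = FALSE]
  }
  p <- ncol(df)
  if (p < 2L) stop("need >= 2 non-constant measures", call. = FALSE)
  Z <- base::scale(as.matrix(df))
  eg <- eigen(stats::cor(as.matrix(df)), symmetric = TRUE)
  k <- sum(eg$values > 1)
  if (k == 0L) {
    message("no eigenvalue exceeds 1; retaining the first component")
    k <- 1L
  }
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  lam <- eg$values[seq_len(k)]
  L <- V %*% diag(sqrt(lam), k)
  Tsc <- Z %*% V %*% diag(1 / sqrt(lam), k)   # unit-variance PC scores
  if (k >= 2L) {
    vm <- stats::varimax(L)
    L <- L %*% vm$rotmat
    Tsc <- Tsc %*% vm$rotmat
  }
  lat <- grep("latency", colnames(df))
  if (length(lat)) {
    for (j in seq_len(k)) {
      if (sum(L[lat, j]) < 0) { L[, j] <- -L[, j]; Tsc[, j] <- -Tsc[, j] }
    }
  }
  dimnames(L) <- list(colnames(df), paste0("PC", seq_len(k)))
  colnames(Tsc) <- paste0("PC", seq_len(k))
  structure(list(loadings = L,
                 variance_explained = 100 * colSums(L^2) / p,
                 scores = Tsc, n_retained = k,
                 eigenvalues = eg$values, dropped = dropped),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("response PCA: %d component(s) retained, explaining %s%% of variance\n",
              x$n_retained,
              paste(sprintf("%.1f", x$variance_explained), collapse = " + ")))
  invisible(x)
}

#' Matched-pairs Wilcoxon comparison of two paired score vectors
#'
#' Exact signed-rank distribution for n <= 25 (when ties and zero
#' differences permit), normal approximation with tie correction
#' otherwise; two-sided.
#'
#' @param scores_a,scores_b paired numeric vectors (n >= 5 recommended).
#' @return list with `statistic` (V), `p_value`, `n`, `method`.
#' @export
compare_conditions <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must be paired (equal length)", call. = FALSE)
  }
  n <- length(scores_a)
  d <- scores_a - scores_b
  if (all(d == 0)) {
    message("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = n,
                method = "degenerate (all differences zero)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                       exact = n <= 25, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
       method = wt$method)
}

#' Within-male permutation test for a distance trend in playback response
#'
#' For designs where each male is tested at several speaker distances,
#' tests whether PC scores trend with distance using a within-male
#' permutation scheme: the statistic is the sum over males of the inner
#' product between z-scored distances and scores, and scores are permuted
#' within each male's block. This is a deliberately assumption-light
#' substitute for a mixed-model analysis of the crossed design; it tests
#' only the monotone-trend component.
#'
#' @param scores data frame with `male_id`, `distance` (m) and `score`.
#' @param distances the complete set of distances each male must have
#'   (default `c(40, 30, 20, 10)`); males with incomplete blocks are
#'   excluded with a notice.
#' @param n_permutations permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `statistic`, `p_value` (two-sided), `n_males`,
#'   `n_permutations`.
#' @export
alpha_distance_test <- function(scores, distances = c(40, 30, 20, 10),
                                n_permutations = 1000L, seed = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  blocks <- split(scores, scores$male_id)
  complete <- vapply(blocks, function(b) {
    setequal(b$distance, distances) && nrow(b) == length(distances)
  }, logical(1))
  if (any(!complete)) {
    message("excluded (incomplete distance block): ",
            paste(names(blocks)[!complete], collapse = ", "))
  }
  blocks <- blocks[complete]
  if (!length(blocks)) stop("no complete blocks", call. = FALSE)
  cvec <- as.numeric(base::scale(distances))
  stat <- function(perm) {
    sum(vapply(blocks, function(b) {
      s <- b$score[match(distances, b$distance)]
      if (perm) s <- sample(s)
      sum(cvec * s)
    }, numeric(1)))
  }
  with_local_seed(seed, {
    obs <- stat(FALSE)
    perm <- vapply(seq_len(n_permutations), function(i) stat(TRUE), numeric(1))
    p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_permutations + 1)
    list(statistic = obs, p_value = p, n_males = length(blocks),
         n_permutations = n_permutations)
  })
}
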