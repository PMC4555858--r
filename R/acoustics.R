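# Temporal and spectral feature extraction for pulsed threat calls.
#
# The measurement chain mirrors standard bioacoustic practice for impulsive
# broadband calls: pulse-train analysis on the smoothed Hilbert envelope of
# the band-limited (0-6 kHz) signal, and energy-distribution statistics on a
# Welch-averaged power spectrum of the rhythmic portion of the call.

#' Construct a calibrated call waveform
#'
#' @param samples numeric vector in \[-1, 1\] (digital full scale).
#' @param sample_rate sampling rate in Hz.
#' @param calibration pascals per digital full-scale unit at 1 m, or `NULL`
#'   when the recording is uncalibrated (all features except the peak level
#'   are amplitude-invariant).
#' @param male_id,year,context optional metadata; `context` is `"directed"`
#'   (emitted towards another male) or `"non_directed"`.
#' @return object of class `"call_waveform"`.
#' @export
call_waveform <- function(samples, sample_rate, calibration = NULL,
                          male_id = NA_character_, year = NA_integer_,
                          context = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  check_scalar_number(sample_rate, "sample_rate")
  if (sample_rate <= 0) stop("`sample_rate` must be > 0", call. = FALSE)
  if (!is.null(calibration)) {
    check_scalar_number(calibration, "calibration")
    if (calibration <= 0) stop("`calibration` must be > 0", call. = FALSE)
  }
  if (!is.na(context) && !context %in% c("directed", "non_directed")) {
    stop("`context` must be \"directed\" or \"non_directed\"", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 calibration = calibration,
                 male_id = male_id, year = year, context = context),
            class = "call_waveform")
}

#' @export
print.call_waveform <- function(x, ...) {
  cat(sprintf("call_waveform: %.3f s at %g Hz%s%s\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              if (!is.null(x$calibration)) ", calibrated" else "",
              if (!is.na(x$male_id)) paste0(", male ", x$male_id) else ""))
  invisible(x)
}

# Analytic-signal magnitude via the frequency-domain Hilbert transform,
# zero-padded to a fast FFT length.
hilbert_envelope <- function(x) {
  n <- length(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  h[1] <- 1
  if (nfft %% 2 == 0) {
    h[nfft / 2 + 1] <- 1
    h[2:(nfft / 2)] <- 2
  } else {
    h[2:((nfft + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / nfft)[seq_len(n)]
}

# Zero-phase band-limiting by zeroing FFT bins outside [lo, hi] Hz.
fft_bandlimit <- function(x, fs, lo, hi) {
  n <- length(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (seq_len(nfft) - 1) * fs / nfft
  f <- pmin(f, fs - f)  # two-sided bin frequencies
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Smoothed, normalized amplitude envelope of a call
#'
#' Band-limits the signal to `band` (default 0-6 kHz, the band that carries
#' the pulsed energy), takes the Hilbert magnitude, smooths it with a
#' moving average of `smooth_pts` samples, and peak-normalizes to 1. An
#' all-zero input is returned flagged degenerate rather than rescaled.
#'
#' @param wave a [call_waveform()].
#' @param smooth_pts moving-average window length in samples (default 41 at
#'   the native rate; the window in milliseconds therefore depends on the
#'   sampling rate, which is why it is exposed).
#' @param band two-element numeric, Hz.
#' @return object of class `"call_envelope"`: list with `env` (normalized),
#'   `sample_rate`, `degenerate`.
#' @export
envelope <- function(wave, smooth_pts = 41L, band = c(0, 6000)) {
  stopifnot(inherits(wave, "call_waveform"))
  x <- wave$samples
  if (length(x) <= smooth_pts) {
    stop("waveform shorter than the smoothing window", call. = FALSE)
  }
  hi <- min(band[2], wave$sample_rate / 2)
  x <- fft_bandlimit(x, wave$sample_rate, band[1], hi)
  env <- hilbert_envelope(x)
  env <- as.numeric(stats::filter(env, rep(1 / smooth_pts, smooth_pts),
                                  sides = 2))
  env[is.na(env)] <- 0
  peak <- max(env)
  degenerate <- !is.finite(peak) || peak <= 0
  if (!degenerate) env <- env / peak
  structure(list(env = env, sample_rate = wave$sample_rate,
                 degenerate = degenerate),
            class = "call_envelope")
}

#' Detect pulse onsets on a normalized envelope
#'
#' Onsets are threshold up-crossings of the normalized envelope, keeping
#' only crossings separated by at least `min_gap` seconds from the last
#' accepted onset (so amplitude wiggles within one pulse are not counted
#' twice).
#'
#' @param env a `"call_envelope"`.
#' @param threshold detection threshold as a fraction of the envelope
#'   maximum (default 0.15).
#' @param min_gap minimum onset separation in seconds (default 0.05).
#' @return numeric vector of onset times (s); empty for a degenerate
#'   envelope or a threshold above the maximum.
#' @export
detect_pulses <- function(env, threshold = 0.15, min_gap = 0.05) {
  stopifnot(inherits(env, "call_envelope"))
  if (env$degenerate) return(numeric(0))
  e <- env$env
  above <- e >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(cross)) return(numeric(0))
  fs <- env$sample_rate
  keep <- cross[1]
  for (i in cross[-1]) {
    if ((i - keep[length(keep)]) / fs >= min_gap) keep <- c(keep, i)
  }
  (keep - 1) / fs
}

#' Temporal features: duration, pulse count, pulse rate
#'
#' Duration is measured from the first to the last above-threshold sample
#' of the smoothed envelope (onset of the first pulse to offset of the
#' last), and the pulse rate is `n_pulses / duration` — the number of
#' pulses per second over the rhythmic portion, not `(n - 1)` over the
#' onset span. Calls are assumed pre-trimmed to their rhythmic portion
#' (introductory/terminal snorts removed upstream).
#'
#' @param onsets onset times from [detect_pulses()].
#' @param env the `"call_envelope"` the onsets were detected on.
#' @param threshold the detection threshold used (defines on/offset).
#' @return list with `duration` (s), `n_pulses`, `pulse_rate` (Hz).
#' @export
temporal_features <- function(onsets, env, threshold = 0.15) {
  stopifnot(inherits(env, "call_envelope"))
  if (length(onsets) < 1L) {
    stop("no pulses detected: temporal features undefined", call. = FALSE)
  }
  idx <- which(env$env >= threshold)
  duration <- (idx[length(idx)] - idx[1]) / env$sample_rate
  if (duration <= 0) stop("degenerate rhythmic portion", call. = FALSE)
  n <- length(onsets)
  list(duration = duration, n_pulses = n, pulse_rate = n / duration)
}

# Welch-averaged one-sided power spectrum: Hann window, `nfft`-point
# segments, 50% overlap. Returns bin frequencies and mean power.
welch_psd <- function(x, fs, nfft = 4096L) {
  n <- length(x)
  if (n < nfft) nfft <- 2^floor(log2(n))
  if (nfft < 8) stop("signal too short for spectral analysis", call. = FALSE)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / nfft)
  step <- nfft %/% 2
  starts <- seq(1L, n - nfft + 1L, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * win
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nfft %/% 2 + 1)]
  }
  list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
       power = acc / length(starts),
       bin_width = fs / nfft)
}

#' Energy-distribution summaries of a power spectrum
#'
#' Given a one-sided power spectrum, returns the frequency of maximal
#' energy, the energy-weighted mean frequency (spectral centroid), the
#' frequencies below which 25/50/75% of the total energy lies (Q25, Q50,
#' Q75), and the -12 dB bandwidth: the width of the contiguous band around
#' the spectral peak within which power stays within 12 dB of the maximum.
#' All quantities are reported at bin resolution, without interpolation.
#'
#' @param freq bin frequencies (Hz).
#' @param power non-negative spectral power per bin.
#' @return list with `f_max`, `centroid`, `q25`, `q50`, `q75`, `bw12` (Hz).
#' @export
spectral_summary <- function(freq, power) {
  if (length(freq) != length(power) || any(power < 0)) {
    stop("`freq` and `power` must be matching non-negative vectors",
         call. = FALSE)
  }
  total <- sum(power)
  if (total <= 0) stop("all-zero spectrum: features undefined", call. = FALSE)
  cum <- cumsum(power) / total
  qat <- function(p) freq[which(cum >= p)[1]]
  imax <- which.max(power)
  thr <- power[imax] * 10^(-12 / 10)
  lo <- imax
  while (lo > 1L && power[lo - 1L] >= thr) lo <- lo - 1L
  hi <- imax
  while (hi < length(power) && power[hi + 1L] >= thr) hi <- hi + 1L
  list(f_max = freq[imax],
       centroid = sum(freq * power) / total,
       q25 = qat(0.25), q50 = qat(0.50), q75 = qat(0.75),
       bw12 = freq[hi] - freq[lo])
}

#' Spectral features of a call waveform
#'
#' Computes [spectral_summary()] on a Welch-averaged periodogram (Hann
#' window, `nfft`-point segments, 50% overlap) of the supplied samples.
#' Within [extract_features()] the spectrum is taken over the rhythmic
#' portion of the call only.
#'
#' @param wave a [call_waveform()].
#' @param nfft FFT segment length (default 4096; spectral resolution is
#'   `sample_rate / nfft`).
#' @return list as in [spectral_summary()] plus `bin_width` (Hz).
#' @export
spectral_features <- function(wave, nfft = 4096L) {
  stopifnot(inherits(wave, "call_waveform"))
  if (all(wave$samples == 0)) {
    stop("all-zero signal: spectral features undefined", call. = FALSE)
  }
  psd <- welch_psd(wave$samples, wave$sample_rate, nfft)
  out <- spectral_summary(psd$freq, psd$power)
  out$bin_width <- psd$bin_width
  out
}

#' Peak sound pressure level of a calibrated call
#'
#' `20 log10(max |p(t)| / 20 uPa)` with the instantaneous pressure obtained
#' from the digital samples through the calibration constant (pascals per
#' full-scale unit at 1 m). Peak rather than RMS level is the appropriate
#' convention for impulsive calls.
#'
#' @param wave a calibrated [call_waveform()].
#' @return dB peak re 20 uPa at 1 m.
#' @export
peak_level <- function(wave) {
  stopifnot(inherits(wave, "call_waveform"))
  if (is.null(wave$calibration)) {
    stop("calibration required to compute an absolute level", call. = FALSE)
  }
  p_peak <- max(abs(wave$samples)) * wave$calibration
  20 * log10(p_peak / 20e-6)
}

#' Extract the full feature set from one call
#'
#' Composition of the envelope, pulse-detection, temporal and spectral
#' stages; returns one tidy row per call. The spectral stage runs on the
#' rhythmic portion only (first to last above-threshold envelope sample).
#'
#' @param wave a [call_waveform()].
#' @param threshold,min_gap pulse-detection settings (see
#'   [detect_pulses()]).
#' @param smooth_pts envelope smoothing window, samples.
#' @param nfft spectral segment length.
#' @return one-row data frame: `male_id`, `year`, `context`, `duration_s`,
#'   `n_pulses`, `pulse_rate_hz`, `f_max_hz`, `centroid_hz`, `q25_hz`,
#'   `q50_hz`, `q75_hz`, `bw12_hz`, `db_peak` (NA when uncalibrated).
#' @export
extract_features <- function(wave, threshold = 0.15, min_gap = 0.05,
                             smooth_pts = 41L, nfft = 4096L) {
  env <- envelope(wave, smooth_pts = smooth_pts)
  if (env$degenerate) stop("degenerate (silent) call", call. = FALSE)
  onsets <- detect_pulses(env, threshold = threshold, min_gap = min_gap)
  tf <- temporal_features(onsets, env, threshold = threshold)
  idx <- which(env$env >= threshold)
  rhythmic <- wave$samples[idx[1]:idx[length(idx)]]
  sf <- spectral_summary_of(rhythmic, wave$sample_rate, nfft)
  data.frame(
    male_id = wave$male_id, year = wave$year, context = wave$context,
    duration_s = tf$duration, n_pulses = tf$n_pulses,
    pulse_rate_hz = tf$pulse_rate,
    f_max_hz = sf$f_max, centroid_hz = sf$centroid,
    q25_hz = sf$q25, q50_hz = sf$q50, q75_hz = sf$q75, bw12_hz = sf$bw12,
    db_peak = if (is.null(wave$calibration)) NA_real_ else peak_level(wave),
    stringsAsFactors = FALSE
  )
}

spectral_summary_of <- function(samples, fs, nfft) {
  psd <- welch_psd(samples, fs, nfft)
  spectral_summary(psd$freq, psd$power)
}

#' Extract features from a list of calls
#'
#' @param waves list of [call_waveform()] objects.
#' @param ... passed to [extract_features()].
#' @return data frame, one row per call.
#' @export
extract_features_batch <- function(waves, ...) {
  do.call(rbind, lapply(waves, extract_features, ...))
}
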