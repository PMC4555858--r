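# Shared I/O: the interaction-log CSV dialect, PCM/float WAV files with a
# calibration sidecar, and the end-to-end synthetic-season pipeline.

#' Read an interaction ledger from CSV
#'
#' Expects the documented dialect: UTF-8, comma-separated, mandatory header
#' `date,winner_id,loser_id,winner_vocalized,loser_vocalized,contact,decided`
#' (`decided` optional). Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV path.
#' @return an [interaction_records()] ledger in file order.
#' @export
read_interaction_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "winner_id", "loser_id", "winner_vocalized",
              "loser_vocalized", "contact")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(as.character(df$winner_id) == as.character(df$loser_id))
  if (length(bad)) {
    stop("winner_id equals loser_id at line(s): ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$contact %in% CONTACT_LEVELS)
  if (length(bad)) {
    stop("unknown contact level at line(s): ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  interaction_records(df)
}

#' Write an interaction ledger to CSV
#'
#' @param records an [interaction_records()] ledger.
#' @param path output path.
#' @export
write_interaction_log <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a call waveform as a WAV file
#'
#' Plain RIFF/WAVE, mono: 16- or 24-bit integer PCM or 32-bit IEEE float.
#' WAV carries no absolute calibration, so the pascals-per-full-scale
#' constant travels in a sidecar CSV (see [write_calibration()]).
#'
#' @param wave a [call_waveform()].
#' @param path output path.
#' @param bit_depth 16, 24 or "float".
#' @export
write_wav <- function(wave, path, bit_depth = 16) {
  stopifnot(inherits(wave, "call_waveform"))
  x <- pmin(pmax(wave$samples, -1), 1)
  fs <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (identical(bit_depth, "float")) {
    fmt <- 3L; bits <- 32L
    data <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  } else if (bit_depth == 16) {
    fmt <- 1L; bits <- 16L
    data <- writeBin(as.integer(round(x * 32767)), raw(), size = 2,
                     endian = "little")
  } else if (bit_depth == 24) {
    fmt <- 1L; bits <- 24L
    v <- as.integer(round(x * 8388607))
    v[v < 0] <- v[v < 0] + 16777216L
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    data <- as.raw(as.vector(b))
  } else stop("bit_depth must be 16, 24 or \"float\"", call. = FALSE)
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(data)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * block, con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(data)), con, size = 4, endian = "little")
  writeBin(data, con)
  invisible(path)
}

#' Read a WAV file as a call waveform
#'
#' Supports mono or multi-channel (first channel kept) 8/16/24-bit PCM and
#' 32-bit float. Calibration, if any, is supplied separately.
#'
#' @param path WAV path.
#' @param calibration optional pascals per full-scale unit.
#' @param ... metadata passed to [call_waveform()].
#' @return a [call_waveform()].
#' @export
read_wav <- function(path, calibration = NULL, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw_fmt <- readBin(con, raw(), n = size)
      u16 <- function(i) sum(as.integer(raw_fmt[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(raw_fmt[i:(i + 3)]) * 256^(0:3))
      fmt <- list(code = u16(1), channels = u16(3), rate = u32(5),
                  bits = u16(15))
    } else if (id == "data") {
      data <- readBin(con, raw(), n = size)
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV", call. = FALSE)
  x <- if (fmt$code == 3 && fmt$bits == 32) {
    readBin(data, numeric(), n = length(data) %/% 4, size = 4,
            endian = "little")
  } else if (fmt$bits == 16) {
    readBin(data, integer(), n = length(data) %/% 2, size = 2,
            signed = TRUE, endian = "little") / 32767
  } else if (fmt$bits == 24) {
    m <- matrix(as.integer(data[seq_len((length(data) %/% 3) * 3)]),
                nrow = 3)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388607
  } else if (fmt$bits == 8) {
    (as.integer(data) - 128) / 127
  } else stop("unsupported WAV encoding", call. = FALSE)
  if (fmt$channels > 1L) x <- x[seq(1L, length(x), by = fmt$channels)]
  call_waveform(x, fmt$rate, calibration = calibration, ...)
}

#' Write / read a calibration sidecar CSV
#'
#' Two columns: `file`, `pascals_per_full_scale`. WAV files carry no
#' absolute-pressure field, so calibration travels alongside.
#'
#' @param df data frame with `file` and `pascals_per_full_scale`.
#' @param path sidecar path.
#' @export
write_calibration <- function(df, path) {
  stopifnot(all(c("file", "pascals_per_full_scale") %in% names(df)))
  utils::write.csv(df[, c("file", "pascals_per_full_scale")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Configuration for a full synthetic-season pipeline run
#'
#' @param seed master integer seed; every stochastic stage derives its
#'   stream from it.
#' @param out_dir output directory (created if absent).
#' @param n_males colony size; `n_interactions` season length.
#' @param calls_per_male calls per male entering the signature analyses.
#' @param K,initial Elo settings.
#' @param pdfa_iterations,pdfa_permutations classifier settings (kept
#'   modest by default so a full run stays interactive).
#' @param n_response_trials matched playback pairs per condition contrast.
#' @param sample_rate synthesis rate for the stimulus demonstration, Hz.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed, out_dir, n_males = 16L, n_interactions = 2000L,
                       calls_per_male = 10L, K = 100, initial = 1000,
                       pdfa_iterations = 20L, pdfa_permutations = 100L,
                       n_response_trials = 10L, sample_rate = 48000) {
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic-season pipeline
#'
#' Generates a colony, scores the season with Elo, extracts a feature
#' matrix, runs the permuted cross-validated classifier and the
#' between-year stability analysis, fits the correlation tables, builds a
#' demonstration stimulus series, scores paired playback responses, and
#' writes every product plus a reproducibility manifest to `out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  seed <- config$seed

  colony <- simulate_colony(config$n_males, seed = seed)
  season <- simulate_season(colony_config(
    n_males = config$n_males,
    strength = unname(colony$strength),
    n_interactions = config$n_interactions, seed = seed + 1L))
  write_interaction_log(season, out("interactions.csv"))

  elo <- score_season(season, K = config$K, initial = config$initial)
  utils::write.csv(elo_final_scores(elo), out("elo.csv"), row.names = FALSE)
  utils::write.csv(elo_trajectories(elo), out("elo_trajectories.csv"),
                   row.names = FALSE)

  feats1 <- simulate_feature_matrix(colony$signatures, config$calls_per_male,
                                    seed = seed + 2L, year = 1L)
  feats2 <- simulate_feature_matrix(colony$signatures, config$calls_per_male,
                                    seed = seed + 3L, year = 2L)
  utils::write.csv(feats1, out("features.csv"), row.names = FALSE)

  pd <- pdfa(feats1, n_iterations = config$pdfa_iterations,
             n_permutations = config$pdfa_permutations, seed = seed + 4L)
  jsonlite::write_json(
    list(mean_correct = pd$mean_correct, chance = pd$chance,
         p_value = pd$p_value, n_iterations = pd$n_iterations,
         n_permutations = pd$n_permutations),
    out("pdfa.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(pd$confusion), out("pdfa_confusion.csv"))

  stab <- stability_distances(rbind(feats1, feats2), grouping = "year")
  utils::write.csv(stab$per_individual, out("stability.csv"),
                   row.names = FALSE)

  corr <- correlation_table(feats1, colony$morph, elo_final_scores(elo))
  utils::write.csv(corr, out("correlations.csv"), row.names = FALSE)

  sig <- colony$signatures[1, ]
  base_call <- simulate_call(
    call_signature(sig$male_id, sig$pulse_rate, sig$n_pulses,
                   sig$centroid_target, sig$q25_target, jitter = 0),
    sample_rate = config$sample_rate, seed = seed + 5L)
  series <- build_series(list(base_call),
                         stimulus_spec("mod_pulse_rate",
                                       target_pulse_rate = 3))
  dir.create(out("stimuli"), showWarnings = FALSE)
  write_wav(series, out("stimuli", "mod_rate_3hz.wav"), bit_depth = 24)
  write_calibration(
    data.frame(file = "mod_rate_3hz.wav",
               pascals_per_full_scale = series$calibration),
    out("stimuli", "calibration.csv"))

  resp <- simulate_responses(condition_effect = c(-5, -8, -12, 3, -10, -2),
                             n_trials = config$n_response_trials,
                             noise_sd = c(6, 6, 8, 2, 8, 2),
                             seed = seed + 6L)
  pca <- response_pca(resp)
  scored <- cbind(resp[, c("trial", "condition")],
                  as.data.frame(pca$scores))
  cmp <- compare_conditions(scored$PC1[scored$condition == "A"],
                            scored$PC1[scored$condition == "B"])
  scored$pc1_p_value <- cmp$p_value
  utils::write.csv(scored, out("responses_scored.csv"), row.names = FALSE)

  params <- config[setdiff(names(config), "out_dir")]
  pfile <- out("params.json")
  jsonlite::write_json(params, pfile, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("rivalcall")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameter_hash = unname(tools::md5sum(pfile)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(elo = elo, pdfa = pd, stability = stab,
                 correlations = corr, series = series, pca = pca,
                 comparison = cmp, manifest = manifest))
}
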