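# Linear correlation tables linking per-male acoustic features,
# morphometrics, and seasonal dominance score.

#' Ordinary least-squares line fit with adjusted R-squared
#'
#' Fits `y ~ x` and reports the slope, intercept, adjusted R-squared
#' (`1 - (1 - R2)(n - 1)/(n - 2)` for a single predictor; negative values
#' are possible and meaningful for null relationships) and the two-sided
#' p-value for the slope.
#'
#' @param x predictor values (non-constant, n >= 3).
#' @param y response values.
#' @return list with `slope`, `intercept`, `r2_adj`, `p_value`, `n`.
#' @export
fit_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate (constant) predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2_adj = sm$adj.r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(x))
}

#' Correlation table of acoustic features, morphometrics and dominance
#'
#' One OLS fit per (acoustic parameter x morphological measure), per
#' (acoustic parameter x final Elo score), and per (Elo score x
#' morphological measure), with the morphological measure (or Elo) as the
#' predictor. Acoustic parameters enter as within-male means (one point
#' per male). No multiple-testing correction is applied to the flagged
#' significance, matching the descriptive presentation of such tables; a
#' Benjamini-Hochberg adjusted column is emitted alongside for
#' transparency.
#'
#' @param features per-call feature data frame (with `male_id`); averaged
#'   within male before fitting.
#' @param morph data frame: `male_id`, `vertical_height`, `body_length`,
#'   `body_perimeter`, `head_perimeter` (m, all > 0).
#' @param elo data frame: `male_id`, `elo_final` (e.g.
#'   [elo_final_scores()]); optional — Elo rows are skipped when absent.
#' @param alpha significance threshold for the flag (default 0.05).
#' @return data frame: `response`, `predictor`, `n`, `slope`, `intercept`,
#'   `r2_adj`, `p_value`, `significant`, `p_bh`.
#' @export
correlation_table <- function(features, morph, elo = NULL, alpha = 0.05) {
  if (any(vapply(c("vertical_height", "body_length", "body_perimeter",
                   "head_perimeter"),
                 function(cl) any(morph[[cl]] <= 0), logical(1)))) {
    stop("morphometric measures must all be positive", call. = FALSE)
  }
  feat_cols <- intersect(c(FEATURE_COLS, "db_peak"), names(features))
  agg <- stats::aggregate(features[feat_cols],
                          by = list(male_id = features$male_id),
                          FUN = mean, na.rm = TRUE)
  unmatched <- setdiff(agg$male_id, morph$male_id)
  if (length(unmatched)) {
    stop("male_ids missing from the morph table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  tab <- merge(agg, morph, by = "male_id")
  if (!is.null(elo)) tab <- merge(tab, elo, by = "male_id")
  predictors <- c("vertical_height", "body_length", "body_perimeter",
                  "head_perimeter", if (!is.null(elo)) "elo_final")
  rows <- list()
  add_fit <- function(resp, pred) {
    f <- tryCatch(fit_line(tab[[pred]], tab[[resp]]), error = function(e) NULL)
    if (is.null(f)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      response = resp, predictor = pred, n = f$n, slope = f$slope,
      intercept = f$intercept, r2_adj = f$r2_adj, p_value = f$p_value)
  }
  for (resp in feat_cols) for (pred in predictors) add_fit(resp, pred)
  if (!is.null(elo)) {
    for (pred in setdiff(predictors, "elo_final")) add_fit("elo_final", pred)
  }
  if (!length(rows)) stop("no fittable pairs (need n >= 3 males)", call. = FALSE)
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
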