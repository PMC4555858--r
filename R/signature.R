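# Individual vocal-signature analysis: cross-validated permuted linear
# discriminant classification of callers, and Euclidean-distance stability
# of signatures across years and social contexts.

FEATURE_COLS <- c("duration_s", "n_pulses", "pulse_rate_hz", "f_max_hz",
                  "centroid_hz", "q25_hz", "q50_hz", "q75_hz", "bw12_hz")

# Extract the numeric feature block + labels from a feature data frame.
as_feature_matrix <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(FEATURE_COLS, names(features))
    if (!length(feature_cols)) {
      feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                     logical(1))],
                              c("year"))
    }
  }
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  if (anyNA(X)) stop("feature matrix contains missing cells", call. = FALSE)
  labels <- as.character(features$male_id)
  list(X = X, labels = labels, feature_cols = feature_cols)
}

# Pooled-covariance linear discriminant classifier with a trace-scaled
# ridge fallback for ill-conditioned covariances.
lda_pooled_fit <- function(X, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  p <- ncol(X)
  n <- nrow(X)
  means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- sweep(X[y == cl, , drop = FALSE], 2L, means[cl == classes, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (n - length(classes))
  Sinv <- tryCatch({
    if (rcond(S) < 1e-10) stop("ill-conditioned")
    solve(S)
  }, error = function(e) {
    message("pooled covariance ill-conditioned: applying trace-scaled ridge")
    solve(S + ridge * mean(diag(S)) * diag(p))
  })
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  W <- Sinv %*% t(means)                       # p x g
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  list(classes = classes, W = W, b = b)
}

lda_pooled_predict <- function(fit, X) {
  scores <- X %*% fit$W + matrix(fit$b, nrow(X), length(fit$b), byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

check_dfa_input <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 labels for DFA", call. = FALSE)
  if (any(tab < 3L)) {
    stop("every individual needs >= 3 calls for the 2/3-1/3 split",
         call. = FALSE)
  }
  tab
}

crossval_core <- function(X, labels, n_iterations) {
  classes <- sort(unique(labels))
  g <- length(classes)
  confusion <- matrix(0, g, g, dimnames = list(truth = classes,
                                               guess = classes))
  per_iter <- numeric(n_iterations)
  idx_by_class <- split(seq_along(labels), labels)
  for (it in seq_len(n_iterations)) {
    train <- unlist(lapply(idx_by_class, function(ii) {
      sample(ii, ceiling(2 * length(ii) / 3))
    }), use.names = FALSE)
    test <- setdiff(seq_along(labels), train)
    fit <- lda_pooled_fit(X[train, , drop = FALSE], labels[train])
    guess <- lda_pooled_predict(fit, X[test, , drop = FALSE])
    truth <- labels[test]
    per_iter[it] <- 100 * mean(guess == truth)
    for (k in seq_along(test)) {
      confusion[truth[k], guess[k]] <- confusion[truth[k], guess[k]] + 1
    }
  }
  list(per_iter = per_iter, confusion = confusion)
}

#' Cross-validated discriminant classification of callers
#'
#' Per iteration, a stratified random two-thirds of each individual's calls
#' (rounded up, so every individual keeps at least one validation call)
#' trains pooled-covariance linear discriminant functions; the held-out
#' third is classified. The effect size is the percentage of correctly
#' classified held-out calls, averaged over iterations, and the confusion
#' matrix aggregates all held-out classifications into conditional
#' probabilities p(guessed j | emitted by i).
#'
#' @param features data frame with a `male_id` column and numeric feature
#'   columns (by default the nine standard call parameters present).
#' @param n_iterations number of random splits (default 100).
#' @param seed optional integer seed for reproducible splits.
#' @param scale z-score features before fitting (default TRUE; the
#'   classification is then invariant to per-feature scaling).
#' @param feature_cols optional character vector naming the feature columns.
#' @return object of class `"pdfa_result"`: `mean_correct` (%),
#'   `per_iteration`, `confusion` (row-stochastic), `chance`
#'   (= 100 / number of labels), `p_value` (NA until [pdfa_pvalue()]),
#'   `n_iterations`, `n_permutations`.
#' @export
crossval_dfa <- function(features, n_iterations = 100L, seed = NULL,
                         scale = TRUE, feature_cols = NULL) {
  n_iterations <- check_count(n_iterations, "n_iterations", min = 1L)
  fm <- as_feature_matrix(features, feature_cols)
  check_dfa_input(fm$labels)
  X <- if (scale) base::scale(fm$X) else fm$X
  X[, apply(fm$X, 2L, stats::sd) == 0] <- 0  # constant features carry no signal
  res <- with_local_seed(seed, crossval_core(X, fm$labels, n_iterations))
  conf <- res$confusion / pmax(rowSums(res$confusion), 1)
  structure(list(mean_correct = mean(res$per_iter),
                 per_iteration = res$per_iter,
                 confusion = conf,
                 chance = 100 / length(unique(fm$labels)),
                 p_value = NA_real_,
                 n_iterations = n_iterations,
                 n_permutations = 0L),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("pDFA: %.1f%% correct (chance %.1f%%, %d iterations)\n",
              x$mean_correct, x$chance, x$n_iterations))
  if (!is.na(x$p_value)) {
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Permutation p-value for the cross-validated classification
#'
#' Builds the null distribution of the effect size by shuffling caller
#' identities across calls and repeating the full train/validate procedure
#' for each permuted dataset. The p-value is the proportion of permuted
#' effect sizes at least as large as the observed one, with the standard
#' +1 correction in numerator and denominator (so the minimum attainable p
#' is 1/(n_permutations + 1) and ties count against significance).
#'
#' @inheritParams crossval_dfa
#' @param n_permutations number of label permutations (default 1000).
#' @param iters_per_perm cross-validation iterations inside each
#'   permutation (default 1; the original protocol does not state whether
#'   the 100 iterations are nested within each permutation).
#' @param observed optionally, a precomputed [crossval_dfa()] result for
#'   the unpermuted data (avoids refitting).
#' @return the permutation p-value (numeric in (0, 1\]), with the permuted
#'   effect sizes attached as attribute `"permuted"`.
#' @export
pdfa_pvalue <- function(features, n_permutations = 1000L,
                        n_iterations = 100L, iters_per_perm = 1L,
                        seed = NULL, scale = TRUE, feature_cols = NULL,
                        observed = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  fm <- as_feature_matrix(features, feature_cols)
  check_dfa_input(fm$labels)
  X <- if (scale) base::scale(fm$X) else fm$X
  X[, apply(fm$X, 2L, stats::sd) == 0] <- 0
  with_local_seed(seed, {
    obs <- if (!is.null(observed)) observed$mean_correct else {
      mean(crossval_core(X, fm$labels, n_iterations)$per_iter)
    }
    permuted <- vapply(seq_len(n_permutations), function(b) {
      mean(crossval_core(X, sample(fm$labels), iters_per_perm)$per_iter)
    }, numeric(1))
    p <- (sum(permuted >= obs) + 1) / (n_permutations + 1)
    attr(p, "permuted") <- permuted
    attr(p, "observed") <- obs
    p
  })
}

#' Full permuted cross-validated DFA
#'
#' Convenience wrapper running [crossval_dfa()] and [pdfa_pvalue()] on the
#' same data and returning one complete result object.
#'
#' @inheritParams pdfa_pvalue
#' @return a `"pdfa_result"` with `p_value` and `n_permutations` filled in.
#' @export
pdfa <- function(features, n_iterations = 100L, n_permutations = 1000L,
                 iters_per_perm = 1L, seed = NULL, scale = TRUE,
                 feature_cols = NULL) {
  res <- crossval_dfa(features, n_iterations = n_iterations, seed = seed,
                      scale = scale, feature_cols = feature_cols)
  p <- pdfa_pvalue(features, n_permutations = n_permutations,
                   n_iterations = n_iterations,
                   iters_per_perm = iters_per_perm,
                   seed = if (is.null(seed)) NULL else seed + 1L,
                   scale = scale, feature_cols = feature_cols,
                   observed = res)
  res$p_value <- as.numeric(p)
  res$permuted <- attr(p, "permuted")
  res$n_permutations <- n_permutations
  res
}

#' Signature stability as Euclidean distances in pulse-rate x centroid space
#'
#' The two parameters that carry most of the individual signature (pulse
#' rate and spectral centroid) are z-scored and each call becomes a point
#' in the resulting 2-D space. Three categories of distances are computed:
#' within each individual's first-level calls (e.g. year 1, or the directed
#' context), between each individual's first- and second-level calls, and
#' between each individual's first-level calls and all other individuals'
#' first-level calls. Per-individual mean within- and between-level
#' distances are compared with a matched-pairs Wilcoxon test: a
#' non-significant difference indicates a stable signature across levels.
#'
#' @param features data frame with `male_id`, the two parameter columns,
#'   and the grouping column.
#' @param grouping name of the two-level grouping column (e.g. `"year"` or
#'   `"context"`).
#' @param params the two parameter columns (default
#'   `c("pulse_rate_hz", "centroid_hz")`).
#' @param levels optional length-2 vector fixing which group level is
#'   "first"; defaults to the sorted unique values.
#' @param zscore_pool `"first_level"` (default: standardize using the
#'   mean/s.d. of first-level calls, applied to all calls) or `"all"`.
#' @return object of class `"stability_result"`: `per_individual` (data
#'   frame of per-male mean within/between distances), `distances` (the
#'   three raw distance vectors), `test` (Wilcoxon statistic and p), and
#'   `densities` (kernel-density summaries of the three categories).
#' @export
stability_distances <- function(features, grouping = "year",
                                params = c("pulse_rate_hz", "centroid_hz"),
                                levels = NULL, zscore_pool = "first_level") {
  if (!grouping %in% names(features)) {
    stop(sprintf("grouping column `%s` not found", grouping), call. = FALSE)
  }
  grp <- features[[grouping]]
  levels <- levels %||% sort(unique(grp))
  if (length(levels) != 2L) {
    stop("stability analysis needs exactly two group levels", call. = FALSE)
  }
  X <- as.matrix(features[, params, drop = FALSE])
  if (anyNA(X)) stop("missing cells in the parameter columns", call. = FALSE)
  ids <- as.character(features$male_id)

  keep <- vapply(unique(ids), function(m) {
    all(vapply(levels, function(l) sum(ids == m & grp == l) >= 2L,
               logical(1)))
  }, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    message("excluded (fewer than 2 calls in a level): ",
            paste(dropped, collapse = ", "))
  }
  males <- names(keep)[keep]
  if (length(males) < 2L) stop("too few individuals retained", call. = FALSE)
  sel <- ids %in% males
  X <- X[sel, , drop = FALSE]; ids <- ids[sel]; grp <- grp[sel]

  pool <- if (identical(zscore_pool, "all")) rep(TRUE, nrow(X)) else grp == levels[1]
  mu <- colMeans(X[pool, , drop = FALSE])
  sdv <- apply(X[pool, , drop = FALSE], 2L, stats::sd)
  if (any(sdv == 0)) stop("constant parameter in the z-score pool", call. = FALSE)
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")

  eu <- function(A, B) {
    out <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
    out
  }
  within_all <- c(); between_all <- c(); other_all <- c()
  per <- data.frame(male_id = males, within_mean = NA_real_,
                    between_mean = NA_real_)
  for (k in seq_along(males)) {
    m <- males[k]
    A1 <- Z[ids == m & grp == levels[1], , drop = FALSE]
    A2 <- Z[ids == m & grp == levels[2], , drop = FALSE]
    O1 <- Z[ids != m & grp == levels[1], , drop = FALSE]
    dw <- eu(A1, A1)[lower.tri(diag(nrow(A1)))]
    db <- as.numeric(eu(A1, A2))
    do <- as.numeric(eu(A1, O1))
    per$within_mean[k] <- mean(dw)
    per$between_mean[k] <- mean(db)
    within_all <- c(within_all, dw)
    between_all <- c(between_all, db)
    other_all <- c(other_all, do)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(per$within_mean, per$between_mean, paired = TRUE)
  )  # ties/zero differences fall back to the normal approximation
  dens <- lapply(list(within = within_all, between = between_all,
                      between_individuals = other_all), function(d) {
    kd <- stats::density(d, from = 0)
    data.frame(distance = kd$x, density = kd$y)
  })
  structure(list(per_individual = per,
                 distances = list(within = within_all, between = between_all,
                                  between_individuals = other_all),
                 test = list(statistic = unname(wt$statistic),
                             p_value = wt$p.value),
                 densities = dens,
                 levels = levels, params = params),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("signature stability: %d individuals; mean within = %.3f, mean between = %.3f; Wilcoxon p = %.3g\n",
              nrow(x$per_individual), mean(x$per_individual$within_mean),
              mean(x$per_individual$between_mean), x$test$p_value))
  invisible(x)
}
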