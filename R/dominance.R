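# Elo-rating dominance engine for dyadic contest ledgers.

CONTACT_LEVELS <- c("none", "single_blows", "sustained")

#' Build a validated table of dyadic interaction records
#'
#' An interaction ledger holds one row per observed dyadic contest between two
#' identified males, in the order the contests were scored: the day of the
#' season, winner and loser identities, whether each of the two vocalized,
#' the level of physical contact, and whether the contest was decided (an
#' escalated fight can end without a clear winner; such rows never update
#' ratings but are counted in the descriptive tallies).
#'
#' @param df data frame with columns `date` (integer season day or anything
#'   sortable), `winner_id`, `loser_id` (character), `winner_vocalized`,
#'   `loser_vocalized` (logical), `contact` (one of `"none"`,
#'   `"single_blows"`, `"sustained"`) and optionally `decided` (logical,
#'   default `TRUE`).
#' @return the validated data frame with class `"interaction_records"`.
#' @export
interaction_records <- function(df) {
  df <- as.data.frame(df)
  needed <- c("date", "winner_id", "loser_id", "winner_vocalized",
              "loser_vocalized", "contact")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("interaction ledger is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$decided)) df$decided <- TRUE
  df$winner_id <- as.character(df$winner_id)
  df$loser_id <- as.character(df$loser_id)
  bad <- which(df$winner_id == df$loser_id)
  if (length(bad)) {
    stop("winner_id equals loser_id on row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$contact %in% CONTACT_LEVELS)
  if (length(bad)) {
    stop("unknown contact level on row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Expected score of the first contestant under the Elo model
#'
#' Probability that the male rated `rank_1` beats the male rated `rank_2`:
#' \deqn{E_a = 1 / (1 + 10^{(rank_2 - rank_1)/400}).}
#' A 400-point rating advantage corresponds to 10:1 win odds.
#'
#' @param rank_1,rank_2 current Elo ratings (points); vectorized.
#' @return win probability of contestant 1, in (0, 1).
#' @export
#' @examples
#' expected_score(1000, 1000)  # 0.5
#' expected_score(1400, 1000)  # 10/11
expected_score <- function(rank_1, rank_2) {
  if (!is.numeric(rank_1) || !is.numeric(rank_2) ||
      any(!is.finite(rank_1)) || any(!is.finite(rank_2))) {
    stop("ratings must be finite numbers", call. = FALSE)
  }
  1 / (1 + 10^((rank_2 - rank_1) / 400))
}

new_elo_table <- function(K, initial) {
  structure(
    list(ratings = numeric(0), trajectories = list(), K = K, initial = initial,
         n_applied = 0L, n_skipped = 0L),
    class = "elo_table"
  )
}

enroll <- function(table, id) {
  if (!id %in% names(table$ratings)) {
    table$ratings[id] <- table$initial
    table$trajectories[[id]] <- list(step = 0L, rating = table$initial)
  }
  table
}

#' Apply one decided interaction to an Elo table
#'
#' The winner gains `K * (1 - E_a)` points and the loser loses the same
#' amount, where `E_a` is the winner's pre-contest expected score; the
#' colony-wide rating sum is conserved exactly. Males are auto-enrolled at
#' the initial rating on first appearance. Undecided records are skipped
#' with a notice and counted, never scored.
#'
#' @param table an `elo_table` (see [score_season()]).
#' @param rec a one-row ledger slice (list or data frame row) with
#'   `winner_id`, `loser_id`, `decided`.
#' @return the updated `elo_table`.
#' @export
apply_interaction <- function(table, rec) {
  stopifnot(inherits(table, "elo_table"))
  if (!isTRUE(as.logical(rec$decided %||% TRUE))) {
    message("undecided interaction skipped (no rating update)")
    table$n_skipped <- table$n_skipped + 1L
    return(table)
  }
  w <- as.character(rec$winner_id)
  l <- as.character(rec$loser_id)
  table <- enroll(table, w)
  table <- enroll(table, l)
  ea <- expected_score(table$ratings[[w]], table$ratings[[l]])
  delta <- table$K * (1 - ea)
  table$ratings[[w]] <- table$ratings[[w]] + delta
  table$ratings[[l]] <- table$ratings[[l]] - delta
  table$n_applied <- table$n_applied + 1L
  for (id in c(w, l)) {
    tr <- table$trajectories[[id]]
    tr$step <- c(tr$step, table$n_applied)
    tr$rating <- c(tr$rating, table$ratings[[id]])
    table$trajectories[[id]] <- tr
  }
  table
}

#' Score a season of dyadic contests with sequential Elo updates
#'
#' Folds the ledger chronologically (stable tie-break by row order for
#' same-day contests) through [apply_interaction()], starting every male at
#' the same initial rating. The final ratings are the seasonal dominance
#' scores; full per-male trajectories are retained.
#'
#' @param records an interaction ledger ([interaction_records()] or a
#'   compatible data frame).
#' @param K Elo update constant (points). The expected-score formula is
#'   K-agnostic; K only scales step sizes. Default 100.
#' @param initial initial rating for every male. Default 1000.
#' @return an `elo_table`: list with `ratings` (named numeric, final
#'   scores), `trajectories` (per-male data frames of step/rating), `K`,
#'   `initial`, and applied/skipped counts.
#' @export
score_season <- function(records, K = 100, initial = 1000) {
  check_scalar_number(K, "K")
  check_scalar_number(initial, "initial")
  table <- new_elo_table(K, initial)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) return(table)
  ord <- order(records$date)  # stable: ties keep ledger order
  records <- records[ord, , drop = FALSE]
  for (i in seq_len(nrow(records))) {
    table <- apply_interaction(table, records[i, , drop = FALSE])
  }
  table
}

#' @export
print.elo_table <- function(x, ...) {
  cat(sprintf("Elo table: %d males, %d interactions scored (%d skipped), K = %g, initial = %g\n",
              length(x$ratings), x$n_applied, x$n_skipped, x$K, x$initial))
  if (length(x$ratings)) {
    print(round(sort(x$ratings, decreasing = TRUE), 1))
  }
  invisible(x)
}

#' Final seasonal Elo scores as a tidy data frame
#'
#' @param table an `elo_table`.
#' @return data frame with `male_id` and `elo_final`, sorted by score.
#' @export
elo_final_scores <- function(table) {
  stopifnot(inherits(table, "elo_table"))
  out <- data.frame(male_id = names(table$ratings),
                    elo_final = unname(table$ratings))
  out[order(-out$elo_final), , drop = FALSE]
}

#' Per-male rating trajectories as a tidy data frame
#'
#' @param table an `elo_table`.
#' @return data frame with `male_id`, `step`, `rating`.
#' @export
elo_trajectories <- function(table) {
  stopifnot(inherits(table, "elo_table"))
  if (!length(table$trajectories)) {
    return(data.frame(male_id = character(0), step = integer(0),
                      rating = numeric(0)))
  }
  do.call(rbind, lapply(names(table$trajectories), function(id) {
    tr <- table$trajectories[[id]]
    data.frame(male_id = id, step = tr$step, rating = tr$rating,
               stringsAsFactors = FALSE)
  }))
}

#' Descriptive network summaries of an interaction ledger
#'
#' Computes the per-male number of unique opponents, the fraction of dyads
#' whose decided contests were all won by the same male (dyad asymmetry —
#' the hallmark of a stable dominance hierarchy), and tallies of
#' vocalization and contact categories. Every percentage is reported next
#' to its denominator because published tallies are not always internally
#' consistent about denominators.
#'
#' @param records an interaction ledger.
#' @return list with `interactant_count` (named integer), `dyad_total`,
#'   `asymmetric_fraction`, and `tallies` (data frame: category, count,
#'   percent, denominator).
#' @export
summarize_network <- function(records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  males <- unique(c(records$winner_id, records$loser_id))
  interactant_count <- vapply(males, function(m) {
    opp <- c(records$loser_id[records$winner_id == m],
             records$winner_id[records$loser_id == m])
    length(unique(opp))
  }, integer(1))

  decided <- records[as.logical(records$decided %||% rep(TRUE, n)), , drop = FALSE]
  dyad_key <- apply(cbind(decided$winner_id, decided$loser_id), 1L,
                    function(p) paste(sort(p), collapse = "\r"))
  dyads <- split(decided$winner_id, dyad_key)
  dyad_total <- length(dyads)
  asymmetric_fraction <- if (dyad_total == 0L) NA_real_ else {
    mean(vapply(dyads, function(w) length(unique(w)) == 1L, logical(1)))
  }

  wv <- as.logical(records$winner_vocalized)
  lv <- as.logical(records$loser_vocalized)
  contact <- as.character(records$contact)
  dec <- as.logical(records$decided %||% rep(TRUE, n))
  counts <- c(
    winner_vocalized = sum(wv),
    loser_vocalized = sum(lv),
    both_vocalized = sum(wv & lv),
    neither_vocalized = sum(!wv & !lv),
    physical_contact = sum(contact != "none"),
    sustained_contact = sum(contact == "sustained"),
    undecided = sum(!dec)
  )
  tallies <- data.frame(
    category = names(counts),
    count = unname(counts),
    percent = if (n > 0) round(100 * unname(counts) / n, 1) else NA_real_,
    denominator = n
  )
  list(interactant_count = interactant_count,
       dyad_total = dyad_total,
       asymmetric_fraction = asymmetric_fraction,
       tallies = tallies)
}
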