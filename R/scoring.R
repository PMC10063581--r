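#' Deduce pairwise duels from one best/worst judgment
#'
#' Choosing a best and a worst sound in a k-tuple determines the partial
#' order: best beats every other presented sound, and every non-worst
#' sound beats the worst. Relations between the middle sounds remain
#' undetermined. For k = 4 with best = A and worst = D on [A, B, C, D]
#' this yields the 5 duels A>B, A>C, A>D, B>D, C>D; in general 2k - 3.
#'
#' @param judgment one-row judgment data.frame (`best_id`, `worst_id`,
#'   `participant_id`, `trial_index`).
#' @param trial_stimulus_ids the trial's stimulus ids.
#' @return data.frame of duels: winner_id, loser_id, participant_id,
#'   trial_index.
#' @export
deduce_duels <- function(judgment, trial_stimulus_ids) {
  best <- judgment$best_id
  worst <- judgment$worst_id
  ids <- trial_stimulus_ids
  if (best == worst) stop_bws("best_id equals worst_id", class = "bws_scoring_error")
  if (!all(c(best, worst) %in% ids)) {
    stop_bws("judgment ids not in trial", class = "bws_scoring_error")
  }
  others <- setdiff(ids, c(best, worst))
  winners <- c(rep(best, length(others) + 1L), others)
  losers <- c(others, worst, rep(worst, length(others)))
  data.frame(winner_id = winners, loser_id = losers,
             participant_id = judgment$participant_id,
             trial_index = judgment$trial_index,
             stringsAsFactors = FALSE)
}

#' Deduce duels for a whole judgment table
#'
#' Applies [deduce_duels()] to every judgment row, looking trial
#' memberships up in the matching design plans.
#'
#' @param judgments judgment data.frame (one row per trial response).
#' @param plans named list of `bws_design_plan` keyed by participant id.
#' @param include_retests keep duels from retest trials (default `FALSE`;
#'   retests measure intra-rater consistency, not corpus ranking).
#' @return data.frame of duels.
#' @export
judgments_to_duels <- function(judgments, plans, include_retests = FALSE) {
  out <- vector("list", nrow(judgments))
  for (i in seq_len(nrow(judgments))) {
    j <- judgments[i, ]
    pl <- plans[[j$participant_id]]
    if (is.null(pl)) stop_bws("no plan for participant %s", j$participant_id,
                              class = "bws_scoring_error")
    row <- which(pl$trials$trial_index == j$trial_index)
    if (!length(row)) stop_bws("trial %d not in plan of %s", j$trial_index,
                               j$participant_id, class = "bws_scoring_error")
    if (pl$trials$is_retest[row] && !include_retests) next
    out[[i]] <- deduce_duels(j, trial_ids(pl, row))
  }
  do.call(rbind, out)
}

#' Rescorla-Wagner scoring configuration
#'
#' The update constants of the tournament scorer: each duel moves both
#' items' scores by `learning_rate` times the prediction error of a
#' logistic win-probability model, repeated for `n_epochs` passes with
#' optional per-epoch duel shuffling.
#'
#' @param learning_rate step size in (0, 1].
#' @param n_epochs number of passes over the duel list.
#' @param initial_score starting score for every stimulus.
#' @param shuffle reshuffle duel order every epoch.
#' @param seed integer seed for the shuffling stream.
#' @return object of class `rw_config`.
#' @export
rw_config <- function(learning_rate = 0.05, n_epochs = 50,
                      initial_score = 0, shuffle = TRUE, seed = 1L) {
  if (learning_rate <= 0 || learning_rate > 1) {
    stop_bws("learning_rate must be in (0, 1]", class = "bws_scoring_error")
  }
  if (n_epochs < 1) stop_bws("n_epochs must be >= 1", class = "bws_scoring_error")
  structure(list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 initial_score = initial_score, shuffle = isTRUE(shuffle),
                 seed = as.integer(seed)),
            class = "rw_config")
}

#' Score stimuli from duels with the Rescorla-Wagner tournament algorithm
#'
#' Iterative value updating over the duel list: for each duel the
#' predicted win probability is `plogis(s_winner - s_loser)`; the
#' prediction error `1 - p` times the learning rate is added to the
#' winner's score and subtracted from the loser's. The symmetric (zero-sum)
#' update conserves the mean score, and because the logistic depends only
#' on score differences the scores are translation-invariant in the
#' initial value. Stimuli appearing in no duel keep `initial_score`.
#'
#' @param duels data.frame with `winner_id`, `loser_id` columns.
#' @param corpus_ids character vector of all stimulus ids to score.
#' @param config an [rw_config()].
#' @param concept,group labels stored on the table.
#' @return object of class `bws_score_table`: list with `scores` (named,
#'   raw), `scores_normalized` (min-max to [0, 1]), `concept`, `group`,
#'   `config`, `n_duels`.
#' @export
score_rescorla_wagner <- function(duels, corpus_ids, config = rw_config(),
                                  concept = NA_character_, group = NA_character_) {
  ids <- as.character(corpus_ids)
  if (!length(ids)) stop_bws("empty corpus", class = "bws_scoring_error")
  if (anyDuplicated(ids)) stop_bws("duplicate corpus ids", class = "bws_scoring_error")
  if (is.null(duels) || nrow(duels) == 0) {
    s <- setNames(rep(config$initial_score, length(ids)), ids)
  } else {
    bad <- setdiff(c(duels$winner_id, duels$loser_id), ids)
    if (length(bad)) stop_bws("duel ids not in corpus: %s",
                              paste(unique(bad), collapse = ", "),
                              class = "bws_scoring_error")
    w <- match(duels$winner_id, ids)
    l <- match(duels$loser_id, ids)
    s <- rw_score_cpp(w, l, length(ids), config$learning_rate,
                      config$n_epochs, config$initial_score,
                      config$shuffle, as.double(config$seed))
    s <- setNames(as.numeric(s), ids)
  }
  rng <- range(s)
  norm <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0.5, length(s))
  structure(list(concept = concept, group = group, scores = s,
                 scores_normalized = setNames(norm, ids), config = config,
                 n_duels = if (is.null(duels)) 0L else nrow(duels)),
            class = "bws_score_table")
}

#' Count-based Best-Worst-Scaling score (oracle baseline)
#'
#' The classical BWS score: `(wins - losses) / max(1, wins + losses)` per
#' stimulus over its deduced duels. Serves as an independent baseline the
#' tournament scorer is validated against.
#'
#' @inheritParams score_rescorla_wagner
#' @return a `bws_score_table` (config is `NULL`).
#' @export
score_count_baseline <- function(duels, corpus_ids,
                                 concept = NA_character_, group = NA_character_) {
  ids <- as.character(corpus_ids)
  if (!length(ids)) stop_bws("empty corpus", class = "bws_scoring_error")
  wins <- table(factor(duels$winner_id, levels = ids))
  losses <- table(factor(duels$loser_id, levels = ids))
  s <- (as.numeric(wins) - as.numeric(losses)) /
    pmax(1, as.numeric(wins) + as.numeric(losses))
  s <- setNames(s, ids)
  rng <- range(s)
  norm <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0.5, length(s))
  structure(list(concept = concept, group = group, scores = s,
                 scores_normalized = setNames(norm, ids), config = NULL,
                 n_duels = if (is.null(duels)) 0L else nrow(duels)),
            class = "bws_score_table")
}

#' @export
print.bws_score_table <- function(x, ...) {
  cat(sprintf("<bws_score_table%s%s: %d stimuli, %d duels>\n",
              if (is.na(x$concept)) "" else paste0(" ", x$concept),
              if (is.na(x$group)) "" else paste0(" / ", x$group),
              length(x$scores), x$n_duels))
  top <- head(sort(x$scores, decreasing = TRUE), 5)
  cat("top:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bws_score_table <- function(object, ...) {
  s <- object$scores
  cat(sprintf("BWS score table (%s / %s)\n",
              object$concept, object$group))
  cat(sprintf("  %d stimuli, %d duels\n", length(s), object$n_duels))
  print(summary(unname(s)))
  invisible(object)
}

#' Dense ranks of a score table
#'
#' Descending dense ranks: the highest score gets rank 1, tied scores
#' share a rank, and the returned mapping is ordered by rank then
#' lexicographic id so the output is deterministic.
#'
#' @param table a `bws_score_table`.
#' @return named integer vector id -> rank.
#' @export
rank_of <- function(table) {
  s <- table$scores
  lev <- sort(unique(s), decreasing = TRUE)
  r <- setNames(match(s, lev), names(s))
  r[order(r, names(r))]
}

#' Write a score table to CSV
#' @param table a `bws_score_table`.
#' @param path output CSV path; a JSON sidecar `<path>.json` records the
#'   scoring configuration.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  df <- data.frame(stimulus_id = names(table$scores),
                   score = unname(table$scores),
                   score_normalized = unname(table$scores_normalized),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(table$config)) {
    jsonlite::write_json(unclass(table$config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
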