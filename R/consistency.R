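#' Compliance: inter-participant consistency of one rater
#'
#' The proportion of a participant's deduced duels whose winner also has
#' the higher group BWS score. A participant answering uniformly at random
#' against an informative group has expected compliance 0.5; a participant
#' who always agrees with the group ranking scores 1. Duels whose two
#' group scores are exactly tied are uninformative and dropped from the
#' denominator; retest trials are excluded by default.
#'
#' @param participant_judgments judgment rows of one participant for one
#'   concept.
#' @param plan that participant's `bws_design_plan`.
#' @param group_scores the group-level `bws_score_table`.
#' @param include_retests include duels from retest trials (default FALSE).
#' @return list of class `compliance_record`: participant_id, group,
#'   concept, compliance, n_duels_scored.
#' @export
compliance <- function(participant_judgments, plan, group_scores,
                       include_retests = FALSE) {
  duels <- judgments_to_duels(participant_judgments,
                              setNames(list(plan), plan$participant_id),
                              include_retests = include_retests)
  if (is.null(duels) || nrow(duels) == 0) {
    stop_bws("no duels to score", class = "bws_consistency_error")
  }
  s <- group_scores$scores
  missing <- setdiff(c(duels$winner_id, duels$loser_id), names(s))
  if (length(missing)) {
    stop_bws("stimuli missing from group scores: %s",
             paste(unique(missing), collapse = ", "),
             class = "bws_consistency_error")
  }
  sw <- s[duels$winner_id]
  sl <- s[duels$loser_id]
  informative <- sw != sl
  if (!any(informative)) {
    stop_bws("all duels tied in group scores", class = "bws_consistency_error")
  }
  matches <- sum(sw[informative] > sl[informative])
  structure(list(
    participant_id = plan$participant_id,
    group = if (is.null(participant_judgments$group)) NA_character_ else
      participant_judgments$group[1],
    concept = plan$concept,
    compliance = matches / sum(informative),
    n_duels_scored = sum(informative)
  ), class = "compliance_record")
}

#' @export
print.compliance_record <- function(x, ...) {
  cat(sprintf("<compliance %s/%s: %.1f%% over %d duels>\n",
              x$participant_id, x$concept, 100 * x$compliance,
              x$n_duels_scored))
  invisible(x)
}

#' Agreement between a trial and its retest presentation
#'
#' Both passes over the same k sounds determine a partial order (via
#' [deduce_duels()]). The comparable duels are the unordered pairs whose
#' winner is determined in BOTH passes; the agreement counts those with
#' the same winner both times.
#'
#' @param test_judgment judgment row of the original trial.
#' @param retest_judgment judgment row of the repeat.
#' @param trial_stimulus_ids the (shared) stimulus ids of the trial.
#' @return list: `agreements`, `comparable`.
#' @export
retest_agreement <- function(test_judgment, retest_judgment, trial_stimulus_ids) {
  d1 <- deduce_duels(test_judgment, trial_stimulus_ids)
  d2 <- deduce_duels(retest_judgment, trial_stimulus_ids)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  k1 <- setNames(d1$winner_id, key(d1$winner_id, d1$loser_id))
  k2 <- setNames(d2$winner_id, key(d2$winner_id, d2$loser_id))
  common <- intersect(names(k1), names(k2))
  list(agreements = sum(k1[common] == k2[common]),
       comparable = length(common))
}

#' Per-participant retest records
#'
#' Aggregates [retest_agreement()] over every retest trial of a plan.
#'
#' @param participant_judgments one participant's judgments for one concept.
#' @param plan that participant's plan (with retest trials).
#' @return list of class `retest_record`: participant_id, concept,
#'   agreement (pooled proportion), n_comparable_duels.
#' @export
retest_record <- function(participant_judgments, plan) {
  tr <- plan$trials
  re_rows <- which(tr$is_retest)
  if (!length(re_rows)) {
    stop_bws("plan has no retest trials", class = "bws_consistency_error")
  }
  agreements <- 0L
  comparable <- 0L
  for (r in re_rows) {
    src_index <- tr$source_trial_index[r]
    jr <- participant_judgments[participant_judgments$trial_index ==
                                  tr$trial_index[r], ]
    js <- participant_judgments[participant_judgments$trial_index == src_index, ]
    if (nrow(jr) != 1 || nrow(js) != 1) {
      stop_bws("missing judgment for retest pair (%d, %d)",
               src_index, tr$trial_index[r], class = "bws_consistency_error")
    }
    src_row <- which(tr$trial_index == src_index)
    ids_src <- sort(trial_ids(plan, src_row))
    ids_re <- sort(trial_ids(plan, r))
    if (!identical(ids_src, ids_re)) {
      stop_bws("retest trial %d does not repeat its source id set",
               tr$trial_index[r], class = "bws_consistency_error")
    }
    a <- retest_agreement(js, jr, ids_src)
    agreements <- agreements + a$agreements
    comparable <- comparable + a$comparable
  }
  structure(list(participant_id = plan$participant_id, concept = plan$concept,
                 agreement = if (comparable > 0) agreements / comparable else NA_real_,
                 n_comparable_duels = comparable),
            class = "retest_record")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-squared approximation
#' (df = groups - 1); wraps [stats::kruskal.test()].
#'
#' @param samples list of numeric vectors, one per group.
#' @return list of class `bws_test_result`: statistic_name `"H"`,
#'   statistic, df, p_value, n_per_group, adjusted flag.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2 || any(!lengths(samples))) {
    stop_bws("need >= 2 nonempty groups", class = "bws_stats_error")
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(unique(x)) == 1) {
    res <- list(statistic = 0, df = length(samples) - 1L, p_value = 1)
  } else {
    kt <- kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(c(list(statistic_name = "H"), res,
              list(n_per_group = lengths(samples), adjusted = FALSE)),
            class = "bws_test_result")
}

#' Mann-Whitney U test between two groups
#'
#' U convention: the number of (a, b) pairs with a > b (plus half-ties),
#' so `a` entirely greater than `b` gives U = n_a * n_b. Exact p by
#' enumeration for small tie-free samples (n_a + n_b <= 12, via
#' [stats::wilcox.test()]), normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param a,b numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return a `bws_test_result` with statistic_name `"U"`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) stop_bws("empty sample", class = "bws_stats_error")
  exact <- (length(a) + length(b) <= 12) &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = TRUE))
  structure(list(statistic_name = "U", statistic = unname(wt$statistic),
                 df = NA_integer_, p_value = wt$p.value,
                 n_per_group = c(length(a), length(b)), adjusted = FALSE,
                 exact = exact),
            class = "bws_test_result")
}

#' Friedman rank test over complete blocks
#'
#' @param blocks numeric matrix, rows = participants (blocks), columns =
#'   conditions; complete (no NA).
#' @return a `bws_test_result` with statistic_name `"Q"`.
#' @export
friedman_rank_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (nrow(blocks) < 2 || ncol(blocks) < 2) {
    stop_bws("need >= 2 blocks and >= 2 conditions", class = "bws_stats_error")
  }
  if (anyNA(blocks)) stop_bws("incomplete blocks", class = "bws_stats_error")
  constant_rows <- all(apply(blocks, 1, function(r) length(unique(r)) == 1))
  if (constant_rows) {
    res <- list(statistic = 0, df = ncol(blocks) - 1L, p_value = 1)
  } else {
    ft <- friedman.test(blocks)
    res <- list(statistic = unname(ft$statistic), df = unname(ft$parameter),
                p_value = ft$p.value)
  }
  structure(c(list(statistic_name = "Q"), res,
              list(n_per_group = rep(nrow(blocks), ncol(blocks)),
                   adjusted = FALSE)),
            class = "bws_test_result")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original treatment). Exact p
#' for n <= 12 tie-free nonzero differences, normal approximation with
#' continuity correction otherwise. All-zero differences give a degenerate
#' result flagged with p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return a `bws_test_result` with statistic_name `"W"` and a
#'   `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop_bws("lengths differ", class = "bws_stats_error")
  d <- a - b
  nz <- d[d != 0]
  if (!length(nz)) {
    return(structure(list(statistic_name = "W", statistic = 0,
                          df = NA_integer_, p_value = 1,
                          n_per_group = c(length(a), length(b)),
                          adjusted = FALSE, degenerate = TRUE),
                     class = "bws_test_result"))
  }
  exact <- length(nz) <= 12 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                     correct = TRUE))
  structure(list(statistic_name = "W", statistic = unname(wt$statistic),
                 df = NA_integer_, p_value = wt$p.value,
                 n_per_group = c(length(a), length(b)), adjusted = FALSE,
                 degenerate = FALSE, exact = exact),
            class = "bws_test_result")
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of raw p values in [0, 1].
#' @param m number of comparisons; defaults to `length(p_values)`.
#' @return adjusted p values, `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p_values, m = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_bws("p values must lie in [0, 1]", class = "bws_stats_error")
  }
  m <- m %||% length(p_values)
  pmin(1, p_values * m)
}

#' @export
print.bws_test_result <- function(x, ...) {
  df_txt <- if (is.na(x$df %||% NA)) "" else sprintf("(%d)", x$df)
  cat(sprintf("%s%s = %.3f, p = %.4g%s\n", x$statistic_name, df_txt,
              x$statistic, x$p_value,
              if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  invisible(x)
}
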