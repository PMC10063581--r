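#' Build Best-Worst-Scaling trial plans under pair uniqueness
#'
#' Partitions the stimulus set into trials of `k` sounds for each
#' participant, such that within the chosen uniqueness scope no unordered
#' pair of stimuli is ever presented together more than once across
#' non-retest trials. Trial order and within-trial order are randomized.
#' Retest trials (exact repeats used for intra-participant consistency) are
#' exempt from the constraint and inserted by [insert_retests()].
#'
#' The constraint is solved by randomized greedy trial construction with
#' depth-first backtracking; on a dead-end budget the plan restarts with a
#' fresh sub-seed, and on repeated failure the whole construction restarts.
#' This is complete enough to find resolvable designs at the feasibility
#' bound `participants x ceiling(N/k) x C(k,2) = C(N,2)`.
#'
#' @param stimulus_ids character vector of distinct stimulus ids.
#' @param k trial size (>= 2); the study uses 4.
#' @param participants character vector of participant ids.
#' @param n_retest number of retest trials appended per plan (default 0
#'   here; [insert_retests()] may also be called separately).
#' @param uniqueness_scope `"per_participant"` (each plan independently
#'   pair-unique — automatic since each stimulus appears once per plan),
#'   `"per_group_concept"` (default; pairs unique across all participants'
#'   plans for one group x concept, the unit scores are computed on) or
#'   `"global"` (alias of the same pooling — the caller decides what the
#'   pool is by which plans are built together).
#' @param concept optional concept label stored on the plans.
#' @param seed integer seed.
#' @param max_dead_ends backtracking dead-end budget per plan attempt.
#' @param max_restarts restarts of the whole construction before giving up.
#' @return named list of `bws_design_plan` objects, one per participant.
#' @export
build_design <- function(stimulus_ids, k = 4, participants = "P1",
                         n_retest = 0,
                         uniqueness_scope = c("per_group_concept",
                                              "per_participant", "global"),
                         concept = NA_character_, seed = 1L,
                         max_dead_ends = 1000, max_restarts = 50) {
  uniqueness_scope <- match.arg(uniqueness_scope)
  ids <- as.character(stimulus_ids)
  if (anyDuplicated(ids)) stop_bws("duplicate stimulus ids", class = "bws_design_error")
  n <- length(ids)
  if (k < 2) stop_bws("k must be >= 2", class = "bws_design_error")
  if (n < k) stop_bws("need at least k stimuli", class = "bws_design_error")
  if (n %% k != 0 && n %% k < 2) {
    stop_bws("N mod k = 1 leaves a single-stimulus trial; adjust N or k",
             class = "bws_design_error")
  }
  n_trials <- ceiling(n / k)
  n_part <- length(participants)
  pooled <- uniqueness_scope != "per_participant"
  # feasibility: pooled plans consume participants * trials * C(k,2) pairs
  budget <- choose(n, 2)
  need <- if (pooled) n_part * n_trials * choose(k, 2) else n_trials * choose(k, 2)
  if (need > budget) {
    stop_bws("infeasible: %d pairs required exceeds C(%d,2) = %d available",
             need, n, budget, class = "bws_design_error")
  }

  for (restart in seq_len(max_restarts)) {
    restart_seed <- derive_seed(seed, "design-restart", restart)
    used <- matrix(FALSE, n, n)  # pooled pair-usage across plans
    plans <- vector("list", n_part)
    ok <- TRUE
    for (p in seq_len(n_part)) {
      if (!pooled) used <- matrix(FALSE, n, n)
      plan_ok <- FALSE
      for (attempt in 1:5) {
        res <- with_seed(derive_seed(restart_seed, participants[p], attempt),
                         build_one_plan(n, k, used, max_dead_ends))
        if (!is.null(res)) {
          plan_ok <- TRUE
          break
        }
      }
      if (!plan_ok) { ok <- FALSE; break }
      if (pooled) used <- mark_pairs(used, res)
      plans[[p]] <- res
    }
    if (ok) {
      out <- lapply(seq_len(n_part), function(p) {
        trials <- plans[[p]]
        plan <- with_seed(derive_seed(restart_seed, "order", participants[p]), {
          trials <- trials[sample(length(trials))]              # trial order
          trials <- lapply(trials, function(tr) tr[sample(length(tr))])
          trials
        })
        make_plan(participants[p], concept, ids, plan, k,
                  seed = derive_seed(seed, participants[p]))
      })
      names(out) <- participants
      if (n_retest > 0) {
        out <- lapply(out, insert_retests, n_retest = n_retest,
                      seed = derive_seed(seed, "retest"))
      }
      return(out)
    }
  }
  remaining <- budget - sum(used) / 2
  stop_bws(paste0("could not satisfy pair-uniqueness after %d restarts ",
                  "(remaining pair budget %d)"), max_restarts, remaining,
           class = "bws_design_infeasible")
}

# Build one participant's partition of 1..n into trials of size k (last
# trial may be smaller), avoiding pairs marked TRUE in `used`. Randomized
# DFS with backtracking. Returns list of integer vectors or NULL.
build_one_plan <- function(n, k, used, max_dead_ends) {
  order0 <- sample(n)
  dead <- 0L
  # local pair usage within this plan is implicit: each stimulus is placed
  # exactly once, so only the pooled `used` matrix constrains choices
  recurse <- function(unplaced) {
    if (!length(unplaced)) return(list())
    size <- min(k, length(unplaced))
    anchor <- unplaced[1]
    rest <- unplaced[-1]
    # candidates compatible with anchor
    cand <- rest[!used[anchor, rest]]
    if (length(cand) < size - 1) { dead <<- dead + 1L; return(NULL) }
    # try random combinations of partners, backtracking over them
    tries <- combos_iter(cand, size - 1, used)
    for (partners in tries) {
      trial <- c(anchor, partners)
      tail_res <- recurse(setdiff(unplaced, trial))
      if (!is.null(tail_res)) return(c(list(trial), tail_res))
      dead <<- dead + 1L
      if (dead > max_dead_ends) return(NULL)
    }
    NULL
  }
  recurse(order0)
}

# Enumerate (in random order, lazily bounded) subsets of `cand` of size m
# that are mutually compatible under `used`. Returns a list of integer
# vectors; bounded to keep backtracking cheap.
combos_iter <- function(cand, m, used, max_out = 30L) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  cand <- cand[sample.int(length(cand))]
  # greedy-random completion, retried from different starting partners
  for (start in seq_along(cand)) {
    sel <- cand[start]
    pool <- cand[-seq_len(start)]
    repeat {
      if (length(sel) == m) break
      pool <- pool[!used[sel[length(sel)], pool]]
      if (!length(pool)) break
      pick <- pool[1]
      sel <- c(sel, pick)
      pool <- pool[-1]
    }
    if (length(sel) == m) out[[length(out) + 1L]] <- sel
    if (length(out) >= max_out) break
  }
  unique(lapply(out, sort))
}

mark_pairs <- function(used, trials) {
  for (tr in trials) {
    for (i in seq_along(tr)) {
      for (j in seq_along(tr)) {
        if (i != j) used[tr[i], tr[j]] <- TRUE
      }
    }
  }
  used
}

make_plan <- function(participant_id, concept, ids, trials, k, seed) {
  kmax <- max(lengths(trials))
  mat <- t(vapply(trials, function(tr) {
    c(ids[tr], rep(NA_character_, kmax - length(tr)))
  }, character(kmax)))
  df <- data.frame(trial_index = seq_along(trials) - 1L,
                   is_retest = FALSE,
                   source_trial_index = NA_integer_,
                   stringsAsFactors = FALSE)
  colnames(mat) <- paste0("id_", seq_len(kmax))
  df <- cbind(df, as.data.frame(mat, stringsAsFactors = FALSE))
  structure(list(participant_id = participant_id, concept = concept,
                 k = k, trials = df, seed = seed),
            class = "bws_design_plan")
}

#' @export
print.bws_design_plan <- function(x, ...) {
  cat(sprintf("<bws_design_plan %s%s: %d trials (%d retest), k = %d>\n",
              x$participant_id,
              if (is.na(x$concept)) "" else paste0(" / ", x$concept),
              nrow(x$trials), sum(x$trials$is_retest), x$k))
  invisible(x)
}

#' Trial ids of one row of a design plan
#' @param plan a `bws_design_plan`.
#' @param row row number in `plan$trials`.
#' @return character vector of the trial's stimulus ids.
#' @export
trial_ids <- function(plan, row) {
  idc <- grep("^id_", names(plan$trials))
  v <- as.character(plan$trials[row, idc])
  v[!is.na(v)]
}

#' Insert retest trials into a plan
#'
#' Samples `n_retest` source trials without replacement and re-presents
#' them (within-trial order reshuffled) at random positions in the second
#' half of the sequence, always after their source. Retest trials are
#' exempt from the pair-uniqueness constraint.
#'
#' @param plan a `bws_design_plan`.
#' @param n_retest number of retest trials.
#' @param seed integer seed.
#' @return the augmented plan; `trial_index` is renumbered 0..(T-1).
#' @export
insert_retests <- function(plan, n_retest, seed = 1L) {
  base <- plan$trials[!plan$trials$is_retest, ]
  t0 <- nrow(base)
  if (n_retest > t0) {
    stop_bws("n_retest (%d) exceeds number of trials (%d)", n_retest, t0,
             class = "bws_design_error")
  }
  if (n_retest == 0) return(plan)
  idc <- grep("^id_", names(base))
  with_seed(derive_seed(seed, plan$participant_id), {
    sources <- sort(sample(t0, n_retest))
    rows <- base
    # positions are gaps after row `pos` in the growing sequence
    for (s in sources) {
      src_row <- which(rows$trial_index == base$trial_index[s] & !rows$is_retest)
      lo <- max(ceiling(nrow(rows) / 2), src_row)
      pos <- sample(seq(lo, nrow(rows)), 1)
      newrow <- rows[src_row, ]
      newrow$is_retest <- TRUE
      newrow$source_trial_index <- base$trial_index[s]
      newrow[1, idc] <- as.list(sample(as.character(newrow[1, idc])))
      rows <- rbind(rows[seq_len(pos), ], newrow,
                    if (pos < nrow(rows)) rows[(pos + 1):nrow(rows), ])
    }
    old_index <- rows$trial_index
    rows$source_trial_index <- ifelse(
      rows$is_retest, rows$source_trial_index, NA_integer_)
    # renumber sequentially but remap source indices to the new numbering
    new_of_old <- setNames(seq_len(nrow(rows)) - 1L,
                           paste0(old_index, "_", rows$is_retest))
    rows$trial_index <- seq_len(nrow(rows)) - 1L
    rows$source_trial_index <- vapply(rows$source_trial_index, function(si) {
      if (is.na(si)) NA_integer_ else new_of_old[[paste0(si, "_FALSE")]]
    }, integer(1))
    plan$trials <- rows
    plan
  })
}

#' Verify the pair-uniqueness constraint over a set of plans
#'
#' Exhaustively enumerates the unordered stimulus pairs co-occurring in
#' non-retest trials and reports any pair presented more than once within
#' the pooled scope.
#'
#' @param plans a `bws_design_plan` or list of them.
#' @param scope `"pooled"` checks across all supplied plans (use for
#'   per-group-concept or global scopes by choosing which plans to pass);
#'   `"per_participant"` checks each plan separately.
#' @return list with `ok` (logical) and `violations` (data.frame of
#'   pair, count and the trials involved).
#' @export
verify_pair_uniqueness <- function(plans, scope = c("pooled", "per_participant")) {
  scope <- match.arg(scope)
  if (inherits(plans, "bws_design_plan")) plans <- list(plans)
  pair_tab <- function(plan_set) {
    recs <- list()
    for (pl in plan_set) {
      tr <- pl$trials[!pl$trials$is_retest, ]
      for (r in seq_len(nrow(tr))) {
        ids <- sort(trial_ids(list(trials = tr), r))
        if (length(ids) < 2) next
        cmb <- utils::combn(ids, 2)
        recs[[length(recs) + 1L]] <- data.frame(
          pair = paste(cmb[1, ], cmb[2, ], sep = "|"),
          where = paste0(pl$participant_id, ":", tr$trial_index[r]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  }
  sets <- if (scope == "pooled") list(plans) else lapply(plans, list)
  viols <- list()
  for (s in sets) {
    tab <- pair_tab(s)
    if (is.null(tab)) next
    counts <- table(tab$pair)
    dup <- names(counts)[counts > 1]
    for (d in dup) {
      viols[[length(viols) + 1L]] <- data.frame(
        pair = d, count = as.integer(counts[[d]]),
        trials = paste(tab$where[tab$pair == d], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  violations <- if (length(viols)) do.call(rbind, viols) else
    data.frame(pair = character(0), count = integer(0), trials = character(0))
  list(ok = nrow(violations) == 0, violations = violations)
}

#' Serialize design plans to a data.frame
#'
#' @param plans list of `bws_design_plan` objects.
#' @return data.frame with participant_id, concept, trial rows and id columns.
#' @export
plans_to_df <- function(plans) {
  if (inherits(plans, "bws_design_plan")) plans <- list(plans)
  do.call(rbind, lapply(plans, function(pl) {
    cbind(data.frame(participant_id = pl$participant_id, concept = pl$concept,
                     stringsAsFactors = FALSE),
          pl$trials)
  }))
}
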