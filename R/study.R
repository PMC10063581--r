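#' Configuration for an end-to-end simulated annotation study
#'
#' Bundles every stage's parameters with one master seed from which all
#' per-stage streams are derived (see [derive_seed()]), so any stage can
#' be re-run in isolation. The defaults describe the package's desk-scale
#' reference study: a 100-stimulus corpus with the seven-family
#' composition scaled down proportionally, trials of 4, three populations
#' of 8 raters with increasing judgment noise, and the four sound
#' concepts.
#'
#' @param n_stimuli corpus size; family counts are scaled proportionally
#'   from [bws_family_counts].
#' @param k trial size.
#' @param concepts concept names.
#' @param groups named list of group configs (see [simulate_group()]);
#'   default [default_group_presets()].
#' @param n_retest retest trials per plan.
#' @param rw an [rw_config()].
#' @param duration_range,sample_rate_hz,target_lufs corpus synthesis
#'   parameters.
#' @param model_params gradient-boosted-tree hyperparameters for
#'   [fit_cv_gbt()].
#' @param n_folds cross-validation folds.
#' @param prune_r multicollinearity pruning threshold.
#' @param top_k portrait size.
#' @param master_seed master seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_stimuli = 100, k = 4,
                         concepts = bws_concepts,
                         groups = default_group_presets(),
                         n_retest = 3,
                         rw = rw_config(),
                         duration_range = c(0.5, 2),
                         sample_rate_hz = 22050,
                         target_lufs = -23,
                         model_params = list(nrounds = 300, max_depth = 4,
                                             eta = 0.05, subsample = 0.8),
                         n_folds = 5, prune_r = 0.9, top_k = 5,
                         master_seed = 1L) {
  counts <- scaled_family_counts(n_stimuli)
  structure(list(n_stimuli = n_stimuli, family_counts = counts, k = k,
                 concepts = concepts, groups = groups, n_retest = n_retest,
                 rw = rw, duration_range = duration_range,
                 sample_rate_hz = sample_rate_hz, target_lufs = target_lufs,
                 model_params = model_params, n_folds = n_folds,
                 prune_r = prune_r, top_k = top_k,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Run the full simulated annotation study
#'
#' Executes every stage in order: corpus synthesis and loudness
#' equalization, BWS design construction (pair-unique per group x
#' concept), rater simulation, duel deduction and Rescorla-Wagner scoring,
#' compliance and retest consistency, acoustic feature extraction with
#' multicollinearity pruning, cross-validated gradient-boosted portraits
#' with Shapley attributions, and concept/consistency correlation
#' analyses. Deterministic: the same config yields identical outputs.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, score tables, feature
#'   matrix, consistency tables and the summary are written as CSV/JSON.
#' @param extract_features_stage set `FALSE` to stop after scoring and
#'   consistency (used when only behavioral outputs are needed).
#' @return object of class `bws_study_result`: corpus metadata, score
#'   tables, consistency and retest tables, feature matrix, portrait fits
#'   and attributions, correlation analyses and a per-cell summary grid.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      extract_features_stage = TRUE) {
  ms <- config$master_seed
  # --- corpus -------------------------------------------------------------
  manifest <- corpus_manifest(config$family_counts,
                              duration_range = config$duration_range,
                              target_loudness_lufs = config$target_lufs,
                              seed = derive_seed(ms, "manifest"))
  corpus <- generate_corpus(manifest, seed = derive_seed(ms, "corpus"),
                            sample_rate_hz = config$sample_rate_hz)
  attrs <- latent_attributes(corpus)
  ids <- rownames(attrs)

  # --- designs, judgments, scores, consistency ---------------------------
  score_tables <- list()
  consistency_rows <- list()
  retest_rows <- list()
  judgments_all <- list()
  for (g in names(config$groups)) {
    gc <- config$groups[[g]]
    rater_ids <- sprintf("%s_R%02d", g, seq_len(gc$n_raters))
    for (concept in config$concepts) {
      plans <- build_design(ids, k = config$k, participants = rater_ids,
                            n_retest = config$n_retest,
                            uniqueness_scope = "per_group_concept",
                            concept = concept,
                            seed = derive_seed(ms, "design", g, concept))
      sim <- simulate_group(gc, plans, attrs,
                            seed = derive_seed(ms, "raters", g, concept))
      judgments <- sim$judgments
      judgments_all[[paste(g, concept)]] <- judgments
      duels <- judgments_to_duels(judgments, plans)
      cfg_rw <- config$rw
      cfg_rw$seed <- derive_seed(ms, "rw", g, concept)
      st <- score_rescorla_wagner(duels, ids, cfg_rw,
                                  concept = concept, group = g)
      score_tables[[paste(g, concept, sep = ".")]] <- st
      for (rid in rater_ids) {
        jr <- judgments[judgments$participant_id == rid, ]
        cr <- compliance(jr, plans[[rid]], st)
        consistency_rows[[length(consistency_rows) + 1L]] <- data.frame(
          participant_id = rid, group = g, concept = concept,
          compliance = cr$compliance, n_duels_scored = cr$n_duels_scored,
          stringsAsFactors = FALSE)
        if (config$n_retest > 0) {
          rr <- retest_record(jr, plans[[rid]])
          retest_rows[[length(retest_rows) + 1L]] <- data.frame(
            participant_id = rid, group = g, concept = concept,
            agreement = rr$agreement,
            n_comparable_duels = rr$n_comparable_duels,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  consistency_tab <- do.call(rbind, consistency_rows)
  retest_tab <- if (length(retest_rows)) do.call(rbind, retest_rows) else NULL

  result <- list(config = config, corpus_metadata = corpus_metadata(corpus),
                 latent_attributes = attrs, score_tables = score_tables,
                 consistency = consistency_tab, retest = retest_tab,
                 judgments = judgments_all)

  # --- features and portraits --------------------------------------------
  if (extract_features_stage) {
    fm <- extract_features(corpus)
    fm_pruned <- prune_multicollinear(fm, config$prune_r)
    fits <- list(); attrs_rep <- list(); portraits <- list()
    for (cell in names(score_tables)) {
      fit <- fit_cv_gbt(fm_pruned, score_tables[[cell]],
                        n_folds = config$n_folds,
                        params = config$model_params,
                        seed = derive_seed(ms, "gbt", cell))
      fits[[cell]] <- fit
      at <- attributions(fit)
      attrs_rep[[cell]] <- at
      portraits[[cell]] <- top_features(at, config$top_k)
    }
    # relations: concept correlations per group, consistency vs accuracy
    correlations <- lapply(names(config$groups), function(g) {
      tabs <- score_tables[paste(g, config$concepts, sep = ".")]
      names(tabs) <- config$concepts
      concept_correlations(tabs, group = g)
    })
    names(correlations) <- names(config$groups)
    mean_comp <- tapply(consistency_tab$compliance,
                        paste(consistency_tab$group, consistency_tab$concept,
                              sep = "."), mean)
    mean_r2 <- vapply(fits, function(f) f$mean_r2, numeric(1))
    cac <- consistency_accuracy_correlation(
      setNames(as.numeric(mean_comp), names(mean_comp)),
      mean_r2[names(mean_comp)])
    result <- c(result, list(
      feature_matrix = fm_pruned, fits = fits, attributions = attrs_rep,
      portraits = portraits, correlations = correlations,
      consistency_accuracy = cac))
  }

  # --- summary grid -------------------------------------------------------
  cells <- unique(paste(consistency_tab$group, consistency_tab$concept, sep = "."))
  summary_grid <- do.call(rbind, lapply(cells, function(cl) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    sel <- consistency_tab$group == parts[1] & consistency_tab$concept == parts[2]
    data.frame(
      group = parts[1], concept = parts[2],
      mean_compliance = mean(consistency_tab$compliance[sel]),
      mean_retest = if (!is.null(retest_tab))
        mean(retest_tab$agreement[retest_tab$group == parts[1] &
                                    retest_tab$concept == parts[2]]) else NA_real_,
      mean_r2 = if (extract_features_stage) result$fits[[cl]]$mean_r2 else NA_real_,
      top_feature = if (extract_features_stage)
        result$portraits[[cl]]$feature[1] else NA_character_,
      stringsAsFactors = FALSE)
  }))
  result$summary <- summary_grid
  result <- structure(result, class = "bws_study_result")

  if (!is.null(out_dir)) write_study_result(result, out_dir)
  result
}

#' @export
print.bws_study_result <- function(x, ...) {
  cat(sprintf("<bws_study_result: %d stimuli, %d group x concept cells>\n",
              nrow(x$corpus_metadata), nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write study artifacts to a directory
#'
#' @param result a `bws_study_result`.
#' @param out_dir output directory, created if missing.
#' @return invisibly, the written paths.
#' @export
write_study_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(result$corpus_metadata, "corpus_metadata.csv")
  w(result$consistency, "compliance.csv")
  if (!is.null(result$retest)) w(result$retest, "retest.csv")
  for (cell in names(result$score_tables)) {
    p <- file.path(out_dir, sprintf("scores_%s.csv", gsub("[^A-Za-z0-9._-]", "_", cell)))
    write_score_table(result$score_tables[[cell]], p)
    paths <- c(paths, p)
  }
  if (!is.null(result$feature_matrix)) {
    p <- file.path(out_dir, "features.csv")
    write_feature_matrix(result$feature_matrix, p)
    paths <- c(paths, p)
  }
  if (!is.null(result$portraits)) {
    port <- do.call(rbind, lapply(names(result$portraits), function(cl) {
      cbind(cell = cl, result$portraits[[cl]])
    }))
    w(port, "portraits.csv")
  }
  w(result$summary, "summary.csv")
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(result$summary, sp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, sp)
  invisible(paths)
}

#' Mean compliance of a uniformly random responder
#'
#' Calibration experiment for the compliance null: one participant answers
#' every trial uniformly at random while the remaining raters share one
#' latent weight vector with moderate judgment noise. Group BWS scores are
#' computed from all participants (random one included), and the random
#' responder's compliance against those scores is averaged over
#' independently seeded replicates. The expected value is 50%.
#'
#' @param n_stimuli corpus size (default 100).
#' @param n_informative number of weight-sharing raters (default 7).
#' @param noise_sd judgment noise of the informative raters in utility
#'   units; the shared utility is a unit weight on one z-scored attribute,
#'   so 0.5 is half the utility SD (moderate noise).
#' @param k trial size.
#' @param n_seeds number of replicates (default 50).
#' @param master_seed master seed; replicate s uses streams derived from
#'   `(master_seed, s)`.
#' @param include_random_in_scores if `TRUE`, the random responder's own
#'   duels also feed the group score table. The default `FALSE` keeps the
#'   reference ranking independent of the responder, which is what makes
#'   the 50% null exact; self-inclusion biases compliance upward because
#'   the iterative scorer partially absorbs the responder's own choices.
#' @return list: `mean_compliance` (proportion), `per_seed` (vector),
#'   `n_seeds`.
#' @export
random_responder_compliance <- function(n_stimuli = 100, n_informative = 7,
                                        noise_sd = 0.5, k = 4, n_seeds = 50,
                                        master_seed = 1L,
                                        include_random_in_scores = FALSE) {
  per_seed <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    seed_s <- derive_seed(master_seed, "replicate", s)
    manifest <- corpus_manifest(scaled_family_counts(n_stimuli),
                                seed = derive_seed(seed_s, "manifest"))
    corpus <- generate_corpus(manifest, seed = derive_seed(seed_s, "corpus"),
                              synthesize = FALSE)
    attrs <- latent_attributes(corpus)
    ids <- rownames(attrs)
    participants <- c(sprintf("INF%02d", seq_len(n_informative)), "RAND")
    plans <- build_design(ids, k = k, participants = participants,
                          uniqueness_scope = "per_group_concept",
                          concept = "calibration",
                          seed = derive_seed(seed_s, "design"))
    judgments <- list()
    for (p in participants) {
      pl <- plans[[p]]
      if (p == "RAND") {
        for (r in seq_len(nrow(pl$trials))) {
          judgments[[length(judgments) + 1L]] <- random_rater_judgment(
            trial_ids(pl, r), seed = derive_seed(seed_s, "rand", r),
            participant_id = p, concept = "calibration",
            trial_index = pl$trials$trial_index[r])
        }
      } else {
        rt <- latent_rater(p, "informative",
                           list(calibration = c(spectral_centroid = 1)),
                           noise_sd = noise_sd,
                           seed = derive_seed(seed_s, "rater", p))
        for (r in seq_len(nrow(pl$trials))) {
          judgments[[length(judgments) + 1L]] <- judge_trial(
            rt, "calibration", trial_ids(pl, r), attrs,
            trial_index = pl$trials$trial_index[r])
        }
      }
    }
    judgments <- do.call(rbind, lapply(judgments, function(j) {
      j$group <- NULL
      j
    }))
    scored <- if (include_random_in_scores) judgments else
      judgments[judgments$participant_id != "RAND", ]
    duels <- judgments_to_duels(scored, plans)
    cfg <- rw_config(seed = derive_seed(seed_s, "rw"))
    st <- score_rescorla_wagner(duels, ids, cfg, concept = "calibration",
                                group = "pooled")
    rec <- compliance(judgments[judgments$participant_id == "RAND", ],
                      plans[["RAND"]], st)
    per_seed[s] <- rec$compliance
  }
  list(mean_compliance = mean(per_seed), per_seed = per_seed,
       n_seeds = n_seeds)
}

#' Render a markdown report of a study result
#'
#' Three sections: consistency (compliance/retest per cell), concept
#' correlation matrices per group, and the top-k acoustic portraits.
#'
#' @param result a `bws_study_result`.
#' @return a single markdown string.
#' @export
study_report <- function(result) {
  if (!length(result$config$concepts)) {
    stop_bws("empty concept list", class = "bws_study_error")
  }
  fmt_pct <- function(v) sprintf("%.1f%%", 100 * v)
  lines <- c("# Simulated BWS study report", "",
             "## Consistency", "",
             "| group | concept | mean compliance | mean retest |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(result$summary))) {
    r <- result$summary[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", r$group, r$concept,
                              fmt_pct(r$mean_compliance),
                              if (is.na(r$mean_retest)) "-" else fmt_pct(r$mean_retest)))
  }
  lines <- c(lines, "", "## Concept correlations", "")
  if (!is.null(result$correlations)) {
    for (g in names(result$correlations)) {
      cc <- result$correlations[[g]]
      lines <- c(lines, sprintf("### %s (n = %d)", g, cc$n), "",
                 paste0("    ", utils::capture.output(print(round(cc$r, 2)))), "")
    }
  }
  lines <- c(lines, "## Acoustic portraits", "")
  if (!is.null(result$portraits)) {
    for (cl in names(result$portraits)) {
      pf <- result$portraits[[cl]]
      lines <- c(lines, sprintf("### %s", cl), "",
                 "| feature | importance | direction |", "|---|---|---|",
                 sprintf("| %s | %.4f | %+d |", pf$feature, pf$importance,
                         pf$direction), "")
    }
  }
  paste(lines, collapse = "\n")
}
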