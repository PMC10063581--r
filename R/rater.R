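#' Define a simulated rater with latent concept utilities
#'
#' A rater's judgments derive from a Thurstonian choice model: each
#' stimulus has a deterministic utility (dot product of the rater's
#' concept-specific weights with the stimulus's z-scored latent
#' attributes), perturbed by independent Gaussian noise at every
#' presentation; the rater picks the noisy argmax as best and argmin as
#' worst.
#'
#' @param rater_id id string.
#' @param group group label (e.g. `"engineers"`).
#' @param concept_weights named list: concept -> named numeric weight
#'   vector over latent attribute names.
#' @param noise_sd standard deviation of per-presentation utility noise.
#' @param seed integer seed for this rater's noise stream.
#' @return object of class `latent_rater`.
#' @export
latent_rater <- function(rater_id, group = "default", concept_weights,
                         noise_sd = 0.5, seed = 1L) {
  if (noise_sd < 0) stop_bws("noise_sd must be >= 0", class = "bws_rater_error")
  for (w in concept_weights) {
    if (!all(is.finite(w))) stop_bws("weights must be finite", class = "bws_rater_error")
  }
  structure(list(rater_id = rater_id, group = group,
                 concept_weights = concept_weights,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "latent_rater")
}

#' Deterministic utility of attribute vectors for a rater and concept
#'
#' @param rater a [latent_rater()].
#' @param concept concept name present in the rater's weights.
#' @param attributes named numeric vector, or matrix with attribute columns
#'   (rows = stimuli), z-scored over the corpus.
#' @return numeric utility (vector if `attributes` is a matrix).
#' @export
utility <- function(rater, concept, attributes) {
  w <- rater$concept_weights[[concept]]
  if (is.null(w)) stop_bws("rater has no weights for concept '%s'", concept,
                           class = "bws_rater_error")
  if (is.matrix(attributes)) {
    missing <- setdiff(names(w), colnames(attributes))
    if (length(missing)) stop_bws("missing attributes: %s",
                                  paste(missing, collapse = ", "),
                                  class = "bws_rater_error")
    drop(attributes[, names(w), drop = FALSE] %*% w)
  } else {
    missing <- setdiff(names(w), names(attributes))
    if (length(missing)) stop_bws("missing attributes: %s",
                                  paste(missing, collapse = ", "),
                                  class = "bws_rater_error")
    sum(w * attributes[names(w)])
  }
}

#' Simulate one best/worst judgment on a trial
#'
#' Draws one independent Normal(0, noise_sd) perturbation per presented
#' stimulus, then picks best = argmax and worst = argmin of the noisy
#' utilities. Ties are broken toward the lexicographically lowest id.
#'
#' @param rater a [latent_rater()].
#' @param concept concept name.
#' @param trial_stimulus_ids character vector of the trial's ids (k >= 2).
#' @param attribute_table matrix of z-scored latent attributes (rows named
#'   by stimulus id).
#' @param trial_index integer index recorded in the judgment.
#' @param seed integer; defaults to a stream derived from the rater's seed
#'   and the trial index.
#' @return one-row data.frame: participant_id, group, concept, trial_index,
#'   best_id, worst_id.
#' @export
judge_trial <- function(rater, concept, trial_stimulus_ids, attribute_table,
                        trial_index = 0L,
                        seed = derive_seed(rater$seed, concept, trial_index)) {
  ids <- trial_stimulus_ids
  if (length(ids) < 2) stop_bws("trial must have k >= 2", class = "bws_rater_error")
  missing <- setdiff(ids, rownames(attribute_table))
  if (length(missing)) stop_bws("ids missing from attribute table: %s",
                                paste(missing, collapse = ", "),
                                class = "bws_rater_error")
  u <- utility(rater, concept, attribute_table[ids, , drop = FALSE])
  noisy <- u + with_seed(seed, rnorm(length(ids), 0, rater$noise_sd))
  ord <- order(-noisy, ids)   # ties -> lowest id wins the argmax
  best <- ids[ord[1]]
  ord_min <- order(noisy, ids)
  worst <- ids[ord_min[1]]
  if (worst == best) worst <- ids[ord_min[2]]
  data.frame(participant_id = rater$rater_id, group = rater$group,
             concept = concept, trial_index = trial_index,
             best_id = best, worst_id = worst, stringsAsFactors = FALSE)
}

#' Uniformly random best/worst judgment
#'
#' Best uniform over the k presented stimuli, worst uniform over the
#' remaining k - 1: the null responder whose expected compliance is 50%.
#'
#' @param trial_stimulus_ids the trial's ids (k >= 2).
#' @param seed integer seed.
#' @param participant_id,group,concept,trial_index metadata for the record.
#' @return one-row judgment data.frame as in [judge_trial()].
#' @export
random_rater_judgment <- function(trial_stimulus_ids, seed,
                                  participant_id = "random", group = "random",
                                  concept = NA_character_, trial_index = 0L) {
  ids <- trial_stimulus_ids
  if (length(ids) < 2) stop_bws("trial must have k >= 2", class = "bws_rater_error")
  picks <- with_seed(seed, {
    best <- sample(ids, 1)
    worst <- sample(setdiff(ids, best), 1)
    c(best, worst)
  })
  data.frame(participant_id = participant_id, group = group, concept = concept,
             trial_index = trial_index, best_id = picks[1], worst_id = picks[2],
             stringsAsFactors = FALSE)
}

#' Simulate a whole rater group over a set of design plans
#'
#' Draws each rater's weight vectors as the group mean plus independent
#' Normal(0, weight_dispersion) deviations, then judges every trial
#' (including retests) of that rater's plan. Fully deterministic from
#' `seed`.
#'
#' @param group_config list with `group` (label), `n_raters`,
#'   `concept_weights_mean` (named list concept -> named weights),
#'   `weight_dispersion` (SD of rater-level weight deviations) and
#'   `noise_sd`.
#' @param plans named list of `bws_design_plan`, one per rater, in rater
#'   order (names become participant ids).
#' @param attribute_table z-scored latent attribute matrix.
#' @param seed master seed for the group.
#' @return list with `judgments` (data.frame over all raters and trials)
#'   and `raters` (the drawn [latent_rater()] objects).
#' @export
simulate_group <- function(group_config, plans, attribute_table, seed = 1L) {
  n <- group_config$n_raters
  if (length(plans) != n) {
    stop_bws("need one plan per rater: %d plans for %d raters",
             length(plans), n, class = "bws_rater_error")
  }
  ids <- names(plans) %||% sprintf("%s_R%02d", group_config$group, seq_len(n))
  raters <- lapply(seq_len(n), function(i) {
    wseed <- derive_seed(seed, "weights", ids[i])
    cw <- with_seed(wseed, lapply(group_config$concept_weights_mean, function(mu) {
      mu + rnorm(length(mu), 0, group_config$weight_dispersion)
    }))
    latent_rater(ids[i], group_config$group, cw,
                 noise_sd = group_config$noise_sd,
                 seed = derive_seed(seed, "noise", ids[i]))
  })
  names(raters) <- ids
  judgments <- list()
  for (i in seq_len(n)) {
    pl <- plans[[i]]
    concept <- pl$concept
    for (r in seq_len(nrow(pl$trials))) {
      tri <- pl$trials$trial_index[r]
      judgments[[length(judgments) + 1L]] <- judge_trial(
        raters[[i]], concept, trial_ids(pl, r), attribute_table,
        trial_index = tri)
    }
  }
  list(judgments = do.call(rbind, judgments), raters = raters)
}

#' Illustrative group presets
#'
#' Three qualitative rater-population presets loosely inspired by how
#' different listener populations might weight acoustic attributes
#' (e.g. a technically minded group ties brightness to spectral centroid,
#' a naive group to pitch height and absence of noise). They are
#' illustrative defaults for simulation studies, not fitted to any data.
#'
#' @param noise_sd per-presentation utility noise SD for the group.
#' @param n_raters raters per group.
#' @param weight_dispersion SD of rater-level weight deviations.
#' @return named list of group-config lists for [simulate_group()].
#' @export
default_group_presets <- function(noise_sd = c(engineers = 0.5,
                                               conductors = 1.0,
                                               nonexperts = 2.0),
                                  n_raters = 8, weight_dispersion = 0.2) {
  w <- function(...) c(...)
  weights <- list(
    engineers = list(
      brightness = w(spectral_centroid = 1.0),
      warmth     = w(spectral_centroid = -0.8, log_f0 = -0.5),
      roundness  = w(spectral_centroid = -0.7, noise_level = -0.6),
      roughness  = w(noise_level = 0.8, am_depth = 0.7)),
    conductors = list(
      brightness = w(spectral_centroid = 0.6, log_f0 = 0.5, attack_s = -0.3),
      warmth     = w(log_f0 = -0.8, spectral_centroid = -0.4),
      roundness  = w(noise_level = -0.8, attack_s = 0.4),
      roughness  = w(noise_level = 0.7, am_depth = 0.7)),
    nonexperts = list(
      brightness = w(log_f0 = 0.9, noise_level = -0.4),
      warmth     = w(log_f0 = -0.9),
      roundness  = w(noise_level = -0.7, log_f0 = -0.3),
      roughness  = w(noise_level = 0.8, am_depth = 0.5)))
  out <- lapply(names(weights), function(g) {
    list(group = g, n_raters = n_raters,
         concept_weights_mean = weights[[g]],
         weight_dispersion = weight_dispersion,
         noise_sd = unname(noise_sd[g]))
  })
  names(out) <- names(weights)
  out
}
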