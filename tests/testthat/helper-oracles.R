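# Independent brute-force oracles and shared fixtures for the suite.

# All relations determined by "best is the maximum, worst is the minimum"
# on a k-tuple: enumerate every total order consistent with the choice and
# keep the pairs ordered identically in all of them.
oracle_determined_pairs <- function(ids, best, worst) {
  others <- setdiff(ids, c(best, worst))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  orders <- lapply(perms(others), function(mid) c(best, mid, worst))
  pairs <- t(combn(ids, 2))
  det <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    a_first <- vapply(orders, function(o) which(o == a) < which(o == b),
                      logical(1))
    if (all(a_first)) det[[length(det) + 1L]] <- c(a, b)
    if (all(!a_first)) det[[length(det) + 1L]] <- c(b, a)
  }
  det  # list of (winner, loser)
}

# Boolean-matrix transitive closure of a duel list.
transitive_closure <- function(duels, ids) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[cbind(duels$winner_id, duels$loser_id)] <- TRUE
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (all(A2 == A)) break
    A <- A2
  }
  A
}

# Simulate duels from raters sharing one latent weight vector on a random
# 1-D utility, via the package's own design/judgment machinery.
shared_weight_duels <- function(n_stimuli, n_raters, noise_sd, seed,
                                scope = "per_participant") {
  ids <- sprintf("s%03d", seq_len(n_stimuli))
  u <- with_seed(derive_seed(seed, "u"), setNames(rnorm(n_stimuli), ids))
  attrs <- matrix(as.numeric(scale(u)), ncol = 1, dimnames = list(ids, "x"))
  plans <- build_design(ids, k = 4, participants = sprintf("R%02d", seq_len(n_raters)),
                        uniqueness_scope = scope, seed = derive_seed(seed, "d"))
  duels <- NULL
  judgments <- NULL
  for (r in seq_len(n_raters)) {
    rt <- latent_rater(sprintf("R%02d", r), "g", list(c = c(x = 1)),
                       noise_sd = noise_sd, seed = derive_seed(seed, "r", r))
    pl <- plans[[r]]
    for (row in seq_len(nrow(pl$trials))) {
      j <- judge_trial(rt, "c", trial_ids(pl, row), attrs,
                       trial_index = pl$trials$trial_index[row])
      judgments <- rbind(judgments, j)
      duels <- rbind(duels, deduce_duels(j, trial_ids(pl, row)))
    }
  }
  list(ids = ids, utilities = u, attrs = attrs, plans = plans,
       duels = duels, judgments = judgments)
}

# One small synthetic corpus reused across feature tests (built once).
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      man <- corpus_manifest(c(strings = 4, brass = 3, harp = 3),
                             duration_range = c(0.5, 1), seed = 7)
      cache <<- generate_corpus(man, seed = 7, sample_rate_hz = 16000)
    }
    cache
  }
})

# Direct stimulus synthesis shorthand for controlled feature tests.
make_tone <- function(note = "C4", n_harmonics = 8, slope = -6,
                      noise_level = 0, am_rate = 0, am_depth = 0,
                      attack_s = 0.05, duration_s = 1, sr = 16000,
                      envelope = "sustain", seed = 1) {
  synthesize_stimulus(stimulus_spec(
    "t1", family = "strings", note = note, duration_s = duration_s,
    n_harmonics = n_harmonics, spectral_slope_db_per_oct = slope,
    noise_level = noise_level, am_rate_hz = am_rate, am_depth = am_depth,
    attack_s = attack_s, envelope = envelope, seed = seed), sr)
}
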