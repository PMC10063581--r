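make_attrs <- function(vals) {
  m <- do.call(rbind, vals)
  rownames(m) <- names(vals)
  m
}

test_that("utility is the dot product of weights and attributes", {
  attrs <- make_attrs(list(a = c(x = 1, y = -1, z = 0.5),
                           b = c(x = 0, y = 2, z = 1)))
  r <- latent_rater("r1", concept_weights = list(c1 = c(x = 2, y = 0.5, z = -1)),
                    noise_sd = 0)
  expect_equal(utility(r, "c1", attrs["a", ]), 2 * 1 + 0.5 * -1 + -1 * 0.5)
  expect_equal(utility(r, "c1", attrs), c(a = 1, b = 0))
  # zero weights -> zero utility everywhere
  r0 <- latent_rater("r0", concept_weights = list(c1 = c(x = 0, y = 0, z = 0)))
  expect_equal(unname(utility(r0, "c1", attrs)), c(0, 0))
  # single positive weight reproduces the attribute's own ranking
  rc <- latent_rater("rc", concept_weights = list(c1 = c(y = 1)))
  expect_equal(order(utility(rc, "c1", attrs)), order(attrs[, "y"]))
  expect_error(utility(r, "c1", c(x = 1)), class = "bws_rater_error")
  expect_error(utility(r, "nope", attrs), class = "bws_rater_error")
})

test_that("noiseless judgments are the deterministic arg-extrema", {
  attrs <- make_attrs(list(a = c(x = 3), b = c(x = 1), c = c(x = 2),
                           d = c(x = -1)))
  r <- latent_rater("r1", concept_weights = list(c1 = c(x = 1)), noise_sd = 0)
  j <- judge_trial(r, "c1", c("a", "b", "c", "d"), attrs)
  expect_identical(j$best_id, "a")
  expect_identical(j$worst_id, "d")
  # same seed twice -> identical record
  j2 <- judge_trial(r, "c1", c("a", "b", "c", "d"), attrs)
  expect_identical(j, j2)
  expect_error(judge_trial(r, "c1", "a", attrs), class = "bws_rater_error")
})

test_that("overwhelming noise makes best choices uniform", {
  attrs <- make_attrs(list(a = c(x = 0.1), b = c(x = 0.2), c = c(x = 0.3),
                           d = c(x = 0.4)))
  r <- latent_rater("r1", concept_weights = list(c1 = c(x = 1)),
                    noise_sd = 1000, seed = 9)
  n <- 8000
  best <- character(n)
  for (i in seq_len(n)) {
    best[i] <- judge_trial(r, "c1", c("a", "b", "c", "d"), attrs,
                           trial_index = i)$best_id
  }
  freq <- table(best) / n
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("the random responder is uniform over ordered (best, worst) pairs", {
  # k = 2: both orderings equally likely
  picks <- vapply(1:4000, function(i) {
    random_rater_judgment(c("a", "b"), seed = i)$best_id
  }, character(1))
  chi <- chisq.test(table(picks))
  expect_gt(chi$p.value, 0.001)
  # k = 4: all 12 ordered pairs near 1/12
  pairs <- vapply(1:6000, function(i) {
    j <- random_rater_judgment(c("a", "b", "c", "d"), seed = 1e6 + i)
    paste0(j$best_id, j$worst_id)
  }, character(1))
  freq <- table(pairs) / length(pairs)
  expect_length(freq, 12)
  expect_true(all(abs(freq - 1 / 12) < 0.015))
  # reproducible under a fixed seed
  expect_identical(random_rater_judgment(letters[1:4], seed = 5),
                   random_rater_judgment(letters[1:4], seed = 5))
})

test_that("a degenerate group (no dispersion, no noise) is unanimous", {
  ids <- sprintf("s%02d", 1:12)
  attrs <- matrix(rnorm(12), ncol = 1, dimnames = list(ids, "x"))
  plan <- build_design(ids, k = 4, participants = "R01", concept = "c1",
                       seed = 1)$R01
  plans <- list(R01 = plan, R02 = plan, R03 = plan)
  plans$R02$participant_id <- "R02"
  plans$R03$participant_id <- "R03"
  cfg <- list(group = "g", n_raters = 3,
              concept_weights_mean = list(c1 = c(x = 1)),
              weight_dispersion = 0, noise_sd = 0)
  sim <- simulate_group(cfg, plans, attrs, seed = 4)
  expect_equal(nrow(sim$judgments), 3 * 3)
  by_trial <- split(sim$judgments, sim$judgments$trial_index)
  for (tr in by_trial) {
    expect_length(unique(tr$best_id), 1)
    expect_length(unique(tr$worst_id), 1)
  }
})

test_that("judgment volume matches raters x trials", {
  ids <- sprintf("s%02d", 1:16)
  attrs <- matrix(rnorm(16), ncol = 1, dimnames = list(ids, "x"))
  plans <- build_design(ids, k = 4, participants = c("R01", "R02"),
                        n_retest = 1, concept = "c1", seed = 2)
  cfg <- list(group = "g", n_raters = 2,
              concept_weights_mean = list(c1 = c(x = 1)),
              weight_dispersion = 0.1, noise_sd = 0.5)
  sim <- simulate_group(cfg, plans, attrs, seed = 4)
  expect_equal(nrow(sim$judgments), 2 * 5)  # 4 base + 1 retest each
  expect_error(simulate_group(cfg, plans["R01"], attrs, seed = 1),
               class = "bws_rater_error")
})

test_that("orthogonal group weights give uncorrelated score tables", {
  ids <- sprintf("s%03d", 1:100)
  A <- with_seed(11, matrix(rnorm(200), ncol = 2,
                            dimnames = list(ids, c("x", "y"))))
  plans <- build_design(ids, k = 4, participants = sprintf("R%02d", 1:4),
                        uniqueness_scope = "per_participant", seed = 3)
  score_for <- function(wname, seed) {
    duels <- NULL
    for (r in 1:4) {
      w <- setNames(list(setNames(1, wname)), "c1")
      rt <- latent_rater(sprintf("R%02d", r), "g", w, noise_sd = 0.2,
                         seed = seed + r)
      pl <- plans[[r]]
      for (row in seq_len(nrow(pl$trials))) {
        j <- judge_trial(rt, "c1", trial_ids(pl, row), A,
                         trial_index = pl$trials$trial_index[row])
        duels <- rbind(duels, deduce_duels(j, trial_ids(pl, row)))
      }
    }
    score_rescorla_wagner(duels, ids, rw_config(seed = seed))$scores[ids]
  }
  sx <- score_for("x", 100)
  sy <- score_for("y", 200)
  expect_lt(abs(cor(sx, sy)), 0.15)
})
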