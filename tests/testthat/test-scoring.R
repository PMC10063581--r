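jrow <- function(best, worst, pid = "P1", tri = 0L) {
  data.frame(participant_id = pid, trial_index = tri, best_id = best,
             worst_id = worst, stringsAsFactors = FALSE)
}

test_that("a k=4 judgment determines exactly the five known relations", {
  d <- deduce_duels(jrow("A", "D"), c("A", "B", "C", "D"))
  got <- paste(d$winner_id, d$loser_id, sep = ">")
  expect_setequal(got, c("A>B", "A>C", "A>D", "B>D", "C>D"))
  # k = 2 gives the single duel
  d2 <- deduce_duels(jrow("A", "B"), c("A", "B"))
  expect_equal(nrow(d2), 1)
  expect_identical(c(d2$winner_id, d2$loser_id), c("A", "B"))
  expect_error(deduce_duels(jrow("A", "A"), c("A", "B")),
               class = "bws_scoring_error")
})

test_that("deduced duels equal the brute-force partial order for k = 2..6", {
  for (k in 2:6) {
    ids <- LETTERS[1:k]
    d <- deduce_duels(jrow(ids[1], ids[k]), ids)
    expect_equal(nrow(d), 2 * k - 3)
    oracle <- oracle_determined_pairs(ids, ids[1], ids[k])
    oracle_keys <- vapply(oracle, paste, character(1), collapse = ">")
    got <- paste(d$winner_id, d$loser_id, sep = ">")
    expect_setequal(got, oracle_keys)
  }
})

test_that("RW scoring handles empty input and conserves the mean", {
  st <- score_rescorla_wagner(NULL, letters[1:4],
                              rw_config(initial_score = 0.7))
  expect_true(all(st$scores == 0.7))
  duels <- deduce_duels(jrow("a", "d"), letters[1:4])
  st2 <- score_rescorla_wagner(duels, letters[1:6], rw_config(seed = 2))
  # zero-sum updates keep the mean at the initial score
  expect_lt(abs(mean(st2$scores) - 0), 1e-9)
  expect_error(score_rescorla_wagner(duels, character(0)),
               class = "bws_scoring_error")
  expect_error(score_rescorla_wagner(duels, c("a", "d")),
               class = "bws_scoring_error")
})

test_that("RW recovers a fully consistent transitive tournament exactly", {
  ids <- c("v", "w", "x", "y", "z")  # generating order: v > w > x > y > z
  pairs <- t(combn(ids, 2))
  duels <- data.frame(winner_id = pairs[, 1], loser_id = pairs[, 2],
                      stringsAsFactors = FALSE)
  st <- score_rescorla_wagner(duels, ids, rw_config(seed = 4))
  expect_identical(names(sort(st$scores, decreasing = TRUE)), ids)
  expect_identical(unname(rank_of(st)), 1:5)
})

test_that("symmetric middle stimuli earn equal scores without shuffling", {
  duels <- deduce_duels(jrow("A", "D"), c("A", "B", "C", "D"))
  st <- score_rescorla_wagner(duels, c("A", "B", "C", "D"),
                              rw_config(shuffle = FALSE))
  s <- st$scores
  expect_gt(s["A"], max(s["B"], s["C"]))
  expect_lt(s["D"], min(s["B"], s["C"]))
  # sequential (online) updates leave an O(alpha^2) order effect between
  # the two middle stimuli; they are equal up to that residue
  expect_lt(abs(s["B"] - s["C"]), 1e-3)
  # and exactly equal when updates are averaged over both duel orders
  rev_duels <- duels[c(2, 1, 3, 5, 4), ]  # roles of B and C exchanged
  s_rev <- score_rescorla_wagner(rev_duels, c("A", "B", "C", "D"),
                                 rw_config(shuffle = FALSE))$scores
  expect_lt(abs(mean(c(s["B"], s_rev["B"])) - mean(c(s["C"], s_rev["C"]))),
            1e-9)
})

test_that("scores are translation-invariant in the initial value", {
  duels <- rbind(deduce_duels(jrow("a", "d"), letters[1:4]),
                 deduce_duels(jrow("c", "b", tri = 1L), letters[1:4]))
  s0 <- score_rescorla_wagner(duels, letters[1:4],
                              rw_config(initial_score = 0, seed = 6))$scores
  s5 <- score_rescorla_wagner(duels, letters[1:4],
                              rw_config(initial_score = 5, seed = 6))$scores
  expect_true(all(abs((s5 - 5) - s0) < 1e-9))
})

test_that("count baseline matches hand-derived scores", {
  ids <- c("A", "B", "C", "D")
  duels <- deduce_duels(jrow("A", "D"), ids)
  st <- score_count_baseline(duels, ids)
  # A wins 3/3, D loses 3/3, B and C split 1-1
  expect_equal(unname(st$scores[c("A", "B", "C", "D")]), c(1, 0, 0, -1))
  # a 3-cycle is perfectly balanced
  cyc <- data.frame(winner_id = c("x", "y", "z"), loser_id = c("y", "z", "x"),
                    stringsAsFactors = FALSE)
  expect_true(all(score_count_baseline(cyc, c("x", "y", "z"))$scores == 0))
})

test_that("dense ranks share ties and order deterministically", {
  st <- list(scores = c(b = 3, a = 3, c = 2, e = 1, d = 2))
  class(st) <- "bws_score_table"
  r <- rank_of(st)
  expect_equal(unname(r[c("a", "b", "c", "d", "e")]), c(1, 1, 2, 2, 3))
  expect_identical(names(r), c("a", "b", "c", "d", "e"))  # rank then id
  st2 <- list(scores = c(a = 5, b = 4, c = 3))
  class(st2) <- "bws_score_table"
  expect_equal(unname(rank_of(st2)), 1:3)
  st3 <- list(scores = c(a = 1, b = 1, c = 1))
  class(st3) <- "bws_score_table"
  expect_true(all(rank_of(st3) == 1))
})

test_that("RW and the count baseline agree on balanced noiseless designs", {
  sim <- shared_weight_duels(n_stimuli = 40, n_raters = 8, noise_sd = 0,
                             seed = 21)
  rw <- score_rescorla_wagner(sim$duels, sim$ids, rw_config(seed = 3))
  cnt <- score_count_baseline(sim$duels, sim$ids)
  expect_gte(cor(rw$scores[sim$ids], cnt$scores[sim$ids],
                 method = "spearman"), 0.95)
})

test_that("doubling epochs barely changes the induced ranking", {
  sim <- shared_weight_duels(n_stimuli = 100, n_raters = 8, noise_sd = 0.5,
                             seed = 31)
  s1 <- score_rescorla_wagner(sim$duels, sim$ids,
                              rw_config(n_epochs = 50, seed = 5))$scores
  s2 <- score_rescorla_wagner(sim$duels, sim$ids,
                              rw_config(n_epochs = 100, seed = 5))$scores
  r1 <- rank(s1); r2 <- rank(s2)
  discordant <- sum(outer(r1, r1, "<") & outer(r2, r2, ">"))
  expect_lte(discordant / choose(length(s1), 2), 0.01)
})

test_that("score tables serialize to CSV with a config sidecar", {
  duels <- deduce_duels(jrow("A", "D"), c("A", "B", "C", "D"))
  st <- score_rescorla_wagner(duels, c("A", "B", "C", "D"),
                              rw_config(seed = 1), concept = "warmth")
  p <- tempfile(fileext = ".csv")
  write_score_table(st, p)
  back <- read.csv(p)
  expect_identical(back$stimulus_id, c("A", "B", "C", "D"))
  expect_equal(back$score, unname(st$scores))
  cfg <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(cfg$learning_rate, 0.05)
  unlink(c(p, paste0(p, ".json")))
})
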