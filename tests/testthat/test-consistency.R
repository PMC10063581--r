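jfor <- function(pid, tri, best, worst, concept = "c1", group = "g") {
  data.frame(participant_id = pid, group = group, concept = concept,
             trial_index = tri, best_id = best, worst_id = worst,
             stringsAsFactors = FALSE)
}

# a score table with prescribed raw scores
st_of <- function(scores, concept = "c1") {
  structure(list(concept = concept, group = "g", scores = scores,
                 scores_normalized = scores, config = NULL,
                 n_duels = 0L), class = "bws_score_table")
}

test_that("compliance is 1 for agreement and 0 for full inversion", {
  ids <- sprintf("s%02d", 1:8)
  plan <- build_design(ids, k = 4, participants = "P1", concept = "c1",
                       seed = 2)$P1
  scores <- st_of(setNames(seq(8, 1), ids))  # s01 highest ... s08 lowest
  agree <- do.call(rbind, lapply(seq_len(nrow(plan$trials)), function(r) {
    tids <- trial_ids(plan, r)
    o <- tids[order(scores$scores[tids], decreasing = TRUE)]
    jfor("P1", plan$trials$trial_index[r], o[1], o[length(o)])
  }))
  expect_equal(compliance(agree, plan, scores)$compliance, 1)
  invert <- agree
  invert$best_id <- agree$worst_id
  invert$worst_id <- agree$best_id
  expect_equal(compliance(invert, plan, scores)$compliance, 0)
})

test_that("tied group scores are dropped from the compliance denominator", {
  plan <- build_design(letters[1:4], k = 4, participants = "P1",
                       concept = "c1", seed = 1)$P1
  tids <- trial_ids(plan, 1)
  j <- jfor("P1", 0L, tids[1], tids[4])
  # best and one middle share a score: that duel is uninformative
  sc <- setNames(c(4, 4, 2, 1), tids)
  rec <- compliance(j, plan, st_of(sc))
  expect_equal(rec$n_duels_scored, 4)
  expect_equal(rec$compliance, 1)
})

test_that("retest agreement counts doubly determined duels", {
  ids <- c("A", "B", "C", "D")
  # identical choices -> all 5 determined duels agree
  a <- retest_agreement(jfor("P", 0, "A", "D"), jfor("P", 9, "A", "D"), ids)
  expect_equal(a, list(agreements = 5L, comparable = 5L))
  # swapped best/worst -> same 5 pairs determined, all reversed
  b <- retest_agreement(jfor("P", 0, "A", "D"), jfor("P", 9, "D", "A"), ids)
  expect_equal(b, list(agreements = 0L, comparable = 5L))
  # differing worst: comparable = {A-B, A-C, A-D, C-D}, C-D flips
  c_ <- retest_agreement(jfor("P", 0, "A", "D"), jfor("P", 9, "A", "C"), ids)
  expect_equal(c_$comparable, 4L)
  expect_equal(c_$agreements, 3L)
})

test_that("retest agreement equals the brute-force double enumeration", {
  ids <- LETTERS[1:4]
  combos <- expand.grid(b1 = ids, w1 = ids, b2 = ids, w2 = ids,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$b1 != combos$w1 & combos$b2 != combos$w2, ]
  set.seed(8)
  for (i in sample(nrow(combos), 25)) {
    row <- combos[i, ]
    got <- retest_agreement(jfor("P", 0, row$b1, row$w1),
                            jfor("P", 1, row$b2, row$w2), ids)
    o1 <- oracle_determined_pairs(ids, row$b1, row$w1)
    o2 <- oracle_determined_pairs(ids, row$b2, row$w2)
    key <- function(p) paste(pmin(p[1], p[2]), pmax(p[1], p[2]), sep = "|")
    k1 <- setNames(vapply(o1, `[`, character(1), 1),
                   vapply(o1, key, character(1)))
    k2 <- setNames(vapply(o2, `[`, character(1), 1),
                   vapply(o2, key, character(1)))
    common <- intersect(names(k1), names(k2))
    expect_equal(got$comparable, length(common))
    expect_equal(got$agreements, sum(k1[common] == k2[common]))
  }
})

test_that("retest records aggregate over a plan's retest trials", {
  ids <- sprintf("s%02d", 1:8)
  plan <- build_design(ids, k = 4, participants = "P1", n_retest = 2,
                       concept = "c1", seed = 3)$P1
  tr <- plan$trials
  j <- do.call(rbind, lapply(seq_len(nrow(tr)), function(r) {
    tids <- sort(trial_ids(plan, r))  # deterministic choice per id set
    jfor("P1", tr$trial_index[r], tids[1], tids[length(tids)])
  }))
  rec <- retest_record(j, plan)
  expect_equal(rec$agreement, 1)  # same choices on source and retest
  expect_equal(rec$n_comparable_duels, 2 * 5)
})

test_that("Kruskal-Wallis matches exhaustive rank enumeration at 3x3", {
  x <- list(c(1.2, 3.4, 2.2), c(0.5, 4.1, 2.8), c(5.0, 0.1, 3.3))
  got <- kruskal_wallis(x)
  # oracle: exact permutation distribution over all assignments of the 9
  # observed values into 3 labeled groups of 3
  vals <- unlist(x)
  H_of <- function(groups) {
    r <- rank(unlist(groups))
    n <- length(r)
    idx <- split(seq_len(n), rep(seq_along(groups), lengths(groups)))
    12 / (n * (n + 1)) * sum(vapply(idx, function(ii)
      length(ii) * (mean(r[ii]) - (n + 1) / 2)^2, numeric(1)))
  }
  expect_equal(unname(got$statistic), H_of(x), tolerance = 1e-12)
  combs <- combn(9, 3)
  stats_null <- c()
  for (i in seq_len(ncol(combs))) {
    g1 <- combs[, i]
    rest <- setdiff(1:9, g1)
    inner <- combn(rest, 3)
    for (j in seq_len(ncol(inner))) {
      g2 <- inner[, j]
      g3 <- setdiff(rest, g2)
      stats_null <- c(stats_null, H_of(list(vals[g1], vals[g2], vals[g3])))
    }
  }
  p_exact <- mean(stats_null >= got$statistic - 1e-12)
  # chi-square approximation must sit near the exact permutation p
  expect_lt(abs(got$p_value - p_exact), 0.08)
  # identical groups degenerate to H = 0, p = 1
  same <- kruskal_wallis(list(rep(2, 3), rep(2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Mann-Whitney exact p equals brute force over all labelings", {
  a <- c(1.3, 2.7, 0.2, 4.1)
  b <- c(2.0, 3.3, 5.6, 0.9)
  got <- mann_whitney_u(a, b)
  U_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(got$statistic), U_of(a, b))
  vals <- c(a, b)
  combs <- combn(8, 4)
  u_null <- vapply(seq_len(ncol(combs)), function(i) {
    U_of(vals[combs[, i]], vals[-combs[, i]])
  }, numeric(1))
  u_obs <- U_of(a, b)
  mu <- length(a) * length(b) / 2
  p_exact <- mean(abs(u_null - mu) >= abs(u_obs - mu) - 1e-12)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  # separation gives the extreme statistic
  expect_equal(unname(mann_whitney_u(c(10, 11, 12), c(1, 2, 3))$statistic), 9)
  # identical multisets -> two-sided p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("Wilcoxon signed-rank exact p equals sign-pattern enumeration", {
  a <- c(4.1, 2.2, 7.3, 0.4, 5.5, 3.9)
  b <- c(3.0, 2.9, 5.1, 1.8, 5.0, 1.2)
  got <- wilcoxon_signed_rank(a, b)
  d <- a - b
  W_of <- function(d) {
    r <- rank(abs(d))
    sum(r[d > 0])
  }
  expect_equal(unname(got$statistic), W_of(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  w_null <- apply(signs, 1, function(s) W_of(abs(d) * s))
  mu <- n * (n + 1) / 4
  p_exact <- mean(abs(w_null - mu) >= abs(W_of(d) - mu) - 1e-12)
  expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  # two-sided p invariant under global sign flip
  got_flip <- wilcoxon_signed_rank(b, a)
  expect_equal(got$p_value, got_flip$p_value)
  # all-zero differences: degenerate, p = 1
  deg <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("Friedman Q matches the within-row permutation oracle at 3x3", {
  m <- rbind(c(1.0, 2.5, 0.3), c(4.2, 3.1, 5.0), c(2.2, 2.9, 1.1))
  got <- friedman_rank_test(m)
  Q_of <- function(mat) {
    r <- t(apply(mat, 1, rank))
    n <- nrow(mat); k <- ncol(mat)
    12 * n / (k * (k + 1)) * sum((colMeans(r) - (k + 1) / 2)^2)
  }
  expect_equal(unname(got$statistic), Q_of(m), tolerance = 1e-12)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  q_null <- c()
  for (p1 in perms) for (p2 in perms) for (p3 in perms) {
    q_null <- c(q_null, Q_of(rbind(m[1, p1], m[2, p2], m[3, p3])))
  }
  p_exact <- mean(q_null >= got$statistic - 1e-12)
  # the chi-square approximation is coarse against the (very discrete)
  # exact distribution at 3 x 3; the statistic itself is checked exactly
  expect_lt(abs(got$p_value - p_exact), 0.25)
  # column permutation leaves Q unchanged; constant rows give Q = 0
  expect_equal(friedman_rank_test(m[, c(3, 1, 2)])$statistic, got$statistic)
  cm <- matrix(5, 3, 3)
  expect_equal(friedman_rank_test(cm)$statistic, 0)
  expect_error(friedman_rank_test(rbind(c(1, NA), c(2, 3))),
               class = "bws_stats_error")
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni_adjust(0.01, m = 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.02, 0.2)), c(0.003, 0.06, 0.6))
  expect_equal(bonferroni_adjust(c(0.001, 0.02, 0.2)),
               p.adjust(c(0.001, 0.02, 0.2), method = "bonferroni"))
  expect_error(bonferroni_adjust(1.2), class = "bws_stats_error")
})

test_that("group compliance decreases with rater noise", {
  mean_comp <- vapply(c(0.1, 1, 10), function(ns) {
    sim <- shared_weight_duels(n_stimuli = 32, n_raters = 6, noise_sd = ns,
                               seed = 17)
    st <- score_rescorla_wagner(sim$duels, sim$ids, rw_config(seed = 2))
    comps <- vapply(sprintf("R%02d", 1:6), function(pid) {
      compliance(sim$judgments[sim$judgments$participant_id == pid, ],
                 sim$plans[[pid]], st)$compliance
    }, numeric(1))
    mean(comps)
  }, numeric(1))
  expect_true(all(diff(mean_comp) < 0))
})
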