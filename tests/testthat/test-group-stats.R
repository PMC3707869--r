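speed_table_of <- function(v, ids = sprintf("S%02d", seq_along(v))) {
  data.frame(stimulus_id = ids, v = v, n_trials = 1L,
             stringsAsFactors = FALSE)
}

test_that("extreme groups take the tails and the middle of the ranking", {
  st <- speed_table_of(seq(90, 90 + 51))        # strictly increasing
  g <- extreme_groups(st)
  expect_identical(g$activating, sprintf("S%02d", 52:43))  # a1 = fastest
  expect_identical(g$relaxing, sprintf("S%02d", 1:10))     # r1 = slowest
  expect_identical(g$neutral, sprintf("S%02d", 22:31))     # ranks 22-31
  expect_length(intersect(g$activating, g$relaxing), 0)
  expect_length(intersect(g$activating, g$neutral), 0)
  expect_error(extreme_groups(speed_table_of(1:20)), "at least")
})

test_that("group assignment is equivariant under row permutation", {
  v <- walkbeat:::with_seed(6, rnorm(52, 100, 5))
  st <- speed_table_of(v)
  perm <- walkbeat:::with_seed(7, sample(52))
  g1 <- extreme_groups(st)
  g2 <- extreme_groups(st[perm, ])
  expect_identical(g1$activating, g2$activating)
  expect_identical(g1$relaxing, g2$relaxing)
  expect_identical(g1$neutral, g2$neutral)
})

test_that("the ANOVA and Scheffe contrasts match a hand computation", {
  # small worked example: 3 groups of 4, computed from first principles
  y <- c(5, 6, 7, 8, 10, 11, 12, 13, 20, 21, 22, 23)
  st <- speed_table_of(y)
  g <- extreme_groups(st, n_group = 4)
  out <- speed_anova(st, g)
  grp <- rep(c("low", "mid", "high"), each = 4)
  gm <- tapply(y, grp, mean); n <- 4; k <- 3
  ss_b <- sum(n * (gm - mean(y))^2)
  ss_w <- sum((y - ave(y, grp))^2)
  F_hand <- (ss_b / (k - 1)) / (ss_w / (12 - k))
  expect_equal(out$F, F_hand, tolerance = 1e-10)
  expect_equal(out$df, c(2, 9))
  # Scheffe p for the low-vs-high contrast, from the closed form
  mse <- ss_w / 9
  Fs <- (gm["high"] - gm["low"])^2 / (mse * (2 / 4)) / (k - 1)
  p_hand <- 1 - pf(Fs, k - 1, 9)
  row <- out$scheffe[out$scheffe$group1 == "activating" &
                       out$scheffe$group2 == "relaxing", ]
  expect_equal(row$p, unname(p_hand), tolerance = 1e-10)
})

test_that("group speeds near the study means give a decisive ANOVA", {
  v <- walkbeat:::with_seed(12, c(
    rnorm(10, 107.0, 1.5),      # activating
    rnorm(32, 99.9, 1.5),       # middle
    rnorm(10, 89.4, 1.5)        # relaxing
  ))
  st <- speed_table_of(v)
  g <- extreme_groups(st)
  out <- speed_anova(st, g)
  expect_gt(out$F, 50)
  expect_lt(out$p, 0.001)
  expect_true(all(out$scheffe$p < 0.01))
  # location invariance of F
  st2 <- st; st2$v <- st2$v + 13
  expect_equal(speed_anova(st2, extreme_groups(st2))$F, out$F,
               tolerance = 1e-9)
})

test_that("identically distributed groups give F near 0 and p near 1", {
  st <- speed_table_of(rep(seq(96, 105), times = 3))
  ids <- st$stimulus_id
  g <- structure(list(activating = ids[1:10], relaxing = ids[11:20],
                      neutral = ids[21:30]), class = "group_assignment")
  out <- speed_anova(st, g)
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
})

test_that("feature t-tests have calibrated sign, null and power", {
  act <- sprintf("A%d", 1:10); rel <- sprintf("R%d", 1:10)
  g <- list(activating = act, relaxing = rel)
  # identical groups: p = 1
  same <- matrix(rep(1:10, 2), ncol = 1,
                 dimnames = list(c(act, rel), "f1"))
  expect_equal(feature_ttests(same, g)$p, 1)
  # planted 2-pooled-sd shift is detected at alpha = 0.01 in >= 95% of seeds
  hits <- sapply(1:100, function(s) {
    x <- walkbeat:::with_seed(s, matrix(rnorm(20), ncol = 1,
                                        dimnames = list(c(act, rel), "f1")))
    x[act, 1] <- x[act, 1] + 2
    res <- feature_ttests(x, g)
    c(res$p < 0.01, sign(res$t) == sign(res$mean_activating -
                                          res$mean_relaxing))
  })
  expect_gte(mean(hits[1, ]), 0.95)
  expect_true(all(hits[2, ]))
})

test_that("Mann-Whitney tests satisfy the U identity and find shifts", {
  act <- sprintf("A%02d", 1:10); rel <- sprintf("R%02d", 1:10)
  g <- list(activating = act, relaxing = rel)
  m <- simulate_ratings(act, rel, shift = 20, seed = 1)
  res <- ratings_tests(m, g)
  expect_identical(nrow(res), 9L)
  expect_equal(res$U + res$U_prime, rep(100, 9))
  shifted <- c("good_bad", "tender_aggressive", "soft_loud", "slow_fast",
               "stuttering_flowing")
  # over seeds, exactly the five planted adjectives are flagged most often
  exact_hits <- sapply(1:20, function(s) {
    r <- ratings_tests(simulate_ratings(act, rel, shift = 20, seed = s), g)
    setequal(r$adjective[r$p < 0.05], shifted)
  })
  expect_gte(sum(exact_hits), 11)
  # identical rating distributions stay unflagged
  flat <- matrix(rep(seq(30, 70, length.out = 10), 2 * 9), ncol = 9,
                 dimnames = list(c(act, rel), adjective_pairs()))
  res0 <- ratings_tests(flat, g)
  expect_true(all(res0$p > 0.9))
  expect_true(all(res0$tied))
})

test_that("the bundled label fixture matches the published ranking scheme", {
  lab <- stimulus_labels()
  expect_identical(nrow(lab), 52L)
  expect_identical(sum(lab$group == "activating"), 10L)
  expect_identical(sum(lab$group == "relaxing"), 10L)
  expect_identical(lab$label[lab$song_id == 1], "r1")
  expect_identical(lab$label[lab$song_id == 52], "a1")
  expect_identical(lab$label[lab$song_id == 43], "a10")
})
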