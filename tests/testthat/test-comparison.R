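test_that("pairing keeps only positions defined on both sides", {
  p <- profile_from_neq(c(NA, 2, 3, NA, 5, 6, 7, 8, 9, 10))
  tr <- track_from_scores(seq(0.1, 1, by = 0.1), positions = 1:10)
  s <- pair_series(p, tr)
  expect_identical(nrow(s), 8L)
  # identical index sets: nothing dropped
  p2 <- profile_from_neq(c(2, 3, 4), positions = 1:3)
  s2 <- pair_series(p2, track_from_scores(c(0.1, 0.2, 0.3)))
  expect_identical(attr(s2, "dropped"), 0L)
  # disjoint ranges
  expect_error(pair_series(p2, track_from_scores(c(0.1, 0.2), positions = 8:9)),
               "fewer than 3")
})

test_that("correlation is Pearson with affine invariance and sign", {
  p <- profile_from_neq(c(1, 2, 4, 6, 8, 10))
  up <- track_from_scores(0.05 + 0.08 * p$neq)
  expect_equal(series_correlation(pair_series(p, up)), 1)
  down <- track_from_scores(0.9 - 0.08 * p$neq)
  expect_equal(series_correlation(pair_series(p, down)), -1)
  set.seed(4)
  x <- stats::rnorm(50); y <- stats::rnorm(50)
  expect_equal(series_correlation(x = x, y = y),
               series_correlation(x = y, y = x))
  expect_equal(series_correlation(x = x, y = y),
               series_correlation(x = 2 * x + 1, y = 0.1 * y - 3))
  expect_error(series_correlation(x = rep(1, 5), y = stats::rnorm(5)),
               "constant")
})

test_that("synthetic tracks recover their target correlation at n = 1000", {
  v <- synth_neq_values(1000, seed = 12)
  for (rho in c(0, 0.35, 0.75)) {
    tr <- synth_score_track(v, rho = rho, seed = 100 + round(100 * rho))
    r <- series_correlation(x = v, y = tr$score)
    expect_lt(abs(r - rho), 0.06)   # Fisher-z 95% band at n = 1000
  }
})

test_that("stratified means match hand-computed values", {
  s <- data.frame(neq = c(1, 2, 5, 8, 9, 12),
                  score = c(0.1, 0.2, 0.5, 0.6, 0.8, 1.0))
  m <- stratified_means(s)
  expect_equal(m$mean_score, c(mean(c(0.1, 0.2)), mean(c(0.5, 0.6)),
                               mean(c(0.8, 1.0))))
  expect_identical(m$n, c(2L, 2L, 2L))
  # boundary convention: Neq = 4 and Neq = 8 belong to the middle stratum
  s2 <- data.frame(neq = c(4, 8, 1), score = c(0.3, 0.5, 0.1))
  m2 <- stratified_means(s2)
  expect_identical(m2$n, c(1L, 2L, 0L))
  expect_true(is.na(m2$mean_score[3]))
  s3 <- data.frame(neq = c(1, 2, 3), score = rep(0.5, 3))
  expect_equal(stratified_means(s3)$mean_score[1], 0.5)
})

test_that("twelve-class binning averages and correlates as specified", {
  s <- data.frame(neq = c(1.5, 1.9, 2.5, 3.5, 12, 15, 16),
                  score = c(0.1, 0.2, 0.3, 0.4, 0.8, 0.9, 1.0))
  cb <- class_binned_averages(s)
  expect_identical(nrow(cb$classes), 12L)
  expect_equal(cb$classes$mean_score[1], 0.15)
  expect_identical(cb$classes$n[12], 3L)      # 12, 15 and 16 in the top class
  expect_gt(cb$correlation, 0.9)              # monotone trend
  expect_error(class_binned_averages(data.frame(neq = c(1.1, 1.2, 1.3),
                                                score = c(0.1, 0.2, 0.3))),
               "populated")
})

test_that("class-level aggregation beats the pair-level correlation", {
  v <- synth_neq_values(1000, seed = 77)
  tr <- synth_score_track(v, rho = 0.35, seed = 78)
  s <- data.frame(neq = v, score = tr$score)
  pair_r <- series_correlation(x = v, y = tr$score)
  class_r <- class_binned_averages(s)$correlation
  expect_gt(class_r, pair_r)
})

test_that("two-state overlap decomposes exactly", {
  a <- track_from_scores(rep(0.5, 10), states = c(rep("D", 3), rep("O", 5), "D", "O"))
  b <- track_from_scores(rep(0.5, 10), states = c(rep("D", 3), rep("O", 5), "O", "D"))
  ov <- two_state_overlap(a, b)
  expect_equal(ov$common_disorder, 0.3)
  expect_equal(ov$common_order, 0.5)
  expect_equal(ov$agreement, 0.8)
  expect_equal(ov$common_disorder + ov$common_order, ov$agreement)
  expect_equal(ov$disorder_fraction_a, 0.4)
  expect_equal(ov$disorder_fraction_b, 0.4)
  expect_equal(two_state_overlap(a, a)$agreement, 1)
  flip <- a; flip$state <- ifelse(a$state == "D", "O", "D")
  expect_equal(two_state_overlap(a, flip)$agreement, 0)
})

test_that("prediction-rate sweep matches its truth definition", {
  # all-order predictions against fully rigid positions agree at any t >= 1
  p <- profile_from_neq(rep(1, 20))
  tr <- track_from_scores(rep(0.1, 20), states = "O")
  sw <- prediction_rate_sweep(p, tr)
  expect_equal(sw$rate, rep(1, 12))
  expect_equal(sw$true_order_fraction, rep(1, 12))
  # perfect oracle at t = 8
  v <- synth_neq_values(200, seed = 5)
  p2 <- profile_from_neq(v)
  oracle <- track_from_scores(rep(0.5, 200), states = ifelse(v > 8, "D", "O"))
  sw2 <- prediction_rate_sweep(p2, oracle)
  expect_equal(sw2$rate[sw2$threshold == 8], 1)
  # equality goes to order: truth at t uses Neq > t strictly
  p3 <- profile_from_neq(c(4, 4, 4, 5))
  tr3 <- track_from_scores(rep(0.9, 4), states = "D")
  sw3 <- prediction_rate_sweep(p3, tr3, thresholds = 4)
  expect_equal(sw3$rate, 0.25)
  # permutation invariance
  set.seed(9)
  perm <- sample(200)
  p4 <- profile_from_neq(v[perm])
  or4 <- track_from_scores(rep(0.5, 200), states = ifelse(v > 8, "D", "O")[perm])
  expect_equal(prediction_rate_sweep(p4, or4)$rate, sw2$rate)
})

test_that("an independent balanced track scores near one half", {
  set.seed(41)
  n <- 1000
  v <- ifelse(stats::runif(n) < 0.5, 2, 10)     # truth balanced at t = 8
  p <- profile_from_neq(v)
  tr <- track_from_scores(rep(0.5, n),
                          states = ifelse(stats::runif(n) < 0.5, "D", "O"))
  sw <- prediction_rate_sweep(p, tr, thresholds = 8)
  expect_lt(abs(sw$rate - 0.5), 0.05)
})

test_that("the assembled report is coherent across its parts", {
  v <- synth_neq_values(400, seed = 50)
  p <- profile_from_neq(v)
  t1 <- synth_score_track(v, rho = 0.75, seed = 51, predictor = "alpha")
  t2 <- synth_score_track(v, rho = 0.35, seed = 52, predictor = "beta")
  rep <- compare_report(p, list(alpha = t1, beta = t2))
  expect_s3_class(rep, "comparison_report")
  expect_identical(rep$correlations$predictor, c("alpha", "beta"))
  expect_gt(rep$correlations$correlation[1], rep$correlations$correlation[2])
  ov <- rep$overlaps[["alpha|beta"]]
  expect_equal(ov$common_disorder + ov$common_order, ov$agreement)
  expect_true(all(rep$sweeps$alpha$rate >= 0 & rep$sweeps$alpha$rate <= 1))
  expect_true(abs(rep$track_correlations$correlation) <= 1)
})
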