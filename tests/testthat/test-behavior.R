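make_behavior <- function(design, remembered, sorted = design$sequence_id,
                          subject_id = 1) {
  tibble::tibble(subject_id = subject_id, event_id = design$event_id,
                 remembered_time = remembered, sorted_group = sorted)
}

test_that("timeline regression caps Z for a perfect reconstruction", {
  d <- reference_design()
  b <- make_behavior(d, d$virtual_time)
  suppressWarnings(
    res <- timeline_regression(b, d, n_perm = 100, n_flips = 100, seed = 1)
  )
  z_virtual <- res$subject_results$z[res$subject_results$term == "virtual_time"]
  expect_equal(z_virtual, qnorm(100 / 101), tolerance = 1e-10)
  expect_error(
    timeline_regression(make_behavior(d, rep(c(8, 9, 10), length.out = 20)),
                        d, n_perm = 10),
    "distinct responses"
  )
})

test_that("timeline regression separates virtual time from its competitors", {
  # responses built from virtual time alone: with enough subjects the
  # group virtual-time effect is detected even with order and real time
  # competing for the (collinear) variance
  d <- reference_design()
  cfg <- sim_config(n_subjects = 28, gamma_bias = 0, behavior_noise_sd = 1.5)
  b <- simulate_behavior(d, cfg, 31)
  res <- timeline_regression(b, d, n_perm = 1000, n_flips = 1000, seed = 2)
  expect_lt(res$group$p, 0.05)
  expect_gt(res$group$statistic, 0)
})

test_that("accuracy metrics compute absolute errors in virtual hours", {
  d <- reference_design()
  b <- make_behavior(d, d$virtual_time)
  acc <- accuracy_metrics(b, d)
  expect_equal(acc$by_subject$mean_abs_error, 0)
  # one response off by 2 hours: mean absolute error 2/20 = 0.1
  rem <- d$virtual_time
  rem[7] <- rem[7] + 2
  acc2 <- accuracy_metrics(make_behavior(d, rem), d)
  expect_equal(acc2$by_subject$mean_abs_error, 0.1)
  # invariance to sequence relabeling
  d2 <- d
  d2$sequence_id <- c(2, 1, 4, 3)[d$sequence_id]
  acc3 <- accuracy_metrics(make_behavior(d2, rem), d2)
  expect_equal(acc3$by_subject$mean_abs_error, 0.1)
  expect_equal(acc2$group$mean, acc3$group$mean)
})

test_that("group-to-sequence assignment is optimal", {
  d <- reference_design()
  perfect <- assign_sorted_groups(d$sequence_id, d)
  expect_equal(perfect$percent_correct, 100)
  # relabeled groups still score 100 (assignment is label-free)
  relabeled <- c(3, 1, 4, 2)[d$sequence_id]
  expect_equal(assign_sorted_groups(relabeled, d)$percent_correct, 100)
  # exchanging two same-position events leaves 18/20 correct
  sorted <- d$sequence_id
  i <- which(d$sequence_id == 1 & d$position == 2)
  j <- which(d$sequence_id == 3 & d$position == 2)
  sorted[c(i, j)] <- sorted[c(j, i)]
  expect_equal(assign_sorted_groups(sorted, d)$percent_correct, 90)
  # equals the independent enumeration oracle on random labelings
  set.seed(15)
  for (r in 1:50) {
    labels <- sample(1:4, 20, replace = TRUE)
    got <- assign_sorted_groups(labels, d)$n_correct
    expect_equal(got, oracle_best_assignment(labels, d$sequence_id))
  }
  expect_error(assign_sorted_groups(rep(5, 20), d), "1..4")
})

test_that("swap errors require a mutual same-position interchange", {
  d <- reference_design()
  sorted <- d$sequence_id
  # mutual interchange at position 3 between sequences 1 and 2
  i <- which(d$sequence_id == 1 & d$position == 3)
  j <- which(d$sequence_id == 2 & d$position == 3)
  sorted[c(i, j)] <- sorted[c(j, i)]
  acc <- sorting_accuracy(make_behavior(d, d$virtual_time, sorted), d)
  expect_equal(acc$n_errors, 2)
  expect_equal(acc$n_swap_errors, 2)
  # a one-sided misplacement is a plain error, not a swap
  sorted2 <- d$sequence_id
  sorted2[i] <- 2
  acc2 <- sorting_accuracy(make_behavior(d, d$virtual_time, sorted2), d)
  expect_equal(acc2$n_errors, 1)
  expect_equal(acc2$n_swap_errors, 0)
})

test_that("swap-error surrogate test behaves at its extremes", {
  d <- reference_design()
  # all errors are same-position interchanges -> proportion 1
  sorted <- d$sequence_id
  for (pos in c(1, 4)) {
    i <- which(d$sequence_id == 1 & d$position == pos)
    j <- which(d$sequence_id == 2 & d$position == pos)
    sorted[c(i, j)] <- sorted[c(j, i)]
  }
  res <- swap_error_test(make_behavior(d, d$virtual_time, sorted), d,
                         n_iter = 300, seed = 1)
  expect_equal(res$observed_proportion, 1)
  expect_false(res$undefined)
  expect_lt(res$p, 0.05)
  expect_gt(res$z, 2)
  # no errors -> undefined, not 0/0
  res0 <- swap_error_test(make_behavior(d, d$virtual_time), d,
                          n_iter = 50, seed = 1)
  expect_true(res0$undefined)
  expect_true(is.na(res0$z))
})

test_that("surrogate null matches exhaustive enumeration of two-error sorts", {
  d <- reference_design()
  # one subject with exactly two random errors: enumerate every way of
  # moving two distinct events to wrong groups and score swaps the same way
  tot_err <- 0; tot_swap <- 0
  combos <- utils::combn(20, 2)
  for (k in seq_len(ncol(combos))) {
    e1 <- combos[1, k]; e2 <- combos[2, k]
    for (w1 in setdiff(1:4, d$sequence_id[e1])) {
      for (w2 in setdiff(1:4, d$sequence_id[e2])) {
        sorted <- d$sequence_id
        sorted[e1] <- w1; sorted[e2] <- w2
        asg <- assign_sorted_groups(sorted, d)
        err <- asg$assigned_sequence != d$sequence_id
        swap <- d$position[e1] == d$position[e2] &&
          w1 == d$sequence_id[e2] && w2 == d$sequence_id[e1]
        tot_err <- tot_err + sum(err)
        tot_swap <- tot_swap + if (swap) 2 else 0
      }
    }
  }
  exact_mean <- tot_swap / tot_err
  # a subject with two errors, matched by the surrogate machinery
  sorted <- d$sequence_id
  sorted[1] <- 2; sorted[7] <- 1  # two errors (not a swap: positions differ)
  res <- swap_error_test(make_behavior(d, d$virtual_time, sorted), d,
                         n_iter = 4000, seed = 3)
  expect_lt(abs(res$null_mean - exact_mean), 0.01)
})

test_that("generalization predictor averages the other three sequences", {
  d <- reference_design()
  # custom check at position 1: event of sequence 1 at 7.0; others at
  # 6.5, 8.0, 7.5 -> other mean 22/3
  pred <- generalization_predictor(d)
  expect_equal(pred$other_mean_time[1], (6.5 + 8.0 + 7.5) / 3)
  expect_equal(pred$deviation[1], (6.5 + 8.0 + 7.5) / 3 - 7.0)
  # worked example: event at 10, same-position others at 12, 11, 13
  d2 <- d
  d2$virtual_time <- c(10, 14, 16, 18, 20,
                       12, 14.5, 16.5, 18.5, 20.5,
                       11, 15, 17, 19, 21,
                       13, 15.5, 17.5, 19.5, 21.5)
  d2$real_time <- rep(c(0, 10, 20, 30, 40), 4) # keeps monotonicity valid
  pred2 <- generalization_predictor(d2)
  expect_equal(pred2$other_mean_time[1], 12)
  expect_equal(pred2$deviation[1], 2)
})

test_that("generalization bias recovers a planted bias weight", {
  d <- reference_design()
  cfg <- sim_config(n_subjects = 28, gamma_bias = 0.5,
                    behavior_noise_sd = 0.25)
  slopes <- numeric(20)
  for (r in 1:20) {
    b <- simulate_behavior(d, cfg, 400 + r)
    res <- generalization_bias(b, d, n_perm = 100, seed = r, group = FALSE)
    slopes[r] <- mean(res$subject_results$slope)
  }
  expect_equal(mean(slopes), 0.5, tolerance = 0.1)
})

test_that("generalization bias is invariant to a constant response shift", {
  d <- reference_design()
  cfg <- sim_config(n_subjects = 1, gamma_bias = 0.4, behavior_noise_sd = 0.3)
  b <- simulate_behavior(d, cfg, 9)
  b2 <- b
  b2$remembered_time <- b2$remembered_time + 1.5
  r1 <- generalization_bias(b, d, n_perm = 100, seed = 1, group = FALSE)
  r2 <- generalization_bias(b2, d, n_perm = 100, seed = 1, group = FALSE)
  expect_equal(r1$subject_results$slope, r2$subject_results$slope,
               tolerance = 1e-10)
})

test_that("chi-squared uniformity test matches hand computation", {
  r1 <- chi_square_uniformity(c(4, 4, 4, 4, 4))
  expect_equal(r1$chisq, 0)
  expect_equal(r1$p, 1)
  r2 <- chi_square_uniformity(c(20, 0, 0, 0, 0))
  expect_equal(r2$chisq, 80)
  expect_equal(r2$df, 4L)
  # invariance under permutation of the positions
  r3 <- chi_square_uniformity(c(0, 0, 20, 0, 0))
  expect_equal(r3$chisq, r2$chisq)
  expect_true(chi_square_uniformity(c(0, 0, 0, 0, 0))$undefined)
  expect_error(chi_square_uniformity(c(-1, 2, 0, 0, 0)), "nonnegative")
})

test_that("Spearman brain-behavior correlation matches rank arithmetic", {
  expect_equal(brain_behavior_correlation(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(brain_behavior_correlation(1:6, 6:1)$rho, -1)
  # 5-point toy against the rank formula 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(10, 20, 30, 40, 50)
  y <- c(1.2, 0.8, 1.9, 1.4, 2.5)
  dr <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(dr^2) / (5 * 24)
  expect_equal(brain_behavior_correlation(x, y)$rho, rho_hand)
  expect_true(brain_behavior_correlation(rep(1, 5), 1:5)$undefined)
  expect_error(brain_behavior_correlation(1:3, 1:3), "at least 5")
})
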