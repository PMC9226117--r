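test_that("a perfect fit yields the capped permutation Z", {
  x <- 1:10
  y <- 2 * x
  fit <- permutation_z(y, data.frame(x = x), n_perm = 100, seed = 1)
  row <- fit[fit$term == "x", ]
  expect_equal(row$p_perm, 1 / 101)
  expect_equal(row$z, qnorm(100 / 101), tolerance = 1e-12)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(7)
  x <- c(0.2, -1.1, 0.5, 1.7, -0.3, 0.9)
  y <- 0.8 * x + rnorm(6, sd = 0.8)
  p_exact <- oracle_perm_p(y, x)
  fit <- permutation_z(y, data.frame(x = x), n_perm = 10000, seed = 3)
  expect_lt(abs(fit$p_perm[fit$term == "x"] - p_exact), 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(permutation_z(rep(1, 6), data.frame(x = 1:6), n_perm = 100),
               "degenerate outcome")
  expect_error(
    permutation_z(rnorm(6), data.frame(a = 1:6, b = 2 * (1:6)), n_perm = 100),
    "rank-deficient"
  )
})

test_that("permutation Z preserves the sign of the effect", {
  set.seed(8)
  x <- rnorm(30)
  y_pos <- x + rnorm(30, sd = 0.5)
  y_neg <- -x + rnorm(30, sd = 0.5)
  z_pos <- permutation_z(y_pos, data.frame(x = x), n_perm = 500, seed = 1)
  z_neg <- permutation_z(y_neg, data.frame(x = x), n_perm = 500, seed = 1)
  expect_gt(z_pos$z[z_pos$term == "x"], 2)
  expect_lt(z_neg$z[z_neg$term == "x"], -2)
})

test_that("sign-flip test matches exhaustive enumeration and its symmetries", {
  set.seed(9)
  x <- c(0.8, 1.3, -0.2, 0.6, 1.0)
  exact <- oracle_signflip_p(x)
  res_ex <- group_signflip_test(x, exhaustive = TRUE)
  expect_equal(res_ex$p, exact)
  res_mc <- group_signflip_test(x, n_flips = 20000, seed = 4)
  expect_lt(abs(res_mc$p - exact), 0.01)
  # negating every value leaves the two-sided p unchanged
  res_neg <- group_signflip_test(-x, n_flips = 20000, seed = 4)
  expect_equal(res_neg$p, res_mc$p)
  expect_equal(res_neg$statistic, -res_mc$statistic)
  # all-zero input: every flip reproduces the observed statistic
  res0 <- group_signflip_test(rep(0, 6))
  expect_equal(res0$p, 1)
  expect_equal(res0$statistic, 0)
  # a nonzero constant vector degrades to an exact sign test: only the
  # all-plus and all-minus patterns are as extreme as t = Inf
  expect_warning(
    res_sat <- group_signflip_test(rep(2, 6), exhaustive = TRUE),
    "sign test"
  )
  expect_equal(res_sat$p, 2 / 64)
  expect_true(is.infinite(res_sat$statistic))
})

test_that("Hedges-corrected d matches the closed form and its invariances", {
  eff <- cohens_d_hedges(c(0, 1, 2))
  expect_equal(eff$correction, 4 / 7)
  expect_equal(eff$d, 4 / 7, tolerance = 1e-12)  # uncorrected d = 1
  # values symmetric about zero
  eff0 <- cohens_d_hedges(c(-1, -0.5, 0, 0.5, 1))
  expect_equal(eff0$d, 0)
  expect_equal(abs(eff0$ci_lower), abs(eff0$ci_upper), tolerance = 1e-6)
  # scale invariance
  set.seed(10)
  v <- rnorm(12, mean = 0.4)
  expect_equal(cohens_d_hedges(v)$d, cohens_d_hedges(2 * v)$d,
               tolerance = 1e-12)
  # the CI contains the point estimate
  expect_true(eff$ci_lower < eff$d && eff$d < eff$ci_upper)
  paired <- cohens_d_hedges(v, paired_with = v - 0.5)
  expect_true(paired$ci_lower < paired$d && paired$d < paired$ci_upper)
  expect_true(is.infinite(cohens_d_hedges(rep(1, 5))$d))
})

test_that("repeated-measures ANOVA matches the classical computation", {
  # fixed 4-subject 2x2 toy, F checked against aov's within-subject strata
  toy <- tidyr::expand_grid(subject_id = 1:4, factor_a = c("a1", "a2"),
                            factor_b = c("b1", "b2"))
  set.seed(11)
  toy$value <- c(1.0, 2.0, 1.5, 3.0,
                 0.5, 2.5, 1.0, 2.0,
                 1.2, 1.8, 0.8, 2.6,
                 0.9, 2.2, 1.4, 2.9)
  res <- permutation_rm_anova(toy, n_perm = 200, seed = 1)
  aovfit <- summary(stats::aov(
    value ~ factor_a * factor_b +
      Error(factor(subject_id) / (factor_a * factor_b)),
    data = toy
  ))
  f_a <- aovfit[["Error: factor(subject_id):factor_a"]][[1]]["factor_a", "F value"]
  f_b <- aovfit[["Error: factor(subject_id):factor_b"]][[1]]["factor_b", "F value"]
  f_ab <- aovfit[["Error: factor(subject_id):factor_a:factor_b"]][[1]][
    "factor_a:factor_b", "F value"]
  expect_equal(res$F[res$effect == "a"], f_a, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "b"], f_b, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "a:b"], f_ab, tolerance = 1e-10)
  expect_true(all(res$ges >= 0 & res$ges <= 1))

  # identical cells: all F = 0, p = 1
  toy0 <- toy
  toy0$value <- 1
  res0 <- permutation_rm_anova(toy0, n_perm = 200, seed = 1)
  expect_equal(res0$F, rep(0, 3))
  expect_equal(res0$p_perm, rep(1, 3))

  # incomplete design is rejected
  expect_error(permutation_rm_anova(toy[-1, ], n_perm = 10), "complete")
})

test_that("rm-ANOVA detects a planted interaction at the right rates", {
  n_runs <- 30
  hit_int <- hit_a <- 0
  set.seed(12)
  for (r in 1:n_runs) {
    n <- 28
    base <- rnorm(n, sd = 1)
    toy <- tidyr::expand_grid(subject_id = 1:n, factor_a = c("a1", "a2"),
                              factor_b = c("b1", "b2"))
    inter <- with(toy, ifelse(factor_a == "a1", 1, -1) *
                         ifelse(factor_b == "b1", 1, -1)) * 0.5
    toy$value <- base[toy$subject_id] + inter + rnorm(nrow(toy), sd = 0.6)
    res <- permutation_rm_anova(toy, n_perm = 300, seed = r)
    hit_int <- hit_int + (res$p_perm[res$effect == "a:b"] < 0.05)
    hit_a <- hit_a + (res$p_perm[res$effect == "a"] < 0.05)
  }
  expect_gte(hit_int / n_runs, 0.85)  # strongly powered planted interaction
  expect_lte(hit_a / n_runs, 0.25)    # null main effect stays near 5%
})

test_that("mixed-model LRT recovers a planted slope", {
  set.seed(13)
  hits <- 0; slopes <- numeric(10)
  for (r in 1:10) {
    n_subj <- 28; n_obs <- 40
    slope_true <- 0.3
    dat <- tidyr::expand_grid(subject_id = factor(1:n_subj),
                              obs = 1:n_obs)
    dat$x <- rnorm(nrow(dat))
    intercepts <- rnorm(n_subj, sd = 0.2)
    dat$y <- intercepts[as.integer(dat$subject_id)] + slope_true * dat$x +
      rnorm(nrow(dat), sd = 0.5)
    fit <- fit_mixed_and_lrt(dat, "y", "x", focal = "x")
    slopes[r] <- lme4::fixef(fit$full)[["x"]]
    hits <- hits + (fit$p < 0.05)
  }
  expect_equal(mean(slopes), 0.3, tolerance = 0.1)
  expect_gte(hits, 9)
})

test_that("mixed-model LRT statistic is a nonnegative chi-squared with df 1", {
  set.seed(14)
  dat <- tidyr::expand_grid(subject_id = factor(1:10), obs = 1:20)
  dat$x <- rnorm(nrow(dat))
  dat$y <- rnorm(nrow(dat))  # null data
  fit <- fit_mixed_and_lrt(dat, "y", "x", focal = "x")
  expect_gte(fit$chisq, 0)
  expect_equal(fit$df, 1L)
  expect_true(fit$p > 0 && fit$p <= 1)
  expect_error(fit_mixed_and_lrt(dat, "y", "x", focal = "z"), "focal")
})
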