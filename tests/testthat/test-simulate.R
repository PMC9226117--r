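test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_subjects = 3)
  d1 <- simulate_design(cfg, 11)
  d2 <- simulate_design(cfg, 11)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1, simulate_design(cfg, 12))))
  b1 <- simulate_behavior(d1, cfg, 5)
  b2 <- simulate_behavior(d1, cfg, 5)
  expect_identical(b1, b2)
  p1 <- simulate_patterns(d1, cfg, 7)
  p2 <- simulate_patterns(d1, cfg, 7)
  expect_identical(p1, p2)
  # the generators restore the ambient RNG state
  set.seed(99); before <- .Random.seed
  invisible(simulate_design(cfg, 1))
  expect_identical(before, .Random.seed)
})

test_that("design generation respects the timeline and the minimum gap", {
  cfg <- sim_config(min_gap = 2)
  for (seed in 1:10) {
    d <- simulate_design(cfg, seed)
    expect_true(all(d$virtual_time >= 6 & d$virtual_time <= 24))
    gaps <- unlist(tapply(d$virtual_time, d$sequence_id, diff))
    expect_true(all(gaps >= 2 - 1e-9))
    expect_silent(validate_design(d))
    pairs <- build_pair_table(d)
    expect_equal(nrow(pairs), 190)
  }
  # 4 gaps x 5 virtual hours cannot fit an 18-hour window
  expect_error(simulate_design(sim_config(min_gap = 5), 1), "infeasible")
})

test_that("behavior generator hits its stated world", {
  d <- reference_design()
  cfg0 <- sim_config(n_subjects = 4, gamma_bias = 0, behavior_noise_sd = 0,
                     p_swap = 0, p_random_sort_error = 0)
  b <- simulate_behavior(d, cfg0, 3)
  expect_equal(b$remembered_time, rep(d$virtual_time, 4))
  acc <- sorting_accuracy(b, d)
  expect_true(all(acc$percent_correct == 100))

  # planted bias shifts responses toward the other sequences' times
  cfgb <- sim_config(n_subjects = 200, gamma_bias = 0.5,
                     behavior_noise_sd = 0)
  bb <- simulate_behavior(d, cfgb, 4)
  pred <- generalization_predictor(d)
  shift <- bb$remembered_time - rep(d$virtual_time, 200)
  expect_equal(shift[1:20], 0.5 * pred$deviation, tolerance = 1e-9)
  # responses stay on the timeline
  expect_true(all(bb$remembered_time >= 6 & bb$remembered_time <= 24))
})

test_that("swap manipulation produces same-position interchanges", {
  d <- reference_design()
  cfg <- sim_config(n_subjects = 50, p_swap = 1, p_random_sort_error = 0)
  b <- simulate_behavior(d, cfg, 8)
  acc <- sorting_accuracy(b, d)
  # a forced swap affects exactly two events, mutually interchanged
  expect_true(all(acc$n_errors == 2))
  expect_true(all(acc$n_swap_errors == 2))
})

test_that("PSD projection is a fixed point on valid correlation matrices", {
  C <- diag(5)
  C[1, 2] <- C[2, 1] <- 0.5
  expect_equal(nearest_psd_corr(C), C, tolerance = 1e-10)
  # an invalid matrix is repaired: PSD with unit diagonal
  M <- matrix(0.9, 3, 3); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- -0.9
  out <- nearest_psd_corr(M)
  expect_true(all(eigen(out, symmetric = TRUE)$values > -1e-12))
  expect_equal(diag(out), rep(1, 3))
})

test_that("pattern generator plants the intended similarity-change structure", {
  d <- reference_design()
  # null configuration: mean change near zero for both pair classes
  cfg0 <- sim_config(a_within = 0, b_across = 0, n_subjects = 1)
  pairs <- build_pair_table(d)
  changes_same <- changes_diff <- numeric(200)
  for (s in 1:200) {
    pat <- simulate_patterns(d, cfg0, s)
    ch <- similarity_change(pairwise_similarity(pat$pre, "pre"),
                            pairwise_similarity(pat$post, "post"))
    v <- change_to_pairs(ch, pairs)$change
    changes_same[s] <- mean(v[pairs$same_sequence])
    changes_diff[s] <- mean(v[!pairs$same_sequence])
  }
  expect_lt(abs(mean(changes_same)), 0.01)
  expect_lt(abs(mean(changes_diff)), 0.01)

  # oversized planted effects are rejected, naming the cause
  expect_error(
    simulate_patterns(d, sim_config(a_within = 0.8, pattern_noise_sd = 2), 1),
    "effect sizes too large"
  )
  # shape contract
  pat <- simulate_patterns(d, sim_config(), 1)
  expect_equal(dim(pat$pre), c(20, 10, 100))
  expect_equal(dim(pat$post), c(20, 10, 100))
})

test_that("planted slopes are recovered without bias", {
  cfg <- sim_config()
  slopes_w <- slopes_a <- numeric(0)
  for (seed in 1:4) {
    exp <- simulate_experiment(cfg, 100 + seed)
    pairs <- build_pair_table(exp$design)
    changes <- experiment_changes(exp)
    zsame <- zscore_predictors(pairs, "virtual_distance", "same")
    zdiff <- zscore_predictors(pairs, "virtual_distance", "different")
    slopes_w <- c(slopes_w, vapply(changes, function(ch) {
      y <- change_to_pairs(ch, zsame)$change
      unname(coef(lm(y ~ zsame$virtual_distance))[2])
    }, numeric(1)))
    slopes_a <- c(slopes_a, vapply(changes, function(ch) {
      y <- change_to_pairs(ch, zdiff)$change
      unname(coef(lm(y ~ zdiff$virtual_distance))[2])
    }, numeric(1)))
  }
  # 112 subject-level slopes: recovery within Monte-Carlo error
  expect_equal(mean(slopes_w), cfg$a_within, tolerance = 0.012)
  expect_equal(mean(slopes_a), cfg$b_across, tolerance = 0.012)
})

test_that("entorhinal-style mode plants one slope for all pairs", {
  cfg <- sim_config(mode = "uniform", n_subjects = 20)
  exp <- simulate_experiment(cfg, 5)
  pairs <- build_pair_table(exp$design)
  changes <- experiment_changes(exp)
  zall <- zscore_predictors(pairs, "virtual_distance", "all")
  slopes <- vapply(changes, function(ch) {
    y <- change_to_pairs(ch, zall)$change
    unname(coef(lm(y ~ zall$virtual_distance))[2])
  }, numeric(1))
  expect_lt(mean(slopes), 0)  # planted b_across < 0 applies everywhere
})

test_that("volume dataset geometry and masks are consistent", {
  cfg <- sim_config(n_subjects = 2)
  vol <- generate_volume_dataset(cfg, 1, n_subjects = 2)
  g <- vol$grid
  expect_true(all(dim(g$brain_mask) == cfg$volume_dims))
  # gray matter nested in brain
  expect_true(all(!(g$graymatter_mask & !g$brain_mask)))
  # cluster recorded and inside the brain
  expect_true(sum(vol$cluster_mask) > 0)
  expect_true(all(g$brain_mask[vol$cluster_mask]))
  # pattern matrices: one column per brain voxel
  expect_equal(ncol(vol$subjects[[1]]$pre), length(vol$brain_index))
  expect_equal(nrow(vol$subjects[[1]]$pre), 20 * cfg$n_miniblocks)
  # cluster outside the volume is rejected
  expect_error(
    generate_volume_dataset(sim_config(cluster_center = c(40, 6, 6)), 1,
                            n_subjects = 1),
    "outside volume"
  )
  expect_error(
    generate_volume_dataset(sim_config(volume_dims = c(8, 12, 12)), 1,
                            n_subjects = 1),
    ">= 12"
  )
})

test_that("experiment writer produces a reproducible manifest", {
  cfg <- sim_config(n_subjects = 2)
  exp <- simulate_experiment(cfg, 2, patterns = FALSE)
  dir <- tempfile()
  write_experiment(exp, dir, seed = 2)
  expect_true(file.exists(file.path(dir, "design.tsv")))
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$seed, 2)
  expect_equal(mf$n_rows$design, 20)
  d2 <- read_design_tsv(file.path(dir, "design.tsv"))
  expect_equal(d2$virtual_time, exp$design$virtual_time, tolerance = 1e-6)
})
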