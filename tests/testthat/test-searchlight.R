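all_true_grid <- function(dims = c(9, 9, 9)) {
  m <- array(TRUE, dim = dims)
  volume_grid(dims, voxel_size = 1.5, brain_mask = m, graymatter_mask = m)
}

test_that("sphere extraction matches brute-force enumeration", {
  grid <- all_true_grid()
  center <- c(5, 5, 5)
  got <- sphere_indices(center, 3, grid)
  expect_equal(nrow(got), 123)  # integer lattice ball of radius 3
  want <- oracle_sphere(center, 3, grid$dims)
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               want[order(want[, 1], want[, 2], want[, 3]), ],
               ignore_attr = TRUE)
  # radius 0: just the center
  expect_equal(nrow(sphere_indices(center, 0, grid)), 1)
  # corner sphere is clipped to a subset of the interior sphere's size
  corner <- sphere_indices(c(1, 1, 1), 3, grid)
  expect_lt(nrow(corner), 123)
  expect_error(sphere_indices(c(0, 5, 5), 3, grid), "outside volume")
})

test_that("the gray-voxel count filter is strict at 25", {
  dims <- c(13, 13, 13)
  brain <- array(TRUE, dim = dims)
  center <- c(9, 9, 9)
  ball <- oracle_sphere(center, 3, dims)
  # exactly 25 gray voxels inside the center's sphere -> discarded; a
  # fully gray corner block keeps other centers valid
  gray25 <- array(FALSE, dim = dims)
  gray25[1:4, 1:4, 1:4] <- TRUE
  gray25[ball[1:25, , drop = FALSE]] <- TRUE
  grid25 <- volume_grid(dims, 1.5, brain, gray25)
  m <- 3
  set.seed(20)
  pats <- matrix(rnorm(20 * m * prod(dims)), 20 * m, prod(dims))
  pairs <- build_pair_table(reference_design())
  maps25 <- run_searchlight(pats, pats + rnorm(length(pats)), grid25, pairs,
                            radius = 3, min_gray = 25, n_miniblocks = m)
  expect_false(is.finite(maps25$same[center[1], center[2], center[3]]))
  # 26 gray voxels -> analyzed
  gray26 <- gray25
  gray26[ball[26, , drop = FALSE]] <- TRUE
  grid26 <- volume_grid(dims, 1.5, brain, gray26)
  maps26 <- run_searchlight(pats, pats + rnorm(length(pats)), grid26, pairs,
                            radius = 3, min_gray = 25, n_miniblocks = m)
  expect_true(is.finite(maps26$same[center[1], center[2], center[3]]))
})

test_that("searchlight t-values reproduce the ROI analysis exactly", {
  # a 3x3x3 all-gray brain with radius 4 spheres: every sphere is the
  # whole region, so every center must equal the ROI-path t-value
  dims <- c(12, 12, 12)
  brain <- array(FALSE, dim = dims)
  brain[5:7, 5:7, 5:7] <- TRUE
  grid <- volume_grid(dims, 1.5, brain, brain)
  d <- reference_design()
  pairs <- build_pair_table(d)
  cfg <- sim_config(n_voxels = 27, n_subjects = 1)
  pat <- simulate_patterns(d, cfg, 33)
  pre <- patterns_to_matrix(pat$pre)
  post <- patterns_to_matrix(pat$post)
  maps <- run_searchlight(pre, post, grid, pairs, radius = 4, min_gray = 25,
                          n_miniblocks = 10)
  centers <- which(is.finite(maps$same))
  expect_equal(length(centers), 27)
  expect_equal(diff(range(maps$same[centers])), 0, tolerance = 1e-10)
  # ROI path: same similarity change, classical regression t
  ch <- similarity_change(pairwise_similarity(pat$pre, "pre"),
                          pairwise_similarity(pat$post, "post"))
  sub <- zscore_predictors(pairs, "virtual_distance", "same")
  y <- change_to_pairs(ch, sub)$change
  t_roi <- summary(lm(y ~ sub$virtual_distance))$coefficients[2, "t value"]
  expect_equal(maps$same[centers[1]], t_roi, tolerance = 1e-10)
  # interaction map as well
  zall <- zscore_predictors(pairs, "virtual_distance", "all")
  y_all <- change_to_pairs(ch, zall)$change
  sq <- ifelse(zall$same_sequence, 0.5, -0.5)
  t_int <- summary(lm(y_all ~ zall$virtual_distance * sq))$coefficients[4, "t value"]
  expect_equal(maps$interaction[centers[1]], t_int, tolerance = 1e-10)
})

test_that("smoothing conserves mass and respects invalid voxels", {
  grid <- all_true_grid(c(10, 10, 10))
  set.seed(21)
  vol <- array(rnorm(1000), dim = c(10, 10, 10))
  sm <- smooth_map(vol, fwhm_mm = 3, grid)
  # constant map is unchanged
  cm <- smooth_map(array(2.5, dim = c(10, 10, 10)), 3, grid)
  expect_equal(cm, array(2.5, dim = c(10, 10, 10)), tolerance = 1e-6)
  # a delta spreads with the right width: sigma = fwhm/(2 sqrt(2 ln 2))/vox
  delta <- array(0, dim = c(21, 21, 21)); delta[11, 11, 11] <- 1
  gridd <- all_true_grid(c(21, 21, 21))
  smd <- smooth_map(delta, 3, gridd)
  profile <- smd[, 11, 11] / sum(smd[, 11, 11])
  sigma_emp <- sqrt(sum(profile * ((1:21) - 11)^2))
  expect_equal(sigma_emp, 3 / (2 * sqrt(2 * log(2))) / 1.5, tolerance = 0.01)
  # NaN voxels stay NaN and do not contaminate neighbors
  vol2 <- vol
  vol2[3, 3, 3] <- NaN
  sm2 <- smooth_map(vol2, 3, grid)
  expect_true(is.nan(sm2[3, 3, 3]))
  expect_true(all(is.finite(sm2[is.finite(vol2)])))
  expect_error(smooth_map(vol, -1, grid), "positive")
})

test_that("TFCE matches the naive oracle and its invariants", {
  dims <- c(6, 6, 6)
  set.seed(22)
  map <- array(rnorm(prod(dims)), dim = dims)
  got <- tfce_transform(map)
  want <- oracle_tfce(as.vector(map), dims)
  expect_equal(as.vector(got), want, tolerance = 1e-10)
  # zero wherever the map is non-positive
  expect_true(all(got[map <= 0] == 0))
  # monotone under pointwise increase
  map2 <- map + 0.5 * (map > 0)
  got2 <- tfce_transform(map2)
  expect_true(all(got2[map > 0] >= got[map > 0] - 1e-12))
})

test_that("group map test controls its extremes", {
  dims <- c(12, 12, 12)
  svc <- array(TRUE, dim = dims)
  # all-zero maps: corrected p = 1 everywhere
  zero_maps <- replicate(10, array(0, dim = dims), simplify = FALSE)
  res0 <- group_map_test(zero_maps, svc, n_flips = 100, seed = 1)
  expect_true(all(res0$p_corrected == 1))
  expect_true(all(res0$t == 0))
  # corrected p dominates uncorrected p inside the mask
  set.seed(23)
  maps <- replicate(12, array(rnorm(prod(dims), mean = 0.1), dim = dims),
                    simplify = FALSE)
  res <- group_map_test(maps, svc, n_flips = 200, seed = 2)
  ok <- is.finite(res$p_corrected)
  expect_true(all(res$p_corrected[ok] >= res$p_uncorrected[ok] - 1e-12))
  # bit-reproducible under the seed
  res_b <- group_map_test(maps, svc, n_flips = 200, seed = 2)
  expect_identical(res$p_corrected, res_b$p_corrected)
})

test_that("peak ROI extraction follows the cluster around the peak", {
  dims <- c(10, 10, 10)
  svc <- array(TRUE, dim = dims)
  t_map <- array(0, dim = dims)
  p_map <- array(1, dim = dims)
  # one suprathreshold voxel
  t_map[5, 5, 5] <- 6; p_map[5, 5, 5] <- 0.001
  roi <- peak_roi_from_cluster(t_map, p_map, 0.01, svc)
  expect_equal(sum(roi), 1)
  expect_true(roi[5, 5, 5])
  # two disjoint blobs: only the peak-containing one is returned
  t_map[2, 2, 2] <- 3; p_map[2, 2, 2] <- 0.005
  t_map[5, 5, 6] <- 5; p_map[5, 5, 6] <- 0.002
  roi2 <- peak_roi_from_cluster(t_map, p_map, 0.01, svc)
  expect_true(roi2[5, 5, 5] && roi2[5, 5, 6])
  expect_false(roi2[2, 2, 2])
  # lowering the threshold never grows the ROI
  roi3 <- peak_roi_from_cluster(t_map, p_map, 0.003, svc)
  expect_true(all(!(roi3 & !roi2)))
  # no survivors -> empty flag
  roi4 <- peak_roi_from_cluster(t_map, array(1, dim = dims), 0.01, svc)
  expect_true(attr(roi4, "empty"))
})

test_that("a planted cluster is localized by the group searchlight", {
  cfg <- sim_config(a_within = 0.12, b_across = -0.12, n_subjects = 12)
  vol <- generate_volume_dataset(cfg, 51, n_subjects = 12)
  pairs <- build_pair_table(vol$design)
  maps <- lapply(vol$subjects, function(su) {
    m <- run_searchlight(su$pre, su$post, vol$grid, pairs)$same
    smooth_map(m, 3, vol$grid)
  })
  res <- group_map_test(maps, vol$grid$graymatter_mask, n_flips = 300,
                        seed = 3)
  tv <- res$t
  tv[!is.finite(tv)] <- -Inf
  peak <- arrayInd(which.max(tv), dim(tv))
  expect_lte(sqrt(sum((peak - vol$cluster_center)^2)), 3)
  # per-subject peak extraction returns one value per subject
  pk <- peak_subject_tvalues(maps, res$t, vol$grid$graymatter_mask)
  expect_equal(nrow(pk), 12)
  expect_true(all(is.finite(pk$peak_t)))
  # the peaks table is sorted by |t| and carries mm coordinates
  pt <- peaks_table(res, vol$grid, n_peaks = 5)
  expect_equal(nrow(pt), 5)
  expect_true(all(diff(abs(pt$t)) <= 0))
  expect_equal(pt$x_mm, (pt$x - 1) * 1.5)
})

test_that("NIfTI volumes round-trip through disk", {
  set.seed(24)
  a <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  path <- tempfile(fileext = ".nii")
  write_nifti(a, path, voxel_size = 2)
  b <- read_nifti(path)
  expect_equal(b$data, a)
  expect_equal(b$voxel_size, rep(2, 3))
  a4 <- array(rnorm(4 * 4 * 4 * 3), dim = c(4, 4, 4, 3))
  write_nifti(a4, path)
  expect_equal(read_nifti(path)$data, a4)
  expect_error(read_nifti(tempfile()), "not found")
})
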