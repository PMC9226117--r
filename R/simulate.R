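#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators. Defaults state
#' the simulated world once: the study's structural constants (28 subjects,
#' 4 sequences x 5 events on a 6-24 virtual-hour timeline, 10 mini-blocks
#' per scan phase) and desk-scale effect sizes for the planted
#' representational structure (see the methods vignette for rationale).
#'
#' @param n_subjects Number of simulated participants.
#' @param n_voxels Voxels per simulated region of interest.
#' @param n_miniblocks Mini-blocks per picture-viewing phase (>= 2).
#' @param pattern_noise_sd SD of independent voxel noise around the
#'   per-event mean pattern (arbitrary activation units).
#' @param signal_sd SD of the per-event mean patterns. Together with
#'   `pattern_noise_sd` it fixes the attenuation of planted correlations,
#'   which the generator compensates analytically.
#' @param a_within Planted slope of post-minus-pre similarity change on the
#'   z-scored virtual temporal distance for same-sequence pairs (positive
#'   under the studied effect).
#' @param b_across Planted slope for different-sequence pairs (negative
#'   under the studied effect).
#' @param baseline_change Constant similarity-change offset for all pairs.
#' @param mode `"contrast"` plants opposite-sign within/across slopes
#'   (hippocampus-style); `"uniform"` plants a single slope (`b_across`) on
#'   the virtual distance of all pairs regardless of sequence membership
#'   (entorhinal-style).
#' @param behavior_noise_sd SD of timeline response noise (virtual hours).
#' @param gamma_bias Generalization-bias weight: how strongly a remembered
#'   time is pulled toward the mean time of same-position events in the
#'   other sequences (dimensionless).
#' @param p_swap Probability that a subject's sorting contains one swap
#'   error (a same-position pair exchanged between two sequences).
#' @param p_random_sort_error Probability of one additional random sorting
#'   error (an event moved to a uniformly chosen wrong group).
#' @param clock_speeds Virtual hours per real second, one value per
#'   sequence; at least two distinct values are required to dissociate
#'   virtual from real time.
#' @param min_gap Minimum virtual-hour gap between successive events of a
#'   sequence.
#' @param volume_dims Integer triple: dimensions of simulated searchlight
#'   volumes (each >= 12).
#' @param voxel_size_mm Isotropic voxel size of simulated volumes (mm).
#' @param brain_radius Radius (voxels) of the spherical "brain" inside the
#'   volume.
#' @param gray_fraction Fraction of brain voxels marked gray matter.
#' @param cluster_center,cluster_radius Center (voxel indices) and radius of
#'   the planted effect cluster inside the brain.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 28L,
                       n_voxels = 100L,
                       n_miniblocks = 10L,
                       pattern_noise_sd = 1.0,
                       signal_sd = 1.0,
                       a_within = 0.04,
                       b_across = -0.04,
                       baseline_change = 0,
                       mode = c("contrast", "uniform"),
                       behavior_noise_sd = 0.5,
                       gamma_bias = 0.5,
                       p_swap = 0.3,
                       p_random_sort_error = 0.3,
                       clock_speeds = c(0.12, 0.24, 0.12, 0.24),
                       min_gap = 1.5,
                       volume_dims = c(12L, 12L, 12L),
                       voxel_size_mm = 1.5,
                       brain_radius = 5,
                       gray_fraction = 0.5,
                       cluster_center = NULL,
                       cluster_radius = 3) {
  mode <- match.arg(mode)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
    n_miniblocks = as.integer(n_miniblocks),
    pattern_noise_sd = pattern_noise_sd, signal_sd = signal_sd,
    a_within = a_within, b_across = b_across,
    baseline_change = baseline_change, mode = mode,
    behavior_noise_sd = behavior_noise_sd, gamma_bias = gamma_bias,
    p_swap = p_swap, p_random_sort_error = p_random_sort_error,
    clock_speeds = clock_speeds, min_gap = min_gap,
    volume_dims = as.integer(volume_dims), voxel_size_mm = voxel_size_mm,
    brain_radius = brain_radius, gray_fraction = gray_fraction,
    cluster_center = if (is.null(cluster_center)) ceiling(as.integer(volume_dims) / 2)
                     else as.integer(cluster_center),
    cluster_radius = cluster_radius
  )
  stopifnot(
    cfg$n_subjects > 0, cfg$n_voxels > 0, cfg$n_miniblocks >= 2,
    cfg$pattern_noise_sd >= 0, cfg$signal_sd > 0,
    cfg$behavior_noise_sd >= 0,
    cfg$p_swap >= 0, cfg$p_swap <= 1,
    cfg$p_random_sort_error >= 0, cfg$p_random_sort_error <= 1,
    length(cfg$clock_speeds) == 4, all(cfg$clock_speeds > 0),
    length(unique(cfg$clock_speeds)) >= 2,
    cfg$min_gap > 0,
    length(cfg$volume_dims) == 3,
    cfg$gray_fraction > 0, cfg$gray_fraction <= 1
  )
  structure(cfg, class = "sim_config")
}

# Evaluate code with a local, restored RNG state so generators are pure
# functions of (config, seed).
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate an experiment design
#'
#' Draws 5 strictly increasing virtual event times per sequence inside the
#' `[6, 24]` virtual-hour timeline with a minimum gap, then derives real
#' times by dividing virtual gaps by the per-sequence hidden-clock speed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical designs.
#' @return A design tibble (see [validate_design()]) with a `clock_speed`
#'   column.
#' @export
simulate_design <- function(config = sim_config(), seed) {
  lo <- 6; hi <- 24
  n_pos <- 5L
  g <- config$min_gap
  if ((n_pos - 1) * g > (hi - lo)) {
    stop("infeasible design constraints: ", n_pos, " events with minimum gap ",
         g, " virtual hours do not fit the ", hi - lo, "-hour timeline",
         call. = FALSE)
  }
  with_seed_(seed, {
    rows <- purrr::map(1:4, function(sq) {
      # sorted uniforms on the gap-shrunk interval, then add the gaps back:
      # guarantees strictly increasing times with gap >= min_gap
      u <- sort(stats::runif(n_pos, lo, hi - (n_pos - 1) * g))
      vt <- u + (seq_len(n_pos) - 1) * g
      speed <- config$clock_speeds[sq]
      rt <- c(0, cumsum(diff(vt) / speed))
      tibble::tibble(
        sequence_id = sq, position = seq_len(n_pos),
        virtual_time = vt, real_time = rt, clock_speed = speed
      )
    })
    design <- dplyr::bind_rows(rows)
    design$event_id <- seq_len(nrow(design))
    design <- dplyr::relocate(design, "event_id")
    validate_design(design)
    design
  })
}

#' Relative time of same-position events in the other sequences
#'
#' For each event, the mean virtual time of the events occupying the same
#' sequence position in the other three sequences, and the deviation
#' `d(e) = other_mean_time - virtual_time(e)`. Positive deviations mean the
#' other sequences' events at that position happen later than the event in
#' question; the generalization bias pulls remembered times toward them.
#'
#' @param design A valid design table.
#' @return The design with columns `other_mean_time` and `deviation` added.
#' @export
generalization_predictor <- function(design) {
  design <- validate_design(design)
  design |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(
      other_mean_time = (sum(.data$virtual_time) - .data$virtual_time) /
        (dplyr::n() - 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(deviation = .data$other_mean_time - .data$virtual_time)
}

#' Simulate behavioral responses
#'
#' Timeline responses follow
#' `remembered = virtual_time + gamma_bias * d(e) + Normal(0, behavior_noise_sd)`
#' (clipped to the 6-24 h timeline), where `d(e)` is the relative time of
#' same-position events in the other sequences. Sorting starts correct; with
#' probability `p_swap` one same-position pair of events is exchanged
#' between two sequences, and with probability `p_random_sort_error` one
#' event is moved to a uniformly chosen wrong group.
#'
#' @param design A valid design table.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_subjects Number of subjects; defaults to `config$n_subjects`.
#' @return A behavior tibble: `subject_id`, `event_id`, `remembered_time`,
#'   `sorted_group`.
#' @export
simulate_behavior <- function(design, config = sim_config(), seed,
                              n_subjects = config$n_subjects) {
  design <- generalization_predictor(design)
  with_seed_(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      # subjects differ in timeline precision (log-normal spread around the
      # nominal noise SD), mirroring the across-subject error spread seen
      # in this paradigm
      subj_sd <- config$behavior_noise_sd * exp(stats::rnorm(1, 0, 0.4))
      remembered <- design$virtual_time +
        config$gamma_bias * design$deviation +
        stats::rnorm(nrow(design), 0, subj_sd)
      remembered <- pmin(pmax(remembered, 6), 24)
      sorted <- design$sequence_id
      if (stats::runif(1) < config$p_swap) {
        pos <- sample.int(5L, 1)
        seqs <- sample.int(4L, 2)
        i <- which(design$position == pos & design$sequence_id == seqs[1])
        j <- which(design$position == pos & design$sequence_id == seqs[2])
        tmp <- sorted[i]; sorted[i] <- sorted[j]; sorted[j] <- tmp
      }
      if (stats::runif(1) < config$p_random_sort_error) {
        ev <- sample.int(nrow(design), 1)
        wrong <- setdiff(1:4, sorted[ev])
        sorted[ev] <- wrong[sample.int(3L, 1)]
      }
      tibble::tibble(
        subject_id = s, event_id = design$event_id,
        remembered_time = remembered, sorted_group = sorted
      )
    })
  })
}

#' Project a symmetric matrix to the nearest positive-semidefinite
#' correlation matrix
#'
#' Eigenvalue clipping at zero followed by re-normalization to unit
#' diagonal. A matrix that is already positive semidefinite with unit
#' diagonal is returned unchanged (up to numerical precision).
#'
#' @param m A symmetric matrix.
#' @return A positive-semidefinite matrix with unit diagonal.
#' @export
nearest_psd_corr <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / (d %o% d)
  (out + t(out)) / 2
}

# Target similarity-change matrix for the planted structure (pair order as
# in build_pair_table). z-scoring of the planted distance predictor is done
# within the same subset that the recovery analyses use.
planted_change_targets <- function(design, config) {
  pairs <- build_pair_table(design)
  target <- rep(config$baseline_change, nrow(pairs))
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  if (config$mode == "contrast") {
    same <- pairs$same_sequence
    target[same] <- target[same] + config$a_within * zs(pairs$virtual_distance[same])
    target[!same] <- target[!same] + config$b_across * zs(pairs$virtual_distance[!same])
  } else {
    target <- target + config$b_across * zs(pairs$virtual_distance)
  }
  list(pairs = pairs, target = target)
}

# Build the 20x20 mean-pattern correlation matrix for one phase, with the
# attenuation compensation kappa applied to the planted raw correlations.
phase_corr_matrix <- function(target_raw, config, n_events = 20L) {
  kappa <- (config$signal_sd^2 + config$pattern_noise_sd^2) / config$signal_sd^2
  scaled <- target_raw * kappa
  if (any(abs(scaled) > 0.95)) {
    stop("planted effect sizes too large for a valid correlation matrix ",
         "(|target * kappa| > 0.95); reduce a_within/b_across or the noise sd",
         call. = FALSE)
  }
  C <- diag(n_events)
  idx <- utils::combn(n_events, 2)
  C[cbind(idx[1, ], idx[2, ])] <- scaled
  C[cbind(idx[2, ], idx[1, ])] <- scaled
  nearest_psd_corr(C)
}

# Draw event x mini-block x voxel patterns whose event means have the given
# correlation structure.
draw_phase_patterns <- function(C, config, n_voxels = config$n_voxels) {
  n_events <- nrow(C)
  L <- t(chol(C + diag(1e-10, n_events)))
  G <- matrix(stats::rnorm(n_events * n_voxels, sd = config$signal_sd),
              n_events, n_voxels)
  M <- L %*% G
  arr <- array(stats::rnorm(n_events * config$n_miniblocks * n_voxels,
                            sd = config$pattern_noise_sd),
               dim = c(n_events, config$n_miniblocks, n_voxels))
  arr + aperm(array(M, dim = c(n_events, n_voxels, config$n_miniblocks)),
              c(1, 3, 2))
}

#' Simulate pre- and post-learning multi-voxel patterns for one subject
#'
#' Plants the expected post-minus-pre similarity-change structure at the
#' level of the post-phase mean-pattern correlation matrix (baseline plus
#' within/across-sequence slopes on z-scored virtual distance, projected to
#' the nearest positive-semidefinite correlation matrix); the pre phase uses
#' the unstructured identity target. Per-mini-block patterns are the event
#' mean plus independent voxel noise, so the downstream RSA is exercised
#' end to end.
#'
#' @param design A valid design table.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `pre` and `post` arrays of dimension
#'   `20 x n_miniblocks x n_voxels`, plus the planted `target` change values
#'   in pair-table order.
#' @export
simulate_patterns <- function(design, config = sim_config(), seed) {
  if (config$n_voxels < 20) stop("n_voxels must be >= 20", call. = FALSE)
  pt <- planted_change_targets(design, config)
  C_post <- phase_corr_matrix(pt$target, config)
  C_pre <- diag(20L)
  with_seed_(seed, {
    list(
      pre = draw_phase_patterns(C_pre, config),
      post = draw_phase_patterns(C_post, config),
      target = pt$target,
      pairs = pt$pairs
    )
  })
}

#' Simulate a full experiment
#'
#' One shared design plus per-subject behavior and pre/post pattern arrays.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param patterns Set `FALSE` to skip pattern simulation (behavior only).
#' @return A list with `design`, `behavior` (tibble over all subjects), and
#'   `patterns` (per-subject list of `pre`/`post` arrays).
#' @export
simulate_experiment <- function(config = sim_config(), seed, patterns = TRUE) {
  design <- simulate_design(config, seed)
  behavior <- simulate_behavior(design, config, seed + 1L)
  pat <- NULL
  if (patterns) {
    pt <- planted_change_targets(design, config)
    C_post <- phase_corr_matrix(pt$target, config)
    pat <- with_seed_(seed + 2L, {
      # draw sequentially under one RNG stream; one stream per experiment
      lapply(seq_len(config$n_subjects), function(s) {
        list(pre = draw_phase_patterns(diag(20L), config),
             post = draw_phase_patterns(C_post, config))
      })
    })
  }
  list(design = design, behavior = behavior, patterns = pat, config = config)
}

sphere_mask_ <- function(dims, center, radius) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = dims)
}

#' Simulate searchlight pattern volumes with a planted cluster
#'
#' Builds, per subject, pre- and post-phase pattern data for every voxel of
#' a spherical "brain" inside a small volume. Voxels inside the planted
#' cluster carry the [simulate_patterns()] structure (sharing one set of
#' event mean patterns, as contiguous cortex would); voxels outside carry
#' null structure. A gray-matter mask (random subset of brain voxels, fixed
#' by the seed) is nested inside the brain mask.
#'
#' @param config A [sim_config()]; `volume_dims`, `brain_radius`,
#'   `gray_fraction`, `cluster_center`, `cluster_radius` control the
#'   geometry. Set `cluster_radius = 0` for a fully null volume.
#' @param seed Integer seed.
#' @param n_subjects Number of subjects; defaults to `config$n_subjects`.
#' @return A list: `design`, `grid` (a [volume_grid()]), `cluster_mask`,
#'   `cluster_center`, and `subjects`, each with `pre`/`post` matrices of
#'   size `(20 * n_miniblocks) x n_brain_voxels` in event-major order plus
#'   the brain-voxel linear indices.
#' @export
generate_volume_dataset <- function(config = sim_config(), seed,
                                    n_subjects = config$n_subjects) {
  dims <- config$volume_dims
  if (any(dims < 12)) stop("volume_dims must be >= 12 per axis", call. = FALSE)
  ctr <- config$cluster_center
  if (any(ctr < 1) || any(ctr > dims)) {
    stop("cluster center ", paste(ctr, collapse = ","),
         " outside volume bounds", call. = FALSE)
  }
  design <- simulate_design(config, seed)
  brain <- sphere_mask_(dims, (dims + 1) / 2, config$brain_radius)
  cluster <- if (config$cluster_radius > 0) {
    sphere_mask_(dims, ctr, config$cluster_radius) & brain
  } else array(FALSE, dim = dims)
  brain_idx <- which(brain)
  n_brain <- length(brain_idx)
  pt <- planted_change_targets(design, config)
  C_post <- phase_corr_matrix(pt$target, config)
  m <- config$n_miniblocks
  with_seed_(seed + 1L, {
    gray <- array(FALSE, dim = dims)
    gray[sample(brain_idx, size = round(config$gray_fraction * n_brain))] <- TRUE
    in_cluster <- cluster[brain_idx]
    subjects <- lapply(seq_len(n_subjects), function(s) {
      make_phase <- function(C) {
        n_clu <- sum(in_cluster)
        mat <- matrix(stats::rnorm(20L * m * n_brain, sd = config$pattern_noise_sd),
                      20L * m, n_brain)
        # event means: structured C inside the cluster, identity outside
        M_null <- matrix(stats::rnorm(20L * n_brain, sd = config$signal_sd), 20L, n_brain)
        if (n_clu > 0) {
          L <- t(chol(C + diag(1e-10, 20L)))
          M_null[, in_cluster] <- L %*%
            matrix(stats::rnorm(20L * n_clu, sd = config$signal_sd), 20L, n_clu)
        }
        mat + M_null[rep(seq_len(20L), each = m), ]
      }
      list(pre = make_phase(diag(20L)), post = make_phase(C_post))
    })
    list(
      design = design,
      grid = volume_grid(dims, voxel_size = config$voxel_size_mm,
                         brain_mask = brain, graymatter_mask = gray),
      cluster_mask = cluster, cluster_center = ctr,
      brain_index = brain_idx, subjects = subjects
    )
  })
}

#' Write a simulated experiment to disk
#'
#' Writes the design and behavior TSVs plus a manifest JSON recording the
#' configuration and seed, so a run is reproducible from files alone.
#'
#' @param experiment Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param seed The seed the experiment was generated with (recorded in the
#'   manifest).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design_path <- file.path(dir, "design.tsv")
  behavior_path <- file.path(dir, "behavior.tsv")
  write_design_tsv(experiment$design, design_path)
  utils::write.table(experiment$behavior, behavior_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  manifest <- list(
    files = list(design = "design.tsv", behavior = "behavior.tsv"),
    n_rows = list(design = nrow(experiment$design),
                  behavior = nrow(experiment$behavior)),
    config = unclass(experiment$config)[
      !vapply(unclass(experiment$config), is.function, logical(1))],
    seed = seed
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}
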