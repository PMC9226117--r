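behavior_for_subject <- function(behavior, s, design) {
  b <- behavior[behavior$subject_id == s, ]
  b <- b[match(design$event_id, b$event_id), ]
  if (nrow(b) != nrow(design) || anyNA(b$event_id)) {
    stop("subject ", s, " does not have one response per event", call. = FALSE)
  }
  b
}

#' Timeline-construction regression
#'
#' Per participant, remembered event times are regressed on virtual time
#' with sequence position (order) and real time as control predictors (all
#' z-scored within participant). Each coefficient's t-value is compared to
#' a null distribution from shuffling the remembered times
#' ([permutation_z()]); the resulting virtual-time Z-values are tested
#' against zero with a group-level sign-flip test.
#'
#' @param behavior Behavior tibble (`subject_id`, `event_id`,
#'   `remembered_time`).
#' @param design A valid design table.
#' @param n_perm Subject-level permutations.
#' @param n_flips Group-level sign flips.
#' @param seed Integer seed.
#' @param group Run the group-level test (requires >= 2 subjects; set
#'   `FALSE` when only the per-subject fits are needed).
#' @return A list: `subject_results` (tibble of per-subject coefficients,
#'   t, and Z per time metric) and `group` (a `group_test` on the
#'   virtual-time Z-values, or `NULL`).
#' @export
timeline_regression <- function(behavior, design, n_perm = 10000L,
                                n_flips = 10000L, seed = 1L, group = TRUE) {
  design <- validate_design(design)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  X <- data.frame(
    virtual_time = zs(design$virtual_time),
    order = zs(design$position),
    real_time = zs(design$real_time)
  )
  subjects <- sort(unique(behavior$subject_id))
  subject_results <- purrr::map_dfr(seq_along(subjects), function(i) {
    b <- behavior_for_subject(behavior, subjects[i], design)
    if (length(unique(b$remembered_time)) < 4) {
      stop("subject ", subjects[i],
           ": fewer than 4 distinct responses (rank-deficient fit)",
           call. = FALSE)
    }
    fit <- permutation_z(b$remembered_time, X, n_perm = n_perm,
                         seed = seed + i)
    dplyr::mutate(fit[fit$term != "(Intercept)", ],
                  subject_id = subjects[i], .before = 1)
  })
  z_virtual <- subject_results$z[subject_results$term == "virtual_time"]
  group_res <- if (group && length(z_virtual) >= 2) {
    group_signflip_test(z_virtual, n_flips = n_flips, seed = seed)
  } else NULL
  list(subject_results = subject_results, group = group_res)
}

#' Timeline accuracy metrics
#'
#' Mean absolute construction error (virtual hours) per subject, overall
#' and split by sequence position, sequence, and hidden-clock speed, with
#' group means and standard deviations.
#'
#' @inheritParams timeline_regression
#' @return A list of tibbles: `by_subject`, `by_position`, `by_sequence`,
#'   `by_clock_speed`, `group`.
#' @export
accuracy_metrics <- function(behavior, design) {
  design <- validate_design(design)
  joined <- dplyr::inner_join(behavior, design, by = "event_id") |>
    dplyr::mutate(abs_error = abs(.data$remembered_time - .data$virtual_time))
  by_subject <- joined |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_abs_error = mean(.data$abs_error), .groups = "drop")
  by_position <- joined |>
    dplyr::group_by(.data$subject_id, .data$position) |>
    dplyr::summarise(mean_abs_error = mean(.data$abs_error), .groups = "drop")
  by_sequence <- joined |>
    dplyr::group_by(.data$subject_id, .data$sequence_id) |>
    dplyr::summarise(mean_abs_error = mean(.data$abs_error), .groups = "drop")
  by_speed <- if ("clock_speed" %in% names(design)) {
    joined |>
      dplyr::group_by(.data$subject_id, .data$clock_speed) |>
      dplyr::summarise(mean_abs_error = mean(.data$abs_error), .groups = "drop")
  } else NULL
  group <- tibble::tibble(
    mean = mean(by_subject$mean_abs_error),
    sd = stats::sd(by_subject$mean_abs_error)
  )
  list(by_subject = by_subject, by_position = by_position,
       by_sequence = by_sequence, by_clock_speed = by_speed, group = group)
}

#' Optimal assignment of sorted groups to sequences
#'
#' Participants sort events into four unlabeled groups; the groups are
#' mapped to sequences so that the number of correctly placed events is
#' maximal (exhaustive search over the 4! = 24 mappings, which is exact).
#'
#' @param sorted_groups Integer vector of group labels (1..4), one per
#'   event, in `design` event order; or a tibble with `event_id` and
#'   `sorted_group`.
#' @param design A valid design table.
#' @return A list: `percent_correct`, `n_correct`, `mapping` (sequence
#'   assigned to each group label), and `correct` (per-event flags, design
#'   order).
#' @export
assign_sorted_groups <- function(sorted_groups, design) {
  design <- validate_design(design)
  if (is.data.frame(sorted_groups)) {
    sorted_groups <-
      sorted_groups$sorted_group[match(design$event_id, sorted_groups$event_id)]
  }
  if (length(sorted_groups) != nrow(design) || anyNA(sorted_groups)) {
    stop("every event needs exactly one group label", call. = FALSE)
  }
  groups <- sort(unique(sorted_groups))
  if (length(groups) > 4 || !all(sorted_groups %in% 1:4)) {
    stop("group labels must be in 1..4", call. = FALSE)
  }
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) all(sort(r) == 1:4)), ]
  best <- NULL; best_n <- -1L
  for (k in seq_len(nrow(perms))) {
    mapped <- perms[k, ][sorted_groups]
    n_ok <- sum(mapped == design$sequence_id)
    if (n_ok > best_n) { best_n <- n_ok; best <- perms[k, ] }
  }
  mapped <- best[sorted_groups]
  list(
    percent_correct = 100 * best_n / nrow(design),
    n_correct = best_n,
    mapping = unname(best),
    assigned_sequence = unname(mapped),
    correct = unname(mapped == design$sequence_id)
  )
}

# Count swap errors in an optimally mapped sorting: events e1 (sequence i)
# and e2 (sequence j) at the same position are a swap when e1 was placed in
# j's group and e2 in i's (mutual interchange). Returns per-event flags.
detect_swap_errors <- function(assigned_sequence, design) {
  err <- assigned_sequence != design$sequence_id
  swap <- rep(FALSE, nrow(design))
  idx <- which(err)
  for (e1 in idx) {
    for (e2 in idx) {
      if (e2 <= e1) next
      if (design$position[e1] == design$position[e2] &&
          assigned_sequence[e1] == design$sequence_id[e2] &&
          assigned_sequence[e2] == design$sequence_id[e1]) {
        swap[e1] <- TRUE; swap[e2] <- TRUE
      }
    }
  }
  list(error = err, swap = swap)
}

score_sorting <- function(sorted_groups, design) {
  asg <- assign_sorted_groups(sorted_groups, design)
  sw <- detect_swap_errors(asg$assigned_sequence, design)
  list(n_errors = sum(sw$error), n_swaps = sum(sw$swap),
       swap_positions = design$position[sw$swap],
       percent_correct = asg$percent_correct)
}

#' Sorting accuracy per subject
#'
#' @inheritParams timeline_regression
#' @return A tibble: `subject_id`, `percent_correct`, `n_errors`,
#'   `n_swap_errors`.
#' @export
sorting_accuracy <- function(behavior, design) {
  design <- validate_design(design)
  subjects <- sort(unique(behavior$subject_id))
  purrr::map_dfr(subjects, function(s) {
    b <- behavior_for_subject(behavior, s, design)
    sc <- score_sorting(b$sorted_group, design)
    tibble::tibble(subject_id = s, percent_correct = sc$percent_correct,
                   n_errors = sc$n_errors, n_swap_errors = sc$n_swaps)
  })
}

#' Surrogate test for systematic swap errors
#'
#' A swap error interchanges events occupying the same sequence position
#' between two sequences. The observed proportion of sorting errors that
#' are swap errors (pooled over subjects) is compared to a surrogate
#' distribution: on each iteration, every subject's observed error count
#' is reproduced by moving that many randomly selected events to uniformly
#' chosen wrong groups, and the surrogate sample's swap proportion is
#' scored through the same optimal-assignment path. `p` is the proportion
#' of surrogate proportions at least as large as the observed one;
#' `z = (observed - null mean) / null sd`. A chi-squared test of swap
#' counts against uniformity over the five positions is attached.
#'
#' @inheritParams timeline_regression
#' @param n_iter Surrogate iterations (the study used 10,000).
#' @return A list: `observed_proportion`, `n_errors`, `n_swaps`, `z`, `p`,
#'   `undefined` (TRUE when there are no sorting errors), `null_mean`,
#'   `null_sd`, and `position_chisq`.
#' @export
swap_error_test <- function(behavior, design, n_iter = 10000L, seed = 1L) {
  design <- validate_design(design)
  subjects <- sort(unique(behavior$subject_id))
  scores <- lapply(subjects, function(s) {
    b <- behavior_for_subject(behavior, s, design)
    score_sorting(b$sorted_group, design)
  })
  n_errors <- sum(vapply(scores, `[[`, numeric(1), "n_errors"))
  n_swaps <- sum(vapply(scores, `[[`, numeric(1), "n_swaps"))
  swap_pos <- unlist(lapply(scores, `[[`, "swap_positions"))
  pos_counts <- vapply(1:5, function(p) sum(swap_pos == p), numeric(1))
  chisq <- chi_square_uniformity(pos_counts)
  if (n_errors == 0) {
    return(list(observed_proportion = NA_real_, n_errors = 0L, n_swaps = 0L,
                z = NA_real_, p = NA_real_, undefined = TRUE,
                null_mean = NA_real_, null_sd = NA_real_,
                position_chisq = chisq))
  }
  observed <- n_swaps / n_errors
  err_counts <- vapply(scores, `[[`, numeric(1), "n_errors")
  null_props <- with_seed_(seed, {
    vapply(seq_len(n_iter), function(it) {
      tot_err <- 0; tot_swap <- 0
      for (k in err_counts[err_counts > 0]) {
        sorted <- design$sequence_id
        evs <- sample.int(nrow(design), k)
        for (ev in evs) {
          wrong <- setdiff(1:4, sorted[ev])
          sorted[ev] <- wrong[sample.int(3L, 1)]
        }
        sc <- score_sorting(sorted, design)
        tot_err <- tot_err + sc$n_errors
        tot_swap <- tot_swap + sc$n_swaps
      }
      if (tot_err == 0) 0 else tot_swap / tot_err
    }, numeric(1))
  })
  list(
    observed_proportion = observed, n_errors = as.integer(n_errors),
    n_swaps = as.integer(n_swaps),
    z = (observed - mean(null_props)) / stats::sd(null_props),
    p = mean(null_props >= observed),
    undefined = FALSE,
    null_mean = mean(null_props), null_sd = stats::sd(null_props),
    position_chisq = chisq
  )
}

#' Generalization-bias regression
#'
#' Tests whether signed timeline errors are predicted by the relative time
#' of same-position events in the other sequences: per participant, signed
#' error is regressed on the deviation `d(e)`, the coefficient's
#' permutation Z is computed by shuffling the outcome, and the Z-values
#' enter a group sign-flip test. Raw per-subject slopes are returned for
#' brain-behavior correlations.
#'
#' @inheritParams timeline_regression
#' @param n_flips Group-level sign flips.
#' @param group Run the group-level test (requires >= 2 subjects).
#' @return A list: `subject_results` (slope, t, Z per subject) and `group`.
#' @export
generalization_bias <- function(behavior, design, n_perm = 10000L,
                                n_flips = 10000L, seed = 1L, group = TRUE) {
  pred <- generalization_predictor(design)
  if (stats::sd(pred$deviation) == 0) {
    stop("degenerate predictor: the four sequences share identical times",
         call. = FALSE)
  }
  subjects <- sort(unique(behavior$subject_id))
  subject_results <- purrr::map_dfr(seq_along(subjects), function(i) {
    b <- behavior_for_subject(behavior, subjects[i], pred)
    signed_error <- b$remembered_time - pred$virtual_time
    fit <- permutation_z(signed_error, data.frame(deviation = pred$deviation),
                         n_perm = n_perm, seed = seed + i)
    row <- fit[fit$term == "deviation", ]
    tibble::tibble(subject_id = subjects[i], slope = row$estimate,
                   t = row$t, z = row$z)
  })
  group_res <- if (group && nrow(subject_results) >= 2) {
    group_signflip_test(subject_results$z, n_flips = n_flips, seed = seed)
  } else NULL
  list(subject_results = subject_results, group = group_res)
}

#' Chi-squared test against uniformity over sequence positions
#'
#' @param counts Nonnegative counts, one per position.
#' @return A tibble with `chisq`, `df`, `p`, `undefined`.
#' @export
chi_square_uniformity <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  k <- length(counts)
  if (total == 0) {
    return(tibble::tibble(chisq = NA_real_, df = k - 1L, p = NA_real_,
                          undefined = TRUE))
  }
  e <- total / k
  chisq <- sum((counts - e)^2 / e)
  tibble::tibble(chisq = chisq, df = k - 1L,
                 p = stats::pchisq(chisq, k - 1, lower.tail = FALSE),
                 undefined = FALSE)
}

#' Spearman correlation between brain and behavior measures
#'
#' Rank correlation of per-subject behavioral bias slopes with per-subject
#' searchlight peak t-values. The caller applies alpha = 0.025 when two
#' such tests are run.
#'
#' @param bias_slopes,peak_tvalues Equal-length per-subject vectors
#'   (n >= 5).
#' @return A tibble with `rho`, `p`, `n`, `undefined`.
#' @export
brain_behavior_correlation <- function(bias_slopes, peak_tvalues) {
  stopifnot(length(bias_slopes) == length(peak_tvalues))
  n <- length(bias_slopes)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (stats::sd(bias_slopes) == 0 || stats::sd(peak_tvalues) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          undefined = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(bias_slopes, peak_tvalues, method = "spearman")
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = n,
                 undefined = FALSE)
}
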