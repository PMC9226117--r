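# Map user-facing metric names to pair-table columns.
metric_column <- function(metric) {
  cols <- c(virtual = "virtual_distance", order = "order_distance",
            real = "real_distance", first_last = "first_last")
  if (!metric %in% names(cols)) {
    stop("unknown predictor '", metric, "'; use one of ",
         paste(names(cols), collapse = ", "), call. = FALSE)
  }
  unname(cols[metric])
}

#' Specification of one region-of-interest model
#'
#' @param roi_id Label of the region the similarity changes come from.
#' @param subset `"same"`, `"different"`, or `"all"`: which event pairs
#'   enter the model.
#' @param predictors Time metrics in the model: any of `"virtual"`,
#'   `"order"`, `"real"`, `"first_last"`.
#' @param focal The predictor under test (must be in `predictors`).
#' @param n_perm Subject-level permutations.
#' @param n_flips Group-level sign flips.
#' @param seed Integer seed.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(roi_id, subset = c("same", "different", "all"),
                     predictors = "virtual", focal = predictors[1],
                     n_perm = 10000L, n_flips = 10000L, seed = 1L) {
  subset <- match.arg(subset)
  if (!focal %in% predictors) {
    stop("focal predictor must be among the model predictors", call. = FALSE)
  }
  if ("first_last" %in% predictors && subset != "same") {
    stop("the first/last control predictor requires the same-sequence subset",
         call. = FALSE)
  }
  vapply(predictors, metric_column, character(1))
  structure(list(roi_id = roi_id, subset = subset, predictors = predictors,
                 focal = focal, n_perm = as.integer(n_perm),
                 n_flips = as.integer(n_flips), seed = as.integer(seed)),
            class = "roi_spec")
}

# Design matrix (as data.frame, no intercept) for one subject/spec:
# time metrics z-scored within the analyzed subset; the binary first/last
# flag enters as 0/1.
spec_design_matrix <- function(pairs, spec) {
  zcols <- setdiff(spec$predictors, "first_last")
  sub <- zscore_predictors(pairs, vapply(zcols, metric_column, character(1)),
                           subset = spec$subset)
  X <- as.data.frame(lapply(spec$predictors, function(pr) {
    v <- sub[[metric_column(pr)]]
    if (pr == "first_last") as.numeric(v) else v
  }))
  names(X) <- spec$predictors
  list(rows = sub, X = X)
}

#' Run one ROI similarity-change model across subjects
#'
#' Per subject, pattern-similarity change is regressed on the spec's
#' predictors over the spec's pair subset with [permutation_z()]; the focal
#' Z-values are then tested against zero with a group sign-flip test.
#'
#' @param changes List of per-subject similarity-change matrices (from
#'   [similarity_change()]).
#' @param pairs Pair table for the shared design.
#' @param spec A [roi_spec()].
#' @return An object of class `roi_result`: `spec`, `subject_z` (tibble
#'   with one row per subject), `group` (a `group_test`).
#' @export
run_roi_model <- function(changes, pairs, spec) {
  subject_z <- roi_subject_z(changes, pairs, spec)
  group <- group_signflip_test(subject_z$z, n_flips = spec$n_flips,
                               seed = spec$seed)
  structure(list(spec = spec, subject_z = subject_z, group = group),
            class = "roi_result")
}

# Per-subject focal permutation Z-values for one spec (no group stage).
roi_subject_z <- function(changes, pairs, spec) {
  dm <- spec_design_matrix(pairs, spec)
  if (nrow(dm$rows) == 0) stop("empty pair subset", call. = FALSE)
  purrr::map_dfr(seq_along(changes), function(s) {
    y <- change_to_pairs(changes[[s]], dm$rows)$change
    fit <- permutation_z(y, dm$X, focal = spec$focal, n_perm = spec$n_perm,
                         seed = spec$seed + s)
    row <- fit[fit$term == spec$focal, ]
    tibble::tibble(subject_id = s, estimate = row$estimate, t = row$t,
                   z = row$z)
  })
}

#' @exportS3Method base::print
print.roi_result <- function(x, ...) {
  cat("ROI model: ", x$spec$roi_id, " | subset = ", x$spec$subset,
      " | focal = ", x$spec$focal, "\n", sep = "")
  print(x$group)
  invisible(x)
}

#' Residual virtual-time test
#'
#' Removes what order and real time explain, then asks whether the
#' leftovers still track virtual time: per subject, same-sequence
#' similarity change is regressed on order and real time, and the
#' residuals are regressed on virtual time with permutation-Z inference;
#' group-level sign-flip test on the residual-model Z-values.
#'
#' @inheritParams run_roi_model
#' @param n_perm,n_flips,seed Resampling controls.
#' @return A `roi_result`-like list with `subject_z` and `group`.
#' @export
residual_virtual_time_test <- function(changes, pairs, n_perm = 10000L,
                                       n_flips = 10000L, seed = 1L) {
  sub <- zscore_predictors(
    pairs, c("virtual_distance", "order_distance", "real_distance"),
    subset = "same"
  )
  X_nuis <- cbind(1, sub$order_distance, sub$real_distance)
  subject_z <- purrr::map_dfr(seq_along(changes), function(s) {
    y <- change_to_pairs(changes[[s]], sub)$change
    res <- stats::lsfit(X_nuis, y, intercept = FALSE)$residuals
    fit <- permutation_z(res, data.frame(virtual = sub$virtual_distance),
                         n_perm = n_perm, seed = seed + s)
    row <- fit[fit$term == "virtual", ]
    tibble::tibble(subject_id = s, estimate = row$estimate, t = row$t,
                   z = row$z)
  })
  group <- group_signflip_test(subject_z$z, n_flips = n_flips, seed = seed)
  structure(list(spec = list(roi_id = "residual", subset = "same",
                             focal = "virtual"),
                 subject_z = subject_z, group = group),
            class = "roi_result")
}

#' Long-format pair-level data for the mixed models
#'
#' Stacks all pairs of all subjects with virtual distance z-scored within
#' subject (over all pairs) and deviation-coded sequence membership
#' (+0.5 same / -0.5 different), the input format of
#' [fit_mixed_and_lrt()].
#'
#' @param changes List of per-subject similarity-change matrices.
#' @param pairs Pair table.
#' @param roi_id Region label attached to every row.
#' @return A tibble with columns `subject_id`, `roi_id`, `vd_z`, `od_z`,
#'   `rd_z`, `seq_dev`, `change`.
#' @export
mixed_model_data <- function(changes, pairs, roi_id = "roi") {
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  purrr::map_dfr(seq_along(changes), function(s) {
    tibble::tibble(
      subject_id = factor(s),
      roi_id = roi_id,
      vd_z = zs(pairs$virtual_distance),
      od_z = zs(pairs$order_distance),
      rd_z = zs(pairs$real_distance),
      seq_dev = ifelse(pairs$same_sequence, 0.5, -0.5),
      change = change_to_pairs(changes[[s]], pairs)$change
    )
  })
}

#' Interaction of sequence membership with virtual time
#'
#' Summary-statistics path: the per-subject focal Z for virtual time is
#' computed separately for same- and different-sequence pairs and the two
#' are compared with a paired sign-flip test. Mixed-model path: pair-level
#' similarity change is modeled with the virtual-time by
#' sequence-membership interaction as the focal fixed effect (deviation
#' coding), tested with a likelihood ratio test; interactions of
#' membership with order and real time can be added as controls.
#'
#' @inheritParams run_roi_model
#' @param n_perm,n_flips,seed Resampling controls.
#' @param mixed Fit the mixed-model path too (slower).
#' @param time_controls Include membership-by-order and membership-by-real
#'   interactions in the mixed model.
#' @return A list: `same`, `different` (both `roi_result`), `paired`
#'   (paired `group_test`), and `mixed` (a `mixed_lrt` or `NULL`).
#' @export
sequence_interaction_test <- function(changes, pairs, n_perm = 10000L,
                                      n_flips = 10000L, seed = 1L,
                                      mixed = TRUE, time_controls = FALSE) {
  res_same <- run_roi_model(changes, pairs,
    roi_spec("roi", "same", "virtual", n_perm = n_perm, n_flips = n_flips,
             seed = seed))
  res_diff <- run_roi_model(changes, pairs,
    roi_spec("roi", "different", "virtual", n_perm = n_perm,
             n_flips = n_flips, seed = seed + 1000L))
  paired <- group_signflip_test(res_same$subject_z$z, n_flips = n_flips,
                                seed = seed, paired_with = res_diff$subject_z$z)
  mixed_fit <- NULL
  if (mixed) {
    dat <- mixed_model_data(changes, pairs)
    fixed <- c("vd_z", "seq_dev", "vd_z:seq_dev")
    if (time_controls) {
      dat$od_seq <- dat$od_z * dat$seq_dev
      dat$rd_seq <- dat$rd_z * dat$seq_dev
      fixed <- c(fixed, "od_z", "rd_z", "od_seq", "rd_seq")
    }
    mixed_fit <- fit_mixed_and_lrt(dat, "change", fixed,
                                   focal = "vd_z:seq_dev")
  }
  list(same = res_same, different = res_diff, paired = paired,
       mixed = mixed_fit)
}

#' Region-by-membership contrast between two ROIs
#'
#' Summary path: per subject and region, the virtual-time Z for same- and
#' different-sequence pairs enters a 2 x 2 permutation repeated-measures
#' ANOVA (region x sequence membership). Mixed path: the three-way
#' interaction of virtual time, membership, and region (deviation coded)
#' is the focal fixed effect of a likelihood ratio test.
#'
#' @param changes_by_roi Named list of two elements, each a list of
#'   per-subject similarity-change matrices (same subjects, same order).
#' @param pairs Pair table.
#' @param n_perm,n_flips,seed Resampling controls.
#' @param mixed Fit the mixed-model path too.
#' @return A list: `anova` (tibble from [permutation_rm_anova()], factor a
#'   = region, factor b = membership), `cell_z`, and `mixed`.
#' @export
region_contrast <- function(changes_by_roi, pairs, n_perm = 10000L,
                            n_flips = 10000L, seed = 1L, mixed = TRUE) {
  if (length(changes_by_roi) != 2 || is.null(names(changes_by_roi))) {
    stop("changes_by_roi must be a named list of two regions", call. = FALSE)
  }
  ns <- vapply(changes_by_roi, length, integer(1))
  if (ns[1] != ns[2]) stop("subject mismatch between ROIs", call. = FALSE)
  cell_z <- purrr::map_dfr(names(changes_by_roi), function(roi) {
    purrr::map_dfr(c(same = "same", different = "different"), function(ss) {
      sz <- roi_subject_z(changes_by_roi[[roi]], pairs,
        roi_spec(roi, ss, "virtual", n_perm = n_perm, n_flips = n_flips,
                 seed = seed))
      dplyr::mutate(sz, factor_a = roi, factor_b = ss)
    })
  })
  anova_data <- dplyr::select(cell_z, "subject_id", "factor_a", "factor_b",
                              value = "z")
  aov_res <- permutation_rm_anova(anova_data, n_perm = n_flips, seed = seed)
  mixed_fit <- NULL
  if (mixed) {
    dat <- dplyr::bind_rows(lapply(names(changes_by_roi), function(roi) {
      mixed_model_data(changes_by_roi[[roi]], pairs, roi_id = roi)
    }))
    rois <- sort(unique(dat$roi_id))
    dat$roi_dev <- ifelse(dat$roi_id == rois[1], 0.5, -0.5)
    dat$vd_seq <- dat$vd_z * dat$seq_dev
    dat$vd_roi <- dat$vd_z * dat$roi_dev
    dat$seq_roi <- dat$seq_dev * dat$roi_dev
    dat$vd_seq_roi <- dat$vd_z * dat$seq_dev * dat$roi_dev
    fixed <- c("vd_z", "seq_dev", "roi_dev", "vd_seq", "vd_roi", "seq_roi",
               "vd_seq_roi")
    mixed_fit <- fit_mixed_and_lrt(dat, "change", fixed, focal = "vd_seq_roi")
  }
  list(anova = aov_res, cell_z = cell_z, mixed = mixed_fit)
}
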