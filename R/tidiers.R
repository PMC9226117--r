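#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group sign-flip test
#'
#' @param x A `group_test`.
#' @param ... Unused.
#' @return One-row tibble: statistic, p, effect size with CI, resampling
#'   metadata.
#' @export
tidy.group_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$n - 1L, p.value = x$p,
    d = x$effect$d, ci_lower = x$effect$ci_lower,
    ci_upper = x$effect$ci_upper,
    n = x$n, n_resamples = x$n_resamples, tail = x$tail
  )
}

#' @rdname tidy.group_test
#' @export
glance.group_test <- function(x, ...) tidy.group_test(x)

#' Tidy an ROI model result
#'
#' @param x A `roi_result`.
#' @param ... Unused.
#' @return Per-subject rows with estimate, t, and permutation Z.
#' @export
tidy.roi_result <- function(x, ...) {
  dplyr::mutate(x$subject_z, roi_id = x$spec$roi_id,
                subset = x$spec$subset, focal = x$spec$focal)
}

#' @rdname tidy.roi_result
#' @export
glance.roi_result <- function(x, ...) {
  dplyr::mutate(tidy.group_test(x$group), roi_id = x$spec$roi_id,
                subset = x$spec$subset, focal = x$spec$focal, .before = 1)
}

#' Tidy a mixed-model likelihood ratio test
#'
#' @param x A `mixed_lrt`.
#' @param ... Unused.
#' @return Fixed-effect estimates of the full model.
#' @export
tidy.mixed_lrt <- function(x, ...) {
  fe <- lme4::fixef(x$full)
  tibble::tibble(term = names(fe), estimate = unname(fe))
}

#' @rdname tidy.mixed_lrt
#' @export
glance.mixed_lrt <- function(x, ...) {
  tibble::tibble(
    focal = x$focal, chisq = x$chisq, df = x$df, p.value = x$p,
    logLik_full = as.numeric(stats::logLik(x$full)),
    logLik_reduced = as.numeric(stats::logLik(x$reduced)),
    ladder_rung = x$ladder_rung, singular = x$singular
  )
}

#' Tidy an MDS embedding
#'
#' @param x An `embedding`.
#' @param ... Unused.
#' @return One row per embedded point with its coordinates.
#' @export
tidy.embedding <- function(x, ...) {
  cfg <- x$config
  out <- tibble::as_tibble(as.data.frame(cfg), .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(ncol(cfg)))
  dplyr::mutate(out, point = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.embedding
#' @export
glance.embedding <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_starts = x$n_starts,
                 best_start = x$best_start,
                 n_iterations = length(x$history))
}
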