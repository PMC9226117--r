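#' Subject-level permutation test of regression coefficients
#'
#' Fits an ordinary least-squares model of `y` on the predictors (with
#' intercept), then builds a null distribution for each focal coefficient's
#' t-value by refitting after randomly permuting the outcome. One shared
#' permutation per iteration is used for all coefficients, matching a
#' shuffle of the dependent variable. The right-tail p-value
#' `p_r = (1 + #\{t_null >= t_obs\}) / (1 + n_perm)` is converted to a
#' sign-preserving Z-score `Z = qnorm(1 - p_r)`: strong positive effects
#' give large positive Z, strong negative effects large negative Z. The
#' add-one rule bounds `|Z|` at the value attainable with `n_perm`
#' resamples and avoids p = 0.
#'
#' @param y Outcome vector.
#' @param X Predictor data frame or matrix (no intercept column; one is
#'   added).
#' @param focal Names (or indices) of predictors to permutation-test;
#'   defaults to all.
#' @param n_perm Number of permutations (the study used 10,000).
#' @param seed Integer seed.
#' @return A tibble of class `perm_fit`: one row per predictor with
#'   `estimate`, `t`, and for focal predictors `p_perm` and `z`.
#' @export
permutation_z <- function(y, X, focal = NULL, n_perm = 10000L, seed = 1L) {
  X <- as.data.frame(X)
  if (length(y) != nrow(X)) stop("y and X have different lengths", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("degenerate outcome: y is constant under every permutation",
         call. = FALSE)
  }
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- nrow(Xm); p <- ncol(Xm)
  if (qr(Xm)$rank < p) stop("rank-deficient predictor matrix", call. = FALSE)
  if (is.null(focal)) focal <- colnames(X)
  if (is.numeric(focal)) focal <- colnames(X)[focal]
  low_perm_warning <- n_perm < 100

  XtXi <- solve(crossprod(Xm))
  A <- XtXi %*% t(Xm)
  invdiag <- diag(XtXi)
  tval <- function(Y) {
    # Y: n x k matrix of outcomes; returns p x k coefficient and t arrays
    coefs <- A %*% Y
    rss <- pmax(colSums(Y^2) - colSums(coefs * (t(Xm) %*% Y)), 0)
    s2 <- rss / (n - p)
    # a saturated fit (rss = 0) gives t = +/- Inf, handled by the
    # surrogate cap downstream
    list(coefs = coefs, t = coefs / sqrt(outer(invdiag, s2)))
  }
  obs <- tval(matrix(y, ncol = 1))
  t_obs <- drop(obs$t)
  names(t_obs) <- colnames(Xm)

  fidx <- match(focal, colnames(Xm))
  if (anyNA(fidx)) stop("unknown focal predictor(s)", call. = FALSE)
  p_perm <- z <- rep(NA_real_, p)
  p_perm[fidx] <- with_seed_(seed, {
    # permute in batches to bound memory at large n_perm
    batch <- 2000L
    counts <- rep(0L, length(fidx))
    done <- 0L
    while (done < n_perm) {
      k <- min(batch, n_perm - done)
      Yp <- vapply(seq_len(k), function(.) y[sample.int(n)], numeric(n))
      t_null <- tval(Yp)$t
      for (ii in seq_along(fidx)) {
        counts[ii] <- counts[ii] + sum(t_null[fidx[ii], ] >= t_obs[fidx[ii]])
      }
      done <- done + k
    }
    (1 + counts) / (1 + n_perm)
  })
  # the add-one rule bounds Z from above; clip the other tail to the same
  # attainable bound so strong negative effects give a finite negative Z
  z[fidx] <- stats::qnorm(1 - pmin(p_perm[fidx], n_perm / (1 + n_perm)))

  out <- tibble::tibble(
    term = colnames(Xm),
    estimate = drop(obs$coefs),
    t = t_obs,
    p_perm = p_perm,
    z = z
  )
  structure(out, class = c("perm_fit", class(out)),
            n_perm = n_perm, seed = seed,
            low_perm_warning = low_perm_warning)
}

#' Hedges-corrected Cohen's d with noncentral-t confidence interval
#'
#' One-sample: `d = mean(values) / sd(values)` times the small-sample
#' correction `J(df) = 1 - 3 / (4 df - 1)`, `df = n - 1`. Paired (with
#' `paired_with`): the test statistic is based on the differences, but d is
#' computed with the pooled standard deviation of the two conditions. The
#' confidence interval inverts the noncentral t distribution of the
#' one-sample t statistic and is rescaled to the d metric.
#'
#' @param values Numeric vector (or first condition if paired).
#' @param paired_with Optional second condition of equal length.
#' @param conf Confidence level.
#' @return A tibble with `d`, `ci_lower`, `ci_upper`, `df`, `correction`.
#' @export
cohens_d_hedges <- function(values, paired_with = NULL, conf = 0.95) {
  if (!is.null(paired_with)) {
    stopifnot(length(values) == length(paired_with))
    diffs <- values - paired_with
    n <- length(diffs)
    sd_pooled <- sqrt(((n - 1) * stats::var(values) +
                       (n - 1) * stats::var(paired_with)) / (2 * n - 2))
    df <- 2 * (n - 1)
    sd_test <- stats::sd(diffs)
    mean_eff <- mean(diffs)
  } else {
    diffs <- values
    n <- length(diffs)
    sd_pooled <- stats::sd(diffs)
    df <- n - 1
    sd_test <- sd_pooled
    mean_eff <- mean(diffs)
  }
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  J <- 1 - 3 / (4 * df - 1)
  if (sd_pooled == 0 || sd_test == 0) {
    return(tibble::tibble(d = sign(mean_eff) * Inf, ci_lower = NA_real_,
                          ci_upper = NA_real_, df = df, correction = J))
  }
  d <- J * mean_eff / sd_pooled
  t_obs <- mean_eff / (sd_test / sqrt(n))
  alpha <- 1 - conf
  # invert the noncentral t CDF for the noncentrality parameter
  ncp_bound <- function(target) {
    f <- function(ncp) {
      suppressWarnings(stats::pt(t_obs, df = n - 1, ncp = ncp)) - target
    }
    lo <- t_obs - 10 - 4 * abs(t_obs)
    hi <- t_obs + 10 + 4 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), extendInt = "yes")$root
  }
  ncp_lo <- ncp_bound(1 - alpha / 2)
  ncp_hi <- ncp_bound(alpha / 2)
  # map ncp (difference metric) back to the reported d metric
  scale <- (sd_test / sqrt(n)) / sd_pooled * J
  tibble::tibble(d = d, ci_lower = ncp_lo * scale, ci_upper = ncp_hi * scale,
                 df = df, correction = J)
}

#' Group-level sign-flip permutation test
#'
#' One-sample t-test of per-subject statistics against zero (or of paired
#' differences), with the null distribution built by randomly negating each
#' subject's value. Two-sided
#' `p = (1 + #\{|t_flip| >= |t_obs|\}) / (1 + n_flips)`. Cohen's d with
#' Hedges correction is attached (pooled-SD variant for paired contrasts).
#'
#' @param values Per-subject statistics (e.g. permutation Z-values).
#' @param n_flips Number of random sign flips (the study used 10,000).
#' @param seed Integer seed.
#' @param paired_with Optional second vector; differences are tested.
#' @param exhaustive Enumerate all `2^n` sign patterns instead of random
#'   flips (exact test; only for n <= 20). The plain proportion of flips
#'   with `|t| >= |t_obs|` is then the p-value (the identity flip makes it
#'   positive).
#' @return An object of class `group_test` with fields `statistic` (t),
#'   `p`, `n`, `n_resamples`, `effect` (d and CI), `tail`, `seed`.
#' @export
group_signflip_test <- function(values, n_flips = 10000L, seed = 1L,
                                paired_with = NULL, exhaustive = FALSE) {
  x <- if (is.null(paired_with)) values else values - paired_with
  n <- length(x)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (all(x == 0)) {
    # every flip reproduces the observed statistic
    return(structure(
      list(statistic = 0, p = 1, n = n, n_resamples = n_flips,
           effect = tibble::tibble(d = 0, ci_lower = NA_real_,
                                   ci_upper = NA_real_, df = n - 1,
                                   correction = 1 - 3 / (4 * (n - 1) - 1)),
           tail = "two-sided", seed = seed, paired = !is.null(paired_with)),
      class = "group_test"
    ))
  }
  if (stats::sd(x) == 0) {
    # all subjects at the same nonzero value (e.g. every permutation Z
    # saturated at the cap): t is infinite and only the all-same-sign flip
    # patterns are as extreme, so the test degrades to a sign test
    warning("zero variance across subjects: sign-flip test degrades to a ",
            "sign test on saturated values")
  }
  t_obs <- if (stats::sd(x) == 0) sign(mean(x)) * Inf else {
    mean(x) / (stats::sd(x) / sqrt(n))
  }
  ssq <- sum(x^2)
  flip_t <- function(signs) {
    m <- colMeans(signs * x)
    sd_flip <- sqrt(pmax(ssq - n * m^2, 0) / (n - 1))
    m / (sd_flip / sqrt(n))
  }
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_flip <- flip_t(t(signs))
    p <- mean(abs(t_flip) >= abs(t_obs) - 1e-12)
    n_flips <- nrow(signs)
  } else {
    p <- with_seed_(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_flips, replace = TRUE), n, n_flips)
      t_flip <- flip_t(signs)
      # tie slack: sign patterns reproducing |t_obs| must count as at least
      # as extreme despite round-off in the streaming sd formula
      (1 + sum(abs(t_flip) >= abs(t_obs) - 1e-12)) / (1 + n_flips)
    })
  }
  effect <- if (is.null(paired_with)) cohens_d_hedges(values)
            else cohens_d_hedges(values, paired_with)
  structure(
    list(statistic = t_obs, p = p, n = n, n_resamples = n_flips,
         effect = effect, tail = "two-sided", seed = seed,
         paired = !is.null(paired_with)),
    class = "group_test"
  )
}

#' @exportS3Method base::print
print.group_test <- function(x, ...) {
  cat("Group sign-flip test (", x$tail, ")\n", sep = "")
  cat(sprintf("  t(%d) = %.3f, p = %.4g  [%d sign-flips]\n",
              x$n - 1, x$statistic, x$p, x$n_resamples))
  cat(sprintf("  Hedges-corrected d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$effect$d, x$effect$ci_lower, x$effect$ci_upper))
  invisible(x)
}

#' Permutation-based 2 x 2 repeated-measures ANOVA
#'
#' Classical repeated-measures F-statistics for the two main effects and
#' the interaction of a complete, balanced 2 x 2 within-subject design,
#' with permutation p-values obtained by exchanging the factor levels
#' within subjects (equivalently, sign-flipping each subject's effect
#' contrast, the exchangeable unit for two-level within factors).
#' Generalized eta squared is attached as effect size.
#'
#' @param data Long tibble with columns `subject_id`, `factor_a`,
#'   `factor_b` (each two levels), `value`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble: one row per effect (`a`, `b`, `a:b`) with `F`, `df1`,
#'   `df2`, `p_perm`, `ges`.
#' @export
permutation_rm_anova <- function(data, n_perm = 10000L, seed = 1L) {
  need <- c("subject_id", "factor_a", "factor_b", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  wide <- data |>
    dplyr::mutate(cell = paste0(.data$factor_a, ".", .data$factor_b)) |>
    dplyr::select("subject_id", "cell", "value") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  cells <- sort(setdiff(names(wide), "subject_id"))
  if (length(cells) != 4 || anyNA(wide)) {
    stop("design must be complete and balanced 2 x 2 within subjects",
         call. = FALSE)
  }
  a_lev <- sort(unique(data$factor_a)); b_lev <- sort(unique(data$factor_b))
  cell <- function(a, b) wide[[paste0(a, ".", b)]]
  y11 <- cell(a_lev[1], b_lev[1]); y12 <- cell(a_lev[1], b_lev[2])
  y21 <- cell(a_lev[2], b_lev[1]); y22 <- cell(a_lev[2], b_lev[2])
  n <- nrow(wide)

  # per-subject effect contrasts (halved so SS bookkeeping matches the
  # classical decomposition)
  cA <- (y11 + y12 - y21 - y22) / 2
  cB <- (y11 - y12 + y21 - y22) / 2
  cAB <- (y11 - y12 - y21 + y22) / 2
  subj_mean <- (y11 + y12 + y21 + y22) / 4
  grand <- mean(subj_mean)

  ss_effect <- function(cvec) n * mean(cvec)^2
  ss_error <- function(cvec) sum((cvec - mean(cvec))^2)
  SS <- list(a = ss_effect(cA), b = ss_effect(cB), `a:b` = ss_effect(cAB))
  SSE <- list(a = ss_error(cA), b = ss_error(cB), `a:b` = ss_error(cAB))
  SS_subj <- 4 * sum((subj_mean - grand)^2)
  Fstat <- vapply(names(SS), function(k) {
    if (SS[[k]] == 0) return(0)  # degenerate all-equal cells
    (SS[[k]] / 1) / (SSE[[k]] / (n - 1))
  }, numeric(1))
  denom_all <- SS_subj + SSE$a + SSE$b + SSE$`a:b`
  ges <- vapply(names(SS), function(k) SS[[k]] / (SS[[k]] + denom_all),
                numeric(1))

  p_perm <- with_seed_(seed, {
    vapply(list(cA, cB, cAB), function(cvec) {
      F_obs <- if (sum(cvec^2) == 0) 0 else {
        ss_effect(cvec) / (ss_error(cvec) / (n - 1))
      }
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
      m <- colMeans(signs * cvec)
      sse <- sum(cvec^2) - n * m^2
      F_null <- (n * m^2) / (sse / (n - 1))
      F_null[!is.finite(F_null)] <- 0
      (1 + sum(F_null >= F_obs)) / (1 + n_perm)
    }, numeric(1))
  })

  tibble::tibble(
    effect = c("a", "b", "a:b"),
    F = unname(Fstat), df1 = 1L, df2 = n - 1L,
    p_perm = p_perm, ges = unname(ges)
  )
}

#' Mixed-model likelihood ratio test with a random-effects ladder
#'
#' Fits a linear mixed model (maximum likelihood) and compares it to a
#' nested reduced model without the focal fixed effect but with the same
#' random-effects structure; reports the chi-squared likelihood-ratio
#' statistic with one degree of freedom. If the maximal model does not
#' converge or is singular, the random-effects structure is simplified
#' along a documented ladder: (1) all slopes with correlations, (2) all
#' slopes without correlations, (3) only the focal slope without
#' correlations. The random slope for the focal effect is never dropped.
#'
#' @param data Long-format data frame.
#' @param response Name of the outcome column.
#' @param fixed Character vector of fixed-effect terms (may include
#'   interactions as `"x:z"`).
#' @param focal The fixed-effect term under test; must be in `fixed`.
#' @param group Name of the grouping (subject) column.
#' @param allow_singular Accept a singular fit at the last ladder rung
#'   instead of erroring (the fit is flagged).
#' @return An object of class `mixed_lrt`: full and reduced fits, `chisq`,
#'   `df`, `p`, the formulas, and convergence flags.
#' @export
fit_mixed_and_lrt <- function(data, response, fixed, focal,
                              group = "subject_id", allow_singular = TRUE) {
  if (!focal %in% fixed) stop("focal term must be one of the fixed terms",
                              call. = FALSE)
  fixed_part <- paste(fixed, collapse = " + ")
  reduced_part <- paste(setdiff(fixed, focal), collapse = " + ")
  if (reduced_part == "") reduced_part <- "1"
  ladder <- list(
    list(terms = fixed, corr = TRUE),
    list(terms = fixed, corr = FALSE),
    list(terms = focal, corr = FALSE)
  )
  make_formula <- function(fe, re_terms, corr) {
    bar <- if (corr) "|" else "||"
    re <- paste0("(1 + ", paste(re_terms, collapse = " + "), " ", bar, " ",
                 group, ")")
    stats::as.formula(paste(response, "~", fe, "+", re))
  }
  fit_ok <- function(fit) {
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    converged <- length(msgs) == 0
    singular <- lme4::isSingular(fit, tol = 1e-4)
    list(fit = fit, converged = converged, singular = singular)
  }
  chosen <- NULL
  for (i in seq_along(ladder)) {
    rung <- ladder[[i]]
    full_f <- make_formula(fixed_part, rung$terms, rung$corr)
    res <- tryCatch(
      fit_ok(lme4::lmer(full_f, data = data, REML = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$converged && !res$singular) {
      chosen <- c(res, list(rung = i, formula = full_f)); break
    }
    if (!is.null(res) && i == length(ladder) && allow_singular) {
      chosen <- c(res, list(rung = i, formula = full_f))
    }
  }
  if (is.null(chosen)) {
    stop("mixed model did not converge on any rung of the random-effects ladder",
         call. = FALSE)
  }
  rung <- ladder[[chosen$rung]]
  reduced_f <- make_formula(reduced_part, rung$terms, rung$corr)
  reduced <- lme4::lmer(reduced_f, data = data, REML = FALSE)
  ll_full <- as.numeric(stats::logLik(chosen$fit))
  ll_red <- as.numeric(stats::logLik(reduced))
  chisq <- max(0, 2 * (ll_full - ll_red))
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(
    list(full = chosen$fit, reduced = reduced, chisq = chisq, df = 1L, p = p,
         formula_full = deparse(chosen$formula),
         formula_reduced = deparse(reduced_f),
         focal = focal, ladder_rung = chosen$rung,
         converged = chosen$converged, singular = chosen$singular),
    class = "mixed_lrt"
  )
}

#' @exportS3Method base::print
print.mixed_lrt <- function(x, ...) {
  cat("Mixed-model likelihood ratio test for '", x$focal, "'\n", sep = "")
  cat("  full:    ", x$formula_full, "\n")
  cat("  reduced: ", x$formula_reduced, "\n")
  cat(sprintf("  chisq(%d) = %.3f, p = %.4g  [ladder rung %d%s]\n",
              x$df, x$chisq, x$p, x$ladder_rung,
              if (x$singular) ", singular fit" else ""))
  invisible(x)
}
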