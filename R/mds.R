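#' Model-derived representational distances
#'
#' Converts fixed-effect predictions of a fitted similarity-change mixed
#' model into a pairwise distance matrix: each pair's predicted similarity
#' (fixed effects only, no random effects) is subtracted from the maximum
#' predicted similarity, so the most similar pair has distance zero and
#' the ordering of similarities is reversed.
#'
#' @param fitted A `mixed_lrt` from [fit_mixed_and_lrt()] (the full model
#'   is used), or any object accepted by `stats::predict` with
#'   `re.form = NA`.
#' @param pairs Pair table; must carry the model's predictor columns (or
#'   they are derived: `vd_z`, `seq_dev` from the pair table).
#' @param n_events Number of events (matrix dimension).
#' @return A symmetric `n_events x n_events` distance matrix with zero
#'   diagonal.
#' @export
model_predicted_distances <- function(fitted, pairs, n_events = 20L) {
  model <- if (inherits(fitted, "mixed_lrt")) fitted$full else fitted
  newdata <- pairs
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  if (!"vd_z" %in% names(newdata)) {
    newdata$vd_z <- zs(pairs$virtual_distance)
  }
  if (!"seq_dev" %in% names(newdata)) {
    newdata$seq_dev <- ifelse(pairs$same_sequence, 0.5, -0.5)
  }
  if (!"vd_seq" %in% names(newdata)) {
    newdata$vd_seq <- newdata$vd_z * newdata$seq_dev
  }
  grp <- names(lme4::ranef(model))[1]
  newdata[[grp]] <- factor(rep(NA, nrow(newdata)))
  sim <- stats::predict(model, newdata = newdata, re.form = NA,
                        allow.new.levels = TRUE)
  if (any(!is.finite(sim))) stop("non-finite model predictions", call. = FALSE)
  d <- max(sim) - sim
  out <- matrix(0, n_events, n_events)
  out[cbind(pairs$event_i, pairs$event_j)] <- d
  out[cbind(pairs$event_j, pairs$event_i)] <- d
  out
}

lower_vec <- function(m) m[lower.tri(m)]

# One SMACOF majorization run of non-metric MDS from a given start.
# Alternates monotone (isotonic) disparity regression with the Guttman
# transform until the stress-1 decrease falls below tol.
nmds_single <- function(delta_vec, ord, n, ndim, X, max_iter, tol) {
  stress1 <- function(dhat, d) sqrt(sum((dhat - d)^2) / sum(d^2))
  d_emb <- function(X) lower_vec(as.matrix(stats::dist(X)))
  d <- d_emb(X)
  history <- numeric(0)
  s_prev <- Inf
  for (it in seq_len(max_iter)) {
    # monotone regression of embedded distances on the input-distance order
    iso <- stats::isoreg(d[ord])
    dhat <- numeric(length(d))
    dhat[ord] <- iso$yf
    s <- stress1(dhat, d)
    history <- c(history, s)
    if (is.finite(s_prev) && (s_prev - s) < tol) break
    s_prev <- s
    # Guttman transform
    ratio <- ifelse(d > 0, dhat / d, 0)
    B <- matrix(0, n, n)
    B[lower.tri(B)] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    d <- d_emb(X)
  }
  # final stress with a fresh isotonic fit on the final configuration
  iso <- stats::isoreg(d[ord])
  dhat <- numeric(length(d))
  dhat[ord] <- iso$yf
  list(X = X, stress = stress1(dhat, d), history = history)
}

#' Non-metric multidimensional scaling with random multi-start
#'
#' Majorization (SMACOF) non-metric MDS with monotone disparity
#' regression. Because the solution depends on the starting
#' configuration, the scaling is run from many random starts and the
#' configuration with the lowest stress-1 is returned.
#'
#' @param distances Symmetric nonnegative distance matrix with zero
#'   diagonal.
#' @param ndim Embedding dimensionality (the study used 2 for
#'   visualization).
#' @param n_starts Number of starts (the study used 1000).
#' @param seed Integer seed.
#' @param max_iter,tol Per-start iteration cap and stress-decrease
#'   threshold.
#' @param classical_start Use the classical-scaling (Torgerson) solution
#'   as the first start, with the remaining starts random — the common
#'   default of majorization implementations. It protects exactly
#'   embeddable inputs from tie-degenerate solutions in which distinct
#'   input distances collapse onto one disparity plateau.
#' @return An object of class `embedding`: `config` (centered
#'   `n x ndim` coordinates), `stress` (stress-1), `n_starts`,
#'   `best_start`, `history` (stress per iteration of the best start).
#' @export
nonmetric_mds <- function(distances, ndim = 2L, n_starts = 1000L, seed = 1L,
                          max_iter = 300L, tol = 1e-6,
                          classical_start = TRUE) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (!isTRUE(all.equal(distances, t(distances))) || any(distances < 0) ||
      any(diag(distances) != 0)) {
    stop("distances must be a symmetric nonnegative matrix with zero diagonal",
         call. = FALSE)
  }
  delta <- lower_vec(distances)
  if (all(delta == 0)) {
    return(structure(list(config = matrix(0, n, ndim), stress = NA_real_,
                          n_starts = n_starts, best_start = NA_integer_,
                          history = numeric(0), degenerate = TRUE),
                     class = "embedding"))
  }
  ord <- order(delta)
  best <- NULL
  with_seed_(seed, {
    for (st in seq_len(n_starts)) {
      X0 <- if (st == 1 && classical_start) {
        cmd <- suppressWarnings(stats::cmdscale(distances, k = ndim))
        if (ncol(cmd) < ndim) cbind(cmd, matrix(0, n, ndim - ncol(cmd)))
        else cmd
      } else {
        matrix(stats::rnorm(n * ndim), n, ndim)
      }
      res <- nmds_single(delta, ord, n, ndim, X0, max_iter, tol)
      if (is.null(best) || res$stress < best$stress) {
        best <- res
        best$start <- st
      }
    }
  })
  config <- scale(best$X, center = TRUE, scale = FALSE)
  structure(list(config = config, stress = best$stress,
                 n_starts = n_starts, best_start = best$start,
                 history = best$history, degenerate = FALSE),
            class = "embedding")
}

#' @exportS3Method base::print
print.embedding <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate embedding (all-zero distances)\n")
    return(invisible(x))
  }
  cat(sprintf("Non-metric MDS embedding: %d points, %d dims, stress-1 = %.4f (best of %d starts)\n",
              nrow(x$config), ncol(x$config), x$stress, x$n_starts))
  invisible(x)
}

#' Permutation test of embedding stress
#'
#' Builds a surrogate stress distribution by permuting the off-diagonal
#' input distances (as a set, preserving symmetry) and re-embedding each
#' permuted matrix. `z = (observed - null mean) / null sd`; `p` is the
#' proportion of surrogate stress values at or below the observed stress.
#'
#' @param distances Symmetric distance matrix.
#' @param n_iter Permutation iterations (the study used 1000).
#' @param seed Integer seed.
#' @param n_starts_null Random starts per null embedding (reduced relative
#'   to the observed embedding for tractability).
#' @param observed Optional precomputed `embedding` for the observed
#'   matrix; otherwise one is computed with `n_starts_observed` starts.
#' @param n_starts_observed Starts for the observed embedding.
#' @param ndim Embedding dimensionality.
#' @return A list: `z`, `p`, `observed_stress`, `null_mean`, `null_sd`,
#'   `null_stress`, `degenerate`.
#' @export
stress_permutation_test <- function(distances, n_iter = 1000L, seed = 1L,
                                    n_starts_null = 10L, observed = NULL,
                                    n_starts_observed = 100L, ndim = 2L) {
  if (n_iter < 100) warning("n_iter < 100: the surrogate distribution is coarse")
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (stats::sd(lower_vec(distances)) == 0) {
    # permuting a constant matrix is the identity: the null has no variance
    return(list(z = NA_real_, p = NA_real_, observed_stress = NA_real_,
                null_mean = NA_real_, null_sd = 0,
                null_stress = numeric(0), degenerate = TRUE))
  }
  if (is.null(observed)) {
    observed <- nonmetric_mds(distances, ndim = ndim,
                              n_starts = n_starts_observed, seed = seed)
  }
  null_stress <- with_seed_(seed + 1L, {
    vapply(seq_len(n_iter), function(it) {
      v <- sample(lower_vec(distances))
      m <- matrix(0, n, n)
      m[lower.tri(m)] <- v
      m <- m + t(m)
      nonmetric_mds(m, ndim = ndim, n_starts = n_starts_null,
                    seed = sample.int(.Machine$integer.max, 1))$stress
    }, numeric(1))
  })
  sd_null <- stats::sd(null_stress)
  if (!is.finite(sd_null) || sd_null == 0) {
    return(list(z = NA_real_, p = NA_real_, observed_stress = observed$stress,
                null_mean = mean(null_stress), null_sd = sd_null,
                null_stress = null_stress, degenerate = TRUE))
  }
  list(
    z = (observed$stress - mean(null_stress)) / sd_null,
    p = mean(null_stress <= observed$stress),
    observed_stress = observed$stress,
    null_mean = mean(null_stress), null_sd = sd_null,
    null_stress = null_stress, degenerate = FALSE
  )
}

#' Embedding diagnostics
#'
#' Contrasts embedded distances between pairs with high vs low (median
#' split) input distances using a two-sample t-test, and quantifies the
#' monotone relationship between input and embedded distances with a
#' Spearman correlation.
#'
#' @param embedding An `embedding` from [nonmetric_mds()].
#' @param distances The input distance matrix.
#' @return A tibble: `t`, `df`, `p_t`, `mean_high`, `mean_low`, `rho`,
#'   `p_rho`.
#' @export
embedding_diagnostics <- function(embedding, distances) {
  delta <- lower_vec(as.matrix(distances))
  d_emb <- lower_vec(as.matrix(stats::dist(embedding$config)))
  low <- delta <= stats::median(delta)
  tt <- stats::t.test(d_emb[!low], d_emb[low], var.equal = FALSE)
  ct <- suppressWarnings(stats::cor.test(delta, d_emb, method = "spearman"))
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p_t = tt$p.value,
    mean_high = mean(d_emb[!low]), mean_low = mean(d_emb[low]),
    rho = unname(ct$estimate), p_rho = ct$p.value
  )
}
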