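# Independent reference implementations used as oracles. These stay naive
# (loops, brute force, enumeration) on purpose: they must not share code
# paths with the package.

# A fixed, hand-written 4 x 5 design with two clock speeds.
reference_design <- function() {
  vt <- list(
    c(7.0, 10.0, 13.5, 16.0, 21.0),
    c(6.5, 11.0, 14.0, 18.5, 23.0),
    c(8.0, 9.5, 15.0, 19.0, 22.5),
    c(7.5, 12.0, 16.5, 20.0, 23.5)
  )
  speeds <- c(0.12, 0.24, 0.12, 0.24)
  rows <- lapply(1:4, function(sq) {
    v <- vt[[sq]]
    data.frame(sequence_id = sq, position = 1:5, virtual_time = v,
               real_time = c(0, cumsum(diff(v) / speeds[sq])),
               clock_speed = speeds[sq])
  })
  d <- do.call(rbind, rows)
  d <- cbind(event_id = 1:20, d)
  tibble::as_tibble(d)
}

# Naive cross-mini-block mean Fisher-z similarity.
oracle_mean_z <- function(patterns) {
  d <- dim(patterns)
  ne <- d[1]; m <- d[2]
  clip <- 1 - 1e-7
  out <- matrix(NA_real_, ne, ne)
  for (i in 1:(ne - 1)) {
    for (j in (i + 1):ne) {
      zs <- c()
      for (a in 1:m) {
        for (b in 1:m) {
          if (a == b) next
          r <- cor(patterns[i, a, ], patterns[j, b, ])
          zs <- c(zs, atanh(min(max(r, -clip), clip)))
        }
      }
      out[i, j] <- out[j, i] <- mean(zs)
    }
  }
  out
}

# Brute-force sphere: every voxel of the volume within `radius`.
oracle_sphere <- function(center, radius, dims) {
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
    radius^2
  as.matrix(g[keep, ])
}

# Exhaustive permutation p for the focal coefficient's t (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(1:n, function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

oracle_perm_p <- function(y, x) {
  tval <- function(yy) summary(lm(yy ~ x))$coefficients[2, "t value"]
  t_obs <- tval(y)
  perms <- all_permutations(length(y))
  t_null <- apply(perms, 1, function(idx) tval(y[idx]))
  mean(t_null >= t_obs)
}

# Exhaustive two-sided sign-flip p.
oracle_signflip_p <- function(x) {
  n <- length(x)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tstat <- function(v) mean(v) / (sd(v) / sqrt(n))
  t_obs <- tstat(x)
  t_null <- apply(signs, 1, function(s) tstat(s * x))
  mean(abs(t_null) >= abs(t_obs) - 1e-12)
}

# Independent optimal group-to-sequence assignment by recursive permutation
# enumeration.
oracle_best_assignment <- function(sorted_groups, sequence_id) {
  best <- -1
  recurse <- function(remaining, mapping) {
    if (length(remaining) == 0) {
      mapped <- mapping[sorted_groups]
      best <<- max(best, sum(mapped == sequence_id))
      return()
    }
    for (s in remaining) {
      recurse(setdiff(remaining, s), c(mapping, s))
    }
  }
  recurse(1:4, integer(0))
  best
}

# Naive TFCE with BFS component search at every threshold step.
oracle_tfce <- function(map, dims, H = 2, E = 0.5, n_steps = 100) {
  valid <- is.finite(map)
  out <- rep(0, length(map))
  h_max <- max(c(0, map[valid]))
  if (h_max <= 0) { out[!valid] <- NA; return(out) }
  dh <- h_max / n_steps
  coord <- arrayInd(seq_along(map), dims)
  for (k in 1:n_steps) {
    h <- k * dh
    supra <- which(valid & map >= h)
    if (length(supra) == 0) next
    labels <- rep(0L, length(map))
    lab <- 0L
    for (s in supra) {
      if (labels[s] != 0) next
      lab <- lab + 1L
      queue <- s; labels[s] <- lab
      while (length(queue) > 0) {
        cur <- queue[1]; queue <- queue[-1]
        for (t in supra) {
          if (labels[t] == 0 &&
              all(abs(coord[t, ] - coord[cur, ]) <= 1)) {
            labels[t] <- lab
            queue <- c(queue, t)
          }
        }
      }
    }
    sizes <- table(labels[supra])
    out[supra] <- out[supra] + as.numeric(sizes[as.character(labels[supra])])^E *
      h^H * dh
  }
  out[!valid] <- NA
  out
}

# Per-subject similarity changes for a simulated experiment.
experiment_changes <- function(exp) {
  lapply(exp$patterns, function(x) {
    similarity_change(pairwise_similarity(x$pre, phase = "pre"),
                      pairwise_similarity(x$post, phase = "post"))
  })
}
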