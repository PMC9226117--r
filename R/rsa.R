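# Fisher z transform with the documented clip: correlations are clipped to
# +/- (1 - 1e-7) before atanh so identical patterns cannot produce
# infinities. The clip bound is exported as an attribute of results.
FISHER_CLIP <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -FISHER_CLIP), FISHER_CLIP))

# memoized combn(n, 2) index pairs (the similarity path runs tens of
# thousands of times in simulation studies)
.pair_cache <- new.env(parent = emptyenv())
pair_index_cache <- function(n) {
  key <- as.character(n)
  if (is.null(.pair_cache[[key]])) {
    idx <- utils::combn(n, 2)
    .pair_cache[[key]] <- list(
      idx = idx,
      upper = cbind(idx[1, ], idx[2, ]),
      lower = cbind(idx[2, ], idx[1, ])
    )
  }
  .pair_cache[[key]]
}

#' Flatten a pattern array to the searchlight matrix layout
#'
#' Converts an `n_events x n_miniblocks x n_voxels` array to the
#' `(n_events * n_miniblocks) x n_voxels` matrix the volumetric engine
#' consumes, rows ordered event-major with the mini-block index fastest.
#'
#' @param patterns A 3-d pattern array.
#' @return A matrix.
#' @export
patterns_to_matrix <- function(patterns) {
  d <- dim(patterns)
  matrix(aperm(patterns, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

# Precomputed flat indices into the (n_events*m) x (n_events*m) row
# correlation matrix: for each unordered event pair, the 90 (at m = 10)
# cross-block entries (a != b), covering both directions.
cross_block_index <- function(n_events, m) {
  idx <- utils::combn(n_events, 2)
  blocks <- expand.grid(a = seq_len(m), b = seq_len(m))
  blocks <- blocks[blocks$a != blocks$b, ]
  n_rows <- n_events * m
  out <- matrix(0L, nrow = nrow(blocks), ncol = ncol(idx))
  for (p in seq_len(ncol(idx))) {
    i <- idx[1, p]; j <- idx[2, p]
    ri <- (i - 1L) * m + blocks$a
    rj <- (j - 1L) * m + blocks$b
    out[, p] <- (rj - 1L) * n_rows + ri  # 1-based column-major flat index
  }
  out
}

#' Cross-mini-block pattern similarity for one scan phase
#'
#' For every pair of distinct events, the Pearson correlation between the
#' multi-voxel pattern of one event in one mini-block and the pattern of
#' the other event in every *other* mini-block is computed (comparisons
#' within the same mini-block are excluded; with 10 mini-blocks this is 90
#' ordered block pairs). Correlations are Fisher z-transformed (clipped at
#' `1 - 1e-7`) and averaged into one 20 x 20 similarity matrix.
#'
#' @param patterns Array `n_events x n_miniblocks x n_voxels`.
#' @param phase Optional phase label, `"pre"` or `"post"`; carried as an
#'   attribute and checked by [similarity_change()].
#' @return A symmetric `n_events x n_events` matrix of mean Fisher-z
#'   similarities with `NA` diagonal, class `similarity_matrix`.
#' @export
pairwise_similarity <- function(patterns, phase = NULL) {
  d <- dim(patterns)
  if (length(d) != 3) stop("patterns must be a 3-d array", call. = FALSE)
  n_events <- d[1]; m <- d[2]
  if (m < 2) stop("need at least 2 mini-blocks", call. = FALSE)
  mat <- patterns_to_matrix(patterns)
  sds <- sqrt(rowSums((mat - rowMeans(mat))^2))
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1]
    ev <- (bad - 1L) %/% m + 1L; bl <- (bad - 1L) %% m + 1L
    stop("zero-variance pattern vector for event ", ev, ", mini-block ", bl,
         call. = FALSE)
  }
  mean_z <- cpp_cross_block_mean_z(mat, n_events, m)
  out <- matrix(NA_real_, n_events, n_events)
  idx <- pair_index_cache(n_events)
  out[idx$upper] <- mean_z
  out[idx$lower] <- mean_z
  structure(out, class = c("similarity_matrix", "matrix"),
            phase = phase, clip = FISHER_CLIP)
}

#' Post-minus-pre pattern similarity change
#'
#' Representational change is the element-wise difference between the
#' post-learning and pre-learning similarity matrices; the diagonal remains
#' undefined.
#'
#' @param pre,post Similarity matrices from [pairwise_similarity()].
#' @return A symmetric matrix of similarity changes (class
#'   `similarity_change`).
#' @export
similarity_change <- function(pre, post) {
  if (!all(dim(pre) == dim(post))) {
    stop("pre and post similarity matrices have different dimensions",
         call. = FALSE)
  }
  ph_pre <- attr(pre, "phase"); ph_post <- attr(post, "phase")
  if (!is.null(ph_pre) && !is.null(ph_post) &&
      !(identical(ph_pre, "pre") && identical(ph_post, "post"))) {
    stop("phase mismatch: expected a 'pre' and a 'post' matrix, got '",
         ph_pre, "' and '", ph_post, "'", call. = FALSE)
  }
  structure(unclass(post) - unclass(pre),
            class = c("similarity_change", "matrix"))
}

#' Extract pair-level similarity-change values
#'
#' Attaches the change value of each unordered event pair to the pair
#' table, the long format all regression analyses consume.
#'
#' @param change A `similarity_change` (or any symmetric) matrix.
#' @param pairs A pair table from [build_pair_table()].
#' @return `pairs` with a `change` column.
#' @export
change_to_pairs <- function(change, pairs) {
  pairs$change <- unclass(change)[cbind(pairs$event_i, pairs$event_j)]
  pairs
}

#' Descriptive median split of similarity change by temporal distance
#'
#' Pairs at or below the median virtual distance of the chosen subset form
#' the "low" half, pairs strictly above form the "high" half. Descriptive
#' only; inference runs through the regression models.
#'
#' @param change A similarity-change matrix.
#' @param pairs A pair table.
#' @param subset `"same"`, `"different"`, or `"all"`.
#' @return A tibble with columns `half` (`"low"`, `"high"`), `n_pairs`, and
#'   `mean_change`.
#' @export
median_split_summary <- function(change, pairs,
                                 subset = c("same", "different", "all")) {
  subset <- match.arg(subset)
  rows <- switch(subset,
    all = rep(TRUE, nrow(pairs)),
    same = pairs$same_sequence,
    different = !pairs$same_sequence
  )
  sub <- change_to_pairs(change, pairs[rows, , drop = FALSE])
  if (nrow(sub) == 0) stop("empty subset", call. = FALSE)
  med <- stats::median(sub$virtual_distance)
  low <- sub$virtual_distance <= med
  tibble::tibble(
    half = c("low", "high"),
    n_pairs = c(sum(low), sum(!low)),
    mean_change = c(mean(sub$change[low]), mean(sub$change[!low]))
  )
}

#' Write / read a similarity matrix as TSV
#'
#' 20 x 20 tab-separated matrix with event ids as header row and first
#' column; `NA` marks the undefined diagonal.
#'
#' @param m A similarity or similarity-change matrix.
#' @param path File path.
#' @export
write_similarity_tsv <- function(m, path) {
  out <- as.data.frame(unclass(m))
  names(out) <- seq_len(ncol(m))
  out <- cbind(event_id = seq_len(nrow(m)), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m
}
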