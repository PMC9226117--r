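#' Validate an experiment design table
#'
#' A design table describes the 20 events of the virtual-clock paradigm:
#' 4 sequences ("virtual days") of 5 events each. Every event has a time on
#' the hidden virtual clock (virtual hours, on the 6 a.m.-midnight timeline,
#' i.e. in `[6, 24]`) and a real time in seconds since the first event of its
#' sequence. Because the clock runs at a different speed for different
#' sequences, virtual time is partially dissociated from both sequence
#' position (order) and real elapsed time.
#'
#' @param design A data frame with columns `event_id` (1..20), `sequence_id`
#'   (1..4), `position` (1..5), `virtual_time` (virtual hours), `real_time`
#'   (seconds since the first event of the sequence), and optionally
#'   `clock_speed` (virtual hours per real second, constant within sequence).
#' @param n_sequences,n_positions Expected design size; defaults match the
#'   4 x 5 paradigm.
#'
#' @return The design as a tibble, invisibly ordered by sequence and
#'   position. Errors name the offending record.
#' @export
validate_design <- function(design, n_sequences = 4L, n_positions = 5L) {
  required <- c("event_id", "sequence_id", "position", "virtual_time", "real_time")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  design <- tibble::as_tibble(design)
  n_events <- n_sequences * n_positions
  if (nrow(design) != n_events) {
    stop("design must have exactly ", n_events, " events, found ", nrow(design),
         call. = FALSE)
  }
  if (anyDuplicated(design$event_id)) {
    dup <- design$event_id[duplicated(design$event_id)][1]
    stop("duplicate event_id: ", dup, call. = FALSE)
  }
  key <- paste(design$sequence_id, design$position, sep = ":")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sequence_id, position): ", dup, call. = FALSE)
  }
  if (!setequal(unique(design$sequence_id), seq_len(n_sequences))) {
    stop("sequence_id must cover 1..", n_sequences, call. = FALSE)
  }
  by_seq <- split(design[order(design$position), ], design$sequence_id[order(design$position)])
  for (sq in by_seq) {
    if (nrow(sq) != n_positions) {
      stop("sequence ", sq$sequence_id[1], " has ", nrow(sq), " events, expected ",
           n_positions, call. = FALSE)
    }
    if (any(diff(sq$virtual_time) <= 0)) {
      stop("virtual_time not strictly increasing with position in sequence ",
           sq$sequence_id[1], call. = FALSE)
    }
    if (any(diff(sq$real_time) <= 0)) {
      stop("real_time not strictly increasing with position in sequence ",
           sq$sequence_id[1], call. = FALSE)
    }
  }
  invisible(dplyr::arrange(design, .data$sequence_id, .data$position))
}

#' Build the table of all unordered event pairs
#'
#' Derives, for each of the `choose(20, 2) = 190` unordered event pairs, the
#' three competing time metrics as absolute pairwise distances: virtual time
#' (hidden-clock hours), order (sequence positions), and real time (seconds).
#' Distances are defined both within and across sequences. The `first_last`
#' flag marks pairs made of the first (position 1) and last (position 5)
#' event of the same sequence, used as a control predictor for
#' sequence-boundary associations.
#'
#' @param design A valid design table (see [validate_design()]).
#' @return A tibble with one row per unordered pair: `event_i`, `event_j`
#'   (`event_i < event_j`), `virtual_distance`, `order_distance`,
#'   `real_distance`, `same_sequence`, `first_last`.
#' @export
#' @examples
#' d <- simulate_design(sim_config(), seed = 1)
#' pairs <- build_pair_table(d)
#' table(pairs$same_sequence)
build_pair_table <- function(design) {
  design <- validate_design(design)
  n <- nrow(design)
  idx <- utils::combn(n, 2)
  di <- design[idx[1, ], ]
  dj <- design[idx[2, ], ]
  same <- di$sequence_id == dj$sequence_id
  max_pos <- max(design$position)
  tibble::tibble(
    event_i = pmin(di$event_id, dj$event_id),
    event_j = pmax(di$event_id, dj$event_id),
    virtual_distance = abs(di$virtual_time - dj$virtual_time),
    order_distance = abs(di$position - dj$position),
    real_distance = abs(di$real_time - dj$real_time),
    same_sequence = same,
    first_last = same &
      (pmin(di$position, dj$position) == 1L) &
      (pmax(di$position, dj$position) == max_pos)
  )
}

#' Standardize predictor columns within an analysis subset
#'
#' Time metrics are z-scored within each participant before entering a
#' model, and the standardization is computed over the rows that actually
#' enter that model (same-sequence pairs, different-sequence pairs, or all
#' pairs).
#'
#' @param pairs A pair table (see [build_pair_table()]).
#' @param columns Character vector of column names to standardize.
#' @param subset One of `"all"`, `"same"`, `"different"`: which pairs enter
#'   the model. The returned tibble contains only those rows.
#' @return The subset of `pairs` with the requested columns z-scored
#'   (mean 0, sd 1 over the returned rows).
#' @export
zscore_predictors <- function(pairs, columns,
                              subset = c("all", "same", "different")) {
  subset <- match.arg(subset)
  rows <- switch(subset,
    all = rep(TRUE, nrow(pairs)),
    same = pairs$same_sequence,
    different = !pairs$same_sequence
  )
  out <- pairs[rows, , drop = FALSE]
  if (nrow(out) < 3) {
    stop("subset '", subset, "' has fewer than 3 rows", call. = FALSE)
  }
  for (col in columns) {
    if (!col %in% names(out)) {
      stop("unknown predictor column: ", col, call. = FALSE)
    }
    x <- as.numeric(out[[col]])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate predictor: column '", col, "' has zero variance in subset '",
           subset, "'", call. = FALSE)
    }
    out[[col]] <- (x - mean(x)) / s
  }
  out
}

#' Correlations between the time metrics across events
#'
#' Pearson correlation of virtual time with sequence position (order) and
#' with real time across the 20 events of a design. These correlations are
#' inevitably high for linearly increasing metrics; the clock-speed
#' manipulation keeps them below 1 so multiple regression can separate the
#' metrics.
#'
#' @param design A valid design table.
#' @return A tibble with columns `metric` (`"order"`, `"real_time"`) and
#'   `r` (Pearson correlation with virtual time).
#' @export
design_metric_correlations <- function(design) {
  design <- validate_design(design)
  tibble::tibble(
    metric = c("order", "real_time"),
    r = c(
      stats::cor(design$virtual_time, design$position),
      stats::cor(design$virtual_time, design$real_time)
    )
  )
}

#' Read / write design tables as TSV
#'
#' Plain tab-separated files with a header line, UTF-8, decimal point.
#'
#' @param path File path.
#' @return `read_design_tsv()` returns a validated design tibble.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  design <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_design(design)
  tibble::as_tibble(design)
}

#' @rdname read_design_tsv
#' @param design A design table.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_design_tsv
#' @param pairs A pair table.
#' @export
write_pair_table_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
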