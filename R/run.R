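#' Validate and load a pipeline configuration
#'
#' Reads a JSON configuration, checks the schema, verifies that referenced
#' files exist, loads any design/behavior tables, and attaches a
#' provenance record (config hash, seed, package version).
#'
#' @param config_path Path to a JSON configuration. Recognized fields:
#'   `seed` (mandatory), `output_dir`, `analyses` (subset of `"behavior"`,
#'   `"roi"`, `"interaction"`, `"mds"`, `"searchlight"`), `n_perm`,
#'   `n_flips`, `exclude_subjects`, `simulate` (overrides for
#'   [sim_config()]) or `paths` (`design`, `behavior` TSVs).
#' @return A validated `run_config` list with loaded data.
#' @export
validate_and_load <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$output_dir <- cfg$output_dir %||% "clockrsa-results"
  cfg$n_perm <- as.integer(cfg$n_perm %||% 1000L)
  cfg$n_flips <- as.integer(cfg$n_flips %||% 1000L)
  cfg$analyses <- cfg$analyses %||% c("behavior", "roi", "interaction", "mds")
  known <- c("behavior", "roi", "interaction", "mds", "searchlight")
  bad <- setdiff(cfg$analyses, known)
  if (length(bad) > 0) {
    stop("unknown analysis stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg$exclude_subjects <- as.integer(cfg$exclude_subjects %||% integer(0))
  if (!is.null(cfg$paths)) {
    for (f in names(cfg$paths)) {
      if (!file.exists(cfg$paths[[f]])) {
        stop("config references a missing file: ", cfg$paths[[f]],
             " (field '", f, "')", call. = FALSE)
      }
    }
    cfg$design <- read_design_tsv(cfg$paths$design)
    if (!is.null(cfg$paths$behavior)) {
      cfg$behavior <- tibble::as_tibble(
        utils::read.delim(cfg$paths$behavior, sep = "\t")
      )
    }
  }
  sim_over <- as.list(cfg$simulate %||% list())
  cfg$sim_config <- do.call(sim_config, sim_over)
  cfg$provenance <- list(
    config_md5 = unname(tools::md5sum(config_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("clockrsa"))
  )
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate-then-analyze pipeline
#'
#' Executes the configured stages on simulated (or loaded) data: behavioral
#' analyses (timeline regression, accuracy, sorting, swap errors,
#' generalization bias), the ROI similarity-change models for same- and
#' different-sequence pairs, the membership-by-virtual-time interaction
#' (summary and mixed paths), non-metric MDS of the model-derived
#' distances, and optionally a searchlight run on simulated volumes. All
#' results are written as JSON/TSV under the output directory; every seed
#' and resample count is recorded.
#'
#' @param config A `run_config` from [validate_and_load()], or a path to a
#'   config JSON.
#' @return A list of stage results, invisibly; files are written to
#'   `config$output_dir`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- validate_and_load(config)
  if (length(config$analyses) == 0) {
    warning("empty analysis list: nothing to do")
    return(invisible(list()))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(provenance = config$provenance)
  sc <- config$sim_config
  seed <- config$seed
  np <- config$n_perm; nf <- config$n_flips

  need_patterns <- any(c("roi", "interaction", "mds") %in% config$analyses)
  if (is.null(config$design)) {
    exp <- simulate_experiment(sc, seed, patterns = need_patterns)
    design <- exp$design
    behavior <- exp$behavior
    patterns <- exp$patterns
  } else {
    design <- config$design
    behavior <- config$behavior
    patterns <- NULL
    if (need_patterns) {
      exp <- simulate_experiment(sc, seed)
      patterns <- exp$patterns
    }
  }
  keep <- setdiff(sort(unique(behavior$subject_id)), config$exclude_subjects)
  behavior <- behavior[behavior$subject_id %in% keep, ]
  pairs <- build_pair_table(design)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("behavior" %in% config$analyses) {
    out$behavior <- stage("behavior", {
      list(
        timeline = timeline_regression(behavior, design, n_perm = np,
                                       n_flips = nf, seed = seed),
        accuracy = accuracy_metrics(behavior, design),
        sorting = sorting_accuracy(behavior, design),
        swap = swap_error_test(behavior, design, n_iter = np, seed = seed),
        bias = generalization_bias(behavior, design, n_perm = np,
                                   n_flips = nf, seed = seed)
      )
    })
  }

  changes <- NULL
  if (need_patterns) {
    changes <- stage("rsa", {
      lapply(patterns[keep], function(p) {
        similarity_change(pairwise_similarity(p$pre, phase = "pre"),
                          pairwise_similarity(p$post, phase = "post"))
      })
    })
  }

  if ("roi" %in% config$analyses) {
    out$roi <- stage("roi", {
      list(
        same = run_roi_model(changes, pairs,
          roi_spec("roi", "same", c("virtual", "order", "real"),
                   focal = "virtual", n_perm = np, n_flips = nf, seed = seed)),
        different = run_roi_model(changes, pairs,
          roi_spec("roi", "different", c("virtual", "order", "real"),
                   focal = "virtual", n_perm = np, n_flips = nf, seed = seed))
      )
    })
  }

  interaction_res <- NULL
  if ("interaction" %in% config$analyses) {
    interaction_res <- stage("interaction", {
      sequence_interaction_test(changes, pairs, n_perm = np, n_flips = nf,
                                seed = seed, mixed = TRUE)
    })
    out$interaction <- interaction_res
  }

  if ("mds" %in% config$analyses) {
    out$mds <- stage("mds", {
      fit <- if (!is.null(interaction_res)) interaction_res$mixed else {
        dat <- mixed_model_data(changes, pairs)
        fit_mixed_and_lrt(dat, "change",
                          c("vd_z", "seq_dev", "vd_z:seq_dev"),
                          focal = "vd_z:seq_dev")
      }
      dmat <- model_predicted_distances(fit, pairs)
      emb <- nonmetric_mds(dmat, n_starts = 100L, seed = seed)
      list(
        distances = dmat, embedding = emb,
        diagnostics = embedding_diagnostics(emb, dmat),
        stress_test = stress_permutation_test(
          dmat, n_iter = min(200L, np), seed = seed,
          n_starts_null = 10L, observed = emb)
      )
    })
  }

  if ("searchlight" %in% config$analyses) {
    out$searchlight <- stage("searchlight", {
      sl_cfg <- config$searchlight %||% list()
      vol <- generate_volume_dataset(sc, seed)
      sl_pairs <- build_pair_table(vol$design)
      maps <- lapply(vol$subjects, function(su) {
        run_searchlight(su$pre, su$post, vol$grid, sl_pairs,
                        radius = sl_cfg$radius %||% 3,
                        min_gray = sl_cfg$min_gray %||% 25L,
                        n_miniblocks = sc$n_miniblocks)
      })
      svc <- vol$grid$graymatter_mask
      same_maps <- lapply(maps, function(m) {
        smooth_map(m$same, sl_cfg$fwhm_mm %||% 3, vol$grid)
      })
      group <- group_map_test(same_maps, svc,
                              n_flips = sl_cfg$n_flips %||% nf, seed = seed)
      list(group = group, cluster_center = vol$cluster_center)
    })
  }

  results_json <- serialize_results(out)
  jsonlite::write_json(results_json,
                       file.path(config$output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(out$behavior)) {
    utils::write.table(out$behavior$sorting,
                       file.path(config$output_dir, "sorting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$roi)) {
    roi_tab <- dplyr::bind_rows(lapply(out$roi, glance))
    utils::write.table(roi_tab, file.path(config$output_dir, "roi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

# Convert the nested result objects into plain JSON-serializable values.
serialize_results <- function(out) {
  simplify <- function(x) {
    if (inherits(x, "group_test")) return(as.list(tidy.group_test(x)))
    if (inherits(x, "roi_result")) return(as.list(glance.roi_result(x)))
    if (inherits(x, "mixed_lrt")) return(as.list(glance.mixed_lrt(x)))
    if (inherits(x, "embedding")) return(as.list(glance.embedding(x)))
    if (is.data.frame(x)) return(x)
    if (is.matrix(x) || is.array(x)) return(NULL)
    if (inherits(x, "merMod")) return(NULL)
    if (is.list(x)) {
      res <- lapply(x, simplify)
      return(res[!vapply(res, is.null, logical(1))])
    }
    x
  }
  simplify(out)
}
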