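# Pipeline wiring: simulate -> indices -> rgg/burden -> train/eval/crossval,
# with a flat config, run manifests and reproducible seeds.

#' Run configuration
#'
#' Flat key-value configuration.  Values may come from a YAML file
#' (`config_file`); arguments given directly override file values.
#'
#' @param ... configuration keys.  Recognized keys include `mesc_order`
#'   (default 1), `window_length` (150), `stride` (30), `ks_mode`
#'   (`"fast"`), `ks_grid_size` (32), `variability_estimator` (`"sd"`),
#'   `max_splits` (30), `seed` (1), plus command-specific I/O paths
#'   (`beats`, `segments`, `indices`, `model`, `out`, ...), `profile`,
#'   `beats_n`, `dims`, `rect`.
#' @param config_file optional YAML file of key-value pairs.
#' @return list of class `run_config`.
#' @export
run_config <- function(..., config_file = NULL) {
  cfg <- list(mesc_order = 1L, window_length = 150L, stride = 30L,
              ks_mode = "fast", ks_grid_size = 32L,
              variability_estimator = "sd", max_splits = 30L, seed = 1L)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      .format_error(paste("no such config file:", config_file))
    }
    cfg <- utils::modifyList(cfg, yaml::read_yaml(config_file))
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "run_config")
}

#' @noRd
.cfg_index_config <- function(cfg) {
  index_config(mesc_order = cfg$mesc_order, window_length = cfg$window_length,
               stride = cfg$stride,
               variability_estimator = cfg$variability_estimator,
               ks_mode = cfg$ks_mode, ks_grid_size = cfg$ks_grid_size)
}

#' @noRd
.require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    .format_error(paste("missing input file(s):",
                        paste(missing, collapse = ", ")))
  }
}

#' Write a run manifest next to the outputs (config + input digests)
#' @noRd
.write_manifest <- function(command, cfg, inputs, outputs) {
  manifest <- list(
    command = command,
    config = unclass(cfg),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)))
  path <- paste0(outputs[[1L]], ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  path
}

#' @noRd
.log_stage <- function(...) message("[regularogram] ", sprintf(...))

#' Run one pipeline command
#'
#' Commands:
#' * `simulate` — generate a synthetic record (`cfg$profile`:
#'   `"af_paroxysmal"` or a [rhythm_profile] kind; `cfg$beats_n` beats;
#'   `cfg$seed`) and write `<out>_beats.csv` / `<out>_segments.csv`.
#' * `indices` — read `cfg$beats` + `cfg$segments` (CSV, seconds), compute
#'   the window-index table, write it to `cfg$out`.
#' * `rgg` — read `cfg$indices`, render the regularogram to `cfg$out`
#'   (`.svg`/`.png`; `cfg$dims` 2 or 3).
#' * `burden` — read `cfg$indices`, estimate AF burden inside `cfg$rect`
#'   (`c(v_min, v_max, n_min, n_max)`), write JSON to `cfg$out`.
#' * `train` — read `cfg$indices` (path or vector of paths), fit a capped
#'   tree, write model JSON to `cfg$out`.
#' * `eval` — read `cfg$model` + `cfg$indices`, write a metrics report JSON
#'   to `cfg$out`.
#' * `crossval` — `cfg$records_dir` holding `<id>_beats.csv` /
#'   `<id>_segments.csv` pairs; run [cross_validate] over `cfg$orders` x
#'   `cfg$window_lengths`, write the grid JSON to `cfg$out`.
#'
#' Every command writes a `<first output>.manifest.json` capturing the
#' command, configuration and input/output digests; identical config and
#' seed yield identical manifests.
#'
#' @param command one of `"simulate"`, `"indices"`, `"rgg"`, `"burden"`,
#'   `"train"`, `"eval"`, `"crossval"`.
#' @param cfg a [run_config].
#' @return named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "indices", "rgg", "burden",
                                     "train", "eval", "crossval"),
                         cfg = run_config()) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "run_config"))
  .log_stage("start %s", command)
  out <- switch(command,
    simulate = .cmd_simulate(cfg),
    indices = .cmd_indices(cfg),
    rgg = .cmd_rgg(cfg),
    burden = .cmd_burden(cfg),
    train = .cmd_train(cfg),
    eval = .cmd_eval(cfg),
    crossval = .cmd_crossval(cfg))
  .log_stage("done %s -> %s", command, paste(out, collapse = ", "))
  invisible(out)
}

#' Paroxysmal-AF demonstration profile sequence
#' @noRd
.af_paroxysmal_sequence <- function(n_beats) {
  fr <- c(0.30, 0.20, 0.20, 0.15, 0.15)   # N, AF, N, AF, N
  kinds <- c("NSR", "AF", "NSR", "AF", "NSR")
  lens <- floor(n_beats * fr)
  lens[1L] <- lens[1L] + n_beats - sum(lens)
  lapply(seq_along(kinds), function(i) {
    list(profile = rhythm_profile(kinds[i]), n_beats = lens[i])
  })
}

#' @noRd
.cmd_simulate <- function(cfg) {
  profile <- if (is.null(cfg$profile)) "af_paroxysmal" else cfg$profile
  n_beats <- if (is.null(cfg$beats_n)) 10000L else as.integer(cfg$beats_n)
  if (is.null(cfg$out)) .format_error("simulate needs an 'out' path prefix")
  seqs <- if (profile == "af_paroxysmal") {
    .af_paroxysmal_sequence(n_beats)
  } else {
    list(list(profile = rhythm_profile(profile), n_beats = n_beats))
  }
  rec <- gen_record(seqs, seed = cfg$seed,
                    record_id = basename(cfg$out))
  paths <- write_synthetic_record(rec, cfg$out)
  .write_manifest("simulate", cfg, character(0), paths)
  paths
}

#' @noRd
.cmd_indices <- function(cfg) {
  if (is.null(cfg$beats) || is.null(cfg$segments) || is.null(cfg$out)) {
    .format_error("indices needs 'beats', 'segments' and 'out' paths")
  }
  .require_inputs(c(cfg$beats, cfg$segments))
  beats <- read_beat_annotations(cfg$beats, dialect = "csv")
  segments <- read_rhythm_segments(cfg$segments, dialect = "csv")
  tab <- compute_indices(rr_from_beats(beats), segments, .cfg_index_config(cfg))
  write_index_table(tab, cfg$out)
  .write_manifest("indices", cfg, c(cfg$beats, cfg$segments), cfg$out)
  c(indices = cfg$out)
}

#' @noRd
.cmd_rgg <- function(cfg) {
  if (is.null(cfg$indices) || is.null(cfg$out)) {
    .format_error("rgg needs 'indices' and 'out' paths")
  }
  .require_inputs(cfg$indices)
  dims <- if (is.null(cfg$dims)) 2L else as.integer(cfg$dims)
  tab <- read_index_table(cfg$indices)
  render_rgg(build_rgg(tab, dims = dims), cfg$out)
  .write_manifest("rgg", cfg, cfg$indices, cfg$out)
  c(plot = cfg$out)
}

#' @noRd
.cmd_burden <- function(cfg) {
  if (is.null(cfg$indices) || is.null(cfg$rect) || is.null(cfg$out)) {
    .format_error("burden needs 'indices', 'rect' and 'out'")
  }
  .require_inputs(cfg$indices)
  r <- as.numeric(cfg$rect)
  if (length(r) != 4L) .format_error("rect must be v_min,v_max,n_min,n_max")
  tab <- read_index_table(cfg$indices)
  est <- estimate_burden(tab, zone_rect(r[1L], r[2L], r[3L], r[4L]))
  truth <- mean(tab$label == "AF")
  jsonlite::write_json(list(burden_estimate = est,
                            annotated_af_window_fraction = truth,
                            n_windows = nrow(tab)),
                       cfg$out, auto_unbox = TRUE, digits = NA)
  .write_manifest("burden", cfg, cfg$indices, cfg$out)
  c(report = cfg$out)
}

#' @noRd
.cmd_train <- function(cfg) {
  if (is.null(cfg$indices) || is.null(cfg$out)) {
    .format_error("train needs 'indices' and 'out'")
  }
  paths <- unlist(cfg$indices)
  .require_inputs(paths)
  tab <- do.call(rbind, lapply(paths, read_index_table))
  fit <- mesc_tree(label ~ variability + normality + mean_rr, tab,
                   max_splits = cfg$max_splits)
  write_tree_json(fit, cfg$out)
  .write_manifest("train", cfg, paths, cfg$out)
  c(model = cfg$out)
}

#' @noRd
.cmd_eval <- function(cfg) {
  if (is.null(cfg$model) || is.null(cfg$indices) || is.null(cfg$out)) {
    .format_error("eval needs 'model', 'indices' and 'out'")
  }
  paths <- unlist(cfg$indices)
  .require_inputs(c(cfg$model, paths))
  fit <- read_tree_json(cfg$model)
  tab <- do.call(rbind, lapply(paths, read_index_table))
  rep <- evaluate_detection(predict(fit, tab), tab$label)
  jsonlite::write_json(lapply(unclass(rep), function(v) v),
                       cfg$out, auto_unbox = TRUE, digits = NA, na = "null")
  .write_manifest("eval", cfg, c(cfg$model, paths), cfg$out)
  c(report = cfg$out)
}

#' @noRd
.cmd_crossval <- function(cfg) {
  if (is.null(cfg$records_dir) || is.null(cfg$out)) {
    .format_error("crossval needs 'records_dir' and 'out'")
  }
  beat_files <- sort(list.files(cfg$records_dir, pattern = "_beats\\.csv$",
                                full.names = TRUE))
  if (length(beat_files) == 0L) {
    .format_error(paste("no *_beats.csv files in", cfg$records_dir))
  }
  seg_files <- sub("_beats\\.csv$", "_segments.csv", beat_files)
  .require_inputs(seg_files)
  records <- lapply(seq_along(beat_files), function(i) {
    beats <- read_beat_annotations(beat_files[i], dialect = "csv")
    list(rr = rr_from_beats(beats),
         segments = read_rhythm_segments(seg_files[i], dialect = "csv"))
  })
  orders <- if (is.null(cfg$orders)) c(1L, 2L) else as.integer(unlist(cfg$orders))
  wls <- if (is.null(cfg$window_lengths)) c(70L, 150L) else
    as.integer(unlist(cfg$window_lengths))
  cv <- cross_validate(records, orders = orders, window_lengths = wls,
                       folds = if (is.null(cfg$folds)) 5L else as.integer(cfg$folds),
                       seed = cfg$seed, max_splits = cfg$max_splits,
                       stride = cfg$stride)
  jsonlite::write_json(list(grid = cv$grid, best = cv$best,
                            fold_of = cv$fold_of),
                       cfg$out, auto_unbox = TRUE, digits = NA, na = "null")
  .write_manifest("crossval", cfg, c(beat_files, seg_files), cfg$out)
  c(report = cfg$out)
}
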