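# Run configuration (YAML) and the command-style entry points that bind the
# pipeline: simulate -> train -> recognize / evaluate. A thin Rscript
# wrapper over these functions ships in inst/cli/eatbn.

#' Read a run configuration
#'
#' YAML file (or a plain named list) with any of: `window_s`, `n_bins`,
#' `alpha`, `threshold`, `seed`, `n_subjects`, `minutes_per_subject`,
#' `eating_fraction`, `context_flip`, `dropout`, and the paths
#' `structure_file`, `model_file`, `sensor_file`, `annotations_file`,
#' `output_file`. Missing entries take the defaults below; a `seed` is
#' mandatory for any stochastic command.
#'
#' @param config path to a YAML file, or a named list.
#' @return Named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(window_s = 1, n_bins = 10, alpha = 1, threshold = 0.6,
                   seed = NULL, n_subjects = 25, minutes_per_subject = 38,
                   eating_fraction = 0.4727, context_flip = 0.05,
                   dropout = 0.02)
  out <- utils::modifyList(defaults, config)
  stopifnot(out$threshold >= 0, out$threshold <= 1, out$alpha >= 0)
  class(out) <- "run_config"
  out
}

.require_paths <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]]))
      stop("config is missing required path '", k, "'")
  }
  invisible(TRUE)
}

#' Simulate a dataset to CSV files
#'
#' Runs [generate_dataset()] with the configured cohort and writes the
#' sensor log (`sensor_file`) and the long-format context annotations
#' (`annotations_file`). The seed is echoed in a `# seed: <n>` comment
#' line atop the sensor file; [read_sensor_csv()] skips comments.
#'
#' @param config a `run_config` (or path/list accepted by
#'   [read_run_config()]) with `seed`, `sensor_file`, `annotations_file`.
#' @param quiet suppress the summary line.
#' @return Invisibly, the dataset list from [generate_dataset()].
#' @export
cli_simulate <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set a seed")
  .require_paths(config, c("sensor_file", "annotations_file"))
  ds <- generate_dataset(n_subjects = config$n_subjects,
                         minutes_per_subject = config$minutes_per_subject,
                         eating_fraction = config$eating_fraction,
                         seed = config$seed,
                         context_flip = config$context_flip,
                         dropout = config$dropout)
  writeLines(paste0("# seed: ", config$seed), config$sensor_file)
  data.table::fwrite(data.table::as.data.table(ds$records),
                     config$sensor_file, append = TRUE, col.names = TRUE)
  write_annotations_csv(ds$contexts, config$annotations_file)
  secs <- nrow(ds$contexts)
  share <- mean(ds$contexts$eating)
  if (!quiet)
    message(sprintf("simulated %.1f min over %d subjects; eating share %.2f%%",
                    secs / 60, config$n_subjects, 100 * share))
  invisible(ds)
}

#' Train a model from sensor + annotation CSVs
#'
#' Windows the sensor log, aligns the context annotations, fits the stump
#' bank and CPTs, and writes the single model JSON. Deterministic given
#' inputs and config.
#'
#' @param config a `run_config` with `sensor_file`, `annotations_file`,
#'   `model_file`; optionally `structure_file`.
#' @param quiet suppress log lines.
#' @return Invisibly, the fitted `mbn_model`.
#' @export
cli_train <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  .require_paths(config, c("sensor_file", "annotations_file", "model_file"))
  s <- if (!is.null(config$structure_file)) load_structure(config$structure_file)
       else build_default_structure()
  records <- read_sensor_csv(config$sensor_file)
  windows <- segment_windows(records, window_s = config$window_s)
  contexts <- read_annotations_csv(config$annotations_file)
  model <- train_model(windows, contexts, structure = s,
                       alpha = config$alpha, threshold = config$threshold)
  save_model(model, config$model_file)
  if (!quiet) {
    accs <- vapply(model$stumps, `[[`, numeric(1), "train_accuracy")
    message(sprintf("trained on %d windows; stump accuracy mean %.3f (min %.3f)",
                    nrow(windows), mean(accs, na.rm = TRUE),
                    min(accs, na.rm = TRUE)))
  }
  invisible(model)
}

#' Recognize eating windows in a sensor CSV
#'
#' Reads the model and an (unlabelled) sensor log, and writes per-window
#' posterior, per-submodule shared-node posteriors and the decision at the
#' configured threshold. A channel absent from the whole stream is
#' tolerated: windows are formed over the channels present and the missing
#' evidence is marginalized out.
#'
#' @param config a `run_config` with `model_file`, `sensor_file`,
#'   `output_file`.
#' @param quiet suppress log lines.
#' @return Invisibly, the decisions data.frame.
#' @export
cli_recognize <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  .require_paths(config, c("model_file", "sensor_file", "output_file"))
  model <- load_model(config$model_file)
  records <- utils::read.csv(config$sensor_file, comment.char = "#")
  if (!"label" %in% names(records)) records$label <- 1L  # unlabelled stream
  missing_ch <- setdiff(eatbn_channels, unique(records$channel))
  if (length(missing_ch)) {
    warning("channel(s) absent from stream: ",
            paste(missing_ch, collapse = ", "),
            "; proceeding by marginalization")
    windows <- .segment_partial(records, config$window_s)
  } else {
    windows <- segment_windows(records, window_s = config$window_s)
  }
  out <- predict_windows(model, windows, threshold = config$threshold)
  data.table::fwrite(data.table::as.data.table(out), config$output_file)
  if (!quiet)
    message(sprintf("recognized %d windows; %.1f%% eating at threshold %.2f",
                    nrow(out),
                    if (nrow(out)) 100 * mean(out$decision == "eating") else 0,
                    config$threshold))
  invisible(out)
}

# windowing over whichever channels are present (recognition tolerates an
# entirely absent channel; its evidence is marginalized downstream)
.segment_partial <- function(records, window_s) {
  present <- intersect(eatbn_channels, unique(records$channel))
  if (length(present) == 0L || nrow(records) == 0L)
    return(segment_windows(records[0, , drop = FALSE], window_s))
  fake <- records[records$channel == present[1], , drop = FALSE][1, , drop = FALSE]
  # pad missing channels with placeholder rows so windows form, then drop
  # the placeholder features
  filled <- records
  for (ch in setdiff(eatbn_channels, present)) {
    pad <- data.frame(timestamp = sort(unique(floor(records$timestamp))),
                      channel = ch, value = NA_real_,
                      label = fake$label, stringsAsFactors = FALSE)
    filled <- rbind(filled[names(pad)], pad)
  }
  w <- segment_windows(filled, window_s)
  bad <- unlist(lapply(setdiff(eatbn_channels, present), function(ch)
    grep(paste0("^", ch, "_"), names(w), value = TRUE)))
  w[bad] <- NULL
  w
}

#' Evaluate a model on a labelled sensor CSV
#'
#' Windows the labelled stream, scores it with the model, and writes a
#' metrics JSON (confusion matrix, accuracy/precision/sensitivity/
#' specificity, AUC) plus a ROC sweep CSV when `roc_file` is configured.
#'
#' @param config a `run_config` with `model_file`, `sensor_file`,
#'   `output_file`; optionally `roc_file`.
#' @param quiet suppress log lines.
#' @return Invisibly, a list with `metrics`, `cm`, `roc`.
#' @export
cli_evaluate <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  .require_paths(config, c("model_file", "sensor_file", "output_file"))
  model <- load_model(config$model_file)
  records <- utils::read.csv(config$sensor_file, comment.char = "#")
  windows <- segment_windows(records, window_s = config$window_s)
  pred <- predict_windows(model, windows, threshold = config$threshold)
  truth <- windows$is_eating
  cm <- confusion_matrix(truth, decision = pred$decision)
  met <- compute_metrics(cm)
  roc <- roc_sweep(pred$posterior, truth)
  jsonlite::write_json(list(
    n_windows = nrow(windows), threshold = config$threshold,
    confusion = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn),
    metrics = unclass(met), auc = attr(roc, "auc")),
    config$output_file, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(config$roc_file))
    data.table::fwrite(data.table::as.data.table(as.data.frame(roc)),
                       config$roc_file)
  if (!quiet) {
    message(sprintf("evaluated %d windows: ", nrow(windows)),
            sprintf("accuracy %.2f%%, AUC %.3f",
                    met$accuracy, attr(roc, "auc")))
  }
  invisible(list(metrics = met, cm = cm, roc = roc))
}
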