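# End-to-end training (windows -> stumps -> CPT counting -> model) and
# model JSON (de)serialization.

#' Train the full recognizer
#'
#' Fits one decision stump per evidence node (targets: the true state of
#' the node's parent context in each window), predicts the evidence states
#' of the training windows with the fitted bank, and counts the joint
#' assignments (true query and context states, stump-predicted evidence
#' states) into Laplace-smoothed CPTs.
#'
#' @param windows window feature data.frame from [segment_windows()].
#' @param contexts aligned context-truth data.frame: one row per window,
#'   logical columns for every inference node and the query node `eating`
#'   (extra columns such as `window_start`/`subject`/`label` are ignored).
#' @param structure network structure (default [build_default_structure()]).
#' @param alpha CPT smoothing pseudo-count (default 1).
#' @param threshold decision threshold stored in the model (default 0.6).
#' @return An `mbn_model` with stump bank and CPTs.
#' @export
train_model <- function(windows, contexts,
                        structure = build_default_structure(),
                        alpha = 1, threshold = 0.6) {
  contexts <- .align_contexts(structure, windows, contexts)
  stumps <- fit_stump_bank(structure, windows, contexts)
  evmat <- predict_evidence_bank(stumps, windows)
  hidden <- structure$nodes$id[structure$nodes$role != "evidence"]
  assign_df <- cbind(contexts[hidden],
                     as.data.frame(evmat, optional = TRUE))
  keep <- stats::complete.cases(assign_df)
  bank <- accumulate(new_count_bank(structure), assign_df[keep, , drop = FALSE])
  cpts <- finalize_cpts(bank, alpha)
  mbn_model(structure, cpts, stumps = stumps, threshold = threshold,
            alpha = alpha)
}

.align_contexts <- function(structure, windows, contexts) {
  hidden <- structure$nodes$id[structure$nodes$role != "evidence"]
  miss <- setdiff(hidden, names(contexts))
  if (length(miss))
    stop("context annotations missing node(s): ", paste(miss, collapse = ", "))
  if (nrow(contexts) != nrow(windows)) {
    if (!("window_start" %in% names(contexts)))
      stop("contexts must align with windows (same rows or a window_start key)")
    i <- match(windows$window_start, contexts$window_start)
    if (anyNA(i))
      stop("no context annotation for window(s) starting at ",
           paste(utils::head(windows$window_start[is.na(i)], 3), collapse = ", "))
    contexts <- contexts[i, , drop = FALSE]
  }
  contexts
}

#' Save / load a recognizer model as JSON
#'
#' A single JSON artifact bundles the structure, the stump bank
#' (`node_id -> {feature, threshold, polarity, train_accuracy,
#' degenerate}`), the CPT bank (`node_id -> {parent_states, states,
#' probs}` rows) and the decision threshold, so recognition needs one
#' file. The round trip is exact up to floating-point text encoding
#' (17 significant digits are written).
#'
#' @param model an `mbn_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` an
#'   `mbn_model`.
#' @export
save_model <- function(model, path) {
  s <- model$structure
  tmp <- tempfile(); on.exit(unlink(tmp))
  save_structure(s, tmp)
  obj <- list(
    structure = jsonlite::read_json(tmp),
    cpts = lapply(model$cpts, function(cpt)
      list(parent_states = as.list(rownames(cpt)),
           states = as.list(colnames(cpt)),
           probs = lapply(seq_len(nrow(cpt)), function(i) as.list(cpt[i, ])))),
    stumps = if (is.null(model$stumps)) NULL else lapply(model$stumps, function(st)
      list(node_id = st$node_id, feature = st$feature,
           threshold = st$threshold, polarity = st$polarity,
           train_accuracy = st$train_accuracy, degenerate = st$degenerate)),
    threshold = model$threshold, alpha = model$alpha)
  # digits = NA keeps full double precision; Inf-valued stump thresholds
  # are encoded as the strings "Inf"/"-Inf"
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  for (key in c("structure", "cpts", "threshold"))
    if (is.null(obj[[key]]))
      stop("malformed model file: missing key '", key, "'")
  tmp <- tempfile(); on.exit(unlink(tmp))
  jsonlite::write_json(obj$structure, tmp, auto_unbox = TRUE)
  s <- load_structure(tmp)
  num <- function(x) {
    if (is.character(x)) as.numeric(x) else x  # "Inf"/"-Inf" round trip
  }
  cpts <- lapply(obj$cpts, function(ct) {
    probs <- do.call(rbind, lapply(ct$probs, function(r)
      vapply(r, as.numeric, numeric(1))))
    rownames(probs) <- vapply(ct$parent_states, as.character, character(1))
    colnames(probs) <- vapply(ct$states, as.character, character(1))
    probs
  })
  class(cpts) <- "cpt_bank"
  attr(cpts, "alpha") <- if (is.null(obj$alpha)) NA_real_ else num(obj$alpha)
  stumps <- if (is.null(obj$stumps)) NULL else lapply(obj$stumps, function(st)
    structure(list(node_id = st$node_id,
                   feature = if (is.null(st$feature)) NA_character_ else st$feature,
                   threshold = num(st$threshold), polarity = st$polarity,
                   train_accuracy = if (is.null(st$train_accuracy)) NA_real_
                                    else num(st$train_accuracy),
                   degenerate = isTRUE(st$degenerate)),
              class = "evidence_stump"))
  mbn_model(s, cpts, stumps = stumps, threshold = num(obj$threshold),
            alpha = attr(cpts, "alpha"))
}

#' Read / write context annotations CSV
#'
#' Long dialect `window_start,node_id,state` with one row per (window,
#' node); states are `"true"`/`"false"`.
#'
#' @param contexts wide context data.frame (logical node columns).
#' @param path file path.
#' @return `read_annotations_csv` returns the wide logical data.frame.
#' @export
write_annotations_csv <- function(contexts, path) {
  meta <- intersect(c("window_start"), names(contexts))
  node_cols <- setdiff(names(contexts), c("window_start", "subject", "label"))
  dt <- data.table::as.data.table(contexts[c(meta, node_cols)])
  long <- data.table::melt(dt, id.vars = meta, variable.name = "node_id",
                           value.name = "state", variable.factor = FALSE)
  long[, state := ifelse(state, "true", "false")]
  data.table::fwrite(long, path)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  long <- data.table::fread(path, header = TRUE)
  need <- c("window_start", "node_id", "state")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("annotation CSV missing column(s): ", paste(miss, collapse = ", "))
  wide <- data.table::dcast(long, window_start ~ node_id, value.var = "state")
  out <- as.data.frame(wide)
  for (cc in setdiff(names(out), "window_start")) {
    x <- out[[cc]]
    # fread may have auto-typed the state column as logical already
    out[[cc]] <- if (is.logical(x)) x else tolower(as.character(x)) == "true"
  }
  out
}
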