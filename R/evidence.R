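# Per-evidence-node decision stumps: one single-threshold binary classifier
# per evidence node, mapping a window feature to the node's observed state.

#' Fit a decision stump for one evidence node
#'
#' Searches all candidate thresholds (midpoints between consecutive sorted
#' distinct feature values, plus the open ends) and both polarities, and
#' keeps the pair maximizing training accuracy. Ties are broken toward the
#' smallest threshold, then toward the `ge` polarity. Polarity `ge` maps
#' values `>= threshold` to state `true`; polarity `le` maps values
#' `<= threshold` to `true`, so a value exactly at the threshold always
#' predicts `true` (the documented tie rule).
#'
#' When the targets contain a single class the stump is degenerate: it
#' predicts the majority (only) class constantly and is flagged via
#' `degenerate = TRUE`.
#'
#' @param node_id evidence node id the stump serves.
#' @param values numeric feature values (training windows).
#' @param targets logical target states.
#' @return List of class `evidence_stump`: `node_id`, `feature` (filled by
#'   [fit_stump_bank()]; `NA` here), `threshold`, `polarity`,
#'   `train_accuracy`, `degenerate`.
#' @export
fit_stump <- function(node_id, values, targets) {
  stopifnot(length(values) == length(targets), length(values) >= 1L)
  ok <- is.finite(values) & !is.na(targets)
  values <- values[ok]; targets <- as.logical(targets[ok])
  n <- length(values)
  if (n == 0L || length(unique(targets)) < 2L) {
    maj <- if (n == 0L) TRUE else mean(targets) >= 0.5
    return(structure(list(
      node_id = node_id, feature = NA_character_,
      threshold = if (maj) -Inf else Inf, polarity = "ge",
      train_accuracy = if (n == 0L) NA_real_ else max(mean(targets), 1 - mean(targets)),
      degenerate = TRUE), class = "evidence_stump"))
  }
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- list(acc = -1)
  for (thr in cand) {
    for (pol in c("ge", "le")) {
      pred <- if (pol == "ge") values >= thr else values <= thr
      acc <- mean(pred == targets)
      if (acc > best$acc + 1e-12) best <- list(acc = acc, thr = thr, pol = pol)
    }
  }
  structure(list(node_id = node_id, feature = NA_character_,
                 threshold = best$thr, polarity = best$pol,
                 train_accuracy = best$acc, degenerate = FALSE),
            class = "evidence_stump")
}

#' Predict an evidence state from a feature map
#'
#' @param stump an `evidence_stump`.
#' @param features named numeric vector (or single-row data.frame) of
#'   window features.
#' @return `TRUE`/`FALSE`, or `NA` (evidence unavailable) when the required
#'   feature is missing or not finite; inference treats `NA` as absent
#'   evidence and marginalizes the node out.
#' @export
predict_evidence <- function(stump, features) {
  f <- stump$feature
  v <- if (is.na(f)) NA_real_ else {
    if (is.data.frame(features)) features[[f]][1] else unname(features[f])
  }
  if (is.null(v) || length(v) == 0L || is.na(v) || !is.finite(v)) {
    if (stump$degenerate && is.na(f)) return(stump$threshold == -Inf)
    return(NA)
  }
  if (stump$polarity == "ge") v >= stump$threshold else v <= stump$threshold
}

#' Fit the full stump bank of a structure
#'
#' Fits one stump per evidence node of `s`, using the feature the structure
#' wires to that node and, as target, the true state of the node's parent
#' context for each training window.
#'
#' @param s an `mbn_structure`.
#' @param windows window feature data.frame from [segment_windows()].
#' @param contexts data.frame of true context states, one row per window
#'   (aligned with `windows`), one logical column per inference/query node.
#' @return Named list (by evidence node id) of `evidence_stump` objects.
#' @export
fit_stump_bank <- function(s, windows, contexts) {
  stopifnot(nrow(windows) == nrow(contexts))
  parents <- node_parents(s)
  ev <- s$nodes[s$nodes$role == "evidence", , drop = FALSE]
  bank <- vector("list", nrow(ev))
  names(bank) <- ev$id
  for (i in seq_len(nrow(ev))) {
    feat <- ev$feature[i]
    parent <- parents[[ev$id[i]]]
    vals <- if (feat %in% names(windows)) windows[[feat]]
            else rep(NA_real_, nrow(windows))
    st <- fit_stump(ev$id[i], vals, contexts[[parent]])
    st$feature <- feat
    bank[[i]] <- st
  }
  bank
}

#' Predict evidence states for a batch of windows
#'
#' @param bank stump bank from [fit_stump_bank()].
#' @param windows window feature data.frame.
#' @return Logical matrix, one row per window, one column per evidence node;
#'   `NA` marks unavailable evidence.
#' @export
predict_evidence_bank <- function(bank, windows) {
  out <- matrix(NA, nrow = nrow(windows), ncol = length(bank),
                dimnames = list(NULL, names(bank)))
  for (id in names(bank)) {
    st <- bank[[id]]
    if (is.na(st$feature) || !(st$feature %in% names(windows))) {
      if (st$degenerate) out[, id] <- st$threshold == -Inf
      next
    }
    v <- windows[[st$feature]]
    pred <- if (st$polarity == "ge") v >= st$threshold else v <= st$threshold
    pred[!is.finite(v)] <- NA
    out[, id] <- pred
  }
  out
}

#' @export
print.evidence_stump <- function(x, ...) {
  cat(sprintf("stump[%s]: %s %s %.4g -> true (train acc %.3f%s)\n",
              x$node_id, if (is.na(x$feature)) "<feature>" else x$feature,
              if (x$polarity == "ge") ">=" else "<=", x$threshold,
              x$train_accuracy, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
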