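# Windowing of raw multi-rate sensor logs, per-window features, and
# attribute-vs-class scoring (Pearson, information gain, gain ratio,
# symmetric uncertainty).

#' Activity vocabulary
#'
#' The ten labelled daily activities; indices 4 ("eating, dinnerware") and
#' 5 ("eating, other") are the positive class.
#' @format Named integer vector.
#' @export
eatbn_activities <- stats::setNames(1:10, c(
  "washing", "walking", "housework", "eating_dinnerware", "eating_etc",
  "conversation", "driving", "sedentary_work", "subway", "piano"))

#' Indices of the eating activities
#' @export
eating_labels <- c(4L, 5L)

#' Read / write a sensor log CSV
#'
#' Dialect: UTF-8, header `timestamp,channel,value,label`, one row per
#' sample; `timestamp` in seconds, `channel` one of [eatbn_channels],
#' `label` an activity index 1-10.
#'
#' @param path file path.
#' @param records data.frame of sensor records.
#' @return `read_sensor_csv` returns a data.frame of records.
#' @export
read_sensor_csv <- function(path) {
  rec <- data.table::fread(path, header = TRUE, sep = ",",
                           skip = "timestamp")  # tolerate leading "# ..." comments
  need <- c("timestamp", "channel", "value", "label")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("sensor CSV missing column(s): ", paste(miss, collapse = ", "))
  rec[, channel := as.character(channel)]
  as.data.frame(rec[, need, with = FALSE])
}

#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

.check_records <- function(records) {
  bad <- setdiff(unique(records$channel), eatbn_channels)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (!all(records$label %in% 1:10))
    stop("labels must be activity indices 1-10")
  for (ch in unique(records$channel)) {
    ts <- records$timestamp[records$channel == ch]
    d <- diff(ts)
    if (length(d) && any(d < 0)) {
      i <- which(d < 0)[1]
      stop("timestamps not sorted on channel ", ch, " at index ", i + 1L)
    }
  }
  invisible(TRUE)
}

#' Segment sensor records into feature windows
#'
#' Cuts the stream into non-overlapping, left-closed right-open windows
#' `[t, t + window_s)` aligned to multiples of `window_s`. A window is kept
#' only if every one of the nine channels contributed at least one sample.
#' Each window carries the majority activity label of its records (ties
#' resolved toward the smaller activity index) and the feature map of
#' [compute_features()].
#'
#' @param records data.frame with columns `timestamp`, `channel`, `value`,
#'   `label` (see [read_sensor_csv()]).
#' @param window_s window length in seconds (default 1, the period of the
#'   slowest channels).
#' @return data.frame with one row per complete window: `window_start`,
#'   `label`, `is_eating`, then one column per feature.
#' @export
segment_windows <- function(records, window_s = 1) {
  stopifnot(window_s > 0)
  empty <- data.frame(window_start = numeric(), label = integer(),
                      is_eating = logical())
  if (is.null(records) || nrow(records) == 0L) return(empty)
  .check_records(records)
  dt <- data.table::as.data.table(records)
  dt[, window_start := floor(timestamp / window_s) * window_s]
  # completeness: all nine channels present
  nch <- dt[, list(nch = data.table::uniqueN(channel)), by = window_start]
  keep <- nch$window_start[nch$nch == length(eatbn_channels)]
  if (length(keep) == 0L) return(empty)
  dt <- dt[window_start %in% keep]

  stat <- dt[, list(mean = mean(value), sd = .sd0(value),
                    range = diff(range(value))),
             by = list(window_start, channel)]
  long <- data.table::melt(stat, id.vars = c("window_start", "channel"),
                           variable.name = "stat", value.name = "value",
                           variable.factor = FALSE)
  # accelerometers contribute mean/sd/range; environmental channels mean only
  long <- long[channel %in% .acc_channels | stat == "mean"]
  long[, feature := paste(channel, stat, sep = "_")]
  wide <- data.table::dcast(long, window_start ~ feature, value.var = "value")
  wide[, time_of_day := (window_start %% 86400) / 3600]

  lab <- dt[, list(label = .majority_label(label)), by = window_start]
  out <- merge(lab, wide, by = "window_start")
  data.table::setorder(out, window_start)
  out <- as.data.frame(out)
  out$is_eating <- out$label %in% eating_labels
  feat_cols <- setdiff(names(out), c("window_start", "label", "is_eating"))
  out[, c("window_start", "label", "is_eating", sort(feat_cols))]
}

# sd with the single-sample case defined as 0 (a one-sample window has no
# spread, not an undefined one)
.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

.majority_label <- function(labels) {
  tab <- table(labels)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)  # tie -> earlier activity index
}

#' Per-window features of one raw sample window
#'
#' Features: per accelerometer channel the mean, standard deviation and
#' range; per environmental channel (illuminance, temperature, humidity)
#' the mean; plus `time_of_day` (hours since midnight of `window_start`).
#' Deterministic in the samples; invariant to record order.
#'
#' @param samples data.frame with columns `channel`, `value`.
#' @param window_start window start time in seconds (feeds `time_of_day`).
#' @return Named numeric vector of features.
#' @export
compute_features <- function(samples, window_start = 0) {
  out <- c(time_of_day = (window_start %% 86400) / 3600)
  for (ch in intersect(eatbn_channels, unique(samples$channel))) {
    v <- samples$value[samples$channel == ch]
    out[[paste0(ch, "_mean")]] <- mean(v)
    if (ch %in% .acc_channels) {
      out[[paste0(ch, "_sd")]] <- .sd0(v)
      out[[paste0(ch, "_range")]] <- diff(range(v))
    }
  }
  out
}

# Equal-frequency bins with deterministic tie handling: equal values always
# share the bin of the first element of their tied run in value order.
.equal_freq_bins <- function(a, n_bins) {
  ord <- order(a)
  prov <- ceiling(seq_along(a) * n_bins / length(a))
  sorted <- a[ord]
  binv <- prov[match(sorted, sorted)]
  bins <- integer(length(a))
  bins[ord] <- binv
  bins
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Score an attribute against the eating class
#'
#' Computes the four standard filter scores of an attribute `a` against the
#' binary class `c`: the sample Pearson correlation (class coded eating = 1),
#' and after equal-frequency discretization of `a` into `n_bins` bins
#' (ties broken by value order), the information gain
#' `H(C) - H(C|A)`, the gain ratio `(H(C) - H(C|A)) / H(A)` (0 when
#' `H(A) = 0`), and the symmetric uncertainty
#' `2 (H(C) - H(C|A)) / (H(C) + H(A))` (0 when both entropies vanish).
#' Entropies in bits.
#'
#' @param a numeric attribute values.
#' @param c class labels: logical, or coercible to logical via
#'   `label %in% eating_labels` when integer activity indices are given.
#' @param n_bins number of equal-frequency bins (default 10).
#' @return List of class `attribute_score` with elements `pearson`,
#'   `info_gain`, `gain_ratio`, `sym_uncert`.
#' @export
score_attribute <- function(a, c, n_bins = 10) {
  if (length(a) != length(c))
    stop("length mismatch: length(a) = ", length(a),
         ", length(c) = ", length(c))
  stopifnot(length(a) >= 2L, n_bins >= 2L)
  cl <- if (is.logical(c)) c else as.integer(c) %in% eating_labels
  y <- as.numeric(cl)
  pearson <- if (stats::sd(a) == 0 || stats::sd(y) == 0) 0
             else stats::cor(a, y)
  bins <- .equal_freq_bins(a, n_bins)
  joint <- table(bins, cl) / length(a)
  pa <- rowSums(joint)
  pc <- colSums(joint)
  h_c <- .entropy2(pc)
  h_a <- .entropy2(pa)
  # conditional entropy H(C|A) over the discretized attribute
  h_c_given_a <- sum(vapply(seq_along(pa), function(i) {
    if (pa[i] == 0) return(0)
    pa[i] * .entropy2(joint[i, ] / pa[i])
  }, numeric(1)))
  ig <- max(0, h_c - h_c_given_a)
  structure(list(
    pearson = pearson,
    info_gain = ig,
    gain_ratio = if (h_a == 0) 0 else ig / h_a,
    sym_uncert = if (h_c + h_a == 0) 0 else 2 * ig / (h_c + h_a)
  ), class = "attribute_score")
}

#' @export
print.attribute_score <- function(x, ...) {
  cat(sprintf("attribute score: pearson %.4f, info gain %.4f bits, gain ratio %.4f, sym. uncertainty %.4f\n",
              x$pearson, x$info_gain, x$gain_ratio, x$sym_uncert))
  invisible(x)
}
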