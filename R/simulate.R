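# Seed-deterministic simulator for the nine-channel sensor stream: activity
# emission profiles, subject heterogeneity (handedness, age, gain/offset,
# dropout), bout scheduling, and per-window ground-truth context states.
# Also provides ancestral sampling from a fitted/known model for
# parameter-recovery checks.

# Per-activity truth of the 15 low-level context properties
# (TRUE = consistent with eating). Rows follow eatbn_activities order.
.context_truth_table <- function() {
  props <- c("position_of_hand", "dinnerware", "movement_of_hand",
             "posture_body", "move_stop_body", "movement_of_body",
             "body_temperature", "posture_operation", "humidity_of_hand",
             "existence_of_food", "eating_place", "indoor_outdoor",
             "move_stop_space", "illuminance_of_space", "eating_time")
  m <- matrix(c(
    # pos  din  mov  post msB  movB btmp psOp humH food plac ind  msS  illu time
      0,   0,   1,   0,   1,   1,   0,   0,   1,   0,   0,   1,   1,   1,   0, # washing
      0,   0,   0,   0,   0,   0,   1,   0,   0,   0,   0,   0,   0,   0,   0, # walking
      0,   0,   1,   0,   0,   0,   1,   0,   1,   0,   1,   1,   1,   1,   0, # housework
      1,   1,   1,   1,   1,   1,   1,   1,   1,   1,   1,   1,   1,   1,   1, # eating (dinnerware)
      1,   0,   0,   1,   1,   1,   1,   1,   1,   1,   0,   0,   1,   0,   1, # eating (etc.)
      0,   0,   0,   1,   1,   1,   1,   1,   0,   0,   1,   1,   1,   1,   1, # conversation
      0,   0,   0,   1,   1,   0,   1,   1,   0,   0,   0,   0,   0,   0,   0, # driving
      1,   0,   0,   1,   1,   1,   1,   1,   0,   0,   1,   1,   1,   1,   1, # sedentary work
      0,   0,   0,   1,   1,   1,   1,   0,   0,   0,   0,   1,   0,   0,   0, # subway
      1,   0,   1,   1,   1,   1,   1,   1,   0,   0,   1,   1,   1,   1,   0  # piano
  ), nrow = 10, byrow = TRUE, dimnames = list(names(eatbn_activities), props))
  m > 0
}

# Fill intermediate-node truths bottom-up: a parent context holds when the
# majority of its child contexts hold.
.full_context_truth <- function() {
  tab <- .context_truth_table()
  hier <- .default_hierarchy()
  for (p in rev(names(hier))) {
    kids <- hier[[p]]
    tab <- cbind(tab, rowMeans(tab[, kids, drop = FALSE]) >= 0.5)
    colnames(tab)[ncol(tab)] <- p
  }
  tab
}

# channel emission spec per activity: mean, sd, sinusoid amplitude, period (s)
.emission_table <- function() {
  spec <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE,
                dimnames = list(eatbn_channels, c("mean", "sd", "amp", "period")))
    as.data.frame(m)
  }
  list(
    washing = spec(3.0, 1.0, 1.0, 1.5,   4.0, 1.2, 1.5, 2.0,   8.0, 1.0, 0, 1,
                   420, 90, 0, 1,   24, 1.0, 0, 1,   20, 3.0, 0, 1,
                   1.0, 0.5, 0, 1,   2.0, 0.5, 0, 1,   9.5, 0.5, 0, 1),
    walking = spec(2.5, 2.2, 1.5, 0.55,   3.0, 2.0, 1.2, 0.55,   8.5, 2.0, 1.0, 0.55,
                   5000, 2200, 0, 1,   18, 1.5, 0, 1,   10, 2.0, 0, 1,
                   2.0, 2.8, 2.0, 0.55,   3.0, 2.8, 1.8, 0.55,   9.0, 2.5, 1.5, 0.55),
    housework = spec(3.0, 1.8, 0.8, 1.2,   3.5, 1.8, 0.8, 1.6,   8.0, 1.5, 0, 1,
                     350, 80, 0, 1,   23, 1.0, 0, 1,   11, 2.0, 0, 1,
                     1.5, 1.2, 0, 1,   2.0, 1.2, 0, 1,   9.3, 1.0, 0, 1),
    eating_dinnerware = spec(2.0, 0.9, 0.6, 3.2,   5.0, 1.2, 2.2, 3.2,   7.5, 0.9, 0.8, 3.2,
                             320, 70, 0, 1,   24, 0.8, 0, 1,   12, 1.5, 0, 1,
                             0.3, 0.15, 0, 1,   0.6, 0.15, 0, 1,   9.7, 0.2, 0, 1),
    eating_etc = spec(1.2, 0.35, 0.2, 4.5,   6.0, 0.5, 0.8, 4.5,   7.2, 0.4, 0.3, 4.5,
                      2500, 800, 0, 1,   19, 1.2, 0, 1,   9, 1.5, 0, 1,
                      0.4, 0.3, 0, 1,   0.7, 0.3, 0, 1,   9.6, 0.3, 0, 1),
    conversation = spec(2.0, 0.6, 0.3, 2.5,   3.0, 0.8, 0.6, 2.5,   8.5, 0.6, 0, 1,
                        300, 70, 0, 1,   23, 0.8, 0, 1,   10, 1.5, 0, 1,
                        0.4, 0.2, 0, 1,   0.7, 0.2, 0, 1,   9.7, 0.25, 0, 1),
    driving = spec(4.0, 0.7, 0.3, 0.8,   2.0, 0.7, 0.3, 0.8,   8.0, 0.8, 0.5, 0.8,
                   800, 250, 0, 1,   21, 1.0, 0, 1,   9, 1.5, 0, 1,
                   1.0, 0.8, 0.5, 0.8,   1.5, 0.8, 0.5, 0.8,   9.4, 0.8, 0.5, 0.8),
    sedentary_work = spec(1.5, 0.5, 0.2, 2.0,   2.5, 0.6, 0.3, 2.0,   9.0, 0.5, 0, 1,
                          450, 90, 0, 1,   24, 0.8, 0, 1,   10, 1.5, 0, 1,
                          0.2, 0.15, 0, 1,   0.4, 0.15, 0, 1,   9.75, 0.15, 0, 1),
    subway = spec(2.5, 1.0, 0.4, 1.2,   3.0, 1.0, 0.4, 1.2,   8.5, 1.0, 0.6, 1.2,
                  250, 70, 0, 1,   22, 1.0, 0, 1,   10, 1.5, 0, 1,
                  1.2, 1.0, 0.6, 1.2,   1.8, 1.0, 0.6, 1.2,   9.3, 1.0, 0.6, 1.2),
    piano = spec(2.0, 1.2, 0.8, 0.7,   4.0, 1.5, 1.8, 0.7,   8.0, 1.0, 0.5, 0.7,
                 380, 80, 0, 1,   23, 0.8, 0, 1,   10, 1.5, 0, 1,
                 0.3, 0.15, 0, 1,   0.5, 0.15, 0, 1,   9.75, 0.2, 0, 1)
  )
}

#' Default activity emission and context profiles
#'
#' One profile per activity of [eatbn_activities]: the per-channel Gaussian
#' emission parameters with an optional sinusoidal component (mean, sd,
#' amplitude, period in seconds), the truth states of every intermediate
#' context node the activity implies, the query truth (`is_eating`), and
#' the hours of day at which bouts of the activity are scheduled.
#'
#' @return Named list of profiles, each with elements `activity`, `index`,
#'   `channels` (data.frame), `contexts` (named logical), `is_eating`,
#'   `hours` (range, or matrix of meal-time mixture components).
#' @export
default_activity_profiles <- function() {
  emis <- .emission_table()
  truth <- .full_context_truth()
  meals <- matrix(c(8, 0.7, 12.5, 1.0, 19, 1.0), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("mean", "sd")))
  lapply(stats::setNames(names(eatbn_activities), names(eatbn_activities)),
         function(a) {
    idx <- eatbn_activities[[a]]
    list(activity = a, index = idx, channels = emis[[a]],
         contexts = truth[a, ], is_eating = idx %in% eating_labels,
         hours = if (idx %in% eating_labels) meals else c(7, 23))
  })
}

#' Generate a cohort of subject profiles
#'
#' Subject heterogeneity: handedness (left-handed with probability
#' `p_left`), an age band, a per-channel multiplicative gain (log-normal
#' around 1) and additive offset, and per-channel dropout rates. A
#' left-handed subject wears the device on the other wrist, which lowers
#' and steadies the wrist x-axis and makes y/z more irregular.
#'
#' @param n number of subjects.
#' @param seed integer seed (sub-seeds are derived deterministically).
#' @param p_left probability of left-handedness (default 0.1).
#' @param dropout per-sample dropout probability applied to every channel
#'   (default 0.02); may be a named vector by channel.
#' @return data.frame with one row per subject plus list-columns `gain`,
#'   `offset`, `dropout`.
#' @export
make_subjects <- function(n, seed, p_left = 0.1, dropout = 0.02) {
  stopifnot(n >= 1)
  set.seed(seed)
  drop <- rep(dropout, length.out = length(eatbn_channels))
  if (!is.null(names(dropout))) {
    drop <- stats::setNames(rep(0.02, length(eatbn_channels)), eatbn_channels)
    drop[names(dropout)] <- dropout
  } else names(drop) <- eatbn_channels
  stopifnot(all(drop >= 0 & drop <= 1))
  out <- data.frame(
    subject = seq_len(n),
    handedness = ifelse(stats::runif(n) < p_left, "left", "right"),
    age_band = sample(c("0-10", "20-30", "30-40", "40-50", "50-60", "60+"),
                      n, replace = TRUE,
                      prob = c(0.08, 0.36, 0.08, 0.12, 0.32, 0.04)),
    stringsAsFactors = FALSE)
  out$gain <- lapply(seq_len(n), function(i)
    stats::setNames(exp(stats::rnorm(length(eatbn_channels), 0, 0.08)),
                    eatbn_channels))
  # offsets on channel scale: small for accelerometers, larger for lux
  out$offset <- lapply(seq_len(n), function(i)
    stats::setNames(stats::rnorm(9, 0, c(0.2, 0.2, 0.2, 30, 0.6, 0.6,
                                         0.2, 0.2, 0.2)), eatbn_channels))
  out$dropout <- lapply(seq_len(n), function(i) drop)
  out
}

# left-handed wear modifies the wrist accelerometer pattern
.handed_adjust <- function(channels, handedness) {
  if (handedness != "left") return(channels)
  channels["h_acc_x", "mean"] <- 0.4 * channels["h_acc_x", "mean"]
  channels["h_acc_x", "sd"] <- 0.5 * channels["h_acc_x", "sd"]
  channels["h_acc_x", "amp"] <- 0.3 * channels["h_acc_x", "amp"]
  channels[c("h_acc_y", "h_acc_z"), "sd"] <-
    1.6 * channels[c("h_acc_y", "h_acc_z"), "sd"]
  channels
}

#' Generate a labelled multi-channel sensor stream with context annotations
#'
#' Simulates the nine channels at their native rates (20 Hz accelerometers,
#' 1 Hz environmental sensors): activities are scheduled as bouts whose
#' class is drawn so the expected eating share equals `eating_fraction`
#' (eating bouts split 11:6 between dinnerware and other eating, mirroring
#' the cohort composition); eating bouts are placed near meal hours. Each
#' sample is Gaussian around the activity profile with an optional
#' sinusoidal component, modulated by the subject's gain/offset and
#' handedness, then thinned by per-channel dropout. Alongside the stream,
#' the per-second truth state of every intermediate context node is
#' emitted (profile truth flipped independently with probability
#' `context_flip`); the query truth is the activity class itself.
#' Fully deterministic given `seed`.
#'
#' @param n_subjects number of simulated subjects (default 25).
#' @param minutes_per_subject minutes of data per subject (default 38, so
#'   the default cohort totals 950 min).
#' @param eating_fraction expected eating share of bouts (default 0.4727).
#' @param seed integer seed.
#' @param profiles activity profiles, see [default_activity_profiles()].
#' @param subjects optional cohort from [make_subjects()]; generated from
#'   `seed` when `NULL`.
#' @param context_flip per-window flip probability of intermediate context
#'   truths (default 0.05).
#' @param dropout default per-sample dropout rate when `subjects` is `NULL`.
#' @return List with `records` (sensor log data.frame: `timestamp`,
#'   `channel`, `value`, `label`, `subject`), `contexts` (one row per
#'   second: `window_start`, `subject`, `label`, plus one logical column
#'   per inference node and the query node `eating`), and `subjects`.
#' @export
generate_dataset <- function(n_subjects = 25, minutes_per_subject = 38,
                             eating_fraction = 0.4727, seed,
                             profiles = default_activity_profiles(),
                             subjects = NULL, context_flip = 0.05,
                             dropout = 0.02) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_subjects >= 1, minutes_per_subject > 0,
            eating_fraction > 0, eating_fraction < 1)
  if (is.null(subjects))
    subjects <- make_subjects(n_subjects, seed = seed + 1000L,
                              dropout = dropout)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  node_cols <- c(colnames(.full_context_truth()), "eating")
  non_eating <- setdiff(1:10, eating_labels)

  rec_list <- list(); ctx_list <- list()
  for (si in seq_len(n_subjects)) {
    set.seed(subseeds[si])
    sub <- subjects[si, ]
    total <- 0; bouts <- list()
    while (total < minutes_per_subject * 60) {
      eat <- stats::runif(1) < eating_fraction
      act <- if (eat) sample(eating_labels, 1, prob = c(11, 6) / 17)
             else sample(non_eating, 1)
      prof <- profiles[[names(eatbn_activities)[act]]]
      hour <- if (is.matrix(prof$hours)) {
        m <- prof$hours[sample.int(nrow(prof$hours), 1), ]
        stats::rnorm(1, m[["mean"]], m[["sd"]])
      } else stats::runif(1, prof$hours[1], prof$hours[2])
      dur <- sample(30:90, 1)
      dur <- min(dur, ceiling(minutes_per_subject * 60 - total))
      bouts[[length(bouts) + 1L]] <- list(act = act, hour = hour, dur = dur)
      total <- total + dur
    }
    bouts <- bouts[order(vapply(bouts, `[[`, numeric(1), "hour"))]
    base <- (si - 1) * 86400
    t_cursor <- base
    for (b in bouts) {
      start <- max(t_cursor, floor(base + b$hour * 3600))
      t_cursor <- start + b$dur
      prof <- profiles[[names(eatbn_activities)[b$act]]]
      chans <- .handed_adjust(prof$channels, sub$handedness)
      gain <- sub$gain[[1]]; offs <- sub$offset[[1]]; drop <- sub$dropout[[1]]
      for (ch in eatbn_channels) {
        hz <- if (ch %in% .acc_channels) 20 else 1
        ts <- start + seq_len(b$dur * hz) / hz - 1 / hz
        p <- chans[ch, ]
        v <- p$mean + p$amp * sin(2 * pi * (ts - start) / p$period) +
          stats::rnorm(length(ts), 0, p$sd)
        v <- gain[[ch]] * v + offs[[ch]]
        keep <- stats::runif(length(ts)) >= drop[[ch]]
        if (!any(keep)) next
        rec_list[[length(rec_list) + 1L]] <- data.frame(
          timestamp = ts[keep], channel = ch, value = v[keep],
          label = b$act, subject = sub$subject, stringsAsFactors = FALSE)
      }
      secs <- start + seq_len(b$dur) - 1L
      truth <- prof$contexts
      flips <- matrix(stats::runif(b$dur * length(truth)) < context_flip,
                      nrow = b$dur)
      ctx <- matrix(rep(truth, each = b$dur), nrow = b$dur,
                    dimnames = list(NULL, names(truth)))
      ctx <- xor(ctx, flips)
      ctx_list[[length(ctx_list) + 1L]] <- data.frame(
        window_start = secs, subject = sub$subject, label = b$act,
        ctx, eating = prof$is_eating, stringsAsFactors = FALSE)
    }
  }
  records <- as.data.frame(data.table::rbindlist(rec_list))
  records <- records[order(records$channel, records$timestamp), ]
  rownames(records) <- NULL
  contexts <- as.data.frame(data.table::rbindlist(ctx_list))
  contexts <- contexts[order(contexts$window_start), ]
  rownames(contexts) <- NULL
  stopifnot(all(node_cols %in% names(contexts)))
  list(records = records, contexts = contexts, subjects = subjects)
}

#' Ancestral sampling from a model's CPTs
#'
#' Draws joint node-state samples root-to-leaves along the tree. Used for
#' parameter-recovery checks: counts refit from the samples converge to
#' the generating CPTs.
#'
#' @param model an `mbn_model`.
#' @param n_samples number of joint samples.
#' @param seed integer seed.
#' @return data.frame of state labels, one row per sample, one column per
#'   node (topological order, query first).
#' @export
generate_from_bn <- function(model, n_samples, seed) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  s <- model$structure
  topo <- model$topo
  parents <- model$parents
  out <- stats::setNames(vector("list", length(topo)), topo)
  idx <- stats::setNames(vector("list", length(topo)), topo)
  for (id in topo) {
    cpt <- model$cpts[[id]]
    k <- ncol(cpt)
    u <- stats::runif(n_samples)
    p <- parents[[id]]
    if (is.na(p)) {
      cum <- cumsum(cpt[1, ])
      ix <- findInterval(u, cum[-k]) + 1L
    } else {
      cum <- t(apply(cpt, 1, cumsum))
      pc <- cum[idx[[p]], -k, drop = FALSE]
      ix <- rowSums(u > pc) + 1L
    }
    idx[[id]] <- ix
    out[[id]] <- s$states[[id]][ix]
  }
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}
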