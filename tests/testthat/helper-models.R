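# Shared fixtures: random tree models, random evidence, tiny hand-built
# structures, and a miniature synthetic sensor stream.

# Random tree-structured binary model: node 1 is the query/root, every later
# node attaches to a uniformly chosen earlier node; leaves are evidence
# nodes, internal nodes inference nodes. CPT rows drawn uniformly inside
# prob_range (both columns positive so every posterior is well defined).
random_tree_model <- function(n_nodes, seed, prob_range = c(0.05, 0.95)) {
  set.seed(seed)
  ids <- c("q", if (n_nodes > 1) paste0("n", seq_len(n_nodes - 1) + 1L))
  parent_idx <- c(NA, if (n_nodes > 1)
    vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), integer(1)))
  edges <- data.frame(parent = ids[parent_idx[-1]], child = ids[-1],
                      stringsAsFactors = FALSE)
  has_child <- ids %in% edges$parent
  roles <- ifelse(ids == "q", "query", ifelse(has_child, "inference", "evidence"))
  nodes <- data.frame(id = ids, role = roles, module = "main",
                      feature = NA_character_, stringsAsFactors = FALSE)
  s <- mbn_structure(nodes, edges,
                     modules = list(main = list(id = "main", root = "q",
                                                nodes = ids)))
  cpts <- setNames(lapply(ids, function(id) {
    rows <- if (id == "q") 1L else 2L
    p_true <- runif(rows, prob_range[1], prob_range[2])
    m <- cbind(true = p_true, false = 1 - p_true)
    rownames(m) <- if (id == "q") "(root)" else c("true", "false")
    m
  }), ids)
  class(cpts) <- "cpt_bank"
  attr(cpts, "alpha") <- 1
  mbn_model(s, cpts)
}

# Random partial evidence over a model's evidence nodes.
random_evidence <- function(model, seed, p_observe = 0.6) {
  set.seed(seed)
  ev_ids <- model$structure$nodes$id[model$structure$nodes$role == "evidence"]
  obs <- ev_ids[runif(length(ev_ids)) < p_observe]
  setNames(as.list(sample(c("true", "false"), length(obs), replace = TRUE)),
           obs)
}

# Three-node chain q -> i -> e with hand-set CPTs (used against hand
# arithmetic on the 8 joint entries).
chain_model <- function(p_q = 0.6, p_i = c(0.8, 0.3), p_e = c(0.9, 0.2)) {
  nodes <- data.frame(id = c("q", "i", "e"),
                      role = c("query", "inference", "evidence"),
                      module = "main", feature = NA_character_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = c("q", "i"), child = c("i", "e"),
                      stringsAsFactors = FALSE)
  s <- mbn_structure(nodes, edges,
                     modules = list(main = list(id = "main", root = "q",
                                                nodes = c("q", "i", "e"))))
  cpts <- list(
    q = matrix(c(p_q, 1 - p_q), 1, dimnames = list("(root)", c("true", "false"))),
    i = matrix(c(p_i, 1 - p_i), 2, dimnames = list(c("true", "false"),
                                                   c("true", "false"))),
    e = matrix(c(p_e, 1 - p_e), 2, dimnames = list(c("true", "false"),
                                                   c("true", "false"))))
  class(cpts) <- "cpt_bank"
  mbn_model(s, cpts)
}

# Nominal-rate sensor records: every channel at its native frequency for
# `seconds` seconds, constant-ish values, one activity label.
nominal_records <- function(seconds, label = 4L, t0 = 0, value = 1) {
  recs <- lapply(eatbn_channels, function(ch) {
    hz <- if (ch %in% c("h_lux", "h_temp", "h_hum")) 1 else 20
    ts <- t0 + seq_len(seconds * hz) / hz - 1 / hz
    data.frame(timestamp = ts, channel = ch, value = value, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# A small simulated training set shared by slower tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(n_subjects = 4, minutes_per_subject = 5, seed = 42)
      w <- segment_windows(ds$records)
      ctx <- ds$contexts[match(w$window_start, ds$contexts$window_start), ]
      cache <<- list(ds = ds, windows = w, contexts = ctx)
    }
    cache
  }
})
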