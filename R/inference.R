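# Exact inference on the modular tree: upward/downward message passing with
# marginalization of absent evidence, plus a full-enumeration oracle and the
# threshold decision rule.

#' Bundle a structure and CPT bank into a recognizer model
#'
#' @param structure an `mbn_structure` (must validate cleanly).
#' @param cpts a `cpt_bank` from [finalize_cpts()].
#' @param stumps optional stump bank from [fit_stump_bank()].
#' @param threshold decision threshold on the eating posterior (default 0.6).
#' @param alpha smoothing pseudo-count the CPTs were finalized with.
#' @return Object of class `mbn_model`.
#' @export
mbn_model <- function(structure, cpts, stumps = NULL, threshold = 0.6,
                      alpha = attr(cpts, "alpha")) {
  v <- validate_structure(structure)
  if (length(v))
    stop("invalid structure: ", v[1])
  stopifnot(threshold >= 0, threshold <= 1)
  topo <- names(igraph::topo_sort(
    igraph::graph_from_data_frame(structure$edges, directed = TRUE,
                                  vertices = data.frame(name = structure$nodes$id))))
  base::structure(list(structure = structure, cpts = cpts, stumps = stumps,
                       threshold = threshold,
                       alpha = if (is.null(alpha)) NA_real_ else alpha,
                       topo = topo,
                       children = .children_of(structure),
                       parents = node_parents(structure)),
                  class = "mbn_model")
}

.children_of <- function(s) {
  split(s$edges$child, factor(s$edges$parent, levels = s$nodes$id))
}

.check_evidence <- function(s, ev) {
  ev <- ev[!vapply(ev, function(x) length(x) == 0L || is.na(x), logical(1))]
  if (length(ev) == 0L) return(list())
  roles <- stats::setNames(s$nodes$role, s$nodes$id)
  bad <- setdiff(names(ev), s$nodes$id[roles == "evidence"])
  if (length(bad))
    stop("evidence on non-evidence node(s): ", paste(bad, collapse = ", "))
  for (id in names(ev)) {
    st <- .states_of(ev[[id]])
    if (!(st %in% s$states[[id]]))
      stop("state '", st, "' not in state list of node ", id)
    ev[[id]] <- st
  }
  ev
}

# Upward (lambda) pass: for each node, the likelihood of the evidence in its
# subtree as a function of the node's own state. Messages are renormalized to
# a unit maximum for numerical stability; the final posterior normalization
# absorbs the constants.
.lambda_pass <- function(model, ev) {
  s <- model$structure
  children <- model$children
  order <- rev(model$topo)
  lam <- stats::setNames(vector("list", nrow(s$nodes)), s$nodes$id)
  for (id in order) {
    states <- s$states[[id]]
    l <- stats::setNames(rep(1, length(states)), states)
    if (!is.null(ev[[id]])) {
      l[] <- 0
      l[ev[[id]]] <- 1
    }
    for (ch in children[[id]]) {
      cpt <- model$cpts[[ch]]          # rows: states of id, cols: states of ch
      l <- l * as.vector(cpt[states, , drop = FALSE] %*% lam[[ch]])
    }
    m <- max(l)
    if (m > 0) l <- l / m
    lam[[id]] <- l
  }
  lam
}

#' Posterior of the query node given (possibly partial) evidence
#'
#' Exact inference by message passing on the tree: each submodule's
#' evidence is summarized into a likelihood message at its shared root,
#' the main module combines the four messages with the class prior, and a
#' downward pass recovers the posterior marginal of each shared node.
#' Evidence nodes not present in `ev` (or set `NA`) are marginalized out.
#' The result is invariant to the order in which submodules are processed.
#'
#' @param model an `mbn_model`.
#' @param ev named list/vector of observed evidence states (`"true"`/
#'   `"false"` or logical), keyed by evidence node id; absent evidence is
#'   simply omitted.
#' @param threshold decision threshold; defaults to the model's.
#' @return Object of class `posterior_report`: `query_posterior`
#'   (probability of eating), `shared_node_posteriors` (named vector over
#'   submodule roots), `decision` (`"eating"`/`"non-eating"`), `threshold`.
#' @export
infer_posterior <- function(model, ev = list(), threshold = model$threshold) {
  s <- model$structure
  ev <- .check_evidence(s, as.list(ev))
  lam <- .lambda_pass(model, ev)
  q <- s$nodes$id[s$nodes$role == "query"]
  qstates <- s$states[[q]]
  prior <- model$cpts[[q]][1, qstates]
  post_q <- prior * lam[[q]]
  if (sum(post_q) == 0)
    stop("evidence has zero probability under the model (alpha = 0 CPTs?)")
  post_q <- post_q / sum(post_q)

  # downward (pi) pass: posterior marginal of any node is pi * lambda
  children <- model$children
  parents <- model$parents
  shared <- vapply(s$modules[setdiff(names(s$modules), s$main_module)],
                   `[[`, character(1), "root")
  if (length(shared) == 0L) {
    return(base::structure(list(
      query_posterior = unname(post_q[[1]]),
      shared_node_posteriors = stats::setNames(numeric(0), character(0)),
      decision = classify(unname(post_q[[1]]), threshold),
      threshold = threshold), class = "posterior_report"))
  }
  topo <- model$topo
  pi_msg <- stats::setNames(vector("list", length(topo)), topo)
  pi_msg[[q]] <- prior
  for (id in topo[-match(q, topo)]) {
    p <- parents[[id]]
    b <- pi_msg[[p]]
    for (k in setdiff(children[[p]], id)) {
      cpt_k <- model$cpts[[k]]
      b <- b * as.vector(cpt_k[s$states[[p]], , drop = FALSE] %*% lam[[k]])
    }
    pi_c <- as.vector(b %*% model$cpts[[id]][s$states[[p]], , drop = FALSE])
    m <- max(pi_c)
    pi_msg[[id]] <- if (m > 0) pi_c / m else pi_c
  }
  shared_post <- stats::setNames(vapply(shared, function(r) {
    marg <- pi_msg[[r]] * lam[[r]]
    marg[[1]] / sum(marg)              # probability of first state ("true")
  }, numeric(1)), shared)
  p_eat <- unname(post_q[[1]])         # first query state = "true"/eating
  structure(list(query_posterior = p_eat,
                 shared_node_posteriors = shared_post,
                 decision = classify(p_eat, threshold),
                 threshold = threshold),
            class = "posterior_report")
}

#' Enumeration oracle for the query posterior
#'
#' Computes the same posterior by brute force: enumerates every joint
#' configuration, multiplies `P(N | Pa(N))` along the tree, zeroes
#' configurations inconsistent with the evidence, and normalizes. Intended
#' as an independent check of [infer_posterior()]; refuses joint state
#' spaces beyond `2^20`.
#'
#' @inheritParams infer_posterior
#' @return Probability that the query node is in its first state (eating).
#' @export
brute_force_posterior <- function(model, ev = list()) {
  s <- model$structure
  ev <- .check_evidence(s, as.list(ev))
  ids <- s$nodes$id
  sizes <- vapply(s$states[ids], length, integer(1))
  if (prod(sizes) > 2^20)
    stop("joint state space larger than 2^20; refusing enumeration")
  grid <- do.call(expand.grid, c(stats::setNames(
    lapply(ids, function(id) seq_along(s$states[[id]])), ids),
    list(KEEP.OUT.ATTRS = FALSE)))
  parents <- node_parents(s)
  p <- rep(1, nrow(grid))
  for (id in ids) {
    cpt <- model$cpts[[id]]
    par <- parents[[id]]
    idx <- if (is.na(par)) cbind(1L, grid[[id]]) else cbind(grid[[par]], grid[[id]])
    p <- p * cpt[idx]
    if (!is.null(ev[[id]]))
      p[grid[[id]] != match(ev[[id]], s$states[[id]])] <- 0
  }
  q <- ids[s$nodes$role == "query"]
  sum(p[grid[[q]] == 1L]) / sum(p)
}

#' Threshold decision rule
#'
#' `"eating"` iff the posterior is greater than or equal to the threshold
#' (tie at the threshold classifies as eating; the inclusive rule is also
#' the ROC sweep convention).
#'
#' @param posterior eating posterior in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`.
#' @return `"eating"` or `"non-eating"` (vectorized over `posterior`).
#' @export
classify <- function(posterior, threshold = 0.6) {
  stopifnot(all(posterior >= 0 & posterior <= 1),
            threshold >= 0, threshold <= 1)
  ifelse(posterior >= threshold, "eating", "non-eating")
}

# Batch message passing: identical math to infer_posterior, vectorized over
# windows. Messages are (n windows x n states) matrices; rows renormalized
# to unit maximum. Evidence nodes are leaves, given as a logical matrix
# (NA = absent evidence, marginalized out).
.batch_posteriors <- function(model, evmat) {
  s <- model$structure
  n <- nrow(evmat)
  children <- model$children
  parents <- model$parents
  roles <- stats::setNames(s$nodes$role, s$nodes$id)
  lam <- stats::setNames(vector("list", length(model$topo)), model$topo)
  for (id in rev(model$topo)) {
    k <- length(s$states[[id]])
    l <- matrix(1, n, k)
    if (roles[[id]] == "evidence" && id %in% colnames(evmat)) {
      obs <- evmat[, id]
      has <- !is.na(obs)
      # states ordered (true, false); observed true -> indicator (1, 0)
      l[has & obs, 2] <- 0
      l[has & !obs, 1] <- 0
    }
    for (ch in children[[id]])
      l <- l * (lam[[ch]] %*% t(model$cpts[[ch]]))
    m <- pmax(do.call(pmax, as.data.frame(l)), .Machine$double.xmin)
    lam[[id]] <- l / m
  }
  q <- s$nodes$id[roles == "query"]
  prior <- model$cpts[[q]][1, ]
  post <- sweep(lam[[q]], 2, prior, "*")
  post_q <- post[, 1] / rowSums(post)

  shared <- vapply(s$modules[setdiff(names(s$modules), s$main_module)],
                   `[[`, character(1), "root")
  pi_msg <- list()
  pi_msg[[q]] <- matrix(prior, n, length(prior), byrow = TRUE)
  shared_post <- matrix(NA_real_, n, length(shared),
                        dimnames = list(NULL, shared))
  if (length(shared)) {
    for (id in model$topo[-match(q, model$topo)]) {
      p <- parents[[id]]
      b <- pi_msg[[p]]
      for (kk in setdiff(children[[p]], id))
        b <- b * (lam[[kk]] %*% t(model$cpts[[kk]]))
      pc <- b %*% model$cpts[[id]]
      m <- pmax(do.call(pmax, as.data.frame(pc)), .Machine$double.xmin)
      pi_msg[[id]] <- pc / m
      if (id %in% shared) {
        marg <- pi_msg[[id]] * lam[[id]]
        shared_post[, id] <- marg[, 1] / rowSums(marg)
      }
    }
  }
  list(posterior = post_q, shared = shared_post)
}

#' Recognize a batch of windows
#'
#' Applies the model's stump bank to each window to obtain the evidence
#' assignment (unavailable features yield absent evidence) and runs
#' [infer_posterior()] per window.
#'
#' @param model an `mbn_model` with a stump bank.
#' @param windows window feature data.frame from [segment_windows()].
#' @param threshold decision threshold; defaults to the model's.
#' @return data.frame: `window_start`, `posterior`, one
#'   `p_<shared node>` column per submodule root, `decision`.
#' @export
predict_windows <- function(model, windows, threshold = model$threshold) {
  if (is.null(model$stumps))
    stop("model has no stump bank; fit with train_model()")
  shared <- vapply(model$structure$modules[
    setdiff(names(model$structure$modules), model$structure$main_module)],
    `[[`, character(1), "root")
  cols <- c("window_start", "posterior", paste0("p_", shared), "decision")
  if (nrow(windows) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric()), length(cols) - 1L), cols[-length(cols)]))
    out$decision <- character()
    return(out)
  }
  evmat <- predict_evidence_bank(model$stumps, windows)
  ev_ids <- model$structure$nodes$id[model$structure$nodes$role == "evidence"]
  stopifnot(all(vapply(model$structure$states[ev_ids],
                       identical, logical(1), c("true", "false"))))
  res <- .batch_posteriors(model, evmat)
  out <- data.frame(window_start = windows$window_start,
                    posterior = res$posterior)
  for (r in shared) out[[paste0("p_", r)]] <- res$shared[, r]
  out$decision <- classify(out$posterior, threshold)
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_report <- function(x, ...) {
  cat(sprintf("P(eating | evidence) = %.4f -> %s (threshold %.2f)\n",
              x$query_posterior, x$decision, x$threshold))
  if (length(x$shared_node_posteriors)) {
    cat("shared-node posteriors:\n")
    for (r in names(x$shared_node_posteriors))
      cat(sprintf("  %-18s %.4f\n", r, x$shared_node_posteriors[[r]]))
  }
  invisible(x)
}

#' @export
print.mbn_model <- function(x, ...) {
  print(x$structure)
  cat(sprintf("  CPTs: %d nodes (alpha = %s)   stumps: %s   threshold: %.2f\n",
              length(x$cpts), format(x$alpha),
              if (is.null(x$stumps)) "none" else length(x$stumps),
              x$threshold))
  invisible(x)
}
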