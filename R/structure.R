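# Modular tree-structured Bayesian network: structure definition, the default
# 88-node eating-activity network, validation, and JSON (de)serialization.

#' Sensor channels of the recognizer
#'
#' The nine low-power channels: wrist ("h_") three-axis accelerometer at
#' 20 Hz, wrist illuminometer/thermometer/hygrometer at 1 Hz, and the phone
#' three-axis accelerometer at 20 Hz.
#'
#' @format Character vector of length 9.
#' @export
eatbn_channels <- c("h_acc_x", "h_acc_y", "h_acc_z",
                    "h_lux", "h_temp", "h_hum",
                    "acc_x", "acc_y", "acc_z")

# Channels sampled at 20 Hz; the remainder are 1 Hz environmental channels.
.acc_channels <- c("h_acc_x", "h_acc_y", "h_acc_z", "acc_x", "acc_y", "acc_z")
.env_channels <- c("h_lux", "h_temp", "h_hum")

#' Construct a modular BN structure object
#'
#' Low-level constructor. Most users want [build_default_structure()].
#' A structure holds the node set (with roles `query`/`inference`/`evidence`),
#' the directed edge set (generative orientation, query at the root), the
#' module partition (one main module whose leaves are the shared roots of the
#' submodules), per-node discrete state labels, and the evidence-to-feature
#' wiring used by the stump layer.
#'
#' @param nodes data.frame with columns `id`, `role`, `module`, `feature`
#'   (feature name for evidence nodes, `NA` otherwise).
#' @param edges data.frame with columns `parent`, `child`.
#' @param modules named list; each element `list(id, root, nodes)`. The
#'   element named by `main_module` is the main module; every other module's
#'   root must also appear among the main module's nodes (shared node).
#' @param states named list mapping node id to its ordered state labels;
#'   nodes absent from the list default to `c("true", "false")`.
#' @param main_module id of the main module.
#' @param max_parents maximum in-degree permitted by validation (default 2).
#' @return An object of class `mbn_structure`.
#' @export
mbn_structure <- function(nodes, edges, modules,
                          states = list(),
                          main_module = "main",
                          max_parents = 2L) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"feature" %in% names(nodes)) nodes$feature <- NA_character_
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  st <- stats::setNames(
    lapply(nodes$id, function(id) {
      s <- states[[id]]
      if (is.null(s)) c("true", "false") else as.character(s)
    }),
    nodes$id)
  structure(
    list(nodes = nodes, edges = edges, modules = modules, states = st,
         main_module = main_module, max_parents = as.integer(max_parents)),
    class = "mbn_structure")
}

# Evidence wiring of the default network: each low-level context property of
# the Table-style hierarchy observes a set of per-window sensor features.
# Counts are fixed (64 evidence leaves over 15 properties); the particular
# feature assignment is a design choice documented in the methods vignette.
.default_evidence_wiring <- function() {
  h_acc_all <- as.vector(outer(c("h_acc_x", "h_acc_y", "h_acc_z"),
                               c("mean", "sd", "range"), paste, sep = "_"))
  acc_mean  <- paste0(c("acc_x", "acc_y", "acc_z"), "_mean")
  acc_sd    <- paste0(c("acc_x", "acc_y", "acc_z"), "_sd")
  acc_range <- paste0(c("acc_x", "acc_y", "acc_z"), "_range")
  list(
    position_of_hand    = h_acc_all,
    dinnerware          = h_acc_all,
    movement_of_hand    = h_acc_all,
    posture_body        = c(paste0(c("h_acc_x", "h_acc_y", "h_acc_z"), "_mean"), acc_mean),
    move_stop_body      = acc_sd,
    movement_of_body    = c(acc_sd, acc_range),
    body_temperature    = "h_temp_mean",
    posture_operation   = acc_mean,
    humidity_of_hand    = "h_hum_mean",
    existence_of_food   = c("h_temp_mean", "h_hum_mean",
                            "h_acc_y_mean", "h_acc_y_sd", "h_acc_y_range"),
    eating_place        = c("h_lux_mean", "h_temp_mean", "h_hum_mean"),
    indoor_outdoor      = c("h_lux_mean", "h_temp_mean"),
    move_stop_space     = acc_mean,
    illuminance_of_space = "h_lux_mean",
    eating_time         = c("time_of_day", "h_lux_mean", "h_temp_mean")
  )
}

# Intermediate (inference) hierarchy of the default network, as
# parent -> children. Mirrors the activity-theory / Five-W's context model:
# subject (action/operation), object, spatial and temporal subclasses.
.default_hierarchy <- function() {
  list(
    subject_property  = c("activity", "body", "operation"),
    activity          = "wrist",
    wrist             = c("position_of_hand", "dinnerware", "movement_of_hand"),
    body              = c("posture_body", "move_stop_body", "movement_of_body"),
    operation         = c("body_temperature", "posture_operation", "humidity_of_hand"),
    object_property   = "existence_of_food",
    spatial_property  = c("eating_place", "indoor_outdoor", "move_stop_space",
                          "illuminance_of_space"),
    temporal_property = "eating_time"
  )
}

#' Build the default 88-node eating-activity network
#'
#' One binary query node (`eating`) roots the main module; its four leaves
#' are the shared roots of the subject/object/spatial/temporal submodules.
#' The submodules are trees over 23 intermediate context nodes in total;
#' their 64 leaves are evidence nodes, each wired to one per-window sensor
#' feature. Deterministic: repeated calls return identical structures.
#'
#' @return An `mbn_structure` with 88 nodes (1 query, 23 inference,
#'   64 evidence), validating cleanly under [validate_structure()].
#' @examples
#' s <- build_default_structure()
#' table(s$nodes$role)
#' @export
build_default_structure <- function() {
  roots <- c(subject = "subject_property", object = "object_property",
             spatial = "spatial_property", temporal = "temporal_property")
  hier <- .default_hierarchy()
  wiring <- .default_evidence_wiring()

  nodes <- data.frame(id = "eating", role = "query", module = "main",
                      feature = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE)
  modules <- list(main = list(id = "main", root = "eating",
                              nodes = c("eating", unname(roots))))

  for (m in names(roots)) {
    root <- roots[[m]]
    edges <- rbind(edges, data.frame(parent = "eating", child = root,
                                     stringsAsFactors = FALSE))
    members <- root
    # walk the hierarchy below this root
    queue <- root
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      kids <- hier[[p]]
      if (is.null(kids)) next
      for (k in kids) {
        members <- c(members, k)
        edges <- rbind(edges, data.frame(parent = p, child = k,
                                         stringsAsFactors = FALSE))
        queue <- c(queue, k)
      }
    }
    inf <- data.frame(id = members, role = "inference", module = m,
                      feature = NA_character_, stringsAsFactors = FALSE)
    nodes <- rbind(nodes, inf)
    # evidence leaves under the property nodes of this submodule
    for (p in members) {
      feats <- wiring[[p]]
      if (is.null(feats)) next
      ev_ids <- paste("ev", p, feats, sep = "_")
      nodes <- rbind(nodes, data.frame(id = ev_ids, role = "evidence",
                                       module = m, feature = feats,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(parent = p, child = ev_ids,
                                       stringsAsFactors = FALSE))
      members <- c(members, ev_ids)
    }
    modules[[m]] <- list(id = m, root = root, nodes = members)
  }
  rownames(nodes) <- NULL
  mbn_structure(nodes, edges, modules)
}

#' Validate a modular BN structure
#'
#' Checks every structural invariant: unique node ids, edges referencing
#' known nodes, no self-loops, global acyclicity, in-degree at most
#' `max_parents`, exactly one query node located in the main module, at
#' least two distinct states per node, each submodule a tree with a single
#' root that is shared with (a leaf of) the main module, module member sets
#' disjoint apart from shared roots, and every evidence node reachable from
#' the query node along directed edges.
#'
#' @param s an `mbn_structure`.
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_structure <- function(s) {
  v <- character()
  ids <- s$nodes$id
  if (anyDuplicated(ids))
    v <- c(v, paste0("duplicate node ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- setdiff(c(s$edges$parent, s$edges$child), ids)
  if (length(bad))
    v <- c(v, paste0("edge references unknown node: ",
                     paste(bad, collapse = ", ")))
  loop <- s$edges$parent == s$edges$child
  if (any(loop))
    v <- c(v, paste0("self-loop on node ", s$edges$parent[loop]))
  if (length(v)) return(v)  # graph checks below need a well-formed edge list

  g <- igraph::graph_from_data_frame(s$edges, directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    v <- c(v, paste0("edge set contains a directed cycle",
                     if (length(cyc)) paste0(" involving {",
                                             paste(sort(cyc), collapse = ", "), "}")))
  }
  indeg <- igraph::degree(g, mode = "in")
  over <- names(indeg)[indeg > s$max_parents]
  if (length(over))
    v <- c(v, paste0("node ", over, " has ", indeg[over],
                     " parents (max ", s$max_parents, ")"))

  nq <- sum(s$nodes$role == "query")
  if (nq != 1L)
    v <- c(v, paste0("expected exactly 1 query node, found ", nq))
  q <- s$nodes$id[s$nodes$role == "query"]
  main <- s$modules[[s$main_module]]
  if (is.null(main)) {
    v <- c(v, paste0("main module '", s$main_module, "' missing"))
    return(v)
  }
  if (nq == 1L && !(q %in% main$nodes))
    v <- c(v, paste0("query node ", q, " not in main module"))

  short <- ids[vapply(s$states[ids], function(x)
    length(unique(x)) < 2L, logical(1))]
  if (length(short))
    v <- c(v, paste0("node ", short, " has fewer than 2 distinct states"))

  # per-module tree checks on the induced subgraph
  for (m in s$modules) {
    sub_edges <- s$edges[s$edges$parent %in% m$nodes &
                           s$edges$child %in% m$nodes, , drop = FALSE]
    par_count <- table(factor(sub_edges$child, levels = m$nodes))
    roots <- names(par_count)[par_count == 0L]
    if (length(roots) != 1L)
      v <- c(v, paste0("module ", m$id, " has ", length(roots),
                       " parentless nodes (", paste(roots, collapse = ", "),
                       "); a tree needs exactly one root"))
    else if (roots != m$root)
      v <- c(v, paste0("module ", m$id, " declares root ", m$root,
                       " but its parentless node is ", roots))
    multi <- names(par_count)[par_count > 1L]
    if (length(multi))
      v <- c(v, paste0("module ", m$id, ": node ", multi,
                       " has >1 in-module parent (not a tree)"))
    if (length(m$nodes) > 1L && nrow(sub_edges) != length(m$nodes) - 1L)
      v <- c(v, paste0("module ", m$id, ": ", nrow(sub_edges),
                       " in-module edges for ", length(m$nodes),
                       " nodes (tree needs n-1)"))
  }

  # shared-node semantics: submodule roots sit in the main module as leaves;
  # apart from those, module member sets are pairwise disjoint
  subs <- s$modules[setdiff(names(s$modules), s$main_module)]
  main_kids <- s$edges$parent[s$edges$child %in% main$nodes]
  for (m in subs) {
    if (!(m$root %in% main$nodes))
      v <- c(v, paste0("submodule ", m$id, " root ", m$root,
                       " is not a main-module node (no shared node)"))
    if (m$root %in% s$edges$parent[s$edges$child %in% setdiff(main$nodes, m$root)])
      v <- c(v, paste0("shared node ", m$root,
                       " is not a leaf of the main module"))
  }
  mm <- lapply(subs, function(m) setdiff(m$nodes, m$root))
  if (length(mm) > 1L) {
    for (i in seq_len(length(mm) - 1L)) for (j in seq(i + 1L, length(mm))) {
      ov <- intersect(mm[[i]], mm[[j]])
      if (length(ov))
        v <- c(v, paste0("modules ", subs[[i]]$id, " and ", subs[[j]]$id,
                         " share non-root nodes: ", paste(ov, collapse = ", ")))
    }
  }

  # every evidence node reachable from the query (generative orientation)
  if (nq == 1L && igraph::is_dag(g)) {
    reach <- igraph::subcomponent(g, q, mode = "out")
    ev <- s$nodes$id[s$nodes$role == "evidence"]
    miss <- setdiff(ev, names(reach))
    if (length(miss))
      v <- c(v, paste0("evidence node ", miss,
                       " unreachable from query node ", q))
  }
  v
}

#' Parent of each node
#'
#' @param s an `mbn_structure`.
#' @return Named character vector mapping node id to its single parent
#'   (`NA` for the root). Errors if some node has more than one parent.
#' @keywords internal
node_parents <- function(s) {
  p <- stats::setNames(rep(NA_character_, nrow(s$nodes)), s$nodes$id)
  if (anyDuplicated(s$edges$child))
    stop("structure is not a tree: a node has multiple parents")
  p[s$edges$child] <- s$edges$parent
  p
}

#' @export
print.mbn_structure <- function(x, ...) {
  cnt <- table(factor(x$nodes$role, levels = c("query", "inference", "evidence")))
  cat("Modular tree-structured Bayesian network\n")
  cat(sprintf("  nodes: %d (%d query, %d inference, %d evidence)\n",
              nrow(x$nodes), cnt[["query"]], cnt[["inference"]], cnt[["evidence"]]))
  cat(sprintf("  edges: %d   modules: %s (main: %s)\n", nrow(x$edges),
              paste(names(x$modules), collapse = ", "), x$main_module))
  invisible(x)
}

#' Save / load a structure as JSON
#'
#' The file holds top-level keys `nodes` (objects with `id`, `role`,
#' `states`, `module`, and optionally `feature`), `edges` (`parent`,
#' `child` pairs), `modules`, `main_module` and `max_parents`. The
#' round-trip `load_structure(save_structure(s, p))` is structurally exact,
#' including the ordering of state labels.
#'
#' @param s an `mbn_structure`.
#' @param path file path.
#' @return `save_structure` returns `path` invisibly; `load_structure`
#'   returns an `mbn_structure`.
#' @export
save_structure <- function(s, path) {
  obj <- list(
    nodes = lapply(seq_len(nrow(s$nodes)), function(i) {
      n <- list(id = s$nodes$id[i], role = s$nodes$role[i],
                states = as.list(s$states[[s$nodes$id[i]]]),
                module = s$nodes$module[i])
      if (!is.na(s$nodes$feature[i])) n$feature <- s$nodes$feature[i]
      n
    }),
    edges = lapply(seq_len(nrow(s$edges)), function(i)
      list(parent = s$edges$parent[i], child = s$edges$child[i])),
    modules = lapply(unname(s$modules), function(m)
      list(id = m$id, root = m$root, nodes = as.list(m$nodes))),
    main_module = s$main_module,
    max_parents = s$max_parents)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_structure
#' @export
load_structure <- function(path) {
  obj <- jsonlite::read_json(path)
  for (key in c("nodes", "edges", "modules"))
    if (is.null(obj[[key]]))
      stop("malformed structure file: missing key '", key, "'")
  nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
    for (key in c("id", "role", "states"))
      if (is.null(n[[key]]))
        stop("malformed structure file: node missing field '", key, "'")
    data.frame(id = n$id, role = n$role,
               module = if (is.null(n$module)) NA_character_ else n$module,
               feature = if (is.null(n$feature)) NA_character_ else n$feature,
               stringsAsFactors = FALSE)
  }))
  states <- stats::setNames(
    lapply(obj$nodes, function(n) vapply(n$states, as.character, character(1))),
    nodes$id)
  edges <- do.call(rbind, lapply(obj$edges, function(e) {
    if (is.null(e$parent) || is.null(e$child))
      stop("malformed structure file: edge missing field 'parent'/'child'")
    data.frame(parent = e$parent, child = e$child, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(), child = character())
  modules <- stats::setNames(
    lapply(obj$modules, function(m)
      list(id = m$id, root = m$root,
           nodes = vapply(m$nodes, as.character, character(1)))),
    vapply(obj$modules, `[[`, character(1), "id"))
  mbn_structure(nodes, edges, modules, states = states,
                main_module = if (is.null(obj$main_module)) "main" else obj$main_module,
                max_parents = if (is.null(obj$max_parents)) 2L else obj$max_parents)
}
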