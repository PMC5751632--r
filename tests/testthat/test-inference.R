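test_that("no evidence returns the prior; consistent hard evidence saturates", {
  m <- random_tree_model(10, seed = 1)
  rep0 <- infer_posterior(m, list())
  expect_equal(rep0$query_posterior, unname(m$cpts$q[1, "true"]),
               tolerance = 1e-12)
  expect_equal(rep0$query_posterior + (1 - rep0$query_posterior), 1,
               tolerance = 1e-12)

  # deterministic chain with consistent full evidence pins the posterior at 1
  det <- chain_model(p_q = 0.5, p_i = c(1, 0), p_e = c(1, 0))
  rep1 <- infer_posterior(det, list(e = "true"))
  expect_equal(rep1$query_posterior, 1, tolerance = 1e-12)
})

test_that("three-node chain matches hand arithmetic over the 8 joint entries", {
  m <- chain_model(p_q = 0.6, p_i = c(0.8, 0.3), p_e = c(0.9, 0.2))
  # P(q,e=t) = 0.6*(0.8*0.9 + 0.2*0.2) = 0.456; P(!q,e=t) = 0.4*(0.3*0.9 + 0.7*0.2) = 0.164
  expect_equal(infer_posterior(m, list(e = "true"))$query_posterior,
               0.456 / (0.456 + 0.164), tolerance = 1e-12)
  expect_equal(brute_force_posterior(m, list(e = "true")),
               0.456 / (0.456 + 0.164), tolerance = 1e-12)
  expect_equal(brute_force_posterior(m, list()), 0.6, tolerance = 1e-12)
})

test_that("message passing agrees with enumeration on random tree models", {
  worst <- 0
  for (seed in 1:100) {
    n <- 3 + (seed %% 18)              # 3..20 nodes
    m <- random_tree_model(n, seed = seed)
    ev <- random_evidence(m, seed = seed + 1000)
    p1 <- infer_posterior(m, ev)$query_posterior
    p2 <- brute_force_posterior(m, ev)
    worst <- max(worst, abs(p1 - p2))
  }
  expect_lt(worst, 1e-10)
})

test_that("shared-node posteriors are exact marginals of the joint", {
  # enumeration oracle for an arbitrary node's marginal
  marginal_oracle <- function(model, ev, node) {
    s <- model$structure
    ids <- s$nodes$id
    grid <- do.call(expand.grid, c(setNames(
      lapply(ids, function(id) seq_along(s$states[[id]])), ids),
      list(KEEP.OUT.ATTRS = FALSE)))
    parents <- setNames(rep(NA_character_, length(ids)), ids)
    parents[s$edges$child] <- s$edges$parent
    p <- rep(1, nrow(grid))
    for (id in ids) {
      par <- parents[[id]]
      idx <- if (is.na(par)) cbind(1L, grid[[id]]) else cbind(grid[[par]], grid[[id]])
      p <- p * model$cpts[[id]][idx]
      if (!is.null(ev[[id]]))
        p[grid[[id]] != match(ev[[id]], s$states[[id]])] <- 0
    }
    sum(p[grid[[node]] == 1L]) / sum(p)
  }
  # modular model: query with two submodule roots, each a small tree
  nodes <- data.frame(
    id = c("q", "r1", "r2", "a", "b"),
    role = c("query", "inference", "inference", "evidence", "evidence"),
    module = c("main", "m1", "m2", "m1", "m2"), feature = NA_character_)
  edges <- data.frame(parent = c("q", "q", "r1", "r2"),
                      child = c("r1", "r2", "a", "b"))
  s <- mbn_structure(nodes, edges, modules = list(
    main = list(id = "main", root = "q", nodes = c("q", "r1", "r2")),
    m1 = list(id = "m1", root = "r1", nodes = c("r1", "a")),
    m2 = list(id = "m2", root = "r2", nodes = c("r2", "b"))))
  set.seed(77)
  mk <- function(rows) {
    p <- runif(rows, 0.1, 0.9)
    m <- cbind(true = p, false = 1 - p)
    rownames(m) <- if (rows == 1) "(root)" else c("true", "false")
    m
  }
  cpts <- list(q = mk(1), r1 = mk(2), r2 = mk(2), a = mk(2), b = mk(2))
  class(cpts) <- "cpt_bank"
  m <- mbn_model(s, cpts)
  ev <- list(a = "true")
  rep <- infer_posterior(m, ev)
  expect_equal(rep$query_posterior, marginal_oracle(m, ev, "q"), tolerance = 1e-12)
  expect_equal(unname(rep$shared_node_posteriors["r1"]),
               marginal_oracle(m, ev, "r1"), tolerance = 1e-12)
  expect_equal(unname(rep$shared_node_posteriors["r2"]),
               marginal_oracle(m, ev, "r2"), tolerance = 1e-12)
})

test_that("the enumeration oracle refuses oversized state spaces", {
  m <- random_tree_model(25, seed = 2)
  expect_error(brute_force_posterior(m, list()), "2\\^20")
})

test_that("invalid evidence states and nodes are rejected", {
  m <- chain_model()
  expect_error(infer_posterior(m, list(e = "maybe")), "maybe")
  expect_error(infer_posterior(m, list(i = "true")), "non-evidence")
})

test_that("classification applies the inclusive threshold rule", {
  expect_equal(classify(0.61, 0.6), "eating")
  expect_equal(classify(0.6, 0.6), "eating")       # tie -> eating
  expect_equal(classify(0.59, 0.6), "non-eating")
  expect_true(all(classify(runif(20), 0) == "eating"))  # degenerate threshold
  # lowering the threshold never flips eating -> non-eating
  p <- 0.47
  d <- classify(p, seq(1, 0, -0.1))
  expect_false(any(d[-length(d)] == "eating" & d[-1] == "non-eating"))
})

test_that("missing evidence keeps posteriors well defined and interior", {
  d <- small_dataset()
  model <- train_model(d$windows, d$contexts)
  evmat <- predict_evidence_bank(model$stumps, d$windows[1:10, ])
  full <- as.list(evmat[1, ][!is.na(evmat[1, ])])
  p_full <- infer_posterior(model, full)$query_posterior
  # removing any single observation keeps the posterior defined in (0,1)
  for (drop in names(full)) {
    p <- infer_posterior(model, full[setdiff(names(full), drop)])$query_posterior
    expect_true(is.finite(p) && p > 0 && p < 1)
  }
  # evidence restricted to a single submodule still yields interior posteriors
  s <- model$structure
  spatial_ev <- intersect(names(full),
                          s$modules$spatial$nodes)
  p_sp <- infer_posterior(model, full[spatial_ev])$query_posterior
  expect_true(p_sp > 0 && p_sp < 1)
  expect_true(is.finite(p_full))
})

test_that("batch recognition equals per-window inference", {
  d <- small_dataset()
  model <- train_model(d$windows, d$contexts)
  w <- d$windows[1:30, ]
  pred <- predict_windows(model, w)
  evmat <- predict_evidence_bank(model$stumps, w)
  for (i in c(1, 7, 30)) {
    obs <- evmat[i, ]
    rep <- infer_posterior(model, as.list(obs[!is.na(obs)]))
    expect_equal(pred$posterior[i], rep$query_posterior, tolerance = 1e-12)
    for (r in names(rep$shared_node_posteriors))
      expect_equal(pred[[paste0("p_", r)]][i],
                   unname(rep$shared_node_posteriors[r]), tolerance = 1e-12)
  }
  # empty input gives an empty, well-formed frame
  empty <- predict_windows(model, d$windows[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("window_start", "posterior", "decision") %in% names(empty)))
})
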