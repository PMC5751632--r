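# CPT learning by counting: a count bank accumulates co-occurrences of
# (parent state, child state) per node over labelled windows; finalize
# turns counts into Laplace-smoothed conditional probability tables.

#' Create an empty count bank for a structure
#'
#' One table per node: the root (query) node gets a plain state-count
#' vector; every other node gets a (#parent states) x (#own states) count
#' matrix. `n_data` is the number of observations accumulated so far
#' and `n_ops` the number of elementary counting updates performed
#' (one per node per observation), exposed so learning cost can be
#' audited — it grows linearly in the data.
#'
#' @param s an `mbn_structure` whose edges form a tree.
#' @return Object of class `count_bank`.
#' @export
new_count_bank <- function(s) {
  parents <- node_parents(s)
  tabs <- stats::setNames(lapply(s$nodes$id, function(id) {
    kid_states <- s$states[[id]]
    p <- parents[[id]]
    if (is.na(p)) {
      matrix(0, nrow = 1, ncol = length(kid_states),
             dimnames = list("(root)", kid_states))
    } else {
      par_states <- s$states[[p]]
      matrix(0, nrow = length(par_states), ncol = length(kid_states),
             dimnames = list(par_states, kid_states))
    }
  }), s$nodes$id)
  structure(list(structure = s, parents = parents, counts = tabs,
                 n_data = 0L, n_ops = 0L),
            class = "count_bank")
}

.states_of <- function(x) {
  # logical TRUE/FALSE maps onto the canonical ("true","false") labels
  if (is.logical(x)) ifelse(x, "true", "false") else as.character(x)
}

#' Accumulate labelled assignments into a count bank
#'
#' Each assignment is a full node-state vector for one window (training data
#' carries the true context memberships). Counting increments `n_data` once
#' per window and, for every node, the cell matching (parent state, own
#' state). Order-independent: any permutation of the same windows yields the
#' same bank. Accepts either a single named vector (one window) or a
#' data.frame with one column per node (many windows, counted vectorized).
#'
#' @param bank a `count_bank`.
#' @param assignment named character/logical vector over all node ids, or a
#'   data.frame with one such column per node.
#' @return The updated `count_bank`.
#' @export
accumulate <- function(bank, assignment) {
  s <- bank$structure
  ids <- s$nodes$id
  if (!is.data.frame(assignment)) {
    assignment <- as.data.frame(as.list(assignment),
                                optional = TRUE, stringsAsFactors = FALSE)
    names(assignment) <- names(assignment)
  }
  miss <- setdiff(ids, names(assignment))
  if (length(miss))
    stop("assignment missing node(s): ", paste(miss, collapse = ", "))
  n <- nrow(assignment)
  if (n == 0L) return(bank)
  for (id in ids) {
    kid <- factor(.states_of(assignment[[id]]), levels = colnames(bank$counts[[id]]))
    if (anyNA(kid))
      stop("invalid state for node ", id)
    p <- bank$parents[[id]]
    if (is.na(p)) {
      bank$counts[[id]][1, ] <- bank$counts[[id]][1, ] + table(kid)
    } else {
      par <- factor(.states_of(assignment[[p]]), levels = rownames(bank$counts[[id]]))
      bank$counts[[id]] <- bank$counts[[id]] + table(par, kid)
    }
  }
  bank$n_data <- bank$n_data + n
  bank$n_ops <- bank$n_ops + n * length(ids)
  bank
}

#' Merge two count banks
#'
#' Banks accumulated on disjoint data merge into the bank of the
#' concatenated data (cell-wise sum).
#'
#' @param a,b `count_bank`s over the same structure.
#' @return Merged `count_bank`.
#' @export
merge_banks <- function(a, b) {
  stopifnot(identical(names(a$counts), names(b$counts)))
  for (id in names(a$counts))
    a$counts[[id]] <- a$counts[[id]] + b$counts[[id]]
  a$n_data <- a$n_data + b$n_data
  a$n_ops <- a$n_ops + b$n_ops
  a
}

#' Finalize a count bank into smoothed CPTs
#'
#' Each row becomes `p(child = s | parents = g) = (count + alpha) /
#' (row total + alpha * #child states)` (Laplace smoothing, `alpha = 1`
#' default). The root's single row is the smoothed empirical class prior.
#' With `alpha = 0` the estimate is the bare empirical quotient
#' `num(child & parent) / num(parent)`, and an all-zero row is an error
#' (undefined distribution).
#'
#' @param bank an accumulated `count_bank`.
#' @param alpha pseudo-count, `>= 0`.
#' @return Named list (by node id) of row-stochastic CPT matrices
#'   (rows: parent states; columns: child states), class `cpt_bank`.
#' @export
finalize_cpts <- function(bank, alpha = 1) {
  stopifnot(alpha >= 0)
  cpts <- lapply(names(bank$counts), function(id) {
    cnt <- bank$counts[[id]]
    tot <- rowSums(cnt)
    if (alpha == 0 && any(tot == 0))
      stop("node ", id, ": zero-count row with alpha = 0 (undefined distribution)")
    (cnt + alpha) / (tot + alpha * ncol(cnt))
  })
  names(cpts) <- names(bank$counts)
  structure(cpts, class = "cpt_bank", alpha = alpha)
}

#' @export
print.count_bank <- function(x, ...) {
  cat(sprintf("count bank: %d nodes, %d observations, %d counting updates\n",
              length(x$counts), x$n_data, x$n_ops))
  invisible(x)
}
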