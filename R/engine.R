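# Asynchronous unitary dynamics.  A state assigns a level to every node; a
# clamp fixes a subset of nodes (inputs and/or perturbed genes).  At each
# state every unclamped node has a target level (first true rule scanning
# target levels downwards, default 0); a node whose target differs from its
# current level may fire, moving ONE level toward the target.  Each firing
# node yields one successor, so successive states differ in exactly one node
# by exactly one level.
#
# The whole clamped subspace is laid out as an integer matrix (one row per
# state, one column per node) in mixed-radix order: nodes in model order,
# levels ascending, later free nodes varying fastest.  Rule evaluation is
# vectorized down the rows, which makes full-subspace work cheap even for
# the 31,104-state Fe-S condition subspaces.

#' Enumerate all states of a clamped subspace
#'
#' @param model A `logical_model`.
#' @param clamp Named integer vector fixing some nodes (may be empty).
#' @param limit Safety cap on the subspace size; exceeding it is an error.
#' @return Integer matrix, one row per state, columns named by node, rows in
#'   deterministic mixed-radix order (model node order, levels ascending).
#' @export
enumerate_states <- function(model, clamp = integer(0), limit = 2e6) {
  check_clamp(model, clamp)
  nms <- node_names(model)
  ml <- max_levels(model)
  free <- setdiff(nms, names(clamp))
  n <- prod(ml[free] + 1)
  if (n > limit) {
    stop("clamped subspace has ", n, " states, above the limit of ", limit)
  }
  S <- matrix(0L, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  for (v in names(clamp)) S[, v] <- as.integer(clamp[[v]])
  if (length(free)) {
    # later free nodes vary fastest
    reps_inner <- 1L
    for (j in rev(seq_along(free))) {
      v <- free[j]
      r <- ml[[v]] + 1L
      block <- rep(0:(r - 1L), each = reps_inner)
      S[, v] <- rep_len(rep(block, length.out = reps_inner * r), n)
      reps_inner <- reps_inner * r
    }
  }
  S
}

check_clamp <- function(model, clamp) {
  if (!length(clamp)) return(invisible(NULL))
  if (is.null(names(clamp)) || any(!nzchar(names(clamp)))) {
    stop("clamp must be a named vector")
  }
  bad <- setdiff(names(clamp), node_names(model))
  if (length(bad)) stop("clamp names unknown node(s): ", paste(bad, collapse = ", "))
  ml <- max_levels(model)
  out <- clamp < 0 | clamp > ml[names(clamp)]
  if (any(out)) {
    stop("clamped level out of range for: ",
         paste(names(clamp)[out], collapse = ", "))
  }
  invisible(NULL)
}

# mixed-radix index (1-based) of each row of a state matrix, over free nodes
state_index <- function(S, model, clamp) {
  ml <- max_levels(model)
  free <- setdiff(node_names(model), names(clamp))
  w <- integer(length(free))
  acc <- 1L
  for (j in rev(seq_along(free))) {
    w[j] <- acc
    acc <- acc * (ml[[free[j]]] + 1L)
  }
  idx <- rep(1, nrow(S))
  for (j in seq_along(free)) idx <- idx + as.numeric(S[, free[j]]) * w[j]
  list(index = idx, free = free, weights = stats::setNames(w, free))
}

# Target levels of every non-input node, vectorized over a state matrix.
# Rules are scanned highest target level first; first match wins; default 0.
# Returns an integer matrix with one column per rule-bearing node.
target_levels_matrix <- function(model, S) {
  out <- list()
  for (nd in model$nodes) {
    if (!length(nd$rules)) next
    tgt <- rep(0L, nrow(S))
    undecided <- rep(TRUE, nrow(S))
    for (r in nd$rules) {            # stored highest level first
      hit <- undecided & eval_expr(r$expr, S)
      tgt[hit] <- r$level
      undecided <- undecided & !hit
    }
    out[[nd$name]] <- tgt
  }
  do.call(cbind, out)
}

#' Target level of one node in one state
#'
#' Scans the node's rules in decreasing target-level order and returns the
#' first target whose expression holds, or 0 when none does.
#'
#' @param model A `logical_model`.
#' @param node Name of a rule-bearing (non-input) node.
#' @param state Named integer vector assigning a level to every node.
#' @return The target level, an integer in `0..max_level(node)`.
#' @export
target_level <- function(model, node, state) {
  nd <- model$nodes[[node]]
  if (is.null(nd)) stop("unknown node: ", node)
  if (!length(nd$rules)) {
    stop("node ", node, " has no rules (input node); clamp it instead")
  }
  for (r in nd$rules) {
    if (isTRUE(eval_expr(r$expr, state))) return(r$level)
  }
  0L
}

#' Asynchronous successors of a state
#'
#' For each unclamped node whose target level differs from its current
#' level, yields the state in which that node has moved one level toward
#' its target (unitary asynchronous updating); all other nodes are
#' unchanged.  A state with no such node is stable and has no successors.
#'
#' @param model A `logical_model`.
#' @param state Named integer vector (complete state).
#' @param clamp Named integer vector of clamped nodes; `state` must agree
#'   with it.
#' @return List of successor states (named integer vectors); empty when the
#'   state is stable.
#' @export
successors <- function(model, state, clamp = integer(0)) {
  check_clamp(model, clamp)
  state <- state[node_names(model)]
  if (length(clamp) &&
      !identical(as.integer(state[names(clamp)]),
                 as.integer(clamp[names(clamp)]))) {
    stop("state disagrees with clamp on a clamped node")
  }
  succ <- list()
  for (v in setdiff(node_names(model), names(clamp))) {
    nd <- model$nodes[[v]]
    if (!length(nd$rules)) next    # unclamped input: held constant
    tgt <- target_level(model, v, state)
    cur <- state[[v]]
    if (tgt != cur) {
      s2 <- state
      s2[[v]] <- cur + sign(tgt - cur)
      succ[[length(succ) + 1L]] <- s2
    }
  }
  succ
}

#' Stable states by direct subspace scan
#'
#' Finds every state of the clamped subspace in which all rule-bearing,
#' unclamped nodes already sit at their target level, without building the
#' transition graph.  An independent cross-check for the size-1 attractors
#' reported by [terminal_sccs()].
#'
#' @inheritParams enumerate_states
#' @return Integer matrix of stable states (possibly 0 rows).
#' @export
stable_states_direct <- function(model, clamp = integer(0), limit = 2e6) {
  S <- enumerate_states(model, clamp, limit)
  Tm <- target_levels_matrix(model, S)
  active <- setdiff(colnames(Tm), names(clamp))
  if (!length(active)) return(S)
  ok <- rep(TRUE, nrow(S))
  for (v in active) ok <- ok & (Tm[, v] == S[, v])
  S[ok, , drop = FALSE]
}
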