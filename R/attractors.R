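# State transition graphs and attractors.  The STG of a clamped subspace has
# every state of that subspace as a vertex and the unitary asynchronous
# successor relation as edges.  Attractors are the terminal strongly
# connected components: strongly connected sets of states with no outgoing
# edge.  A size-1 attractor is a stable state; larger ones are cyclic
# (homeostatic oscillations).

#' Build the full asynchronous state transition graph of a clamped subspace
#'
#' @param model A `logical_model`.
#' @param clamp Named integer vector; must clamp at least every input node.
#' @param limit Safety cap on the subspace size.
#' @return An `stg` object: list with the state matrix (`states`), the edge
#'   list as from/to row indices (`edges`), and the generating `clamp`.
#' @export
build_stg <- function(model, clamp, limit = 2e6) {
  miss <- setdiff(input_nodes(model), names(clamp))
  if (length(miss)) {
    stop("clamp must cover all input nodes; missing: ",
         paste(miss, collapse = ", "))
  }
  S <- enumerate_states(model, clamp, limit)
  ix <- state_index(S, model, clamp)
  Tm <- target_levels_matrix(model, S)
  movers <- setdiff(colnames(Tm), names(clamp))
  from <- integer(0); to <- integer(0)
  for (v in movers) {
    d <- sign(Tm[, v] - S[, v])
    mv <- which(d != 0L)
    if (!length(mv)) next
    from <- c(from, mv)
    to <- c(to, as.integer(ix$index[mv] + d[mv] * ix$weights[[v]]))
  }
  structure(list(model = model, clamp = clamp, states = S,
                 edges = cbind(from = from, to = to)),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph:", nrow(x$states), "states,",
      nrow(x$edges), "transitions\n")
  if (length(x$clamp)) {
    cat("  clamp:", paste(names(x$clamp), x$clamp, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Attractors of a state transition graph
#'
#' Terminal strongly connected components of the STG, in deterministic order
#' (by the smallest member state in enumeration order).
#'
#' @param stg An `stg` from [build_stg()].
#' @return List of `attractor` objects; each holds its state matrix
#'   (`states`), its `size` and its `kind` (`"stable_state"` or `"cyclic"`).
#' @export
terminal_sccs <- function(stg) {
  n <- nrow(stg$states)
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (nrow(stg$edges)) {
    g <- igraph::add_edges(g, t(stg$edges))
  }
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # a component is terminal iff it has no edge into another component
  cross <- memb[stg$edges[, 1]] != memb[stg$edges[, 2]]
  nonterminal <- unique(memb[stg$edges[cross, 1]])
  term <- setdiff(seq_len(comp$no), nonterminal)
  atts <- lapply(term, function(cid) {
    rows <- which(memb == cid)
    new_attractor(stg$states[rows, , drop = FALSE], stg$clamp,
                  first_index = min(rows))
  })
  first_row <- vapply(atts, function(a) a$first_index, numeric(1))
  atts[order(first_row)]
}

new_attractor <- function(states, clamp, first_index = NULL) {
  structure(list(states = states,
                 size = nrow(states),
                 kind = if (nrow(states) == 1L) "stable_state" else "cyclic",
                 clamp = clamp,
                 first_index = if (is.null(first_index)) NA_real_ else first_index),
            class = "attractor")
}

# keep the ordering key without exposing it in the public fields
#' @export
print.attractor <- function(x, ...) {
  cat("Attractor:", x$kind, "with", x$size,
      if (x$size == 1L) "state" else "states", "\n")
  s <- summary(x)
  osc <- s$node[s$oscillating]
  if (length(osc)) cat("  oscillating:", paste(osc, collapse = ", "), "\n")
  invisible(x)
}

#' Per-node asymptotic summary of an attractor
#'
#' For every node, the minimum, maximum and unweighted arithmetic mean of
#' its level over the attractor's states, and whether it oscillates
#' (min < max).
#'
#' @param object An `attractor`.
#' @param ... Unused.
#' @return Data frame with columns `node`, `min`, `max`, `mean`,
#'   `oscillating`.
#' @export
summary.attractor <- function(object, ...) {
  S <- object$states
  data.frame(node = colnames(S),
             min = apply(S, 2, min),
             max = apply(S, 2, max),
             mean = colMeans(S),
             oscillating = apply(S, 2, min) < apply(S, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attractor(s) of one environmental condition
#'
#' Builds the STG of the subspace clamped by the input condition (plus an
#' optional perturbation clamp) and extracts its terminal SCCs.  The Fe-S
#' model has a unique attractor per condition; arbitrary models may have
#' several, in which case all are returned and multiplicity is flagged.
#'
#' @param model A `logical_model`.
#' @param inputs Named integer vector clamping (at least) every input node.
#' @param perturbation Optional additional clamp over internal nodes (a
#'   named vector or a [perturbation()] object).
#' @param limit Safety cap on the subspace size.
#' @return If a single attractor exists, that `attractor`; otherwise a list
#'   of attractors with attribute `multiple = TRUE`.
#' @export
condition_attractor <- function(model, inputs, perturbation = NULL,
                                limit = 2e6) {
  clamp <- combine_clamps(model, inputs, perturbation)
  atts <- terminal_sccs(build_stg(model, clamp, limit))
  if (length(atts) == 1L) return(atts[[1L]])
  structure(atts, multiple = TRUE)
}

combine_clamps <- function(model, inputs, perturbation) {
  extra <- if (inherits(perturbation, "perturbation")) perturbation$clamp
           else perturbation
  if (length(extra)) {
    both <- intersect(names(inputs), names(extra))
    conflict <- both[inputs[both] != extra[both]]
    if (length(conflict)) {
      stop("conflicting clamps on: ", paste(conflict, collapse = ", "))
    }
    clamp <- c(inputs, extra[setdiff(names(extra), names(inputs))])
  } else {
    clamp <- inputs
  }
  check_clamp(model, clamp)
  clamp
}

#' Export an attractor's states as a data frame
#'
#' @param x An `attractor`.
#' @param ... Unused.
#' @return Data frame, one row per attractor state, one column per node,
#'   plus `kind` and `size`.
#' @export
as.data.frame.attractor <- function(x, ...) {
  df <- as.data.frame(x$states)
  df$kind <- x$kind
  df$size <- x$size
  df
}
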