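# Random multivalued logical networks and an independent brute-force
# attractor oracle.  The generator exists so the dynamics engine can be
# validated on networks with known-size state spaces; the oracle finds the
# same attractors by a deliberately different route (its own scalar rule
# evaluator, per-state reachability, mutual-reachability grouping), so a
# shared bug cannot hide.

#' Configuration for the random-network generator
#'
#' @param n_nodes Total node count (>= 1).
#' @param frac_ternary Fraction of nodes given max level 2 instead of 1.
#' @param n_inputs Number of input (rule-less, clamped) nodes; must not
#'   exceed `n_nodes`, and at least one node must remain internal when
#'   `n_nodes > 1`.
#' @param density Expected number of regulators per rule conjunction
#'   (atoms are drawn per clause with this mean, minimum 1).
#' @param seed Integer seed; the same config and seed always produce the
#'   identical model.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_nodes, frac_ternary = 0.5, n_inputs = 1,
                             density = 2, seed = 1) {
  stopifnot(n_nodes >= 1, n_inputs >= 0, n_inputs <= n_nodes,
            frac_ternary >= 0, frac_ternary <= 1, density >= 1)
  if (n_inputs == n_nodes && n_nodes > 0) {
    stop("infeasible config: every node is an input; no dynamics remain")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 frac_ternary = frac_ternary,
                 n_inputs = as.integer(n_inputs),
                 density = density, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a random multivalued logical network
#'
#' Produces a well-formed model whose non-input nodes each carry ordered
#' rules built from random atoms over randomly chosen regulators.  Rule
#' expressions are emitted in disjunctive normal form so the text grammar
#' round-trips them exactly.  Generation is bit-reproducible: the same
#' config yields the same model, and the caller's RNG state is left
#' untouched.
#'
#' @param config A [generator_config()].
#' @return A `logical_model` passing [validate_model()].
#' @export
random_model <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  n <- config$n_nodes
  nms <- sprintf("n%02d", seq_len(n))
  maxlev <- ifelse(runif(n) < config$frac_ternary, 2L, 1L)
  is_input <- seq_len(n) <= config$n_inputs

  rand_atom <- function(reg) {
    ml <- maxlev[match(reg, nms)]
    form <- sample(c("truthy", "eq", "lt", "ge", "neg"), 1)
    switch(form,
      truthy = reg,
      neg = paste0("!", reg),
      eq = paste0(reg, "=", sample.int(ml, 1)),
      lt = paste0(reg, "<", sample.int(ml, 1)),
      ge = paste0(reg, ">=", sample.int(ml, 1)))
  }
  rand_clause <- function(regs) {
    k <- max(1L, min(length(regs), stats::rpois(1, config$density - 1) + 1L))
    picked <- sample(regs, k)
    paste(vapply(picked, rand_atom, character(1)), collapse = " & ")
  }
  rand_rule <- function(regs) {
    nclause <- sample.int(2L, 1)
    clauses <- vapply(seq_len(nclause), function(i) rand_clause(regs),
                      character(1))
    paste(clauses, collapse = " | ")
  }

  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_input[i]) {
      nodes[[i]] <- node_spec(nms[i], maxlev[i], input = TRUE)
      next
    }
    nreg <- max(1L, min(n, stats::rpois(1, config$density - 1) + 1L))
    regs <- sample(nms, nreg)
    rules <- list()
    for (lev in seq_len(maxlev[i])) {
      rules[[as.character(lev)]] <- rand_rule(regs)
    }
    nodes[[i]] <- node_spec(nms[i], maxlev[i], rules = rules)
  }
  logical_model(nodes, name = sprintf("random_n%d_seed%d", n, config$seed))
}

#' Brute-force attractor oracle
#'
#' Finds the attractors of a clamped subspace without any strongly-
#' connected-component machinery: it enumerates all transitions with its
#' own scalar rule evaluator, computes each state's forward reachable set
#' by breadth-first search, keeps the states `s` for which every reachable
#' `t` can reach `s` back (exactly the states trapped in a terminal
#' strongly connected set), and groups them by mutual reachability.
#' Intended as an independent oracle for [terminal_sccs()] on small
#' networks.
#'
#' @param model A `logical_model`.
#' @param clamp Named integer vector covering at least the input nodes.
#' @param max_states Hard cap on the subspace size (default 10^4).
#' @return List of `attractor` objects in the same deterministic order as
#'   [terminal_sccs()] (smallest member state first).
#' @export
brute_force_attractors <- function(model, clamp = integer(0),
                                   max_states = 1e4) {
  S <- enumerate_states(model, clamp, limit = max_states)
  n <- nrow(S)
  nms <- node_names(model)
  free <- setdiff(nms, names(clamp))
  rule_nodes <- free[vapply(model$nodes[free], function(nd) length(nd$rules) > 0,
                            logical(1))]

  # scalar target evaluation, written against the AST directly (no shared
  # vectorized path, no matrices)
  eval_scalar <- function(e, st) {
    switch(e$op,
      atom = {
        v <- st[[e$var]]
        switch(e$cmp, ge = v >= e$k, eq = v == e$k, lt = v < e$k)
      },
      not = !eval_scalar(e$arg, st),
      and = { for (a in e$args) if (!eval_scalar(a, st)) return(FALSE); TRUE },
      or  = { for (a in e$args) if (eval_scalar(a, st)) return(TRUE); FALSE })
  }
  scalar_target <- function(nd, st) {
    for (r in nd$rules) if (eval_scalar(r$expr, st)) return(r$level)
    0L
  }

  # index lookup by state key
  key_of <- function(st) paste(st[free], collapse = ",")
  keys <- apply(S[, free, drop = FALSE], 1, paste, collapse = ",")
  lookup <- stats::setNames(seq_len(n), keys)

  adj <- vector("list", n)
  for (i in seq_len(n)) {
    st <- S[i, ]
    nxt <- integer(0)
    for (v in rule_nodes) {
      tgt <- scalar_target(model$nodes[[v]], st)
      if (tgt != st[[v]]) {
        s2 <- st
        s2[[v]] <- st[[v]] + if (tgt > st[[v]]) 1L else -1L
        nxt <- c(nxt, lookup[[key_of(s2)]])
      }
    }
    adj[[i]] <- nxt
  }

  reach <- vector("list", n)
  for (i in seq_len(n)) {
    seen <- logical(n)
    seen[i] <- TRUE
    frontier <- i
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- nxt[!seen[nxt]]
      seen[frontier] <- TRUE
    }
    reach[[i]] <- which(seen)
  }

  in_attractor <- vapply(seq_len(n), function(i) {
    all(vapply(reach[[i]], function(t) i %in% reach[[t]], logical(1)))
  }, logical(1))

  members <- which(in_attractor)
  atts <- list()
  while (length(members)) {
    s0 <- members[1]
    grp <- intersect(reach[[s0]], members)  # mutual by construction
    atts[[length(atts) + 1L]] <- new_attractor(
      S[sort(grp), , drop = FALSE], clamp, first_index = min(grp))
    members <- setdiff(members, grp)
  }
  first_row <- vapply(atts, function(a) a$first_index, numeric(1))
  atts[order(first_row)]
}
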