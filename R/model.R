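# Logical models: named collections of node specifications.  Each node has a
# maximum level (1 = Boolean, 2 = ternary), an input flag, and for non-input
# nodes an ordered list of (target level, rule) pairs.  Rules are scanned
# highest target level first; the first rule whose expression is true gives
# the node's target level, and 0 is the default when none applies.

#' Define a node of a logical model
#'
#' @param name Node name (letters, digits, `_`, `-`, `.`; must start with a
#'   letter).
#' @param max_level Highest level the node can take (1 for Boolean, 2 for
#'   ternary).
#' @param rules Named list mapping target levels (as names, e.g. `"1"`,
#'   `"2"`) to rule strings in the grammar of [parse_rule()].  Must be empty
#'   for input nodes.
#' @param input Logical; input nodes carry no rules and are clamped to an
#'   environmental level for every simulation.
#' @param semantics Optional named character vector annotating what
#'   individual levels mean biologically (names are levels).
#' @return A `node_spec` object.
#' @export
node_spec <- function(name, max_level, rules = list(), input = FALSE,
                      semantics = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            grepl("^[A-Za-z][A-Za-z0-9_.-]*$", name))
  max_level <- as.integer(max_level)
  stopifnot(max_level >= 1L)
  parsed <- list()
  if (length(rules)) {
    levs <- as.integer(names(rules))
    if (anyNA(levs)) stop("rules must be named by target level")
    ord <- order(levs, decreasing = TRUE)  # highest-first scan order
    parsed <- lapply(ord, function(i) {
      list(level = levs[i],
           expr = if (inherits(rules[[i]], "level_expr")) rules[[i]]
                  else parse_rule(rules[[i]]))
    })
  }
  structure(list(name = name, max_level = max_level, input = isTRUE(input),
                 rules = parsed, semantics = semantics),
            class = "node_spec")
}

#' Assemble a logical model
#'
#' @param nodes List of [node_spec()] objects, in the order that defines
#'   state enumeration and reporting.
#' @param name Model name.
#' @return A validated `logical_model` object.
#' @export
logical_model <- function(nodes, name = "model") {
  stopifnot(all(vapply(nodes, inherits, logical(1), "node_spec")))
  m <- structure(list(name = name, nodes = nodes), class = "logical_model")
  names(m$nodes) <- vapply(nodes, `[[`, character(1), "name")
  diags <- validate_model(m)
  if (length(diags)) {
    stop("invalid logical model:\n  ", paste(diags, collapse = "\n  "))
  }
  m
}

#' Validate a logical model
#'
#' Checks the structural invariants of a model and returns diagnostics
#' instead of throwing: unique node names, input nodes without rules,
#' distinct target levels per node, every referenced variable an existing
#' node, and every comparison level within the referenced node's range.
#'
#' @param model A `logical_model` (or a bare list shaped like one).
#' @return Character vector of diagnostics; empty when the model is
#'   well-formed.
#' @export
validate_model <- function(model) {
  diags <- character(0)
  nms <- vapply(model$nodes, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    diags <- c(diags, paste0("duplicate node name: ", dup))
  }
  maxlev <- stats::setNames(
    vapply(model$nodes, `[[`, integer(1), "max_level"), nms)
  for (nd in model$nodes) {
    if (nd$input && length(nd$rules)) {
      diags <- c(diags, paste0("input node ", nd$name, " has rules"))
    }
    levs <- vapply(nd$rules, `[[`, integer(1), "level")
    if (anyDuplicated(levs)) {
      diags <- c(diags, paste0("node ", nd$name, " repeats a target level"))
    }
    if (any(levs < 1L | levs > nd$max_level)) {
      diags <- c(diags, paste0("node ", nd$name,
                               " has a target level outside 1..", nd$max_level))
    }
    for (r in nd$rules) {
      for (a in expr_atoms_raw(r$expr)) {
        if (!a$var %in% nms) {
          diags <- c(diags, paste0("rule for ", nd$name, " level ", r$level,
                                   " references unknown node ", a$var))
        } else if (a$k < 0L || a$k > maxlev[[a$var]]) {
          diags <- c(diags, paste0("rule for ", nd$name, " level ", r$level,
                                   " compares ", a$var, " against out-of-range level ",
                                   a$k))
        }
      }
    }
  }
  diags
}

# raw atoms (var, cmp, k) without the threshold normalization of expr_atoms()
expr_atoms_raw <- function(expr) {
  acc <- list()
  walk <- function(e) {
    if (e$op == "atom") acc[[length(acc) + 1L]] <<- e
    else if (e$op == "not") walk(e$arg)
    else lapply(e$args, walk)
    invisible(NULL)
  }
  walk(expr)
  acc
}

node_names <- function(model) names(model$nodes)

max_levels <- function(model) {
  stats::setNames(vapply(model$nodes, `[[`, integer(1), "max_level"),
                  node_names(model))
}

input_nodes <- function(model) {
  node_names(model)[vapply(model$nodes, `[[`, logical(1), "input")]
}

#' Internal (non-input) nodes of a model
#' @param model A `logical_model`.
#' @return Character vector of node names.
#' @export
internal_nodes <- function(model) {
  setdiff(node_names(model), input_nodes(model))
}

#' @export
print.logical_model <- function(x, ...) {
  ml <- max_levels(x)
  cat("Logical model:", x$name, "\n")
  cat(" ", length(x$nodes), "nodes (",
      sum(ml == 1L), "Boolean,", sum(ml > 1L), "multivalued ),",
      length(input_nodes(x)), "inputs\n")
  cat("  state space:", format(prod(ml + 1), big.mark = ","), "states\n")
  invisible(x)
}

#' @export
summary.logical_model <- function(object, ...) {
  df <- do.call(rbind, lapply(object$nodes, function(nd) {
    data.frame(node = nd$name, max_level = nd$max_level,
               input = nd$input, n_rules = length(nd$rules),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Regulatory dependency graph of a model
#'
#' One row per (regulator, target) pair such that the regulator's level is
#' tested by at least one rule of the target.  The `thresholds` column lists
#' the comparison levels at which the regulator appears in those rules; a
#' regulator acting at several thresholds is still a single edge.
#'
#' @param model A `logical_model`.
#' @return A data frame with columns `regulator`, `target`, `thresholds`
#'   (comma-separated levels).
#' @export
dependency_graph <- function(model) {
  rows <- list()
  for (nd in model$nodes) {
    th <- list()
    for (r in nd$rules) {
      for (a in expr_atoms(r$expr)) {
        th[[a$var]] <- sort(unique(c(th[[a$var]], a$level)))
      }
    }
    for (reg in names(th)) {
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = reg, target = nd$name,
        thresholds = paste(th[[reg]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(regulator = character(0), target = character(0),
                      thresholds = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(match(df$target, node_names(model)),
           match(df$regulator, node_names(model))), , drop = FALSE] ->
    df
  rownames(df) <- NULL
  df
}

#' Regulators of one node
#' @param model A `logical_model`.
#' @param node Node name.
#' @return Character vector of regulator node names.
#' @export
regulators <- function(model, node) {
  dg <- dependency_graph(model)
  dg$regulator[dg$target == node]
}
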