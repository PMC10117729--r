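# Module-level behavior classification.  A module oscillates in an
# attractor when at least one of its member nodes does; the pattern of
# oscillating modules across the three process modules (oxidative stress,
# iron homeostasis, IscRSUA) defines the behavior class of a condition.
# For the wild-type Fe-S network five classes arise (I-V).

#' Oscillation signature of an attractor at the module scale
#'
#' @param attractor An `attractor`.
#' @param modules Named list of node sets (default [fes_modules()]).
#' @return Named logical vector: for each module, `TRUE` iff at least one
#'   member node oscillates in the attractor.
#' @export
module_signature <- function(attractor, modules = fes_modules()) {
  s <- summary(attractor)
  miss <- setdiff(unlist(modules), s$node)
  if (length(miss)) {
    stop("module member(s) absent from the model: ",
         paste(miss, collapse = ", "))
  }
  vapply(modules, function(mem) any(s$oscillating[s$node %in% mem]),
         logical(1))
}

# The five wild-type signature patterns over the three process modules,
# keyed by which modules oscillate: I none; II iron only; III iron+IscRSUA
# (no oxidative stress); IV oxidative+iron (no IscRSUA); V all three.
wt_class_patterns <- function() {
  list(I   = c(oxidative_stress = FALSE, iron = FALSE, iscrsua = FALSE),
       II  = c(oxidative_stress = FALSE, iron = TRUE,  iscrsua = FALSE),
       III = c(oxidative_stress = FALSE, iron = TRUE,  iscrsua = TRUE),
       IV  = c(oxidative_stress = TRUE,  iron = TRUE,  iscrsua = FALSE),
       V   = c(oxidative_stress = TRUE,  iron = TRUE,  iscrsua = TRUE))
}

#' Classify the conditions of an atlas by module signature
#'
#' Class identity is the oscillation signature over the three process
#' modules (`oxidative_stress`, `iron`, `iscrsua`); readout singletons are
#' reported but do not enter class identity.  Signatures matching one of
#' the five canonical wild-type patterns get its Roman numeral (I-V);
#' any other signature gets the next numeral in first-appearance order.
#'
#' @param atlas A `condition_atlas`.
#' @param modules Named list of node sets; only the three process modules
#'   participate in class identity.
#' @return Data frame with one row per condition: `condition`, `Fe_ext`,
#'   `O2`, one logical column per process module, and `class`.
#' @export
classify_grid <- function(atlas, modules = fes_modules()) {
  core <- c("oxidative_stress", "iron", "iscrsua")
  core <- core[core %in% names(modules)]
  if (!length(core)) core <- names(modules)
  rows <- lapply(names(atlas$entries), function(cn) {
    e <- atlas$entries[[cn]]
    if (e$multiple) stop("condition ", cn, " has multiple attractors")
    sig <- module_signature(e$attractor, modules[core])
    fe <- if ("Fe_ext" %in% names(e$inputs)) e$inputs[["Fe_ext"]] else NA_integer_
    o2 <- if ("O2" %in% names(e$inputs)) e$inputs[["O2"]] else NA_integer_
    cbind(data.frame(condition = cn, Fe_ext = fe, O2 = o2,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sig)))
  })
  df <- do.call(rbind, rows)
  sigkey <- apply(df[, make.names(core), drop = FALSE], 1,
                  function(r) paste(as.logical(r), collapse = "/"))
  pats <- wt_class_patterns()
  patkey <- vapply(pats, function(p) {
    paste(p[core], collapse = "/")
  }, character(1))
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  cls <- character(nrow(df))
  extra <- list()
  for (i in seq_len(nrow(df))) {
    hit <- names(patkey)[patkey == sigkey[i]]
    if (length(hit) == 1L && length(core) == 3L) {
      cls[i] <- hit
    } else {
      if (is.null(extra[[sigkey[i]]])) {
        extra[[sigkey[i]]] <- roman[length(pats) + length(extra) + 1L]
      }
      cls[i] <- extra[[sigkey[i]]]
    }
  }
  df$class <- cls
  rownames(df) <- NULL
  df
}

#' Heatmap data table for selected nodes of an atlas
#'
#' Long-format table (condition, node, mean, oscillating, min, max) for the
#' requested nodes: the numbers behind the per-node condition-grid
#' heatmaps.
#'
#' @param atlas A `condition_atlas`.
#' @param nodes Nodes to include (default: the six readout nodes
#'   `Fe_free`, `H2O2`, `Isc`, `Suf`, `ErpA`, `NfuA`).
#' @return Data frame with columns `condition`, `Fe_ext`, `O2`, `node`,
#'   `mean`, `oscillating`, `min`, `max`.
#' @export
heatmap_table <- function(atlas, nodes = c("Fe_free", "H2O2", "Isc",
                                           "Suf", "ErpA", "NfuA")) {
  df <- as.data.frame(atlas)
  df <- df[df$node %in% nodes, ]
  df$node <- factor(df$node, levels = nodes)
  df <- df[order(df$node, df$Fe_ext, df$O2), ]
  df$node <- as.character(df$node)
  rownames(df) <- NULL
  df[, c("condition", "Fe_ext", "O2", "node", "mean", "oscillating",
         "min", "max")]
}
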