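# Genetic perturbations are clamps over internal nodes: a knock-out fixes a
# node at 0, an ectopic expression fixes it at a nonzero level.  Inputs are
# environmental conditions, not genotypes, and cannot be perturbed.

#' Define a perturbation (mutant)
#'
#' @param clamp Named integer vector over internal (non-input) nodes; 0 for
#'   a knock-out, a nonzero level for ectopic expression.
#' @param model Model the perturbation applies to (used for validation).
#' @param label Optional label; derived from the clamp when missing
#'   (e.g. `"Fur KO"`, `"Suf=2"`).
#' @return A `perturbation` object with fields `label` and `clamp`.
#' @export
perturbation <- function(clamp, model = fes_model(), label = NULL) {
  check_clamp(model, clamp)
  bad <- intersect(names(clamp), input_nodes(model))
  if (length(bad)) {
    stop("cannot perturb input node(s): ", paste(bad, collapse = ", "),
         "; inputs are environmental conditions, not genotypes")
  }
  if (is.null(label)) {
    label <- paste(ifelse(clamp == 0, paste(names(clamp), "KO"),
                          paste0(names(clamp), "=", clamp)),
                   collapse = " + ")
  }
  structure(list(label = label, clamp = clamp), class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("Perturbation:", x$label, "\n")
  invisible(x)
}

#' Combine two perturbations
#'
#' The union of the two clamps; clamping the same node at two different
#' levels is an error.
#'
#' @param a,b `perturbation` objects (for the same model).
#' @param model Model used for validation.
#' @return A combined `perturbation`.
#' @export
combine_perturbations <- function(a, b, model = fes_model()) {
  both <- intersect(names(a$clamp), names(b$clamp))
  conflict <- both[a$clamp[both] != b$clamp[both]]
  if (length(conflict)) {
    stop("conflicting clamps on: ", paste(conflict, collapse = ", "))
  }
  perturbation(c(a$clamp, b$clamp[setdiff(names(b$clamp), names(a$clamp))]),
               model = model,
               label = paste(a$label, "+", b$label))
}

#' Enumerate single-node perturbations
#'
#' Each internal node clamped at each of its levels: the knock-out (level 0)
#' and one ectopic variant per level >= 1.  For the Fe-S model this yields
#' 29 perturbations (7 Boolean x 2 + 5 ternary x 3).
#'
#' @param model A `logical_model`.
#' @param ko_only If `TRUE`, only the knock-outs (clamp to 0).
#' @return List of `perturbation` objects in deterministic (node, level)
#'   order.
#' @export
enumerate_single_mutants <- function(model, ko_only = FALSE) {
  ml <- max_levels(model)
  out <- list()
  for (v in internal_nodes(model)) {
    levs <- if (ko_only) 0L else 0:ml[[v]]
    for (k in levs) {
      out[[length(out) + 1L]] <-
        perturbation(stats::setNames(as.integer(k), v), model = model)
    }
  }
  out
}

#' Enumerate knock-out pairs
#'
#' All unordered pairs of internal-node knock-outs (66 pairs for the 12
#' internal nodes of the Fe-S model).
#'
#' @param model A `logical_model`.
#' @return List of `perturbation` objects clamping two nodes to 0.
#' @export
enumerate_double_kos <- function(model) {
  vs <- internal_nodes(model)
  out <- list()
  for (i in seq_along(vs)) {
    for (j in seq_along(vs)) {
      if (j <= i) next
      out[[length(out) + 1L]] <- perturbation(
        stats::setNames(c(0L, 0L), c(vs[i], vs[j])), model = model)
    }
  }
  out
}

#' Attractor atlas of a mutant
#'
#' Nine-condition atlas under a perturbation clamp; same contract as the
#' wild-type atlas.
#'
#' @param model A `logical_model`.
#' @param perturbation A [perturbation()] or named clamp vector.
#' @param conditions List of input clamps (default [fes_conditions()]).
#' @return A `condition_atlas`.
#' @export
mutant_atlas <- function(model = fes_model(), perturbation,
                         conditions = fes_conditions()) {
  condition_atlas(model, perturbation = perturbation,
                  conditions = conditions)
}

#' Growth-defect screen over perturbations and conditions
#'
#' For every (perturbation, condition) pair, computes the attractor and
#' flags a predicted growth defect when *both* Fe-S biogenesis machineries
#' are fully off — `Isc = 0` and `Suf = 0` in every attractor state — so
#' that no Fe-S cluster assembly route remains, even transiently.  The
#' wild type is always included as a baseline.
#'
#' @param model A `logical_model` (default: the Fe-S model).
#' @param perturbations List of [perturbation()] objects (default: all
#'   single knock-outs).
#' @param conditions List of input clamps (default [fes_conditions()]).
#' @param machinery Nodes that must all be off to flag a defect.
#' @return A `screen_report`: data frame with one row per (perturbation,
#'   condition, node) summary plus the per-condition `defect` flag, and the
#'   attribute `defective`, the character vector of perturbation labels
#'   with at least one flagged condition.
#' @export
growth_defect_screen <- function(model = fes_model(),
                                 perturbations = enumerate_single_mutants(model, ko_only = TRUE),
                                 conditions = fes_conditions(),
                                 machinery = c("Isc", "Suf")) {
  stopifnot(all(machinery %in% node_names(model)))
  rows <- list()
  baseline <- list(structure(list(label = "WT", clamp = integer(0)),
                             class = "perturbation"))
  for (p in c(baseline, perturbations)) {
    for (cn in names(conditions)) {
      inputs <- conditions[[cn]]
      res <- condition_attractor(model, inputs, p)
      atts <- if (inherits(res, "attractor")) list(res) else res
      # defect: machinery nodes are 0 in every state of every attractor
      off <- all(vapply(atts, function(a) {
        all(a$states[, machinery, drop = FALSE] == 0L)
      }, logical(1)))
      for (a in atts) {
        s <- summary(a)
        s$perturbation <- p$label
        s$Fe_ext <- inputs[["Fe_ext"]]
        s$O2 <- inputs[["O2"]]
        s$defect <- off
        rows[[length(rows) + 1L]] <- s
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[, c("perturbation", "Fe_ext", "O2", "node", "min", "max",
               "mean", "oscillating", "defect")]
  rownames(df) <- NULL
  flagged <- unique(df$perturbation[df$defect])
  structure(df, defective = flagged, class = c("screen_report", "data.frame"))
}

#' @export
print.screen_report <- function(x, ...) {
  labs <- unique(x$perturbation)
  flagged <- attr(x, "defective")
  cat("Growth-defect screen:", length(labs) - 1L, "perturbations x",
      length(unique(paste(x$Fe_ext, x$O2))), "conditions\n")
  if (length(flagged)) {
    cat("  defect-flagged:", paste(flagged, collapse = ", "), "\n")
    sub <- unique(x[x$defect, c("perturbation", "Fe_ext", "O2")])
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %s at Fe_ext=%d, O2=%d\n", sub$perturbation[i],
                  sub$Fe_ext[i], sub$O2[i]))
    }
  } else {
    cat("  no defect-flagged perturbation\n")
  }
  invisible(x)
}

#' Perturbation labels flagged by a screen
#' @param report A `screen_report`.
#' @return Character vector of defect-bearing perturbation labels.
#' @export
defective_perturbations <- function(report) {
  attr(report, "defective")
}
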