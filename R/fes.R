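# The Fe-S cluster biogenesis regulatory network of E. coli: 14 nodes, two
# environmental inputs (external iron Fe_ext and oxygen O2, both ternary),
# and twelve internal nodes spanning three biological processes — oxidative
# stress (H2O2, OxyR, Hpx), iron homeostasis (Fe_free, Fur, RyhB) and the
# IscRSUA module (IscR-A, IscR-H, Isc) — plus the readouts Suf, ErpA, NfuA.
#
# Level conventions: Fe_ext 0/1/2 = starvation / 1-5 uM / >5-10 uM external
# iron; O2 0/1/2 = anaerobiosis / aerobiosis / oxidative stress (external
# H2O2 > 2 uM); Fe_free 0/1/2 = <=1 uM / ~10 uM / >=50 uM internal Fe2+;
# H2O2 = 1 means internal [H2O2] >= 50 nM; Hpx basal level is 1
# (constitutive catalases), level 2 the OxyR-induced level, level 0 being
# reserved for a Hpx knock-out; Fur 1/2 = partial / full repression; RyhB
# 1/2 = Isc inhibition / Isc+ErpA inhibition; Suf 1/2 = medium / high
# expression.

#' The Fe-S cluster biogenesis logical model
#'
#' Constructs the 14-node multivalued logical model of the regulatory
#' network coordinating the Isc and Suf Fe-S cluster assembly machineries
#' with iron homeostasis (Fur, RyhB) and the peroxide stress response
#' (OxyR, Hpx) in *Escherichia coli*.
#'
#' @return A `logical_model` with nodes, in order: Fe_ext, O2, Fe_free,
#'   H2O2, OxyR, Hpx, Fur, RyhB, IscR-A, IscR-H, Isc, Suf, ErpA, NfuA.
#' @examples
#' m <- fes_model()
#' summary(m)
#' @export
fes_model <- function() {
  logical_model(name = "FeS_biogenesis", nodes = list(
    node_spec("Fe_ext", 2, input = TRUE, semantics = c(
      "0" = "external iron < 1 uM (starvation)",
      "1" = "external iron 1-5 uM",
      "2" = "external iron > 5-10 uM")),
    node_spec("O2", 2, input = TRUE, semantics = c(
      "0" = "anaerobiosis",
      "1" = "aerobiosis",
      "2" = "oxidative stress, external [H2O2] > 2 uM")),
    node_spec("Fe_free", 2, rules = list(
      "1" = paste0(
        "(!Fe_ext & ((H2O2 & !OxyR) | RyhB=2))",
        " | ((Fe_ext=2 | (Fe_ext=1 & !O2)) & Fur=2 & RyhB<2)",
        " | (Fe_ext=1 & O2>=1 & RyhB<2 & !(H2O2 & Fur<2))"),
      "2" = paste0(
        "((Fe_ext=2 | (Fe_ext=1 & !O2)) & (Fur<2 | (RyhB=2 & Fur=2)))",
        " | (Fe_ext=1 & O2>=1 & (RyhB=2 | (H2O2 & Fur<2)))")),
      semantics = c("0" = "free Fe2+ <= 1 uM",
                    "1" = "free Fe2+ around 10 uM",
                    "2" = "free Fe2+ >= 50 uM")),
    node_spec("H2O2", 1, rules = list(
      "1" = "(O2=1 & !Hpx & Fe_free=2) | (O2=2 & Hpx<2)"),
      semantics = c("1" = "internal [H2O2] >= 50 nM (activates OxyR)")),
    node_spec("OxyR", 1, rules = list("1" = "H2O2")),
    node_spec("Hpx", 2, rules = list(
      "1" = "!OxyR",
      "2" = "OxyR"),
      semantics = c("0" = "Hpx knock-out only",
                    "1" = "basal catalase/peroxidase expression",
                    "2" = "OxyR-induced expression")),
    node_spec("Fur", 2, rules = list(
      "1" = "Fe_free=1 & (!H2O2 | OxyR)",
      "2" = "Fe_free=2 & (!H2O2 | OxyR)"),
      semantics = c("1" = "partial repression (RyhB only)",
                    "2" = "full repression of the Fur regulon")),
    node_spec("RyhB", 2, rules = list(
      "1" = "Fur=1",
      "2" = "!Fur"),
      semantics = c("1" = "inhibits Isc translation",
                    "2" = "inhibits Isc and ErpA")),
    node_spec("IscR-A", 1, rules = list("1" = "!IscR-H")),
    node_spec("IscR-H", 1, rules = list("1" = "IscR-A & Isc & !H2O2")),
    node_spec("Isc", 1, rules = list(
      "1" = "!IscR-H & !RyhB & Fe_free=2 & !H2O2")),
    node_spec("Suf", 2, rules = list(
      "1" = "Fur<2 & (OxyR | IscR-A) & !(OxyR & IscR-A)",
      "2" = "Fur<2 & OxyR & IscR-A"),
      semantics = c("1" = "medium suf operon expression",
                    "2" = "high suf operon expression")),
    node_spec("ErpA", 1, rules = list("1" = "!IscR-H & RyhB<2")),
    node_spec("NfuA", 1, rules = list("1" = "!IscR-H"))
  ))
}

#' The module partition of the Fe-S model
#'
#' The three strongly connected biological-process modules used for behavior
#' classification, plus the three readout nodes tracked individually.
#'
#' @return Named list of character vectors: `oxidative_stress`, `iron`,
#'   `iscrsua`, and singleton sets `Suf`, `ErpA`, `NfuA`.
#' @export
fes_modules <- function() {
  list(oxidative_stress = c("H2O2", "OxyR", "Hpx"),
       iron = c("Fe_free", "Fur", "RyhB"),
       iscrsua = c("IscR-A", "IscR-H", "Isc"),
       Suf = "Suf", ErpA = "ErpA", NfuA = "NfuA")
}

#' The 3 x 3 grid of environmental conditions
#'
#' All nine input clamps \{(Fe_ext, O2)\} with each input at level 0, 1
#' or 2, in row-major order (Fe_ext slowest).
#'
#' @return Named list of input clamps (named integer vectors); names are of
#'   the form `"Fe_ext=i,O2=j"`.
#' @export
fes_conditions <- function() {
  out <- list()
  for (fe in 0:2) for (o2 in 0:2) {
    out[[sprintf("Fe_ext=%d,O2=%d", fe, o2)]] <-
      c(Fe_ext = fe, O2 = o2)
  }
  out
}

#' Attractor atlas over a condition grid
#'
#' Computes the attractor of every condition of the grid (optionally under a
#' perturbation clamp) and its per-node asymptotic summary.  Conditions
#' whose subspace carries more than one attractor are flagged, never
#' silently dropped.
#'
#' @param model A `logical_model` (default: the Fe-S model).
#' @param perturbation Optional [perturbation()] or named clamp vector over
#'   internal nodes.
#' @param conditions List of input clamps (default: [fes_conditions()]).
#' @return A `condition_atlas`: named list with one entry per condition,
#'   each holding `inputs`, `attractor` (or the list of attractors when
#'   multiple), `multiple` flag and `summary` (the data frame of
#'   [summary.attractor()]).
#' @export
condition_atlas <- function(model = fes_model(), perturbation = NULL,
                            conditions = fes_conditions()) {
  entries <- lapply(names(conditions), function(cn) {
    inputs <- conditions[[cn]]
    res <- condition_attractor(model, inputs, perturbation)
    if (inherits(res, "attractor")) {
      list(inputs = inputs, attractor = res, multiple = FALSE,
           summary = summary(res))
    } else {
      list(inputs = inputs, attractor = res, multiple = TRUE,
           summary = NULL)
    }
  })
  names(entries) <- names(conditions)
  structure(list(entries = entries,
                 perturbation = perturbation,
                 model_name = model$name),
            class = "condition_atlas")
}

#' Wild-type attractor atlas of the Fe-S model
#'
#' The nine-condition atlas of the unperturbed Fe-S network: one attractor
#' per (Fe_ext, O2) combination, summarized per node.
#'
#' @return A `condition_atlas` (see [condition_atlas()]).
#' @export
wildtype_atlas <- function() {
  condition_atlas(fes_model())
}

#' @export
print.condition_atlas <- function(x, ...) {
  cat("Condition atlas (", x$model_name, "), ",
      length(x$entries), " conditions\n", sep = "")
  pert <- x$perturbation
  if (inherits(pert, "perturbation")) {
    cat("  perturbation:", pert$label, "\n")
  } else if (length(pert)) {
    cat("  perturbation:", paste(names(pert), pert, sep = "=", collapse = ","),
        "\n")
  }
  for (cn in names(x$entries)) {
    e <- x$entries[[cn]]
    if (e$multiple) {
      cat(" ", cn, ": MULTIPLE attractors (", length(e$attractor), ")\n")
    } else {
      cat(sprintf("  %-16s %-12s size %d\n", cn, e$attractor$kind,
                  e$attractor$size))
    }
  }
  invisible(x)
}

#' Long-format summary table of an atlas
#'
#' @param x A `condition_atlas`.
#' @param ... Unused.
#' @return Data frame with columns `condition`, `Fe_ext`, `O2`, `node`,
#'   `min`, `max`, `mean`, `oscillating` — the data behind the heatmap
#'   figures.
#' @export
as.data.frame.condition_atlas <- function(x, ...) {
  rows <- lapply(names(x$entries), function(cn) {
    e <- x$entries[[cn]]
    if (e$multiple) {
      stop("condition ", cn, " has multiple attractors; summarize them ",
           "individually")
    }
    s <- e$summary
    s$condition <- cn
    s$Fe_ext <- e$inputs[["Fe_ext"]]
    s$O2 <- e$inputs[["O2"]]
    s
  })
  df <- do.call(rbind, rows)
  df[, c("condition", "Fe_ext", "O2", "node", "min", "max", "mean",
         "oscillating")]
}

#' Heat-map style plot of an atlas
#'
#' Draws the 3 x 3 condition grid for a set of nodes, shading each cell by
#' the mean attractor level and marking oscillating nodes with a tilde —
#' a base-graphics view of the table from [as.data.frame.condition_atlas()].
#'
#' @param x A `condition_atlas`.
#' @param nodes Nodes to draw (default: the six readout nodes).
#' @param ... Unused.
#' @return Invisibly, the plotted data frame.
#' @export
plot.condition_atlas <- function(x, nodes = c("Fe_free", "H2O2", "Isc",
                                              "Suf", "ErpA", "NfuA"), ...) {
  df <- as.data.frame(x)
  df <- df[df$node %in% nodes, ]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(nodes)),
                       mar = c(2.5, 2.5, 2, 0.5))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("white", "firebrick"))(101)
  for (nd in nodes) {
    d <- df[df$node == nd, ]
    mx <- max(d$max, 1)
    graphics::plot(NA, xlim = c(-0.5, 2.5), ylim = c(-0.5, 2.5),
                   xlab = "", ylab = "", axes = FALSE, main = nd, asp = 1)
    graphics::axis(1, at = 0:2, labels = 0:2, tick = FALSE, line = -0.8)
    graphics::axis(2, at = 0:2, labels = 0:2, tick = FALSE, line = -0.8,
                   las = 1)
    graphics::mtext("O2", 1, line = 1.3, cex = 0.7)
    graphics::mtext("Fe_ext", 2, line = 1.3, cex = 0.7)
    for (i in seq_len(nrow(d))) {
      col <- pal[round(100 * d$mean[i] / mx) + 1]
      graphics::rect(d$O2[i] - 0.5, d$Fe_ext[i] - 0.5,
                     d$O2[i] + 0.5, d$Fe_ext[i] + 0.5,
                     col = col, border = "grey40")
      lab <- sprintf("%.2g%s", d$mean[i], if (d$oscillating[i]) "~" else "")
      graphics::text(d$O2[i], d$Fe_ext[i], lab, cex = 0.8)
    }
  }
  invisible(df)
}

#' Path to the shipped Fe-S model-definition file
#'
#' The Fe-S network also ships as a plain-text model file readable with
#' [read_model()]; it loads identically to [fes_model()].
#'
#' @return File path.
#' @export
fes_model_file <- function() {
  system.file("extdata", "fes_model.txt", package = "fesnet", mustWork = TRUE)
}
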