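# Plain-text model-definition files.  One model per file:
#
#   model <name>
#   node <name> max=<k> [input]
#     <level>: <rule>          # rules, highest target level first
#     @<level>: <annotation>   # optional level semantics
#
# write_model() emits the canonical form; read_model() of a canonical file
# followed by write_model() reproduces the file byte for byte.

#' Write a logical model to a definition file
#'
#' @param model A `logical_model`.
#' @param path Output file path (or `""` to return the text invisibly only).
#' @return Invisibly, the character vector of lines written.
#' @export
write_model <- function(model, path) {
  lines <- c(paste("model", model$name))
  for (nd in model$nodes) {
    hdr <- paste0("node ", nd$name, " max=", nd$max_level,
                  if (nd$input) " input" else "")
    lines <- c(lines, hdr)
    for (r in nd$rules) {
      lines <- c(lines, paste0("  ", r$level, ": ", deparse_rule(r$expr)))
    }
    if (!is.null(nd$semantics)) {
      for (lev in names(nd$semantics)) {
        lines <- c(lines, paste0("  @", lev, ": ", nd$semantics[[lev]]))
      }
    }
  }
  if (nzchar(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  invisible(lines)
}

#' Read a logical model from a definition file
#'
#' @param path Path to a file written by [write_model()] (or hand-written in
#'   the same format).
#' @return A `logical_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- "model"
  nodes <- list()
  cur <- NULL
  flush_node <- function() {
    if (is.null(cur)) return()
    sem <- if (length(cur$semantics)) unlist(cur$semantics) else NULL
    nodes[[length(nodes) + 1L]] <<- node_spec(
      cur$name, cur$max, rules = cur$rules, input = cur$input,
      semantics = sem)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || grepl("^\\s*#", ln)) next
    if (grepl("^model\\s+", ln)) {
      name <- trimws(sub("^model\\s+", "", ln))
    } else if (grepl("^node\\s+", ln)) {
      flush_node()
      m <- regmatches(ln, regexec(
        "^node\\s+([A-Za-z][A-Za-z0-9_.-]*)\\s+max=([0-9]+)(\\s+input)?\\s*$",
        ln))[[1]]
      if (!length(m)) stop("malformed node line: ", ln)
      cur <- list(name = m[2], max = as.integer(m[3]),
                  input = nzchar(m[4]), rules = list(), semantics = list())
    } else if (grepl("^\\s+@", ln)) {
      m <- regmatches(ln, regexec("^\\s+@([0-9]+):\\s*(.*)$", ln))[[1]]
      if (!length(m) || is.null(cur)) stop("malformed semantics line: ", ln)
      cur$semantics[[m[2]]] <- m[3]
    } else if (grepl("^\\s+[0-9]+:", ln)) {
      m <- regmatches(ln, regexec("^\\s+([0-9]+):\\s*(.*)$", ln))[[1]]
      if (is.null(cur)) stop("rule line before any node: ", ln)
      cur$rules[[m[2]]] <- m[3]
    } else {
      stop("unrecognized line in model file: ", ln)
    }
  }
  flush_node()
  logical_model(nodes, name = name)
}
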