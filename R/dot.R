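#' Export a causality graph to Graphviz DOT
#'
#' Node shapes follow the graphical convention of the model family:
#' root causes (B) are boxes, observables (X) ellipses, logic gates (G)
#' diamonds, default causes (D) pentagons.  When evidence is supplied the
#' observed state colors the node: green for the normal state 0, sky blue
#' for state 1, yellow for state 2, blue for state 3, brown for state 4;
#' unobserved variables stay uncolored.  Arcs are solid edges; gate inputs
#' are dashed.
#'
#' @param model a [ducg_model()] (original or simplified).
#' @param evidence optional [ducg_evidence()].
#' @param path optional file path to write to.
#' @return the DOT source as a character scalar (invisibly when written
#'   to a file).
#' @export
export_dot <- function(model, evidence = NULL, path = NULL) {
  state_fill <- c("0" = "green", "1" = "skyblue", "2" = "yellow",
                  "3" = "blue", "4" = "brown")
  shapes <- c(B = "box", X = "ellipse", G = "diamond", D = "pentagon")
  obs <- if (!is.null(evidence)) check_evidence(model, evidence)
  else stats::setNames(integer(0), character(0))
  lines <- c("digraph ducg {", "  rankdir=BT;")
  for (i in seq_len(nrow(model$variables))) {
    id <- model$variables$id[[i]]
    kind <- model$variables$kind[[i]]
    attrs <- c(paste0("shape=", shapes[[kind]]))
    if (kind == "D") attrs <- c("shape=polygon", "sides=5")
    o <- obs[id]
    if (!is.na(o) && as.character(o) %in% names(state_fill)) {
      attrs <- c(attrs, "style=filled",
                 paste0("fillcolor=", state_fill[[as.character(o)]]))
      attrs <- c(attrs, paste0("label=\"", id, ",", o, "\""))
    }
    lines <- c(lines, paste0("  \"", id, "\" [", paste(attrs, collapse = ", "), "];"))
  }
  for (arc in model$arcs) {
    lines <- c(lines, paste0("  \"", arc$parent, "\" -> \"", arc$child, "\";"))
  }
  for (g in model$gates) {
    for (inp in g$inputs) {
      lines <- c(lines, paste0("  \"", inp, "\" -> \"", g$gate,
                               "\" [style=dashed];"))
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}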