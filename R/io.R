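#' Read an activity-network model file
#'
#' The model format is a single JSON document with top-level `"nodes"` and
#' `"edges"` arrays plus an optional `"metadata"` object; a machine-readable
#' description ships with the package
#' (`system.file("extdata", "model-format.md", package = "actnet")`).
#' Every structural invariant is checked on load and all violations are
#' reported together.
#'
#' @param path path to a model file.
#' @return a validated `actnet_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$nodes) || length(doc$nodes) == 0L) {
    stop("model file '", path, "' has no \"nodes\" array", call. = FALSE)
  }
  num_or <- function(x, default) if (is.null(x)) default else x
  nodes <- do.call(rbind, lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    if (is.null(nd$name)) stop("node #", i, ": missing \"name\"", call. = FALSE)
    node_spec(nd$name,
              levels = num_or(nd$levels, 100L),
              initial = num_or(nd$initial, 0L),
              clamp = num_or(nd$clamp, NA_integer_),
              reaction_class = num_or(nd$reaction_class, "fast"))
  }))
  edges <- NULL
  if (length(doc$edges)) {
    edges <- do.call(rbind, lapply(seq_along(doc$edges), function(i) {
      ed <- doc$edges[[i]]
      regs <- unlist(ed$regulators)
      if (is.null(regs) || !length(regs) || is.null(ed$target)) {
        stop("edge #", i, ": needs \"regulators\" and \"target\"", call. = FALSE)
      }
      if (length(regs) > 2L) {
        stop("edge #", i, ": at most two regulators", call. = FALSE)
      }
      edge_spec(reg1 = regs[[1L]],
                reg2 = if (length(regs) == 2L) regs[[2L]] else NA_character_,
                target = ed$target,
                sign = num_or(ed$sign, "activation"),
                scenario = num_or(ed$scenario, 1L),
                k = num_or(ed$k, 1.0))
    }))
  }
  metadata <- if (is.null(doc$metadata)) list() else doc$metadata
  network_model(nodes, edges, metadata)
}

#' Write an activity-network model file
#'
#' `load_model(save_model(m))` round-trips the structural content of any
#' valid model.
#'
#' @param model an `actnet_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  nd <- model$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    out <- list(name = nd$name[i], levels = nd$levels[i],
                initial = nd$initial[i],
                reaction_class = nd$reaction_class[i])
    if (!is.na(nd$clamp[i])) out$clamp <- nd$clamp[i]
    out
  })
  ed <- model$edges
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    regs <- ed$reg1[i]
    if (!is.na(ed$reg2[i])) regs <- c(regs, ed$reg2[i])
    list(regulators = as.list(regs), target = ed$target[i], sign = ed$sign[i],
         scenario = ed$scenario[i], k = ed$k[i])
  })
  doc <- list(metadata = model$metadata, nodes = nodes, edges = edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a model as a SIF interaction table
#'
#' One row per edge, `"source relation target"`, with relation tokens
#' `activates` / `inhibits`.  A scenario-3 (AND) edge is a single row whose
#' source field lists both regulators joined by `&`.  SIF drops kinetic
#' detail; it is a one-way export for Cytoscape-style viewers.
#'
#' @param model an `actnet_model`.
#' @param path optional output path; when `NULL` the rows are returned.
#' @return character vector of SIF rows, invisibly when written to a file.
#' @export
export_sif <- function(model, path = NULL) {
  e <- model$edges
  src <- ifelse(is.na(e$reg2), e$reg1, paste0(e$reg1, "&", e$reg2))
  rel <- ifelse(e$sign == "activation", "activates", "inhibits")
  rows <- paste(src, rel, e$target)
  if (is.null(path)) return(rows)
  writeLines(rows, path)
  invisible(rows)
}

#' Export a model as GraphML
#'
#' Emits a directed graph with Cytoscape-standard edge attribute
#' `interaction` (activation/inhibition) plus `scenario` and `k`; node
#' attributes carry `levels`, `initial`, `clamp` and `reaction_class`.  A
#' scenario-3 edge is emitted once, from its first regulator, with the
#' second in the `coregulator` attribute.
#'
#' @param model an `actnet_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(model, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    c("d_levels", "node", "levels", "int"),
    c("d_initial", "node", "initial", "int"),
    c("d_clamp", "node", "clamp", "int"),
    c("d_class", "node", "reaction_class", "string"),
    c("d_int", "edge", "interaction", "string"),
    c("d_scen", "edge", "scenario", "int"),
    c("d_k", "edge", "k", "double"),
    c("d_coreg", "edge", "coregulator", "string"))
  for (kd in keydefs) {
    xml2::xml_add_child(doc, "key", id = kd[1], `for` = kd[2],
                        attr.name = kd[3], attr.type = kd[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  nd <- model$nodes
  for (i in seq_len(nrow(nd))) {
    n <- xml2::xml_add_child(g, "node", id = nd$name[i])
    xml2::xml_add_child(n, "data", key = "d_levels", nd$levels[i])
    xml2::xml_add_child(n, "data", key = "d_initial", nd$initial[i])
    if (!is.na(nd$clamp[i])) {
      xml2::xml_add_child(n, "data", key = "d_clamp", nd$clamp[i])
    }
    xml2::xml_add_child(n, "data", key = "d_class", nd$reaction_class[i])
  }
  ed <- model$edges
  for (i in seq_len(nrow(ed))) {
    e <- xml2::xml_add_child(g, "edge", source = ed$reg1[i],
                             target = ed$target[i])
    xml2::xml_add_child(e, "data", key = "d_int", ed$sign[i])
    xml2::xml_add_child(e, "data", key = "d_scen", ed$scenario[i])
    xml2::xml_add_child(e, "data", key = "d_k", format(ed$k[i], digits = 17))
    if (!is.na(ed$reg2[i])) {
      xml2::xml_add_child(e, "data", key = "d_coreg", ed$reg2[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
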