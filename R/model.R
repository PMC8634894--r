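#' @useDynLib actnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qnorm runif setNames
#' @importFrom utils write.csv modifyList
NULL

#' Construct a node table for an activity network
#'
#' Each node represents a molecular species whose state is an integer
#' activity level between 0 and `levels` (interpreted as a concentration on
#' an arbitrary scale, or as the percentage of active molecules in the
#' population).  A clamped node is held constant during simulation: clamps
#' encode both constant "dummy" inputs and knockout (clamp 0) /
#' constitutive-activation (clamp `levels`) perturbations.
#'
#' @param name character vector of unique node identifiers.
#' @param levels activity granularity per node (default 100).
#' @param initial initial activity in `[0, levels]`.
#' @param clamp optional constant activity; `NA` for unclamped nodes.
#' @param reaction_class `"fast"` (post-translational, k = 1.0 scale) or
#'   `"slow"` (gene expression, k = 0.1 scale); governs default
#'   self-inhibition strength on translation.
#' @return a data frame with one row per node.
#' @export
node_spec <- function(name, levels = 100L, initial = 0L, clamp = NA_integer_,
                      reaction_class = "fast") {
  data.frame(name = as.character(name),
             levels = as.integer(levels),
             initial = as.integer(initial),
             clamp = as.integer(clamp),
             reaction_class = as.character(reaction_class),
             stringsAsFactors = FALSE)
}

#' Construct an edge table for an activity network
#'
#' An edge is one interaction with a sign, a kinetic scenario and a single
#' rate parameter `k`.  Scenario 1 (`R = k * [E]`) depends only on the
#' regulator; scenario 2 (`R = k * [E] * [S]`) also on the availability of
#' the target substrate (its inactive fraction for activations, active
#' fraction for inhibitions); scenario 3 (`R = k * [E1] * [E2]`) is the
#' two-regulator AND kinetics and is the only scenario taking `reg2`.
#'
#' @param reg1,reg2 regulator node names; `reg2` is `NA` except scenario 3.
#' @param target target node name.
#' @param sign `"activation"` or `"inhibition"`.
#' @param scenario 1, 2 or 3.
#' @param k positive interaction strength.
#' @return a data frame with one row per edge.
#' @export
edge_spec <- function(reg1, target, sign = "activation", scenario = 1L,
                      k = 1.0, reg2 = NA_character_) {
  data.frame(reg1 = as.character(reg1),
             reg2 = as.character(reg2),
             target = as.character(target),
             sign = as.character(sign),
             scenario = as.integer(scenario),
             k = as.numeric(k),
             stringsAsFactors = FALSE)
}

#' Assemble and validate an activity-network model
#'
#' @param nodes node table from [node_spec()] (rows may be concatenated with
#'   `rbind`).
#' @param edges edge table from [edge_spec()]; may be `NULL` for an edgeless
#'   model.
#' @param metadata free-form named list (name, provenance, ...).
#' @param validate check all structural invariants (default `TRUE`).
#' @return an object of class `actnet_model`.
#' @export
network_model <- function(nodes, edges = NULL, metadata = list(),
                          validate = TRUE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(reg1 = character(0), reg2 = character(0),
                        target = character(0), sign = character(0),
                        scenario = integer(0), k = numeric(0),
                        stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  m <- structure(list(nodes = nodes, edges = edges, metadata = metadata),
                 class = "actnet_model")
  if (validate) validate_model(m)
  m
}

#' Validate an activity-network model
#'
#' Checks every structural invariant and reports *all* violations at once:
#' unique node names, activity bounds on `initial` and `clamp`, referential
#' integrity of edges, scenario/regulator-arity coherence (scenario 3 takes
#' exactly two regulators, scenarios 1-2 exactly one), positive `k`, and
#' admissible field values.
#'
#' @param model an `actnet_model`.
#' @return the model, invisibly; errors with the full list of violations
#'   otherwise.
#' @export
validate_model <- function(model) {
  nodes <- model$nodes
  edges <- model$edges
  bad <- character(0)

  if (anyDuplicated(nodes$name)) {
    bad <- c(bad, paste0("duplicate node names: ",
                         paste(unique(nodes$name[duplicated(nodes$name)]),
                               collapse = ", ")))
  }
  if (any(nodes$levels < 1L)) bad <- c(bad, "node 'levels' must be >= 1")
  i <- which(nodes$initial < 0L | nodes$initial > nodes$levels)
  if (length(i)) bad <- c(bad, paste0("initial out of [0, levels] for node(s): ",
                                      paste(nodes$name[i], collapse = ", ")))
  i <- which(!is.na(nodes$clamp) & (nodes$clamp < 0L | nodes$clamp > nodes$levels))
  if (length(i)) bad <- c(bad, paste0("clamp out of [0, levels] for node(s): ",
                                      paste(nodes$name[i], collapse = ", ")))
  i <- which(!nodes$reaction_class %in% c("slow", "fast"))
  if (length(i)) bad <- c(bad, paste0("reaction_class must be slow/fast for node(s): ",
                                      paste(nodes$name[i], collapse = ", ")))

  if (nrow(edges)) {
    for (col in c("reg1", "target")) {
      unknown <- setdiff(edges[[col]], nodes$name)
      if (length(unknown)) {
        bad <- c(bad, paste0("edge ", col, " references unknown node(s): ",
                             paste(unknown, collapse = ", ")))
      }
    }
    unknown <- setdiff(edges$reg2[!is.na(edges$reg2)], nodes$name)
    if (length(unknown)) {
      bad <- c(bad, paste0("edge reg2 references unknown node(s): ",
                           paste(unknown, collapse = ", ")))
    }
    i <- which(!edges$scenario %in% 1:3)
    if (length(i)) bad <- c(bad, paste0("edge scenario must be 1, 2 or 3 (edge rows ",
                                        paste(i, collapse = ", "), ")"))
    i <- which(edges$scenario == 3L & is.na(edges$reg2))
    if (length(i)) bad <- c(bad, paste0("scenario-3 edge needs two regulators (edge rows ",
                                        paste(i, collapse = ", "), ")"))
    i <- which(edges$scenario != 3L & !is.na(edges$reg2))
    if (length(i)) bad <- c(bad, paste0("only scenario-3 edges take reg2 (edge rows ",
                                        paste(i, collapse = ", "), ")"))
    i <- which(!edges$sign %in% c("activation", "inhibition"))
    if (length(i)) bad <- c(bad, paste0("edge sign must be activation/inhibition (edge rows ",
                                        paste(i, collapse = ", "), ")"))
    i <- which(!is.finite(edges$k) | edges$k <= 0)
    if (length(i)) bad <- c(bad, paste0("edge k must be > 0 (edge rows ",
                                        paste(i, collapse = ", "), ")"))
  }

  if (length(bad)) {
    stop("invalid model:\n  - ", paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.actnet_model <- function(x, ...) {
  nm <- x$metadata$name
  cat("<actnet_model", if (!is.null(nm)) paste0("'", nm, "'") else "", ">\n")
  cat("  nodes:", nrow(x$nodes),
      "(", sum(!is.na(x$nodes$clamp)), "clamped )\n")
  cat("  edges:", nrow(x$edges),
      "(", sum(x$edges$sign == "inhibition"), "inhibitions,",
      sum(x$edges$scenario == 3L), "scenario-3 )\n")
  invisible(x)
}

node_index <- function(model, names) {
  i <- match(names, model$nodes$name)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(names[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

is_self_inhibition <- function(edges) {
  !is.na(edges$reg1) & edges$reg1 == edges$target &
    edges$sign == "inhibition" & edges$scenario != 3L
}

#' Clamp nodes to constant activity levels
#'
#' Returns a modified copy of the model in which the given nodes are held at
#' a fixed activity for the whole simulation (they never schedule update
#' events but still drive the rates of their targets).  A clamp at 0 is an
#' in-silico knockout; a clamp at full scale a constitutive activation.
#'
#' @param model an `actnet_model`.
#' @param clamps named vector/list, node name -> clamp level.  An empty
#'   clamp set returns the model unchanged.
#' @return the clamped model.
#' @export
apply_clamps <- function(model, clamps) {
  if (length(clamps) == 0L) return(model)
  idx <- node_index(model, names(clamps))
  lv <- as.integer(unlist(clamps, use.names = FALSE))
  bad <- lv < 0L | lv > model$nodes$levels[idx]
  if (any(bad)) {
    stop("clamp out of [0, levels] for node(s): ",
         paste(names(clamps)[bad], collapse = ", "), call. = FALSE)
  }
  model$nodes$clamp[idx] <- lv
  model$nodes$initial[idx] <- lv
  model
}

#' Scale all interactions downstream of a node
#'
#' Multiplies `k` by `factor` for every edge whose regulator set includes
#' `node`, excluding the node's own self-inhibition.  Used to adapt a model
#' to measured expression differences: when a regulator is expressed at a
#' fraction `f` of its reference tissue, the strengths of its downstream
#' effects are scaled by `f` (e.g. the 0.64 articular/growth-plate ratio for
#' p38).
#'
#' @param model an `actnet_model`.
#' @param node regulator node name.
#' @param factor positive multiplier.
#' @return the rescaled model.
#' @export
scale_downstream <- function(model, node, factor) {
  node_index(model, node)
  stopifnot(is.numeric(factor), factor > 0)
  e <- model$edges
  hit <- (e$reg1 == node | (!is.na(e$reg2) & e$reg2 == node)) &
    !is_self_inhibition(e)
  model$edges$k[hit] <- e$k[hit] * factor
  model
}

#' Contract pass-through nodes out of a model
#'
#' Removes each given node and re-targets its incoming edges to its unique
#' successor, preserving sign, scenario and `k`; the contracted node's
#' self-inhibition is dropped.  This is the simplification that removes
#' promoter ("prom") helper nodes after a Boolean translation, redirecting
#' influences on transcription straight to the protein node.  A node is
#' contractible only if it regulates exactly one non-self edge, alone.
#'
#' @param model an `actnet_model`.
#' @param nodes character vector of node names to contract.
#' @return the contracted model.
#' @export
contract_nodes <- function(model, nodes) {
  for (u in nodes) {
    node_index(model, u)
    e <- model$edges
    out <- which((e$reg1 == u | (!is.na(e$reg2) & e$reg2 == u)) & e$target != u)
    if (length(out) != 1L) {
      stop("cannot contract '", u, "': it has ", length(out),
           " outgoing non-self edges (need exactly 1)", call. = FALSE)
    }
    if (!is.na(e$reg2[out]) ) {
      stop("cannot contract '", u, "': its outgoing edge has two regulators",
           call. = FALSE)
    }
    succ <- e$target[out]
    keep <- e[-out, , drop = FALSE]
    keep <- keep[!(keep$reg1 == u & keep$target == u), , drop = FALSE]  # self-loop
    keep$target[keep$target == u] <- succ
    if (any(keep$reg1 == u | (!is.na(keep$reg2) & keep$reg2 == u))) {
      stop("cannot contract '", u, "': it regulates other edges", call. = FALSE)
    }
    model$edges <- keep
    model$nodes <- model$nodes[model$nodes$name != u, , drop = FALSE]
    rownames(model$edges) <- rownames(model$nodes) <- NULL
  }
  validate_model(model)
  model
}

#' Build a cell-fate classifier
#'
#' A classifier is an ordered list of `(label, predicate)` rules evaluated
#' on the reported attractor levels; the first rule whose conjunction of
#' threshold comparisons holds wins, the special predicate `"ALL_ZERO"`
#' matches the Null state, and states matching no rule get
#' `fallback_label`.  Unresolved attractors are always labelled
#' `"unresolved"`.
#'
#' @param rules named list: label -> predicate text (see
#'   [parse_predicate()]) or the literal `"ALL_ZERO"`.
#' @param fallback_label label for states matching no rule.
#' @return an object of class `actnet_classifier`.
#' @seealso [default_classifier()]
#' @export
fate_classifier <- function(rules, fallback_label = "other") {
  stopifnot(is.list(rules), length(names(rules)) == length(rules))
  if (anyDuplicated(names(rules))) stop("classifier labels must be unique",
                                        call. = FALSE)
  parsed <- lapply(rules, function(r) {
    if (identical(r, "ALL_ZERO")) "ALL_ZERO" else parse_predicate(r)
  })
  structure(list(rules = parsed, fallback = fallback_label),
            class = "actnet_classifier")
}

#' Default two-master-regulator fate classifier
#'
#' Encodes the usual readout for a mutually exclusive pair of master
#' regulators: `<x>+` when `x >= hi` and `y < lo`, `<y>+` symmetrically,
#' `Null` when every node is at 0, `"other"` otherwise.  With the defaults
#' this is the chondrocyte readout (`SOX9+` / `RUNX2+` / `Null`) with the
#' standard thresholds 60 and 20.
#'
#' @param x,y names of the two master-regulator nodes.
#' @param hi activity threshold the active master must reach (default 60).
#' @param lo threshold the silenced master must stay under (default 20).
#' @export
default_classifier <- function(x = "SOX9", y = "RUNX2", hi = 60L, lo = 20L) {
  rules <- list(
    sprintf("%s >= %d && %s < %d", x, hi, y, lo),
    sprintf("%s >= %d && %s < %d", y, hi, x, lo),
    "ALL_ZERO")
  names(rules) <- c(paste0(x, "+"), paste0(y, "+"), "Null")
  fate_classifier(rules)
}
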