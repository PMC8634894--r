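#' Build an initial activity state for a model
#'
#' @param model an `actnet_model`.
#' @param init optional named vector of activity levels overriding the
#'   node table's `initial` values.  Clamped nodes are always forced to
#'   their clamp value.
#' @return named integer vector of activities, one per node.
#' @export
sim_state <- function(model, init = NULL) {
  nd <- model$nodes
  a <- setNames(nd$initial, nd$name)
  if (!is.null(init)) {
    idx <- node_index(model, names(init))
    a[idx] <- as.integer(round(unlist(init, use.names = FALSE)))
  }
  a[!is.na(nd$clamp)] <- nd$clamp[!is.na(nd$clamp)]
  if (any(a < 0L | a > nd$levels)) {
    stop("initial activity out of [0, levels]", call. = FALSE)
  }
  a
}

#' Rate of a single interaction in a given state
#'
#' With activities normalised to `[0, 1]` (`a = level / levels`), scenario 1
#' gives `k * a[E]`; scenario 2 gives `k * a[E] * avail(S)` where the
#' substrate availability `avail(S)` is the target's inactive fraction
#' `1 - a[S]` for activations and its active fraction `a[S]` for
#' inhibitions; scenario 3 gives `k * a[E1] * a[E2]`.  Always non-negative.
#'
#' @param model an `actnet_model`.
#' @param edge edge row index into `model$edges`.
#' @param state named activity vector (see [sim_state()]).
#' @return non-negative rate of occurrence.
#' @export
edge_rate <- function(model, edge, state) {
  e <- model$edges[edge, ]
  lv <- setNames(model$nodes$levels, model$nodes$name)
  a1 <- state[[e$reg1]] / lv[[e$reg1]]
  if (e$scenario == 1L) return(e$k * a1)
  if (e$scenario == 2L) {
    at <- state[[e$target]] / lv[[e$target]]
    return(e$k * a1 * if (e$sign == "activation") 1 - at else at)
  }
  e$k * a1 * state[[e$reg2]] / lv[[e$reg2]]
}

#' Net (signed) rate of change of one node
#'
#' Sum of the rates of all activating edges into the node minus the sum over
#' its inhibiting edges, evaluated at `state`.  The sign determines the
#' direction of the node's next discrete update; its magnitude sets the
#' update's timeout.
#'
#' @inheritParams edge_rate
#' @param node node name.
#' @return signed rate; 0 for a node with no incoming edges.
#' @export
net_rate <- function(model, node, state) {
  node_index(model, node)
  e <- model$edges
  idx <- which(e$target == node)
  if (!length(idx)) return(0)
  rates <- vapply(idx, function(i) edge_rate(model, i, state), numeric(1))
  sum(ifelse(e$sign[idx] == "activation", 1, -1) * rates)
}

engine_args <- function(model, state) {
  nd <- model$nodes
  e <- model$edges
  idx <- function(nm) match(nm, nd$name) - 1L
  list(levels = nd$levels,
       init = as.integer(state[nd$name]),
       clamped = !is.na(nd$clamp),
       reg1 = idx(e$reg1),
       reg2 = ifelse(is.na(e$reg2), 0L, idx(e$reg2)),
       target = idx(e$target),
       sign = ifelse(e$sign == "activation", 1L, -1L),
       scenario = e$scenario,
       k = e$k)
}

default_max_events <- function(model) {
  10L * max(model$nodes$levels) * nrow(model$nodes)
}

run_engine <- function(model, init, max_events, record, intervention = NULL) {
  state <- sim_state(model, init)
  a <- engine_args(model, state)
  if (is.null(intervention)) {
    int_after <- -1L; int_node <- 0L; int_level <- 0L
  } else {
    int_after <- as.integer(intervention$after)
    int_node <- node_index(model, intervention$node) - 1L
    int_level <- as.integer(intervention$level)
  }
  res <- .sim_engine(a$levels, a$init, a$clamped, a$reg1, a$reg2, a$target,
                     a$sign, a$scenario, a$k, as.integer(max_events), record,
                     int_after, int_node, int_level)
  res$init <- state
  res
}

round_half_down <- function(x) as.integer(ceiling(x - 0.5))

wrap_attractor <- function(res, model) {
  nm <- model$nodes$name
  kind <- res$kind
  reported <- setNames(round_half_down(res$reported_raw), nm)
  if (kind == "fixed_point" && all(reported == 0L)) kind <- "null"
  structure(list(kind = kind,
                 reported_levels = reported,
                 reported_raw = setNames(res$reported_raw, nm),
                 period = res$period,
                 events_to_reach = res$events_to_reach,
                 n_events = res$n_events,
                 final = setNames(res$final, nm),
                 time = res$time),
            class = "actnet_attractor")
}

#' @export
print.actnet_attractor <- function(x, ...) {
  cat("<actnet_attractor>", x$kind,
      if (x$kind == "limit_cycle") paste0("(period ", x$period, ")"), "\n")
  cat("  events to reach:", x$events_to_reach, "\n")
  top <- sort(x$reported_levels[x$reported_levels > 0], decreasing = TRUE)
  if (length(top)) {
    cat("  active nodes:",
        paste(names(top), top, sep = "=", collapse = ", "), "\n")
  } else cat("  all nodes at 0\n")
  invisible(x)
}

#' Run the deterministic event-driven simulation
#'
#' Each event advances exactly one node by one activity level: the node
#' whose timeout `t_last + (1/levels) / |net_rate|` is earliest fires
#' (simultaneous timeouts resolved by node declaration order), and all
#' timeouts are recomputed from the new state.  Simulation stops at
#' quiescence, at a confirmed recurrence of the activity vector (a limit
#' cycle), or after `max_events` events (recorded as truncation).  The run
#' is a pure function of its arguments: identical inputs give bit-identical
#' trajectories.
#'
#' @param model an `actnet_model`.
#' @param init optional named initial-activity overrides (see
#'   [sim_state()]).
#' @param max_events event budget; default `10 * levels * n_nodes`.
#' @return an `actnet_trajectory`: the initial state, a tidy event table
#'   (`time`, `node`, `level`), the terminal state and the attractor
#'   summary.
#' @export
simulate_network <- function(model, init = NULL, max_events = NULL) {
  if (is.null(max_events)) max_events <- default_max_events(model)
  res <- run_engine(model, init, max_events, record = TRUE)
  att <- wrap_attractor(res, model)
  ev <- res$trajectory
  events <- data.frame(time = ev$time,
                       node = model$nodes$name[ev$node + 1L],
                       level = ev$level,
                       stringsAsFactors = FALSE)
  structure(list(init = res$init,
                 events = events,
                 final = att$final,
                 truncated = att$kind == "unresolved",
                 attractor = att),
            class = "actnet_trajectory")
}

#' @export
print.actnet_trajectory <- function(x, ...) {
  cat("<actnet_trajectory>", nrow(x$events), "events",
      if (x$truncated) "(truncated)", "\n")
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' @param trajectory an `actnet_trajectory`.
#' @param path output path; columns `time`, `node`, `level`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory$events, path, row.names = FALSE)
  invisible(path)
}

#' Simulate to the attractor and summarise it
#'
#' The attractor is the terminal behaviour of the deterministic dynamics: a
#' `fixed_point` (quiescent state), a `limit_cycle` (the first confirmed
#' recurrence of the activity vector closes the cycle), `null` (the
#' all-zero fixed point), or `unresolved` when `max_events` is exhausted.
#' For a cycle the reported level of each node is its time-weighted mean
#' activity over one period, rounded to the nearest integer with ties
#' rounded down.
#'
#' @inheritParams simulate_network
#' @return an `actnet_attractor`.
#' @export
find_attractor <- function(model, init = NULL, max_events = NULL) {
  if (is.null(max_events)) max_events <- default_max_events(model)
  wrap_attractor(run_engine(model, init, max_events, record = FALSE), model)
}

#' Classify the cell fate of an attractor
#'
#' Applies the classifier's rules in order to the attractor's reported
#' levels; the first matching rule's label wins, otherwise the fallback.
#' Unresolved attractors are labelled `"unresolved"` and never folded into
#' another fate.
#'
#' @param attractor an `actnet_attractor` (or a named level vector).
#' @param classifier an `actnet_classifier` (see [fate_classifier()]).
#' @return a fate label (character scalar).
#' @export
classify_fate <- function(attractor, classifier) {
  stopifnot(inherits(classifier, "actnet_classifier"))
  if (inherits(attractor, "actnet_attractor")) {
    if (attractor$kind == "unresolved") return("unresolved")
    lv <- attractor$reported_levels
  } else {
    lv <- attractor
  }
  for (lab in names(classifier$rules)) {
    rule <- classifier$rules[[lab]]
    hit <- if (identical(rule, "ALL_ZERO")) all(lv == 0L)
           else predicate_holds(rule, lv)
    if (hit) return(lab)
  }
  classifier$fallback
}
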