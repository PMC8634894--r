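#' Parse an activity predicate
#'
#' Grammar: atoms `name op integer` with `op` one of `<`, `<=`, `>=`, `>`,
#' `=`, joined by `&&` into a conjunction — e.g.
#' `"RUNX2 >= 60 && SOX9 < 20"`.  When `model` is given, node names are
#' checked for existence and thresholds for being within `[0, levels]`.
#'
#' @param text predicate text.
#' @param model optional `actnet_model` for validation.
#' @return an `actnet_predicate`; `format()` round-trips it to canonical
#'   text.
#' @export
parse_predicate <- function(text, model = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  atoms <- trimws(strsplit(text, "&&", fixed = TRUE)[[1L]])
  if (!length(atoms) || any(!nzchar(atoms))) {
    stop("empty predicate: '", text, "'", call. = FALSE)
  }
  pat <- "^([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*(<=|>=|<|>|==|=)[[:space:]]*([0-9]+)$"
  m <- regmatches(atoms, regexec(pat, atoms))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("cannot parse predicate atom(s): ",
         paste(sQuote(atoms[bad]), collapse = ", "),
         " (expected 'name op integer')", call. = FALSE)
  }
  p <- data.frame(node = vapply(m, `[`, "", 2L),
                  op = vapply(m, `[`, "", 3L),
                  threshold = as.integer(vapply(m, `[`, "", 4L)),
                  stringsAsFactors = FALSE)
  p$op[p$op == "=="] <- "="
  if (!is.null(model)) {
    idx <- node_index(model, p$node)
    out <- p$threshold < 0L | p$threshold > model$nodes$levels[idx]
    if (any(out)) {
      stop("threshold out of [0, levels] for: ",
           paste(p$node[out], collapse = ", "), call. = FALSE)
    }
  }
  structure(p, class = c("actnet_predicate", "data.frame"))
}

#' @export
format.actnet_predicate <- function(x, ...) {
  paste(paste(x$node, x$op, x$threshold), collapse = " && ")
}

#' @export
print.actnet_predicate <- function(x, ...) {
  cat("<actnet_predicate>", format(x), "\n")
  invisible(x)
}

#' Evaluate a predicate on a named activity vector
#'
#' @param predicate an `actnet_predicate` (or predicate text).
#' @param levels named activity vector.
#' @return `TRUE`/`FALSE`.
#' @export
predicate_holds <- function(predicate, levels) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate)
  miss <- setdiff(predicate$node, names(levels))
  if (length(miss)) {
    stop("predicate references unknown node(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- levels[predicate$node]
  ok <- mapply(function(val, op, th) switch(op,
      "<" = val < th, "<=" = val <= th, ">" = val > th,
      ">=" = val >= th, "=" = val == th),
    v, predicate$op, predicate$threshold)
  all(ok)
}

#' Describe a delayed clamp intervention
#'
#' The only nondeterminism exercised by the reachability layer: a clamp of
#' one node that may be applied after any of a finite set of event counts.
#' `NA` in `choices` means "never"; `0` means "immediately" (before the
#' first event).  If the model goes quiescent before the chosen event index
#' is reached, the clamp is applied at that quiescent point and the
#' simulation continues.
#'
#' @param node node to clamp.
#' @param level clamp level (typically 0 or full scale).
#' @param choices integer event indices, plus `NA` for "never"; default
#'   `c(0:200, NA)`.
#' @return an `actnet_intervention`.
#' @export
intervention <- function(node, level, choices = c(0:200, NA)) {
  structure(list(node = node, level = as.integer(level),
                 choices = choices),
            class = "actnet_intervention")
}

states_along <- function(trajectory) {
  # list of named activity vectors: init plus the state after each event
  a <- trajectory$init
  out <- vector("list", nrow(trajectory$events) + 1L)
  out[[1L]] <- a
  if (nrow(trajectory$events)) {
    for (i in seq_len(nrow(trajectory$events))) {
      a[[trajectory$events$node[i]]] <- trajectory$events$level[i]
      out[[i + 1L]] <- a
    }
  }
  out
}

#' Check that a predicate persists along the whole deterministic run
#'
#' The bounded analogue of the temporal-logic query "A[] predicate": since
#' the unperturbed model is deterministic, the property is certified by one
#' simulation — the predicate must hold at the initial state, after every
#' event, and over one full period of the attractor.  If the run is
#' truncated before resolving and no violation was seen, the verdict is
#' `"unknown"` (the bounded horizon cannot certify an infinite claim).
#'
#' @param model an `actnet_model`.
#' @param init optional named initial-activity overrides.
#' @param predicate an `actnet_predicate` or predicate text.
#' @param max_events event budget.
#' @return an `actnet_check`: `verdict` (`"true"`/`"false"`/`"unknown"`),
#'   a counterexample `witness` trajectory prefix when falsified, and
#'   `checked_choices`.
#' @export
check_persist <- function(model, init = NULL, predicate, max_events = NULL) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate, model)
  tr <- simulate_network(model, init, max_events)
  states <- states_along(tr)
  for (i in seq_along(states)) {
    if (!predicate_holds(predicate, states[[i]])) {
      wit <- tr
      wit$events <- tr$events[seq_len(i - 1L), , drop = FALSE]
      return(structure(list(verdict = "false", witness = wit,
                            checked_choices = 1L),
                       class = "actnet_check"))
    }
  }
  verdict <- if (tr$truncated) "unknown" else "true"
  structure(list(verdict = verdict, witness = NULL, checked_choices = 1L),
            class = "actnet_check")
}

#' Bounded reachability with optional delayed intervention
#'
#' The analogues of "E<> predicate" (`mode = "possible"`) and
#' "A<> predicate" (`mode = "guaranteed"`), checked by enumerating one
#' deterministic simulation per intervention-time choice.  A branch
#' satisfies the predicate if it holds at any visited state (including the
#' initial one).  `possible` is true as soon as one branch succeeds (its
#' trajectory is returned as witness); `guaranteed` requires every branch
#' to succeed.  A truncated branch that never satisfied the predicate makes
#' `guaranteed` at best `"unknown"`; `possible` can still be `"true"` via
#' another branch.  Without an intervention the two modes coincide.
#'
#' @inheritParams check_persist
#' @param mode `"possible"` or `"guaranteed"`.
#' @param intervene optional [intervention()].
#' @return an `actnet_check` with `verdict`, `witness` (a satisfying
#'   trajectory plus the `choice` that produced it, for `possible`),
#'   and `checked_choices`.
#' @export
check_reach <- function(model, init = NULL, predicate,
                        mode = c("possible", "guaranteed"),
                        intervene = NULL, max_events = NULL) {
  mode <- match.arg(mode)
  if (is.character(predicate)) predicate <- parse_predicate(predicate, model)
  if (is.null(max_events)) max_events <- default_max_events(model)
  choices <- if (is.null(intervene)) NA else intervene$choices
  if (!length(choices)) choices <- NA

  any_true <- FALSE; any_unknown <- FALSE; all_true <- TRUE
  witness <- NULL
  for (ch in choices) {
    if (is.null(intervene) || is.na(ch)) {
      res <- run_engine(model, init, max_events, record = TRUE)
    } else {
      res <- run_engine(model, init, max_events, record = TRUE,
                        intervention = list(node = intervene$node,
                                            level = intervene$level,
                                            after = ch))
    }
    att <- wrap_attractor(res, model)
    tr <- structure(list(init = res$init,
                         events = data.frame(
                           time = res$trajectory$time,
                           node = model$nodes$name[res$trajectory$node + 1L],
                           level = res$trajectory$level,
                           stringsAsFactors = FALSE),
                         final = att$final,
                         truncated = att$kind == "unresolved",
                         attractor = att),
                    class = "actnet_trajectory")
    sat <- FALSE
    states <- states_along(tr)
    for (si in seq_along(states)) {
      if (predicate_holds(predicate, states[[si]])) { sat <- TRUE; break }
    }
    if (sat) {
      any_true <- TRUE
      if (is.null(witness)) {
        witness <- tr
        # the witness is the prefix up to the first satisfying state
        witness$events <- tr$events[seq_len(si - 1L), , drop = FALSE]
        witness$choice <- ch
      }
    } else if (tr$truncated) {
      any_unknown <- TRUE; all_true <- FALSE
    } else {
      all_true <- FALSE
    }
    if (mode == "possible" && any_true) break
  }

  verdict <- if (mode == "possible") {
    if (any_true) "true" else if (any_unknown) "unknown" else "false"
  } else {
    if (all_true) "true" else if (any_unknown) "unknown" else "false"
  }
  structure(list(verdict = verdict, witness = witness,
                 checked_choices = length(choices)),
            class = "actnet_check")
}

#' @export
print.actnet_check <- function(x, ...) {
  cat("<actnet_check> verdict:", x$verdict,
      "(", x$checked_choices, "choice(s) checked )\n")
  if (!is.null(x$witness)) {
    cat("  witness:", nrow(x$witness$events), "events",
        if (!is.null(x$witness$choice))
          paste0("(intervention choice ",
                 ifelse(is.na(x$witness$choice), "never", x$witness$choice),
                 ")"), "\n")
  }
  invisible(x)
}
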