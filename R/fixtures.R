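#' Bundled network motifs
#'
#' Small, fully documented activity networks shipped as model files with
#' the package and used throughout the test suite:
#'
#' * `abc_example` — the two-regulator race: `A -> B` (k = 0.5) against
#'   `C -| B` (k = 0.4), so with both regulators full, B climbs at net rate
#'   +0.1 and pins at the top of its range.
#' * `ras_motif` — a hub with four independent scenario-1 activators
#'   (k = 0.444 each) and a fast self-inhibition (k = 1.0); with exactly
#'   one activator clamped at 100 the hub settles at activity 44, the
#'   canonical worked example of the additive-OR translation.
#' * `and_gate` — one scenario-3 (AND) edge `(A, B) -> C` plus
#'   self-inhibition: C activates only when both regulators are active.
#' * `destruction_complex` — a dummy-node subnetwork whose output node
#'   realises the piecewise formula `(1 - Dsh) * min(1.5 - ERK, 1)` at
#'   steady state: a constant dummy (clamped at 100) drives one helper to
#'   `1 - Dsh` and another, saturating at its upper bound, to
#'   `min(1.5 - ERK, 1)`; a scenario-3 edge multiplies them.
#' * `delayed_switch` — a network whose target `T` can latch on only if
#'   the input `IGF` is clamped on *after* an initial fast transient has
#'   passed: immediate addition lets a blocker `B` latch instead, very
#'   late addition finds the permissive gate decayed.  Used by the
#'   reachability layer ("possible only with later addition").
#' * `mini_chondro` — a 12-node mutual-inhibition network with two master
#'   regulators `X` and `Y` (each sustained by a cooperative feedback loop
#'   through its branch activator `AX`/`AY`, fed by transient signal nodes
#'   and read out by downstream markers) whose attractors are `X+`, `Y+`
#'   and the all-zero Null state; `X+` and `Y+` are mutually exclusive and
#'   switchable by pairwise clamps.  A desk-scale stand-in, synthetic by
#'   construction, for full-size tri-stable chondrocyte-style networks.
#'
#' @param name one of `"abc_example"`, `"ras_motif"`, `"and_gate"`,
#'   `"destruction_complex"`, `"delayed_switch"`, `"mini_chondro"`.
#' @return a validated `actnet_model`.
#' @export
motif <- function(name) {
  known <- c("abc_example", "ras_motif", "and_gate", "destruction_complex",
             "delayed_switch", "mini_chondro")
  if (!name %in% known) {
    stop("unknown motif '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "actnet", mustWork = TRUE)
  load_model(path)
}

#' Seeded random activity-network generator
#'
#' Stands in for large hand-curated networks in property tests.  Every node
#' gets a reaction class (slow with probability `frac_slow`) and the
#' class's self-inhibition (k = 0.1 slow / 1.0 fast); each ordered pair of
#' distinct nodes carries an edge with probability `edge_density`
#' (activation with probability 0.7), which becomes a scenario-3 edge with
#' a second random co-regulator with probability `frac_and`; edge k is the
#' class strength of its (first) regulator.  No clamped nodes are
#' generated, so the all-zero state is always quiescent.  Identical
#' parameters give identical models.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_density probability of each possible cross edge, in (0, 1].
#' @param frac_slow probability a node is slow-class.
#' @param frac_and probability a cross edge is scenario-3.
#' @param seed integer seed.
#' @param levels activity granularity (default 100).
#' @return a validated `actnet_model`.
#' @export
random_network <- function(n_nodes, edge_density = 0.3, frac_slow = 0.3,
                           frac_and = 0.1, seed, levels = 100L) {
  stopifnot(n_nodes >= 1, edge_density > 0, edge_density <= 1,
            frac_slow >= 0, frac_slow <= 1, frac_and >= 0, frac_and <= 1,
            !missing(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  names <- sprintf("n%02d", seq_len(n_nodes))
  cls <- ifelse(runif(n_nodes) < frac_slow, "slow", "fast")
  nodes <- node_spec(names, levels = levels, reaction_class = cls)
  edges <- list()
  for (i in seq_len(n_nodes)) {
    edges[[length(edges) + 1L]] <- edge_spec(
      names[i], names[i], sign = "inhibition", scenario = 1L,
      k = k_class[[cls[i]]])
  }
  if (n_nodes > 1L) {
    for (u in seq_len(n_nodes)) {
      for (v in seq_len(n_nodes)) {
        if (u == v || runif(1) >= edge_density) next
        sign <- if (runif(1) < 0.7) "activation" else "inhibition"
        and <- runif(1) < frac_and
        reg2 <- NA_character_
        if (and) {
          others <- setdiff(seq_len(n_nodes), u)
          reg2 <- names[others[floor(runif(1) * length(others)) + 1L]]
        }
        edges[[length(edges) + 1L]] <- edge_spec(
          names[u], names[v], sign = sign,
          scenario = if (and) 3L else 1L,
          k = k_class[[cls[u]]], reg2 = reg2)
      }
    }
  }
  network_model(nodes, do.call(rbind, edges),
                metadata = list(name = sprintf("random(n=%d, seed=%d)",
                                               n_nodes, seed)))
}

#' Continuous rate-equation oracle
#'
#' Integrates the normalised rate equations `da/dt = net_rate(a)` on
#' `[0, 1]^n` by small fixed explicit-Euler steps (projected onto the box;
#' clamped nodes held constant) until the residual `max |da/dt|` over
#' movable nodes falls below `tol`, or `t_max` is reached.  This is an
#' independent implementation — it shares no code with the event-driven
#' simulator — and serves as its correctness oracle: on networks with a
#' unique stable fixed point the discrete attractor levels must match
#' `round(levels * fixed_point)` within one level.
#'
#' @param model an `actnet_model`.
#' @param init optional named initial levels (same convention as
#'   [sim_state()]; on the 0-levels scale, not 0-1).
#' @param dt Euler step (default 1e-3, small against the fastest rate).
#' @param t_max integration horizon.
#' @param tol convergence tolerance on the residual (default 1e-9).
#' @return list with `fixed_point` (named, on the 0-1 scale), `converged`
#'   and `t`; non-convergence is reported, not raised.
#' @export
ode_oracle <- function(model, init = NULL, dt = 1e-3, t_max = 1000,
                       tol = 1e-9) {
  state <- sim_state(model, init)
  a <- engine_args(model, state)
  res <- .ode_engine(a$levels, a$init / a$levels, a$clamped, a$reg1, a$reg2,
                     a$target, a$sign, a$scenario, a$k, dt, t_max, tol)
  list(fixed_point = setNames(res$fixed_point, model$nodes$name),
       converged = res$converged, t = res$t)
}
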