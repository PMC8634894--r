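test_that("edge_rate implements the three kinetic scenarios", {
  m <- network_model(
    nodes_of(node_spec("E"), node_spec("S"), node_spec("E2")),
    rbind(edge_spec("E", "S", "activation", 1L, 0.444),
          edge_spec("E", "S", "activation", 2L, 1.0),
          edge_spec("E", "S", "inhibition", 2L, 1.0),
          edge_spec("E", "S", "activation", 3L, 1.0, reg2 = "E2")))
  st <- c(E = 100L, S = 0L, E2 = 0L)
  expect_equal(edge_rate(m, 1L, st), 0.444)
  expect_equal(edge_rate(m, 4L, st), 0)         # scenario 3, one regulator at 0
  st2 <- c(E = 100L, S = 100L, E2 = 50L)
  expect_equal(edge_rate(m, 2L, st2), 0)        # activation: no inactive substrate
  expect_equal(edge_rate(m, 3L, st2), 1.0)      # inhibition uses active fraction
  expect_equal(edge_rate(m, 4L, st2), 0.5)
  # rates are never negative, over random states
  for (s in 1:20) {
    set.seed(s)
    st3 <- setNames(as.integer(sample(0:100, 3, replace = TRUE)),
                    c("E", "S", "E2"))
    for (e in 1:4) expect_gte(edge_rate(m, e, st3), 0)
  }
})

test_that("net_rate sums activations minus inhibitions", {
  race <- two_regulator_race()
  st <- c(A = 100L, B = 0L, C = 100L)
  expect_equal(net_rate(race, "B", st), 0.1)
  expect_equal(net_rate(race, "A", st), 0)      # no incoming edges
  hub <- additive_hub()
  st2 <- c(S1 = 100L, S2 = 0L, S3 = 0L, S4 = 0L, hub = 44L)
  expect_equal(net_rate(hub, "hub", st2), 0.444 - 0.44)
})

test_that("net_rate is monotone in a regulator's activity (sign coherence)", {
  hub <- additive_hub()
  lv <- seq(0L, 100L, by = 10L)
  rates <- vapply(lv, function(x) {
    net_rate(hub, "hub", c(S1 = x, S2 = 0L, S3 = 0L, S4 = 0L, hub = 40L))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  # and decreasing in an inhibitor's activity
  race <- two_regulator_race()
  rates2 <- vapply(lv, function(x) {
    net_rate(race, "B", c(A = 100L, B = 50L, C = x))
  }, numeric(1))
  expect_true(all(diff(rates2) < 0))
})

test_that("a self-inhibited node decays to 0 in exactly its level count", {
  for (init in c(1L, 7L, 100L)) {
    tr <- simulate_network(decay_node(init))
    expect_equal(nrow(tr$events), init)
    expect_identical(tr$final[["D"]], 0L)
    expect_identical(tr$attractor$kind, if (init) "null" else "null")
  }
  # one step: activity 1 -> 0
  tr1 <- simulate_network(decay_node(1L))
  expect_equal(tr1$events$level, 0L)
})

test_that("simultaneous timeouts resolve by declaration order", {
  m <- network_model(
    nodes_of(node_spec("n1", initial = 50L), node_spec("n2", initial = 50L)),
    rbind(edge_spec("n1", "n1", "inhibition", 1L, 1.0),
          edge_spec("n2", "n2", "inhibition", 1L, 1.0)))
  tr <- simulate_network(m)
  expect_identical(tr$events$node[1L], "n1")
  # ties alternate deterministically afterwards
  expect_identical(tr$events$node[2L], "n2")
})

test_that("trajectories are bounded, single-step and deterministic", {
  for (s in 1:10) {
    m <- random_network(5, edge_density = 0.4, frac_and = 0.2, seed = s)
    init <- random_init(m, seed = 1000 + s)
    t1 <- simulate_network(m, init)
    t2 <- simulate_network(m, init)
    expect_identical(t1, t2)                       # bit-identical replay
    expect_true(all(t1$events$level >= 0 & t1$events$level <= 100))
    expect_true(all(diff(t1$events$time) >= 0))    # time never runs backwards
    # each event moves exactly one node by +-1
    lv <- t1$init
    for (i in seq_len(nrow(t1$events))) {
      nd <- t1$events$node[i]
      expect_equal(abs(t1$events$level[i] - lv[[nd]]), 1L)
      lv[[nd]] <- t1$events$level[i]
    }
  }
})

test_that("the all-zero state is quiescent without positive clamps", {
  for (s in 1:5) {
    m <- random_network(6, edge_density = 0.5, frac_and = 0.2, seed = 20 + s)
    zero <- setNames(rep(0L, 6), m$nodes$name)
    tr <- simulate_network(m, zero)
    expect_equal(nrow(tr$events), 0L)
    expect_identical(tr$attractor$kind, "null")
  }
})

test_that("a constant positive net rate pins the target at its upper bound", {
  tr <- simulate_network(two_regulator_race())     # +0.1 throughout
  b <- tr$events$level[tr$events$node == "B"]
  expect_true(all(diff(b) == 1L))                  # monotone rise
  expect_identical(tr$final[["B"]], 100L)
  expect_identical(tr$attractor$kind, "fixed_point")
})

test_that("find_attractor reports the additive-hub limit cycle at 44", {
  m <- apply_clamps(additive_hub(),
                    list(S1 = 100L, S2 = 0L, S3 = 0L, S4 = 0L))
  att <- find_attractor(m)
  expect_identical(att$kind, "limit_cycle")
  expect_equal(att$period, 2L)
  expect_equal(att$reported_raw[["hub"]], 44.4, tolerance = 1e-9)
  expect_identical(att$reported_levels[["hub"]], 44L)
  # the hub keeps oscillating between 44 and 45
  tr <- simulate_network(m)
  hub_levels <- tail(tr$events$level[tr$events$node == "hub"], 4)
  expect_setequal(unique(hub_levels), c(44L, 45L))
})

test_that("cycle means round half-down", {
  expect_identical(actnet:::round_half_down(44.4), 44L)
  expect_identical(actnet:::round_half_down(44.5), 44L)
  expect_identical(actnet:::round_half_down(44.51), 45L)
})

test_that("exhausting max_events yields an unresolved attractor, not an error", {
  m <- apply_clamps(additive_hub(),
                    list(S1 = 100L, S2 = 0L, S3 = 0L, S4 = 0L))
  att <- find_attractor(m, max_events = 5L)
  expect_identical(att$kind, "unresolved")
  tr <- simulate_network(m, max_events = 5L)
  expect_true(tr$truncated)
  expect_equal(nrow(tr$events), 5L)
})

test_that("discrete attractors agree with the continuous oracle within 1 level", {
  checked <- 0L
  for (s in 1:60) {
    n <- 3L + s %% 4L
    m <- random_network(n, edge_density = 0.4, frac_and = 0, frac_slow = 0.3,
                        seed = 400 + s)
    m <- apply_clamps(m, setNames(list(37L), m$nodes$name[1L]))
    o1 <- ode_oracle(m, dt = 5e-3)
    o2 <- ode_oracle(m, setNames(rep(100L, n), m$nodes$name), dt = 5e-3)
    if (!o1$converged || !o2$converged) next
    if (max(abs(o1$fixed_point - o2$fixed_point)) > 1e-6) next  # not unique
    att <- find_attractor(m)
    if (att$kind == "unresolved") next
    checked <- checked + 1L
    expect_lte(max(abs(att$reported_levels - round(100 * o1$fixed_point))), 1)
  }
  expect_gte(checked, 25L)
})
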