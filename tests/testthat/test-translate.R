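test_that("parse_boolean_rules handles OR, AND, NOT and annotations", {
  bm <- parse_boolean_rules(c("A =", "B =", "C = A | B"))
  expect_identical(bm$rules$C$type, "or")
  expect_setequal(vapply(bm$rules$C$args, `[[`, "", "name"), c("A", "B"))

  bm2 <- parse_boolean_rules(c("A =", "B =", "C = A & !B"))
  expect_identical(bm2$rules$C$type, "and")
  expect_identical(bm2$rules$C$args[[2]]$type, "not")

  bm3 <- parse_boolean_rules(c("A = @slow", "B = A @dual @w(A)=0.5"))
  expect_identical(bm3$class_tags[["A"]], "slow")
  expect_identical(bm3$dual_regulation, "B")
  expect_equal(bm3$weights$B[["A"]], 0.5)

  expect_error(parse_boolean_rules("C = A | Z"), "undeclared")
  expect_error(parse_boolean_rules(c("A =", "C = A |")), "line 2")
  expect_error(parse_boolean_rules(c("A =", "C = A @wizz")), "unknown annotation")
  expect_error(parse_boolean_rules(c("A =", "A = A")), "duplicate rule")
})

test_that("OR branches become independent edges, ANDs one scenario-3 edge", {
  m <- boolean_to_network(parse_boolean_rules(c("A =", "B =", "C = A | B")))
  to_c <- m$edges[m$edges$target == "C" & m$edges$reg1 != "C", ]
  expect_equal(nrow(to_c), 2L)
  expect_true(all(to_c$scenario == 1L & to_c$k == 1.0))
  self_c <- m$edges[m$edges$reg1 == "C" & m$edges$target == "C", ]
  expect_equal(nrow(self_c), 1L)
  expect_identical(self_c$sign, "inhibition")
  expect_equal(self_c$k, 1.0)

  m2 <- boolean_to_network(parse_boolean_rules(c("A =", "B =", "C = A & B")))
  to_c2 <- m2$edges[m2$edges$target == "C" & m2$edges$reg1 != "C", ]
  expect_equal(nrow(to_c2), 1L)
  expect_identical(to_c2$scenario, 3L)
  expect_setequal(c(to_c2$reg1, to_c2$reg2), c("A", "B"))

  # NOT literal -> inhibition edge
  m3 <- boolean_to_network(parse_boolean_rules(c("A =", "B =", "C = A | !B")))
  inh <- m3$edges[m3$edges$target == "C" & m3$edges$reg1 == "B", ]
  expect_identical(inh$sign, "inhibition")

  # n-ary AND and NOT-in-AND are rejected with guidance
  expect_error(boolean_to_network(parse_boolean_rules(
    c("A =", "B =", "C =", "D = A & B & C"))), "exactly two conjuncts")
  expect_error(boolean_to_network(parse_boolean_rules(
    c("A =", "B =", "C = A & !B"))), "positive")
})

test_that("additive weights and classes set the edge strengths", {
  rules <- c("W =", "B =", "F1 =", "F3 =",
             "Ras = W | B | F1 | F3 @w(W)=0.444 @w(B)=0.444 @w(F1)=0.444 @w(F3)=0.444")
  m <- boolean_to_network(parse_boolean_rules(rules))
  acts <- m$edges[m$edges$target == "Ras" & m$edges$sign == "activation", ]
  expect_equal(nrow(acts), 4L)
  expect_true(all(acts$k == 0.444))
  self <- m$edges[m$edges$reg1 == "Ras" & m$edges$target == "Ras", ]
  expect_equal(self$k, 1.0)
  # slow sources drive slow edges (0.1 scale)
  m2 <- boolean_to_network(parse_boolean_rules(c("G = @slow", "P = G")))
  eg <- m2$edges[m2$edges$reg1 == "G" & m2$edges$target == "P", ]
  expect_equal(eg$k, 0.1)
})

test_that("every translated non-constant node has exactly one self-inhibition", {
  rules <- c("A =", "B = @slow", "D = @const(100)",
             "C = A | B", "E = A & C", "F = !C")
  # C legitimately mixes classes here; the advisory warning is expected
  m <- suppressWarnings(boolean_to_network(parse_boolean_rules(rules)))
  for (nm in m$nodes$name) {
    self <- sum(m$edges$reg1 == nm & m$edges$target == nm &
                m$edges$sign == "inhibition")
    expect_equal(self, if (nm == "D") 0L else 1L, info = nm)
  }
  expect_identical(m$nodes$clamp[m$nodes$name == "D"], 100L)
})

test_that("translated OR saturates when any source is up; AND needs both", {
  rules <- c("A =", "B =", "OrT = A | B", "AndT = A & B")
  m <- boolean_to_network(parse_boolean_rules(rules))
  m_or <- apply_clamps(m, list(A = 100L, B = 0L))
  att <- find_attractor(m_or)
  expect_gt(att$reported_levels[["OrT"]], 0L)
  expect_identical(att$reported_levels[["AndT"]], 0L)
  m_and <- apply_clamps(m, list(A = 100L, B = 100L))
  att2 <- find_attractor(m_and)
  expect_gt(att2$reported_levels[["AndT"]], 0L)
})

test_that("dual regulation expands into the prot/PTM three-node pattern", {
  rules <- c("TFgene = @slow", "Kin =", "SOX = TFgene | Kin @dual")
  bm <- parse_boolean_rules(rules)
  m <- boolean_to_network(bm)
  expect_true(all(c("SOX_prot", "SOX_PTM", "SOX") %in% m$nodes$name))
  # slow influence rewired to _prot, fast to _PTM
  expect_identical(
    m$edges$target[m$edges$reg1 == "TFgene" & m$edges$target != "TFgene"],
    "SOX_prot")
  expect_identical(
    m$edges$target[m$edges$reg1 == "Kin" & m$edges$target != "Kin"],
    "SOX_PTM")
  # sole activation of the main node is the scenario-3 pair
  main_in <- m$edges[m$edges$target == "SOX" & m$edges$sign == "activation", ]
  expect_equal(nrow(main_in), 1L)
  expect_identical(main_in$scenario, 3L)
  expect_setequal(c(main_in$reg1, main_in$reg2), c("SOX_prot", "SOX_PTM"))
  # semantics: expressed AND modified -> active; either missing -> silent
  both <- find_attractor(apply_clamps(m, list(TFgene = 100L, Kin = 100L)))
  expect_gt(both$reported_levels[["SOX"]], 0L)
  onlyk <- find_attractor(apply_clamps(m, list(TFgene = 0L, Kin = 100L)))
  expect_identical(onlyk$reported_levels[["SOX"]], 0L)
})

test_that("expand_dual_regulation rewires an existing model once", {
  rules <- c("TFgene = @slow", "Kin =", "SOX = TFgene | Kin")
  m <- suppressWarnings(boolean_to_network(parse_boolean_rules(rules)))
  n0 <- nrow(m$nodes); e_in <- sum(m$edges$target == "SOX")
  m2 <- expand_dual_regulation(m, "SOX")
  expect_equal(nrow(m2$nodes), n0 + 2L)
  expect_error(expand_dual_regulation(m2, "SOX"), "already expanded")
  # a dual node with no slow inputs can never activate: flagged
  m3 <- boolean_to_network(parse_boolean_rules(c("Kin =", "P = Kin")))
  expect_warning(expand_dual_regulation(m3, "P"), "never activate")
})

test_that("mixed-class influences on a non-dual node are flagged", {
  rules <- c("G = @slow", "Kin =", "T = G | Kin")
  expect_warning(boolean_to_network(parse_boolean_rules(rules)),
                 "both classes")
})

test_that("the dummy-node subnetwork reproduces the piecewise formula", {
  dc_formula <- function(dsh, erk) (1 - dsh) * min(1.5 - erk, 1)
  m <- motif("destruction_complex")
  corners <- list(c(0, 0), c(0, 100), c(100, 0), c(100, 100),
                  c(50, 75), c(0, 50), c(25, 100))
  for (cc in corners) {
    mm <- apply_clamps(m, list(Dsh = cc[1], ERK = cc[2]))
    att <- find_attractor(mm)
    expect_lte(abs(att$reported_raw[["DC"]] -
                   100 * dc_formula(cc[1] / 100, cc[2] / 100)),
               1, label = paste("Dsh", cc[1], "ERK", cc[2]))
  }
})
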