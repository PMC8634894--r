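test_that("parse_predicate round-trips and validates", {
  p <- parse_predicate("RUNX2 >= 60 && SOX9 < 20")
  expect_equal(nrow(p), 2L)
  expect_identical(format(p), "RUNX2 >= 60 && SOX9 < 20")
  p1 <- parse_predicate("SOX9 >= 60")
  expect_equal(nrow(p1), 1L)
  expect_identical(format(parse_predicate(format(p1))), format(p1))
  expect_error(parse_predicate("SOX9 >="), "cannot parse")
  expect_error(parse_predicate(""), "empty predicate")
  m <- motif("mini_chondro")
  expect_error(parse_predicate("X >= 200", m), "out of \\[0, levels\\]")
  expect_error(parse_predicate("Q >= 2", m), "unknown node")
  expect_true(predicate_holds(p, c(RUNX2 = 100L, SOX9 = 0L)))
  expect_false(predicate_holds(p, c(RUNX2 = 59L, SOX9 = 0L)))
  expect_error(predicate_holds(p, c(RUNX2 = 1L)), "unknown node")
})

test_that("check_persist certifies attractor states and finds violations", {
  m <- motif("mini_chondro")
  xplus <- find_attractor(m, c(X = 100L, AX = 100L))$reported_levels
  r <- check_persist(m, xplus, "X >= 60 && Y < 20")
  expect_identical(r$verdict, "true")
  expect_null(r$witness)

  # the Y-branch forced on breaks persistence, with a counterexample trace
  r2 <- check_persist(apply_clamps(m, list(AY = 100L, AX = 0L)), xplus,
                      "X >= 60 && Y < 20")
  expect_identical(r2$verdict, "false")
  expect_s3_class(r2$witness, "actnet_trajectory")
  # the witness replays to a violating state
  lv <- r2$witness$init
  for (i in seq_len(nrow(r2$witness$events))) {
    lv[[r2$witness$events$node[i]]] <- r2$witness$events$level[i]
  }
  expect_false(predicate_holds("X >= 60 && Y < 20", lv))

  # predicate violated at the initial state: immediate counterexample
  r3 <- check_persist(m, xplus, "Y >= 60")
  expect_identical(r3$verdict, "false")
  expect_equal(nrow(r3$witness$events), 0L)

  # truncation without violation is unknown, never a false claim
  r4 <- check_persist(m, c(SX1 = 100L), "X < 90", max_events = 3L)
  expect_identical(r4$verdict, "unknown")
})

test_that("check_reach without intervention equals one deterministic run", {
  m <- motif("mini_chondro")
  rp <- check_reach(m, c(X = 100L, AX = 100L), "MX >= 60", mode = "possible")
  rg <- check_reach(m, c(X = 100L, AX = 100L), "MX >= 60", mode = "guaranteed")
  expect_identical(rp$verdict, "true")
  expect_identical(rg$verdict, "true")
  # predicate true at the initial state: zero-length witness
  r0 <- check_reach(m, c(X = 100L, AX = 100L), "X >= 60", mode = "possible")
  expect_identical(r0$verdict, "true")
  expect_equal(nrow(r0$witness$events), 0L)
  # empty time-choice set reduces to the unperturbed trajectory
  re <- check_reach(m, c(X = 100L, AX = 100L), "Y >= 60", mode = "possible",
                    intervene = intervention("AY", 100L, choices = NA))
  expect_identical(re$verdict, "false")
})

test_that("persist and possible-reach are dual on deterministic runs", {
  m <- motif("mini_chondro")
  inits <- list(c(X = 100L, AX = 100L), c(Y = 100L, AY = 100L),
                c(SX1 = 80L, SY1 = 80L))
  for (init in inits) {
    for (pred_txt in c("X >= 60", "Y < 20", "MX < 50")) {
      pers <- check_persist(m, init, pred_txt)$verdict
      neg <- vapply(strsplit(pred_txt, " ")[[1]][2], function(op) switch(op,
        ">=" = "<", "<" = ">="), character(1))
      parts <- strsplit(pred_txt, " ")[[1]]
      reach_neg <- check_reach(m, init,
                               paste(parts[1], neg, parts[3]),
                               mode = "possible")$verdict
      if (pers != "unknown" && reach_neg != "unknown") {
        expect_identical(pers == "true", reach_neg == "false",
                         label = paste(pred_txt, "from",
                                       paste(names(init), collapse = ",")))
      }
    }
  }
})

test_that("a witness trajectory replays to a predicate-satisfying state", {
  ds <- motif("delayed_switch")
  r <- check_reach(ds, predicate = "T >= 60", mode = "possible",
                   intervene = intervention("IGF", 100L, choices = c(0L, 150L, NA)))
  expect_identical(r$verdict, "true")
  lv <- r$witness$init
  hit <- predicate_holds("T >= 60", lv)
  for (i in seq_len(nrow(r$witness$events))) {
    lv[[r$witness$events$node[i]]] <- r$witness$events$level[i]
    if (predicate_holds("T >= 60", lv)) hit <- TRUE
  }
  expect_true(hit)
})

test_that("enlarging the time-choice set never flips possible to false", {
  ds <- motif("delayed_switch")
  verdicts <- vapply(list(c(0L, NA), c(0L, 100L, NA), c(0L, 100L, 150L, NA),
                          c(0L, 50L, 100L, 150L, 180L, NA)),
                     function(ch) check_reach(ds, predicate = "T >= 60",
                                              mode = "possible",
                                              intervene = intervention("IGF", 100L,
                                                                       choices = ch))$verdict,
                     character(1))
  # once true, stays true as the set grows
  first_true <- match("true", verdicts)
  if (!is.na(first_true)) {
    expect_true(all(verdicts[first_true:length(verdicts)] == "true"))
  }
})
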