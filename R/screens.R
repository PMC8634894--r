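#' Derive a per-run seed from a master seed and a counter
#'
#' Counter-based splitting: every simulation in a screen gets its own
#' reproducible seed, so runs are independent of execution order and can be
#' parallelised deterministically.  The result is always in
#' `[0, 2^31 - 2]`.
#'
#' @param master master seed (integer).
#' @param counter run counter (integer, vectorised).
#' @return derived integer seed(s).
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483647
  x <- (as.double(master) %% m) * 48271 + as.double(counter) * 16807 + 12345
  as.integer(x %% m)
}

#' Draw a random initial state
#'
#' Every unclamped node is drawn uniformly on the integers `0..levels`
#' (activity over the entire range of theoretical values); clamped nodes
#' sit at their clamp value.
#'
#' @param model an `actnet_model`.
#' @param seed integer seed (required: reproducibility contract).
#' @return named integer activity vector.
#' @export
random_init <- function(model, seed) {
  stopifnot(!missing(seed))
  nd <- model$nodes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- as.integer(floor(runif(nrow(nd)) * (nd$levels + 1L)))
  a <- pmin(a, nd$levels)
  a[!is.na(nd$clamp)] <- nd$clamp[!is.na(nd$clamp)]
  setNames(a, nd$name)
}

#' Normal-approximation confidence half-width for a proportion
#'
#' `z[(1+conf)/2] * sqrt(p_hat * (1 - p_hat) / n)`; at `p_hat` 0 or 1 the
#' degenerate variance gives 0.  At `n = 10^6` and 99% confidence this
#' reproduces the conventional printed "+-" columns of Monte Carlo fate
#' tables (e.g. 1.49% +- 0.03, 91.56% +- 0.07).
#'
#' @param p_hat proportion estimate in `[0, 1]` (vectorised).
#' @param n number of simulations.
#' @param conf confidence level, default 0.99.
#' @param percent return the half-width in percentage points.
#' @return half-width(s), same scale as `p_hat` (or x100 with `percent`).
#' @export
proportion_ci <- function(p_hat, n, conf = 0.99, percent = FALSE) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), n >= 1, conf > 0, conf < 1)
  z <- qnorm((1 + conf) / 2)
  hw <- z * sqrt(p_hat * (1 - p_hat) / n)
  if (percent) hw * 100 else hw
}

#' Monte Carlo cell-fate distribution
#'
#' Runs `n` independent simulations, each from a fresh uniform random
#' initialization ([random_init()] with a counter-derived seed), to its
#' attractor, classifies the fate, and tabulates counts, proportions and
#' confidence-interval half-widths.  Unresolved attractors are counted
#' under their own `"unresolved"` label, never dropped.  Identical
#' `(model, n, seed)` give identical distributions.
#'
#' @param model an `actnet_model`.
#' @param n number of simulations.
#' @param seed master seed.
#' @param classifier an `actnet_classifier`.
#' @param conf confidence level for the half-widths (default 0.99).
#' @param max_events per-simulation event budget.
#' @param ratio optional character pair of fate labels: report the ratio
#'   `counts[ratio[1]] / counts[ratio[2]]` with a first-order delta-method
#'   CI (approximate).  Defaults to the classifier's first two labels.
#' @return a `fate_distribution`.
#' @export
monte_carlo_fates <- function(model, n, seed, classifier, conf = 0.99,
                              max_events = NULL, ratio = NULL) {
  stopifnot(n >= 1)
  if (is.null(max_events)) max_events <- default_max_events(model)
  labels <- character(n)
  for (i in seq_len(n)) {
    init <- random_init(model, derive_seed(seed, i))
    att <- find_attractor(model, init, max_events)
    labels[i] <- classify_fate(att, classifier)
  }
  lab_order <- unique(c(names(classifier$rules), classifier$fallback,
                        "unresolved", labels))
  counts <- table(factor(labels, levels = lab_order))
  counts <- counts[names(counts) %in% c(names(classifier$rules),
                                        classifier$fallback, "unresolved") |
                   counts > 0]
  props <- as.numeric(counts) / n
  hw <- proportion_ci(props, n, conf)
  if (is.null(ratio)) ratio <- names(classifier$rules)[seq_len(
    min(2L, length(classifier$rules)))]
  rat <- NULL
  if (length(ratio) == 2L && all(ratio %in% names(counts))) {
    p1 <- counts[[ratio[1L]]] / n
    p2 <- counts[[ratio[2L]]] / n
    if (p2 > 0) {
      r <- p1 / p2
      rhw <- if (p1 > 0) {
        # delta method on a multinomial pair: cov(p1,p2) = -p1 p2 / n
        qnorm((1 + conf) / 2) * r *
          sqrt(((1 - p1) / p1 + (1 - p2) / p2 + 2) / n)
      } else 0
      rat <- list(labels = ratio, value = r, ci_halfwidth = rhw)
    }
  }
  structure(list(n = n, seed = seed, conf = conf,
                 counts = setNames(as.integer(counts), names(counts)),
                 proportions = setNames(props, names(counts)),
                 ci_halfwidth = setNames(hw, names(counts)),
                 ratio = rat),
            class = "fate_distribution")
}

#' @export
print.fate_distribution <- function(x, ...) {
  cat("<fate_distribution> n =", x$n, "\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate a fate distribution
#'
#' @param x a `fate_distribution`.
#' @param ... unused.
#' @return data frame with columns `fate`, `count`, `proportion`,
#'   `ci_halfwidth`, `ratio` (the ratio row carries the between-fates
#'   ratio and its approximate CI; `NA` elsewhere).
#' @export
as.data.frame.fate_distribution <- function(x, ...) {
  df <- data.frame(fate = names(x$counts),
                   count = as.integer(x$counts),
                   proportion = as.numeric(x$proportions),
                   ci_halfwidth = as.numeric(x$ci_halfwidth),
                   ratio = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(x$ratio)) {
    df <- rbind(df, data.frame(
      fate = paste(x$ratio$labels, collapse = "/"),
      count = NA_integer_, proportion = NA_real_,
      ci_halfwidth = x$ratio$ci_halfwidth, ratio = x$ratio$value,
      stringsAsFactors = FALSE))
  }
  df
}

#' Single-node knockout / constitutive-activation screen
#'
#' For every node and each clamp level in `{0, levels}` (in-silico knockout
#' and constitutive activation), runs a Monte Carlo fate distribution with
#' that single perturbation and reports the deviation of each fate
#' proportion from the unperturbed baseline (computed once, with the same
#' `n` and seed policy).  Output has exactly `2 * n_nodes` records.
#'
#' @inheritParams monte_carlo_fates
#' @param nodes optional subset of node names to screen (default: all).
#' @return list with `baseline` (a `fate_distribution`) and `records`, a
#'   long data frame: `node`, `clamp`, `fate`, `proportion`, `deviation`,
#'   `ci_halfwidth`.
#' @export
single_perturbation_screen <- function(model, n, seed, classifier,
                                       nodes = NULL, conf = 0.99,
                                       max_events = NULL) {
  if (is.null(nodes)) nodes <- model$nodes$name
  baseline <- monte_carlo_fates(model, n, seed, classifier, conf, max_events)
  records <- list()
  run <- 0L
  for (nd in nodes) {
    full <- model$nodes$levels[node_index(model, nd)]
    for (cl in c(0L, full)) {
      run <- run + 1L
      pert <- apply_clamps(model, setNames(list(cl), nd))
      fd <- monte_carlo_fates(pert, n, derive_seed(seed, 100000L + run),
                              classifier, conf, max_events)
      fates <- union(names(baseline$proportions), names(fd$proportions))
      p0 <- ifelse(fates %in% names(baseline$proportions),
                   baseline$proportions[fates], 0)
      p1 <- ifelse(fates %in% names(fd$proportions), fd$proportions[fates], 0)
      records[[run]] <- data.frame(node = nd, clamp = cl, fate = fates,
                                   proportion = as.numeric(p1),
                                   deviation = as.numeric(p1 - p0),
                                   ci_halfwidth = proportion_ci(as.numeric(p1),
                                                                n, conf),
                                   stringsAsFactors = FALSE)
    }
  }
  list(baseline = baseline, records = do.call(rbind, records))
}

#' Pairwise fate-switch screen from an attractor state
#'
#' Starting from the levels of a verified attractor, perturbs every
#' unordered pair of nodes in all four knockout / constitutive-activation
#' combinations — plus every single node at each of the two clamp levels,
#' so perturbations sufficient alone are identifiable — runs one
#' deterministic simulation per combination, and records the fate of the
#' resulting attractor.  Output is a long table with `4 * choose(n, 2)`
#' pair rows plus `2 * n` single rows.
#'
#' @param model an `actnet_model` (unperturbed).
#' @param start_levels named levels of an attractor of `model`; rejected if
#'   simulating from it does not reproduce itself.
#' @param classifier an `actnet_classifier`.
#' @param nodes optional subset of node names to screen.
#' @param max_events per-simulation event budget.
#' @return data frame: `node1`, `clamp1`, `node2`, `clamp2`, `fate`
#'   (single-node rows have `NA` in `node2`/`clamp2`).
#' @export
pairwise_switch_screen <- function(model, start_levels, classifier,
                                   nodes = NULL, max_events = NULL) {
  if (inherits(start_levels, "actnet_attractor")) {
    start_levels <- start_levels$reported_levels
  }
  base <- find_attractor(model, start_levels, max_events)
  if (base$kind == "unresolved" ||
      !all(base$reported_levels == start_levels[names(base$reported_levels)])) {
    stop("start_levels is not an attractor of the unperturbed model",
         call. = FALSE)
  }
  if (is.null(nodes)) nodes <- model$nodes$name
  full <- setNames(model$nodes$levels[node_index(model, nodes)], nodes)

  run1 <- function(clamps) {
    pert <- apply_clamps(model, clamps)
    classify_fate(find_attractor(pert, start_levels, max_events), classifier)
  }
  rows <- list()
  for (nd in nodes) {
    for (cl in c(0L, full[[nd]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        node1 = nd, clamp1 = cl, node2 = NA_character_, clamp2 = NA_integer_,
        fate = run1(setNames(list(cl), nd)), stringsAsFactors = FALSE)
    }
  }
  if (length(nodes) > 1L) {
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in seq(i + 1L, length(nodes))) {
        for (c1 in c(0L, full[[nodes[i]]])) {
          for (c2 in c(0L, full[[nodes[j]]])) {
            rows[[length(rows) + 1L]] <- data.frame(
              node1 = nodes[i], clamp1 = c1, node2 = nodes[j], clamp2 = c2,
              fate = run1(setNames(list(c1, c2), c(nodes[i], nodes[j]))),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
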