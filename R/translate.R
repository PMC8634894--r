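k_class <- c(slow = 0.1, fast = 1.0)

# --- Boolean expression parsing (recursive descent) ------------------------
# expr := term ('|' term)* ; term := factor ('&' factor)* ;
# factor := '!' factor | '(' expr ')' | name.  AND/OR/NOT words also accepted.

tokenize_expr <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_.]*|\\||&|!|\\(|\\)"
  toks <- regmatches(text, gregexpr(pat, text))[[1L]]
  leftover <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", leftover)) {
    stop("unexpected character(s) in expression: '",
         gsub("[[:space:]]", "", leftover), "'", call. = FALSE)
  }
  up <- toupper(toks)
  toks[up == "AND"] <- "&"
  toks[up == "OR"] <- "|"
  toks[up == "NOT"] <- "!"
  toks
}

parse_expr_tokens <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression", call. = FALSE)
    if (t == "!") { take(); return(list(type = "not", arg = parse_factor())) }
    if (t == "(") {
      take()
      e <- parse_or()
      if (!identical(peek(), ")")) stop("missing ')'", call. = FALSE)
      take()
      return(e)
    }
    if (t %in% c("&", "|", ")")) stop("unexpected '", t, "'", call. = FALSE)
    take()
    list(type = "var", name = t)
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "&")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)
  }
  e <- parse_or()
  if (!is.na(peek())) stop("trailing tokens after expression", call. = FALSE)
  e
}

expr_vars <- function(e) {
  switch(e$type,
         var = e$name,
         "not" = expr_vars(e$arg),
         unique(unlist(lapply(e$args, expr_vars))))
}

#' Parse a Boolean rule file
#'
#' One rule per line, `target = expression`, with expressions over declared
#' node names using `&`/`AND`, `|`/`OR`, `!`/`NOT` and parentheses.  A line
#' `name =` (empty right-hand side) declares an input node with no
#' regulators.  Per-rule annotations: `@slow` (gene-expression class,
#' default is fast), `@dual` (the node requires both expression and
#' post-translational activation and is expanded into the three-node
#' prot/PTM pattern on translation), `@const(v)` (constant dummy node
#' clamped at level `v`), and `@w(source)=value` (additive OR-branch weight
#' multiplying the class strength).  `#` starts a comment.
#'
#' @param text rule file content (character vector of lines, or a single
#'   string with newlines), or a file path.
#' @return an `actnet_boolean` model: `rules` (expression ASTs),
#'   `class_tags`, `dual_regulation`, `weights`, `consts`.
#' @export
parse_boolean_rules <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  rules <- list(); tags <- character(0); dual <- character(0)
  weights <- list(); consts <- integer(0)
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!grepl("[^[:space:]]", raw)) next
    oops <- function(msg) stop("line ", ln, ": ", msg, call. = FALSE)

    w <- list()
    wm <- gregexpr("@w\\(([A-Za-z_][A-Za-z0-9_.]*)\\)[[:space:]]*=[[:space:]]*([0-9.]+)", raw)
    for (hit in regmatches(raw, wm)[[1L]]) {
      src <- sub("@w\\(([^)]*)\\).*", "\\1", hit)
      val <- as.numeric(sub(".*=[[:space:]]*", "", hit))
      if (!is.finite(val) || val <= 0) oops("weights must be positive")
      w[[src]] <- val
    }
    raw <- gsub("@w\\([^)]*\\)[[:space:]]*=[[:space:]]*[0-9.]+", "", raw)
    const <- NA_integer_
    cm <- regmatches(raw, regexec("@const\\(([0-9]+)\\)", raw))[[1L]]
    if (length(cm)) const <- as.integer(cm[2L])
    raw <- gsub("@const\\([0-9]+\\)", "", raw)
    is_slow <- grepl("@slow\\b", raw)
    is_dual <- grepl("@dual\\b", raw)
    raw <- gsub("@(slow|fast|dual)\\b", "", raw)
    if (grepl("@", raw, fixed = TRUE)) oops("unknown annotation")

    eq <- regexpr("=", raw, fixed = TRUE)
    if (eq < 0L) oops("expected 'target = expression'")
    target <- trimws(substr(raw, 1L, eq - 1L))
    rhs <- trimws(substr(raw, eq + 1L, nchar(raw)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", target)) {
      oops(paste0("bad target name '", target, "'"))
    }
    if (target %in% names(rules)) oops(paste0("duplicate rule for '", target, "'"))
    e <- if (nzchar(rhs)) {
      tryCatch(parse_expr_tokens(tokenize_expr(rhs)),
               error = function(err) oops(conditionMessage(err)))
    } else NULL
    rules[[target]] <- if (is.null(e)) list(type = "empty") else e
    tags[target] <- if (is_slow) "slow" else "fast"
    if (is_dual) dual <- c(dual, target)
    if (length(w)) weights[[target]] <- unlist(w)
    if (!is.na(const)) consts[target] <- const
  }
  if (!length(rules)) stop("no rules found", call. = FALSE)
  declared <- names(rules)
  used <- unique(unlist(lapply(rules, function(e) {
    if (e$type == "empty") character(0) else expr_vars(e)
  })))
  unknown <- setdiff(used, declared)
  if (length(unknown)) {
    stop("expression(s) reference undeclared node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(rules = rules, class_tags = tags,
                 dual_regulation = unique(dual), weights = weights,
                 consts = consts),
            class = "actnet_boolean")
}

# Flatten an AST into OR branches; each branch is a list
# (regs = chr vector of 1 or 2, sign = "activation"/"inhibition").
expr_branches <- function(e, target) {
  branches <- if (e$type == "or") e$args else list(e)
  lapply(branches, function(b) {
    if (b$type == "var") {
      list(regs = b$name, sign = "activation")
    } else if (b$type == "not") {
      if (b$arg$type != "var") {
        stop("rule for '", target,
             "': NOT may only be applied to a plain node name", call. = FALSE)
      }
      list(regs = b$arg$name, sign = "inhibition")
    } else if (b$type == "and") {
      if (length(b$args) != 2L) {
        stop("rule for '", target, "': AND takes exactly two conjuncts; ",
             "nest n-ary ANDs through an intermediate node", call. = FALSE)
      }
      regs <- vapply(b$args, function(a) {
        if (a$type != "var") {
          stop("rule for '", target, "': AND conjuncts must be plain ",
               "(positive) node names", call. = FALSE)
        }
        a$name
      }, character(1))
      list(regs = regs, sign = "activation")
    } else {
      stop("rule for '", target, "': unsupported expression shape", call. = FALSE)
    }
  })
}

branch_class <- function(regs, tags) {
  if (any(tags[regs] == "slow")) "slow" else "fast"
}

branch_k <- function(regs, target, bm) {
  kc <- k_class[[branch_class(regs, bm$class_tags)]]
  w <- bm$weights[[target]]
  for (r in regs) if (!is.null(w) && r %in% names(w)) return(w[[r]] * kc)
  kc
}

#' Translate a Boolean model into an activity network
#'
#' Applies the standard translation rules: every OR branch becomes an
#' independent edge (additive, non-exclusive OR semantics); every binary
#' AND becomes one scenario-3 edge; every NOT literal becomes an inhibition
#' edge; every non-constant node receives exactly one self-inhibition loop
#' so that activity decays to 0 absent upstream activation.  Interaction
#' strengths are `0.1` for the slow (gene expression) class and `1.0` for
#' the fast (post-translational) class — an edge inherits the class of its
#' regulator(s), slow dominating — optionally multiplied by per-branch
#' additive weights supplied as data.  Nodes tagged `@dual` are expanded
#' into the three-node expression/PTM pattern (see
#' [expand_dual_regulation()]).  Nodes receiving influences of both classes
#' without being tagged dual are flagged with a warning.
#'
#' @param bm an `actnet_boolean` from [parse_boolean_rules()].
#' @param levels activity granularity of every node (default 100).
#' @return a validated `actnet_model`.
#' @export
boolean_to_network <- function(bm, levels = 100L) {
  stopifnot(inherits(bm, "actnet_boolean"))
  targets <- names(bm$rules)
  nodes <- do.call(rbind, lapply(targets, function(nm) {
    node_spec(nm, levels = levels,
              clamp = if (nm %in% names(bm$consts)) bm$consts[[nm]] else NA_integer_,
              reaction_class = bm$class_tags[[nm]])
  }))
  edges <- list()
  add_edge <- function(...) edges[[length(edges) + 1L]] <<- edge_spec(...)

  for (nm in targets) {
    e <- bm$rules[[nm]]
    is_const <- nm %in% names(bm$consts)
    is_dual <- nm %in% bm$dual_regulation
    branches <- if (e$type == "empty") list() else expr_branches(e, nm)

    if (is_dual) {
      prot <- paste0(nm, "_prot"); ptm <- paste0(nm, "_PTM")
      nodes <- rbind(nodes,
                     node_spec(prot, levels = levels, reaction_class = "slow"),
                     node_spec(ptm, levels = levels, reaction_class = "fast"))
      cls <- vapply(branches, function(b) branch_class(b$regs, bm$class_tags),
                    character(1))
      if (!any(cls == "slow")) {
        warning("dual node '", nm, "' has no slow (expression) influences: ",
                "its _prot side only decays, so it can never activate",
                call. = FALSE)
      }
      for (i in seq_along(branches)) {
        b <- branches[[i]]
        side <- if (cls[i] == "slow") prot else ptm
        add_edge(reg1 = b$regs[1L],
                 reg2 = if (length(b$regs) == 2L) b$regs[2L] else NA_character_,
                 target = side, sign = b$sign,
                 scenario = if (length(b$regs) == 2L) 3L else 1L,
                 k = branch_k(b$regs, nm, bm))
      }
      add_edge(reg1 = prot, reg2 = ptm, target = nm, sign = "activation",
               scenario = 3L, k = k_class[["fast"]])
      add_edge(reg1 = prot, target = prot, sign = "inhibition",
               scenario = 1L, k = k_class[["slow"]])
      add_edge(reg1 = ptm, target = ptm, sign = "inhibition",
               scenario = 1L, k = k_class[["fast"]])
    } else {
      cls <- vapply(branches, function(b) branch_class(b$regs, bm$class_tags),
                    character(1))
      if (length(unique(cls)) > 1L) {
        warning("node '", nm, "' receives influences of both classes but is ",
                "not tagged @dual", call. = FALSE)
      }
      for (b in branches) {
        add_edge(reg1 = b$regs[1L],
                 reg2 = if (length(b$regs) == 2L) b$regs[2L] else NA_character_,
                 target = nm, sign = b$sign,
                 scenario = if (length(b$regs) == 2L) 3L else 1L,
                 k = branch_k(b$regs, nm, bm))
      }
    }
    if (!is_const) {
      add_edge(reg1 = nm, target = nm, sign = "inhibition", scenario = 1L,
               k = k_class[[bm$class_tags[[nm]]]])
    }
  }
  network_model(nodes, do.call(rbind, edges),
                metadata = list(name = "translated"))
}

#' Expand a node into the dual expression / PTM three-node pattern
#'
#' Some proteins must be both expressed and post-translationally activated
#' to act.  This rewires an existing node `N` into three: `N_prot`
#' (expression; receives every incoming edge whose regulators are of the
#' slow class), `N_PTM` (post-translational activation; receives the fast
#' ones), and `N` itself, activated solely by the scenario-3 edge
#' `(N_prot AND N_PTM) -> N`.  Both helper nodes get their class's
#' self-inhibition.  Re-expansion of an already expanded node is rejected.
#'
#' @param model an `actnet_model`.
#' @param node name of the node to expand.
#' @return the expanded model.
#' @export
expand_dual_regulation <- function(model, node) {
  node_index(model, node)
  prot <- paste0(node, "_prot"); ptm <- paste0(node, "_PTM")
  if (any(c(prot, ptm) %in% model$nodes$name)) {
    stop("node '", node, "' is already expanded", call. = FALSE)
  }
  lv <- model$nodes$levels[node_index(model, node)]
  e <- model$edges
  incoming <- which(e$target == node & !is_self_inhibition(e))
  cls <- vapply(incoming, function(i) {
    regs <- c(e$reg1[i], e$reg2[i])
    regs <- regs[!is.na(regs)]
    branch_class(regs, setNames(model$nodes$reaction_class, model$nodes$name))
  }, character(1))
  if (length(incoming) && !any(cls == "slow")) {
    warning("dual node '", node, "' has no slow (expression) influences: ",
            "its _prot side only decays, so it can never activate",
            call. = FALSE)
  }
  model$edges$target[incoming[cls == "slow"]] <- prot
  model$edges$target[incoming[cls == "fast"]] <- ptm
  model$nodes <- rbind(model$nodes,
                       node_spec(prot, levels = lv, reaction_class = "slow"),
                       node_spec(ptm, levels = lv, reaction_class = "fast"))
  model$edges <- rbind(
    model$edges,
    edge_spec(prot, node, sign = "activation", scenario = 3L,
              k = k_class[["fast"]], reg2 = ptm),
    edge_spec(prot, prot, sign = "inhibition", scenario = 1L,
              k = k_class[["slow"]]),
    edge_spec(ptm, ptm, sign = "inhibition", scenario = 1L,
              k = k_class[["fast"]]))
  rownames(model$edges) <- rownames(model$nodes) <- NULL
  validate_model(model)
  model
}
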