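# Independent oracles used to cross-check the package implementation.
# These deliberately take different routes from the code under test:
# rule evaluation goes through R's own parser, merge formulas are coded
# directly from their pointwise definitions, synchronous attractors come
# from per-state iteration, and asynchronous attractors from a hand-written
# Kosaraju SCC pass over a state-transition graph built with
# asyncSuccessors().

# Evaluate rule text via R's parser: `!`, `&`, `|` have the same precedence
# in R as in the rule grammar. `state` is a named 0/1 vector.
oracleEvalRule <- function(text, state) {
  env <- list2env(as.list(stats::setNames(as.logical(state), names(state))))
  v <- eval(parse(text = text)[[1]], envir = env)
  as.integer(as.logical(v))
}

# All assignments over `vars` as a data.frame (first var varies fastest,
# matching the package's bit-0-first encoding).
oracleAssignments <- function(vars) {
  g <- do.call(expand.grid, stats::setNames(rep(list(0:1), length(vars)), vars))
  as.matrix(g)
}

oracleTruthTable <- function(text, vars) {
  asg <- oracleAssignments(vars)
  vapply(seq_len(nrow(asg)), function(i) oracleEvalRule(text, asg[i, ]),
         integer(1))
}

# Flip-test sign classification straight from the definition, by loops.
oracleSigns <- function(text, vars) {
  asg <- oracleAssignments(vars)
  out <- character(0)
  for (v in vars) {
    up <- FALSE; down <- FALSE
    for (i in seq_len(nrow(asg))) {
      s <- asg[i, ]
      if (s[[v]] == 1) next
      f0 <- oracleEvalRule(text, s)
      s[[v]] <- 1
      f1 <- oracleEvalRule(text, s)
      if (f0 < f1) up <- TRUE
      if (f0 > f1) down <- TRUE
    }
    out[[v]] <- if (up && down) "dual" else if (up) "activator"
                else if (down) "inhibitor" else "none"
  }
  out
}

# Pointwise merge formulas, coded directly from their definitions.
# `ruleTexts`: character vector of the node's source rules. Returns the
# merged truth column over all assignments of the union of variables.
oracleMergedColumn <- function(ruleTexts, vars, strategy) {
  asg <- oracleAssignments(vars)
  cols <- vapply(ruleTexts, function(tx)
    vapply(seq_len(nrow(asg)), function(i) oracleEvalRule(tx, asg[i, ]),
           integer(1)),
    integer(nrow(asg)))
  cols <- matrix(cols, nrow = nrow(asg))
  if (strategy == "OR") return(as.integer(apply(cols, 1, max)))
  if (strategy == "AND") return(as.integer(apply(cols, 1, min)))
  # Inhibitor Wins: 0 whenever any regulator that inhibits the node in any
  # source rule is ON; otherwise the OR combination.
  inh <- character(0)
  for (tx in ruleTexts) {
    sg <- oracleSigns(tx, all.vars(parse(text = tx)[[1]]))
    inh <- union(inh, names(sg)[sg %in% c("inhibitor", "dual")])
  }
  orCol <- as.integer(apply(cols, 1, max))
  if (length(inh) == 0) return(orCol)
  anyInh <- as.integer(rowSums(asg[, inh, drop = FALSE]) > 0)
  ifelse(anyInh == 1L, 0L, orCol)
}

# Truth column of a package BoolExpr over the same assignment order.
pkgColumn <- function(expr, vars) {
  asg <- oracleAssignments(vars)
  evalRule(expr, asg)
}

# ---- attractor oracles -------------------------------------------------

# Every state of a model, rows ordered by encoded value, columns sorted.
allStates <- function(model) {
  nodes <- sort(nodeIds(model))
  decodeState(seq_len(2^length(nodes)) - 1, nodes)
}

# Synchronous attractors by per-state iteration with cycle extraction.
# Returns a sorted character vector of canonical attractor keys
# ("c1,c2,..." over sorted encoded states).
oracleSyncAttractors <- function(model) {
  nodes <- sort(nodeIds(model))
  states <- allStates(model)
  keys <- character(0)
  for (s0 in seq_len(nrow(states))) {
    path <- integer(0)
    seenAt <- new.env(parent = emptyenv())
    st <- states[s0, ]
    repeat {
      code <- encodeState(st, nodes)
      k <- as.character(code)
      at <- get0(k, envir = seenAt)
      if (!is.null(at)) {
        cyc <- path[at:length(path)]
        keys <- c(keys, paste(sort(cyc), collapse = ","))
        break
      }
      path <- c(path, code)
      assign(k, length(path), envir = seenAt)
      st[] <- as.integer(syncStep(model, st))
    }
  }
  sort(unique(keys))
}

# Iterative Kosaraju strongly connected components.
# adj/radj: lists of integer successor/predecessor vectors, 1-based.
kosarajuComponents <- function(adj, radj) {
  n <- length(adj)
  visited <- logical(n)
  order <- integer(n); oi <- 0L
  ptr <- integer(n)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- s
    visited[s] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      if (ptr[v] < length(adj[[v]])) {
        ptr[v] <- ptr[v] + 1L
        w <- adj[[v]][[ptr[v]]]
        if (!visited[w]) { visited[w] <- TRUE; stack <- c(stack, w) }
      } else {
        oi <- oi + 1L; order[oi] <- v
        stack <- stack[-length(stack)]
      }
    }
  }
  comp <- integer(n); cid <- 0L
  for (v in rev(order)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    stack <- v; comp[v] <- cid
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (w in radj[[u]]) if (comp[w] == 0L) {
        comp[w] <- cid; stack <- c(stack, w)
      }
    }
  }
  comp
}

# Asynchronous attractors as the terminal SCCs of the state-transition
# graph, built state by state with asyncSuccessors(). Same key format as
# oracleSyncAttractors.
oracleAsyncAttractors <- function(model) {
  nodes <- sort(nodeIds(model))
  states <- allStates(model)
  n <- nrow(states)
  adj <- vector("list", n)
  radj <- vector("list", n)
  for (i in seq_len(n)) {
    succ <- asyncSuccessors(model, states[i, ])
    tos <- if (length(succ) == 0L) integer(0)
           else vapply(succ, function(s) as.integer(encodeState(s, nodes)) + 1L,
                       integer(1))
    adj[[i]] <- tos
    for (t in tos) radj[[t]] <- c(radj[[t]], i)
  }
  for (i in seq_len(n)) if (is.null(radj[[i]])) radj[[i]] <- integer(0)
  comp <- kosarajuComponents(adj, radj)
  nonTerminal <- integer(0)
  for (i in seq_len(n))
    for (t in adj[[i]]) if (comp[t] != comp[i])
      nonTerminal <- c(nonTerminal, comp[i])
  terminal <- setdiff(unique(comp), unique(nonTerminal))
  keys <- vapply(terminal, function(cc)
    paste(sort(which(comp == cc) - 1L), collapse = ","), "")
  sort(keys)
}

# Canonical keys of a package AttractorSet, for comparison with oracles.
attractorKeys <- function(aset) {
  nodes <- aset@nodes
  sort(vapply(seq_len(length(aset)), function(i) {
    a <- aset[[i]]
    paste(sort(encodeState(a@states, nodes)), collapse = ",")
  }, ""))
}

# Random rule text over `vars` for parser fuzzing: random tree rendered
# with full parentheses so the oracle and the parser see the same formula.
randomRuleText <- function(vars, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    v <- sample(vars, 1)
    return(if (stats::runif(1) < 0.3) paste0("!", v) else v)
  }
  op <- sample(c("&", "|", "!"), 1)
  if (op == "!")
    return(paste0("!(", randomRuleText(vars, depth - 1), ")"))
  paste0("(", randomRuleText(vars, depth - 1), " ", op, " ",
         randomRuleText(vars, depth - 1), ")")
}

# Round-trip model comparison aware of the bnet input convention: an input
# node and a self-identity rule (A = A) have identical dynamics (both hold
# their value), so either counts as preserving the original node.
expectModelsEquivalent <- function(m2, m) {
  expect_equal(sort(nodeIds(m2)), sort(nodeIds(m)))
  for (id in nodeIds(m)) {
    r <- nodeRule(m, id); r2 <- nodeRule(m2, id)
    if (is.null(r)) r <- bVar(id)
    if (is.null(r2)) r2 <- bVar(id)
    expect_true(exprsEquivalent(r, r2),
                label = paste("rule of", id, "round-trips"))
  }
}
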