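## State-space dynamics: synchronous and asynchronous attractor detection.
##
## States are encoded as nonnegative integers over the lexicographically
## sorted node order: bit j-1 of the code is the value of the j-th sorted
## node. External inputs hold their value under both update schemes, so the
## exhaustive enumeration automatically analyses every input combination
## and each attractor carries a constant input context.

#' Attractor: a fixed point or cyclic attractor
#'
#' A terminal state set of the dynamics: a single stable state (fixed
#' point) or a set the dynamics cannot leave and will revisit (cyclic). For
#' the synchronous scheme a cyclic attractor is a closed orbit of the
#' deterministic update map; for the asynchronous scheme it is a terminal
#' strongly connected component of the state-transition graph.
#'
#' @slot kind `"fixed_point"` or `"cyclic"`.
#' @slot states Integer 0/1 matrix, one row per attractor state, columns
#'   named by node (lexicographic order), rows in increasing encoded order.
#' @slot scheme `"synchronous"` or `"asynchronous"`.
#' @slot label Attractor label, e.g. `"M3"`.
#' @slot inputContext Named integer vector: values of the external input
#'   nodes in this attractor (inputs are frozen, so they are constant
#'   across its states).
#' @export
setClass("Attractor",
  representation(kind = "character", states = "matrix", scheme = "character",
                 label = "character", inputContext = "integer"))

setValidity("Attractor", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("fixed_point", "cyclic"))
    msgs <- c(msgs, "kind must be 'fixed_point' or 'cyclic'")
  if (!object@scheme %in% c("synchronous", "asynchronous"))
    msgs <- c(msgs, "scheme must be 'synchronous' or 'asynchronous'")
  if (nrow(object@states) < 1L)
    msgs <- c(msgs, "attractor must contain at least one state")
  if (object@kind == "fixed_point" && nrow(object@states) != 1L)
    msgs <- c(msgs, "a fixed point has exactly one state")
  if (!all(object@states %in% c(0L, 1L)))
    msgs <- c(msgs, "states must be 0/1")
  if (length(msgs) == 0L) TRUE else msgs
})

setMethod("show", "Attractor", function(object) {
  cat("Attractor ", object@label, " (", object@kind, ", ", object@scheme,
      ", ", nrow(object@states), " state",
      if (nrow(object@states) > 1L) "s", ")\n", sep = "")
  if (length(object@inputContext) > 0L)
    cat("  inputs: ", paste(names(object@inputContext), object@inputContext,
                            sep = "=", collapse = " "), "\n", sep = "")
  print(object@states)
  invisible(object)
})

#' AttractorSet: all attractors of a model under one update scheme
#'
#' Container for the result of [attractors()]: the list of
#' [Attractor-class] objects in canonical order (smallest encoded state
#' first), the scheme, and a completeness flag (`"exact"` for exhaustive
#' enumeration, `"unknown"` for sampling mode).
#'
#' @slot attractors List of `Attractor`.
#' @slot modelId Model identifier the labels are prefixed with.
#' @slot nodes Node names (lexicographic), the column order of all state
#'   matrices.
#' @slot scheme `"synchronous"` or `"asynchronous"`.
#' @slot completeness `"exact"` or `"unknown"`.
#' @export
setClass("AttractorSet",
  representation(attractors = "list", modelId = "character",
                 nodes = "character", scheme = "character",
                 completeness = "character"))

setValidity("AttractorSet", function(object) {
  ok <- all(vapply(object@attractors, methods::is, logical(1), "Attractor"))
  if (!ok) return("attractors must all be Attractor objects")
  if (!object@completeness %in% c("exact", "unknown"))
    return("completeness must be 'exact' or 'unknown'")
  TRUE
})

#' @export
setMethod("length", "AttractorSet", function(x) length(x@attractors))

#' @export
setMethod("[[", "AttractorSet", function(x, i) x@attractors[[i]])

setMethod("show", "AttractorSet", function(object) {
  kinds <- vapply(object@attractors, function(a) a@kind, "")
  cat("AttractorSet for '", object@modelId, "' (", object@scheme,
      ", ", object@completeness, "): ", length(object@attractors),
      " attractor(s): ", sum(kinds == "fixed_point"), " fixed point(s), ",
      sum(kinds == "cyclic"), " cyclic\n", sep = "")
  for (a in object@attractors)
    cat("  ", a@label, ": ", a@kind, ", ", nrow(a@states), " state(s)\n",
        sep = "")
  invisible(object)
})

## ---- state encoding ---------------------------------------------------

.dynNodes <- function(model) sort(model@nodeIds)

#' Encode and decode model states
#'
#' A state is a total 0/1 assignment over the model's nodes; its canonical
#' integer code packs the values of the lexicographically sorted nodes as
#' bits (first sorted node = least significant bit). Encoding and decoding
#' are inverse bijections.
#'
#' @param state Named 0/1 vector (or matrix with one row per state).
#' @param nodes Character vector giving the canonical node order.
#' @return `encodeState`: numeric code(s); `decodeState`: 0/1 integer
#'   matrix with one row per code, columns named by node.
#' @export
encodeState <- function(state, nodes) {
  if (!is.matrix(state)) state <- matrix(state, nrow = 1L,
                                         dimnames = list(NULL, names(state)))
  stopifnot(all(nodes %in% colnames(state)))
  as.numeric(state[, nodes, drop = FALSE] %*% 2^(seq_along(nodes) - 1L))
}

#' @rdname encodeState
#' @param code Numeric state code(s).
#' @export
decodeState <- function(code, nodes) {
  m <- vapply(seq_along(nodes),
              function(j) as.integer(code %/% 2^(j - 1L)) %% 2L,
              integer(length(code)))
  m <- matrix(m, nrow = length(code), dimnames = list(NULL, nodes))
  m
}

## Next-value columns over the whole state space: list per node of the
## updated value in every state (inputs: their own column).
.nextColumns <- function(model, nodes) {
  n <- length(nodes)
  nStates <- 2^n
  if (nStates > .Machine$integer.max)
    stop("state space too large to enumerate")
  varCol <- function(name) {
    j <- match(name, nodes)
    if (is.na(name) || is.na(j))
      stop("evaluation error: variable '", name, "' is not assigned")
    period <- 2^(j - 1L)
    rep(rep(c(0L, 1L), each = period), length.out = nStates)
  }
  lapply(nodes, function(id) {
    r <- model@rules[[id]]
    if (is.null(r)) varCol(id) else .evalColumns(r, varCol, nStates)
  })
}

## Synchronous successor of every state, as 1-based index vector.
.syncImage <- function(model, nodes) {
  cols <- .nextColumns(model, nodes)
  succ <- numeric(2^length(nodes))
  for (j in seq_along(nodes)) succ <- succ + cols[[j]] * 2^(j - 1L)
  as.integer(succ) + 1L
}

#' Synchronous update step
#'
#' Applies every node's rule simultaneously: each regulated node takes the
#' value of its rule evaluated in `state`; external inputs keep their
#' value.
#'
#' @param model A valid `LogicalModel`.
#' @param state Named 0/1 vector assigning every node.
#' @return The successor state, same names and order as `state`.
#' @examples
#' m <- logicalModel(c(A = "B", B = "A"))
#' syncStep(m, c(A = 0, B = 1))
#' @export
syncStep <- function(model, state) {
  stopifnot(all(model@nodeIds %in% names(state)))
  out <- state
  for (id in model@nodeIds) {
    r <- model@rules[[id]]
    if (!is.null(r)) out[[id]] <- evalRule(r, state)
  }
  out
}

#' Asynchronous successor states
#'
#' One successor per unstable node: for each node whose rule output differs
#' from its current value, the state with only that node flipped. A state
#' with no successors is a fixed point.
#'
#' @param model A valid `LogicalModel`.
#' @param state Named 0/1 vector assigning every node.
#' @return List of successor states (possibly empty).
#' @export
asyncSuccessors <- function(model, state) {
  out <- list()
  for (id in model@nodeIds) {
    r <- model@rules[[id]]
    if (is.null(r)) next
    v <- evalRule(r, state)
    if (v != state[[id]]) {
      s2 <- state
      s2[[id]] <- v
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

## ---- attractor detection ----------------------------------------------

.mkAttractor <- function(codes, nodes, scheme, inputIds, fixed) {
  codes <- sort(codes)
  states <- decodeState(codes, nodes)
  ctx <- if (length(inputIds) > 0L)
    stats::setNames(as.integer(states[1L, inputIds]), inputIds)
  else stats::setNames(integer(0), character(0))
  methods::new("Attractor",
               kind = if (fixed) "fixed_point" else "cyclic",
               states = states, scheme = scheme, label = "",
               inputContext = ctx)
}

.finishSet <- function(atts, model, nodes, scheme, completeness) {
  firsts <- vapply(atts, function(a) encodeState(a@states[1L, ], nodes),
                   numeric(1))
  atts <- atts[order(firsts)]
  for (i in seq_along(atts)) atts[[i]]@label <- paste0(model@modelId, i)
  methods::new("AttractorSet", attractors = atts, modelId = model@modelId,
               nodes = nodes, scheme = scheme, completeness = completeness)
}

.syncAttractorsExact <- function(model, nodes, inputIds) {
  succ <- .syncImage(model, nodes)
  nStates <- length(succ)
  ## pointer doubling: after >= nStates steps every state sits on a cycle
  t <- succ
  steps <- 1
  while (steps < nStates) { t <- t[t]; steps <- steps * 2 }
  cyclic <- sort(unique(t))
  seen <- logical(nStates)
  atts <- list()
  for (s in cyclic) {
    if (seen[s]) next
    orbit <- s
    cur <- succ[s]
    while (cur != s) { orbit <- c(orbit, cur); cur <- succ[cur] }
    seen[orbit] <- TRUE
    atts[[length(atts) + 1L]] <- .mkAttractor(orbit - 1L, nodes,
                                              "synchronous", inputIds,
                                              fixed = length(orbit) == 1L)
  }
  atts
}

## Asynchronous state-transition graph as an edge matrix (1-based codes).
.asyncEdges <- function(model, nodes) {
  cols <- .nextColumns(model, nodes)
  nStates <- 2^length(nodes)
  from <- integer(0); to <- integer(0)
  for (j in seq_along(nodes)) {
    period <- 2^(j - 1L)
    cur <- rep(rep(c(0L, 1L), each = period), length.out = nStates)
    delta <- which(cols[[j]] != cur)     # 1-based state indices
    if (length(delta) > 0L) {
      from <- c(from, delta)
      to <- c(to, as.integer(bitwXor(delta - 1L, as.integer(period))) + 1L)
    }
  }
  cbind(from, to)
}

.asyncAttractorsExact <- function(model, nodes, inputIds) {
  edges <- .asyncEdges(model, nodes)
  nStates <- 2^length(nodes)
  if (nrow(edges) == 0L) {
    ## every state is a fixed point
    return(lapply(seq_len(nStates) - 1L, .mkAttractor, nodes = nodes,
                  scheme = "asynchronous", inputIds = inputIds, fixed = TRUE))
  }
  g <- igraph::make_graph(t(edges), n = nStates, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  crossing <- memb[edges[, 1L]] != memb[edges[, 2L]]
  nonTerminal <- unique(memb[edges[crossing, 1L]])
  terminal <- setdiff(seq_len(comp$no), nonTerminal)
  atts <- list()
  for (cc in terminal) {
    codes <- which(memb == cc) - 1L
    atts[[length(atts) + 1L]] <- .mkAttractor(codes, nodes, "asynchronous",
                                              inputIds,
                                              fixed = length(codes) == 1L)
  }
  atts
}

## Sampling fallbacks for models beyond the exhaustive cap. Attractors
## found are genuine, but the enumeration may be incomplete.
.syncAttractorsSample <- function(model, nodes, inputIds, nStarts, maxSteps) {
  n <- length(nodes)
  found <- new.env(parent = emptyenv())
  atts <- list()
  for (s in seq_len(nStarts)) {
    state <- stats::setNames(sample(c(0L, 1L), n, replace = TRUE), nodes)
    trace <- new.env(parent = emptyenv())
    step <- 0L
    repeat {
      key <- paste(state, collapse = "")
      prev <- get0(key, envir = trace)
      if (!is.null(prev)) {
        ## closed orbit = states from first visit of `key` onward
        hist <- get("hist", envir = trace)
        orbit <- hist[prev:length(hist)]
        okey <- paste(sort(orbit), collapse = ",")
        if (is.null(get0(okey, envir = found))) {
          assign(okey, TRUE, envir = found)
          atts[[length(atts) + 1L]] <- .mkAttractor(
            orbit, nodes, "synchronous", inputIds,
            fixed = length(orbit) == 1L)
        }
        break
      }
      hist <- get0("hist", envir = trace, ifnotfound = numeric(0))
      assign("hist", c(hist, encodeState(state, nodes)), envir = trace)
      assign(key, length(hist) + 1L, envir = trace)
      state[] <- as.integer(syncStep(model, state))
      step <- step + 1L
      if (step > maxSteps) break
    }
  }
  atts
}

.asyncAttractorsSample <- function(model, nodes, inputIds, nStarts, maxSteps,
                                   maxSet = 65536L) {
  n <- length(nodes)
  found <- new.env(parent = emptyenv())
  atts <- list()
  for (s in seq_len(nStarts)) {
    state <- stats::setNames(sample(c(0L, 1L), n, replace = TRUE), nodes)
    for (step in seq_len(maxSteps)) {
      succs <- asyncSuccessors(model, state)
      if (length(succs) == 0L) break
      state <- succs[[sample.int(length(succs), 1L)]]
    }
    ## forward closure from the endpoint; if it closes, its terminal SCCs
    ## are true attractors
    frontier <- list(state)
    seen <- new.env(parent = emptyenv())
    assign(paste(state, collapse = ""), state, envir = seen)
    closed <- TRUE
    while (length(frontier) > 0L) {
      nxt <- list()
      for (st in frontier) {
        for (sc in asyncSuccessors(model, st)) {
          key <- paste(sc, collapse = "")
          if (is.null(get0(key, envir = seen))) {
            assign(key, sc, envir = seen)
            nxt[[length(nxt) + 1L]] <- sc
          }
        }
      }
      frontier <- nxt
      if (length(ls(seen)) > maxSet) { closed <- FALSE; break }
    }
    if (!closed) next
    states <- do.call(rbind, mget(ls(seen), envir = seen))
    codes <- encodeState(states, nodes)
    idx <- stats::setNames(seq_along(codes), as.character(codes))
    ef <- integer(0); et <- integer(0)
    for (i in seq_len(nrow(states))) {
      for (sc in asyncSuccessors(model, states[i, ])) {
        ef <- c(ef, i); et <- c(et, idx[[as.character(encodeState(sc, nodes))]])
      }
    }
    if (length(ef) == 0L) {
      codesA <- codes
      okey <- paste(sort(codesA), collapse = ",")
      if (is.null(get0(okey, envir = found))) {
        assign(okey, TRUE, envir = found)
        atts[[length(atts) + 1L]] <- .mkAttractor(codesA, nodes,
                                                  "asynchronous", inputIds,
                                                  fixed = length(codesA) == 1L)
      }
      next
    }
    g <- igraph::make_graph(rbind(ef, et), n = nrow(states), directed = TRUE)
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership
    nonTerm <- unique(memb[ef[memb[ef] != memb[et]]])
    for (cc in setdiff(seq_len(comp$no), nonTerm)) {
      codesA <- codes[memb == cc]
      okey <- paste(sort(codesA), collapse = ",")
      if (is.null(get0(okey, envir = found))) {
        assign(okey, TRUE, envir = found)
        atts[[length(atts) + 1L]] <- .mkAttractor(codesA, nodes,
                                                  "asynchronous", inputIds,
                                                  fixed = length(codesA) == 1L)
      }
    }
  }
  atts
}

#' Detect the attractors of a logical model
#'
#' Exact mode enumerates the full state space (up to `cap` nodes).
#' Synchronous attractors are the cycles of the deterministic update map,
#' found by iterating every state; asynchronous attractors are the terminal
#' strongly connected components of the asynchronous state-transition
#' graph. External inputs hold their value, so the enumeration covers every
#' input combination and each attractor records its input context. Fixed
#' points coincide between the two schemes (both are the solutions of
#' f(x) = x).
#'
#' Beyond the cap, request `mode = "sampling"`: random initial states with
#' trajectory cycle detection (synchronous) or random walks plus a bounded
#' forward-closure terminal-SCC test (asynchronous). Sampling finds genuine
#' attractors but may miss some; the result is flagged
#' `completeness = "unknown"`.
#'
#' @param model A valid `LogicalModel`.
#' @param scheme `"asynchronous"` (default) or `"synchronous"`.
#' @param mode `"exact"` or `"sampling"`.
#' @param cap Maximum node count for exact mode (default 22).
#' @param nStarts,maxSteps Sampling-mode effort.
#' @return An [AttractorSet-class], attractors in canonical order (smallest
#'   encoded state first) and labelled `<modelId><i>`.
#' @examples
#' m <- logicalModel(c(A = "B", B = "A"))
#' attractors(m, "synchronous")   # 00, 11, and the {01,10} cycle
#' attractors(m, "asynchronous")  # only the two fixed points
#' @export
attractors <- function(model, scheme = c("asynchronous", "synchronous"),
                       mode = c("exact", "sampling"), cap = 22L,
                       nStarts = 500L, maxSteps = 1000L) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  d <- validateModel(model)
  if (length(d) > 0L) stop("invalid model: ", d[[1L]])
  nodes <- .dynNodes(model)
  inputIds <- sort(inputNodes(model))
  if (mode == "exact" && length(nodes) > cap)
    stop("model has ", length(nodes), " nodes, above the exhaustive cap of ",
         cap, "; request mode = \"sampling\" explicitly")
  atts <- if (mode == "exact") {
    if (scheme == "synchronous") .syncAttractorsExact(model, nodes, inputIds)
    else .asyncAttractorsExact(model, nodes, inputIds)
  } else {
    if (scheme == "synchronous")
      .syncAttractorsSample(model, nodes, inputIds, nStarts, maxSteps)
    else .asyncAttractorsSample(model, nodes, inputIds, nStarts, maxSteps)
  }
  .finishSet(atts, model, nodes, scheme,
             if (mode == "exact") "exact" else "unknown")
}

#' Tabulate an attractor set
#'
#' One row per attractor state with the gene values as columns plus the
#' attractor label, state label (`<label>.<k>`), kind, scheme, and input
#' context -- the tabular twin of a steady-state heatmap. Suitable for
#' `write.csv`.
#'
#' @param aset An [AttractorSet-class].
#' @return data.frame.
#' @export
attractorTable <- function(aset) {
  stopifnot(methods::is(aset, "AttractorSet"))
  rows <- lapply(aset@attractors, function(a) {
    k <- nrow(a@states)
    ctx <- if (length(a@inputContext) > 0L)
      paste(names(a@inputContext), a@inputContext, sep = "=", collapse = ";")
    else ""
    data.frame(attractor = a@label,
               state = paste0(a@label, ".", seq_len(k)),
               kind = a@kind, scheme = a@scheme, inputs = ctx,
               a@states, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean activation frequency of each node over the attractors
#'
#' Summarises long-term behaviour as a per-node activation frequency in
#' [0,1], comparable to measured expression frequencies.
#' `uniform_attractor` (default) averages each node within each attractor
#' and then across attractors, weighting attractors equally;
#' `uniform_state` averages over the multiset of all attractor states,
#' weighting states equally.
#'
#' @param aset An [AttractorSet-class] with at least one attractor.
#' @param weighting `"uniform_attractor"` or `"uniform_state"`.
#' @return Named numeric vector in [0,1], one entry per node.
#' @export
activationFrequency <- function(aset,
                                weighting = c("uniform_attractor",
                                              "uniform_state")) {
  weighting <- match.arg(weighting)
  stopifnot(methods::is(aset, "AttractorSet"), length(aset@attractors) >= 1L)
  if (weighting == "uniform_attractor") {
    per <- vapply(aset@attractors, function(a) colMeans(a@states),
                  numeric(length(aset@nodes)))
    if (is.null(dim(per))) per <- matrix(per, nrow = 1L)  # single-node model
    rowMeans(matrix(per, nrow = length(aset@nodes),
                    dimnames = list(aset@nodes, NULL)))
  } else {
    all <- do.call(rbind, lapply(aset@attractors, function(a) a@states))
    colMeans(all)
  }
}

#' Clamp mutated genes in a model
#'
#' Personalises a model with a mutation profile: each gain-of-function
#' (GoF) gene's rule is replaced by the constant 1 and each
#' loss-of-function (LoF) gene's by the constant 0, fixing the gene ON or
#' OFF in all subsequent dynamics. Other rules are untouched.
#'
#' @param model A valid `LogicalModel`.
#' @param profile data.frame with columns `gene` and `effect`
#'   (`"GoF"`/`"LoF"`, case-insensitive), at most one row per gene.
#' @return The clamped `LogicalModel`.
#' @examples
#' m <- logicalModel(c(A = "B", B = "A"))
#' clampModel(m, data.frame(gene = "A", effect = "LoF"))
#' @export
clampModel <- function(model, profile) {
  stopifnot(is.data.frame(profile),
            all(c("gene", "effect") %in% names(profile)))
  if (nrow(profile) == 0L) return(model)
  if (anyDuplicated(profile$gene))
    stop("mutation profile assigns more than one effect to: ",
         paste(unique(profile$gene[duplicated(profile$gene)]), collapse = ", "))
  missing <- setdiff(profile$gene, model@nodeIds)
  if (length(missing) > 0L)
    stop("mutation profile names gene(s) absent from the model: ",
         paste(missing, collapse = ", "))
  eff <- toupper(profile$effect)
  if (!all(eff %in% c("GOF", "LOF")))
    stop("mutation effects must be 'GoF' or 'LoF'")
  for (i in seq_len(nrow(profile)))
    model@rules[[profile$gene[i]]] <- bConst(if (eff[i] == "GOF") 1L else 0L)
  model
}

#' Read mutation profiles from a TSV cohort file
#'
#' Reads a long-format TSV with header `patient_id<TAB>gene<TAB>effect`
#' (one row per mutated gene per patient) into a named list of per-patient
#' mutation-profile data.frames for [clampModel()] and [cohortScores()].
#' A patient id appearing with no gene (empty `gene` field) yields an empty
#' profile (wild type).
#'
#' @param path TSV file path.
#' @return Named list of data.frames with columns `gene`, `effect`.
#' @export
readMutationProfiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("patient_id", "gene", "effect")
  if (!all(need %in% names(tab)))
    stop("mutation profile table must have columns: ",
         paste(need, collapse = ", "))
  lapply(split(tab, tab$patient_id), function(d) {
    d <- d[nzchar(d$gene), c("gene", "effect"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
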