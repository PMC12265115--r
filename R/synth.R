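## Seeded generators of random Boolean networks and overlapping model
## pairs, so that harmonization, merging, and attractor analysis can all be
## exercised without any external model files.

## Run `fn()` under a pinned, seeded RNG and restore the caller's RNG
## state. The generator pins Mersenne-Twister / Inversion / Rejection so
## the same seed gives the same model on every platform and R version.
.withSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasOld) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  fn()
}

## A random OR-of-ANDs rule over up to k of the given regulator pool.
## Literal signs are positive with probability `bias`.
.randomRule <- function(pool, k, bias) {
  k <- min(k, length(pool))
  nReg <- sample.int(k, 1L)
  regs <- sample(pool, nReg)
  nClauses <- if (nReg >= 2L) sample.int(2L, 1L) else 1L
  split <- if (nClauses == 2L) {
    cut <- sample.int(nReg - 1L, 1L)
    list(regs[seq_len(cut)], regs[seq(cut + 1L, nReg)])
  } else list(regs)
  clauses <- lapply(split, function(rs) {
    lits <- lapply(rs, function(r) {
      v <- bVar(r)
      if (stats::runif(1) < bias) v else bNot(v)
    })
    do.call(bAnd, lits)
  })
  do.call(bOr, clauses)
}

#' Generate a seeded random Boolean network
#'
#' Generates a model with `nNodes` nodes whose rules are random
#' OR-of-ANDs over at most `kRegulators` regulators, with each literal
#' positive with probability `activationBias`. The same seed always yields
#' the same model (RNG algorithm pinned to Mersenne-Twister); the caller's
#' RNG state is left untouched. With `activationBias = 1` the model
#' contains no inhibitory interactions.
#'
#' @param nNodes Number of nodes.
#' @param kRegulators Maximum in-degree per rule (default 2).
#' @param activationBias Probability a literal is positive (default 0.5).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param modelId Model identifier (default `"S"`).
#' @param symbolPrefix Node-name prefix (default `"G"`; nodes are
#'   `G01`, `G02`, ...).
#' @param pInput Probability a node is an external input instead of a
#'   regulated node (default 0).
#' @return A valid [LogicalModel-class].
#' @examples
#' randomModel(5, seed = 1)
#' @export
randomModel <- function(nNodes, kRegulators = 2L, activationBias = 0.5,
                        seed = NULL, modelId = "S", symbolPrefix = "G",
                        pInput = 0) {
  stopifnot(nNodes >= 1L, kRegulators >= 1L, kRegulators <= nNodes,
            activationBias >= 0, activationBias <= 1,
            pInput >= 0, pInput <= 1)
  ids <- sprintf("%s%02d", symbolPrefix, seq_len(nNodes))
  .withSeed(seed, function() {
    rules <- stats::setNames(vector("list", nNodes), ids)
    for (i in seq_len(nNodes)) {
      if (stats::runif(1) < pInput) { rules[[i]] <- NA; next }
      rules[[i]] <- .randomRule(ids, kRegulators, activationBias)
    }
    logicalModel(rules, modelId = modelId)
  })
}

#' Generate a pair of overlapping random models
#'
#' Emulates the typical merge setting: two models of one biological system
#' that complement each other -- each covers nodes the other lacks while
#' sharing a set of key regulators. Exactly `overlap` node symbols (named
#' `GS..`) occur in both models; shared nodes' rules are built over the
#' shared set only, so with `divergence = 0` the two models carry
#' equivalent rules for every shared node. With probability `divergence`, a
#' shared node's rule is independently regenerated in the second model
#' (over its own node set); the returned ground truth records which nodes
#' diverged, so merge behaviour can be asserted against construction.
#'
#' @param nA,nB Node counts of the two models (each >= `overlap`).
#' @param overlap Number of shared node symbols.
#' @param kRegulators,activationBias As in [randomModel()].
#' @param divergence Probability a shared node's rule differs between the
#'   models (default 0).
#' @param seed Integer seed.
#' @return List with `a`, `b` (the two [LogicalModel-class] objects),
#'   `shared` (shared symbols), and `diverged` (shared symbols whose rules
#'   were regenerated).
#' @examples
#' p <- overlappingPair(nA = 8, nB = 10, overlap = 4, seed = 1)
#' findOverlap(p$a, p$b)
#' @export
overlappingPair <- function(nA, nB, overlap, kRegulators = 2L,
                            activationBias = 0.5, divergence = 0,
                            seed = NULL) {
  stopifnot(overlap >= 0L, overlap <= nA, overlap <= nB,
            divergence >= 0, divergence <= 1)
  shared <- if (overlap > 0L) sprintf("GS%02d", seq_len(overlap))
            else character(0)
  privA <- if (nA > overlap) sprintf("GA%02d", seq_len(nA - overlap))
           else character(0)
  privB <- if (nB > overlap) sprintf("GB%02d", seq_len(nB - overlap))
           else character(0)
  .withSeed(seed, function() {
    sharedRules <- stats::setNames(
      lapply(shared, function(s) .randomRule(shared, kRegulators,
                                             activationBias)),
      shared)
    mkModel <- function(priv, id, rules0, pool) {
      rules <- rules0
      for (p in priv) rules[[p]] <- .randomRule(pool, kRegulators,
                                                activationBias)
      logicalModel(rules[order(names(rules))], modelId = id)
    }
    a <- mkModel(privA, "A", sharedRules, c(shared, privA))
    diverged <- character(0)
    rulesB <- sharedRules
    for (s in shared) {
      if (stats::runif(1) < divergence) {
        repeat {
          cand <- .randomRule(shared, kRegulators, activationBias)
          if (!exprsEquivalent(cand, sharedRules[[s]])) break
        }
        rulesB[[s]] <- cand
        diverged <- c(diverged, s)
      }
    }
    b <- mkModel(privB, "B", rulesB, c(shared, privB))
    list(a = a, b = b, shared = shared, diverged = diverged)
  })
}

#' Write synthetic fixtures with a ground-truth sidecar
#'
#' Writes the two models of an [overlappingPair()] in the requested format
#' plus a JSON sidecar recording the generator's ground truth (shared
#' symbols, diverged nodes, RNG pin), so downstream analyses can be checked
#' against construction.
#'
#' @param pair Result of [overlappingPair()].
#' @param dir Output directory (created if needed).
#' @param format `"bnet"` or `"sbml"`.
#' @return Invisibly, the paths written.
#' @export
writeSynthFixtures <- function(pair, dir, format = c("bnet", "sbml")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "bnet") ".bnet" else ".sbml"
  pa <- file.path(dir, paste0("modelA", ext))
  pb <- file.path(dir, paste0("modelB", ext))
  writeModel(pair$a, pa, format = format)
  writeModel(pair$b, pb, format = format)
  pg <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(shared = pair$shared, diverged = pair$diverged,
         rng = list(kind = "Mersenne-Twister", normal.kind = "Inversion",
                    sample.kind = "Rejection")),
    pg, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(pa, pb, pg))
}
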