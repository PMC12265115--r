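## Rule composition: merging n harmonized logical models into one.
##
## For a node shared by several models with rules f^{M_1}, ..., f^{M_n}:
##   OR  :  f = f^{M_1} | ... | f^{M_n}          (any model activating wins)
##   AND :  f = f^{M_1} & ... & f^{M_n}          (all models must agree)
##   IW  :  f = !(i_1 | ... | i_k) & f^OR        (Inhibitor Wins)
## where i_1..i_k are the regulators that act as inhibitors of the node in
## any source rule. Under IW an active inhibitor forces the node off,
## overriding every activator -- mirroring repressors that dominate
## transcriptional activation, e.g. in oncogene suppression.

#' MergeConfig: strategy selection for model merging
#'
#' Holds the default rule-composition strategy, per-node overrides (the
#' customization function: e.g. Inhibitor Wins for tumour-suppressor genes,
#' OR elsewhere), and how inhibitors are detected for Inhibitor Wins --
#' `semantic` (exhaustive flip test, the default) or `syntactic`
#' (odd-negation-depth fallback for large supports).
#'
#' @slot defaultStrategy `"OR"`, `"AND"`, or `"IW"`.
#' @slot perNode Named character vector: node symbol -> strategy override.
#' @slot inhibitorDetection `"semantic"` or `"syntactic"`.
#' @export
setClass("MergeConfig",
  representation(defaultStrategy = "character", perNode = "character",
                 inhibitorDetection = "character"),
  prototype(defaultStrategy = "OR", perNode = character(0),
            inhibitorDetection = "semantic"))

setValidity("MergeConfig", function(object) {
  msgs <- character(0)
  if (!object@defaultStrategy %in% c("OR", "AND", "IW"))
    msgs <- c(msgs, "defaultStrategy must be one of OR, AND, IW")
  if (length(object@perNode) > 0L &&
      (is.null(names(object@perNode)) || any(!nzchar(names(object@perNode)))))
    msgs <- c(msgs, "perNode must be a fully named character vector")
  if (!all(object@perNode %in% c("OR", "AND", "IW")))
    msgs <- c(msgs, "perNode strategies must be one of OR, AND, IW")
  if (!object@inhibitorDetection %in% c("semantic", "syntactic"))
    msgs <- c(msgs, "inhibitorDetection must be 'semantic' or 'syntactic'")
  if (length(msgs) == 0L) TRUE else msgs
})

setMethod("show", "MergeConfig", function(object) {
  cat("MergeConfig: default ", object@defaultStrategy,
      ", inhibitor detection ", object@inhibitorDetection, "\n", sep = "")
  if (length(object@perNode) > 0L)
    cat("  overrides: ",
        paste(names(object@perNode), object@perNode, sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(object)
})

#' @rdname MergeConfig-class
#' @param default Default strategy, one of `"OR"`, `"AND"`, `"IW"`
#'   (case-insensitive).
#' @param perNode Named character vector or list of per-node overrides.
#' @param inhibitorDetection `"semantic"` or `"syntactic"`.
#' @return A `MergeConfig`.
#' @examples
#' mergeConfig("OR", perNode = c(TP53 = "IW"))
#' @export
mergeConfig <- function(default = "OR", perNode = character(0),
                        inhibitorDetection = c("semantic", "syntactic")) {
  perNode <- vapply(perNode, function(s) toupper(as.character(s)), "")
  methods::new("MergeConfig", defaultStrategy = toupper(default),
               perNode = perNode,
               inhibitorDetection = match.arg(inhibitorDetection))
}

#' @rdname MergeConfig-class
#' @param path Path to a JSON configuration, e.g.
#'   `{"default": "OR", "per_node": {"TP53": "IW"},
#'   "inhibitor_detection": "semantic"}`.
#' @export
readMergeConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mergeConfig(default = if (is.null(cfg$default)) "OR" else cfg$default,
              perNode = if (is.null(cfg$per_node)) character(0)
                        else unlist(cfg$per_node),
              inhibitorDetection = if (is.null(cfg$inhibitor_detection))
                "semantic" else cfg$inhibitor_detection)
}

#' Combine rules of one node across models
#'
#' The three deterministic rule combinators applied to the list of source
#' rules of a single shared node. `combineOR` returns the disjunction
#' (pointwise maximum over states), `combineAND` the conjunction (pointwise
#' minimum), and `combineIW` the Inhibitor Wins composition: the node is
#' forced off whenever any regulator that inhibits it in any source rule is
#' active, and otherwise follows the OR combination. With no inhibitors,
#' `combineIW` reduces to `combineOR`. For any state, AND <= IW <= OR.
#'
#' @param rules List of `BoolExpr` rules (length >= 1).
#' @return A `BoolExpr`.
#' @examples
#' r <- lapply(c("A", "!B"), parseRule)
#' ruleToString(combineOR(r))
#' ruleToString(combineIW(r))   # B inhibits: !B & (A | !B), i.e. !B
#' @export
combineOR <- function(rules) {
  stopifnot(length(rules) >= 1L)
  do.call(bOr, rules)
}

#' @rdname combineOR
#' @export
combineAND <- function(rules) {
  stopifnot(length(rules) >= 1L)
  do.call(bAnd, rules)
}

#' @rdname combineOR
#' @param detection Inhibitor detection mode, `"semantic"` or
#'   `"syntactic"`; see [inferSigns()].
#' @param cap Support cap for semantic sign inference.
#' @return `combineIW` returns the combined `BoolExpr` with attribute
#'   `"inhibitors"` listing the pooled inhibitor set.
#' @export
combineIW <- function(rules, detection = c("semantic", "syntactic"),
                      cap = 16L) {
  detection <- match.arg(detection)
  stopifnot(length(rules) >= 1L)
  inh <- character(0)
  for (r in rules) {
    s <- inferSigns(r, "node", cap = cap, method = detection)
    dual <- s$regulator[s$sign == "dual"]
    if (length(dual) > 0L)
      warning("dual-signed regulator(s) treated as inhibitors under ",
              "Inhibitor Wins: ", paste(dual, collapse = ", "))
    inh <- c(inh, s$regulator[s$sign %in% c("inhibitor", "dual")])
  }
  inh <- sort(unique(inh))
  orPart <- combineOR(rules)
  out <- if (length(inh) == 0L) orPart
         else bAnd(bNot(do.call(bOr, lapply(inh, bVar))), orPart)
  attr(out, "inhibitors") <- inh
  out
}

#' Merge logical models into one executable model
#'
#' Composes two or more harmonized models. The merged node set is the union
#' of all node sets; a node present in one model keeps its rule unchanged; a
#' node regulated in several models gets the configured combination of its
#' source rules ([combineOR()], [combineAND()], [combineIW()]). A node that
#' is an external input in some models but regulated in at least one takes
#' the combination of the regulated rules only: absence of a rule is treated
#' as absence of knowledge, not as a constant, and the merge report logs the
#' resolution. Merging generalises to any number of models; strategies are
#' associative and commutative up to logical equivalence.
#'
#' @param models List of >= 2 valid, harmonized `LogicalModel` objects.
#' @param config A [MergeConfig-class] (default: OR everywhere, semantic
#'   inhibitor detection). Per-node override keys must name a node present
#'   in at least one input model.
#' @param modelId Identifier of the merged model (default `"M"`).
#' @param cap Support cap for semantic sign inference under Inhibitor Wins.
#' @return List with `model` (the merged [LogicalModel-class]) and `report`
#'   (data.frame: `node`, `sources`, `strategy`, `inhibitors_used`,
#'   `input_conflict`).
#' @examples
#' a <- logicalModel(c(GATA1 = "INPUT", TAL1 = "GATA1"), modelId = "A")
#' b <- logicalModel(c(TAL1 = "!KLF1", KLF1 = "TAL1"), modelId = "B")
#' mergeModels(list(a, b), mergeConfig("IW"))$model
#' @export
mergeModels <- function(models, config = mergeConfig(), modelId = "M",
                        cap = 16L) {
  stopifnot(is.list(models), length(models) >= 2L)
  for (m in models) {
    stopifnot(methods::is(m, "LogicalModel"))
    d <- validateModel(m)
    if (length(d) > 0L)
      stop("invalid input model '", m@modelId, "': ", d[[1L]])
  }
  methods::validObject(config)
  allNodes <- unique(unlist(lapply(models, nodeIds)))
  unknown <- setdiff(names(config@perNode), allNodes)
  if (length(unknown) > 0L)
    stop("per-node strategy override(s) for node(s) absent from every ",
         "input model: ", paste(unknown, collapse = ", "))

  rules <- stats::setNames(vector("list", length(allNodes)), allNodes)
  rep_rows <- vector("list", length(allNodes))
  for (i in seq_along(allNodes)) {
    node <- allNodes[[i]]
    has <- vapply(models, function(m) node %in% m@nodeIds, logical(1))
    srcRules <- list(); srcIds <- character(0); nInput <- 0L
    for (m in models[has]) {
      r <- m@rules[[node]]
      if (is.null(r)) nInput <- nInput + 1L
      else { srcRules[[length(srcRules) + 1L]] <- r
             srcIds <- c(srcIds, m@modelId) }
    }
    inputConflict <- nInput > 0L && length(srcRules) > 0L
    strategy <- if (!is.na(config@perNode[node]))
      unname(config@perNode[node]) else config@defaultStrategy
    inhUsed <- character(0)
    if (length(srcRules) == 0L) {
      combined <- NULL
      applied <- "input"
    } else if (length(srcRules) == 1L) {
      combined <- srcRules[[1L]]
      applied <- "single"
    } else {
      combined <- switch(strategy,
        OR = combineOR(srcRules),
        AND = combineAND(srcRules),
        IW = {
          e <- combineIW(srcRules, detection = config@inhibitorDetection,
                         cap = cap)
          inhUsed <- attr(e, "inhibitors")
          attr(e, "inhibitors") <- NULL
          e
        })
      applied <- strategy
    }
    rules[[node]] <- if (is.null(combined)) NA else combined
    rep_rows[[i]] <- data.frame(
      node = node,
      sources = paste(vapply(models[has], function(m) m@modelId, ""),
                      collapse = ","),
      strategy = applied,
      inhibitors_used = paste(inhUsed, collapse = ","),
      input_conflict = inputConflict,
      stringsAsFactors = FALSE)
  }
  merged <- logicalModel(rules, modelId = modelId,
                         species = models[[1L]]@species)
  ann <- list()
  for (m in models) ann[names(m@annotations)] <- m@annotations
  merged@annotations <- ann
  list(model = merged, report = do.call(rbind, rep_rows))
}
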