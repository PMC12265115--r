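## The LogicalModel container: nodes, rules, annotations, provenance.

setOldClass("BoolExpr")

#' LogicalModel: a Boolean gene-regulatory-network model
#'
#' An S4 container for a logical model: a named node set where each node
#' carries either a Boolean update rule over other nodes or the marker
#' `INPUT` (an external input that holds its value during simulation unless
#' clamped), plus display symbols, per-node annotations (e.g. HGNC ids as
#' namespace-tagged identifiers), edge-evidence notes, and publication
#' provenance.
#'
#' @slot modelId Single string identifying the model (used to prefix
#'   attractor labels, e.g. `"M"` gives `"M1"`, `"M2"`, ...).
#' @slot species Species the model describes (free text, e.g. `"Homo
#'   sapiens"`).
#' @slot source Named list of publication metadata (title, doi, year, ...).
#' @slot nodeIds Character vector of unique node identifiers, in model
#'   order.
#' @slot symbols Named character vector: display (gene) symbol per node.
#' @slot rules Named list: a `BoolExpr` per regulated node, `NULL` for
#'   inputs.
#' @slot annotations Named list of named character vectors
#'   (namespace -> identifier) per node.
#' @slot evidence Named list of free-text evidence notes per node.
#' @seealso [logicalModel()] to construct one; [validateModel()] for
#'   diagnostics; [interactionGraph()] for the signed regulatory graph.
#' @export
setClass("LogicalModel",
  representation(
    modelId = "character",
    species = "character",
    source = "list",
    nodeIds = "character",
    symbols = "character",
    rules = "list",
    annotations = "list",
    evidence = "list"
  ),
  prototype(
    modelId = "M", species = NA_character_, source = list(),
    nodeIds = character(0), symbols = character(0), rules = list(),
    annotations = list(), evidence = list()
  )
)

setValidity("LogicalModel", function(object) {
  msgs <- character(0)
  n <- length(object@nodeIds)
  if (length(object@modelId) != 1L || is.na(object@modelId) ||
      !nzchar(object@modelId))
    msgs <- c(msgs, "modelId must be a single nonempty string")
  if (n == 0L) msgs <- c(msgs, "model must have at least one node")
  if (anyDuplicated(object@nodeIds))
    msgs <- c(msgs, paste0("duplicate node ids: ",
      paste(unique(object@nodeIds[duplicated(object@nodeIds)]), collapse = ", ")))
  if (!all(grepl("^[A-Za-z0-9_]+$", object@nodeIds)))
    msgs <- c(msgs, "node ids must match [A-Za-z0-9_]+")
  if (!identical(names(object@rules), object@nodeIds))
    msgs <- c(msgs, "rules must be named exactly by nodeIds, in order")
  if (!identical(names(object@symbols), object@nodeIds))
    msgs <- c(msgs, "symbols must be named exactly by nodeIds, in order")
  if (length(msgs) == 0L) {
    for (id in object@nodeIds) {
      r <- object@rules[[id]]
      if (is.null(r)) next
      if (!inherits(r, "BoolExpr")) {
        msgs <- c(msgs, paste0("rule of '", id, "' is not a BoolExpr"))
        next
      }
      missing <- setdiff(.syntacticVars(r), object@nodeIds)
      if (length(missing) > 0L)
        msgs <- c(msgs, paste0("rule of '", id,
          "' references absent node(s): ", paste(missing, collapse = ", ")))
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' Construct a LogicalModel from rule text
#'
#' Builds a [LogicalModel-class] from a named character vector (or named
#' list) of rules. The special value `"INPUT"` (or `NA`) marks an external
#' input node; any other value is parsed with [parseRule()]. Node order is
#' taken from the argument order.
#'
#' @param rules Named character vector or named list mapping node id to rule
#'   text, `"INPUT"`, `NA`, or a ready-made `BoolExpr`.
#' @param modelId Model identifier (default `"M"`).
#' @param species Optional species string.
#' @param source Optional named list of publication metadata.
#' @param symbols Optional named character vector of display symbols
#'   (defaults to the node ids).
#' @param annotations,evidence Optional named lists of per-node metadata.
#' @return A validated `LogicalModel`.
#' @examples
#' m <- logicalModel(c(A = "INPUT", B = "A & !C", C = "B"), modelId = "toy")
#' m
#' @export
logicalModel <- function(rules, modelId = "M", species = NA_character_,
                         source = list(), symbols = NULL,
                         annotations = list(), evidence = list()) {
  ids <- names(rules)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("rules must be a fully named vector or list")
  parsed <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    r <- if (is.list(rules)) rules[[i]] else rules[[i]]
    if (is.null(r) || (length(r) == 1L && is.na(r))) next
    if (inherits(r, "BoolExpr")) { parsed[[i]] <- r; next }
    if (identical(toupper(as.character(r)), "INPUT")) next
    parsed[[i]] <- parseRule(as.character(r))
  }
  if (is.null(symbols)) symbols <- stats::setNames(ids, ids)
  else {
    symbols <- symbols[ids]
    symbols[is.na(symbols)] <- ids[is.na(symbols)]
    names(symbols) <- ids
  }
  methods::new("LogicalModel", modelId = modelId, species = species,
               source = source, nodeIds = ids, symbols = symbols,
               rules = parsed, annotations = annotations,
               evidence = evidence)
}

#' @describeIn logicalModel Node identifiers, in model order.
#' @param model A `LogicalModel`.
#' @export
nodeIds <- function(model) model@nodeIds

#' @describeIn logicalModel Display symbols, named by node id.
#' @export
nodeSymbols <- function(model) model@symbols

#' @describeIn logicalModel The rule (`BoolExpr`) of a node, or `NULL` for
#'   an input.
#' @param node Node identifier.
#' @export
nodeRule <- function(model, node) {
  if (!node %in% model@nodeIds) stop("no node '", node, "' in model")
  model@rules[[node]]
}

#' @describeIn logicalModel Ids of external input nodes (those without a
#'   rule).
#' @export
inputNodes <- function(model) {
  model@nodeIds[vapply(model@rules, is.null, logical(1))]
}

#' @describeIn logicalModel Model identifier.
#' @export
modelId <- function(model) model@modelId

setMethod("show", "LogicalModel", function(object) {
  n <- length(object@nodeIds)
  nIn <- length(inputNodes(object))
  cat("LogicalModel '", object@modelId, "': ", n, " nodes (", nIn,
      " inputs)\n", sep = "")
  if (!is.na(object@species)) cat("  species: ", object@species, "\n", sep = "")
  shown <- utils::head(object@nodeIds, 8L)
  for (id in shown) {
    r <- object@rules[[id]]
    cat("  ", format(id, width = max(nchar(shown))), " <- ",
        if (is.null(r)) "INPUT" else ruleToString(r), "\n", sep = "")
  }
  if (n > 8L) cat("  ... and ", n - 8L, " more nodes\n", sep = "")
  invisible(object)
})

#' Validate a logical model
#'
#' Checks model invariants -- nonempty node set, unique identifiers, legal
#' identifier tokens, and no rule referencing an absent node -- and returns
#' diagnostics instead of raising, so a pipeline can collect all problems at
#' once. An empty character vector means the model is well formed.
#'
#' @param model A `LogicalModel` (possibly constructed unchecked).
#' @return Character vector of diagnostic messages, each naming the
#'   offending node; `character(0)` if valid.
#' @export
validateModel <- function(model) {
  v <- methods::validObject(model, test = TRUE)
  if (isTRUE(v)) character(0) else v
}

#' Signed interaction graph of a model
#'
#' Derives the regulator-to-target edge list with signs from the rules, by
#' exhaustive flip testing per rule ([inferSigns()]). Regulators with no
#' semantic effect (sign `none`) are dropped. Rows are ordered by target,
#' then regulator.
#'
#' @param model A valid `LogicalModel`.
#' @param cap,method Passed to [inferSigns()].
#' @return data.frame with columns `regulator`, `target`, `sign`.
#' @examples
#' m <- logicalModel(c(A = "INPUT", B = "!A"))
#' interactionGraph(m)
#' @export
interactionGraph <- function(model, cap = 16L,
                             method = c("semantic", "syntactic")) {
  method <- match.arg(method)
  rows <- lapply(model@nodeIds, function(id) {
    r <- model@rules[[id]]
    if (is.null(r)) return(NULL)
    s <- inferSigns(r, id, cap = cap, method = method)
    s[s$sign != "none", , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(regulator = character(0), target = character(0),
                      sign = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$target, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Internal: rebuild a model with renamed nodes (map old id -> new id).
.renameModel <- function(model, map) {
  newIds <- ifelse(model@nodeIds %in% names(map),
                   unname(map[model@nodeIds]), model@nodeIds)
  rules <- lapply(model@rules, function(r)
    if (is.null(r)) NULL else .renameVars(r, map))
  names(rules) <- newIds
  symbols <- stats::setNames(newIds, newIds)
  ann <- model@annotations
  if (length(ann) > 0L)
    names(ann) <- ifelse(names(ann) %in% names(map),
                         unname(map[names(ann)]), names(ann))
  ev <- model@evidence
  if (length(ev) > 0L)
    names(ev) <- ifelse(names(ev) %in% names(map),
                        unname(map[names(ev)]), names(ev))
  methods::new("LogicalModel", modelId = model@modelId,
               species = model@species, source = model@source,
               nodeIds = newIds, symbols = symbols, rules = rules,
               annotations = ann, evidence = ev)
}
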