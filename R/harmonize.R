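## Gene-symbol harmonization: offline mapping tables are the source of
## truth. Node symbols (aliases, previous symbols, mouse orthologs) are
## renamed to approved human gene symbols before models are compared or
## merged; identifier matching across models happens only after this step.

#' Read a symbol mapping table
#'
#' Reads a TSV with header `alias<TAB>approved<TAB>hgnc_id<TAB>source`
#' mapping model node symbols (aliases, previous symbols, orthologs, manual
#' curation results) to approved gene symbols. Alias values must be unique
#' and approved symbols nonempty; `source` is one of `alias`, `previous`,
#' `ortholog`, `manual`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `alias`, `approved`, `hgnc_id`, `source`.
#' @export
readMappingTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("alias", "approved")
  if (!all(need %in% names(tab)))
    stop("mapping table must have columns 'alias' and 'approved'")
  if (!"hgnc_id" %in% names(tab)) tab$hgnc_id <- NA_character_
  if (!"source" %in% names(tab)) tab$source <- "manual"
  .checkMappingTable(tab)
  tab[, c("alias", "approved", "hgnc_id", "source")]
}

.checkMappingTable <- function(tab) {
  if (anyDuplicated(tab$alias))
    stop("mapping table aliases must be unique; duplicated: ",
         paste(unique(tab$alias[duplicated(tab$alias)]), collapse = ", "))
  if (any(is.na(tab$approved) | !nzchar(tab$approved)))
    stop("mapping table approved symbols must be nonempty")
  invisible(tab)
}

#' Apply a symbol mapping to a model
#'
#' Renames every node whose symbol matches an alias in the table to the
#' approved symbol, rewriting all rules consistently. Two distinct nodes
#' mapping (or one mapping onto another already-approved node) to the same
#' symbol is a collision and raises an error -- renaming never merges nodes
#' silently; resolve such cases by manual curation of the table. The
#' returned report classifies every node as `mapped`, `exact` (already an
#' approved symbol in the table), or `unmapped` (e.g. fusion proteins and
#' complexes without standard nomenclature, which pass through unchanged).
#' Applying the same table twice is a no-op the second time.
#'
#' @param model A valid `LogicalModel`.
#' @param table Mapping data.frame as returned by [readMappingTable()].
#' @return A list with elements `model` (the renamed `LogicalModel`) and
#'   `report` (data.frame: `node`, `new_symbol`, `status`, `source`).
#' @examples
#' m <- logicalModel(c(Gata1 = "INPUT", Tal1 = "Gata1"))
#' tab <- data.frame(alias = c("Gata1", "Tal1"),
#'                   approved = c("GATA1", "TAL1"),
#'                   hgnc_id = NA, source = "ortholog")
#' applyMapping(m, tab)$model
#' @export
applyMapping <- function(model, table) {
  stopifnot(length(validateModel(model)) == 0L)
  .checkMappingTable(table)
  syms <- model@symbols
  hit <- match(unname(syms), table$alias)
  newSym <- ifelse(is.na(hit), unname(syms), table$approved[hit])
  status <- ifelse(!is.na(hit),
                   ifelse(table$approved[hit] == unname(syms), "exact", "mapped"),
                   ifelse(unname(syms) %in% table$approved, "exact", "unmapped"))
  if (anyDuplicated(newSym)) {
    dup <- unique(newSym[duplicated(newSym)])
    clash <- model@nodeIds[newSym %in% dup]
    stop("mapping collision: nodes ", paste(clash, collapse = ", "),
         " would map to the same approved symbol(s) ",
         paste(dup, collapse = ", "), "; resolve by manual curation")
  }
  report <- data.frame(node = model@nodeIds, new_symbol = newSym,
                       status = status,
                       source = ifelse(is.na(hit), NA_character_,
                                       table$source[hit]),
                       stringsAsFactors = FALSE)
  changed <- newSym != model@nodeIds
  if (any(changed)) {
    map <- stats::setNames(newSym[changed], model@nodeIds[changed])
    model <- .renameModel(model, map)
  }
  list(model = model, report = report)
}

#' Shared nodes of two harmonized models
#'
#' Exact intersection of the display-symbol sets. Meaningful only after both
#' models have been harmonized to the same nomenclature with
#' [applyMapping()].
#'
#' @param a,b `LogicalModel` objects.
#' @return Sorted character vector of shared symbols.
#' @export
findOverlap <- function(a, b) {
  sort(intersect(unname(a@symbols), unname(b@symbols)))
}

#' Translate a signed interaction graph to a logical model
#'
#' Instantiates the Inhibitor Wins template on a signed edge list, the
#' standard recipe for turning pathway-database interaction graphs into an
#' executable Boolean model: each target's rule is
#' `(OR of activators) & !(OR of inhibitors)`, targets with only inhibitors
#' get `!(OR of inhibitors)`, and nodes that are never a target become
#' external inputs. Inhibition therefore dominates activation at every
#' node. Dual-signed edges cannot be expressed by this template and raise
#' an error.
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`
#'   (`activator`/`inhibitor`), as produced by [interactionGraph()].
#' @param modelId Identifier for the resulting model.
#' @return A [LogicalModel-class].
#' @examples
#' g <- data.frame(regulator = c("A", "B"), target = c("C", "C"),
#'                 sign = c("activator", "inhibitor"))
#' nodeRule(graphToRules(g), "C")
#' @export
graphToRules <- function(edges, modelId = "G") {
  stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
  if (any(edges$sign == "dual"))
    stop("dual-signed edge(s) cannot be expressed by the ",
         "activator/inhibitor template: ",
         paste(unique(edges$regulator[edges$sign == "dual"]), collapse = ", "))
  if (!all(edges$sign %in% c("activator", "inhibitor")))
    stop("edge signs must be 'activator' or 'inhibitor'")
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  rules <- stats::setNames(as.list(rep(NA, length(nodes))), nodes)
  for (tgt in unique(edges$target)) {
    e <- edges[edges$target == tgt, , drop = FALSE]
    act <- sort(unique(e$regulator[e$sign == "activator"]))
    inh <- sort(unique(e$regulator[e$sign == "inhibitor"]))
    actPart <- if (length(act) > 0L) do.call(bOr, lapply(act, bVar)) else NULL
    inhPart <- if (length(inh) > 0L)
      bNot(do.call(bOr, lapply(inh, bVar))) else NULL
    rules[[tgt]] <- if (is.null(inhPart)) actPart
                    else if (is.null(actPart)) inhPart
                    else bAnd(actPart, inhPart)
  }
  logicalModel(rules, modelId = modelId)
}
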