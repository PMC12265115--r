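## Model import/export: bnet-style plain text and SBML-qual (Level 3, qual
## package, Boolean maxLevel = 1 only).

#' Read and write bnet-style rule files
#'
#' The bnet format is one line per node, `target, factors`, where `factors`
#' is a rule in the grammar of [parseRule()]. A header line
#' `targets, factors` and `#` comment lines are tolerated. Because the
#' format has no input keyword, the self-identity line `A, A` marks `A` as
#' an external input; this convention is applied on read and emitted on
#' write.
#'
#' @param path File path.
#' @param modelId Model identifier for the resulting model (default: file
#'   name without extension).
#' @return `readBNet`: a [LogicalModel-class]. `writeBNet`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".bnet")
#' writeBNet(logicalModel(c(A = "INPUT", B = "A & !C", C = "B")), f)
#' readBNet(f)
#' @export
readBNet <- function(path, modelId = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(modelId)) modelId <- sub("\\.[^.]*$", "", basename(path))
  rules <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^targets\\s*,\\s*factors\\s*$", ln, ignore.case = TRUE)) next
    m <- regexpr(",", ln, fixed = TRUE)
    if (m < 0L)
      stop("bnet syntax error at line ", i, ": expected 'target, factors'")
    target <- trimws(substr(ln, 1L, m - 1L))
    factors <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z0-9_]+$", target))
      stop("bnet syntax error at line ", i, ": bad target '", target, "'")
    if (target %in% names(rules))
      stop("bnet syntax error at line ", i, ": duplicate target '", target, "'")
    rules[[target]] <- if (identical(factors, target)) "INPUT" else factors
  }
  if (length(rules) == 0L) stop("bnet file has no rules: ", path)
  logicalModel(rules, modelId = modelId)
}

#' @rdname readBNet
#' @param model A valid `LogicalModel`.
#' @export
writeBNet <- function(model, path) {
  stopifnot(length(validateModel(model)) == 0L)
  lines <- c("targets, factors",
             vapply(model@nodeIds, function(id) {
               r <- model@rules[[id]]
               paste0(id, ", ", if (is.null(r)) id else ruleToString(r))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

## ---- SBML-qual --------------------------------------------------------

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
.RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

## Attribute lookup tolerant of the qual: prefix.
.qattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- names(at) == name | endsWith(names(at), paste0(":", name))
  if (!any(hit)) return(NA_character_)
  unname(at[hit][[1L]])
}

.localFind <- function(x, localName) {
  xml2::xml_find_all(x, sprintf(".//*[local-name()='%s']", localName))
}

## MathML -> BoolExpr. Accepts and/or/not applies, eq tests `ci = cn`
## (cn 1 -> variable, cn 0 -> negated variable), bare ci, and cn constants.
.mathToExpr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("SBML-qual parse error: math must have one child")
    return(.mathToExpr(kids[[1L]]))
  }
  if (name == "ci") return(bVar(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    v <- as.integer(trimws(xml2::xml_text(node)))
    return(bConst(v))
  }
  if (name == "true") return(bConst(1L))
  if (name == "false") return(bConst(0L))
  if (name != "apply")
    stop("SBML-qual parse error: unsupported MathML element <", name, ">")
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- kids[-1L]
  switch(op,
    and = do.call(bAnd, lapply(args, .mathToExpr)),
    or  = do.call(bOr, lapply(args, .mathToExpr)),
    not = bNot(.mathToExpr(args[[1L]])),
    eq  = {
      if (length(args) != 2L)
        stop("SBML-qual parse error: eq needs two operands")
      ci <- args[[which(xml2::xml_name(args) == "ci")]]
      cn <- args[[which(xml2::xml_name(args) == "cn")]]
      lvl <- as.integer(trimws(xml2::xml_text(cn)))
      if (!lvl %in% c(0L, 1L))
        stop("SBML-qual parse error: only Boolean levels 0/1 supported, got ",
             lvl)
      v <- bVar(trimws(xml2::xml_text(ci)))
      if (lvl == 1L) v else bNot(v)
    },
    stop("SBML-qual parse error: unsupported MathML operator <", op, ">"))
}

## Extract identifiers.org-style CV terms from a species annotation block.
.readAnnotations <- function(speciesNode) {
  lis <- .localFind(speciesNode, "li")
  if (length(lis) == 0L) return(NULL)
  res <- character(0)
  for (li in lis) {
    url <- .qattr(li, "resource")
    if (is.na(url)) next
    m <- regmatches(url, regexec("identifiers\\.org/([^/]+)/(.+)$", url))[[1L]]
    if (length(m) == 3L) res[[m[[2L]]]] <- m[[3L]]
  }
  if (length(res) == 0L) NULL else res
}

#' Read and write SBML-qual logical models
#'
#' Reads SBML Level 3 documents using the qualitative-models (`qual`)
#' package into a [LogicalModel-class]: one node per qualitative species,
#' with each transition's level-1 function term translated from MathML
#' (`and`/`or`/`not` over `species = 1` equality tests) into a Boolean rule.
#' Species without a transition become external inputs. Species CV-term
#' annotations pointing at identifiers.org are carried into the node
#' annotations. Only Boolean models are in scope: a species with
#' `maxLevel > 1` raises an error naming the species, never a silent
#' binarisation -- multi-valued models must be booleanised upstream.
#'
#' `writeSBMLQual` emits Level 3 Version 1 with qual version 1, species in
#' lexicographic order, one transition per regulated node with a level-0
#' default term and a level-1 function term, and `bqbiol:is` CV terms for
#' node annotations.
#'
#' @param path File path.
#' @param modelId Model identifier (default: the document's model id, or
#'   file name).
#' @return `readSBMLQual`: a [LogicalModel-class]. `writeSBMLQual`: `path`,
#'   invisibly.
#' @export
readSBMLQual <- function(path, modelId = NULL) {
  doc <- xml2::read_xml(path)
  modelNode <- .localFind(doc, "model")
  if (length(modelNode) == 0L) stop("SBML parse error: no <model> element")
  if (is.null(modelId)) {
    modelId <- .qattr(modelNode[[1L]], "id")
    if (is.na(modelId)) modelId <- sub("\\.[^.]*$", "", basename(path))
  }
  spNodes <- .localFind(doc, "qualitativeSpecies")
  if (length(spNodes) == 0L)
    stop("SBML-qual parse error: no qualitative species found")
  ids <- vapply(spNodes, .qattr, "", name = "id")
  maxLevels <- vapply(spNodes, .qattr, "", name = "maxLevel")
  bad <- !is.na(maxLevels) & suppressWarnings(as.integer(maxLevels)) > 1L
  if (any(bad))
    stop("unsupported construct: species ", paste(ids[bad], collapse = ", "),
         " have maxLevel > 1; only Boolean models are supported ",
         "(booleanise the model first)")
  anns <- stats::setNames(lapply(spNodes, .readAnnotations), ids)
  anns <- anns[!vapply(anns, is.null, logical(1))]
  names <- vapply(spNodes, .qattr, "", name = "name")
  symbols <- ifelse(is.na(names) | !nzchar(names), ids, names)

  rules <- stats::setNames(as.list(rep(NA, length(ids))), ids)
  for (tr in .localFind(doc, "transition")) {
    outs <- .localFind(tr, "output")
    if (length(outs) != 1L)
      stop("SBML-qual parse error: each transition needs exactly one output")
    target <- .qattr(outs[[1L]], "qualitativeSpecies")
    if (!target %in% ids)
      stop("SBML-qual parse error: transition output '", target,
           "' is not a declared species")
    if (!is.null(rules[[target]]) && inherits(rules[[target]], "BoolExpr"))
      stop("SBML-qual parse error: species '", target,
           "' is the output of more than one transition")
    fts <- .localFind(tr, "functionTerm")
    dts <- .localFind(tr, "defaultTerm")
    if (length(fts) != 1L || length(dts) != 1L)
      stop("SBML-qual parse error: transition for '", target,
           "' must have one functionTerm and one defaultTerm")
    lvl <- as.integer(.qattr(fts[[1L]], "resultLevel"))
    mathNode <- .localFind(fts[[1L]], "math")
    if (length(mathNode) == 0L)
      stop("SBML-qual parse error: functionTerm for '", target,
           "' has no math")
    e <- .mathToExpr(mathNode[[1L]])
    rules[[target]] <- if (lvl == 1L) e else bNot(e)
  }
  rules <- lapply(rules, function(r) if (inherits(r, "BoolExpr")) r else NA)
  logicalModel(rules, modelId = modelId,
               symbols = stats::setNames(symbols, ids), annotations = anns)
}

.exprToMathXML <- function(expr) {
  rec <- function(e) {
    switch(e$op,
      var   = sprintf("<apply><eq/><ci> %s </ci><cn type=\"integer\"> 1 </cn></apply>",
                      e$name),
      const = if (e$value == 1L) "<true/>" else "<false/>",
      not   = paste0("<apply><not/>", rec(e$child), "</apply>"),
      and   = paste0("<apply><and/>",
                     paste(vapply(e$children, rec, ""), collapse = ""),
                     "</apply>"),
      or    = paste0("<apply><or/>",
                     paste(vapply(e$children, rec, ""), collapse = ""),
                     "</apply>"))
  }
  rec(expr)
}

.annotationXML <- function(id, ann) {
  if (is.null(ann) || length(ann) == 0L) return("")
  lis <- paste(sprintf("<rdf:li rdf:resource=\"https://identifiers.org/%s/%s\"/>",
                       names(ann), unname(ann)), collapse = "")
  paste0(
    "<annotation><rdf:RDF xmlns:rdf=\"", .RDF_NS,
    "\" xmlns:bqbiol=\"", .BQBIOL_NS, "\">",
    "<rdf:Description rdf:about=\"#", id, "\">",
    "<bqbiol:is><rdf:Bag>", lis, "</rdf:Bag></bqbiol:is>",
    "</rdf:Description></rdf:RDF></annotation>")
}

#' @rdname readSBMLQual
#' @param model A valid `LogicalModel`.
#' @export
writeSBMLQual <- function(model, path) {
  stopifnot(length(validateModel(model)) == 0L)
  ids <- sort(model@nodeIds)
  species <- vapply(ids, function(id) {
    ann <- model@annotations[[id]]
    body <- .annotationXML(id, ann)
    sym <- model@symbols[[id]]
    if (nzchar(body))
      sprintf(paste0("<qual:qualitativeSpecies qual:id=\"%s\" qual:name=\"%s\" ",
                     "qual:compartment=\"default\" qual:constant=\"false\" ",
                     "qual:maxLevel=\"1\">%s</qual:qualitativeSpecies>"),
              id, sym, body)
    else
      sprintf(paste0("<qual:qualitativeSpecies qual:id=\"%s\" qual:name=\"%s\" ",
                     "qual:compartment=\"default\" qual:constant=\"false\" ",
                     "qual:maxLevel=\"1\"/>"), id, sym)
  }, "")
  transitions <- character(0)
  for (id in ids) {
    r <- model@rules[[id]]
    if (is.null(r)) next
    regs <- sort(.syntacticVars(r))
    inputs <- if (length(regs) > 0L)
      paste0("<qual:listOfInputs>",
             paste(sprintf(paste0("<qual:input qual:qualitativeSpecies=\"%s\" ",
                                  "qual:transitionEffect=\"none\"/>"), regs),
                   collapse = ""),
             "</qual:listOfInputs>")
    else ""
    transitions <- c(transitions, paste0(
      "<qual:transition qual:id=\"tr_", id, "\">", inputs,
      "<qual:listOfOutputs>",
      "<qual:output qual:qualitativeSpecies=\"", id,
      "\" qual:transitionEffect=\"assignmentLevel\"/>",
      "</qual:listOfOutputs>",
      "<qual:listOfFunctionTerms>",
      "<qual:defaultTerm qual:resultLevel=\"0\"/>",
      "<qual:functionTerm qual:resultLevel=\"1\">",
      "<math xmlns=\"", .MATHML_NS, "\">", .exprToMathXML(r), "</math>",
      "</qual:functionTerm>",
      "</qual:listOfFunctionTerms>",
      "</qual:transition>"))
  }
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"", .SBML_NS, "\" xmlns:qual=\"", .QUAL_NS,
    "\" level=\"3\" version=\"1\" qual:required=\"true\">",
    "<model id=\"", gsub("[^A-Za-z0-9_]", "_", model@modelId), "\">",
    "<listOfCompartments>",
    "<compartment id=\"default\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<qual:listOfQualitativeSpecies>",
    paste(species, collapse = ""),
    "</qual:listOfQualitativeSpecies>",
    if (length(transitions) > 0L)
      paste0("<qual:listOfTransitions>",
             paste(transitions, collapse = ""),
             "</qual:listOfTransitions>")
    else "",
    "</model></sbml>")
  doc <- xml2::read_xml(xml)  # validates well-formedness before writing
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read or write a model, dispatching on file extension
#'
#' `.bnet`/`.txt` are treated as bnet rule files, `.sbml`/`.xml` as
#' SBML-qual. An explicit `format` overrides the extension.
#'
#' @param path File path.
#' @param format `"bnet"`, `"sbml"`, or `NULL` to infer from the extension.
#' @param ... Passed to the underlying reader/writer.
#' @return `readModel`: a [LogicalModel-class]; `writeModel`: `path`,
#'   invisibly.
#' @export
readModel <- function(path, format = NULL, ...) {
  fmt <- .modelFormat(path, format)
  if (fmt == "bnet") readBNet(path, ...) else readSBMLQual(path, ...)
}

#' @rdname readModel
#' @param model A valid `LogicalModel`.
#' @export
writeModel <- function(model, path, format = NULL, ...) {
  fmt <- .modelFormat(path, format)
  if (fmt == "bnet") writeBNet(model, path, ...)
  else writeSBMLQual(model, path, ...)
}

.modelFormat <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("bnet", "sbml")))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("bnet", "txt")) "bnet"
  else if (ext %in% c("sbml", "xml")) "sbml"
  else stop("cannot infer model format from extension '.", ext,
            "'; pass format = \"bnet\" or \"sbml\"")
}
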