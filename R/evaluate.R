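## Model comparison and scoring: attractor-pattern clustering by Hamming
## distance, phenotype network scores, and cohort-level score/outcome
## correlation.

#' Per-gene activation pattern of an attractor
#'
#' The within-attractor mean activation of every node: 0/1 for a fixed
#' point, fractions in [0,1] for a cyclic attractor. Patterns are the
#' objects compared by [hammingDistance()] and [clusterAttractors()].
#'
#' @param a An [Attractor-class].
#' @return Named numeric vector in [0,1].
#' @export
attractorPattern <- function(a) {
  stopifnot(methods::is(a, "Attractor"))
  colMeans(a@states)
}

#' Hamming distance between attractor patterns
#'
#' Mean absolute difference of two per-gene activation patterns over a
#' shared gene set, in [0,1]. Fixed points give the classical Hamming
#' distance (fraction of disagreeing genes); cyclic attractors are compared
#' via their within-attractor mean activation vectors.
#'
#' @param a,b Named numeric patterns in [0,1] (see [attractorPattern()]),
#'   or [Attractor-class] objects.
#' @param genes Genes to compare over; default: the intersection of the two
#'   pattern supports. Must be nonempty and present in both.
#' @return Numeric distance in [0,1].
#' @examples
#' hammingDistance(c(A = 0, B = 1, C = 0, D = 1),
#'                 c(A = 1, B = 0, C = 1, D = 0))   # 1
#' @export
hammingDistance <- function(a, b, genes = NULL) {
  if (methods::is(a, "Attractor")) a <- attractorPattern(a)
  if (methods::is(b, "Attractor")) b <- attractorPattern(b)
  if (is.null(genes)) genes <- intersect(names(a), names(b))
  if (length(genes) == 0L)
    stop("empty shared gene set: patterns have no genes in common")
  if (!all(genes %in% names(a)) || !all(genes %in% names(b)))
    stop("both patterns must be defined on every requested gene")
  mean(abs(a[genes] - b[genes]))
}

#' Cluster attractor patterns by Hamming distance
#'
#' Agglomerative (average-linkage) clustering of attractor activation
#' patterns on their pairwise Hamming distance over the genes shared by all
#' patterns, with flat clusters cut at a distance threshold. Used to check
#' which attractors of a merged model correspond to attractors of the
#' source models.
#'
#' @param patterns Named list of patterns (named numeric vectors in [0,1]),
#'   or a list of [Attractor-class] objects (labels become pattern names),
#'   length >= 2.
#' @param threshold Cut height for flat clusters (default 0.5).
#' @param linkage Agglomeration method; `"average"`.
#' @return List with `clusters` (named integer vector of cluster ids),
#'   `hclust` (the dendrogram), `distances` (the pairwise matrix), and
#'   `genes` (the shared gene set used).
#' @export
clusterAttractors <- function(patterns, threshold = 0.5,
                              linkage = c("average")) {
  linkage <- match.arg(linkage)
  stopifnot(length(patterns) >= 2L)
  patterns <- lapply(patterns, function(p)
    if (methods::is(p, "Attractor")) attractorPattern(p) else p)
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    names(patterns) <- paste0("P", seq_along(patterns))
  genes <- Reduce(intersect, lapply(patterns, names))
  if (length(genes) == 0L)
    stop("empty shared gene set across patterns")
  k <- length(patterns)
  m <- matrix(0, k, k, dimnames = list(names(patterns), names(patterns)))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    d <- hammingDistance(patterns[[i]], patterns[[j]], genes)
    m[i, j] <- d; m[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  cl <- stats::cutree(hc, h = threshold)
  list(clusters = cl, hclust = hc, distances = m, genes = genes)
}

#' Phenotype read-out expressions
#'
#' Defines the three high-level cellular phenotypes -- proliferation,
#' apoptosis, and differentiation -- as Boolean expressions over model
#' nodes. These are read-outs evaluated on attractor states, not model
#' nodes: they leave the dynamics untouched.
#'
#' @param proliferation,apoptosis,differentiation Rule strings (grammar of
#'   [parseRule()]) or `BoolExpr` objects.
#' @return A `PhenotypeSpec` (list with the three parsed expressions).
#' @examples
#' phenotypeSpec("MYC & !CDKN2A", "TP53", "GATA1 | KLF1")
#' @export
phenotypeSpec <- function(proliferation, apoptosis, differentiation) {
  asExpr <- function(x) if (inherits(x, "BoolExpr")) x else parseRule(x)
  out <- list(proliferation = asExpr(proliferation),
              apoptosis = asExpr(apoptosis),
              differentiation = asExpr(differentiation))
  class(out) <- "PhenotypeSpec"
  out
}

#' @export
print.PhenotypeSpec <- function(x, ...) {
  cat("PhenotypeSpec:\n")
  for (nm in names(x))
    cat("  ", nm, ": ", ruleToString(x[[nm]]), "\n", sep = "")
  invisible(x)
}

.checkPhenotypes <- function(model, phenotypes) {
  stopifnot(inherits(phenotypes, "PhenotypeSpec"))
  for (nm in names(phenotypes)) {
    missing <- setdiff(.syntacticVars(phenotypes[[nm]]), model@nodeIds)
    if (length(missing) > 0L)
      stop("phenotype '", nm, "' references node(s) absent from the model: ",
           paste(missing, collapse = ", "))
  }
}

#' Phenotype-based network score
#'
#' For each attractor state the score is `proliferation - apoptosis -
#' differentiation`, each phenotype expression evaluated to 0/1 on the
#' state; the attractor score is the mean over its states and the model
#' score the mean over attractors. The score lies in [-2, 1]; +1 means
#' every attractor state is purely proliferative, and lower values reflect
#' death or maturation -- a proxy for disease aggressiveness comparable to
#' clinical blast percentage.
#'
#' @param model A valid `LogicalModel`.
#' @param phenotypes A [phenotypeSpec()] over the model's nodes.
#' @param aset An [AttractorSet-class] of the model.
#' @param mode `"mean"` (single model score, default) or `"per_attractor"`
#'   (named vector of attractor scores).
#' @return Numeric scalar or named numeric vector in [-2, 1].
#' @export
networkScore <- function(model, phenotypes, aset,
                         mode = c("mean", "per_attractor")) {
  mode <- match.arg(mode)
  .checkPhenotypes(model, phenotypes)
  stopifnot(methods::is(aset, "AttractorSet"), length(aset@attractors) >= 1L)
  per <- vapply(aset@attractors, function(a) {
    p <- evalRule(phenotypes$proliferation, a@states)
    ap <- evalRule(phenotypes$apoptosis, a@states)
    d <- evalRule(phenotypes$differentiation, a@states)
    mean(p - ap - d)
  }, numeric(1))
  names(per) <- vapply(aset@attractors, function(a) a@label, "")
  if (mode == "per_attractor") per else mean(per)
}

#' Network scores for a mutation cohort
#'
#' For each patient profile: clamp the mutated genes ([clampModel()]),
#' recompute the attractors, and take the [networkScore()]. Identical
#' profiles are computed once and weighted by their patient count. Profile
#' genes absent from the model are dropped with a warning and counted in
#' the output.
#'
#' @param model A valid `LogicalModel`.
#' @param phenotypes A [phenotypeSpec()].
#' @param profiles Named list of mutation-profile data.frames (columns
#'   `gene`, `effect`), e.g. from [readMutationProfiles()].
#' @param scheme,mode,cap Passed to [attractors()].
#' @return data.frame with one row per distinct profile: `profile`
#'   (canonical `gene:effect` string, `"WT"` if empty), `n` (patients),
#'   `score`, `genes_dropped`.
#' @export
cohortScores <- function(model, phenotypes, profiles,
                         scheme = c("asynchronous", "synchronous"),
                         mode = c("exact", "sampling"), cap = 22L) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  keyed <- vapply(profiles, function(p) {
    if (nrow(p) == 0L) return("WT")
    paste(sort(paste0(p$gene, ":", toupper(p$effect))), collapse = ",")
  }, "")
  rows <- list()
  for (key in sort(unique(keyed))) {
    p <- profiles[[which(keyed == key)[1L]]]
    known <- p$gene %in% model@nodeIds
    nDropped <- sum(!known)
    if (nDropped > 0L) {
      warning("profile '", key, "': dropping gene(s) absent from model: ",
              paste(p$gene[!known], collapse = ", "))
      p <- p[known, , drop = FALSE]
    }
    clamped <- clampModel(model, p)
    aset <- attractors(clamped, scheme = scheme, mode = mode, cap = cap)
    rows[[length(rows) + 1L]] <- data.frame(
      profile = key, n = sum(keyed == key),
      score = networkScore(clamped, phenotypes, aset),
      genes_dropped = nDropped, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate network scores with an outcome
#'
#' Pearson or Spearman correlation between model scores and an outcome
#' measure (e.g. blast percentage per mutation profile), optionally
#' weighted by patient counts: with integer `weights` each observation is
#' replicated by its count before correlating, matching cohort tables where
#' one row summarises several patients.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @param weights Optional positive counts, same length as `x`.
#' @return Correlation coefficient in [-1, 1].
#' @export
correlateScores <- function(x, y, method = c("pearson", "spearman"),
                            weights = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(x), all(weights > 0))
    reps <- as.integer(round(weights))
    x <- rep(x, reps); y <- rep(y, reps)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::var(x) == 0) "x" else "y")
  stats::cor(x, y, method = method)
}

#' Report whether merged attractors retain the source models' attractors
#'
#' Operationalises functional retention after merging: for every attractor
#' of each source model, the nearest merged attractor by Hamming distance
#' on the genes shared with that source model, and whether it falls within
#' the threshold. A self-merge retains everything at threshold 0.
#'
#' @param originals List of [AttractorSet-class] objects of the source
#'   models.
#' @param merged [AttractorSet-class] of the merged model.
#' @param threshold Retention threshold on the Hamming distance (default
#'   0.1).
#' @return data.frame: `model`, `attractor`, `nearest`, `distance`,
#'   `retained`.
#' @export
retentionReport <- function(originals, merged, threshold = 0.1) {
  stopifnot(is.list(originals), methods::is(merged, "AttractorSet"))
  rows <- list()
  for (aset in originals) {
    stopifnot(methods::is(aset, "AttractorSet"))
    genes <- intersect(aset@nodes, merged@nodes)
    for (a in aset@attractors) {
      ds <- vapply(merged@attractors, hammingDistance, numeric(1),
                   a = attractorPattern(a), genes = genes)
      j <- which.min(ds)
      rows[[length(rows) + 1L]] <- data.frame(
        model = aset@modelId, attractor = a@label,
        nearest = merged@attractors[[j]]@label, distance = ds[j],
        retained = ds[j] <= threshold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
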