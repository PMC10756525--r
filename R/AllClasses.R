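#' @import methods
NULL

.DIRECTIONS <- c("high", "low")
.SIGNS <- c("activation", "inhibition", "unknown")
.EDGE_DIRECTIONS <- c("forward", "both", "undirected")
.ANNOTATION_DIRECTIONS <- c("a_to_b", "b_to_a", "both", "none")

#' MiRNASignature: a signed, provenance-tagged miRNA set
#'
#' Holds the aggregated set of differentially expressed circulating miRNAs,
#' each labelled \code{"high"} (elevated) or \code{"low"} (decreased) and
#' tagged with the set of studies reporting it. A miRNA may never carry both
#' directions: a conflict across studies is an input error and is rejected at
#' construction/aggregation time rather than silently resolved.
#'
#' @slot mirna character vector of miRBase-style identifiers
#'   (e.g. \code{"hsa-miR-21-5p"}); unique after case-insensitive trimming.
#' @slot direction character vector, one of \code{"high"}/\code{"low"} per
#'   miRNA.
#' @slot sources list of non-empty character vectors of study identifiers,
#'   parallel to \code{mirna}.
#'
#' @seealso [readSignatureLists()], [nHigh()], [highMirnas()]
#' @export
setClass("MiRNASignature",
  representation(mirna = "character", direction = "character",
                 sources = "list"))

setValidity("MiRNASignature", function(object) {
  msgs <- character()
  n <- length(object@mirna)
  if (length(object@direction) != n || length(object@sources) != n)
    msgs <- c(msgs, "mirna, direction and sources must have equal length")
  if (anyDuplicated(tolower(trimws(object@mirna))))
    msgs <- c(msgs, "duplicate miRNA identifiers in signature")
  if (n > 0 && !all(object@direction %in% .DIRECTIONS))
    msgs <- c(msgs, "direction must be 'high' or 'low'")
  if (n > 0 && any(!nzchar(trimws(object@mirna))))
    msgs <- c(msgs, "empty miRNA identifier")
  bad <- vapply(object@sources,
                function(s) length(s) == 0L || any(!nzchar(s)), logical(1))
  if (any(bad))
    msgs <- c(msgs, "every miRNA needs at least one non-empty source tag")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MiRNASignature
#'
#' @param mirna character vector of miRNA identifiers.
#' @param direction character vector (\code{"high"}/\code{"low"}).
#' @param sources list of character vectors of study tags, or a single
#'   character vector recycled as one tag per miRNA.
#' @return A [MiRNASignature-class] object.
#' @examples
#' MiRNASignature(c("hsa-miR-21-5p", "hsa-miR-607"),
#'                c("high", "low"), "studyA")
#' @export
MiRNASignature <- function(mirna = character(), direction = character(),
                           sources = list()) {
  mirna <- trimws(as.character(mirna))
  if (is.character(sources))
    sources <- as.list(rep_len(sources, length(mirna)))
  new("MiRNASignature", mirna = mirna,
      direction = as.character(direction), sources = sources)
}

#' TargetInteractionTable: deduplicated miRNA-gene interaction pairs
#'
#' Unique (miRNA, gene) pairs taken from a miRNA-target interaction (MTI)
#' table. Evidence multiplicity is deliberately discarded: a gene supported by
#' ten publications for one miRNA still counts a single vote from that miRNA
#' in the targeting-frequency score.
#'
#' @slot pairs data.frame with character columns \code{mirna} and \code{gene};
#'   rows unique.
#' @slot speciesFilter organism tag applied at load (or \code{"synthetic"}).
#' @slot recordCountRaw integer, number of evidence records before
#'   deduplication (for logging).
#' @seealso [readMtiTable()], [scoreGenes()]
#' @export
setClass("TargetInteractionTable",
  representation(pairs = "data.frame", speciesFilter = "character",
                 recordCountRaw = "integer"))

setValidity("TargetInteractionTable", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("mirna", "gene") %in% names(p)))
    msgs <- c(msgs, "pairs needs columns 'mirna' and 'gene'")
  else {
    if (anyDuplicated(p[c("mirna", "gene")]))
      msgs <- c(msgs, "duplicate (miRNA, gene) pairs")
    if (nrow(p) > 0 && any(!nzchar(trimws(p$mirna)) | !nzchar(trimws(p$gene))))
      msgs <- c(msgs, "empty miRNA or gene identifier")
  }
  if (length(object@recordCountRaw) != 1L || is.na(object@recordCountRaw) ||
      object@recordCountRaw < nrow(p))
    msgs <- c(msgs, "recordCountRaw must be a single integer >= nrow(pairs)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TargetInteractionTable
#'
#' @param mirna,gene character vectors of equal length; duplicate pairs are
#'   collapsed.
#' @param speciesFilter organism tag recorded on the table.
#' @param recordCountRaw raw (pre-deduplication) record count; defaults to the
#'   number of input rows.
#' @return A [TargetInteractionTable-class] object.
#' @export
TargetInteractionTable <- function(mirna = character(), gene = character(),
                                   speciesFilter = "unspecified",
                                   recordCountRaw = length(mirna)) {
  p <- unique(data.frame(mirna = trimws(as.character(mirna)),
                         gene = trimws(as.character(gene)),
                         stringsAsFactors = FALSE))
  rownames(p) <- NULL
  new("TargetInteractionTable", pairs = p, speciesFilter = speciesFilter,
      recordCountRaw = as.integer(recordCountRaw))
}

#' UndirectedPPINetwork: confidence-scored protein-protein interactions
#'
#' Undirected gene-gene (protein-protein) edges with a confidence in
#' \eqn{[0, 1]}. Pairs are stored once in canonical order
#' (\code{geneA < geneB} lexicographically); self-loops are never stored.
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB} (character)
#'   and \code{confidence} (numeric in \eqn{[0,1]}).
#' @seealso [readPpiNetwork()], [edgeCountAmong()]
#' @export
setClass("UndirectedPPINetwork", representation(edges = "data.frame"))

setValidity("UndirectedPPINetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("geneA", "geneB", "confidence") %in% names(e)))
    return("edges needs columns geneA, geneB, confidence")
  if (nrow(e) > 0) {
    if (any(e$geneA == e$geneB)) msgs <- c(msgs, "self-loop present")
    if (any(e$geneA > e$geneB))
      msgs <- c(msgs, "edges must be canonically ordered (geneA < geneB)")
    if (anyDuplicated(e[c("geneA", "geneB")]))
      msgs <- c(msgs, "duplicate undirected edge")
    if (any(e$confidence < 0 | e$confidence > 1))
      msgs <- c(msgs, "confidence outside [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an UndirectedPPINetwork
#'
#' Canonicalizes pair order, drops self-loops, and collapses duplicate pairs
#' keeping the maximum confidence.
#'
#' @param geneA,geneB character vectors of endpoints.
#' @param confidence numeric vector in \eqn{[0,1]}.
#' @return An [UndirectedPPINetwork-class] object.
#' @export
UndirectedPPINetwork <- function(geneA = character(), geneB = character(),
                                 confidence = numeric()) {
  a <- trimws(as.character(geneA)); b <- trimws(as.character(geneB))
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  conf <- as.numeric(confidence)[keep]
  if (length(a2)) {
    key <- paste(a2, b2, sep = "\r")
    conf <- vapply(split(conf, key), max, numeric(1))
    first <- !duplicated(key)
    e <- data.frame(geneA = a2[first], geneB = b2[first],
                    confidence = conf[paste(a2[first], b2[first], sep = "\r")],
                    stringsAsFactors = FALSE)
    e <- e[order(e$geneA, e$geneB), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(geneA = character(), geneB = character(),
                    confidence = numeric(), stringsAsFactors = FALSE)
  }
  new("UndirectedPPINetwork", edges = e)
}

#' DirectedInteractionNetwork: signed, (partially) directed gene-gene edges
#'
#' Functional gene-gene interactions with a sign
#' (\code{activation}/\code{inhibition}/\code{unknown}) and a direction marker.
#' Freshly loaded networks may contain \code{"both"} (bidirectional) and
#' \code{"undirected"} rows; [trimToDirected()] resolves those, after which
#' every edge is \code{"forward"}.
#'
#' @slot edges data.frame with character columns \code{source}, \code{target},
#'   \code{direction} (\code{forward}/\code{both}/\code{undirected}),
#'   \code{sign} (\code{activation}/\code{inhibition}/\code{unknown}) and
#'   \code{provenance}.
#' @seealso [trimToDirected()], [filterActivating()], [katzCentrality()]
#' @export
setClass("DirectedInteractionNetwork", representation(edges = "data.frame"))

setValidity("DirectedInteractionNetwork", function(object) {
  e <- object@edges
  need <- c("source", "target", "direction", "sign", "provenance")
  if (!all(need %in% names(e)))
    return(paste("edges needs columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(e) > 0) {
    if (any(e$source == e$target)) msgs <- c(msgs, "self-loop present")
    if (!all(e$direction %in% .EDGE_DIRECTIONS))
      msgs <- c(msgs, "unknown direction marker")
    if (!all(e$sign %in% .SIGNS)) msgs <- c(msgs, "unknown sign token")
    if (anyDuplicated(e[c("source", "target")]))
      msgs <- c(msgs, "duplicate ordered (source, target) pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DirectedInteractionNetwork
#'
#' @param source,target character endpoint vectors.
#' @param direction direction markers (\code{forward}/\code{both}/
#'   \code{undirected}); default all \code{forward}.
#' @param sign edge signs; default \code{unknown}.
#' @param provenance free-text/PMID provenance; default \code{""} becomes
#'   \code{"unspecified"}.
#' @return A [DirectedInteractionNetwork-class] object.
#' @export
DirectedInteractionNetwork <- function(source = character(),
                                       target = character(),
                                       direction = "forward",
                                       sign = "unknown",
                                       provenance = "unspecified") {
  n <- length(source)
  e <- data.frame(source = trimws(as.character(source)),
                  target = trimws(as.character(target)),
                  direction = rep_len(as.character(direction), n),
                  sign = rep_len(as.character(sign), n),
                  provenance = rep_len(as.character(provenance), n),
                  stringsAsFactors = FALSE)
  rownames(e) <- NULL
  new("DirectedInteractionNetwork", edges = e)
}

#' AnnotationTable: manual direction/sign resolution of gene pairs
#'
#' The product of manual literature curation: for each unordered gene pair, a
#' resolved direction (\code{a_to_b}, \code{b_to_a}, \code{both},
#' \code{none}) and a sign, with provenance. Consumed by [applyAnnotations()].
#'
#' @slot rows data.frame with columns \code{geneA}, \code{geneB},
#'   \code{resolvedDirection}, \code{sign}, \code{provenance}.
#' @export
setClass("AnnotationTable", representation(rows = "data.frame"))

setValidity("AnnotationTable", function(object) {
  r <- object@rows
  need <- c("geneA", "geneB", "resolvedDirection", "sign", "provenance")
  if (!all(need %in% names(r)))
    return(paste("rows needs columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(r) > 0) {
    if (!all(r$resolvedDirection %in% .ANNOTATION_DIRECTIONS))
      msgs <- c(msgs, "unknown resolvedDirection token")
    if (!all(r$sign %in% .SIGNS)) msgs <- c(msgs, "unknown sign token")
    key <- paste(pmin(r$geneA, r$geneB), pmax(r$geneA, r$geneB))
    if (anyDuplicated(key))
      msgs <- c(msgs, "an unordered gene pair is annotated more than once")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotationTable
#'
#' @param geneA,geneB character endpoints of the annotated pair.
#' @param resolvedDirection one of \code{a_to_b}, \code{b_to_a}, \code{both},
#'   \code{none} per row.
#' @param sign edge sign per row.
#' @param provenance provenance string per row.
#' @return An [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(geneA = character(), geneB = character(),
                            resolvedDirection = character(),
                            sign = character(), provenance = "manual review") {
  n <- length(geneA)
  r <- data.frame(geneA = as.character(geneA), geneB = as.character(geneB),
                  resolvedDirection = as.character(resolvedDirection),
                  sign = as.character(sign),
                  provenance = rep_len(as.character(provenance), n),
                  stringsAsFactors = FALSE)
  rownames(r) <- NULL
  new("AnnotationTable", rows = r)
}

#' GeneScoreTable: per-gene miRNA-targeting frequency scores
#'
#' For every gene targeted by at least one signature miRNA: the number of
#' distinct elevated (high) miRNAs targeting it, the number of distinct
#' decreased (low) miRNAs targeting it, and the targeting frequency score
#' \code{high - low}. Genes targeted by no signature miRNA are absent rather
#' than scored 0.
#'
#' @slot scores data.frame with columns \code{gene}, \code{highCount},
#'   \code{lowCount}, \code{frequencyScore}, sorted by score descending then
#'   gene ascending.
#' @seealso [scoreGenes()], [selectTopK()], [selectByThreshold()]
#' @export
setClass("GeneScoreTable", representation(scores = "data.frame"))

setValidity("GeneScoreTable", function(object) {
  s <- object@scores
  need <- c("gene", "highCount", "lowCount", "frequencyScore")
  if (!all(need %in% names(s)))
    return(paste("scores needs columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(s) > 0) {
    if (any(s$highCount < 0 | s$lowCount < 0))
      msgs <- c(msgs, "negative targeting count")
    if (any(s$frequencyScore != s$highCount - s$lowCount))
      msgs <- c(msgs, "frequencyScore must equal highCount - lowCount")
    if (any(s$highCount == 0 & s$lowCount == 0))
      msgs <- c(msgs, "untargeted gene present in the table")
    if (anyDuplicated(s$gene)) msgs <- c(msgs, "duplicate gene")
  }
  if (length(msgs)) msgs else TRUE
})

.newGeneScoreTable <- function(gene, highCount, lowCount) {
  s <- data.frame(gene = as.character(gene),
                  highCount = as.integer(highCount),
                  lowCount = as.integer(lowCount),
                  stringsAsFactors = FALSE)
  s$frequencyScore <- s$highCount - s$lowCount
  s <- s[order(-s$frequencyScore, s$gene), , drop = FALSE]
  rownames(s) <- NULL
  new("GeneScoreTable", scores = s)
}

#' PermutationResult: observed statistics, null distributions and p-values
#'
#' Result of [permutationTest()]. Two statistics are assessed: the summed
#' frequency score of the top-\code{k} genes, and the number of PPI
#' connections among those genes at each confidence threshold. Both empirical
#' p-value conventions are reported: \code{pStrict = r/N} with \code{r} the
#' number of null values strictly greater than the observed, and
#' \code{pAddone = (r' + 1)/(N + 1)} with \code{r'} counting null values
#' greater than or equal to the observed (never exactly zero).
#'
#' @slot observedSum numeric, observed top-k summed score.
#' @slot observedEdges named numeric, observed edge counts per threshold.
#' @slot nullSums numeric vector of length \code{nIter}.
#' @slot nullEdges named list of numeric vectors per threshold.
#' @slot nIter,k,seed integers describing the run.
#' @slot pStrict,pAddone lists with elements \code{sum} (scalar) and
#'   \code{edges} (named numeric per threshold).
#' @export
setClass("PermutationResult",
  representation(observedSum = "numeric", observedEdges = "numeric",
                 nullSums = "numeric", nullEdges = "list",
                 nIter = "integer", k = "integer", seed = "integer",
                 pStrict = "list", pAddone = "list"))

setValidity("PermutationResult", function(object) {
  msgs <- character()
  if (length(object@nullSums) != object@nIter)
    msgs <- c(msgs, "nullSums length must equal nIter")
  if (!all(vapply(object@nullEdges, length, integer(1)) == object@nIter))
    msgs <- c(msgs, "each nullEdges vector must have length nIter")
  if (!all(c("sum", "edges") %in% names(object@pStrict)) ||
      !all(c("sum", "edges") %in% names(object@pAddone)))
    msgs <- c(msgs, "pStrict/pAddone need elements 'sum' and 'edges'")
  else if (object@pAddone$sum <= 0)
    msgs <- c(msgs, "pAddone must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' CentralityTable: Katz centrality and combined gene scores
#'
#' Katz centrality \eqn{x_v = \beta + \alpha \sum_{u \to v} x_u} over the
#' activating network (incoming-edge convention, unnormalized) and the
#' combined score \code{katz * frequencyScore}, the final per-gene impact
#' measure.
#'
#' @slot scores data.frame with columns \code{gene}, \code{katz},
#'   \code{frequencyScore}, \code{combined} (the latter two \code{NA} until
#'   [combinedScores()] is applied).
#' @slot alpha,beta the Katz coefficients used.
#' @export
setClass("CentralityTable",
  representation(scores = "data.frame", alpha = "numeric", beta = "numeric"))

setValidity("CentralityTable", function(object) {
  s <- object@scores
  need <- c("gene", "katz", "frequencyScore", "combined")
  if (!all(need %in% names(s)))
    return(paste("scores needs columns", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(s) > 0) {
    if (any(s$katz <= 0)) msgs <- c(msgs, "katz scores must be positive")
    if (anyDuplicated(s$gene)) msgs <- c(msgs, "duplicate gene")
    done <- !is.na(s$combined) & !is.na(s$frequencyScore)
    if (any(abs(s$combined[done] -
                s$katz[done] * s$frequencyScore[done]) > 1e-8))
      msgs <- c(msgs, "combined must equal katz * frequencyScore")
  }
  if (length(msgs)) msgs else TRUE
})

#' InfluenceResult: per-miRNA path-attenuation influence scores
#'
#' For each elevated miRNA, the influence score
#' \eqn{I = \sum_g s_g \sum_p \alpha^{l_p}} over all simple paths \eqn{p}
#' (length \eqn{l_p \le} \code{maxPathLen}) from the miRNA to each reachable
#' gene \eqn{g} with final combined score \eqn{s_g}.
#'
#' @slot scores data.frame with columns \code{mirna}, \code{influence},
#'   sorted by influence descending then miRNA ascending.
#' @slot alpha attenuation factor.
#' @slot maxPathLen path-length cap used during enumeration.
#' @slot geneScores the [CentralityTable-class] supplying \eqn{s_g}.
#' @export
setClass("InfluenceResult",
  representation(scores = "data.frame", alpha = "numeric",
                 maxPathLen = "integer", geneScores = "CentralityTable"))

setValidity("InfluenceResult", function(object) {
  s <- object@scores
  if (!all(c("mirna", "influence") %in% names(s)))
    return("scores needs columns mirna, influence")
  if (nrow(s) > 0 && any(s$influence < 0))
    return("influence scores must be non-negative")
  TRUE
})

#' SyntheticConfig: parameters of the planted-cluster data generators
#'
#' Describes a synthetic study: a universe of miRNAs and genes, a signature of
#' \code{nHigh} elevated plus \code{nLow} decreased miRNAs, and a planted
#' convergent cluster of \code{clusterSize} genes that the elevated signature
#' miRNAs target with probability \code{pCluster} (vs \code{pBackground}
#' elsewhere) and that is internally PPI-connected with probability
#' \code{qCluster} (vs \code{qBackground}). Setting
#' \code{pCluster = pBackground} and \code{qCluster = qBackground} yields an
#' exchangeable null with no planted signal. All generation is a pure
#' function of the configuration (including its \code{seed}).
#'
#' @slot nMirnaUniverse,nGenes,nHigh,nLow,clusterSize,seed integers.
#' @slot pBackground,pCluster,qBackground,qCluster probabilities in
#'   \eqn{[0,1]}.
#' @slot confidenceBackground,confidenceCluster length-2 numeric ranges in
#'   \eqn{[0,1]} from which PPI confidences are drawn uniformly.
#' @slot pDirectedEdge per-pair edge probability of the directed-network
#'   generator.
#' @slot directedFraction,bidirectionalFraction fractions of directed-network
#'   edges marked \code{forward} and \code{both}; the remainder is
#'   \code{undirected}.
#' @slot inhibitionFraction,unknownFraction fractions of edges signed
#'   \code{inhibition} and \code{unknown}; the remainder is
#'   \code{activation}.
#' @seealso [syntheticConfig()], [generateMtiTable()], [generatePpi()],
#'   [generateDirectedNet()], [generateSignature()]
#' @export
setClass("SyntheticConfig",
  representation(nMirnaUniverse = "integer", nGenes = "integer",
                 nHigh = "integer", nLow = "integer",
                 pBackground = "numeric", clusterSize = "integer",
                 pCluster = "numeric", qBackground = "numeric",
                 qCluster = "numeric", confidenceBackground = "numeric",
                 confidenceCluster = "numeric", pDirectedEdge = "numeric",
                 directedFraction = "numeric",
                 bidirectionalFraction = "numeric",
                 inhibitionFraction = "numeric", unknownFraction = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  probs <- c(object@pBackground, object@pCluster, object@qBackground,
             object@qCluster, object@pDirectedEdge,
             object@confidenceBackground, object@confidenceCluster)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "all probabilities/confidence bounds must lie in [0, 1]")
  if (object@clusterSize > object@nGenes)
    msgs <- c(msgs, "clusterSize must not exceed nGenes")
  if (object@nHigh + object@nLow > object@nMirnaUniverse)
    msgs <- c(msgs, "nHigh + nLow must not exceed nMirnaUniverse")
  if (object@directedFraction + object@bidirectionalFraction > 1)
    msgs <- c(msgs, "directedFraction + bidirectionalFraction must be <= 1")
  if (object@inhibitionFraction + object@unknownFraction > 1)
    msgs <- c(msgs, "inhibitionFraction + unknownFraction must be <= 1")
  if (length(object@confidenceBackground) != 2L ||
      length(object@confidenceCluster) != 2L)
    msgs <- c(msgs, "confidence ranges must have length 2")
  if (length(msgs)) msgs else TRUE
})

#' RunConfig: end-to-end pipeline configuration
#'
#' Default parameter values reproduce the published analysis settings
#' exactly: top \code{k = 100} genes for the permutation statistics,
#' frequency-score cutoff \code{minScore = 5} for the directed-network gene
#' set, \code{nIter = 10000} permutation replicates, PPI thresholds
#' 0.4/0.7/0.9, cross-referencing threshold 0.95, Katz \eqn{\alpha = 0.1},
#' \eqn{\beta = 1}, influence attenuation \eqn{\alpha = 0.1}.
#'
#' @slot signatureFiles named character vector of per-study signature files.
#' @slot mtiFile,ppiFile,directedFile,annotationFile input paths
#'   (\code{annotationFile} may be \code{NA}).
#' @slot species organism tag for MTI filtering.
#' @slot ppiScoreScale \code{"0-1000"} or \code{"0-1"}.
#' @slot k,minScore,nIter,maxPathLen,seed integer parameters.
#' @slot thresholds numeric PPI thresholds for the edge statistic.
#' @slot crossRefThreshold,alphaKatz,betaKatz,alphaInfluence numeric
#'   parameters.
#' @seealso [runConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
  representation(signatureFiles = "character", mtiFile = "character",
                 ppiFile = "character", directedFile = "character",
                 annotationFile = "character", species = "character",
                 ppiScoreScale = "character",
                 k = "integer", minScore = "integer", nIter = "integer",
                 thresholds = "numeric", crossRefThreshold = "numeric",
                 alphaKatz = "numeric", betaKatz = "numeric",
                 alphaInfluence = "numeric", maxPathLen = "integer",
                 seed = "integer"))
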