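#' Accessors for MiRNASignature
#'
#' @param x a [MiRNASignature-class].
#' @return \code{mirnaIds}: character vector of identifiers; \code{nHigh} /
#'   \code{nLow}: integer counts; \code{highMirnas} / \code{lowMirnas}:
#'   identifier subsets; \code{studySources}: named list of study tags.
#' @aliases mirnaIds nHigh nLow highMirnas lowMirnas studySources
#' @name signature-accessors
#' @examples
#' sig <- MiRNASignature(c("hsa-miR-21-5p", "hsa-miR-607"),
#'                       c("high", "low"), "studyA")
#' nHigh(sig)
#' highMirnas(sig)
NULL

#' @rdname signature-accessors
#' @export
setMethod("mirnaIds", "MiRNASignature", function(x) x@mirna)

#' @rdname signature-accessors
#' @export
setMethod("nHigh", "MiRNASignature",
          function(x) sum(x@direction == "high"))

#' @rdname signature-accessors
#' @export
setMethod("nLow", "MiRNASignature",
          function(x) sum(x@direction == "low"))

#' @rdname signature-accessors
#' @export
setMethod("highMirnas", "MiRNASignature",
          function(x) x@mirna[x@direction == "high"])

#' @rdname signature-accessors
#' @export
setMethod("lowMirnas", "MiRNASignature",
          function(x) x@mirna[x@direction == "low"])

#' @rdname signature-accessors
#' @export
setMethod("studySources", "MiRNASignature",
          function(x) stats::setNames(x@sources, x@mirna))

#' Accessors for interaction tables and networks
#'
#' @param x a domain object.
#' @return \code{interactionPairs}: the deduplicated (mirna, gene)
#'   data.frame; \code{rawRecordCount}: pre-deduplication record count;
#'   \code{networkEdges}: the edge data.frame; \code{networkNodes}: sorted
#'   character vector of node names.
#' @aliases interactionPairs rawRecordCount networkEdges networkNodes
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setMethod("interactionPairs", "TargetInteractionTable",
          function(x) x@pairs)

#' @rdname network-accessors
#' @export
setMethod("rawRecordCount", "TargetInteractionTable",
          function(x) x@recordCountRaw)

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "UndirectedPPINetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setMethod("networkEdges", "DirectedInteractionNetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "UndirectedPPINetwork", function(x)
  sort(unique(c(x@edges$geneA, x@edges$geneB))))

#' @rdname network-accessors
#' @export
setMethod("networkNodes", "DirectedInteractionNetwork", function(x)
  sort(unique(c(x@edges$source, x@edges$target))))

#' Score-table accessor
#'
#' Returns the underlying data.frame of a result object.
#'
#' @param x a [GeneScoreTable-class], [CentralityTable-class] or
#'   [InfluenceResult-class].
#' @return data.frame of per-gene (or per-miRNA) scores.
#' @aliases scoreTable
#' @name scoreTable
NULL

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "GeneScoreTable", function(x) x@scores)

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "CentralityTable", function(x) x@scores)

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "InfluenceResult", function(x) x@scores)

#' @export
setMethod("as.data.frame", "GeneScoreTable",
          function(x, ...) x@scores)

#' @export
setMethod("as.data.frame", "CentralityTable",
          function(x, ...) x@scores)

#' @export
setMethod("as.data.frame", "InfluenceResult",
          function(x, ...) x@scores)

setMethod("show", "MiRNASignature", function(object) {
  cat(sprintf("MiRNASignature with %d miRNAs (%d high, %d low)\n",
              length(object@mirna), nHigh(object), nLow(object)))
  multi <- sum(lengths(object@sources) > 1)
  cat(sprintf("  reported by >1 study: %d\n", multi))
})

setMethod("show", "TargetInteractionTable", function(object) {
  cat(sprintf(
    "TargetInteractionTable: %d unique pairs (%d raw records), %d miRNAs, %d genes\n",
    nrow(object@pairs), object@recordCountRaw,
    length(unique(object@pairs$mirna)), length(unique(object@pairs$gene))))
  cat(sprintf("  species filter: %s\n", object@speciesFilter))
})

setMethod("show", "UndirectedPPINetwork", function(object) {
  cat(sprintf("UndirectedPPINetwork: %d edges over %d nodes\n",
              nrow(object@edges), length(networkNodes(object))))
})

setMethod("show", "DirectedInteractionNetwork", function(object) {
  e <- object@edges
  cat(sprintf("DirectedInteractionNetwork: %d edges over %d nodes\n",
              nrow(e), length(networkNodes(object))))
  if (nrow(e)) {
    cat("  direction:", paste(sprintf("%s=%d", names(table(e$direction)),
                                      as.integer(table(e$direction))),
                              collapse = " "), "\n")
    cat("  sign:", paste(sprintf("%s=%d", names(table(e$sign)),
                                 as.integer(table(e$sign))),
                         collapse = " "), "\n")
  }
})

setMethod("show", "GeneScoreTable", function(object) {
  s <- object@scores
  cat(sprintf("GeneScoreTable: %d genes, frequency scores in [%s, %s]\n",
              nrow(s),
              if (nrow(s)) min(s$frequencyScore) else "-",
              if (nrow(s)) max(s$frequencyScore) else "-"))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d replicates, top-k = %d, seed = %d\n",
              object@nIter, object@k, object@seed))
  cat(sprintf("  sum statistic: observed %g, p_strict %.4g, p_addone %.4g\n",
              object@observedSum, object@pStrict$sum, object@pAddone$sum))
  for (th in names(object@observedEdges))
    cat(sprintf(
      "  edges @ %s: observed %d, p_strict %.4g, p_addone %.4g\n",
      th, object@observedEdges[[th]], object@pStrict$edges[[th]],
      object@pAddone$edges[[th]]))
})

setMethod("show", "CentralityTable", function(object) {
  cat(sprintf("CentralityTable: %d genes, alpha = %g, beta = %g\n",
              nrow(object@scores), object@alpha, object@beta))
  if (nrow(object@scores) && !all(is.na(object@scores$combined)))
    cat(sprintf("  top combined: %s (%.3f)\n", object@scores$gene[1],
                object@scores$combined[1]))
})

setMethod("show", "InfluenceResult", function(object) {
  cat(sprintf(
    "InfluenceResult: %d miRNAs, alpha = %g, max path length = %d\n",
    nrow(object@scores), object@alpha, object@maxPathLen))
  if (nrow(object@scores))
    cat(sprintf("  top: %s (%.2f)\n", object@scores$mirna[1],
                object@scores$influence[1]))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d miRNAs x %d genes, signature %d high / %d low\n",
    object@nMirnaUniverse, object@nGenes, object@nHigh, object@nLow))
  cat(sprintf("  cluster: %d genes, p %g vs background %g; PPI q %g vs %g\n",
              object@clusterSize, object@pCluster, object@pBackground,
              object@qCluster, object@qBackground))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: k = %d, minScore = %d, nIter = %d, seed = %d\n",
    object@k, object@minScore, object@nIter, object@seed))
  cat(sprintf("  thresholds: %s; crossRef %g; Katz a=%g b=%g; influence a=%g, L=%d\n",
              paste(object@thresholds, collapse = ", "),
              object@crossRefThreshold, object@alphaKatz, object@betaKatz,
              object@alphaInfluence, object@maxPathLen))
})
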