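# Generics for the domain classes. Table-like classes additionally get
# as.data.frame methods (see accessors.R) so results drop straight into
# base-R workflows.

#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @export
setGeneric("nHigh", function(x) standardGeneric("nHigh"))

#' @export
setGeneric("nLow", function(x) standardGeneric("nLow"))

#' @export
setGeneric("highMirnas", function(x) standardGeneric("highMirnas"))

#' @export
setGeneric("lowMirnas", function(x) standardGeneric("lowMirnas"))

#' @export
setGeneric("studySources", function(x) standardGeneric("studySources"))

#' @export
setGeneric("interactionPairs", function(x) standardGeneric("interactionPairs"))

#' @export
setGeneric("rawRecordCount", function(x) standardGeneric("rawRecordCount"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @export
setGeneric("scoreGenes", function(signature, mti)
  standardGeneric("scoreGenes"))

#' @export
setGeneric("trimToDirected", function(net) standardGeneric("trimToDirected"))

#' @export
setGeneric("findMissingConnections", function(net, ppi, threshold = 0.95)
  standardGeneric("findMissingConnections"))

#' @export
setGeneric("applyAnnotations", function(net, ann)
  standardGeneric("applyAnnotations"))

#' @export
setGeneric("filterActivating", function(net)
  standardGeneric("filterActivating"))

#' @export
setGeneric("katzCentrality",
  function(net, alpha = 0.1, beta = 1, nodes = NULL)
    standardGeneric("katzCentrality"))

#' @export
setGeneric("combinedScores", function(katz, freq)
  standardGeneric("combinedScores"))
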