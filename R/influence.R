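# Per-miRNA path-attenuation influence scores. The activating gene network
# is used in reverse: from each elevated miRNA, every unique (simple)
# directed path to every reachable gene contributes alpha^length, and the
# per-gene path sums are weighted by the gene's final combined score:
#
#   I_miRNA = sum_g s_g * sum_p alpha^(l_p)
#
# Simple paths (no repeated node) are the finite reading of "unique paths"
# in a network that may contain cycles; a configurable length cap bounds
# enumeration cost, with a negligible truncation error at alpha = 0.1.

#' Build the miRNA-to-gene influence graph
#'
#' Directed igraph with one node per elevated signature miRNA and one per
#' network gene: an edge miRNA -> gene for every interaction pair whose gene
#' is in the gene set, plus all gene -> gene activating edges. miRNA nodes
#' never receive edges. A miRNA targeting only genes outside the network
#' remains as an isolated node (influence 0).
#'
#' @param highMirnas character vector of elevated miRNA ids (or a
#'   [MiRNASignature-class], whose high subset is used).
#' @param mti a [TargetInteractionTable-class].
#' @param activatingNet the activating-only
#'   [DirectedInteractionNetwork-class] on which the final gene scores were
#'   computed.
#' @param genes optional character vector of gene nodes; defaults to the
#'   network's node set. Supply the full scored gene set to keep genes that
#'   are isolated in the activating network reachable by direct targeting.
#' @return A directed \code{igraph} object with vertex attribute
#'   \code{type} (\code{"mirna"}/\code{"gene"}).
#' @export
buildInfluenceGraph <- function(highMirnas, mti, activatingNet,
                                genes = NULL) {
  if (is(highMirnas, "MiRNASignature"))
    highMirnas <- highMirnas(highMirnas)
  highMirnas <- unique(highMirnas)
  if (is.null(genes)) genes <- networkNodes(activatingNet)
  genes <- sort(unique(c(genes, networkNodes(activatingNet))))
  if (length(intersect(highMirnas, genes)))
    stop("miRNA ids and gene symbols overlap; node names must be unique",
         call. = FALSE)
  p <- mti@pairs
  keep <- tolower(p$mirna) %in% tolower(highMirnas) & p$gene %in% genes
  hit <- match(tolower(p$mirna[keep]), tolower(highMirnas))
  mg <- unique(data.frame(from = highMirnas[hit], to = p$gene[keep],
                          stringsAsFactors = FALSE))
  gg <- data.frame(from = activatingNet@edges$source,
                   to = activatingNet@edges$target,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    rbind(mg, gg), directed = TRUE,
    vertices = data.frame(name = c(highMirnas, genes),
                          type = rep(c("mirna", "gene"),
                                     c(length(highMirnas), length(genes))),
                          stringsAsFactors = FALSE))
  g
}

#' Enumerate simple directed paths up to a length cap
#'
#' All directed paths from \code{source} to \code{target} with no repeated
#' node and at most \code{maxLen} edges.
#'
#' @param graph a directed \code{igraph} object.
#' @param source,target vertex names.
#' @param maxLen maximum path length in edges (\code{>= 1}).
#' @return list with elements \code{paths} (list of character vectors of
#'   vertex names, source first) and \code{lengths} (integer edge counts).
#' @export
enumerateSimplePaths <- function(graph, source, target, maxLen) {
  stopifnot(maxLen >= 1)
  ps <- igraph::all_simple_paths(graph, from = source, to = target,
                                 mode = "out", cutoff = maxLen)
  paths <- lapply(ps, function(p) igraph::as_ids(p))
  list(paths = paths,
       lengths = vapply(paths, function(p) length(p) - 1L, integer(1)))
}

# per-gene sum over simple paths of alpha^length for one source vertex
.pathWeights <- function(graph, source, alpha, maxLen) {
  ps <- igraph::all_simple_paths(graph, from = source, mode = "out",
                                 cutoff = maxLen)
  if (!length(ps)) return(numeric(0))
  ends <- vapply(ps, function(p) igraph::as_ids(p)[length(p)], character(1))
  w <- vapply(ps, function(p) alpha^(length(p) - 1L), numeric(1))
  vapply(split(w, ends), sum, numeric(1))
}

#' Influence score of a single miRNA
#'
#' Computes \eqn{I = \sum_g s_g \sum_p \alpha^{l_p}} where the inner sum
#' runs over all simple directed paths from the miRNA to gene \eqn{g} with
#' at most \code{maxLen} edges, and \eqn{s_g} is the gene's final combined
#' score.
#'
#' @param mirna miRNA vertex name; must be present in the graph.
#' @param graph influence graph from [buildInfluenceGraph()].
#' @param scores a [CentralityTable-class] with the \code{combined} column
#'   filled (see [combinedScores()]); every reachable gene must be scored.
#' @param alpha attenuation factor in (0, 1), default 0.1.
#' @param maxLen path-length cap in edges, default 8 (at \eqn{\alpha = 0.1}
#'   any longer path contributes at most \eqn{10^{-8}} per unit gene score).
#' @return numeric influence score (non-negative when all gene scores are).
#' @export
influenceScore <- function(mirna, graph, scores, alpha = 0.1, maxLen = 8L) {
  stopifnot(alpha > 0, alpha < 1)
  if (!(mirna %in% igraph::V(graph)$name))
    stop("miRNA '", mirna, "' is not a node of the influence graph",
         call. = FALSE)
  w <- .pathWeights(graph, mirna, alpha, maxLen)
  if (!length(w)) return(0)
  s <- scores@scores
  hit <- match(names(w), s$gene)
  if (anyNA(hit) || anyNA(s$combined[hit]))
    stop("reachable gene(s) without a combined score: ",
         paste(utils::head(names(w)[is.na(hit) | is.na(s$combined[hit])], 5),
               collapse = ", "), call. = FALSE)
  sum(s$combined[hit] * w)
}

#' Rank elevated miRNAs by influence on the final phenotype
#'
#' Applies [influenceScore()] to every elevated miRNA node of the influence
#' graph and sorts descending (ties broken by miRNA id ascending). Higher
#' scores mark miRNAs contributing to the suppression of many genes with
#' high final scores, directly or indirectly.
#'
#' @param highMirnas character vector of elevated miRNA ids (or a
#'   [MiRNASignature-class]); each must be a node of \code{graph}.
#' @param graph influence graph from [buildInfluenceGraph()].
#' @param scores a [CentralityTable-class] with combined scores.
#' @param alpha attenuation factor, default 0.1.
#' @param maxLen path-length cap, default 8.
#' @return An [InfluenceResult-class].
#' @export
rankMirnas <- function(highMirnas, graph, scores, alpha = 0.1,
                       maxLen = 8L) {
  if (is(highMirnas, "MiRNASignature"))
    highMirnas <- highMirnas(highMirnas)
  highMirnas <- unique(highMirnas)
  infl <- vapply(highMirnas, influenceScore, numeric(1), graph = graph,
                 scores = scores, alpha = alpha, maxLen = maxLen)
  d <- data.frame(mirna = highMirnas, influence = as.numeric(infl),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$influence, d$mirna), , drop = FALSE]
  rownames(d) <- NULL
  new("InfluenceResult", scores = d, alpha = alpha,
      maxPathLen = as.integer(maxLen), geneScores = scores)
}
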