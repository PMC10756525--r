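# Curation of the directed activating network over high-scoring genes and
# Katz-centrality-based combined gene scores.
#
# The curation sequence mirrors the intended analysis order:
# trimToDirected -> findMissingConnections (cross-reference against a
# high-confidence PPI graph) -> applyAnnotations (manually resolved
# direction/sign of the missing pairs) -> filterActivating -> katzCentrality
# -> combinedScores.

#' Trim a network to discrete directed edges
#'
#' Removes undirected edges and splits each bidirectional edge into two
#' opposite directed edges carrying the same sign and provenance. The node
#' set of the result is the set of endpoints of surviving edges, so output
#' edge count = directed-in + 2 x bidirectional-in.
#'
#' @param net a [DirectedInteractionNetwork-class] possibly containing
#'   \code{both}/\code{undirected} direction markers.
#' @return A [DirectedInteractionNetwork-class] whose edges are all
#'   \code{forward}.
#' @export
setMethod("trimToDirected", "DirectedInteractionNetwork", function(net) {
  e <- net@edges
  fwd <- e[e$direction == "forward", , drop = FALSE]
  bi <- e[e$direction == "both", , drop = FALSE]
  rev <- bi
  if (nrow(rev)) {
    tmp <- rev$source; rev$source <- rev$target; rev$target <- tmp
  }
  out <- rbind(fwd, bi, rev)
  out$direction <- rep("forward", nrow(out))
  rownames(out) <- NULL
  new("DirectedInteractionNetwork", edges = out)
})

#' Find high-confidence PPI pairs missing from a directed network
#'
#' Cross-references the directed network against an undirected PPI graph
#' restricted to the network's node set: every unordered pair with PPI
#' confidence at or above \code{threshold} for which the network has no edge
#' in either direction is reported (these are the pairs whose direction and
#' sign must be resolved by manual review).
#'
#' @param net a [DirectedInteractionNetwork-class].
#' @param ppi an [UndirectedPPINetwork-class].
#' @param threshold PPI confidence threshold, default 0.95.
#' @return data.frame with columns \code{geneA}, \code{geneB} (canonical
#'   order) and \code{confidence}.
#' @export
setMethod("findMissingConnections",
  c("DirectedInteractionNetwork", "UndirectedPPINetwork"),
  function(net, ppi, threshold = 0.95) {
    stopifnot(threshold >= 0, threshold <= 1)
    nodes <- networkNodes(net)
    e <- ppi@edges
    cand <- e[e$confidence >= threshold & e$geneA %in% nodes &
                e$geneB %in% nodes, , drop = FALSE]
    d <- net@edges
    have <- unique(c(paste(d$source, d$target, sep = "\r"),
                     paste(d$target, d$source, sep = "\r")))
    miss <- !(paste(cand$geneA, cand$geneB, sep = "\r") %in% have)
    out <- cand[miss, , drop = FALSE]
    rownames(out) <- NULL
    out
  })

#' Add manually resolved edges to a directed network
#'
#' For each annotated pair, adds the resolved directed signed edge(s):
#' \code{a_to_b} / \code{b_to_a} add one edge, \code{both} adds two opposite
#' edges, \code{none} adds nothing. Existing edges are never overwritten; an
#' annotation whose sign conflicts with an existing edge on the same ordered
#' pair is a hard error.
#'
#' @param net a [DirectedInteractionNetwork-class].
#' @param ann an [AnnotationTable-class].
#' @return The augmented [DirectedInteractionNetwork-class].
#' @export
setMethod("applyAnnotations",
  c("DirectedInteractionNetwork", "AnnotationTable"),
  function(net, ann) {
    e <- net@edges
    key <- paste(e$source, e$target, sep = "\r")
    addRow <- function(src, tgt, sign, prov) {
      k <- paste(src, tgt, sep = "\r")
      hit <- match(k, key)
      if (!is.na(hit)) {
        if (e$sign[hit] != sign)
          stop("annotation sign '", sign, "' conflicts with existing '",
               e$sign[hit], "' edge ", src, " -> ", tgt, call. = FALSE)
        return(invisible(NULL))  # same edge already present: keep it
      }
      e <<- rbind(e, data.frame(source = src, target = tgt,
                                direction = "forward", sign = sign,
                                provenance = prov, stringsAsFactors = FALSE))
      key <<- c(key, k)
      invisible(NULL)
    }
    r <- ann@rows
    for (i in seq_len(nrow(r))) {
      switch(r$resolvedDirection[i],
        a_to_b = addRow(r$geneA[i], r$geneB[i], r$sign[i], r$provenance[i]),
        b_to_a = addRow(r$geneB[i], r$geneA[i], r$sign[i], r$provenance[i]),
        both = {
          addRow(r$geneA[i], r$geneB[i], r$sign[i], r$provenance[i])
          addRow(r$geneB[i], r$geneA[i], r$sign[i], r$provenance[i])
        },
        none = NULL)
    }
    rownames(e) <- NULL
    new("DirectedInteractionNetwork", edges = e)
  })

#' Restrict a network to activating edges
#'
#' Drops inhibiting edges and edges of uncertain (unknown) sign, leaving
#' the high-confidence activating interactions only. Idempotent.
#'
#' @param net a [DirectedInteractionNetwork-class].
#' @return A [DirectedInteractionNetwork-class] with only
#'   \code{sign = "activation"} edges.
#' @export
setMethod("filterActivating", "DirectedInteractionNetwork", function(net) {
  e <- net@edges[net@edges$sign == "activation", , drop = FALSE]
  rownames(e) <- NULL
  new("DirectedInteractionNetwork", edges = e)
})

#' Katz centrality of a directed network (incoming-edge convention)
#'
#' Solves the linear system \eqn{x_v = \beta + \alpha \sum_{u \to v} x_u}
#' exactly (no truncation): \eqn{(I - \alpha A^\top) x = \beta 1} with
#' \eqn{A_{uv} = 1} for each edge \eqn{u \to v}. Scores are left
#' unnormalized, so a node with no incoming edges scores exactly
#' \eqn{\beta}. Before solving, the convergence precondition
#' \eqn{\alpha \rho(A) < 1} (spectral radius of the adjacency matrix) is
#' verified and violated values are a hard error reporting \eqn{\rho}.
#'
#' @param net a [DirectedInteractionNetwork-class]; edges of every sign and
#'   direction marker count as structural edges, so apply
#'   [trimToDirected()] / [filterActivating()] first.
#' @param alpha attenuation coefficient, default 0.1.
#' @param beta baseline score, default 1.
#' @param nodes optional character vector of additional node names to score
#'   (isolated genes that must keep \eqn{x = \beta}); merged with the edge
#'   endpoints.
#' @return A [CentralityTable-class] with the \code{katz} column filled and
#'   \code{frequencyScore}/\code{combined} set to \code{NA} until
#'   [combinedScores()].
#' @examples
#' net <- DirectedInteractionNetwork(c("A", "B"), c("B", "C"),
#'                                   sign = "activation")
#' scoreTable(katzCentrality(net))  # chain: 1, 1.1, 1.11
#' @export
setMethod("katzCentrality", "DirectedInteractionNetwork",
  function(net, alpha = 0.1, beta = 1, nodes = NULL) {
    genes <- sort(unique(c(networkNodes(net), nodes)))
    n <- length(genes)
    if (n == 0L)
      return(new("CentralityTable",
                 scores = data.frame(gene = character(), katz = numeric(),
                                     frequencyScore = numeric(),
                                     combined = numeric(),
                                     stringsAsFactors = FALSE),
                 alpha = alpha, beta = beta))
    A <- matrix(0, n, n, dimnames = list(genes, genes))
    e <- net@edges
    A[cbind(match(e$source, genes), match(e$target, genes))] <- 1
    rho <- if (nrow(e)) max(Mod(eigen(A, only.values = TRUE)$values)) else 0
    if (alpha * rho >= 1)
      stop("Katz centrality does not converge: alpha * spectral radius = ",
           format(alpha * rho), " (spectral radius ", format(rho),
           "); choose alpha < ", format(1 / rho), call. = FALSE)
    x <- solve(diag(n) - alpha * t(A), rep(beta, n))
    s <- data.frame(gene = genes, katz = as.numeric(x),
                    frequencyScore = NA_real_, combined = NA_real_,
                    stringsAsFactors = FALSE)
    s <- s[order(-s$katz, s$gene), , drop = FALSE]
    rownames(s) <- NULL
    new("CentralityTable", scores = s, alpha = alpha, beta = beta)
  })

#' Combine Katz centrality with targeting frequency
#'
#' Multiplies each gene's Katz centrality by its targeting frequency score,
#' yielding the final combined score (how much the gene is impacted both
#' directly and indirectly). Every scored network gene must have a frequency
#' score; a missing gene is a hard error.
#'
#' @param katz a [CentralityTable-class] from [katzCentrality()].
#' @param freq a [GeneScoreTable-class] from [scoreGenes()].
#' @return The [CentralityTable-class] with \code{frequencyScore} and
#'   \code{combined} filled, sorted by combined score descending then gene
#'   ascending.
#' @export
setMethod("combinedScores", c("CentralityTable", "GeneScoreTable"),
  function(katz, freq) {
    s <- katz@scores
    hit <- match(s$gene, freq@scores$gene)
    if (anyNA(hit))
      stop("no frequency score for network gene(s): ",
           paste(utils::head(s$gene[is.na(hit)], 5), collapse = ", "),
           call. = FALSE)
    s$frequencyScore <- freq@scores$frequencyScore[hit]
    s$combined <- s$katz * s$frequencyScore
    s <- s[order(-s$combined, s$gene), , drop = FALSE]
    rownames(s) <- NULL
    new("CentralityTable", scores = s, alpha = katz@alpha, beta = katz@beta)
  })
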