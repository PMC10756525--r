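# Seeded generators for synthetic study data with a planted convergent
# cluster. The planted structure emulates what the analysis is designed to
# detect: a subset of genes preferentially targeted by the elevated
# signature miRNAs (pCluster vs pBackground) and densely PPI-interconnected
# (qCluster vs qBackground). Setting the cluster parameters equal to the
# background ones yields an exchangeable null. Everything is a pure
# function of the configuration, including its seed; each generator draws
# from its own fixed offset of the seed so the four outputs are mutually
# independent but individually reproducible.

#' Construct a SyntheticConfig
#'
#' Defaults describe the study conditions the package is calibrated on: a
#' signature of 37 elevated and 19 decreased miRNAs (the aggregated
#' circulating-miRNA signature composition), a universe of 300 miRNAs by
#' 1000 genes with background targeting probability 0.02, and a planted
#' cluster of 60 genes targeted at 0.35 by the elevated signature miRNAs
#' and internally PPI-connected at 0.5 (background 0.005). Cluster PPI
#' confidences are drawn high (0.9-1) so they survive stringent thresholds;
#' background confidences span 0.15-0.95.
#'
#' @param nMirnaUniverse,nGenes universe sizes.
#' @param nHigh,nLow signature composition.
#' @param pBackground,pCluster per-pair miRNA-gene targeting probabilities.
#' @param clusterSize number of planted cluster genes.
#' @param qBackground,qCluster per-pair PPI edge probabilities.
#' @param confidenceBackground,confidenceCluster length-2 uniform sampling
#'   ranges for PPI confidences.
#' @param pDirectedEdge per-pair edge probability of the directed-network
#'   generator.
#' @param directedFraction,bidirectionalFraction,inhibitionFraction,unknownFraction
#'   mixture fractions of the directed-network generator.
#' @param seed integer seed.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nMirnaUniverse = 300L, nGenes = 1000L,
                            nHigh = 37L, nLow = 19L, pBackground = 0.02,
                            clusterSize = 60L, pCluster = 0.35,
                            qBackground = 0.005, qCluster = 0.5,
                            confidenceBackground = c(0.15, 0.95),
                            confidenceCluster = c(0.9, 1),
                            pDirectedEdge = 0.03, directedFraction = 0.6,
                            bidirectionalFraction = 0.15,
                            inhibitionFraction = 0.2,
                            unknownFraction = 0.1, seed = 1L) {
  new("SyntheticConfig",
      nMirnaUniverse = as.integer(nMirnaUniverse),
      nGenes = as.integer(nGenes), nHigh = as.integer(nHigh),
      nLow = as.integer(nLow), pBackground = pBackground,
      clusterSize = as.integer(clusterSize), pCluster = pCluster,
      qBackground = qBackground, qCluster = qCluster,
      confidenceBackground = confidenceBackground,
      confidenceCluster = confidenceCluster,
      pDirectedEdge = pDirectedEdge, directedFraction = directedFraction,
      bidirectionalFraction = bidirectionalFraction,
      inhibitionFraction = inhibitionFraction,
      unknownFraction = unknownFraction, seed = as.integer(seed))
}

.synMirnas <- function(cfg)
  sprintf("syn-miR-%04d", seq_len(cfg@nMirnaUniverse))
.synGenes <- function(cfg) sprintf("GENE%04d", seq_len(cfg@nGenes))

# planted designations are deterministic: the first nHigh miRNAs are the
# signature-high set, the next nLow are the low set, the first clusterSize
# genes are the cluster
.synDesign <- function(cfg) {
  m <- .synMirnas(cfg); g <- .synGenes(cfg)
  list(mirnas = m, genes = g,
       highMirnas = m[seq_len(cfg@nHigh)],
       lowMirnas = m[cfg@nHigh + seq_len(cfg@nLow)],
       clusterGenes = g[seq_len(cfg@clusterSize)])
}

#' Generate a synthetic miRNA-target interaction table
#'
#' Every (miRNA, gene) pair is included independently with probability
#' \code{pBackground}, except pairs of a signature-high miRNA with a planted
#' cluster gene, which are included with probability \code{pCluster}.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with elements \code{mti} (a
#'   [TargetInteractionTable-class]), \code{clusterGenes},
#'   \code{highMirnas}, \code{lowMirnas} (ground-truth labels).
#' @export
generateMtiTable <- function(cfg) {
  d <- .synDesign(cfg)
  set.seed(cfg@seed + 1L)
  p <- matrix(cfg@pBackground, cfg@nMirnaUniverse, cfg@nGenes)
  p[match(d$highMirnas, d$mirnas), match(d$clusterGenes, d$genes)] <-
    cfg@pCluster
  hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
  mti <- TargetInteractionTable(d$mirnas[hit[, 1]], d$genes[hit[, 2]],
                                speciesFilter = "synthetic",
                                recordCountRaw = nrow(hit))
  list(mti = mti, clusterGenes = d$clusterGenes,
       highMirnas = d$highMirnas, lowMirnas = d$lowMirnas)
}

#' Generate a synthetic PPI network
#'
#' Each unordered gene pair receives an edge with probability
#' \code{qBackground} (confidence uniform in \code{confidenceBackground});
#' pairs with both endpoints in the planted cluster use \code{qCluster} and
#' \code{confidenceCluster} instead.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param clusterGenes character vector of cluster gene symbols (from
#'   [generateMtiTable()]; defaults to the configuration's planted set).
#' @return An [UndirectedPPINetwork-class].
#' @export
generatePpi <- function(cfg, clusterGenes = NULL) {
  d <- .synDesign(cfg)
  if (is.null(clusterGenes)) clusterGenes <- d$clusterGenes
  set.seed(cfg@seed + 2L)
  n <- cfg@nGenes
  pair <- utils::combn(n, 2L)
  inCl <- d$genes %in% clusterGenes
  cl <- inCl[pair[1, ]] & inCl[pair[2, ]]
  q <- ifelse(cl, cfg@qCluster, cfg@qBackground)
  keep <- stats::runif(ncol(pair)) < q
  a <- pair[1, keep]; b <- pair[2, keep]; clK <- cl[keep]
  lo <- ifelse(clK, cfg@confidenceCluster[1], cfg@confidenceBackground[1])
  hi <- ifelse(clK, cfg@confidenceCluster[2], cfg@confidenceBackground[2])
  conf <- stats::runif(length(a), lo, hi)
  UndirectedPPINetwork(d$genes[a], d$genes[b], conf)
}

#' Generate a synthetic signed, partially directed network
#'
#' Each unordered pair of the supplied genes receives an edge with
#' probability \code{pDirectedEdge}; the edge is marked \code{forward}
#' (random orientation), \code{both} or \code{undirected} according to the
#' configured direction fractions, and signed
#' \code{inhibition}/\code{unknown}/\code{activation} according to the sign
#' fractions. Suitable for exercising [trimToDirected()],
#' [findMissingConnections()], [applyAnnotations()] and
#' [filterActivating()].
#'
#' @param cfg a [SyntheticConfig-class].
#' @param genes character vector of gene symbols to connect; defaults to the
#'   planted cluster genes.
#' @return A [DirectedInteractionNetwork-class] (pre-trimming).
#' @export
generateDirectedNet <- function(cfg, genes = NULL) {
  if (is.null(genes)) genes <- .synDesign(cfg)$clusterGenes
  set.seed(cfg@seed + 3L)
  n <- length(genes)
  if (n < 2L) return(DirectedInteractionNetwork())
  pair <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pair)) < cfg@pDirectedEdge
  a <- pair[1, keep]; b <- pair[2, keep]
  m <- length(a)
  if (m == 0L) return(DirectedInteractionNetwork())
  u <- stats::runif(m)
  dirn <- ifelse(u < cfg@directedFraction, "forward",
                 ifelse(u < cfg@directedFraction + cfg@bidirectionalFraction,
                        "both", "undirected"))
  v <- stats::runif(m)
  sgn <- ifelse(v < cfg@inhibitionFraction, "inhibition",
                ifelse(v < cfg@inhibitionFraction + cfg@unknownFraction,
                       "unknown", "activation"))
  flip <- stats::runif(m) < 0.5
  src <- ifelse(flip, genes[b], genes[a])
  tgt <- ifelse(flip, genes[a], genes[b])
  DirectedInteractionNetwork(src, tgt, dirn, sgn, "synthetic")
}

#' Generate the planted synthetic signature
#'
#' The designated \code{nHigh} planted miRNAs labelled high plus the
#' \code{nLow} designated non-planted miRNAs labelled low; deterministic
#' given the configuration.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return A [MiRNASignature-class] with source tag \code{"synthetic"}.
#' @export
generateSignature <- function(cfg) {
  d <- .synDesign(cfg)
  MiRNASignature(c(d$highMirnas, d$lowMirnas),
                 rep(c("high", "low"), c(cfg@nHigh, cfg@nLow)),
                 "synthetic")
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper producing the signature, interaction table, PPI
#' network and directed network (over the planted cluster genes) for one
#' configuration.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with elements \code{signature}, \code{mti}, \code{ppi},
#'   \code{directed}, \code{clusterGenes}.
#' @export
generateBundle <- function(cfg) {
  gen <- generateMtiTable(cfg)
  list(signature = generateSignature(cfg), mti = gen$mti,
       ppi = generatePpi(cfg, gen$clusterGenes),
       directed = generateDirectedNet(cfg, gen$clusterGenes),
       clusterGenes = gen$clusterGenes)
}
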