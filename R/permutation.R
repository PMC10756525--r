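# Resampling null for target-set convergence. Random signatures of matched
# composition (same number of high and low miRNAs, drawn from the
# interaction table's miRNA universe) are scored in exactly the same fashion
# as the observed signature, and two statistics are compared: the summed
# frequency score of the top-k genes, and the number of PPI connections
# among those k genes at each confidence threshold.

#' Draw a random signature of matched composition
#'
#' Samples \code{nHigh + nLow} miRNAs uniformly without replacement from the
#' given universe; the first \code{nHigh} are labelled high, the remainder
#' low (so the two groups never overlap). Uses R's current RNG stream: call
#' \code{set.seed()} beforehand for reproducibility.
#'
#' @param universe character vector of distinct candidate miRNA ids
#'   (typically \code{unique(interactionPairs(mti)$mirna)}).
#' @param nHigh,nLow group sizes.
#' @return A [MiRNASignature-class] with sources tagged \code{"resampled"}.
#' @export
sampleRandomSignature <- function(universe, nHigh, nLow) {
  universe <- unique(universe)
  n <- nHigh + nLow
  if (length(universe) < n)
    stop("miRNA universe (", length(universe),
         ") smaller than requested signature size (", n, ")", call. = FALSE)
  if (n == 0L) return(MiRNASignature())
  draw <- universe[sample.int(length(universe), n)]
  MiRNASignature(draw, rep(c("high", "low"), c(nHigh, nLow)), "resampled")
}

# Threshold-prefiltered PPI edge endpoints as indices into a gene universe.
# Edges with an endpoint outside the universe can never join a top-k set and
# are discarded up front.
.ppiEdgeIndex <- function(ppi, genes, thresholds) {
  e <- ppi@edges
  ia <- match(e$geneA, genes); ib <- match(e$geneB, genes)
  keep <- !is.na(ia) & !is.na(ib)
  lapply(stats::setNames(thresholds, format(thresholds)), function(th) {
    sel <- keep & e$confidence >= th
    list(a = ia[sel], b = ib[sel])
  })
}

#' Count PPI connections within a gene set
#'
#' Number of undirected PPI edges whose two endpoints both belong to
#' \code{genes} and whose confidence is at least \code{threshold}.
#'
#' @param genes character vector of gene symbols.
#' @param ppi an [UndirectedPPINetwork-class].
#' @param threshold confidence threshold in \eqn{[0, 1]} (inclusive).
#' @return integer edge count.
#' @examples
#' ppi <- UndirectedPPINetwork(c("A", "A", "B"), c("B", "C", "C"),
#'                             c(0.95, 0.95, 0.95))
#' edgeCountAmong(c("A", "B", "C"), ppi, 0.9)  # the full triangle: 3
#' @export
edgeCountAmong <- function(genes, ppi, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  e <- ppi@edges
  sum(e$confidence >= threshold & e$geneA %in% genes & e$geneB %in% genes)
}

#' Permutation test for target-set convergence and interconnectivity
#'
#' Compares the observed signature against \code{nIter} random signatures of
#' matched high/low composition drawn from the interaction table's miRNA
#' universe. Every random signature is scored exactly as the observed one:
#' genes are scored by targeting frequency, the top \code{k} genes are
#' selected (score descending, gene ascending on ties), and two statistics
#' are recorded — the summed frequency score of those \code{k} genes, and
#' the number of PPI connections among them at each confidence threshold.
#'
#' Two empirical p-value conventions are reported per statistic:
#' \code{pStrict = r/N} (null values strictly greater than observed) and
#' \code{pAddone = (r' + 1)/(N + 1)} (null values \eqn{\ge} observed, add
#' one), the latter never exactly zero.
#'
#' @param signature the observed [MiRNASignature-class].
#' @param mti a [TargetInteractionTable-class]; its distinct miRNAs form the
#'   resampling universe (the observed miRNAs are not excluded).
#' @param ppi an [UndirectedPPINetwork-class].
#' @param nIter number of random signatures (default 10000).
#' @param k top-gene count for both statistics (default 100).
#' @param thresholds PPI confidence thresholds (default 0.4, 0.7, 0.9).
#' @param seed integer seed; the whole run is a pure function of
#'   (inputs, seed).
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(signature, mti, ppi, nIter = 10000L, k = 100L,
                            thresholds = c(0.4, 0.7, 0.9), seed = 1L) {
  stopifnot(nIter >= 1, k >= 1)
  idx <- .mtiIndex(mti)
  nU <- length(idx$mirnas)
  nh <- nHigh(signature); nl <- nLow(signature)
  if (nU < nh + nl)
    stop("miRNA universe (", nU, ") smaller than signature size (",
         nh + nl, ")", call. = FALSE)
  edgeIdx <- .ppiEdgeIndex(ppi, idx$genes, thresholds)
  thrNames <- names(edgeIdx)
  nG <- length(idx$genes)

  # both statistics for a high/low split given as miRNA indices
  statsFor <- function(hiIdx, loIdx) {
    hi <- tabulate(as.integer(unlist(idx$targets[hiIdx], use.names = FALSE)),
                   nbins = nG)
    lo <- tabulate(as.integer(unlist(idx$targets[loIdx], use.names = FALSE)),
                   nbins = nG)
    freq <- hi - lo
    targeted <- which(hi + lo > 0L)
    ord <- targeted[order(-freq[targeted], idx$genes[targeted])]
    sel <- ord[seq_len(min(k, length(ord)))]
    member <- logical(nG); member[sel] <- TRUE
    edges <- vapply(edgeIdx, function(ei) sum(member[ei$a] & member[ei$b]),
                    numeric(1))
    list(sum = sum(freq[sel]), edges = edges)
  }

  lookup <- function(ids) {
    hit <- match(tolower(ids), tolower(idx$mirnas))
    hit[!is.na(hit)]
  }
  obs <- statsFor(lookup(highMirnas(signature)),
                  lookup(lowMirnas(signature)))

  set.seed(seed)
  nullSums <- numeric(nIter)
  nullEdges <- matrix(0, nrow = nIter, ncol = length(thrNames),
                      dimnames = list(NULL, thrNames))
  for (i in seq_len(nIter)) {
    draw <- sample.int(nU, nh + nl)
    st <- statsFor(draw[seq_len(nh)], draw[nh + seq_len(nl)])
    nullSums[i] <- st$sum
    nullEdges[i, ] <- st$edges
  }

  pS <- function(null, o) sum(null > o) / nIter
  pA <- function(null, o) (sum(null >= o) + 1) / (nIter + 1)
  new("PermutationResult",
      observedSum = obs$sum, observedEdges = obs$edges,
      nullSums = nullSums,
      nullEdges = lapply(stats::setNames(thrNames, thrNames),
                         function(th) nullEdges[, th]),
      nIter = as.integer(nIter), k = as.integer(k), seed = as.integer(seed),
      pStrict = list(sum = pS(nullSums, obs$sum),
                     edges = vapply(thrNames, function(th)
                       pS(nullEdges[, th], obs$edges[[th]]), numeric(1))),
      pAddone = list(sum = pA(nullSums, obs$sum),
                     edges = vapply(thrNames, function(th)
                       pA(nullEdges[, th], obs$edges[[th]]), numeric(1))))
}
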