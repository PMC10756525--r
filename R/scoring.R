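# Per-gene targeting-frequency scoring. The score of a gene is the number
# of distinct elevated signature miRNAs with a recorded interaction to it,
# minus the number of distinct decreased ones. Internally both the public
# scorer and the permutation loop share one indexed representation of the
# interaction table so they cannot drift apart.

# Integer-indexed view of a TargetInteractionTable: sorted miRNA and gene
# universes plus, per miRNA, the integer indices of its target genes.
.mtiIndex <- function(mti) {
  p <- mti@pairs
  mirnas <- sort(unique(p$mirna))
  genes <- sort(unique(p$gene))
  targets <- split(match(p$gene, genes), factor(p$mirna, levels = mirnas))
  list(mirnas = mirnas, genes = genes,
       targets = lapply(targets, as.integer))
}

# High/low counts over the full gene universe for a set of miRNA ids
# (case-insensitive match against the index).
.countsFromIndex <- function(idx, highIds, lowIds) {
  lookup <- function(ids) {
    hit <- match(tolower(ids), tolower(idx$mirnas))
    hit[!is.na(hit)]
  }
  hi <- lookup(highIds); lo <- lookup(lowIds)
  nG <- length(idx$genes)
  high <- tabulate(as.integer(unlist(idx$targets[hi], use.names = FALSE)),
                   nbins = nG)
  low <- tabulate(as.integer(unlist(idx$targets[lo], use.names = FALSE)),
                  nbins = nG)
  list(high = high, low = low,
       nMatched = length(hi) + length(lo))
}

#' Score genes by miRNA-targeting frequency
#'
#' For each gene in the interaction table, counts how many distinct elevated
#' (high) signature miRNAs target it and how many distinct decreased (low)
#' ones do; the difference of the two counts is the gene's targeting
#' frequency score. Genes targeted by no signature miRNA are omitted.
#' Signature miRNAs entirely absent from the table trigger a warning (they
#' simply contribute nothing), not an error.
#'
#' @param signature a non-empty [MiRNASignature-class].
#' @param mti a [TargetInteractionTable-class].
#' @return A [GeneScoreTable-class], sorted by frequency score descending
#'   then gene ascending.
#' @examples
#' sig <- MiRNASignature(c("m1", "m2", "m3"), c("high", "high", "low"), "s")
#' mti <- TargetInteractionTable(c("m1", "m2", "m3"), c("G1", "G1", "G1"))
#' scoreTable(scoreGenes(sig, mti))  # G1: 2 high - 1 low = 1
#' @export
setMethod("scoreGenes", c("MiRNASignature", "TargetInteractionTable"),
  function(signature, mti) {
    if (length(signature@mirna) == 0L)
      stop("signature is empty", call. = FALSE)
    idx <- .mtiIndex(mti)
    cn <- .countsFromIndex(idx, highMirnas(signature), lowMirnas(signature))
    if (cn$nMatched == 0L)
      warning("no signature miRNA is present in the interaction table")
    else if (cn$nMatched < length(signature@mirna))
      message(length(signature@mirna) - cn$nMatched,
              " signature miRNA(s) absent from the interaction table")
    keep <- cn$high + cn$low > 0L
    .newGeneScoreTable(idx$genes[keep], cn$high[keep], cn$low[keep])
  })

#' Select the top-k genes by frequency score
#'
#' Genes are sorted by frequency score descending with ties broken by gene
#' symbol ascending (a fixed deterministic rule so downstream permutation
#' statistics are reproducible). When genes tied with the k-th entry are
#' excluded by the cut, the returned vector carries attribute
#' \code{tieAtBoundary = TRUE} to flag that a different tie rule could give
#' a different set.
#'
#' @param scores a [GeneScoreTable-class].
#' @param k number of genes to select (\code{k >= 1}); capped at the table
#'   size.
#' @return character vector of gene symbols (ordered), with attribute
#'   \code{tieAtBoundary}.
#' @export
selectTopK <- function(scores, k) {
  stopifnot(k >= 1)
  s <- scores@scores  # already sorted (-score, gene)
  n <- min(k, nrow(s))
  out <- s$gene[seq_len(n)]
  tie <- n > 0 && nrow(s) > n && s$frequencyScore[n + 1] == s$frequencyScore[n]
  attr(out, "tieAtBoundary") <- tie
  out
}

#' Select genes at or above a score threshold
#'
#' @param scores a [GeneScoreTable-class].
#' @param minScore minimum frequency score (inclusive).
#' @return character vector of gene symbols, sorted by score descending then
#'   symbol ascending.
#' @export
selectByThreshold <- function(scores, minScore) {
  s <- scores@scores
  s$gene[s$frequencyScore >= minScore]
}
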