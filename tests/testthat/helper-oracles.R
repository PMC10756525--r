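# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no .mtiIndex, no igraph, no linear solve) so that
# agreement between the two routes is informative.

# recount per-gene high/low targeting straight off the raw pair list
oracleScores <- function(signature, mti) {
  p <- interactionPairs(mti)
  hi <- tolower(highMirnas(signature)); lo <- tolower(lowMirnas(signature))
  genes <- sort(unique(p$gene))
  out <- data.frame(gene = character(), highCount = integer(),
                    lowCount = integer(), frequencyScore = integer(),
                    stringsAsFactors = FALSE)
  for (g in genes) {
    ms <- tolower(unique(p$mirna[p$gene == g]))
    h <- sum(ms %in% hi); l <- sum(ms %in% lo)
    if (h + l > 0)
      out <- rbind(out, data.frame(gene = g, highCount = h, lowCount = l,
                                   frequencyScore = h - l,
                                   stringsAsFactors = FALSE))
  }
  out[order(-out$frequencyScore, out$gene), , drop = FALSE]
}

# quadratic all-pairs edge count
oracleEdgeCount <- function(genes, ppi, threshold) {
  e <- networkEdges(ppi)
  n <- 0L
  for (i in seq_len(nrow(e)))
    if (e$confidence[i] >= threshold && e$geneA[i] %in% genes &&
        e$geneB[i] %in% genes)
      n <- n + 1L
  n
}

# truncated Katz walk series: x = beta * sum_{k=0..K} alpha^k (A^T)^k 1
oracleKatzSeries <- function(A, alpha, beta, K = 40L) {
  n <- nrow(A)
  x <- rep(0, n); v <- rep(1, n)
  for (k in 0:K) {
    x <- x + alpha^k * v
    v <- t(A) %*% v
  }
  as.numeric(beta * x)
}

# exhaustive recursive simple-path enumeration over an adjacency list
oraclePaths <- function(adj, from, maxLen) {
  out <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (length(path) - 1L >= maxLen) return()
    for (nxt in adj[[last]]) {
      if (nxt %in% path) next
      p2 <- c(path, nxt)
      out[[length(out) + 1L]] <<- p2
      recurse(p2)
    }
  }
  recurse(from)
  out
}

adjListOf <- function(net, nodes = NULL) {
  e <- networkEdges(net)
  nodes <- sort(unique(c(nodes, e$source, e$target)))
  adj <- stats::setNames(lapply(nodes, function(v)
    sort(e$target[e$source == v])), nodes)
  adj
}

# influence by exhaustive enumeration (sum over paths of alpha^len times
# endpoint score)
oracleInfluence <- function(adj, from, scores, alpha, maxLen) {
  if (!(from %in% names(adj))) adj[[from]] <- character()
  paths <- oraclePaths(adj, from, maxLen)
  total <- 0
  for (p in paths) {
    g <- p[length(p)]
    if (g %in% names(scores))
      total <- total + scores[[g]] * alpha^(length(p) - 1L)
  }
  total
}

# exact permutation p for tiny universes: enumerate every (high set, low
# set) split and compare the top-k summed score against the observed
oracleExactP <- function(signature, mti, k) {
  p <- interactionPairs(mti)
  universe <- sort(unique(p$mirna))
  nh <- nHigh(signature); nl <- nLow(signature)
  statOf <- function(hi, lo) {
    tab <- oracleScores(MiRNASignature(c(hi, lo),
                                       rep(c("high", "low"),
                                           c(length(hi), length(lo))),
                                       "x"), mti)
    sum(utils::head(tab$frequencyScore, k))
  }
  obs <- statOf(highMirnas(signature), lowMirnas(signature))
  vals <- numeric()
  hiSets <- utils::combn(universe, nh, simplify = FALSE)
  for (hi in hiSets) {
    rest <- setdiff(universe, hi)
    for (lo in utils::combn(rest, nl, simplify = FALSE))
      vals <- c(vals, statOf(hi, lo))
  }
  list(observed = obs, null = vals, pStrict = mean(vals > obs))
}

# random activation-only directed network helpers for property tests
randomActivatingNet <- function(nNodes, p = 0.15, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(nNodes))
  src <- character(); tgt <- character()
  for (i in seq_len(nNodes)) for (j in seq_len(nNodes)) {
    if (i != j && stats::runif(1) < p) {
      src <- c(src, labels[i]); tgt <- c(tgt, labels[j])
    }
  }
  DirectedInteractionNetwork(src, tgt, sign = "activation")
}

writeTempSignature <- function(mirna, direction, dir = tempdir()) {
  f <- tempfile("sig", tmpdir = dir, fileext = ".tsv")
  utils::write.table(data.frame(mirna_id = mirna, direction = direction),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# write a synthetic bundle to disk in the external-file dialects, returning
# a runConfig pointing at it
bundleConfig <- function(b, dir = tempfile("run"), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sigFile <- file.path(dir, "signature.tsv")
  utils::write.table(
    data.frame(mirna_id = mirnaIds(b$signature),
               direction = b$signature@direction),
    sigFile, sep = "\t", quote = FALSE, row.names = FALSE)
  writeMtiTable(b$mti, file.path(dir, "mti.tsv"))
  writePpiNetwork(b$ppi, file.path(dir, "ppi.tsv"))
  writeDirectedNetwork(b$directed, file.path(dir, "directed.tsv"))
  runConfig(signatureFiles = c(synthetic = sigFile),
            mtiFile = file.path(dir, "mti.tsv"),
            ppiFile = file.path(dir, "ppi.tsv"),
            directedFile = file.path(dir, "directed.tsv"),
            species = "synthetic", ppiScoreScale = "0-1", ...)
}
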