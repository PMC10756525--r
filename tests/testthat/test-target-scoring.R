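makeMti <- function(mirna, gene)
  TargetInteractionTable(mirna, gene, speciesFilter = "synthetic")

test_that("frequency score is distinct-high minus distinct-low", {
  sig <- MiRNASignature(c("m1", "m2", "m3", "m4"),
                        c("high", "high", "high", "low"), "s")
  mti <- makeMti(c("m1", "m2", "m3", "m4", "m1"),
                 c("G1", "G1", "G1", "G1", "G2"))
  tab <- scoreTable(scoreGenes(sig, mti))
  expect_equal(tab$frequencyScore[tab$gene == "G1"], 2L)  # 3 high - 1 low
  expect_equal(tab$highCount[tab$gene == "G2"], 1L)

  # empty intersection -> empty table, with a warning
  other <- MiRNASignature("mX", "high", "s")
  expect_warning(empty <- scoreGenes(other, mti), "no signature miRNA")
  expect_equal(nrow(scoreTable(empty)), 0L)
})

test_that("scores match a brute-force recount on planted-cluster data", {
  cfg <- syntheticConfig(nMirnaUniverse = 40, nGenes = 60, nHigh = 8,
                         nLow = 4, clusterSize = 12, pBackground = 0.05,
                         pCluster = 0.6, seed = 31)
  gen <- generateMtiTable(cfg)
  sig <- generateSignature(cfg)
  got <- scoreTable(scoreGenes(sig, gen$mti))
  want <- oracleScores(sig, gen$mti)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
  # the planted cluster genes out-score background on average
  inCl <- got$gene %in% gen$clusterGenes
  expect_gt(mean(got$frequencyScore[inCl]),
            mean(got$frequencyScore[!inCl]))
})

test_that("adding a high miRNA never decreases targeted-gene scores", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 15
    mirnas <- sprintf("m%02d", 1:8)
    genes <- sprintf("G%02d", 1:n)
    pairs <- expand.grid(mirna = mirnas, gene = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.3, ]
    mti <- makeMti(pairs$mirna, pairs$gene)
    sig <- MiRNASignature(mirnas[1:5],
                          c("high", "high", "low", "low", "high"), "s")
    base <- scoreTable(scoreGenes(sig, mti))
    sig2 <- MiRNASignature(mirnas[1:6],
                           c("high", "high", "low", "low", "high", "high"),
                           "s")
    more <- scoreTable(scoreGenes(sig2, mti))
    newTargets <- pairs$gene[pairs$mirna == mirnas[6]]
    for (g in base$gene) {
      b <- base$frequencyScore[base$gene == g]
      m <- more$frequencyScore[more$gene == g]
      if (g %in% newTargets) expect_gte(m, b) else expect_equal(m, b)
    }
  }
})

test_that("swapping high/low labels negates every score", {
  cfg <- syntheticConfig(nMirnaUniverse = 25, nGenes = 40, nHigh = 6,
                         nLow = 6, clusterSize = 10, seed = 13)
  gen <- generateMtiTable(cfg)
  sig <- generateSignature(cfg)
  flipped <- MiRNASignature(mirnaIds(sig),
                            ifelse(sig@direction == "high", "low", "high"),
                            "s")
  a <- scoreTable(scoreGenes(sig, gen$mti))
  b <- scoreTable(scoreGenes(flipped, gen$mti))
  b <- b[match(a$gene, b$gene), ]
  expect_equal(b$frequencyScore, -a$frequencyScore)
  expect_equal(b$highCount, a$lowCount)
})

test_that("count totals are conserved against the raw pair list", {
  cfg <- syntheticConfig(nMirnaUniverse = 30, nGenes = 50, nHigh = 7,
                         nLow = 5, clusterSize = 10, seed = 17)
  gen <- generateMtiTable(cfg)
  sig <- generateSignature(cfg)
  tab <- scoreTable(scoreGenes(sig, gen$mti))
  p <- interactionPairs(gen$mti)
  expect_equal(sum(tab$highCount),
               sum(p$mirna %in% highMirnas(sig)))
  expect_equal(sum(tab$lowCount),
               sum(p$mirna %in% lowMirnas(sig)))
})

test_that("top-k selection is deterministic and flags boundary ties", {
  sig <- MiRNASignature(c("m1", "m2"), c("high", "high"), "s")
  mti <- makeMti(c("m1", "m2", "m1", "m1", "m2"),
                 c("GB", "GB", "GA", "GC", "GD"))
  gs <- scoreGenes(sig, mti)  # GB:2, GA/GC/GD: 1
  top2 <- selectTopK(gs, 2)
  expect_equal(as.character(top2), c("GB", "GA"))  # lexicographic tie-break
  expect_true(attr(top2, "tieAtBoundary"))
  all4 <- selectTopK(gs, 99)
  expect_length(all4, 4L)
  expect_false(attr(all4, "tieAtBoundary"))
})

test_that("top-k summed score equals the exhaustive k-subset maximum", {
  set.seed(7)
  for (rep in 1:5) {
    genes <- sprintf("G%02d", 1:10)
    mirnas <- sprintf("m%d", 1:9)
    pairs <- expand.grid(mirna = mirnas, gene = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[runif(nrow(pairs)) < 0.35, ]
    if (!nrow(pairs)) next
    mti <- makeMti(pairs$mirna, pairs$gene)
    sig <- MiRNASignature(mirnas, rep(c("high", "low", "high"), each = 3),
                          "s")
    gs <- scoreGenes(sig, mti)
    tab <- scoreTable(gs)
    k <- min(4, nrow(tab))
    got <- sum(tab$frequencyScore[match(selectTopK(gs, k), tab$gene)])
    best <- max(vapply(utils::combn(nrow(tab), k, simplify = FALSE),
                       function(ix) sum(tab$frequencyScore[ix]),
                       numeric(1)))
    expect_equal(got, best)
  }
})

test_that("threshold selection honors the cutoff inclusively", {
  sig <- MiRNASignature(c("m1", "m2", "m3"), c("high", "high", "low"), "s")
  mti <- makeMti(c("m1", "m2", "m1", "m3"), c("GA", "GA", "GB", "GC"))
  gs <- scoreGenes(sig, mti)  # GA:2, GB:1, GC:-1
  expect_equal(selectByThreshold(gs, 5), character(0))
  expect_equal(selectByThreshold(gs, 2), "GA")
  expect_equal(selectByThreshold(gs, -100), c("GA", "GB", "GC"))
})
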