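# CentralityTable with prescribed combined scores (katz set to 1)
scoresOf <- function(...) {
  s <- c(...)
  d <- data.frame(gene = names(s), katz = 1, frequencyScore = unname(s),
                  combined = unname(s), stringsAsFactors = FALSE)
  new("CentralityTable", scores = d, alpha = 0.1, beta = 1)
}

test_that("influence graph has the constructed node and edge sets", {
  net <- DirectedInteractionNetwork(c("g1", "g2"), c("g2", "g3"),
                                    sign = "activation")
  mti <- TargetInteractionTable(c("m1", "m1", "m2", "m3"),
                                c("g1", "g9", "g2", "g9"))
  g <- buildInfluenceGraph(c("m1", "m2", "m3"), mti, net)
  expect_equal(igraph::vcount(g), 3L + 3L)
  # m1->g1, m2->g2 (g9 outside the network) + 2 gene-gene edges
  expect_equal(igraph::ecount(g), 2L + 2L)
  # m3 targets only g9: isolated node
  expect_equal(igraph::degree(g, "m3"), c(m3 = 0))
  # no edges into miRNA nodes
  expect_equal(unname(igraph::degree(g, c("m1", "m2", "m3"),
                                     mode = "in")), c(0, 0, 0))
})

test_that("simple-path enumeration handles the diamond and direct edge", {
  net <- DirectedInteractionNetwork(c("g1", "g2"), c("g3", "g3"),
                                    sign = "activation")
  mti <- TargetInteractionTable(c("m", "m"), c("g1", "g2"))
  g <- buildInfluenceGraph("m", mti, net)
  ps <- enumerateSimplePaths(g, "m", "g3", maxLen = 5)
  expect_length(ps$paths, 2L)
  expect_equal(sort(ps$lengths), c(2L, 2L))
  direct <- enumerateSimplePaths(g, "m", "g1", maxLen = 5)
  expect_equal(direct$lengths, 1L)
})

test_that("path sets match exhaustive DFS enumeration on random DAG-ish graphs", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    net <- randomActivatingNet(n, p = 0.25)
    mti <- TargetInteractionTable(c("mm", "mm"),
                                  c("N01", sprintf("N%02d", min(2, n))))
    g <- buildInfluenceGraph("mm", mti, net,
                             genes = sprintf("N%02d", seq_len(n)))
    adj <- adjListOf(net)
    adj[["mm"]] <- sort(unique(interactionPairs(mti)$gene))
    for (target in sprintf("N%02d", seq_len(n))) {
      got <- enumerateSimplePaths(g, "mm", target, maxLen = 6)
      want <- Filter(function(p) p[length(p)] == target,
                     oraclePaths(adj, "mm", 6))
      canon <- function(paths) sort(vapply(paths, paste, character(1),
                                           collapse = ">"))
      expect_equal(canon(got$paths), canon(want))
    }
  }
})

test_that("influence matches the hand-worked examples", {
  # single direct target with s_g = 10: I = 10 * 0.1 = 1
  net <- DirectedInteractionNetwork()
  mti <- TargetInteractionTable("m", "g1")
  g <- buildInfluenceGraph("m", mti, net, genes = "g1")
  expect_equal(influenceScore("m", g, scoresOf(g1 = 10)), 1.0,
               tolerance = 1e-12)

  # chain m -> g1 -> g2 with s = (5, 10): I = 5*0.1 + 10*0.01 = 0.6
  net2 <- DirectedInteractionNetwork("g1", "g2", sign = "activation")
  g2 <- buildInfluenceGraph("m", TargetInteractionTable("m", "g1"), net2)
  expect_equal(influenceScore("m", g2, scoresOf(g1 = 5, g2 = 10)), 0.6,
               tolerance = 1e-12)

  # two paths of lengths 1 and 2 to one gene with s = 1: 0.1 + 0.01
  net3 <- DirectedInteractionNetwork("ga", "gb", sign = "activation")
  g3 <- buildInfluenceGraph(
    "m", TargetInteractionTable(c("m", "m"), c("ga", "gb")), net3)
  expect_equal(influenceScore("m", g3, scoresOf(ga = 0, gb = 1)), 0.11,
               tolerance = 1e-12)

  expect_error(influenceScore("absent", g3, scoresOf(ga = 0, gb = 1)),
               "not a node")
})

test_that("influence equals exhaustive enumeration on random graphs", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:11, 1)
    net <- randomActivatingNet(n, p = 0.2)
    genes <- sprintf("N%02d", seq_len(n))
    targets <- sample(genes, sample(1:3, 1))
    mti <- TargetInteractionTable(rep("mm", length(targets)), targets)
    g <- buildInfluenceGraph("mm", mti, net, genes = genes)
    sv <- stats::setNames(round(runif(n, 0, 10), 2), genes)
    tab <- do.call(scoresOf, as.list(sv))
    adj <- adjListOf(net, nodes = genes)
    adj[["mm"]] <- sort(unique(targets))
    for (L in c(3, 6)) {
      expect_equal(influenceScore("mm", g, tab, alpha = 0.1, maxLen = L),
                   oracleInfluence(adj, "mm", as.list(sv), 0.1, L),
                   tolerance = 1e-12)
    }
  }
})

test_that("influence is additive over disconnected components", {
  netA <- DirectedInteractionNetwork("a1", "a2", sign = "activation")
  netB <- DirectedInteractionNetwork("b1", "b2", sign = "activation")
  both <- DirectedInteractionNetwork(c("a1", "b1"), c("a2", "b2"),
                                     sign = "activation")
  sc <- scoresOf(a1 = 2, a2 = 4, b1 = 1, b2 = 3)
  mtiA <- TargetInteractionTable("m", "a1")
  mtiB <- TargetInteractionTable("m", "b1")
  mtiBoth <- TargetInteractionTable(c("m", "m"), c("a1", "b1"))
  iA <- influenceScore("m", buildInfluenceGraph("m", mtiA, netA), sc)
  iB <- influenceScore("m", buildInfluenceGraph("m", mtiB, netB), sc)
  iBoth <- influenceScore("m", buildInfluenceGraph("m", mtiBoth, both), sc)
  expect_equal(iBoth, iA + iB, tolerance = 1e-12)
})

test_that("influence grows with path cap and attenuation factor", {
  net <- DirectedInteractionNetwork(sprintf("g%d", 1:5),
                                    sprintf("g%d", 2:6),
                                    sign = "activation")
  mti <- TargetInteractionTable("m", "g1")
  g <- buildInfluenceGraph("m", mti, net)
  sc <- do.call(scoresOf, as.list(stats::setNames(rep(1, 6),
                                                  sprintf("g%d", 1:6))))
  vals <- vapply(1:6, function(L)
    influenceScore("m", g, sc, maxLen = L), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_lt(influenceScore("m", g, sc, alpha = 0.05),
            influenceScore("m", g, sc, alpha = 0.2))
})

test_that("miRNA ranking is deterministic, symmetric, and localized", {
  net <- DirectedInteractionNetwork("g1", "g2", sign = "activation")
  mti <- TargetInteractionTable(c("m1", "m2", "m3"),
                                c("g1", "g1", "g2"))
  g <- buildInfluenceGraph(c("m1", "m2", "m3"), mti, net)
  sc <- scoresOf(g1 = 5, g2 = 10)
  res <- scoreTable(rankMirnas(c("m1", "m2", "m3"), g, sc))
  # identical target sets give identical influence; tie broken by id
  expect_equal(res$influence[res$mirna == "m1"],
               res$influence[res$mirna == "m2"])
  # m3 hits g2 directly (10 * 0.1 = 1) and outranks the m1/m2 tie (0.6)
  expect_equal(res$mirna, c("m3", "m1", "m2"))
  # removing m3's only edge zeroes its influence, others unchanged
  mti2 <- TargetInteractionTable(c("m1", "m2"), c("g1", "g1"))
  g2 <- buildInfluenceGraph(c("m1", "m2", "m3"), mti2, net)
  res2 <- scoreTable(rankMirnas(c("m1", "m2", "m3"), g2, sc))
  expect_equal(res2$influence[res2$mirna == "m3"], 0)
  expect_equal(res2$influence[res2$mirna == "m1"],
               res$influence[res$mirna == "m1"])
  # all-zero gene scores -> all-zero influence
  res3 <- scoreTable(rankMirnas(c("m1", "m2", "m3"), g,
                                scoresOf(g1 = 0, g2 = 0)))
  expect_true(all(res3$influence == 0))
})
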