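test_that("trimming drops undirected edges and splits bidirectional ones", {
  net <- DirectedInteractionNetwork(
    c("A", "C", "E"), c("B", "D", "F"),
    direction = c("undirected", "forward", "both"),
    sign = c("unknown", "activation", "activation"))
  out <- networkEdges(trimToDirected(net))
  expect_equal(nrow(out), 3L)
  expect_true(all(out$direction == "forward"))
  key <- paste(out$source, out$target)
  expect_setequal(key, c("C D", "E F", "F E"))

  allUndir <- DirectedInteractionNetwork(c("A", "B"), c("B", "C"),
                                         direction = "undirected")
  expect_equal(nrow(networkEdges(trimToDirected(allUndir))), 0L)
})

test_that("trimmed edge count = directed + 2 x bidirectional on random inputs", {
  for (seed in 1:5) {
    cfg <- syntheticConfig(nMirnaUniverse = 10, nGenes = 40, nHigh = 3,
                           nLow = 2, clusterSize = 25, pDirectedEdge = 0.25,
                           seed = seed)
    net <- generateDirectedNet(cfg)
    e <- networkEdges(net)
    out <- networkEdges(trimToDirected(net))
    expect_equal(nrow(out),
                 sum(e$direction == "forward") + 2L * sum(e$direction == "both"))
  }
  # degenerate: all forward -> trimming is the identity on edges
  cfgF <- syntheticConfig(nMirnaUniverse = 10, nGenes = 30, nHigh = 3,
                          nLow = 2, clusterSize = 20, pDirectedEdge = 0.3,
                          directedFraction = 1, bidirectionalFraction = 0,
                          seed = 3)
  netF <- generateDirectedNet(cfgF)
  expect_equal(networkEdges(trimToDirected(netF)), networkEdges(netF))
})

test_that("cross-referencing reports only absent high-confidence pairs", {
  net <- DirectedInteractionNetwork(c("A", "C"), c("B", "D"),
                                    sign = "activation")
  ppi <- UndirectedPPINetwork(c("A", "A", "B", "A"),
                              c("B", "C", "D", "Z"),
                              c(0.96, 0.96, 0.94, 0.99))
  miss <- findMissingConnections(net, ppi, 0.95)
  # A-B covered by the net; B-D below threshold; A-Z outside the node set
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$geneA, "A")
  expect_equal(miss$geneB, "C")
  # an edge in the reverse direction also counts as covered
  net2 <- DirectedInteractionNetwork(c("C"), c("A"), sign = "activation")
  expect_equal(nrow(findMissingConnections(net2, ppi, 0.95)), 0L)
})

test_that("annotations add resolved edges without overwriting", {
  net <- DirectedInteractionNetwork("A", "B", sign = "activation")
  ann <- AnnotationTable(c("B", "C", "D"), c("C", "E", "A"),
                         c("a_to_b", "none", "both"),
                         c("activation", "unknown", "inhibition"))
  out <- networkEdges(applyAnnotations(net, ann))
  key <- paste(out$source, out$target, out$sign)
  expect_setequal(key, c("A B activation", "B C activation",
                         "D A inhibition", "A D inhibition"))
  # conflicting sign on an existing ordered pair is a hard error
  bad <- AnnotationTable("A", "B", "a_to_b", "inhibition")
  expect_error(applyAnnotations(net, bad), "conflicts")
  # same sign on an existing pair is a no-op
  same <- AnnotationTable("A", "B", "a_to_b", "activation")
  expect_equal(networkEdges(applyAnnotations(net, same)),
               networkEdges(net))
})

test_that("activating filter keeps only activation edges and is idempotent", {
  net <- DirectedInteractionNetwork(
    c("A", "B", "C"), c("B", "C", "A"),
    sign = c("activation", "inhibition", "unknown"))
  act <- filterActivating(net)
  expect_equal(networkEdges(act)$sign, "activation")
  expect_equal(networkEdges(filterActivating(act)), networkEdges(act))
  allInhib <- DirectedInteractionNetwork(c("A", "B"), c("B", "C"),
                                         sign = "inhibition")
  expect_equal(nrow(networkEdges(filterActivating(allInhib))), 0L)
})

test_that("Katz centrality solves the hand-checkable cases", {
  # edgeless graph: every score is beta
  empty <- DirectedInteractionNetwork()
  tab <- scoreTable(katzCentrality(empty, nodes = sprintf("N%d", 1:5)))
  expect_equal(tab$katz, rep(1, 5))
  # chain A -> B -> C at alpha 0.1: (1, 1.1, 1.11)
  chain <- DirectedInteractionNetwork(c("A", "B"), c("B", "C"),
                                      sign = "activation")
  tab <- scoreTable(katzCentrality(chain))
  expect_equal(tab$katz[match(c("A", "B", "C"), tab$gene)],
               c(1, 1.1, 1.11), tolerance = 1e-12)
  # 2-cycle closed form: x = 1.1 / 0.99
  cyc <- DirectedInteractionNetwork(c("A", "B"), c("B", "A"),
                                    sign = "activation")
  tab <- scoreTable(katzCentrality(cyc))
  expect_equal(tab$katz, rep(1.1 / 0.99, 2), tolerance = 1e-12)
})

test_that("Katz rejects alpha at or beyond the convergence bound", {
  cyc <- DirectedInteractionNetwork(c("A", "B"), c("B", "A"))
  expect_error(katzCentrality(cyc, alpha = 1), "spectral radius")
  expect_silent(katzCentrality(cyc, alpha = 0.99))
})

test_that("linear solve matches the truncated walk series on random graphs", {
  set.seed(314)
  for (rep in 1:20) {
    n <- sample(2:15, 1)
    net <- randomActivatingNet(n, p = 0.15)
    nodes <- sprintf("N%02d", seq_len(n))
    tab <- scoreTable(katzCentrality(net, nodes = nodes))
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    e <- networkEdges(net)
    if (nrow(e)) A[cbind(match(e$source, nodes), match(e$target, nodes))] <- 1
    want <- oracleKatzSeries(A, 0.1, 1, K = 40)
    expect_equal(tab$katz[match(nodes, tab$gene)], want, tolerance = 1e-9)
  }
})

test_that("incoming edges only increase the receiving node's score", {
  base <- DirectedInteractionNetwork(c("A", "B"), c("B", "C"))
  more <- DirectedInteractionNetwork(c("A", "B", "A"), c("B", "C", "C"))
  t1 <- scoreTable(katzCentrality(base))
  t2 <- scoreTable(katzCentrality(more))
  expect_gt(t2$katz[t2$gene == "C"], t1$katz[t1$gene == "C"])
})

test_that("node relabelling permutes Katz scores identically", {
  set.seed(27)
  net <- randomActivatingNet(8, p = 0.3)
  nodes <- sprintf("N%02d", 1:8)
  perm <- sample(nodes)
  relabel <- stats::setNames(perm, nodes)
  e <- networkEdges(net)
  net2 <- DirectedInteractionNetwork(unname(relabel[e$source]),
                                     unname(relabel[e$target]),
                                     sign = "activation")
  t1 <- scoreTable(katzCentrality(net, nodes = nodes))
  t2 <- scoreTable(katzCentrality(net2, nodes = unname(relabel)))
  expect_equal(t2$katz[match(unname(relabel[nodes]), t2$gene)],
               t1$katz[match(nodes, t1$gene)], tolerance = 1e-12)
})

test_that("combined scores multiply centrality by frequency", {
  sig <- MiRNASignature(c("m1", "m2", "m3"), c("high", "high", "low"), "s")
  mti <- TargetInteractionTable(c("m1", "m2", "m1", "m3"),
                                c("A", "A", "B", "C"))
  gs <- scoreGenes(sig, mti)  # A:2, B:1, C:-1
  net <- DirectedInteractionNetwork("B", "A", sign = "activation")
  comb <- combinedScores(katzCentrality(net, nodes = c("A", "B", "C")), gs)
  tab <- scoreTable(comb)
  expect_equal(tab$combined[tab$gene == "A"], 1.1 * 2, tolerance = 1e-12)
  expect_equal(tab$combined[tab$gene == "B"], 1)
  expect_equal(tab$combined[tab$gene == "C"], -1)
  # edgeless network: combined ranking equals frequency ranking
  comb2 <- combinedScores(
    katzCentrality(DirectedInteractionNetwork(), nodes = c("A", "B", "C")),
    gs)
  expect_equal(scoreTable(comb2)$gene, scoreTable(gs)$gene)
  # a network gene without a frequency score is a hard error
  net3 <- DirectedInteractionNetwork("A", "ZZZ", sign = "activation")
  expect_error(combinedScores(katzCentrality(net3), gs), "ZZZ")
})
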