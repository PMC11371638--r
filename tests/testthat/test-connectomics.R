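test_that("preprocessing zeroes negatives and diagonal, never reduces degree", {
  parc <- generateParcellation(4L, 0L)
  W <- randomGraphMatrix(8, 1)
  W[1, 2] <- W[2, 1] <- -0.3
  diag(W) <- 0.7
  raw <- ConnectivityMatrix(W, parc, "functional")
  pp <- preprocessConnectivity(raw)
  expect_equal(connWeights(pp)[1, 2], 0)
  expect_equal(unname(diag(connWeights(pp))), rep(0, 8))
  expect_equal(connWeights(pp)[3, 4], W[3, 4])
  ## structural matrices only lose the diagonal
  st <- preprocessConnectivity(ConnectivityMatrix(abs(W), parc, "structural"))
  expect_equal(connWeights(st)[1, 2], 0.3)
  ## zeroing negatives can only raise degree
  for (s in 1:20) {
    Wn <- randomGraphMatrix(8, 100 + s) - 0.5
    Wn <- (Wn + t(Wn)) / 2; diag(Wn) <- 0
    degNeg <- rowSums(Wn)
    pp2 <- preprocessConnectivity(ConnectivityMatrix(Wn, parc, "functional"))
    expect_true(all(rowSums(connWeights(pp2)) >= degNeg - 1e-12))
  }
})

test_that("degree centrality is exact row sums over the named block", {
  parc <- generateParcellation(4L, 0L)
  W <- matrix(0, 8, 8)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.1
  conn <- preprocessConnectivity(ConnectivityMatrix(W, parc, "functional"))
  expect_equal(unname(mapValues(degreeCentrality(conn))[1:3]),
               c(0.7, 0.6, 0.3))
  expect_equal(unname(mapValues(degreeCentrality(conn))[4:8]), rep(0, 5))
  ## subcortico-cortical scope sums each subcortical row over cortex
  parc2 <- smallParcellation()
  net <- generateConnectome(parc2, seed = 2)
  pp <- preprocessConnectivity(net$functional)
  expect_equal(mapValues(degreeCentrality(pp, "subcortico-cortical")),
               rowSums(subcorticoCortical(pp)))
})

test_that("eigenvector centrality is uniform on complete graphs, sqrt(k) on stars", {
  ## complete graph with equal weights: all 1 after scaling
  Wc <- matrix(0.4, 6, 6); diag(Wc) <- 0
  expect_equal(unname(mapValues(eigenvectorCentrality(graphConn(Wc)))),
               rep(1, 6), tolerance = 1e-10)
  ## star, center 1 with 5 unit leaves: center-to-leaf ratio sqrt(5)
  Ws <- matrix(0, 6, 6); Ws[1, 2:6] <- Ws[2:6, 1] <- 1
  ev <- unname(mapValues(eigenvectorCentrality(graphConn(Ws))))
  expect_equal(ev[1] / ev[2], sqrt(5), tolerance = 1e-8)
})

test_that("betweenness and closeness follow path definitions on toy graphs", {
  ## path a-b-c-d with unit weights
  Wp <- matrix(0, 4, 4)
  Wp[1, 2] <- Wp[2, 3] <- Wp[3, 4] <- 1
  Wp <- Wp + t(Wp)
  conn <- graphConn(Wp)
  expect_equal(unname(mapValues(betweennessCentrality(conn))), c(0, 2, 2, 0))
  expect_equal(unname(mapValues(closenessCentrality(conn))),
               c(3 / 6, 3 / 4, 3 / 4, 3 / 6))
  ## complete equal-weight graph: direct edges always shortest
  Wc <- matrix(2, 6, 6); diag(Wc) <- 0
  expect_equal(unname(mapValues(betweennessCentrality(graphConn(Wc)))),
               rep(0, 6))
  expect_equal(sd(mapValues(closenessCentrality(graphConn(Wc)))), 0)
})

test_that("centrality metrics match brute-force oracles on random graphs", {
  for (s in 1:50) {
    n <- sample(c(4, 6), 1)
    W <- randomGraphMatrix(n, 400 + s)
    conn <- graphConn(W)
    expect_equal(unname(mapValues(degreeCentrality(conn))), rowSums(W),
                 tolerance = 1e-12)
    expect_equal(unname(mapValues(eigenvectorCentrality(conn))),
                 powerIterationOracle(W), tolerance = 1e-8)
    expect_equal(unname(mapValues(betweennessCentrality(conn))),
                 bruteBetweenness(W), tolerance = 1e-10)
    expect_equal(unname(mapValues(closenessCentrality(conn))),
                 bruteCloseness(W), tolerance = 1e-10)
  }
})

test_that("metrics respect global weight rescaling", {
  W <- randomGraphMatrix(6, 77)
  c1 <- graphConn(W); c2 <- graphConn(3.7 * W)
  expect_equal(mapValues(eigenvectorCentrality(c1)),
               mapValues(eigenvectorCentrality(c2)), tolerance = 1e-8)
  expect_equal(mapValues(betweennessCentrality(c1)),
               mapValues(betweennessCentrality(c2)), tolerance = 1e-10)
  expect_equal(rank(mapValues(degreeCentrality(c1))),
               rank(mapValues(degreeCentrality(c2))))
  expect_equal(rank(mapValues(closenessCentrality(c1))),
               rank(mapValues(closenessCentrality(c2))))
})

test_that("hubs-most-affected combines ranks as documented", {
  parc <- smallParcellation()
  net <- generateConnectome(parc, seed = 9)
  pp <- preprocessConnectivity(net$functional)
  cen <- degreeCentrality(pp)
  ## alteration identical to centrality: the top-centrality set is returned
  altSame <- RegionalMap(mapValues(cen), parc, "cortical", "t")
  top <- hubsMostAffected(cen, altSame, fraction = 0.25)
  expect_setequal(top, names(sort(mapValues(cen), decreasing = TRUE))[1:4])
  ## fraction 1 returns everything
  expect_setequal(hubsMostAffected(cen, altSame, 1), names(mapValues(cen)))
  ## exactly reversed rankings tie every combined score; the tie-break by
  ## centrality rank then decides
  altRev <- RegionalMap(-mapValues(cen), parc, "cortical", "t")
  mid <- hubsMostAffected(cen, altRev, fraction = 0.25)
  rc <- rank(-mapValues(cen))
  expect_setequal(mid, names(sort(rc)[1:4]))
  ## enumerated discordant case: winners sit mid-list on both rankings
  p6 <- graphParcellation(6L)
  cen6 <- new("CentralityProfile",
              map = RegionalMap(c(6, 5, 4, 3, 2, 1), p6, "cortical",
                                "centrality"),
              metric = "degree", modality = "functional",
              scope = "cortico-cortical")
  alt6 <- RegionalMap(c(1, 2, 6, 5, 3, 4), p6, "cortical", "t")
  ## combined mean ranks: 3.5, 3.5, 2.0, 3.0, 4.5, 4.5 -> regions 3 and 4,
  ## neither of which tops either individual list
  expect_identical(hubsMostAffected(cen6, alt6, fraction = 1 / 3),
                   regionNames(p6)[3:4])
  expect_error(hubsMostAffected(cen, altSame, 0), "fraction")
  ## intersection variant agrees in the concordant case
  expect_setequal(hubsMostAffected(cen, altSame, 0.25, "intersection"), top)
})
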