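# a small fully-scored network over given frame coordinates
.toyNetwork <- function(nodes, scores = NULL, subfamily = "t", alg = "omes") {
  p <- combn(nodes, 2L)
  e <- data.frame(a = p[1L, ], b = p[2L, ])
  e$score <- if (is.null(scores)) rev(seq_len(ncol(p))) else scores
  new("CoevolutionNetwork", subfamily = subfamily, algorithm = alg,
      nodes = as.integer(nodes), edges = e)
}

test_that("networks keep only frame-mapped endpoints", {
  s <- matrix(NA_real_, 5, 5)
  s[upper.tri(s)] <- seq_len(10)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  sm <- new("ScoreMatrix", algorithm = "omes", scores = s)
  refAln <- aln("ACDEF", "ACDEF", ids = c("r1", "anchor"))
  frame <- buildFamilyFrame(refAln, "anchor")
  pmAll <- new("PositionMap", subfamily = "x", refId = "r1",
               columns = 1:5, refResidues = 1:5)
  net <- buildNetwork(sm, pmAll, frame)
  expect_equal(nrow(networkEdges(net)), 10L)  # C(5,2)
  # drop column 3: its 4 incident edges disappear
  pmPart <- new("PositionMap", subfamily = "x", refId = "r1",
                columns = c(1L, 2L, 4L, 5L), refResidues = 1:4)
  net2 <- buildNetwork(sm, pmPart, frame)
  expect_equal(nrow(networkEdges(net2)), 6L)
  expect_equal(attr(networkEdges(net2), "nDroppedEdges"), 4L)
  # alignment columns 1,2,4,5 land on frame residues 1:4; frame column 5
  # has no mapped position
  expect_equal(networkNodes(net2), 1:4)
})

test_that("Jaccard index follows its definition", {
  expect_equal(jaccardIndex(1:5, 1:5), 1)
  expect_equal(jaccardIndex(1:3, 4:6), 0)
  expect_equal(jaccardIndex(character(), character()), 0)
  expect_equal(jaccardIndex(1:5, 3:7), 3 / 7)  # k/(2N-k), N=5, k=3
})

test_that("agreement model matches exhaustive small-universe search", {
  expect_equal(agreementModel(theta = 6, N = 3), 1)
  expect_equal(agreementModel(theta = 0, N = 4), 0)
  expect_equal(agreementModel(theta = 6, N = 10), 6 / 14)
  for (theta in 0:3) {
    uA <- c(letters[seq_len(theta)], paste0("a", 1:3))
    uB <- c(letters[seq_len(theta)], paste0("b", 1:3))
    for (N in 1:3) {
      expect_equal(agreementModel(theta, N), oracleMaxJaccard(uA, uB, N),
                   label = sprintf("theta=%d N=%d", theta, N))
    }
  }
})

test_that("random model is exact in degenerate cases and calibrated otherwise", {
  u <- letters[1:5]
  rm1 <- randomModel(u, u, 5, nShuffles = 200, seed = 1)
  expect_equal(rm1$mean, 1)
  expect_equal(rm1$sd, 0)
  rm0 <- randomModel(letters[1:4], LETTERS[1:4], 2, nShuffles = 200, seed = 1)
  expect_equal(rm0$mean, 0)
  expect_equal(rm0$ci95, 0)
  # enumeration oracle: |U_A| = |U_B| = 6, theta = 4
  uA <- c("s1", "s2", "s3", "s4", "a1", "a2")
  uB <- c("s1", "s2", "s3", "s4", "b1", "b2")
  for (N in 2:3) {
    exact <- oracleNullMoments(uA, uB, N)
    got <- randomModel(uA, uB, N, nShuffles = 2000, seed = 42)
    mcse <- exact$sd / sqrt(2000)
    expect_lt(abs(got$mean - exact$mean), 3 * mcse)
    expect_lt(abs(got$sd - exact$sd), 0.1 * exact$sd)
  }
})

test_that("sweep hits its trivial anchors", {
  net <- .toyNetwork(1:6)
  ra <- rankEdges(net)
  sw <- jaccardSweep(ra, ra, nShuffles = 100, seed = 1)
  tab <- sweepTable(sw)
  expect_equal(tab$jObs, tab$jMax)
  expect_equal(tab$jObs[nrow(tab)], 1)  # full lists over one universe
  expect_true(all(tab$jObs >= 0 & tab$jObs <= tab$jMax + 1e-12))
  expect_true(all(tab$jRandomMean <= tab$jMax + 1e-12))
  # disjoint universes
  netB <- .toyNetwork(7:12)
  sw2 <- jaccardSweep(rankEdges(net), rankEdges(netB), nShuffles = 100, seed = 1)
  tab2 <- sweepTable(sw2)
  expect_true(all(tab2$jObs == 0))
  expect_true(all(tab2$jMax == 0))
})

test_that("node ranking uses strongest incident edge with coordinate ties", {
  # star: center 10 on max-weight edges
  e <- data.frame(a = c(10L, 10L, 10L), b = c(20L, 30L, 40L),
                  score = c(5, 4, 3))
  net <- new("CoevolutionNetwork", subfamily = "t", algorithm = "omes",
             nodes = c(10L, 20L, 30L, 40L), edges = e)
  rn <- rankNodes(net)
  expect_equal(rn@keys[1], "10")
  expect_equal(rn@scores[1], 5)
  # equal weights: coordinate order
  e2 <- data.frame(a = c(1L, 2L), b = c(3L, 4L), score = c(2, 2))
  net2 <- new("CoevolutionNetwork", subfamily = "t", algorithm = "omes",
              nodes = 1:4, edges = e2)
  expect_equal(rankNodes(net2)@keys, c("1", "2", "3", "4"))
  # random graph vs brute-force max per node
  set.seed(31)
  nodes <- 1:8
  p <- combn(nodes, 2L)
  keep <- runif(ncol(p)) < 0.6
  e3 <- data.frame(a = p[1, keep], b = p[2, keep],
                   score = round(runif(sum(keep)), 3))
  net3 <- new("CoevolutionNetwork", subfamily = "t", algorithm = "omes",
              nodes = nodes, edges = e3)
  rn3 <- rankNodes(net3)
  for (v in as.integer(rn3@keys)) {
    inc <- e3$score[e3$a == v | e3$b == v]
    expect_equal(rn3@scores[rn3@keys == as.character(v)], max(inc))
  }
})

test_that("consensus ranking reduces correctly and matches hand arithmetic", {
  g <- generateMsa(syntheticSpec(nSeq = 60, nCol = 10,
    plantedPairs = data.frame(i = 2, j = 7, coupling = 0.9), seed = 13))
  sm <- scoreOmes(g$alignment)
  # single algorithm: consensus order equals max-edge order
  cr1 <- consensusNodes(list(omes = sm), k = 3)
  w <- suppressWarnings(apply(scoreValues(sm), 1, max, na.rm = TRUE))
  w[!is.finite(w)] <- NA
  expect_equal(consensusTable(cr1)$node,
               order(-w, seq_along(w), na.last = TRUE)[seq_len(nrow(consensusTable(cr1)))])
  # five identical matrices: consensus z equals the single-algorithm z
  cr5 <- consensusNodes(list(a = sm, b = sm, c = sm, d = sm, e = sm), k = 3)
  expect_equal(consensusTable(cr5)$consensus, consensusTable(cr5)$z_a)
  expect_equal(consensusTable(cr5)$node, consensusTable(cr1)$node)
  # 3-node hand example with two algorithms
  mk <- function(w12, w13, w23) {
    s <- matrix(NA_real_, 3, 3)
    s[1, 2] <- s[2, 1] <- w12
    s[1, 3] <- s[3, 1] <- w13
    s[2, 3] <- s[3, 2] <- w23
    new("ScoreMatrix", algorithm = "x", scores = s)
  }
  smA <- mk(3, 1, 2)  # max-edge: node1 = 3, node2 = 3, node3 = 2
  smB <- mk(1, 5, 4)  # max-edge: node1 = 5, node2 = 4, node3 = 5
  wa <- c(3, 3, 2); wb <- c(5, 4, 5)
  za <- (wa - mean(wa)) / sd(wa)
  zb <- (wb - mean(wb)) / sd(wb)
  cons <- (za + zb) / 2
  cr <- consensusNodes(list(A = smA, B = smB), k = 2)
  tab <- consensusTable(cr)
  expect_equal(tab$consensus[match(1:3, tab$node)], cons)
  # z columns have mean 0, sd 1
  expect_equal(mean(tab$z_A), 0, tolerance = 1e-9)
  expect_equal(sd(tab$z_A), 1, tolerance = 1e-9)
  # invariance under per-algorithm affine transforms
  smB2 <- mk(1 * 10 + 2, 5 * 10 + 2, 4 * 10 + 2)
  cr2 <- consensusNodes(list(A = smA, B = smB2), k = 2)
  expect_equal(consensusTable(cr2)$consensus, tab$consensus)
})

test_that("degenerate consensus inputs follow the documented rules", {
  flat <- matrix(NA_real_, 3, 3)
  flat[upper.tri(flat)] <- 1
  flat[lower.tri(flat)] <- 1
  smFlat <- new("ScoreMatrix", algorithm = "flat", scores = flat)
  cr <- consensusNodes(list(flat = smFlat), k = 2)
  expect_true(all(consensusTable(cr)$z_flat == 0))
})
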