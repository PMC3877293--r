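# small helper: score matrix over all columns of a gapless toy alignment
.fullMask <- function(a, znmi = FALSE) {
  m <- eligibilityMask(a, znmiMode = znmi)
  m
}

test_that("mutual information matches analytic values and the brute-force oracle", {
  # perfectly coupled two-state pair
  a <- Alignment(cbind(rep(c("A", "C"), each = 5), rep(c("D", "E"), each = 5)),
                 ids = paste0("s", 1:10))
  mi <- mutualInformation(pairCounts(a, 1, 2))
  expect_equal(mi$I, log(2))
  expect_equal(mi$NMI, 1)
  # independent balanced pair
  b <- Alignment(cbind(c("A", "A", "C", "C"), c("D", "E", "D", "E")),
                 ids = paste0("s", 1:4))
  expect_equal(mutualInformation(pairCounts(b, 1, 2))$I, 0)
  # random columns vs oracle, with gaps
  for (seed in 1:5) {
    m <- randAlnMatrix(10, 2, gapP = 0.2, seed = seed, alphabet = AA20[1:4])
    cc <- Alignment(cbind(m, "A"), ids = paste0("s", 1:10))
    got <- mutualInformation(pairCounts(cc, 1, 2))
    want <- oracleMI(m[, 1], m[, 2])
    expect_equal(got$I, want$I, tolerance = 1e-12)
    expect_equal(got$H, want$H, tolerance = 1e-12)
    expect_equal(got$NMI, want$NMI, tolerance = 1e-12)
  }
})

test_that("OMES matches the worked example and the contingency oracle", {
  a <- Alignment(cbind(rep(c("A", "C"), each = 5), rep(c("D", "E"), each = 5)),
                 ids = paste0("s", 1:10))
  s <- scoreValues(scoreOmes(a, .fullMask(a)))
  expect_equal(s[1, 2], 2.5)  # four cells, each (2.5)^2 = 6.25, sum 25, / 10
  b <- Alignment(cbind(c("A", "A", "C", "C"), c("D", "E", "D", "E")),
                 ids = paste0("s", 1:4))
  expect_equal(scoreValues(scoreOmes(b, .fullMask(b)))[1, 2], 0)
  for (seed in 1:4) {
    m <- randAlnMatrix(8, 6, gapP = 0.1, seed = seed, alphabet = AA20[1:5])
    cc <- Alignment(m, ids = paste0("s", 1:8))
    s <- scoreValues(scoreOmes(cc, .fullMask(cc)))
    for (i in 1:5) for (j in (i + 1):6) {
      if (is.finite(s[i, j]))
        expect_equal(s[i, j], oracleOmes(m[, i], m[, j]), tolerance = 1e-9)
    }
  }
})

test_that("McBASC matches the quadruple-loop oracle and its degenerate rules", {
  # duplicated variable column: perfect self-correlation
  col <- c("A", "C", "D", "E", "F", "A", "C", "D")
  a <- Alignment(cbind(col, col, sample(AA20[1:4], 8, TRUE)),
                 ids = paste0("s", 1:8))
  s <- scoreValues(scoreMcbasc(a, .fullMask(a)))
  expect_equal(s[1, 2], 1)
  # constant column: zero similarity variance -> 0
  b <- Alignment(cbind(col, rep("W", 8)), ids = paste0("s", 1:8))
  mask <- new("EligibilityMask", eligible = c(TRUE, TRUE),
              gapFraction = c(0, 0), entropy = c(1, 0),
              reasons = list(character(), character()), mode = "standard")
  expect_equal(scoreValues(scoreMcbasc(b, mask))[1, 2], 0)
  # random toy alignment vs oracle
  for (seed in 1:3) {
    m <- randAlnMatrix(8, 6, gapP = 0.1, seed = seed + 10, alphabet = AA20[1:6])
    cc <- Alignment(m, ids = paste0("s", 1:8))
    s <- scoreValues(scoreMcbasc(cc, .fullMask(cc)))
    for (i in 1:5) for (j in (i + 1):6) {
      if (is.finite(s[i, j]))
        expect_equal(s[i, j], oracleMcbasc(m, i, j), tolerance = 1e-9)
    }
  }
})

test_that("ELSC is zero at ideal composition, positive under skew, symmetric", {
  # two perfectly coupled two-state columns, balanced: the modal-residue
  # subalignment at i is maximally skewed at j -> strictly positive
  m <- cbind(rep(c("A", "C"), each = 10), rep(c("D", "E"), each = 10),
             rep(AA20[1:4], 5))
  a <- Alignment(m, ids = paste0("s", 1:20))
  s <- scoreValues(scoreElsc(a, .fullMask(a)))
  expect_gt(s[1, 2], 0)
  # direct log-binomial evaluation for the coupled pair, both directions:
  # sub = 10 sequences carrying "A"; at j: N_D = N_E = 10, n_D = 10, n_E = 0,
  # ideal m_D = m_E = 5
  want <- sum(lchoose(c(10, 10), c(5, 5))) - sum(lchoose(c(10, 10), c(10, 0)))
  expect_equal(s[1, 2], want, tolerance = 1e-9)
  expect_equal(s, t(s))
  # independent balanced pair: subalignment composition equals ideal -> 0
  b <- Alignment(cbind(rep(c("A", "C"), each = 4),
                       rep(c("D", "E", "D", "E"), 2)), ids = paste0("s", 1:8))
  expect_equal(scoreValues(scoreElsc(b, .fullMask(b)))[1, 2], 0)
})

test_that("SCA is zero for an unperturbed profile and symmetric", {
  # column j has identical composition within and outside the modal-residue
  # subalignment at i -> zero statistical-energy shift in that direction,
  # and vice versa -> symmetrized score 0
  m <- cbind(rep(c("A", "C"), each = 4), rep(c("D", "E"), 4))
  a <- Alignment(m, ids = paste0("s", 1:8))
  s <- scoreValues(scoreSca(a, .fullMask(a)))
  expect_equal(s[1, 2], 0, tolerance = 1e-12)
  g <- generateMsa(syntheticSpec(nSeq = 60, nCol = 8,
    plantedPairs = data.frame(i = 2, j = 6, coupling = 1), seed = 2))
  s <- scoreValues(scoreSca(g$alignment))
  expect_equal(s, t(s))
})

test_that("ZNMI standardization yields zero scores for flat NMI and symmetry", {
  # three mutually independent uniform columns: all pairwise NMIs equal in
  # expectation; with identical column copies every NMI is exactly 1
  col <- sample(AA20[1:6], 30, replace = TRUE)
  a <- Alignment(cbind(col, col, col), ids = paste0("s", 1:30))
  s <- scoreValues(scoreZnmi(a))
  expect_true(all(s[upper.tri(s)] == 0))
  g <- generateMsa(syntheticSpec(nSeq = 80, nCol = 10,
    plantedPairs = data.frame(i = 3, j = 8, coupling = 1), seed = 4))
  s <- scoreValues(scoreZnmi(g$alignment))
  expect_equal(s, t(s))
  expect_error(scoreZnmi(g$alignment, eligibilityMask(g$alignment)),
               "ZNMI-mode")
})

test_that("planted coupled pairs top the rankings for every algorithm", {
  g <- generateMsa(syntheticSpec(nSeq = 200, nCol = 20,
    plantedPairs = data.frame(i = c(2, 7, 11), j = c(5, 15, 19), coupling = 1),
    gapRate = 0.01, seed = 3))
  truthKeys <- paste(g$truth$pairs$i, g$truth$pairs$j)
  for (alg in coevolutionAlgorithms()) {
    s <- scoreValues(scoreAlignment(g$alignment, alg))
    ut <- which(upper.tri(s) & is.finite(s), arr.ind = TRUE)
    o <- order(-s[ut])
    top <- paste(ut[o, 1], ut[o, 2])[seq_len(nrow(g$truth$pairs) + 2L)]
    expect_equal(sum(truthKeys %in% top), 3L, label = alg)
  }
})

test_that("all score matrices are symmetric, finite and mask-restricted", {
  g <- generateMsa(syntheticSpec(nSeq = 60, nCol = 12,
    conserved = data.frame(column = 4, consensus = "W", freq = 0.98),
    plantedPairs = data.frame(i = 2, j = 9, coupling = 0.8),
    gapRate = 0.05, seed = 8))
  a <- g$alignment
  for (alg in coevolutionAlgorithms()) {
    mask <- eligibilityMask(a, znmiMode = alg == "znmi")
    s <- scoreValues(scoreAlignment(a, alg, mask))
    expect_equal(s, t(s), label = alg)
    expect_false(any(is.infinite(s)), label = alg)
    bad <- setdiff(seq_len(nCol(a)), eligibleColumns(mask))
    expect_true(all(is.na(s[bad, ])), label = alg)
    expect_true(all(is.na(diag(s))), label = alg)
  }
})

test_that("scores are invariant to sequence-order permutation", {
  g <- generateMsa(syntheticSpec(nSeq = 50, nCol = 10,
    plantedPairs = data.frame(i = 2, j = 7, coupling = 0.7),
    gapRate = 0.05, seed = 12))
  a <- g$alignment
  set.seed(99)
  perm <- sample(nSeq(a))
  b <- selectSequences(a, perm)
  for (alg in coevolutionAlgorithms()) {
    expect_equal(scoreValues(scoreAlignment(a, alg)),
                 scoreValues(scoreAlignment(b, alg)), label = alg)
  }
})
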