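# Independent brute-force implementations used as oracles. These stay
# deliberately naive (explicit loops over sequences and residue pairs) so
# they share no code path with the package kernels.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# alignment from residue strings with auto ids
aln <- function(..., ids = NULL) {
  s <- c(...)
  if (is.null(ids)) ids <- paste0("s", seq_along(s))
  Alignment(s, ids = ids)
}

# random gapless-or-gappy alignment as a character matrix
randAlnMatrix <- function(nSeq, nCol, gapP = 0, seed = 1, alphabet = AA20) {
  set.seed(seed)
  m <- matrix(sample(alphabet, nSeq * nCol, replace = TRUE), nSeq, nCol)
  if (gapP > 0) m[matrix(runif(nSeq * nCol) < gapP, nSeq, nCol)] <- "-"
  m
}

oracleMI <- function(x, y) {
  ok <- x != "-" & y != "-"
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  I <- 0; H <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / n
      if (pab == 0) next
      pa <- sum(x == a) / n
      pb <- sum(y == b) / n
      I <- I + pab * log(pab / (pa * pb))
      H <- H - pab * log(pab)
    }
  }
  list(I = I, H = H, NMI = if (H > 0) I / H else 0)
}

oracleOmes <- function(x, y) {
  ok <- x != "-" & y != "-"
  x <- x[ok]; y <- y[ok]
  nv <- length(x)
  if (nv == 0) return(NA_real_)
  s <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      obs <- sum(x == a & y == b)
      ex <- sum(x == a) * sum(y == b) / nv
      s <- s + (obs - ex)^2 / nv
    }
  }
  s
}

# quadruple loop over ordered sequence pairs; gap-involving pairs score 0
oracleMcbasc <- function(m, i, j) {
  M <- mclachlanMatrix()
  n <- nrow(m)
  si <- c(); sj <- c()
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (k == l) next
      si <- c(si, if (m[k, i] != "-" && m[l, i] != "-") M[m[k, i], m[l, i]] else 0)
      sj <- c(sj, if (m[k, j] != "-" && m[l, j] != "-") M[m[k, j], m[l, j]] else 0)
    }
  }
  np <- length(si)
  sdi <- sqrt(sum((si - mean(si))^2) / np)
  sdj <- sqrt(sum((sj - mean(sj))^2) / np)
  if (sdi == 0 || sdj == 0) return(0)
  sum((si - mean(si)) * (sj - mean(sj))) / (np * sdi * sdj)
}

oracleIdentity <- function(x, y) {
  keep <- x != "-" | y != "-"
  sum(x[keep] == y[keep] & x[keep] != "-") / sum(keep)
}

# exact null-model moments by enumerating all C(|A|,N) x C(|B|,N) draws
oracleNullMoments <- function(uA, uB, N) {
  subsA <- combn(uA, N, simplify = FALSE)
  subsB <- combn(uB, N, simplify = FALSE)
  js <- c()
  for (a in subsA) for (b in subsB)
    js <- c(js, length(intersect(a, b)) / length(union(a, b)))
  list(mean = mean(js), sd = sd(js))
}

# maximum achievable J by exhaustive search over subset pairs
oracleMaxJaccard <- function(uA, uB, N) {
  subsA <- combn(uA, N, simplify = FALSE)
  subsB <- combn(uB, N, simplify = FALSE)
  best <- 0
  for (a in subsA) for (b in subsB)
    best <- max(best, length(intersect(a, b)) / length(union(a, b)))
  best
}
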