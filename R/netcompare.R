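#' Build a co-evolution network in frame coordinates
#'
#' Nodes are the frame coordinates of scored columns that map through the
#' position map into the family frame; edges whose either endpoint is
#' unmapped are dropped (the count is attached as attribute
#' `nDroppedEdges`).
#'
#' @param sm a [ScoreMatrix-class]
#' @param pm the subfamily's [PositionMap-class]
#' @param frame the [FamilyFrame-class]
#' @return a [CoevolutionNetwork-class]
#' @export
buildNetwork <- function(sm, pm, frame) {
  s <- sm@scores
  idx <- which(upper.tri(s) & is.finite(s), arr.ind = TRUE)
  cols <- sort(unique(c(idx[, 1], idx[, 2])))
  fc <- mapToFrame(cols, pm, frame)
  fa <- fc[match(idx[, 1], cols)]
  fb <- fc[match(idx[, 2], cols)]
  keep <- !is.na(fa) & !is.na(fb)
  nDropped <- sum(!keep)
  a <- pmin(fa[keep], fb[keep])
  b <- pmax(fa[keep], fb[keep])
  edges <- data.frame(a = a, b = b, score = s[idx][keep])
  nodes <- sort(unique(fc[!is.na(fc)]))
  if (!length(nodes)) stop("empty network: no columns map into the frame")
  net <- new("CoevolutionNetwork", subfamily = pm@subfamily,
             algorithm = sm@algorithm, nodes = as.integer(nodes),
             edges = edges)
  attr(net@edges, "nDroppedEdges") <- nDropped
  net
}

#' Jaccard index of two sets
#'
#' J = |A intersect B| / |A union B|, with J(empty, empty) := 0.
#'
#' @param A,B vectors treated as sets.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccardIndex <- function(A, B) {
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' Maximum achievable Jaccard ("perfect agreement" model)
#'
#' With top-N sets drawn from universes sharing theta elements, the
#' intersection can reach m = min(N, theta), giving J_max = m / (2N - m).
#'
#' @param theta size of the universe intersection.
#' @param N threshold (elements taken from each list).
#' @return J_max.
#' @export
agreementModel <- function(theta, N) {
  m <- pmin(N, theta)
  ifelse(2 * N - m > 0, m / (2 * N - m), 0)
}

#' Rank a network's edges by descending score
#'
#' Ties are broken by ascending frame coordinates (a, then b) for
#' deterministic prefixes.
#'
#' @param net a [CoevolutionNetwork-class]
#' @return a [RankedSet-class] with edge keys `"a-b"`.
#' @export
rankEdges <- function(net) {
  e <- net@edges
  o <- order(-e$score, e$a, e$b)
  new("RankedSet", kind = "edge",
      keys = paste0(e$a[o], "-", e$b[o]), scores = e$score[o])
}

#' Rank a network's nodes by strongest incident edge
#'
#' Node score is the maximum weight over incident edges; nodes with no
#' edges are excluded. Ties are broken by ascending frame coordinate.
#'
#' @param net a [CoevolutionNetwork-class]
#' @return a [RankedSet-class] with node keys (frame coordinates).
#' @export
rankNodes <- function(net) {
  e <- net@edges
  if (!nrow(e)) stop("network has no edges")
  w <- tapply(c(e$score, e$score), c(e$a, e$b), max)
  node <- as.integer(names(w))
  o <- order(-w, node)
  new("RankedSet", kind = "node",
      keys = as.character(node[o]), scores = as.numeric(w[o]))
}

#' Edge universe of a network
#'
#' All unordered pairs over the node set, as edge keys.
#'
#' @param net a [CoevolutionNetwork-class]
#' @return character vector of `"a-b"` keys.
#' @export
edgeUniverse <- function(net) {
  n <- net@nodes
  if (length(n) < 2L) return(character())
  p <- combn(n, 2L)
  paste0(p[1L, ], "-", p[2L, ])
}

## Prefix-intersection counts: for shared elements of two ranked lists,
## k(N) = #{elements whose rank is <= N in both}. Returns cumulative
## counts at thresholds 1..maxN.
.prefixOverlap <- function(keysA, keysB, maxN) {
  shared <- intersect(keysA, keysB)
  if (!length(shared)) return(integer(maxN))
  m <- pmax(match(shared, keysA), match(shared, keysB))
  m <- m[m <= maxN]
  cumsum(tabulate(m, nbins = maxN))
}

#' Random (null) model of top-N Jaccard overlap
#'
#' Approximates the null distribution of J for top-N sets drawn at random
#' from the two universes by shuffling the rank-ordered element lists
#' `nShuffles` times and taking top-N prefixes (equivalent to uniform
#' N-subsets of each universe). Returns the sample mean, SD, and the 95%
#' CI half-width 1.96 x SD.
#'
#' @param universeA,universeB element-key vectors of the two universes.
#' @param N threshold; must not exceed either universe size.
#' @param nShuffles number of shufflings (default 1000).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `ci95`.
#' @export
randomModel <- function(universeA, universeB, N, nShuffles = 1000L,
                        seed = 1L) {
  stopifnot(N >= 1, N <= length(universeA), N <= length(universeB))
  js <- .nullSweep(universeA, universeB, N, nShuffles, seed)[, 1L]
  list(mean = mean(js), sd = sd(js), ci95 = 1.96 * sd(js))
}

## Null J samples at several thresholds at once; returns an
## nShuffles x length(Ns) matrix of Jaccard values.
.nullSweep <- function(universeA, universeB, Ns, nShuffles, seed) {
  sharedB <- match(intersect(universeA, universeB), universeB)
  nA <- length(universeA)
  nB <- length(universeB)
  maxN <- max(Ns)
  set.seed(seed)
  out <- matrix(0, nShuffles, length(Ns))
  theta <- length(sharedB)
  for (s in seq_len(nShuffles)) {
    if (theta) {
      ## ranks of the shared elements under a uniform shuffle of each list
      rA <- sample.int(nA, theta)
      rB <- sample.int(nB, theta)
      m <- pmax(rA, rB)
      m <- m[m <= maxN]
      k <- cumsum(tabulate(m, nbins = maxN))[Ns]
    } else {
      k <- numeric(length(Ns))
    }
    out[s, ] <- k / (2 * Ns - k)
  }
  out
}

#' Threshold-swept Jaccard comparison of two ranked sets
#'
#' For each threshold N in the sweep grid, computes the observed Jaccard
#' of the two top-N prefixes, the random-model mean/SD/95% CI, and the
#' perfect-agreement envelope. The grid is every integer N up to the
#' shorter list when that is <= 500, else 100 evenly spaced thresholds
#' starting at 1% of the list length.
#'
#' @param ra,rb [RankedSet-class] objects of the same kind.
#' @param universeA,universeB element-key universes of the two networks;
#'   default to the ranked keys themselves.
#' @param nShuffles shufflings for the random model (default 1000).
#' @param seed integer seed for the random model.
#' @return a [JaccardSweep-class]
#' @export
jaccardSweep <- function(ra, rb, universeA = ra@keys, universeB = rb@keys,
                         nShuffles = 1000L, seed = 1L) {
  if (ra@kind != rb@kind)
    stop("ranked sets must have the same element kind")
  L <- min(length(ra@keys), length(rb@keys))
  if (L < 1L) stop("empty ranked set")
  Ns <- if (L <= 500L) seq_len(L) else
    unique(round(seq(max(1L, ceiling(0.01 * L)), L, length.out = 100L)))
  ## observed prefix overlap; elements outside both lists cannot co-occur
  k <- .prefixOverlap(ra@keys, rb@keys, max(Ns))[Ns]
  jObs <- k / (2 * Ns - k)
  theta <- length(intersect(universeA, universeB))
  jMax <- agreementModel(theta, Ns)
  nullNs <- pmin(Ns, length(universeA), length(universeB))
  nulls <- .nullSweep(universeA, universeB, nullNs, nShuffles, seed)
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2L, sd)
  tab <- data.frame(N = Ns, jObs = jObs, jRandomMean = mu, jRandomSd = sdv,
                    jRandomCi95 = 1.96 * sdv, jMax = jMax)
  new("JaccardSweep", table = tab, kind = ra@kind,
      sizeA = length(universeA), sizeB = length(universeB),
      theta = as.integer(theta))
}

#' Cross-algorithm consensus ranking of positions
#'
#' Each position is scored by the maximum weight of its edges in each
#' algorithm's score matrix; the max-edge scores are Z-normalized per
#' algorithm over the scored nodes and averaged across algorithms. The
#' node set is the intersection of the algorithms' scored column sets
#' (the ZNMI mask differs from the others').
#'
#' @param matrices named list of [ScoreMatrix-class], one per algorithm.
#' @param k number of top positions to flag (default 10).
#' @return a [ConsensusRanking-class]
#' @export
consensusNodes <- function(matrices, k = 10L) {
  stopifnot(length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- vapply(matrices, scoreAlgorithm, "")
  maxEdge <- lapply(matrices, function(sm) {
    s <- sm@scores
    w <- suppressWarnings(apply(s, 1L, max, na.rm = TRUE))
    w[!is.finite(w)] <- NA_real_
    w
  })
  scoredSets <- lapply(maxEdge, function(w) which(!is.na(w)))
  nodes <- Reduce(intersect, scoredSets)
  if (!length(nodes)) stop("no nodes scored by every algorithm")
  zs <- lapply(maxEdge, function(w) {
    v <- w[nodes]
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  consensus <- Reduce(`+`, zs) / length(zs)
  o <- order(-consensus, nodes)
  tab <- data.frame(node = nodes[o])
  for (nm in names(matrices)) {
    tab[[paste0("w_", nm)]] <- maxEdge[[nm]][nodes][o]
    tab[[paste0("z_", nm)]] <- zs[[nm]][o]
  }
  tab$consensus <- consensus[o]
  tab$rank <- seq_len(nrow(tab))
  tab$topK <- tab$rank <= k
  new("ConsensusRanking", table = tab, k = as.integer(k))
}

#' Export a Jaccard sweep as TSV
#'
#' @param sweep a [JaccardSweep-class]
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportSweep <- function(sweep, path) {
  write.table(sweep@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a consensus ranking as TSV, with anchor numbers
#'
#' @param cr a [ConsensusRanking-class]; `node` is interpreted in the
#'   coordinate system of `frame` when one is supplied.
#' @param path output TSV path.
#' @param frame optional [FamilyFrame-class] to add anchor numbers.
#' @return `path`, invisibly.
#' @export
exportConsensus <- function(cr, path, frame = NULL) {
  tab <- cr@table
  if (!is.null(frame))
    tab <- cbind(tab, anchor_number = frame@anchorNumbers[tab$node])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
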