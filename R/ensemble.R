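#' Ensemble specification
#'
#' @param fraction fraction of sequences retained per replicate (the study
#'   design uses 0.9 and 0.5).
#' @param nReps number of replicate subalignments (default 100).
#' @param seed master seed; replicate seeds are derived from it by counter.
#' @return list with class-checked fields.
#' @export
ensembleSpec <- function(fraction = 0.9, nReps = 100L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, nReps >= 1)
  list(fraction = fraction, nReps = as.integer(nReps),
       seed = as.integer(seed))
}

#' Random subsample of an alignment
#'
#' Draws floor(fraction * nSeq) records uniformly without replacement;
#' the column set is unchanged and record order is preserved.
#'
#' @param a a [SubfamilyAlignment-class]
#' @param fraction fraction of sequences to keep.
#' @param seed integer seed.
#' @return a [SubfamilyAlignment-class]
#' @export
subsampleAlignment <- function(a, fraction, seed) {
  k <- floor(fraction * nSeq(a))
  if (k < 2) stop("subsample of ", k, " sequence(s) is too small (need >= 2)")
  set.seed(seed)
  keep <- sort(sample.int(nSeq(a), k))
  selectSequences(a, keep)
}

#' Ensemble-averaged covariation scores
#'
#' Scores `nReps` independent subsamples with one algorithm and averages
#' entrywise. The eligibility mask is computed once on the full alignment
#' and held fixed across replicates so every replicate scores the same
#' column set. Replicates yielding a non-finite score for an eligible pair
#' are excluded from that entry's mean; the per-entry replicate counts are
#' attached as attribute `nContributing`.
#'
#' @param a a [SubfamilyAlignment-class]
#' @param algorithm one of [coevolutionAlgorithms()].
#' @param spec an [ensembleSpec()].
#' @param mask fixed [EligibilityMask-class]; computed from `a` when NULL.
#' @return a [ScoreMatrix-class] of ensemble means.
#' @export
ensembleScores <- function(a, algorithm, spec = ensembleSpec(), mask = NULL) {
  algorithm <- match.arg(algorithm, coevolutionAlgorithms())
  if (is.null(mask))
    mask <- eligibilityMask(a, znmiMode = algorithm == "znmi")
  nc <- nCol(a)
  acc <- matrix(0, nc, nc)
  cnt <- matrix(0L, nc, nc)
  for (r in seq_len(spec$nReps)) {
    sub <- subsampleAlignment(a, spec$fraction, .substreamSeed(spec$seed, r))
    s <- scoreAlignment(sub, algorithm, mask)@scores
    ok <- is.finite(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt <- cnt + ok
  }
  mean_ <- acc / cnt
  mean_[cnt == 0L] <- NA_real_
  out <- new("ScoreMatrix", algorithm = algorithm, scores = mean_)
  attr(out@scores, "nContributing") <- cnt
  out
}

#' Cross-validation agreement between two ensemble means
#'
#' Pearson correlation over all pairs scored in both matrices (e.g. the
#' 90% and 50% subsampling ensembles of the same alignment/algorithm).
#'
#' @param m90,m50 [ScoreMatrix-class] objects over the same columns.
#' @return Pearson r.
#' @export
ensembleAgreement <- function(m90, m50) {
  s1 <- m90@scores
  s2 <- m50@scores
  if (!all(dim(s1) == dim(s2)))
    stop("score matrices have different dimensions")
  ut <- upper.tri(s1)
  ok <- ut & is.finite(s1) & is.finite(s2)
  if (sum(ok) < 2L)
    stop("fewer than 2 shared scored pairs; correlation undefined")
  cor(s1[ok], s2[ok])
}
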