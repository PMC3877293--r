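#' Number of sequences in an alignment
#' @param x a [SubfamilyAlignment-class]
#' @return integer
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))

#' Number of alignment columns
#' @param x a [SubfamilyAlignment-class]
#' @return integer
#' @export
setGeneric("nCol", function(x) standardGeneric("nCol"))

#' Sequence identifiers
#' @param x a [SubfamilyAlignment-class]
#' @return character vector
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Alignment as a character matrix (sequences x columns)
#' @param x a [SubfamilyAlignment-class]
#' @return character matrix with ids as rownames
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))

#' @rdname nSeq
setMethod("nSeq", "SubfamilyAlignment", function(x) nrow(x@seqs))

#' @rdname nCol
setMethod("nCol", "SubfamilyAlignment", function(x) ncol(x@seqs))

#' @rdname seqIds
setMethod("seqIds", "SubfamilyAlignment", function(x) x@ids)

#' @rdname alnMatrix
setMethod("alnMatrix", "SubfamilyAlignment", function(x) {
  m <- x@seqs
  rownames(m) <- x@ids
  m
})

#' Which columns are eligible for co-evolution scoring
#' @param x an [EligibilityMask-class]
#' @return integer vector of 1-based eligible column indices
#' @export
eligibleColumns <- function(x) {
  stopifnot(is(x, "EligibilityMask"))
  which(x@eligible)
}

#' Raw score matrix of a ScoreMatrix object
#' @param x a [ScoreMatrix-class]
#' @return numeric matrix
#' @export
scoreValues <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  x@scores
}

#' Algorithm label of a ScoreMatrix
#' @param x a [ScoreMatrix-class]
#' @return character
#' @export
scoreAlgorithm <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  x@algorithm
}

#' Edge table of a co-evolution network
#' @param x a [CoevolutionNetwork-class]
#' @return data.frame with columns a, b, score
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoevolutionNetwork"))
  x@edges
}

#' Node set of a co-evolution network
#' @param x a [CoevolutionNetwork-class]
#' @return integer frame coordinates
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CoevolutionNetwork"))
  x@nodes
}

#' Per-threshold table of a Jaccard sweep
#' @param x a [JaccardSweep-class]
#' @return data.frame with N, jObs, jRandomMean, jRandomSd, jRandomCi95, jMax
#' @export
sweepTable <- function(x) {
  stopifnot(is(x, "JaccardSweep"))
  x@table
}

#' Node table of a consensus ranking
#' @param x a [ConsensusRanking-class]
#' @return data.frame
#' @export
consensusTable <- function(x) {
  stopifnot(is(x, "ConsensusRanking"))
  x@table
}

#' Atom table of a structure model
#' @param x a [StructureModel-class]
#' @return data.frame
#' @export
atomTable <- function(x) {
  stopifnot(is(x, "StructureModel"))
  x@atoms
}
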