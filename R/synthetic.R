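#' Specification for a synthetic subfamily alignment
#'
#' Defaults emulate the shape of a curated bacterial transcription-factor
#' subfamily alignment: ~200 sequences over ~330 columns with a core of
#' strongly conserved sites, a minority of gappy columns, and a set of
#' planted covarying column pairs.
#'
#' @param nSeq number of sequences.
#' @param nCol number of columns.
#' @param conserved data.frame with columns `column`, `consensus`
#'   (residue), `freq` (majority frequency, >= 0.95), or NULL.
#' @param plantedPairs data.frame with columns `i`, `j`, `coupling`
#'   (in `[0, 1]`), or NULL. Each pair covaries through a paired-state
#'   alphabet: with probability `coupling` a sequence draws one hidden
#'   state realized as a residue in each column, otherwise the two
#'   columns draw their states independently. Optional columns `statesI`
#'   and `statesJ` (residue strings of equal length, e.g. `"AC"`/`"LD"`)
#'   fix the alphabet with uniform state probabilities; without them each
#'   pair gets a 20-state alphabet with Dirichlet-distributed state
#'   probabilities and a random residue bijection, so planted columns are
#'   marginally indistinguishable from background columns and only their
#'   joint dependence is anomalous.
#' @param background Dirichlet concentration for background column
#'   profiles (smaller = spikier columns; default 0.5).
#' @param gapRate per-column gap probability, scalar or length-`nCol`.
#' @param seed integer seed; generation is fully determined by it.
#' @return a `syntheticSpec` list.
#' @export
syntheticSpec <- function(nSeq = 200L, nCol = 330L, conserved = NULL,
                          plantedPairs = NULL,
                          background = 0.5, gapRate = 0.02, seed = 1L) {
  spec <- list(nSeq = as.integer(nSeq), nCol = as.integer(nCol),
               conserved = conserved, plantedPairs = plantedPairs,
               background = background,
               gapRate = rep_len(gapRate, nCol), seed = as.integer(seed))
  .validateSyntheticSpec(spec)
  spec
}

.validateSyntheticSpec <- function(spec) {
  cons <- spec$conserved
  pp <- spec$plantedPairs
  consCols <- if (is.null(cons)) integer() else cons$column
  pairCols <- if (is.null(pp)) integer() else c(pp$i, pp$j)
  if (any(consCols > spec$nCol) || any(pairCols > spec$nCol) ||
      any(c(consCols, pairCols) < 1))
    stop("conserved/planted column indices out of range")
  if (length(intersect(consCols, pairCols)))
    stop("planted pair columns must be disjoint from conserved columns")
  if (!is.null(pp)) {
    if (any(pp$i == pp$j)) stop("planted pair with i == j")
    if (any(pp$coupling < 0 | pp$coupling > 1))
      stop("coupling must lie in [0, 1]")
    if (!is.null(pp$statesI)) {
      if (any(nchar(pp$statesI) != nchar(pp$statesJ)) ||
          any(nchar(pp$statesI) < 2))
        stop("statesI/statesJ must be residue strings of equal length >= 2")
    }
  }
  if (!is.null(cons) && any(cons$freq < 0.95))
    stop("conserved majority frequency must be >= 0.95")
  invisible(TRUE)
}

## paired-state alphabet for one planted pair: residue letters realizing
## each hidden state in column i and column j, plus state probabilities.
## Explicit states come with uniform probabilities; the default is a
## 20-state alphabet with Dirichlet state weights and a random residue
## bijection, which makes the planted columns' marginal residue
## distributions exchangeable with background columns.
.pairAlphabet <- function(pairRow, background) {
  if (!is.null(pairRow$statesI) && !is.na(pairRow$statesI)) {
    iLetters <- strsplit(pairRow$statesI, "")[[1]]
    jLetters <- strsplit(pairRow$statesJ, "")[[1]]
    probs <- rep(1 / length(iLetters), length(iLetters))
  } else {
    w <- rgamma(20L, shape = background)
    if (sum(w) == 0) w <- rep(1, 20L)
    probs <- w / sum(w)
    iLetters <- AA_ALPHABET
    jLetters <- sample(AA_ALPHABET)
  }
  list(i = iLetters, j = jLetters, probs = probs)
}

#' Generate a synthetic alignment with planted structure
#'
#' Conserved columns draw their consensus residue with the stated majority
#' frequency (the remainder as a single minority residue, keeping the
#' column below the conservation entropy threshold); planted pairs draw,
#' with probability `coupling`, a shared hidden state realized as a
#' residue in each column, and otherwise draw the two columns' states
#' independently; background columns draw i.i.d. from a
#' Dirichlet-distributed profile. Gaps are injected per column at
#' `gapRate`. Output is fully determined by the spec's seed.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `alignment` (a [SubfamilyAlignment-class]) and
#'   `truth` (list: `conserved`, `pairs` data.frame with coupling).
#' @export
generateMsa <- function(spec) {
  .validateSyntheticSpec(spec)
  set.seed(spec$seed)
  n <- spec$nSeq
  m <- matrix(GAP, n, spec$nCol)
  consCols <- if (is.null(spec$conserved)) integer() else spec$conserved$column
  pairCols <- if (is.null(spec$plantedPairs)) integer() else
    c(spec$plantedPairs$i, spec$plantedPairs$j)
  ## background columns: Dirichlet profile via normalized gammas
  for (j in setdiff(seq_len(spec$nCol), c(consCols, pairCols))) {
    w <- rgamma(20L, shape = spec$background)
    if (sum(w) == 0) w <- rep(1, 20L)
    m[, j] <- sample(AA_ALPHABET, n, replace = TRUE, prob = w / sum(w))
  }
  ## conserved columns: consensus plus a single minority residue, so the
  ## column's entropy stays below the conservation threshold
  if (length(consCols)) {
    for (r in seq_len(nrow(spec$conserved))) {
      cc <- spec$conserved[r, ]
      alt <- setdiff(AA_ALPHABET, cc$consensus)[1L]
      m[, cc$column] <- sample(c(cc$consensus, alt), n, replace = TRUE,
                               prob = c(cc$freq, 1 - cc$freq))
    }
  }
  ## planted covarying pairs: shared hidden state with prob = coupling
  if (!is.null(spec$plantedPairs)) {
    for (p in seq_len(nrow(spec$plantedPairs))) {
      pr <- spec$plantedPairs[p, ]
      ab <- .pairAlphabet(pr, spec$background)
      K <- length(ab$probs)
      coupled <- runif(n) < pr$coupling
      sI <- sample.int(K, n, replace = TRUE, prob = ab$probs)
      sAlt <- sample.int(K, n, replace = TRUE, prob = ab$probs)
      sJ <- ifelse(coupled, sI, sAlt)
      m[, pr$i] <- ab$i[sI]
      m[, pr$j] <- ab$j[sJ]
    }
  }
  ## column-wise independent gap injection
  for (j in seq_len(spec$nCol)) {
    g <- runif(n) < spec$gapRate[j]
    m[g, j] <- GAP
  }
  aln <- Alignment(m, ids = sprintf("syn%04d", seq_len(n)))
  truth <- list(conserved = consCols,
                pairs = if (is.null(spec$plantedPairs))
                  data.frame(i = integer(), j = integer(), coupling = numeric())
                else spec$plantedPairs)
  list(alignment = aln, truth = truth)
}

#' Generate two synthetic subfamilies with controlled network overlap
#'
#' Both subfamilies share a trivial family frame (ungapped reference
#' sequences of equal length, so frame columns equal alignment columns).
#' A fraction `networkOverlap` of the planted pairs occupies identical
#' frame coordinates in both subfamilies; the remainder are disjoint.
#'
#' @param nSeq,nCol alignment shape (shared by both subfamilies).
#' @param nPairs number of planted pairs per subfamily.
#' @param coupling coupling strength of every planted pair.
#' @param networkOverlap fraction of pairs at shared coordinates, in
#'   `[0, 1]`.
#' @param nConserved number of conserved columns per subfamily.
#' @param gapRate per-column gap probability.
#' @param seed integer seed.
#' @return list with elements `A`, `B` (each a list of `alignment`,
#'   `truth`, `positionMap`), and `frame`.
#' @export
generateSubfamilyPair <- function(nSeq = 200L, nCol = 330L, nPairs = 10L,
                                  coupling = 0.9, networkOverlap = 1,
                                  nConserved = 20L, gapRate = 0.02,
                                  seed = 1L) {
  stopifnot(networkOverlap >= 0, networkOverlap <= 1)
  nShared <- round(networkOverlap * nPairs)
  nDisjoint <- nPairs - nShared
  needed <- 2L * (nShared + 2L * nDisjoint) + nConserved
  if (needed > nCol)
    stop("infeasible overlap: ", needed, " distinct columns needed but only ",
         nCol, " available")
  set.seed(.substreamSeed(seed, 0L))
  cols <- sample.int(nCol, needed)
  take <- function(k) {
    out <- cols[seq_len(k)]
    cols <<- cols[setdiff(seq_along(cols), seq_len(k))]
    out
  }
  consCols <- sort(take(nConserved))
  sharedCols <- take(2L * nShared)
  aOnly <- take(2L * nDisjoint)
  bOnly <- take(2L * nDisjoint)
  mkPairs <- function(shared, own) {
    ij <- matrix(c(shared, own), ncol = 2L, byrow = TRUE)
    data.frame(i = pmin(ij[, 1], ij[, 2]), j = pmax(ij[, 1], ij[, 2]),
               coupling = coupling)
  }
  consensus <- AA_ALPHABET[(seq_len(nConserved) - 1L) %% 20L + 1L]
  conserved <- if (nConserved > 0)
    data.frame(column = consCols, consensus = consensus, freq = 0.97)
  ## conserved core sites are ungapped, as in real subfamily alignments
  gapRates <- rep_len(gapRate, nCol)
  gapRates[consCols] <- 0
  specFor <- function(own, stream) {
    syntheticSpec(nSeq = nSeq, nCol = nCol, conserved = conserved,
                  plantedPairs = mkPairs(sharedCols, own),
                  gapRate = gapRates, seed = .substreamSeed(seed, stream))
  }
  genA <- generateMsa(specFor(aOnly, 1L))
  genB <- generateMsa(specFor(bOnly, 2L))
  genA$alignment@subfamily <- "synA"
  genB$alignment@subfamily <- "synB"
  ## trivial shared frame: ungapped references spanning every column
  refSeq <- paste(rep("A", nCol), collapse = "")
  refAln <- Alignment(c(refA = refSeq, refB = refSeq, anchor = refSeq))
  frame <- buildFamilyFrame(refAln, "anchor")
  pmFor <- function(gen, refId) {
    new("PositionMap", subfamily = gen$alignment@subfamily, refId = refId,
        columns = seq_len(nCol), refResidues = seq_len(nCol))
  }
  list(A = c(genA, list(positionMap = pmFor(genA, "refA"))),
       B = c(genB, list(positionMap = pmFor(genB, "refB"))),
       frame = frame)
}

#' Build a toy two-chain structure with labeled entities
#'
#' Constructs a [StructureModel-class] from explicit atom placements;
#' useful for exercising contact detection with known geometry. Entities
#' use the standard vocabulary (`protein_A`, `protein_B`, `DNA`,
#' `ligand`, `partner_protein`).
#'
#' @param atoms data.frame with columns `entity`, `chain`, `resno`,
#'   `elety`, `x`, `y`, `z`.
#' @param path optional path; when given, the model is also written as a
#'   PDB file (via bio3d).
#' @return a [StructureModel-class]
#' @export
makeToyStructure <- function(atoms, path = NULL) {
  s <- new("StructureModel", atoms = atoms)
  if (!is.null(path)) writeStructure(s, path)
  s
}
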