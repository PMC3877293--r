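#' SubfamilyAlignment: an aligned protein sequence set
#'
#' Holds one subfamily (or subcluster) multiple sequence alignment over
#' the 20 standard amino acids plus the gap character `-`. All scoring,
#' filtering and network construction operates on this class.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot seqs character matrix (sequences x columns) of single residues.
#' @slot subfamily optional subfamily label.
#' @export
setClass("SubfamilyAlignment",
  slots = c(ids = "character", seqs = "matrix", subfamily = "character"))

setValidity("SubfamilyAlignment", function(object) {
  msg <- character()
  if (nrow(object@seqs) != length(object@ids))
    msg <- c(msg, "number of ids must match number of sequences")
  if (length(object@ids) < 2L)
    msg <- c(msg, "an alignment needs at least 2 sequences")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate sequence ids: %s",
                          paste(unique(object@ids[duplicated(object@ids)]),
                                collapse = ", ")))
  bad <- !(object@seqs %in% c(AA_ALPHABET, GAP))
  if (any(bad))
    msg <- c(msg, sprintf("non-standard residues present (%s); convert on read",
                          paste(unique(object@seqs[bad]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PositionMap: subfamily columns to reference residues
#'
#' Maps alignment columns of one subfamily to the 1-based ungapped residue
#' indices of its designated reference sequence. Columns where the
#' reference carries a gap are unmapped.
#'
#' @slot subfamily subfamily label.
#' @slot refId id of the designated reference sequence.
#' @slot columns 1-based subfamily alignment columns (increasing).
#' @slot refResidues 1-based reference residue index per mapped column.
#' @export
setClass("PositionMap",
  slots = c(subfamily = "character", refId = "character",
            columns = "integer", refResidues = "integer"))

setValidity("PositionMap", function(object) {
  msg <- character()
  if (length(object@columns) != length(object@refResidues))
    msg <- c(msg, "columns and refResidues must have equal length")
  if (is.unsorted(object@refResidues, strictly = TRUE))
    msg <- c(msg, "refResidues must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' FamilyFrame: the shared coordinate system across subfamilies
#'
#' Built from the reference-sequence alignment: each subfamily's reference
#' residues are tied to reference-alignment (frame) columns, and frame
#' columns carry anchor residue numbers (e.g. LacI numbering) where the
#' anchor row is ungapped.
#'
#' @slot width number of frame (reference alignment) columns.
#' @slot refToFrame named list; per subfamily an integer vector giving the
#'   frame column of each reference residue (index = residue number).
#' @slot anchorId id of the numbering anchor sequence.
#' @slot anchorNumbers integer vector of length `width`; anchor residue
#'   number per frame column, NA where the anchor has a gap.
#' @export
setClass("FamilyFrame",
  slots = c(width = "integer", refToFrame = "list",
            anchorId = "character", anchorNumbers = "integer"))

#' EligibilityMask: per-column admission to co-evolution scoring
#'
#' @slot eligible logical per column.
#' @slot gapFraction numeric per column.
#' @slot entropy numeric per column (nats; gap-as-21st-symbol, or
#'   gap-ignoring in ZNMI mode).
#' @slot reasons list of character vectors of rejection reasons per column
#'   (subset of `gap_gt_50`, `low_entropy`, `gap_gt_10_znmi`).
#' @slot mode `"standard"` or `"znmi"`.
#' @export
setClass("EligibilityMask",
  slots = c(eligible = "logical", gapFraction = "numeric",
            entropy = "numeric", reasons = "list", mode = "character"))

setValidity("EligibilityMask", function(object) {
  ok <- object@eligible == (lengths(object@reasons) == 0L)
  if (!all(ok)) "eligible flag must match empty reason set" else TRUE
})

#' ScoreMatrix: symmetric pairwise co-evolution scores
#'
#' @slot algorithm one of `znmi`, `omes`, `mcbasc`, `elsc`, `sca`.
#' @slot scores symmetric numeric matrix over alignment columns; NA marks
#'   the diagonal and ineligible/unscored pairs.
#' @export
setClass("ScoreMatrix",
  slots = c(algorithm = "character", scores = "matrix"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  msg <- character()
  if (nrow(s) != ncol(s)) msg <- c(msg, "score matrix must be square")
  if (any(is.finite(s) & abs(s - t(s)) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "score matrix must be symmetric")
  if (any(is.infinite(s))) msg <- c(msg, "scores must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' CoevolutionNetwork: weighted undirected graph of positions
#'
#' Nodes are frame coordinates of eligible, frame-mapped positions; edges
#' are position pairs weighted by their co-evolution score.
#'
#' @slot subfamily subfamily label.
#' @slot algorithm scoring algorithm label.
#' @slot nodes integer frame coordinates.
#' @slot edges data.frame with columns `a`, `b` (frame coords, a < b) and
#'   `score`.
#' @export
setClass("CoevolutionNetwork",
  slots = c(subfamily = "character", algorithm = "character",
            nodes = "integer", edges = "data.frame"))

setValidity("CoevolutionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e) && any(e$a >= e$b)) msg <- c(msg, "edges must satisfy a < b (no self-loops)")
  if (nrow(e) && !all(c(e$a, e$b) %in% object@nodes))
    msg <- c(msg, "edge endpoints must be network nodes")
  if (length(msg)) msg else TRUE
})

#' RankedSet: elements ordered by descending score
#'
#' @slot kind `"edge"` or `"node"`.
#' @slot keys character element keys (edges as `"a-b"`, nodes as frame
#'   coordinates), in rank order.
#' @slot scores numeric, non-increasing.
#' @export
setClass("RankedSet",
  slots = c(kind = "character", keys = "character", scores = "numeric"))

setValidity("RankedSet", function(object) {
  if (length(object@keys) != length(object@scores))
    return("keys and scores must have equal length")
  if (is.unsorted(rev(object@scores)))
    return("scores must be non-increasing")
  TRUE
})

#' JaccardSweep: threshold-swept network similarity
#'
#' Per threshold N: observed Jaccard of the top-N prefixes, the random
#' model mean/SD/95% CI half-width (1.96 x SD), and the perfect-agreement
#' envelope J_max.
#'
#' @slot table data.frame with columns `N`, `jObs`, `jRandomMean`,
#'   `jRandomSd`, `jRandomCi95`, `jMax`.
#' @slot kind `"edge"` or `"node"`.
#' @slot sizeA,sizeB universe sizes.
#' @slot theta size of the universe intersection.
#' @export
setClass("JaccardSweep",
  slots = c(table = "data.frame", kind = "character",
            sizeA = "integer", sizeB = "integer", theta = "integer"))

setValidity("JaccardSweep", function(object) {
  t <- object@table
  msg <- character()
  if (any(t$jObs > t$jMax + 1e-9)) msg <- c(msg, "jObs must not exceed jMax")
  if (any(t$jObs < 0 | t$jMax > 1 + 1e-12)) msg <- c(msg, "Jaccard values must lie in [0,1]")
  if (any(t$jRandomCi95 < 0)) msg <- c(msg, "CI half-width must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ConsensusRanking: cross-algorithm consensus of top positions
#'
#' @slot table data.frame with one row per node: per-algorithm max-edge
#'   score and z-score columns, `consensus` (mean z), `rank`, `topK`.
#' @slot k size of the flagged top set.
#' @export
setClass("ConsensusRanking",
  slots = c(table = "data.frame", k = "integer"))

#' StructureModel: labeled heavy-atom coordinates
#'
#' @slot atoms data.frame with columns `entity` (one of `protein_A`,
#'   `protein_B`, `DNA`, `ligand`, `partner_protein`), `chain`, `resno`,
#'   `elety`, `x`, `y`, `z`.
#' @export
setClass("StructureModel", slots = c(atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("entity", "chain", "resno", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SubfamilyAlignment", function(object) {
  cat(sprintf("SubfamilyAlignment%s: %d sequences x %d columns\n",
              if (nzchar(object@subfamily)) paste0(" [", object@subfamily, "]") else "",
              nrow(object@seqs), ncol(object@seqs)))
})

setMethod("show", "PositionMap", function(object) {
  cat(sprintf("PositionMap [%s] ref=%s: %d mapped columns\n",
              object@subfamily, object@refId, length(object@columns)))
})

setMethod("show", "FamilyFrame", function(object) {
  cat(sprintf("FamilyFrame: width %d, %d subfamilies, anchor=%s (%d numbered columns)\n",
              object@width, length(object@refToFrame), object@anchorId,
              sum(!is.na(object@anchorNumbers))))
})

setMethod("show", "EligibilityMask", function(object) {
  cat(sprintf("EligibilityMask (%s): %d/%d columns eligible\n",
              object@mode, sum(object@eligible), length(object@eligible)))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix [%s]: %d columns, %d scored pairs\n",
              object@algorithm, ncol(object@scores),
              sum(is.finite(object@scores[upper.tri(object@scores)]))))
})

setMethod("show", "CoevolutionNetwork", function(object) {
  cat(sprintf("CoevolutionNetwork [%s/%s]: %d nodes, %d edges\n",
              object@subfamily, object@algorithm,
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "JaccardSweep", function(object) {
  cat(sprintf("JaccardSweep (%s): %d thresholds; |U_A|=%d |U_B|=%d theta=%d\n",
              object@kind, nrow(object@table), object@sizeA, object@sizeB,
              object@theta))
})

setMethod("show", "ConsensusRanking", function(object) {
  cat(sprintf("ConsensusRanking: %d nodes, top-%d flagged\n",
              nrow(object@table), object@k))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d atoms, entities: %s\n",
              nrow(object@atoms),
              paste(unique(object@atoms$entity), collapse = ", ")))
})
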