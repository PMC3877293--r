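#' Construct a SubfamilyAlignment from residue strings
#'
#' Non-standard residue codes (B, J, O, U, X, Z and `.`) are converted to
#' gaps with a warning reporting the number of replacements; all scoring
#' kernels are defined on the 20-residue + gap alphabet only.
#'
#' @param seqs character vector of equal-length residue strings, or a
#'   character matrix of single residues.
#' @param ids sequence identifiers (unique); defaults to names of `seqs`.
#' @param subfamily optional subfamily label.
#' @return a [SubfamilyAlignment-class]
#' @export
Alignment <- function(seqs, ids = names(seqs), subfamily = "") {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(ids)) ids <- rownames(m)
  } else {
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      off <- ids[lens != lens[1L]][1L]
      stop("ragged alignment: sequence '", off, "' has length ",
           lens[ids == off][1L], " but expected ", lens[1L])
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  nonstd <- !(m %in% c(AA_ALPHABET, GAP))
  if (any(nonstd)) {
    warning(sum(nonstd), " non-standard residue(s) (",
            paste(unique(m[nonstd]), collapse = ", "),
            ") converted to gaps")
    m[nonstd] <- GAP
  }
  rownames(m) <- NULL
  new("SubfamilyAlignment", ids = as.character(ids), seqs = m,
      subfamily = subfamily)
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @param subfamily optional subfamily label attached to the result.
#' @return a [SubfamilyAlignment-class]; sequence order is preserved.
#' @export
readAlignment <- function(path, subfamily = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    off <- ids[w != w[1L]][1L]
    stop("ragged alignment in ", path, ": sequence '", off,
         "' has length ", w[ids == off][1L], " but expected ", w[1L])
  }
  Alignment(as.character(ss), ids = ids, subfamily = subfamily)
}

#' Write an alignment as FASTA
#'
#' @param a a [SubfamilyAlignment-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(a, path) {
  seqs <- apply(a@seqs, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(setNames(seqs, a@ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Subset an alignment by sequence indices
#'
#' @param a a [SubfamilyAlignment-class]
#' @param i integer or logical index over sequences.
#' @return a [SubfamilyAlignment-class] with the selected records.
#' @export
selectSequences <- function(a, i) {
  new("SubfamilyAlignment", ids = a@ids[i],
      seqs = a@seqs[i, , drop = FALSE], subfamily = a@subfamily)
}

#' Designate a reference sequence and derive its position map
#'
#' The map covers exactly the columns where the reference record carries a
#' residue; columns gapped in the reference are unmapped.
#'
#' @param a a [SubfamilyAlignment-class]
#' @param refId id of the reference record in `a`.
#' @return a [PositionMap-class]
#' @export
designateReference <- function(a, refId) {
  k <- match(refId, a@ids)
  if (is.na(k)) stop("reference id '", refId, "' not present in alignment")
  row <- a@seqs[k, ]
  cols <- which(row != GAP)
  new("PositionMap", subfamily = a@subfamily, refId = refId,
      columns = as.integer(cols), refResidues = seq_along(cols))
}

#' Build the family frame from the reference-sequence alignment
#'
#' Each row of the reference alignment ties that sequence's ungapped
#' residues to frame columns; the anchor row's residues provide anchor
#' (e.g. LacI) numbering for frame columns.
#'
#' @param refAlignment a [SubfamilyAlignment-class] holding one reference
#'   sequence per subfamily plus the anchor sequence.
#' @param anchorId id of the numbering anchor row.
#' @return a [FamilyFrame-class]
#' @export
buildFamilyFrame <- function(refAlignment, anchorId) {
  if (!(anchorId %in% refAlignment@ids))
    stop("anchor id '", anchorId, "' not present in reference alignment")
  width <- ncol(refAlignment@seqs)
  refToFrame <- lapply(seq_len(nrow(refAlignment@seqs)), function(k) {
    as.integer(which(refAlignment@seqs[k, ] != GAP))
  })
  names(refToFrame) <- refAlignment@ids
  anchorCols <- refToFrame[[anchorId]]
  anchorNumbers <- rep(NA_integer_, width)
  anchorNumbers[anchorCols] <- seq_along(anchorCols)
  new("FamilyFrame", width = as.integer(width), refToFrame = refToFrame,
      anchorId = anchorId, anchorNumbers = anchorNumbers)
}

#' Map subfamily alignment columns to frame coordinates
#'
#' Composes a subfamily [PositionMap-class] (column -> reference residue)
#' with the [FamilyFrame-class] (reference residue -> frame column).
#'
#' @param columns 1-based subfamily alignment columns.
#' @param pm the subfamily's [PositionMap-class].
#' @param frame the [FamilyFrame-class]; the map of `pm@refId` is used.
#' @return integer frame columns, NA where unmapped.
#' @export
mapToFrame <- function(columns, pm, frame) {
  refRow <- frame@refToFrame[[pm@refId]]
  if (is.null(refRow))
    stop("reference id '", pm@refId, "' has no row in the family frame")
  res <- pm@refResidues[match(columns, pm@columns)]
  out <- rep(NA_integer_, length(columns))
  ok <- !is.na(res) & res <= length(refRow)
  out[ok] <- refRow[res[ok]]
  out
}

#' Map frame coordinates back to subfamily alignment columns
#'
#' @param frameColumns integer frame columns.
#' @param pm the subfamily's [PositionMap-class].
#' @param frame the [FamilyFrame-class].
#' @return integer subfamily columns, NA where the subfamily has no
#'   position at a frame column.
#' @export
mapFromFrame <- function(frameColumns, pm, frame) {
  refRow <- frame@refToFrame[[pm@refId]]
  res <- match(frameColumns, refRow)
  pm@columns[match(res, pm@refResidues)]
}

#' All-vs-all fractional sequence identity
#'
#' Identity of a pair is the number of columns with identical residues
#' (both ungapped) divided by the number of columns where at least one of
#' the two sequences is ungapped; mutual-gap columns are excluded from the
#' denominator.
#'
#' @param a a [SubfamilyAlignment-class]
#' @return symmetric numeric matrix with unit diagonal.
#' @export
pairwiseIdentity <- function(a) {
  m <- a@seqs
  n <- nrow(m)
  enc <- matrix(match(m, c(AA_ALPHABET, GAP)), nrow = n)
  gapIdx <- length(AA_ALPHABET) + 1L
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in seq(i + 1L, n)) {
      xj <- enc[j, ]
      denom <- sum(xi != gapIdx | xj != gapIdx)
      match_ <- sum(xi == xj & xi != gapIdx)
      out[i, j] <- out[j, i] <- if (denom > 0) match_ / denom else NA_real_
    }
  }
  dimnames(out) <- list(a@ids, a@ids)
  out
}

#' Export the frame map as TSV
#'
#' One row per mapped subfamily column, with columns `subfamily_id`,
#' `subfamily_column`, `ref_residue`, `frame_column`, `anchor_number`
#' (all columns 1-based).
#'
#' @param frame a [FamilyFrame-class]
#' @param positionMaps list of [PositionMap-class], one per subfamily.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
exportFrameMap <- function(frame, positionMaps, path) {
  rows <- lapply(positionMaps, function(pm) {
    fc <- mapToFrame(pm@columns, pm, frame)
    data.frame(subfamily_id = pm@subfamily,
               subfamily_column = pm@columns,
               ref_residue = pm@refResidues,
               frame_column = fc,
               anchor_number = frame@anchorNumbers[fc])
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
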