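#' Residue profile of one alignment column
#'
#' @param column character vector of single residues (gaps as `-`).
#' @param gapMode `"count_gap_as_21st"` (gaps enter the frequency vector as
#'   a 21st symbol) or `"ignore_gaps"` (frequencies over ungapped residues
#'   only; the ZNMI convention).
#' @return list with `counts` (named, 21 symbols), `freqs` (over included
#'   symbols, summing to 1), `gapFraction`, `gapMode`.
#' @export
columnProfile <- function(column, gapMode = c("count_gap_as_21st", "ignore_gaps")) {
  gapMode <- match.arg(gapMode)
  symbols <- c(AA_ALPHABET, GAP)
  counts <- table(factor(column, levels = symbols))
  counts <- setNames(as.integer(counts), symbols)
  gapFraction <- counts[GAP] / length(column)
  inc <- if (gapMode == "count_gap_as_21st") counts else counts[AA_ALPHABET]
  tot <- sum(inc)
  freqs <- if (tot > 0) inc / tot else inc * 0
  list(counts = counts, freqs = freqs,
       gapFraction = unname(gapFraction), gapMode = gapMode)
}

#' Positional entropy of a residue frequency profile
#'
#' S = -sum f_i ln f_i in nats, with 0 ln 0 := 0.
#'
#' @param p a profile from [columnProfile()], or a numeric frequency vector.
#' @return entropy in nats (>= 0).
#' @export
positionalEntropy <- function(p) {
  f <- if (is.list(p)) p$freqs else p
  f <- f[f > 0]
  if (!length(f)) return(0)
  -sum(f * log(f))
}

#' Conservation / variability entropy threshold
#'
#' The entropy of a column with 5% variability: -(0.05 ln 0.05 +
#' 0.95 ln 0.95), about 0.1985 nats. Columns with entropy strictly below
#' this are treated as conserved and excluded from covariation scoring.
#'
#' @return threshold in nats.
#' @export
entropyThreshold <- function() {
  -(0.05 * log(0.05) + 0.95 * log(0.95))
}

#' Column eligibility mask for co-evolution scoring
#'
#' A column is rejected when its gap fraction exceeds `gapThreshold`
#' (reason `gap_gt_50`), when its entropy falls strictly below the 5%
#' variability threshold (reason `low_entropy`; gap-as-21st-symbol entropy,
#' or gap-ignoring entropy in ZNMI mode), or -- in ZNMI mode only -- when
#' its gap fraction exceeds 10% (reason `gap_gt_10_znmi`).
#'
#' @param a a [SubfamilyAlignment-class]
#' @param gapThreshold gap-fraction rejection bound (default 0.5).
#' @param znmiMode logical; apply the ZNMI conventions.
#' @return an [EligibilityMask-class]
#' @export
eligibilityMask <- function(a, gapThreshold = 0.5, znmiMode = FALSE) {
  m <- a@seqs
  thr <- entropyThreshold()
  gapMode <- if (znmiMode) "ignore_gaps" else "count_gap_as_21st"
  nc <- ncol(m)
  gapFraction <- numeric(nc)
  entropy <- numeric(nc)
  reasons <- vector("list", nc)
  for (j in seq_len(nc)) {
    p <- columnProfile(m[, j], gapMode = gapMode)
    gapFraction[j] <- p$gapFraction
    entropy[j] <- positionalEntropy(p)
    r <- character()
    if (gapFraction[j] > gapThreshold) r <- c(r, "gap_gt_50")
    if (entropy[j] < thr) r <- c(r, "low_entropy")
    if (znmiMode && gapFraction[j] > 0.10) r <- c(r, "gap_gt_10_znmi")
    reasons[[j]] <- r
  }
  new("EligibilityMask", eligible = lengths(reasons) == 0L,
      gapFraction = gapFraction, entropy = entropy, reasons = reasons,
      mode = if (znmiMode) "znmi" else "standard")
}

#' Conserved columns of an alignment
#'
#' Columns with gap-as-21st-symbol entropy strictly below the threshold
#' and gap fraction <= 0.5; the consensus is the modal ungapped residue
#' (ties broken alphabetically).
#'
#' @param a a [SubfamilyAlignment-class]
#' @return data.frame with columns `column`, `consensus`, `entropy`.
#' @export
conservedSet <- function(a) {
  m <- a@seqs
  thr <- entropyThreshold()
  rows <- lapply(seq_len(ncol(m)), function(j) {
    p <- columnProfile(m[, j], gapMode = "count_gap_as_21st")
    s <- positionalEntropy(p)
    if (s < thr && p$gapFraction <= 0.5) {
      aa <- p$counts[AA_ALPHABET]
      cons <- names(aa)[which.max(aa)]  # which.max: first (alphabetical) tie
      data.frame(column = j, consensus = cons, entropy = s)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(column = integer(), consensus = character(),
                      entropy = numeric())
  out
}

#' Cross-subfamily conservation classification in frame coordinates
#'
#' Labels each frame column by the number of subfamilies conserving it:
#' `unique` (exactly one), `shared` (two or more), `not_conserved`
#' (present somewhere but conserved nowhere), `absent` (no subfamily has a
#' position there).
#'
#' @param conservedFrameSets named list of integer vectors: frame columns
#'   conserved in each subfamily.
#' @param presentFrameSets named list of integer vectors: frame columns at
#'   which each subfamily has a position. Defaults to all frame columns.
#' @param frame a [FamilyFrame-class] (used for width and anchor numbers).
#' @return data.frame with `frame_column`, `anchor_number`, `n_conserved`,
#'   `label`, and one logical column per subfamily.
#' @export
classifyConservation <- function(conservedFrameSets, frame,
                                 presentFrameSets = NULL) {
  if (length(conservedFrameSets) < 2L)
    stop("classification needs at least 2 subfamilies")
  width <- frame@width
  if (is.null(presentFrameSets))
    presentFrameSets <- lapply(conservedFrameSets, function(x) seq_len(width))
  consMat <- sapply(conservedFrameSets, function(s) seq_len(width) %in% s)
  present <- rowSums(sapply(presentFrameSets, function(s) seq_len(width) %in% s)) > 0
  k <- rowSums(consMat)
  label <- ifelse(!present, "absent",
           ifelse(k == 0, "not_conserved",
           ifelse(k == 1, "unique", "shared")))
  out <- data.frame(frame_column = seq_len(width),
                    anchor_number = frame@anchorNumbers,
                    n_conserved = as.integer(k), label = label)
  cbind(out, as.data.frame(consMat))
}

#' Overlap of two conserved-position sets
#'
#' @param consA,consB integer vectors of frame columns conserved in each
#'   subcluster.
#' @return list with `nBoth` (conserved in both) and `nOnlyOne`
#'   (conserved in exactly one).
#' @export
subclusterOverlap <- function(consA, consB) {
  both <- intersect(consA, consB)
  only <- union(setdiff(consA, consB), setdiff(consB, consA))
  list(nBoth = length(both), nOnlyOne = length(only))
}

#' Export a conservation classification as TSV
#'
#' @param classification data.frame from [classifyConservation()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
exportConservation <- function(classification, path) {
  write.table(classification, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
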