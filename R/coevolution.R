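#' Joint residue counts for a column pair
#'
#' Counts are taken over the valid sequences: those with no gap at either
#' column.
#'
#' @param a a [SubfamilyAlignment-class]
#' @param i,j 1-based column indices.
#' @return list with `joint` (20x20 count matrix), `nx`, `ny` (marginals),
#'   `nValid`.
#' @export
pairCounts <- function(a, i, j) {
  m <- a@seqs
  x <- m[, i]
  y <- m[, j]
  ok <- x != GAP & y != GAP
  joint <- table(factor(x[ok], levels = AA_ALPHABET),
                 factor(y[ok], levels = AA_ALPHABET))
  joint <- matrix(as.integer(joint), 20, 20,
                  dimnames = list(AA_ALPHABET, AA_ALPHABET))
  list(joint = joint, nx = rowSums(joint), ny = colSums(joint),
       nValid = sum(ok))
}

#' Mutual information of a column pair
#'
#' I = sum p_xy ln(p_xy / (p_x p_y)) in nats; joint entropy
#' H = -sum p_xy ln p_xy; NMI = I/H (0 when H = 0).
#'
#' @param pc pair counts from [pairCounts()].
#' @return list with `I`, `H`, `NMI`.
#' @export
mutualInformation <- function(pc) {
  stopifnot(pc$nValid >= 1)
  p <- pc$joint / pc$nValid
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  I <- sum(p[nz] * log(p[nz] / (px[nz[, 1]] * py[nz[, 2]])))
  H <- -sum(p[nz] * log(p[nz]))
  list(I = I, H = H, NMI = if (H > 0) I / H else 0)
}

.emptyScores <- function(ncol) {
  matrix(NA_real_, ncol, ncol)
}

.wrapKernel <- function(a, mask, algorithm, kernelFun) {
  if (is.null(mask))
    mask <- eligibilityMask(a, znmiMode = algorithm == "znmi")
  cols <- eligibleColumns(mask)
  scores <- .emptyScores(nCol(a))
  if (length(cols) >= 2L) {
    enc <- .encodeAlignment(a)
    scores[cols, cols] <- kernelFun(enc, as.integer(cols))
  }
  new("ScoreMatrix", algorithm = algorithm, scores = scores)
}

#' OMES covariation scores
#'
#' Observed-minus-expected-squared statistic per column pair:
#' sum over residue-pair cells of (N_obs - N_ex)^2 / N_valid with
#' N_ex = N_x N_y / N_valid, over the sequences ungapped at both columns.
#'
#' @param a a [SubfamilyAlignment-class]
#' @param mask an [EligibilityMask-class] (standard mode); computed from
#'   `a` when NULL.
#' @return a [ScoreMatrix-class]
#' @export
scoreOmes <- function(a, mask = NULL) {
  .wrapKernel(a, mask, "omes", omesKernel)
}

#' McBASC covariation scores
#'
#' Correlation of McLachlan similarity profiles over all ordered sequence
#' pairs; no sequence-identity prefilter is applied. Sequence pairs with a
#' gap at a column contribute similarity 0 there, and columns with zero
#' similarity variance yield score 0 for their pairs.
#'
#' @inheritParams scoreOmes
#' @return a [ScoreMatrix-class]
#' @export
scoreMcbasc <- function(a, mask = NULL) {
  .wrapKernel(a, mask, "mcbasc",
              function(enc, cols) mcbascKernel(enc, cols, .MCLACHLAN))
}

#' ELSC covariation scores
#'
#' Explicit likelihood of subset covariation: perturbing at one column
#' keeps the sequences carrying its modal residue; the score at the other
#' column is -ln of the product over residues of C(N_y, n_y)/C(N_y, m_y),
#' with m_y ideal (largest-remainder) counts. The two perturbation
#' directions are averaged.
#'
#' @inheritParams scoreOmes
#' @return a [ScoreMatrix-class]
#' @export
scoreElsc <- function(a, mask = NULL) {
  .wrapKernel(a, mask, "elsc", elscKernel)
}

#' SCA covariation scores
#'
#' Statistical coupling analysis: perturbing at one column keeps its
#' modal-residue subalignment (size M); the coupling at the other column
#' is kT* sqrt(sum_x (dG_x^sub - dG_x^full)^2), where dG_x is the
#' log-binomial statistical energy of residue x's frequency at depth M
#' relative to background residue frequencies (the mean residue
#' frequencies of the input alignment). Both energies are evaluated at
#' the subalignment depth, so an unperturbed frequency profile scores
#' exactly zero; residue classes absent from the background are excluded.
#' kT* = 1; the two perturbation directions are averaged.
#'
#' @inheritParams scoreOmes
#' @return a [ScoreMatrix-class]
#' @export
scoreSca <- function(a, mask = NULL) {
  bg <- backgroundFrequencies(a)
  .wrapKernel(a, mask, "sca", function(enc, cols) scaKernel(enc, cols, bg))
}

#' Background residue frequencies of an alignment
#'
#' Mean frequency of each of the 20 residues over all ungapped characters;
#' used as the SCA background distribution.
#'
#' @param a a [SubfamilyAlignment-class]
#' @return named numeric vector of length 20 summing to 1.
#' @export
backgroundFrequencies <- function(a) {
  counts <- table(factor(a@seqs, levels = AA_ALPHABET))
  n <- sum(counts)
  if (n == 0) stop("alignment contains no residues")
  setNames(as.numeric(counts) / n, AA_ALPHABET)
}

#' ZNMI covariation scores
#'
#' Normalized mutual information (I over joint entropy) of each eligible
#' column pair, standardized per column: z_i(j) = (NMI_ij - mu_i)/sigma_i
#' with mu_i, sigma_i the mean/SD of column i's NMI values to all other
#' eligible columns. The two column z-scores are combined by
#' inverse-variance weighting; a column with sigma = 0 contributes 0.
#' Requires the ZNMI mask conventions (gap-ignoring entropy, columns with
#' more than 10% gaps excluded).
#'
#' @param a a [SubfamilyAlignment-class]
#' @param mask an [EligibilityMask-class] in ZNMI mode; computed from `a`
#'   when NULL.
#' @return a [ScoreMatrix-class]
#' @export
scoreZnmi <- function(a, mask = NULL) {
  if (is.null(mask)) mask <- eligibilityMask(a, znmiMode = TRUE)
  if (mask@mode != "znmi")
    stop("scoreZnmi requires a ZNMI-mode eligibility mask")
  cols <- eligibleColumns(mask)
  scores <- .emptyScores(nCol(a))
  if (length(cols) >= 2L) {
    enc <- .encodeAlignment(a)
    nmi <- nmiKernel(enc, as.integer(cols))$NMI
    m <- length(cols)
    mu <- numeric(m)
    sigma <- numeric(m)
    for (i in seq_len(m)) {
      v <- nmi[i, -i]
      v <- v[is.finite(v)]
      mu[i] <- if (length(v)) mean(v) else NA_real_
      sigma[i] <- if (length(v) >= 2L) sd(v) else 0
    }
    sigma[!is.finite(sigma)] <- 0
    w <- ifelse(sigma > 0, 1 / sigma^2, 0)
    out <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (!is.finite(nmi[i, j])) next
        zi <- if (sigma[i] > 0) (nmi[i, j] - mu[i]) / sigma[i] else 0
        zj <- if (sigma[j] > 0) (nmi[i, j] - mu[j]) / sigma[j] else 0
        s <- if (w[i] + w[j] > 0) (w[i] * zi + w[j] * zj) / (w[i] + w[j]) else 0
        out[i, j] <- out[j, i] <- s
      }
    }
    scores[cols, cols] <- out
  }
  new("ScoreMatrix", algorithm = "znmi", scores = scores)
}

#' Supported covariation algorithms
#' @return character vector of algorithm ids.
#' @export
coevolutionAlgorithms <- function() {
  c("znmi", "omes", "mcbasc", "elsc", "sca")
}

#' Score an alignment with a named covariation algorithm
#'
#' @param a a [SubfamilyAlignment-class]
#' @param algorithm one of [coevolutionAlgorithms()].
#' @param mask an [EligibilityMask-class] of the algorithm-appropriate
#'   mode; computed from `a` when NULL.
#' @return a [ScoreMatrix-class]
#' @export
scoreAlignment <- function(a, algorithm, mask = NULL) {
  algorithm <- match.arg(algorithm, coevolutionAlgorithms())
  switch(algorithm,
         znmi = scoreZnmi(a, mask),
         omes = scoreOmes(a, mask),
         mcbasc = scoreMcbasc(a, mask),
         elsc = scoreElsc(a, mask),
         sca = scoreSca(a, mask))
}

#' Export a score matrix as a TSV edge list
#'
#' One row per scored pair with frame coordinates and anchor numbers.
#'
#' @param sm a [ScoreMatrix-class]
#' @param pm the subfamily's [PositionMap-class]
#' @param frame the [FamilyFrame-class]
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
exportEdgeList <- function(sm, pm, frame, path) {
  s <- sm@scores
  idx <- which(upper.tri(s) & is.finite(s), arr.ind = TRUE)
  fa <- mapToFrame(idx[, 1], pm, frame)
  fb <- mapToFrame(idx[, 2], pm, frame)
  out <- data.frame(frame_column_a = fa, frame_column_b = fb,
                    anchor_a = frame@anchorNumbers[fa],
                    anchor_b = frame@anchorNumbers[fb],
                    algorithm = sm@algorithm,
                    score = s[idx])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
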