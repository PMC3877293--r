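## McLachlan (1972) amino-acid chemical similarity matrix, integer scores
## 0-9, rows/columns in alphabetical one-letter order. Used by the McBASC
## covariation score; the matrix has no gap entry, so sequence pairs with
## a gap at a column contribute similarity 0 there.
.MCLACHLAN <- matrix(c(
  8, 1, 3, 4, 1, 3, 3, 2, 3, 2, 3, 3, 4, 3, 2, 4, 3, 3, 1, 1,
  1, 9, 1, 0, 0, 1, 3, 1, 0, 0, 3, 1, 0, 0, 1, 2, 2, 1, 2, 1,
  3, 1, 8, 5, 1, 3, 4, 1, 3, 1, 2, 5, 3, 4, 1, 3, 3, 1, 0, 1,
  4, 0, 5, 8, 0, 3, 2, 1, 4, 1, 1, 4, 4, 5, 3, 4, 4, 2, 1, 2,
  1, 0, 1, 0, 9, 0, 4, 3, 0, 5, 5, 0, 1, 0, 1, 2, 1, 3, 6, 6,
  3, 1, 3, 3, 0, 8, 2, 1, 3, 1, 1, 3, 3, 2, 3, 3, 2, 2, 1, 0,
  3, 3, 4, 2, 4, 2, 8, 2, 4, 2, 3, 4, 3, 4, 5, 3, 4, 2, 3, 4,
  2, 1, 1, 1, 3, 1, 2, 8, 1, 5, 5, 1, 1, 0, 1, 2, 3, 5, 3, 3,
  3, 0, 3, 4, 0, 3, 4, 1, 8, 2, 1, 4, 3, 4, 5, 3, 3, 2, 1, 1,
  2, 0, 1, 1, 5, 1, 2, 5, 2, 8, 6, 1, 1, 3, 2, 2, 3, 5, 3, 3,
  3, 3, 2, 1, 5, 1, 3, 5, 1, 6, 8, 2, 1, 3, 1, 2, 3, 4, 1, 2,
  3, 1, 5, 4, 0, 3, 4, 1, 4, 1, 2, 8, 1, 4, 3, 5, 3, 1, 0, 2,
  4, 0, 3, 4, 1, 3, 3, 1, 3, 1, 1, 1, 8, 3, 3, 3, 3, 2, 0, 0,
  3, 0, 4, 5, 0, 2, 4, 0, 4, 3, 3, 4, 3, 8, 5, 4, 3, 2, 2, 1,
  2, 1, 1, 3, 1, 3, 5, 1, 5, 2, 1, 3, 3, 5, 8, 4, 3, 2, 3, 2,
  4, 2, 3, 4, 2, 3, 3, 2, 3, 2, 2, 5, 3, 4, 4, 8, 5, 2, 3, 3,
  3, 2, 3, 4, 1, 2, 4, 3, 3, 3, 3, 3, 3, 3, 3, 5, 8, 3, 2, 1,
  3, 1, 1, 2, 3, 2, 2, 5, 2, 5, 4, 1, 2, 2, 2, 2, 3, 8, 2, 3,
  1, 2, 0, 1, 6, 1, 3, 3, 1, 3, 1, 0, 0, 2, 3, 3, 2, 2, 9, 6,
  1, 1, 1, 2, 6, 0, 4, 3, 1, 3, 2, 2, 0, 1, 2, 3, 1, 3, 6, 9),
  nrow = 20, byrow = TRUE)

#' McLachlan amino-acid similarity matrix
#'
#' The 20x20 chemical similarity matrix of McLachlan (1972), used as the
#' residue similarity kernel by the McBASC covariation score.
#'
#' @return numeric 20x20 symmetric matrix with residues in alphabetical
#'   one-letter order as dimnames.
#' @export
mclachlanMatrix <- function() {
  m <- .MCLACHLAN
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}
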