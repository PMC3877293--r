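CONTACT_LABELS <- c("DNA", "dimer_interface", "ligand", "partner_protein")

#' Read a PDB file into a StructureModel
#'
#' Hydrogens are discarded and, for alternate conformations, only the
#' highest-occupancy conformer of each atom is kept. Entities are assigned
#' per chain via `entityMap`.
#'
#' @param path PDB file path.
#' @param entityMap named character vector mapping chain ids to entities
#'   (`protein_A`, `protein_B`, `DNA`, `ligand`, `partner_protein`);
#'   chains absent from the map are dropped with a message.
#' @return a [StructureModel-class]
#' @export
readStructure <- function(path, entityMap) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  ## highest-occupancy conformer per (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety)
  o <- order(key, -ifelse(is.na(at$o), 1, at$o))
  at <- at[o, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  known <- at$chain %in% names(entityMap)
  if (any(!known))
    message("dropping ", sum(!known), " atom(s) in unmapped chain(s): ",
            paste(unique(at$chain[!known]), collapse = ", "))
  at <- at[known, , drop = FALSE]
  atoms <- data.frame(entity = unname(entityMap[at$chain]),
                      chain = at$chain, resno = at$resno,
                      elety = at$elety, x = at$x, y = at$y, z = at$z)
  new("StructureModel", atoms = atoms)
}

#' Write a StructureModel as a PDB file
#'
#' @param s a [StructureModel-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- s@atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain,
                   resid = rep("GLY", nrow(a)), elety = a$elety)
  invisible(path)
}

.entityCoords <- function(s, entity) {
  a <- s@atoms[s@atoms$entity %in% entity, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

.minDist <- function(xyzA, xyzB) {
  if (!nrow(xyzA) || !nrow(xyzB)) return(NA_real_)
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  sqrt(max(0, min(d2)))
}

#' Minimum inter-residue heavy-atom distance (closest-monomer convention)
#'
#' Distance between residue `posA` in the first monomer (`protein_A`) and
#' residue `posB` in whichever monomer is closer (`protein_A` or
#' `protein_B`), so each pair is measured once across the homodimer.
#'
#' @param s a [StructureModel-class]
#' @param posA,posB residue numbers.
#' @return distance in Angstroms, or NA when a residue is unresolved.
#' @export
minResidueDistance <- function(s, posA, posB) {
  a <- s@atoms
  xyzA <- as.matrix(a[a$entity == "protein_A" & a$resno == posA,
                      c("x", "y", "z"), drop = FALSE])
  dists <- vapply(c("protein_A", "protein_B"), function(ent) {
    xyzB <- as.matrix(a[a$entity == ent & a$resno == posB,
                        c("x", "y", "z"), drop = FALSE])
    if (posA == posB && ent == "protein_A") {
      ## same residue in the same monomer: distance 0 by definition
      if (nrow(xyzA)) 0 else NA_real_
    } else .minDist(xyzA, xyzB)
  }, numeric(1))
  if (all(is.na(dists))) return(NA_real_)
  min(dists, na.rm = TRUE)
}

#' Distance-based structural contact annotation
#'
#' A protein position is labeled `DNA`, `ligand` or `partner_protein` when
#' any of its heavy atoms (in either monomer) lies within `cutoff` of that
#' entity, and `dimer_interface` when within `cutoff` of the other
#' monomer. Label sets grow monotonically with the cutoff.
#'
#' @param s a [StructureModel-class]
#' @param cutoff heavy-atom distance cutoff in Angstroms (default 4.5).
#' @return data.frame with columns `resno` and one logical column per
#'   label, plus `labels` (comma-separated).
#' @export
detectContacts <- function(s, cutoff = 4.5) {
  a <- s@atoms
  prot <- a[a$entity %in% c("protein_A", "protein_B"), , drop = FALSE]
  resnos <- sort(unique(prot$resno))
  ent <- list(DNA = .entityCoords(s, "DNA"),
              ligand = .entityCoords(s, "ligand"),
              partner_protein = .entityCoords(s, "partner_protein"))
  out <- data.frame(resno = resnos)
  for (lab in CONTACT_LABELS) out[[lab]] <- FALSE
  for (r in seq_along(resnos)) {
    for (mono in c("protein_A", "protein_B")) {
      xyz <- as.matrix(prot[prot$entity == mono & prot$resno == resnos[r],
                            c("x", "y", "z"), drop = FALSE])
      if (!nrow(xyz)) next
      for (lab in c("DNA", "ligand", "partner_protein")) {
        d <- .minDist(xyz, ent[[lab]])
        if (!is.na(d) && d <= cutoff) out[[lab]][r] <- TRUE
      }
      other <- a[a$entity == setdiff(c("protein_A", "protein_B"), mono), ,
                 drop = FALSE]
      d <- .minDist(xyz, as.matrix(other[, c("x", "y", "z"), drop = FALSE]))
      if (!is.na(d) && d <= cutoff) out$dimer_interface[r] <- TRUE
    }
  }
  out$labels <- apply(out[, CONTACT_LABELS], 1L, function(v)
    paste(CONTACT_LABELS[v], collapse = ","))
  out
}

#' Distance versus co-evolution score scatter
#'
#' One point per scored edge whose two positions resolve in the structure;
#' scores are Z-normalized. Returns the paired list and the Pearson
#' correlation (NA when score variance is zero).
#'
#' @param net a [CoevolutionNetwork-class]; node coordinates must be the
#'   structure's residue numbers (map via the family frame/anchor first).
#' @param s a [StructureModel-class]
#' @return list with `points` (data.frame: a, b, distance, zscore) and
#'   `r` (Pearson correlation or NA).
#' @export
distanceScoreScatter <- function(net, s) {
  e <- net@edges
  dist <- mapply(function(a, b) minResidueDistance(s, a, b), e$a, e$b)
  keep <- !is.na(dist)
  sdv <- sd(e$score[keep])
  z <- if (!is.finite(sdv) || sdv == 0) rep(NA_real_, sum(keep)) else
    (e$score[keep] - mean(e$score[keep])) / sdv
  pts <- data.frame(a = e$a[keep], b = e$b[keep],
                    distance = dist[keep], zscore = z)
  r <- if (nrow(pts) >= 2L && !all(is.na(z))) cor(pts$distance, pts$zscore)
       else NA_real_
  list(points = pts, r = r)
}

#' Tally a consensus top-positions table
#'
#' Takes a table of top co-evolving positions (one row per position,
#' one mark column per subfamily, a structural-contact label column) and
#' returns exact tallies: unique positions, positions with any contact
#' label, per-label counts, and the number of positions marked in exactly
#' m subfamilies.
#'
#' @param tab data.frame with a `position` column, logical/0-1 subfamily
#'   mark columns given by `subfamilies`, and a `contact` column (empty
#'   string for none).
#' @param subfamilies names of the mark columns; defaults to all columns
#'   except `position`, `domain`, `contact`.
#' @return list with `nPositions`, `nWithContact`, `labelCounts` (named),
#'   `bySubfamilyCount` (named by m).
#' @export
tallyTable <- function(tab, subfamilies = NULL) {
  if (is.null(subfamilies))
    subfamilies <- setdiff(names(tab), c("position", "domain", "contact"))
  contact <- trimws(as.character(tab$contact))
  known <- c("", CONTACT_LABELS)
  if (any(!contact %in% known))
    stop("unknown contact label(s): ",
         paste(unique(contact[!contact %in% known]), collapse = ", "))
  marks <- sapply(tab[subfamilies], function(v) as.logical(as.integer(v)))
  m <- rowSums(marks)
  labelCounts <- vapply(CONTACT_LABELS, function(l) sum(contact == l), 0L)
  list(nPositions = length(unique(tab$position)),
       nWithContact = sum(nzchar(contact)),
       labelCounts = labelCounts,
       bySubfamilyCount = table(factor(m, levels = seq_len(length(subfamilies)))))
}

#' Packaged consensus top-positions table for the LacI/GalR family
#'
#' Loads the packaged transcription of the published consensus table of
#' top co-evolving positions across six LacI/GalR subfamilies (LacI
#' numbering) with their structural-contact annotations.
#'
#' @return data.frame with columns `position`, `domain`, six subfamily
#'   mark columns, and `contact`.
#' @export
lacigalrConsensusTable <- function() {
  path <- system.file("extdata", "lacigalr_top_positions.tsv",
                      package = "coevnet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
}
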