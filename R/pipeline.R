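#' Run configuration for an end-to-end analysis
#'
#' @param alignments named character vector of subfamily FASTA paths, or a
#'   named list of [SubfamilyAlignment-class] objects.
#' @param referenceIds named character vector: reference sequence id per
#'   subfamily.
#' @param referenceAlignment path to the aligned reference FASTA (or a
#'   [SubfamilyAlignment-class]).
#' @param anchorId id of the numbering anchor row in the reference
#'   alignment.
#' @param algorithms subset of [coevolutionAlgorithms()].
#' @param ensemble an [ensembleSpec()]; downstream analyses use this (90%)
#'   ensemble only.
#' @param nShuffles shufflings for the random model (default 1000).
#' @param outDir output directory for TSV exports and the run manifest.
#' @param seed master seed; ensemble and null-model streams are derived
#'   from it.
#' @return a validated config list.
#' @export
runConfig <- function(alignments, referenceIds, referenceAlignment,
                      anchorId, algorithms = coevolutionAlgorithms(),
                      ensemble = ensembleSpec(), nShuffles = 1000L,
                      outDir = tempfile("coevnet_run_"), seed = 1L) {
  algorithms <- match.arg(algorithms, coevolutionAlgorithms(),
                          several.ok = TRUE)
  if (is.character(alignments)) {
    missing_ <- alignments[!file.exists(alignments)]
    if (length(missing_))
      stop("alignment file not found: ", paste(missing_, collapse = ", "))
  }
  if (is.character(referenceAlignment) && !file.exists(referenceAlignment))
    stop("reference alignment file not found: ", referenceAlignment)
  if (is.null(names(alignments)) || !all(names(alignments) %in% names(referenceIds)))
    stop("every subfamily alignment needs a named entry in referenceIds")
  list(alignments = alignments, referenceIds = referenceIds,
       referenceAlignment = referenceAlignment, anchorId = anchorId,
       algorithms = algorithms, ensemble = ensemble,
       nShuffles = as.integer(nShuffles), outDir = outDir,
       seed = as.integer(seed))
}

.loadAlignment <- function(x, subfamily) {
  if (is(x, "SubfamilyAlignment")) {
    if (!nzchar(x@subfamily)) x@subfamily <- subfamily
    x
  } else readAlignment(x, subfamily = subfamily)
}

#' Run the full pipeline: conserve, score, map, compare, consensus
#'
#' For each subfamily: computes eligibility masks and conserved sets,
#' ensemble-averaged scores per algorithm, and frame-mapped networks.
#' Between every subfamily pair (per algorithm): edge- and node-wise
#' threshold-swept Jaccard comparisons against random and agreement
#' models. Per subfamily: cross-algorithm consensus ranking. All tables
#' are written as TSV under `cfg$outDir` along with a JSON run manifest
#' recording seeds and per-stage filtering counts. Deterministic given the
#' config.
#'
#' @param cfg a [runConfig()].
#' @return invisible list with networks, sweeps, consensus rankings, the
#'   frame, and the manifest.
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  subfams <- names(cfg$alignments)
  alns <- lapply(subfams, function(sf) .loadAlignment(cfg$alignments[[sf]], sf))
  names(alns) <- subfams
  refAln <- .loadAlignment(cfg$referenceAlignment, "reference")
  frame <- buildFamilyFrame(refAln, cfg$anchorId)
  manifest <- list(seed = cfg$seed, algorithms = cfg$algorithms,
                   ensemble = cfg$ensemble, nShuffles = cfg$nShuffles,
                   subfamilies = list())
  pms <- list()
  masks <- list()
  networks <- list()
  consensus <- list()
  for (sf in subfams) {
    a <- alns[[sf]]
    pms[[sf]] <- designateReference(a, cfg$referenceIds[[sf]])
    masks[[sf]] <- list(standard = eligibilityMask(a),
                        znmi = eligibilityMask(a, znmiMode = TRUE))
    cons <- conservedSet(a)
    info <- list(nSeq = nSeq(a), nCol = nCol(a),
                 nEligibleStandard = sum(masks[[sf]]$standard@eligible),
                 nEligibleZnmi = sum(masks[[sf]]$znmi@eligible),
                 nConserved = nrow(cons), droppedEdges = list())
    networks[[sf]] <- list()
    sms <- list()
    for (alg in cfg$algorithms) {
      mask <- if (alg == "znmi") masks[[sf]]$znmi else masks[[sf]]$standard
      spec <- ensembleSpec(cfg$ensemble$fraction, cfg$ensemble$nReps,
                           .substreamSeed(cfg$seed, match(sf, subfams) * 100L +
                                            match(alg, cfg$algorithms)))
      sm <- ensembleScores(a, alg, spec, mask)
      sms[[alg]] <- sm
      net <- buildNetwork(sm, pms[[sf]], frame)
      info$droppedEdges[[alg]] <- attr(net@edges, "nDroppedEdges")
      networks[[sf]][[alg]] <- net
      exportEdgeList(sm, pms[[sf]], frame,
                     file.path(cfg$outDir, paste0("edges_", sf, "_", alg, ".tsv")))
    }
    consensus[[sf]] <- consensusNodes(sms)
    exportConsensus(consensus[[sf]],
                    file.path(cfg$outDir, paste0("consensus_", sf, ".tsv")))
    manifest$subfamilies[[sf]] <- info
  }
  ## conservation classification across subfamilies, with per-subfamily
  ## consensus residue and entropy at each frame column
  if (length(subfams) >= 2L) {
    consTabs <- lapply(subfams, function(sf) {
      cs <- conservedSet(alns[[sf]])
      cs$frame <- mapToFrame(cs$column, pms[[sf]], frame)
      cs[!is.na(cs$frame), , drop = FALSE]
    })
    names(consTabs) <- subfams
    consSets <- lapply(consTabs, function(cs) sort(cs$frame))
    presSets <- lapply(subfams, function(sf) {
      fc <- mapToFrame(seq_len(nCol(alns[[sf]])), pms[[sf]], frame)
      sort(fc[!is.na(fc)])
    })
    names(presSets) <- subfams
    cls <- classifyConservation(consSets, frame, presSets)
    for (sf in subfams) {
      idx <- match(cls$frame_column, consTabs[[sf]]$frame)
      cls[[paste0("consensus_", sf)]] <- consTabs[[sf]]$consensus[idx]
      cls[[paste0("entropy_", sf)]] <- consTabs[[sf]]$entropy[idx]
    }
    exportConservation(cls, file.path(cfg$outDir, "conservation.tsv"))
  }
  ## pairwise network comparisons
  sweeps <- list()
  if (length(subfams) >= 2L) {
    pairs <- combn(subfams, 2L)
    for (p in seq_len(ncol(pairs))) {
      sfA <- pairs[1L, p]
      sfB <- pairs[2L, p]
      for (alg in cfg$algorithms) {
        cmp <- compareNetworks(networks[[sfA]][[alg]], networks[[sfB]][[alg]],
                               nShuffles = cfg$nShuffles,
                               seed = .substreamSeed(cfg$seed, 10000L + p))
        key <- paste(sfA, sfB, alg, sep = "_")
        sweeps[[key]] <- cmp
        exportSweep(cmp$edges,
                    file.path(cfg$outDir, paste0("sweep_edges_", key, ".tsv")))
        exportSweep(cmp$nodes,
                    file.path(cfg$outDir, paste0("sweep_nodes_", key, ".tsv")))
      }
    }
  }
  exportFrameMap(frame, pms, file.path(cfg$outDir, "frame_map.tsv"))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(networks = networks, sweeps = sweeps, consensus = consensus,
                 frame = frame, positionMaps = pms, masks = masks,
                 manifest = manifest, outDir = cfg$outDir))
}

#' Compare two co-evolution networks (edges and nodes)
#'
#' Threshold-swept Jaccard statistics for the ranked edge sets and ranked
#' node sets of two networks in the same family frame, each against its
#' random and perfect-agreement models.
#'
#' @param netA,netB [CoevolutionNetwork-class] objects in the same frame.
#' @param nShuffles shufflings for the random model.
#' @param seed integer seed.
#' @return list with `edges` and `nodes` ([JaccardSweep-class] each).
#' @export
compareNetworks <- function(netA, netB, nShuffles = 1000L, seed = 1L) {
  edges <- jaccardSweep(rankEdges(netA), rankEdges(netB),
                        universeA = edgeUniverse(netA),
                        universeB = edgeUniverse(netB),
                        nShuffles = nShuffles, seed = seed)
  nodes <- jaccardSweep(rankNodes(netA), rankNodes(netB),
                        universeA = as.character(netA@nodes),
                        universeB = as.character(netB@nodes),
                        nShuffles = nShuffles, seed = .substreamSeed(seed, 1L))
  list(edges = edges, nodes = nodes)
}
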