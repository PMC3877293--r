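# coevnet

Conservation and co-evolution network comparison for protein subfamily
multiple sequence alignments.

Paralogous subfamilies of a protein family — the motivating case is the
LacI/GalR transcription regulators (CcpA, GalRS, GntR, PurR, RbsR-A,
TreR) — share one tertiary scaffold but may distribute their functional
constraints over different positions. `coevnet` quantifies two positional
signals per subfamily and compares them *between* subfamilies on a common
reference frame with anchor (LacI-style) numbering:

- **Conservation.** Column entropy `S = -Σ f_i ln f_i` (nats, gap as a
  21st symbol); columns with `S` below the 5%-variability bound
  `-(0.05 ln 0.05 + 0.95 ln 0.95) ≈ 0.1985` are conserved. Conserved
  (>5%-variability) and gappy (>50% gaps) columns are excluded from
  covariation scoring.
- **Co-evolution.** Five covariation scores over eligible column pairs —
  ZNMI (standardized normalized mutual information), OMES
  (observed-minus-expected-squared), McBASC (McLachlan-similarity
  correlation, no identity prefilter), ELSC and SCA (perturbation-based
  subalignment statistics) — each averaged over subsample-and-reanalyze
  ensembles (default 100 replicates at 90% of sequences) and
  cross-validated against a 50% ensemble.

Per-subfamily scores become weighted undirected networks whose ranked
edge and node sets are compared by a threshold-swept Jaccard index
`J = k/(2N − k)` against a 1000-shuffle random model (±1.96·SD band) and
a perfect-agreement envelope `J_max = m/(2N − m)`, `m = min(N, θ)`.
Positions are ranked within each subfamily by a cross-algorithm consensus
of Z-normalized strongest-edge scores, and annotated with distance-based
structural contacts (DNA, dimer interface, ligand, partner protein). A
synthetic-alignment generator with planted conservation and covariation
makes every stage testable end to end.

## Worked example

Two synthetic subfamilies, 200 sequences × 100 columns, 8 planted
covarying pairs each at coupling 0.9, of which half occupy identical
frame coordinates (`networkOverlap = 0.5`):

```r
library(coevnet)

gp <- generateSubfamilyPair(nSeq = 200, nCol = 100, nPairs = 8,
                            coupling = 0.9, networkOverlap = 0.5,
                            nConserved = 10, seed = 7)
a <- gp$A$alignment
a
#> SubfamilyAlignment [synA]: 200 sequences x 100 columns
eligibilityMask(a)
#> EligibilityMask (standard): 92/100 columns eligible

smA <- ensembleScores(a, "omes", ensembleSpec(fraction = 0.9, nReps = 25, seed = 7))
netA <- buildNetwork(smA, gp$A$positionMap, gp$frame)
netA
#> CoevolutionNetwork [synA/omes]: 92 nodes, 4186 edges

smB <- ensembleScores(gp$B$alignment, "omes", ensembleSpec(0.9, 25, 8))
netB <- buildNetwork(smB, gp$B$positionMap, gp$frame)

ra <- rankEdges(netA); rb <- rankEdges(netB)
jaccardIndex(ra@keys[1:8], rb@keys[1:8])
#> [1] 0.3333333
randomModel(edgeUniverse(netA), edgeUniverse(netB), 8, seed = 10)[c("mean", "ci95")]
#> $mean
#> [1] 6e-04
#> $ci95
#> [1] 0.01229347
```

The top-8 edge sets of the two networks share exactly the 4 planted
pairs placed at common coordinates: `J = 4/(2·8 − 4) = 0.333`, far above
the random expectation at `N = 8` (0.0006 ± 0.012). The full threshold
sweep carries the random band and the agreement envelope at every `N`:

```r
cmp <- compareNetworks(netA, netB, nShuffles = 1000, seed = 9)
sweepTable(cmp$edges)[c(1, 25, 99), ]
#>       N   jObs jRandomMean jRandomSd jRandomCi95 jMax
#> 1    41 0.0649     0.00518   0.00822     0.01611    1
#> 25 1002 0.1445     0.13596   0.00768     0.01506    1
#> 99 3965 0.9800     0.89964   0.00145     0.00284    1
```

At small `N` the observed overlap sits well above the random band
(planted agreement); across most of the sweep it tracks the random
model, i.e. the non-planted bulk of the two networks is unrelated.
Consensus node ranking (here a single algorithm) recovers planted
columns as top positions:

```r
head(consensusTable(consensusNodes(list(omes = smA))), 3)
#>   node w_omes z_omes consensus rank topK
#> 1   22   16.4   2.66      2.66    1 TRUE
#> 2   40   16.4   2.66      2.66    2 TRUE
#> 3   12   16.0   2.58      2.58    3 TRUE
```

(nodes 22, 40 and 12 are all members of planted pairs in this
simulation). `runPipeline()` orchestrates the same steps for any number
of real subfamily FASTA alignments plus a reference alignment, writing
TSV exports and a JSON manifest; `lacigalrConsensusTable()` ships the
published top-position/structural-contact table of the LacI/GalR family,
and `detectContacts()` annotates positions on PDB structures.

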