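---
title: "Comparing co-evolution networks between protein subfamilies"
author: "coevnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing co-evolution networks between protein subfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

## The scientific question

Paralogous protein subfamilies — such as the LacI/GalR transcription
regulators, where each subfamily (CcpA, GalRS, GntR, PurR, RbsR-A, TreR,
...) is a cluster of orthologs with high internal sequence identity —
share a tertiary scaffold but diverge in function. Two kinds of positional
signal distinguish them:

* **subfamily-specific conservation** — columns nearly invariant within
  one subfamily but variable in another, and
* **co-evolution (covariation)** — pairs of non-conserved columns whose
  residues change in a correlated way across the subfamily.

`coevnet` scores both signals per subfamily, projects them onto a common
reference frame so subfamilies can be compared position-by-position, and
asks a quantitative question: *are the co-evolution networks of two
subfamilies more similar than random chance, and how far are they from
perfect agreement?*

## Conservation and column eligibility

Positional entropy of an alignment column with residue frequencies
$f_i$ is $S = -\sum_i f_i \ln f_i$ (nats), computed over a 21-letter
alphabet in which the gap counts as a 21st symbol. A column with 5%
variability (95% one residue, 5% another) has

$$S_{0.05} = -(0.05\ln 0.05 + 0.95\ln 0.95) \approx 0.1985,$$

which is the package's conservation threshold (`entropyThreshold()`):
columns with $S$ strictly below it are *conserved*; the boundary value
itself remains eligible. Before covariation scoring, columns are
excluded when they carry more than 50% gaps or fall below the entropy
threshold (`eligibilityMask()`). The ZNMI algorithm follows its original
conventions instead: entropy computed ignoring gaps, plus exclusion of
columns with more than 10% gaps. Conservation reporting always uses the
gap-as-21st-symbol entropy, even when displayed alongside ZNMI results;
ZNMI's gap-ignoring entropy affects only ZNMI eligibility.

The eligibility mask is computed once on the full alignment and held
fixed across all ensemble subsamples, so every replicate scores the same
column set and entrywise averages are well defined. Whether eligibility
should instead be recomputed per subsample is genuinely open; the fixed
mask is the package's choice and is configurable by passing any mask you
like to `ensembleScores()`.

## The five covariation scores

All five algorithms score symmetric matrices over eligible column pairs
(`scoreAlignment()`); ineligible pairs are `NA`. For OMES, MI/ZNMI, ELSC
and SCA, the *valid* sequence set of a pair is the sequences ungapped at
both columns. Raw scores are never compared across algorithms; every
cross-algorithm use is rank- or Z-based.

* **OMES** — $\sum_{x,y} (N_{obs} - N_{ex})^2 / N_v$ over residue-pair
  cells with positive marginals, $N_{ex} = N_x N_y / N_v$.
* **ZNMI** — normalized mutual information $\mathrm{NMI} = I/H_{joint}$
  per pair, standardized per column ($z_i(j) = (\mathrm{NMI}_{ij} -
  \mu_i)/\sigma_i$ over column $i$'s NMI distribution) and combined
  across the two columns by inverse-variance weighting. A column with
  zero NMI dispersion contributes 0. The precise weighting of the
  original formulation is not fully specified in our sources; the
  inverse-variance rule is this package's documented stand-in, and all
  validation of ZNMI is rank-based.
* **McBASC** — the correlation, over all ordered sequence pairs, of
  McLachlan-similarity profiles at the two columns. No 90%-identity
  sequence prefilter is applied (deliberately — subfamilies are
  internally similar, and filtering would discard most of the signal).
  Gap-involving sequence pairs contribute similarity 0; zero-variance
  columns score 0.
* **ELSC** — perturbation at column $i$ keeps the sequences carrying its
  modal residue; the score at $j$ is $-\ln \prod_y
  \binom{N_y}{n_y} / \binom{N_y}{m_y}$ with ideal counts $m_y$ assigned
  by largest remainder (alphabetical tie-break). Directions averaged.
* **SCA** — perturbation as in ELSC; the coupling at $j$ is $kT^*
  \sqrt{\sum_x (\Delta G_x^{sub} - \Delta G_x^{full})^2}$ with
  log-binomial statistical energies of the residue frequencies at the
  subalignment depth, relative to background frequencies taken as the
  mean residue frequencies of the input alignment itself (self-contained
  and rank-stable; an external background would shift raw values but the
  package only consumes ranks and Z-scores). Evaluating both energies at
  the same depth makes an unperturbed frequency profile score exactly
  zero; residues absent from the background are excluded; $kT^* = 1$.

Degenerate cases follow explicit rules rather than NaN propagation:
pairs with no valid sequences are absent; zero-variance columns give 0
(McBASC, ZNMI); the empty-universe Jaccard is 0.

## Ensemble averaging

To suppress artifacts from individual (possibly misaligned) sequences,
scores are averaged over ensembles of random subalignments
(`ensembleScores()`): by default 100 replicates retaining 90% or 50% of
sequences (`floor(fraction * n)`, drawn uniformly without replacement).
Replicate seeds derive deterministically from one master seed by
counter, so ensembles are reproducible and parallelizable. Agreement
between the 90% and 50% ensembles (`ensembleAgreement()`, Pearson r over
shared pairs) is the cross-validation diagnostic; downstream analyses
use the 90% ensemble only.

## The family frame and network comparison

Each subfamily designates a reference sequence; `designateReference()`
maps its alignment columns to reference residues, and
`buildFamilyFrame()` ties reference residues to the columns of a
reference-sequence alignment, with one row (e.g. *E. coli* LacI)
providing anchor numbering for uniform reporting. Scores become
undirected weighted graphs (`buildNetwork()`) whose nodes are
frame-mapped eligible positions; edges with an unmapped endpoint are
dropped and counted.

Two networks are compared by sweeping a rank threshold N
(`jaccardSweep()`): at each N, the Jaccard index
$J = |A \cap B| / |A \cup B| = k/(2N - k)$ of the top-N edge (or node)
prefixes, alongside two reference models:

* **random model** — mean and SD of J over 1000 shufflings of the
  rank-ordered lists (equivalently, uniform N-subsets of each network's
  universe), with a 95% band of $1.96 \times$ SD;
* **perfect agreement** — $J_{max} = m/(2N - m)$, $m = \min(N, \theta)$,
  where $\theta$ is the overlap of the two universes. $J_{max}$ falls
  below 1 at large N whenever the two networks' eligible universes
  differ (different alignment lengths, different conserved sets).

The sweep grid is every integer N for lists up to 500 elements, else 100
evenly spaced thresholds from 1% of the list length; equal N is taken
from both networks, as the $k/(2N-k)$ form requires. Ties at a prefix
boundary are broken by ascending frame coordinates for reproducibility;
this perturbs J by at most the tie-group size.

Node rankings use each position's strongest incident edge, and the
cross-algorithm **consensus** (`consensusNodes()`) averages Z-normalized
max-edge scores over the algorithms (so no algorithm dominates by raw
scale), flagging the top 10 positions.

### Interpreting the sweep honestly

The observed sweep is *one* realized pair of rankings evaluated at many
serially correlated thresholds, while the null band reflects independent
redraws at each threshold. A single realized path therefore shifts
coherently: even for truly independent rankings, the fraction of sweep
points inside the 95% band has expectation near 0.95 but substantial
spread (in simulation, roughly one path in five dips below 90% inside).
Conclusions should rest on the overall position of the path relative to
the random and agreement envelopes — as in the package's tests, which
fix seeds — not on any single threshold.

## Synthetic data: what it emulates and what it does not

`generateMsa()` builds alignments in the shape of curated bacterial
transcription-factor subfamily MSAs (defaults: 200 sequences, 330
columns, per-column gap rate 2%): background columns draw i.i.d. from
column-specific Dirichlet(0.5) profiles; conserved columns carry a
consensus residue at >= 0.95 majority (single minority residue, no gap
injection, keeping them below the entropy threshold as real conserved
core sites are); planted pairs covary through a hidden-state model —
with probability `coupling` both columns realize one shared state.

By default a planted pair's states are the 20 residues with
Dirichlet-distributed weights, linked by a random residue bijection.
This makes planted columns *marginally indistinguishable* from
background columns — only the joint dependence is anomalous — which
matters when two "independently planted" subfamilies are compared: a
marginally anomalous planted column (e.g. a uniform k-state column)
would rank systematically differently in the subfamily where it is
planted versus the one where it is background, leaking single-column
structure into the between-subfamily comparison. Explicit paired-state
alphabets remain available (`statesI`/`statesJ`); a fully coupled
two-state pair carries exactly $\ln 2$ of mutual information.

`generateSubfamilyPair()` emits two such subfamilies over a trivial
shared frame with a controllable fraction of planted pairs at identical
frame coordinates (`networkOverlap`).

The generator is deliberately i.i.d. across sequences: no phylogenetic
tree, no indel process, no alignment error. Passing tests on synthetic
data therefore demonstrates the correctness of the scoring, filtering,
mapping and comparison machinery — not robustness to phylogenetic
autocorrelation or misalignment, which real subfamily MSAs exhibit and
which the ensemble averaging is designed to damp.

## Structural annotation

`detectContacts()` labels positions contacting DNA, ligand, a partner
protein, or the other protein monomer, using a single heavy-atom
distance cutoff (default 4.5 Å, configurable; hydrogens discarded,
highest-occupancy conformers kept). This deliberately replaces
atom-class-specific contact chemistry with one transparent, monotone
criterion: label sets can only grow with the cutoff, which makes
sensitivity analysis trivial. Published per-position contact tables of
this protein family are shipped as a plain-text fixture
(`lacigalrConsensusTable()`) and tallied exactly (`tallyTable()`);
reproducing such labels de novo from coordinates is best-effort, since
atom-class contact criteria differ between tools.
`minResidueDistance()` follows the closest-monomer convention of
homodimer analyses: a pair's distance is measured from the first monomer
to the nearer of the partner's two copies.

## Problem sizes used in tests

The package's deeper checks run two synthetic subfamilies of 250
sequences by 120 columns with 10 planted pairs at coupling 0.9, ensemble
averaging over 25 replicates at 90% retention, and 1000-shuffle null
models; oracle-equivalence checks run on 10 x 10 alignments against
brute-force reimplementations, and null-model calibration is checked
against exhaustive enumeration on universes of six elements. These sizes
were chosen so the full suite exercises every stage of the pipeline at
statistically meaningful depth while remaining quick to run.

## Known limitations

* No correction for phylogenetic relatedness or average-product
  correction; the analysis assumes exchangeable rows, as the ensemble
  subsampling framework does.
* ZNMI's combination rule and SCA's energy formula are documented
  package choices where the original descriptions underdetermine them;
  both are validated by rank behavior, not raw values.
* Contact annotation approximates atom-class criteria by a distance
  cutoff; per-position labels from real structures may differ from
  published tables derived with chemistry-aware tools.
* The reference alignment (family frame) is an input artifact; its
  quality bounds the validity of all cross-subfamily statements.
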