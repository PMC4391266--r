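---
title: "Methods: genome-scale phylogenetics and trophic-guild profiling with guildphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-scale phylogenetics and trophic-guild profiling with guildphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Delineating higher bacterial taxa (families, orders) from single marker
genes is often unreliable: 16S rRNA carries too few informative
characters, and deep branching orders come out unstable with
insignificant bootstrap support. Genome-scale data solve this in two
complementary ways. Concatenated protein alignments (supermatrices)
resolve the *sequence* phylogeny with near-maximal support, while binary
gene-content matrices — which genome carries which gene family — capture
a different signal: the *ecological* inventory. In marine
gammaproteobacteria these two signals famously disagree in an
informative way: gene content separates slow-growing oligotrophs
(*K*-strategists) from fast-responding copiotrophs (*r*-strategists)
even where the sequence phylogeny says the two guilds arose from
different ancestors. COG functional-category profiles then characterize
what distinguishes the guilds: oligotrophs are enriched in lipid
transport/metabolism (I) and secondary metabolites (Q), copiotrophs in
motility (N), signal transduction (T), transcription (K) and defense
(V), with cytochrome-P450 genes (COG2124) roughly eleven times more
abundant in the oligotrophs.

guildphylo packages this whole analysis as reusable, tested stages —
similarity search, family clustering, alignment and filtering, matrix
construction, multi-method tree inference with composite support
annotation, and guild profiling — and couples it to a genome-evolution
simulator with known ground truth, so that every stage and the
end-to-end pipeline are validated by recovery experiments rather than
by eyeballing.

# Pipeline stages and models

## Similarity

The built-in scorer is exact Smith–Waterman with affine gaps (a gap of
length $k$ costs $o + k e$), BLOSUM62, and the published gapped
constants $o = 11$, $e = 1$. Raw scores convert to E-values by the
Karlin–Altschul form $E = K m n e^{-\lambda S}$ with $\lambda = 0.267$,
$K = 0.041$. Only hits with $E \le 10^{-5}$ enter clustering.
Exactness is the point: unlike a heuristic search stage, the scorer can
be checked against a brute-force dynamic-programming oracle, and the
hit list is a deterministic function of the input. Users with real
BLAST tabular output can ingest it instead; the two routes share one
hit-table format. Within-genome hits are computed and kept — they are
what inparalog detection runs on.

## Family clustering

Homolog families come from a from-scratch Markov clustering (MCL) of
the symmetrized similarity graph in the TribeMCL setup: edge weight =
mean over the two hit directions of $-\log_{10} E$, capped at 200
($E = 0$ counts as the cap, a missing direction contributes 0 to the
mean), self-loops equal to each node's maximum incident weight, column
normalization, then alternating expansion (matrix squaring) and
inflation (entrywise power 2.0 with renormalization), pruning entries
below $10^{-6}$, until the matrix is idempotent to $10^{-8}$ (cap 200
iterations; non-convergence clusters the current matrix under a
warning). Clusters are connected components of the nonzero pattern of
the limit matrix. The graph is split into connected components first
and MCL runs densely per component — mathematically identical and fast
at desk scale.

Ortholog families use reciprocal best hits between genome pairs (best
by E-value, ties by bit score then lexicographic subject id) plus
inparalog edges: a within-genome pair qualifies when its E-value is at
most the worse of the two genes' best between-genome E-values (a gene
with no between-genome hit counts as $+\infty$). This combined graph is
clustered by the same MCL at inflation 1.5 (the conventional
ortholog-clustering default; the 2.0 setting is specific to the homolog
run). Inparalog removal then keeps, per family and genome, the member
with the greatest summed bit score to the family's members in other
genomes (ties to the lexicographically smaller gene id); the
alternative reading — dropping whole multi-copy families — is exposed
as `drop_multicopy_families`. The inter-genome weight rescaling of the
original ortholog-clustering algorithm is deliberately omitted: with a
single divergence regime at desk scale it has no testable effect, and
inparalogs are removed afterwards anyway.

## Alignment and block filtering

Each family is aligned progressively: a neighbor-joining guide tree on
$1 - $ shared-3-mer-fraction distances, then bottom-up profile merges
by global affine-gap dynamic programming with expected sum-of-pairs
scores. There is no iterative refinement; determinism was prioritized
over alignment accuracy, which suffices because the simulator's
substitution-only evolution produces alignable, equal-length family
members.

The block filter is a simplified, fully specified GBLOCKS-style rule
with the original's defaults: a column is *conserved* when strictly
more than half the rows share a residue, *highly conserved* at 85%;
gap-containing columns are removed; maximal runs of
nonconserved/removed columns longer than 8 are removed; remaining
blocks are trimmed inward to highly conserved end columns (this is
where the original's flank rule is folded in) and dropped when shorter
than 10 columns. Removing everything is a warning, not an error. The
exact stringency of the original program is not reproducible from its
description, so the filter here is a documented variant sharing its
parameters and defaults.

## Character matrices

Four matrices are built from the filtered alignments and families:

* **Supermatrix** — all filtered alignments with at least 4 sequences,
  concatenated in family order; a taxon absent from an alignment is
  filled with `?` across that partition (`?` = absent from the family,
  distinct from the indel symbol `-`).
* **Information-filtered supermatrix** — a documented stand-in for
  tree-likeness ("MARE"-style) gene filtering: each partition's score
  is the fraction of sampled 4-taxon subsets (100 per partition, drawn
  among taxa with data in it) for which exactly one of the three
  quartet topologies has strictly minimal parsimony score on that
  partition's columns. Partitions scoring below 0.25 are dropped —
  unless removal would leave a taxon with zero data (organism deletion
  is disallowed; such partitions are retained with a log notice).
* **Core-genes matrix** — exactly the alignments holding one sequence
  per genome for *every* genome; by construction it has no missing
  symbols.
* **Gene-/ortholog-content matrices** — one binary column per homolog
  (respectively ortholog) family: 1 iff the genome has at least one
  member. Constant columns are retained and flagged.

Partition files use 1-based inclusive coordinates; matrices and trees
are byte-deterministic given the seed.

## Trees, bootstrap and support annotation

Distances: the raw mismatch fraction $p$, the Felsenstein (F81-type)
correction $d = -B \ln(1 - p/B)$ with $B = 1 - \sum_i \pi_i^2$ computed
from the empirical state frequencies (0.75 for uniform nucleotides,
about 0.95 for near-uniform amino acids), and Kimura's PAM-approximating
protein distance $d = -\ln(1 - p - 0.2 p^2)$; values at or beyond a
formula's domain — or beyond the ceiling itself — saturate at
$d_{\max} = 5$ with a warning. Pairs are compared over mutually
non-missing columns. Neighbor joining is the Saitou–Nei algorithm (via
ape), with negative branch lengths clamped to zero.

On real proteomes the conventional pairing is neighbor joining with the
PAM distance, and that is the package default. The simulator, however,
evolves sequences under an equal-frequency replacement process for
which the *general Felsenstein correction with empirical-frequency B*
is the exactly additive distance, while the PAM approximation (being
calibrated to the PAM process) is mildly non-additive and can misplace
the shortest internal edges at deeper divergence. The recovery and
bootstrap validation experiments therefore pass the process-matched
Felsenstein model to the NJ stage explicitly; this is model matching,
not tuning — the experiment should not be handicapped by an
intentionally mismatched correction.

Parsimony uses the Fitch set-intersection count (an in-package bitmask
implementation, cross-checked in the tests against both exhaustive
internal-labeling enumeration and an independent library
implementation), with `?`, `-` and `X` fully ambiguous; tree search is
steepest-descent NNI from the NJ tree with seeded random restarts
(default 3). Likelihood uses the pruning algorithm via phangorn: LG
exchangeabilities with empirical (+F) frequencies and 4-category
discrete gamma for protein matrices — discrete gamma replaces the
CAT-style rate approximation, which is implementation-specific and not
reproducible — and the 2-state Mk model for binary matrices.

Bootstrap resamples matrix columns with replacement to the original
width (site-level on sequence matrices; on content matrices the columns
*are* families, so the same operation is family-level resampling); a
replicate tree is inferred per resample and a bipartition's support is
the percentage of replicate trees containing it. Gene-level jackknife
of the supermatrix is deliberately not the default. The study
convention is 1000 replicates; validation runs here use 100–400
(stated below) — support percentages are binomial proportions, so the
scaling only widens their Monte-Carlo error.

The composite annotation condenses several methods' supports per edge
into the published dot convention: with $m$ methods and $c$ of them at
$\ge 95\%$, an edge is **black** when $c = m$, **white** when
$\lceil 2m/3 \rceil \le c < m$, otherwise **hollow** when any method
reaches 75% (printing, in fixed method order, the values $\ge 75$), and
unmarked otherwise. The single $\lceil 2m/3 \rceil$ white-dot rule
reconciles the three published figure legends ($m=3 \to 2$,
$m=4 \to 3$, $m=6 \to 4$ or $5$) and is tested exhaustively on a grid
of support combinations at the 75/95 boundaries.

## COG guild profiling

Per genome, the percentage of genes in each of the 25 standard
functional categories is computed with the total number of
protein-coding genes as denominator (unannotated genes dilute all
categories; a gene annotated "IQ" counts once in I and once in Q). The
guild comparison labels a category `+`/`-` when a two-sided rank-sum
test at $\alpha = 0.05$ *and* an absolute mean difference of at least
1.0 percentage point agree; the sign follows the larger mean, so labels
are antisymmetric by construction. The published table's own labeling
rule is unstated; this declared rule reproduces the labeled/unlabeled
split for large-difference categories and is what the calibration tests
check (type-I rate under the null, power at 2-point shifts). It cannot
be expected to reproduce every borderline label of the original
(rounded means of unavailable underlying values). Marker-COG analysis
reports mean copies per genome per guild and their ratio, with a
zero-denominator flagged as an infinite ratio.

# The simulator: what it emulates, and what not

The simulator provides a known species tree, known family structure and
a planted guild signature, emulating the statistical structure a
real-world multi-genome dataset is assumed to have. It is the basis of
every recovery experiment; its parameters are artifact decisions (the
source study is observational and specifies no generative model).

* **Species tree** — Yule topology; branch lengths i.i.d. exponential
  (default mean 0.08 expected substitutions/site) floored at 0.02. The
  floor is an identifiability choice: an exponential draw can be
  arbitrarily close to zero, and a split carrying only a handful of
  expected substitutions across a desk-scale supermatrix is
  unrecoverable by any method, which would make recovery experiments
  measure luck rather than correctness.
* **Families** — core single-copy families present exactly once
  everywhere; shared accessory families present at the root with
  probability 0.5 and toggling by a gain/loss telegraph process (rates
  0.3/0.3 per unit branch length); guild-specific accessory families
  present with probability 0.8 in their guild and absent outside
  (patchy, guild-biased presence); present accessory families
  duplicate with probability 0.05, creating an inparalog copy on the
  terminal branch; one marker family with Poisson copy numbers, means
  1.1 (K) vs 0.1 (r), the planted 11:1 ratio.
* **Category planting** — each family carries one COG category. The
  common pool (core + shared accessory) draws categories proportional
  to the pointwise minimum of the two guild profiles; each
  guild-specific pool draws from that guild's excess over the minimum;
  pool sizes are solved so that the expected per-genome category
  proportions match the profiles. Default profiles are the published
  per-guild category means (e.g. lipid 7 vs 3, signal transduction 3
  vs 6).
* **Guild placement** — "clade" mode assigns the two clades flanking
  the root to the two guilds; "convergent" mode alternates guilds
  across the cladewise tip order, making the guild signal orthogonal to
  the sequence phylogeny. Convergent mode is what reproduces the
  content-vs-sequence dichotomy: the gene-content tree splits the
  guilds while the supermatrix tree tracks the species tree.
* **Sequences** — per family a uniform-random root sequence (default
  length 100); along each branch of length $t$, Poisson($tL$)
  substitution events at uniform sites with replacements drawn from the
  stationary (uniform) frequencies; duplicates branch at a uniform
  point on the terminal branch. This stationary i.i.d.-site replacement
  model is deliberately simple: the clustering and tree stages need
  divergence *structure*, not model realism, and the simple model keeps
  the simulator fast and exactly seedable.

Not emulated: insertions/deletions (so true alignments are gap-free and
the aligner/filter face no real indel structure), lateral gene
transfer, across-site rate heterogeneity, amino-acid compositional
bias, codon structure, and genome rearrangement. Passing recovery tests
therefore show that the pipeline's logic is correct and well calibrated
on clean signal of realistic shape; they do not certify accuracy on
real proteomes with indels, LGT and heterogeneous rates.

# Validation problem sizes

The test-suite experiments run at sizes chosen to exercise every stage
while keeping a full run on one CPU comfortable: oracle equivalences on
hundreds of random miniatures (sequences of length 8–25, trees of 4–8
tips, graphs of up to 15 nodes); exact ortholog recovery at 6 genomes,
10 seeds; end-to-end species-tree recovery at 20 genomes (about 700
genes), 10 seeds, requiring both NJ and MP supermatrix trees at
Robinson–Foulds distance 0 in at least 9; a 200-replicate bootstrap on
one such supermatrix requiring at least 95% on every true clade; the
convergent-guild dichotomy at 12 genomes, 10 seeds, requiring the
content tree to split the guilds in at least 8 while the supermatrix
tree matches the species tree in at least 9; and guild-comparison
calibration at the published group sizes (17 vs 9 genomes), 50
simulations each for the type-I and power checks. The "strong-signal"
bootstrap condition is defined as moderate divergence with more data
(mean branch 0.1, floor 0.04, sequences of length 150) rather than as
longer branches: at 20 taxa, stretching branches drives deep pairwise
distances past the correction formulas' domain, which destroys rather
than strengthens the distance signal. `scripts/acceptance.R`
re-runs the same computations at 5 seeds per recovery experiment and
writes the headline numbers as JSON.

# Numerical choices and degenerate inputs

Ties are broken deterministically throughout (lexicographic ids for
best hits, representatives and family numbering). E-value 0 maps to the
weight cap. Saturated distances go to $d_{\max}$ with a warning rather
than an error. An alignment whose columns are all filtered yields an
empty result with a warning. A guild with fewer than two genomes
suppresses labels but still reports means. Zero-length branches are
raised to $10^{-8}$ before likelihood evaluation. All stochastic stages
take explicit seeds; the pipeline derives per-stage seeds from one
master seed by fixed offsets, so stages are independently reproducible
and reruns are byte-identical.

# Known limitations

The progressive aligner is deterministic but not refinement-based, and
the block filter is a declared simplification — on real, indel-rich
proteins both would be the first components to upgrade. The quartet
information filter shares only the *intent* of tree-likeness-based gene
selection; its scores are not comparable to the original program's.
ML on large protein supermatrices is the one stage that can exceed desk
scale and is therefore opt-in in the pipeline configuration (NJ and MP
always run). The guild-labeling rule is a declared convention, not an
inference of the original table's unstated procedure.
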