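---
title: "Discovering and profiling gut bacterial steroid hormone reductases"
author: "SteroScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and profiling gut bacterial steroid hormone reductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SteroScreen)
```

# The scientific problem

Several common gut bacteria reduce host steroid hormones — most prominently
the conversion of progesterone to 5β-dihydroprogesterone by a
Δ⁴-3-ketosteroid 5β-reductase of the Old Yellow Enzyme (flavin-dependent
ene-reductase) family — but for decades the genes behind these activities
were unknown. SteroScreen implements the computational strategy that
identifies such enzyme families and quantifies them in human gut
metagenomes:

1. **Phenotype-concordance screen.** Given genomes of experimentally
   confirmed reducer and non-reducer species, proteins are clustered into
   orthogroups and the screen keeps exactly the orthogroups present in every
   reducer and absent from every non-reducer, then narrows to those carrying
   the ene-reductase family label.
2. **Family modelling.** The candidate family is aligned, trimmed
   (gap-heavy columns and short sequences removed), and summarised as a
   profile hidden Markov model with a calibrated E-value null. Proteins
   carrying two non-overlapping hits from distinct models are recognised as
   natural fusions (the 5β-reductase / 3β-HSDH-isomerase fusion being the
   motivating case) and split into their domain parts.
3. **Genomic context.** Hits are classified by their colocalization with
   marker genes (bile-acid-inducible operon analogs): close proximity,
   same genome, or absent — the evidence used to separate a steroid-hormone
   reductase clade from the bile acid reductase clade.
4. **Phylogeny and residues.** A distance tree over family members is built
   by neighbor joining, clades are delineated by anchor sequences and an
   outgroup, per-clade residue frequencies are tabulated at mapped catalytic
   positions (the active-site positions 166, 167, 171 and 253 in reference
   numbering), and ancestral states are reconstructed by Fitch parsimony.
5. **Metagenomic profiling.** Reads from paired-group gut metagenomes are
   assigned to family genes, counts are aggregated per biosample, converted
   to counts per million (CPM), thresholded into presence calls, and group
   prevalence and abundance are compared with one-sided two-proportion
   z-tests and Wilcoxon rank-sum tests.

Because the original discovery rests on large external resources (a
many-thousand-genome taxonomy database and 1549 public gut metagenomes),
the package ships a synthetic-data generator that plants ground truth with
the same statistical structure, so that every stage can be validated
end-to-end on a desk-scale problem.

# The synthetic-data generator

`simulatePangenome()` emulates the discovery screen: a configurable number
of phenotype-positive and -negative genomes (default 3 + 3, matching the
six-genome screen design), exactly one planted family whose
presence/absence equals the phenotype, decoy families that each violate the
pattern in at least one genome, core families present everywhere, a marker
family placed immediately next to the planted gene in a configurable subset
of carriers, and optional fused two-domain variants of the planted protein.
Proteins evolve from a family ancestor by independent per-site substitution
(uniform choice among the 19 alternative residues, no indels), which keeps
diagnostic-column logic and identity expectations exact. Genes are
reverse-translated with a fixed codon per amino acid and tiled
left-to-right on the '+' strand with fixed 200-bp spacers.

`simulateHomologFamily()` grows a clade-structured family along a labelled
tree whose branch lengths are per-branch, per-site substitution
probabilities; designated diagnostic columns never mutate and instead carry
a fixed clade-specific residue, mirroring the clade-diagnostic active-site
residues of the real families. Under this model the expected pairwise
identity between two leaves has a closed form (a two-state recursion over
the branch path), which the tests verify.

`simulateMetagenome()` emulates a sex-stratified survey at reduced scale:
two groups of biosamples; each sample's community carries each panel gene
with a group-specific probability (a presence/absence prevalence design,
not abundance-only); reads drawn uniformly from the realised community —
five background genomes of 20 kb by default, each carried gene contributing
1% of community bases — with i.i.d. per-base substitution errors at 0.5%
and a fixed 150-bp read length (standard short-read geometry). At the
default depths, a carried gene yields a CPM around 10⁴, so presence calls
recover carriage essentially perfectly; what remains stochastic is the
carriage sampling itself, which is exactly the quantity the prevalence
tests address.

What the generator deliberately does **not** model: indel evolution, codon
or rate heterogeneity, quality-score error profiles, host-read
contamination, strain mixtures, and uneven community compositions. Passing
tests therefore demonstrate correctness of the algorithms under the stated
generative assumptions, not robustness to every property of real data.

# Models and algorithms

## Orthogroups and the screen

All proteome pairs are compared with global Needleman–Wunsch alignment
under BLOSUM62 and affine gap penalties (open 11, extend 1; a gap of length
L costs `11 + L`). Raw scores convert to bits with the ungapped BLOSUM62
Karlin–Altschul parameters (λ = 0.267, K = 0.041). A pair of genes from two
genomes forms an orthology edge when each is the other's best hit in that
genome pair (ties broken by higher raw score, then lexicographic gene id)
and the score reaches the bit floor (default 50 bits). Orthogroups are
connected components; unmatched genes are singletons; same-genome paralogs
count once towards presence. The original analysis used a dedicated
orthology tool with an E-value cutoff of 1e-120; that cutoff is tied to the
tool's own calibration, so the package exposes a configurable bit floor
instead — the screen is driven by presence/absence, not by the exact
cutoff, and at the default divergence the planted-family scores
(hundreds of bits) and random-pair scores (negative) are separated by two
orders of magnitude.

## Progressive alignment and trimming

The guide tree is average-linkage clustering of fractional common 3-mer
distances; profiles are merged by profile–profile global alignment with the
same affine penalties (column pair score = average pairwise substitution
score; gap symbols score zero). With two sequences this reduces exactly to
pairwise alignment, which the tests verify against exhaustive enumeration.
Trimming excludes sequences below the length floor first (500 residues for
the reductase family, 450 for the Δ⁶-reductase analog, per the published
thresholds; the floor applies to the length each sequence had when it
entered the alignment, which makes trimming idempotent), restricts columns
to the modelled domain window given in reference coordinates, and removes
columns whose gap fraction strictly exceeds 0.95 (a column at exactly 95%
is retained).

## Profile HMMs

Columns with residue occupancy ≥ 0.5 become match states. Emissions and
transitions are maximum-likelihood counts with a Laplace pseudocount
(default α = 1); insert states and sequence flanks emit the background
(Robinson–Robinson frequencies), so their emissions cancel in log-odds
scoring. The topology is a reduced Plan7: match, insert and delete states
per column, no insert–delete transitions (rows crossing such adjacency are
doctored through match, the standard resolution), free
N/C flanks, and either glocal alignment (model traversed begin-to-end) or
local alignment (uniform entry `1/M` into any match state, free exit).
Viterbi and forward run in log space; on every model with at most five
match states and sequences up to eight residues both equal exhaustive path
enumeration to 1e-9 nats.

E-values come from a Gumbel null fitted by the method of moments
(`beta = s·sqrt(6)/π`, `mu = mean − 0.5772·beta`) to the local Viterbi bit
scores of at least 200 background-sampled sequences of model length.
Method of moments is used because it is stable at these null sizes and
needs no iterative solver. `E = dbSize · P(S > s)` under the fitted null.
The published search used fixed E-value ceilings (1e-240/1e-220/1e-260)
that belong to the original tool's calibration and database scale; E-value
scales are not transferable across calibrations, so the package default
ceiling (1e-3) is chosen from the synthetic null and is a configuration
value.

Fusion calls: a protein with two or more non-overlapping hits from
distinct models, ordered along the sequence, is split at the integer
midpoint (floor) of each inter-envelope gap — ties are impossible by
construction. On planted two-domain proteins the split lands within ±10
residues of the true junction.

## Genomic context

"Close proximity" is quantified as: some marker on the same contig within
8 intervening genes or within 10 kb between nearest feature edges (either
suffices; both windows configurable). These defaults express typical
operon-scale neighbourhoods; the original figures state adjacency
qualitatively. Strand is recorded but ignored, since the published
adjacency statements do not condition on strand. The summary counts
satisfy `n_proximal ≤ n_copresent ≤ n_targets` by construction, and the
gene-rank distance is reported so that "directly adjacent" can be read as
rank 0 or any other cutoff downstream.

## Phylogeny, clades, residues, ancestral states

Distances are normalized alignment differences `p` over mutually ungapped
columns with the Poisson correction `d = −ln(1 − p)`, capped at 5 so
saturated pairs stay finite. Neighbor joining uses the standard Q
criterion; ties break at the lowest (row, column) pair; negative branch
lengths are clamped to zero with the deficit shifted to the sister edge.
The published trees were inferred by maximum likelihood with ultrafast
bootstrap; distance NJ is the package's stated substitution — topology
recovery on additive distances is exact (Robinson–Foulds 0 on random
additive trees), which is the property the clade analysis needs.

Clades are delineated by anchors: the tree is rooted on the outgroup edge,
each label's clade is the smallest rooted clade containing all of its
anchors, leaves inside exactly one labelled clade inherit its label, and
leaves in nested/overlapping claims or outside every clade are
`unassigned` (anchors keep their own label). Residue positions of interest
(166, 167, 171, 253 in reference numbering) are mapped through the
reference row's gaps to alignment columns, and per-clade frequency vectors
over the 20 residues plus gap are tabulated. Ancestral states use two-pass
Fitch parsimony (score = number of union events; the downward pass yields
the states attainable in at least one most-parsimonious reconstruction),
substituting for the probabilistic reconstruction behind the published
ancestral-state logos; posterior probabilities are out of scope.

## Metagenomic profiling

Read mapping is k-mer containment: a read is assigned to the panel gene
sharing the largest fraction of its k-mers (k = 21, both orientations via
double-strand indexing) when that fraction reaches θ = 0.3; ties are
unassigned, totals count all reads. This replaces a short-read aligner with
a deterministic, dependency-free rule that is fully adequate for
presence/CPM at synthetic error rates. An optional stride-8 probe
prefilter skips reads with no indexed k-mer at any probed window; a read
with at least `θ·(L−k+1)` matching windows in at most five maximal runs
must contain a run of eight consecutive matching windows, so for 150-bp
reads the filter is provably exact up to four substitution errors and is
enabled by default.

Counts are summed across runs per biosample **before** QC; samples below
the one-million-read floor are flagged and excluded from tests (the floor
is configurable, and scaled-down synthetic cohorts set it to their design
depth). CPM is `count/total × 1e6`; presence is CPM strictly greater
than 1. Prevalence differences use the pooled two-proportion z statistic
with Yates continuity correction by default — matching the default of the
standard R routine for this test — with a flag to disable it; degenerate
pooled proportions (0 or 1) return the conventions p = 1 and p = 0.5,
flagged. Abundance differences use the one-sided Wilcoxon rank-sum test in
its normal approximation with midranks, tie-corrected variance and
continuity correction; all-tied inputs are flagged degenerate with p = 0.5.
Zero-CPM samples are kept in the Wilcoxon test by default (the published
analysis excluded them only from the log-scale plot; a flag reproduces
that behaviour), and Benjamini–Hochberg adjusted p-values are reported
alongside raw ones whenever several genes are tested.

# Worked example

```{r pipeline, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "SteroScreen")
paths <- runPipeline(cfg, outDir = "demo_out")
readStageTable(paths$screen)       # orthogroups, concordance, selection
readStageTable(paths$metaprofile)  # per-gene prevalence and abundance tests
```

The demo configuration simulates a 3 + 3 pangenome with six decoys,
screens it, models the selected family, classifies marker context, builds
the clade tree, simulates a 12 + 12 metagenome cohort at depth 2×10⁴
(QC floor lowered to 10⁴ accordingly) and tests the groups. All stage
tables carry a `# config=<fingerprint> seed=<seed>` provenance line.

# Numerical choices and edge cases

* Alignment gap cost `open + ext·L`; empty-vs-nonempty sequences are legal
  and score as one gap.
* `X` residues score 0 in alignments and emit the background in HMMs.
* Forward/Viterbi run in natural-log space; bit scores divide by ln 2.
* Gumbel calibration refuses a zero-scale (degenerate) null.
* NJ ties and the all-zero matrix resolve by the lowest-index rule.
* Distance cap `d = 5` applies whenever `p ≥ 1 − e⁻⁵`.
* CPM presence is a strict inequality: CPM exactly 1 is absent.
* The z-test's continuity correction shrinks |Δp| toward zero at most to 0.

# Problem sizes used by the validation suite

The acceptance checks run the screen on one hundred seeded 3 + 3-genome
pangenomes with ten decoys at 30% divergence; verify the HMM dynamic
programs against exhaustive enumeration on a grid of models up to five
match states and sequences up to eight residues; recover fifty planted
fusion junctions; recover one hundred random additive tree topologies;
check Fitch against brute force on fifty 6-leaf cases; compare the group
tests with closed forms and exact enumeration; and run the metagenome
recovery design (carriage 0.9 vs 0.6, 60 + 60 samples, plus an
equal-carriage type-I arm) over one hundred seeds each at a sequencing
depth of 2×10⁴ reads per sample with the QC floor set to that depth. The
depth choice is statistically inert for every reported rate: at 1% panel
abundance a carried gene maps about 0.01×depth reads (CPM ≈ 10⁴ against a
presence threshold of 1) and a non-carried gene maps none, so presence
calls equal the per-sample carriage draws at any depth above a few
thousand reads, and the prevalence statistics depend only on those draws.
These sizes keep the whole suite reproducible on a single CPU while
leaving every statistical property testable.

# Known limitations

* The generator's substitution process has no indels outside designated
  drift segments, so alignment-quality stress (long insertions, repeats)
  is untested.
* E-value ceilings are calibration-relative; absolute values from the
  original search tool are not reproduced and should not be compared
  numerically.
* Fitch parsimony yields state sets, not posterior probabilities; the
  published ancestral-probability logos have no quantitative counterpart
  here.
* The prevalence z-test's power at the validation design is 0.92–0.95
  depending on the continuity correction; single-seed conclusions at
  α = 0.01 remain stochastic, which is why the suite reports rates over
  many seeds.
* Real-data prevalence figures require the original 1549-sample cohort and
  genome database and are outside desk scale.
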