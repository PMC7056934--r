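---
title: "Assembling and quantifying circular RNA isoforms with circflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and quantifying circular RNA isoforms with circflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circflow)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream 5' splice donor is joined
back to an upstream 3' splice acceptor, producing a covalently closed loop.
Upstream detectors (CIRCexplorer2, CIRI2, UROBORUS and kin) report only the
back-splice junction (BSJ) — the two outer boundaries of the circle. The
internal structure is not determined by the BSJ: alternative splicing
between the back-spliced exons produces multiple circular isoforms from the
same junction, and these isoforms can differ from the cognate linear mRNA.
circflow reconstructs the full exon chain of each circular isoform from
ordinary spliced short-read alignments plus the BSJ list, and estimates
per-isoform expression.

## Splice graphs per back-splice event

For every BSJ assigned to an annotated locus (both junction coordinates
must coincide with annotated exon boundaries; a `tolerance` flag allows a
few bp of slack for off-by-one conventions of upstream tools) circflow
builds one directed acyclic splice graph:

* **nodes** — annotated exon intervals lying entirely inside the
  back-spliced span. Exons that only partially overlap the span are
  excluded: the method is annotation-based and does not invent boundaries.
* **edges** — a directed edge (u, v) is added when a single alignment
  record spans the junction from u's 3' boundary to v's 5' boundary (an
  `N` gap in the CIGAR). Edges always point in genomic coordinate order;
  node indexing, path logic and output are identical for both strands, and
  transcription orientation is applied only where it matters (fragment
  lengths in the quantifier, read simulation).
* **source and sink** — the exons whose boundaries are the BSJ
  coordinates. The circular sink-to-source junction is implicit and never
  an edge, so the graph stays acyclic. Every source-to-sink path is a
  candidate full-length circular transcript.
* a mate aligned in two primary records (split at the BSJ) marks the
  fragment as BSJ-spanning; its pieces contribute edges after rotation but
  never an edge across the circular junction itself.

A locus with several BSJs gets several graphs; fragments falling inside
more than one back-spliced span are shared between the graphs. Nodes on no
source-to-sink path are dropped; if the sink is unreachable the BSJ is
reported unassembled (with shallow data, forward-spliced reads are simply
missing). A BSJ whose span is one single annotated exon yields the trivial
one-node graph.

**Subpath evidence.** A fragment whose combined mate segments touch three
or more nodes forming one edge-connected run witnesses that these exons
are consecutive in some isoform; the run must appear contiguously in at
least one assembled path. For BSJ-spanning fragments the touched nodes are
taken per alignment record (a record never crosses the circular junction),
which splits the evidence at the junction. The inference assumes the
unsequenced inner part of a fragment does not skip an entire exon; with
the default fragment geometry (100 bp reads, 250 bp fragments, exons of
60 bp and up) the inner gap is ~50 bp and this assumption rarely bites.

## Extended minimum path cover

The assembly problem per graph: find the minimum number k of
source-to-sink paths such that every node (a), every edge (b) and every
subpath (c) is covered, with all paths running source to sink (d). Each
path of a minimal solution is reported as one isoform.

Conditions (a), (b), (d) form a minimum-flow problem with lower bounds:
each node is split into an arc with lower bound 1, each edge becomes an
arc with lower bound 1, and the minimum source-to-sink flow is computed by
constructing a feasible flow (routing one unit through every
lower-bounded arc) and then cancelling surplus circulation with
Edmonds-Karp style augmentation in the residual network. The integral flow
is decomposed into paths, always preferring the smallest node index, so
results are deterministic.

Subpath constraints (c) enter the same network as *token arcs*: a subpath
(v1, ..., vm) becomes an arc with lower bound 1 jumping from v1 to vm, and
every node/edge covered by some subpath loses its own lower bound (the
token's expansion covers them). During decomposition a token arc is
expanded back into its full run. Any feasible flow expands to a feasible
path set, so the answer is always valid; it is provably minimal whenever
no single solution path would need to chain two overlapping subpath
constraints. Because that corner case exists, on graphs of at most 12
nodes (in practice almost every circle) a branch-and-bound set-cover
search over all enumerated source-to-sink paths — bounded below by the
token-free minimum flow and seeded with the flow solution — certifies or
restores optimality. Larger graphs keep the token-flow answer, flagged
`exact = FALSE`. The test suite checks the solver against an independent
brute-force enumeration oracle on hundreds of random DAGs.

**Ties between minimum covers.** The data can admit several minimum
covers: with isoforms {1-2-3-4-5, 1-3-5} but no single fragment jointly
witnessing three exons of either chain, the crossed pair
{1-2-3-5, 1-3-4-5} covers the same nodes, edges and subpaths. Among
covers of minimum size the search prefers the one whose sorted path
lengths are lexicographically largest — the cover containing the most
complete chain — because the all-exon isoform is the a-priori common one
(in real data, most back-splice events express the full chain). Remaining
ties fall back to smallest node order, keeping results deterministic.

Evidence runs that are not walks in the graph are dropped with a warning;
runs of length two are plain edges and are treated as such.

## Abundance estimation

Fragments are assigned to isoforms by maximum likelihood. For a circular
transcript t of length l(t), a fragment f compatible with t has an implied
length lt(f) — the distance from mate1's 5'-most transcript coordinate to
mate2's 3'-most coordinate *along the circle*. When the footprints imply
that the fragment runs past the back-splice junction (a split mate, or
mate2 upstream of mate1 on the linearized circle) one full transcript
length is added. When a fragment's coordinates admit both a linear and a
wrapped layout (possible only when the implied span equals l(t) exactly),
the linear reading is used; the two layouts have identical footprints and
the choice is immaterial to the fit. Read ends overlapping an exon by
fewer than `k_effective` bases (default 3 bp) are ignored both for
compatibility and for length.

The likelihood over all fragments R is

$$ L(\theta \mid R) \;=\; \prod_{f \in R} \sum_{t \in T}
   \frac{\theta_t / l(t)}{\sum_{\alpha \in T} \theta_\alpha / l(\alpha)}
   \cdot \frac{F[l_t(f)]}{l(t) - 2k + 2} $$

with F a normal fragment-length density and 1/(l(t)−2k+2) the probability
of drawing a fragment position given t. No effective-length correction is
applied: a circle has no ends, hence no edge effects, so the raw l(t) is
used throughout (including FPKM/TPM). The log-likelihood is concave in the
mixture weights, so EM from a uniform start reaches the global maximum;
initialization affects only speed. EM runs per locus (the likelihood
factorizes across loci), stopping at a relative log-likelihood change
below 1e-6 or 1000 iterations. Per-fragment posteriors sum to expected
read counts; fragments compatible with no assembled transcript are
excluded and reported as a diagnostic count.

After convergence, isoforms below 1 per mille of the most abundant isoform
are discarded and one further EM pass reassigns their fragments. The
filter is scoped per gene locus — the same scope in which the path cover
and the EM operate — rather than per BSJ or globally; with the default
ratio the distinction is rarely visible.

Fragment-length parameters (mean, sd of F) are estimated by moments from
fragments of single-isoform loci, where the implied length is unambiguous;
with fewer than 50 usable fragments the model falls back to 250 ± 25 bp,
and both values can be overridden on the command line.

**Reported units.** Read counts are EM expected counts;
FPKM = count / (l/10^3) / (library/10^6) with the library size equal to
all mapped fragments; TPM renormalizes count/l to a million. Because the
likelihood draws fragments with probability proportional to θ/l, the
reported θ is proportional to count × length — the FPKM-like scale on
which relative abundances are compared.

## Relation index

Overlapping circles share fragments and confuse both assembly and
quantification. The relation index (RI) of a BSJ is the size of its
equivalence class under the transitive closure of "genomic spans overlap
by ≥ 1 bp on the same chromosome" (strand-agnostic by default; a stranded
mode is available — the choice matters only for rare antisense nests).
It is computed by a linear sweep over sorted intervals, equivalent to
union-find over the pairwise relation, and reported as a per-transcript
output column. RI is a diagnostic: it does not change the assembly.

## The simulator

`simulate_truth()` / `simulate_reads()` generate gene models, back-splice
events, circular isoforms and pre-aligned paired-end fragments with known
ground truth, so the whole pipeline is testable without external data or
an aligner. Reads are emitted as SAM alignments (plus optional FASTQ);
running an aligner is out of scope, and emitting coordinates directly
removes the only external-tool dependency from the tests.

Default study conditions, chosen to mimic RNase R-enriched short-read
libraries:

| parameter | default | rationale |
|---|---|---|
| exons per locus | 4–12 | typical mammalian gene span |
| exon length | 60–300 bp | median exon ≈ 150 bp |
| intron length | 200–2000 bp | enough to force N gaps |
| exons per circle span | weights 0.08/0.22/0.28/0.22/0.12/0.08 for 1–6 | most circles span 2–4 exons |
| isoforms per BSJ | 1–2 (first keeps all exons, others skip internal exons at random) | most junctions express one or two isoforms |
| expression level | log-uniform on [1, 1000] | a stand-in for the biological dynamic range |
| read length | 100 bp; fragments normal 250 ± 25 bp | standard paired-end library, ~300 bp optimum |
| depth | 250 fragments per transcript | mid-range of the depth series analysed below |

Fragment counts are multinomial with probability proportional to the raw
expression level a_t; start positions are uniform on the circle (any
rotation, including across the BSJ); a mate crossing the junction is
written as two primary records split at the junction. Because the fitted
likelihood draws fragments proportional to θ/l, the simulator defines the
per-locus truth abundance as θ_true ∝ a_t·l(t) — the quantity the
estimator recovers; absolute accuracy is always scored on fragment counts,
which are convention-free. Transcripts shorter than the read length are
skipped (a read would wrap the circle more than once, which one SAM split
cannot represent); they drop out of the truth denominator, which counts
only transcripts with at least one emitted fragment.

What the simulator does **not** emulate: remnant linear mRNA (libraries
are assumed perfectly RNase R-digested), sequencing errors that change
alignments (an optional substitution rate perturbs FASTQ bases only),
alignment artefacts, GC/positional bias, unannotated exons, and intronic
or intergenic circles. Passing tests therefore demonstrate correctness of
the method under clean conditions, not robustness to dirty libraries.

The simulated BSJ list carries the realized number of junction-crossing
read pairs as support and is fed to the pipeline unfiltered
(`min_support = 0`), mirroring how a simulation's junction list is a given
input; the pipeline default of `min_support = 10` reflects practice on
real data, where upstream junction calls need independent support.

## Problem sizes used in the bundled analyses

The packaged evaluation (`scripts/acceptance.R` and the heavier test
blocks) uses scaled-down re-runs of the simulation protocol: about 200
loci (≈ 400–600 truth isoforms) at 250 fragments per transcript for the
headline sensitivity/precision, the same annotation at 8× depth for the
deep-coverage precision check, 4 multi-isoform loci under 8 expression
conditions for relative quantification — the condition series draws
levels log-uniform on [30, 1000], a ~30-fold dynamic range that keeps
every tracked locus expressed in every condition, which is the premise of
a cross-condition comparison — and ~140 loci with 75% of loci
carrying 2–4 mutually overlapping BSJs — at 1000 fragments per transcript,
matching the deeper read-length series — for the RI-stratified
sensitivity. These sizes keep a full run on one CPU in minutes while
leaving every per-locus quantity (depth, isoform counts, fragment
geometry) at the study's scale.

## Numerical choices and degenerate inputs

* Tie-breaks (flow decomposition, path enumeration, branch and bound)
  always prefer the smallest node index; identical inputs give
  byte-identical outputs.
* Fragment-length densities are floored at 1e-12 to keep extreme outliers
  from zeroing a posterior row; fragments incompatible with every isoform
  are excluded before EM.
* Empty BSJ lists, BSJs matching no annotated boundary, loci without
  spliced reads, and single-exon circles are all legal inputs and produce
  empty or one-node results rather than errors.
* A BSJ whose boundaries match exons of two overlapping genes is assembled
  in both (with a warning); a `.` strand is resolved from the annotation,
  and an annotation conflict is resolved in favour of the annotation and
  flagged.

## Known limitations

* Annotation-bound: unannotated exons, intronic and intergenic circles
  are invisible by construction.
* The subpath heuristic can assert exon adjacency across a fragment's
  unsequenced gap if the gap swallows an entire short exon.
* On graphs above the exact-search size the token-flow solution may
  exceed the true minimum path count when overlapping subpath constraints
  interact; such solutions are flagged.
* Fragments longer than twice the circle are mapped modulo the circle
  length, slightly flattening the length likelihood for very short
  circles — an information limit of short-read data, not of the
  implementation.
* One sample at a time; no bias correction or differential testing.
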