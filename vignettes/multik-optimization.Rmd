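---
title: "Optimizing multi-k de novo transcriptome assemblies for functional annotation"
author: "multika"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing multi-k de novo transcriptome assemblies for functional annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multika)
```

## The model

De Bruijn graph assemblers build contigs from read overlaps of a fixed word
length k. For transcriptomes — where coverage spans orders of magnitude across
transcripts — no single k is right: small k recovers low-abundance transcripts
at the cost of fragmented, shorter contigs; large k yields longer, more
accurate contigs but only where coverage is high. A multi-k strategy therefore
assembles the same reads at every odd k in a window (19 to 63 is the window
this package parameterizes its labels around), pools the per-k contig sets,
and removes redundancy by identity clustering to obtain a single clustered
assembly (CA).

The quantity this package optimizes is not contig length but *retrievable
functional annotation*: the set of distinct KEGG Ortholog Identifiers (KOIs,
`K` + five digits) assignable to an assembly's contigs. Two observations
drive the workflow:

1. Each single-k assembly carries KOIs absent from every other single-k
   assembly, so no single k suffices.
2. Greedy redundancy removal is heuristic: a cluster representative may be a
   contig that received no annotation while a collapsed member did, so the CA
   can lose KOIs that single-k assemblies had.

The workflow is: per-assembly metrics and KOI summaries; CA construction;
pairwise missing-KOI comparison; and a recovery step that re-adds, from the
single-k assemblies, a minimal set of contigs covering every KOI the CA
lost. Its defining postcondition, tested exactly on every synthetic
scenario, is set equality:

$$\mathrm{KOI}(\text{final}) \;=\; \mathrm{KOI}(\mathrm{CA}) \;\cup\; \bigcup_k \mathrm{KOI}(k).$$

## Assembly metrics

`nStatistic(assembly, f)` is the length-weighted quantile: sort contig
lengths decreasing, return the length at which the cumulative sum first
reaches `f` times the total (N50 at `f = 0.5`, N90 at `0.9`). This is the
most common of the N50 conventions; a brute-force sort-and-prefix-sum oracle
pins it in the tests. All contigs present in the input enter the statistic —
thresholds such as "contigs ≥ 100 bp" are reporting rows
(`countGe`/`assemblyMetrics`), never filters, because the metrics should
describe the file as given. Average length is kept at full precision
internally and rounded only for display.

`lengthHistogram` bins lengths into half-open bins `[start, start + width)`
at floor multiples of the width and also emits the cumulative series; counts
always sum to the contig count.

## Fold coverage

Reads shorter than an assembly's k cannot have contributed to that assembly,
so `filterReadsByK` removes them (inclusive boundary: length ≥ k is kept)
before mapping. `countAlignments` consumes either SAM (via Rsamtools; only
the reference name of mapped records is used) or the legacy one-name-per-line
text that remains when an aligner is asked to print all alignments with every
other column suppressed. Because the upstream aligner reports *all*
alignments, a multi-mapping read contributes one count per alignment record;
users wanting per-read counts should deduplicate upstream. `foldCoverage`
implements fold coverage literally as the average number of mapped reads per
contig (records / contigs). A base-level fold coverage
(records × read length / total assembled length) is offered as a clearly
separate secondary statistic, because reads-per-contig and base-level
coverage differ by orders of magnitude and published "fold coverage" figures
do not always say which normalization was used. The `mismatchesAllowed`
field (0, 1 or 2) is report metadata describing how the alignments were
produced; no mismatch counting happens here.

## Clustering: identity definition and algorithm

The identity between two contigs is **gap-free containment identity**: the
maximum, over every ungapped placement of the shorter sequence within the
longer (and over the reverse complement of the shorter, by default), of the
number of matching bases divided by the length of the shorter sequence.
Choices embedded there, and why:

* **Denominator = shorter sequence** (CD-HIT's convention): an exact
  substring scores 1.0, which is what makes "redundancy removal" at
  threshold 1.0 well-defined — contained contigs are redundant.
* **Gap-free**: the redundancy this step removes comes from re-assembling
  the same transcript at different k (identical copies, fragments,
  near-copies differing by substitutions), not from indel variation. A
  gap-free definition keeps the threshold semantics exact — at `c = 1.0`
  two sequences merge if and only if the shorter matches perfectly at some
  offset on some strand — and keeps synthetic expectations analytic.
* **N never matches**, on either side; consequently a shorter sequence
  containing N cannot reach identity 1.0.

`clusterContigs` is greedy longest-first with first-fit assignment, the
CD-HIT family's scheme: sort by decreasing length (ties by id, ascending, so
results are independent of input order); each contig joins the cluster of
the *first* representative reaching identity ≥ c, else founds a new cluster.
Representatives are therefore never shorter than their members, and the
representative set is invariant under permutation of the input files.

Parameters (`ClusterParams`): `identityThreshold` c ∈ (0.8, 1], defaults to
1.0, with 0.9 / 0.95 / 1.0 being the values of practical interest;
`wordSize` (default 8, mirroring the `-n 8` word length of CD-HIT-EST-style
tools); `bothStrands` (default `TRUE`, because different k runs may
assemble opposite strands of the same transcript).

### Word seeding is exact

Scoring every offset of every pair is quadratic and wasteful; multika scores
only offsets on which the two sequences share an exact word ("diagonal
seeding"), using a word index over the current representatives. This is an
optimization, not an approximation: if an offset achieves identity ≥ c for
a shorter sequence of length S, it has at most `m = floor(S(1-c))`
non-matching positions, hence contains a run of at least
`ceil((S-m)/(m+1))` consecutive matching non-N bases. The seeding word
length is the minimum of `wordSize` and that bound (capped at 12 for
hashing), so every offset that could cross the threshold is guaranteed to
be seeded. Setting `usePrefilter = FALSE` scores every offset and must —
and is tested to — give byte-identical results. Contigs shorter than the
word size are kept as their own representatives and reported; at the
default word size this only affects contigs under 8 bp.

`pairIdentity` (the user-facing pairwise operation) always scores every
offset, so the value it returns is exact even below the threshold.

A deliberate scope decision: VMATCH-style 100%-identity substring
non-redundancy is represented by `c = 1.0` rather than by a separate code
path, and no attempt is made to reproduce any external tool's output
bit-for-bit — those tools' internal identity definitions are not public in
the detail required, which is why the published per-k missing-KOI counts
shipped with the package are treated as input data, never as a
reproduction target.

## KOI comparison conventions

`pairwiseMissingMatrix` computes `cell(r, c) = |KOI(r) \ KOI(c)|` for every
ordered pair — strictly pairwise, one column = one assembly, which is how a
"missing in the set of column assemblies" matrix is conventionally filled in
pair-wise comparisons. Because the caption language for such matrices can
also be read as row-versus-everyone-else, a `mode = "vs-rest"` computes
`|KOI(r) \ ∪_{j≠r} KOI(j)|` instead; the default is pairwise. A useful
identity for validation (tested):
`cell(r,c) − cell(c,r) = |KOI(r)| − |KOI(c)|`.

`caComparison` reports, per single-k assembly, the KOIs missing from the CA
(forward) and the KOIs the CA has that the single-k lacks (reverse). The
TOTAL row sums the forward per-k counts even though one KOI may be missing
from several rows — that is the summation convention of printed missing-KOI
tables, and `caReportFromCounts` applies the same convention to published
count columns; the deduplicated union size is always reported alongside,
clearly labeled.

Recovery (`recoverAnnotations`) processes single-k assemblies in ascending
k order, so a KOI recovered once is not re-added from a later k. For each
batch of missing KOIs, `uniqueContigsForKois` selects covering contigs by
visiting KOIs in sorted order and picking, per still-uncovered KOI, the
longest contig annotated with it (ties by id) — longer contigs are preferred
because annotation accuracy improves with contig length. Whole contigs (not
just annotation rows) are incorporated, so the final product is a usable
FASTA for downstream annotation. Weak minimality holds: every recovered
contig contributes at least one KOI that neither the CA nor an earlier
recovered contig had.

## The synthetic-data generator

`simulateCatalog` draws `n` uniform-random DNA transcripts (default 60,
lengths uniform in 150–900 bp), labels a fraction (default 0.6) with
distinct synthetic KO tokens, and assigns each a low or high abundance
class. Uniform random sequence composition is sufficient because no
downstream operation is composition-sensitive beyond identity alignment.
The default catalog size keeps a full 23-assembly scenario (k = 19, 21, …,
63, the study design the labels encode) around a two-thousand-contig pool,
which the tests and the acceptance script run dozens of times; the vignette
states these sizes as the package's chosen test scale.

`simulateAssembly` captures each transcript independently with a
class-dependent probability, then emits it whole, split into two fragments
(both inheriting the KO label), or duplicated alongside a copy with a 2%
substitution load — substitutions only, so pairwise identities stay
analytically predictable (a duplicate scores exactly
`1 − round(0.02·L)/L`, merging at c ≤ 0.95 but not at 1.0). The default
capture schedule over k is monotone — capture of low-abundance transcripts
falls from 0.95 to 0.35 across the k window while capture of high-abundance
transcripts rises from 0.55 to 0.75, and fragmentation falls from 0.25 to
0.10 — reproducing the qualitative trends of real multi-k series: contig
counts fall as k grows, and low-k assemblies reach transcripts high-k ones
miss (tested in expectation over 20 seeds).

With every emitted contig annotated, greedy clustering cannot actually lose
a KOI: fragments and duplicates always collapse into an equally annotated
copy of the same transcript. Real annotation loss arises because annotation
itself is imperfect — a representative can be an unannotated contig that
absorbs annotated members. `simulateMultikScenario` therefore **plants**
losses explicitly (default 3): for chosen KO-labeled transcripts, one host
k emits an unannotated elongated copy (a 30 bp random tail appended, so it
out-lengths every copy and wins representative selection at any threshold,
while whole copies and fragments remain its exact substrings and collapse
into it), and another k is guaranteed an annotated whole copy. Edited
duplicate copies of planted transcripts are suppressed in other k values
because at `c = 1.0` they would survive as annotated representatives and
undo the plant. The truth record lists the planted lost KOIs, the per-k KOI
sets, each assembly's unique KOIs and the overall union — giving exact
expectations for comparison matrices and recovery.

What the generator does *not* emulate: read errors and quality profiles,
chimeric or misassembled contigs, indel variation between k runs,
paralogous gene families sharing a KOI, and annotation false positives.
Passing tests therefore demonstrate the correctness of the set algebra,
clustering semantics and recovery logic under controlled redundancy — not
robustness to assembler pathology on real data.

`simulateAlignments` plants exactly `r` reads per contig and emits the
matching legacy alignment stream (and, via `writeSam`, a valid SAM file),
closing the loop: `foldCoverage` must return exactly `r`.

## Numerical and degenerate-input choices

* Threshold comparisons use `matches ≥ c·S − 10⁻⁹` to keep exact-ratio
  cases (e.g. 95 matches at c = 0.95, S = 100) stable against floating
  rounding.
* Ties everywhere break by id (ascending) after length (descending), so
  every result is deterministic and input-order-free.
* Empty assemblies: metrics and coverage raise errors (there is no N50 of
  nothing); an empty FASTA parses to an empty assembly with a warning so
  that pipelines fail at the point of use, not of parse.
* Unknown reference names in alignment streams are an error in strict mode
  and are counted under their own name with a warning in permissive mode,
  preserving the records = counts conservation law either way.
* Seeds: every stochastic function takes an explicit `seed` and restores
  the caller's RNG state, so library use never perturbs a session's RNG.

## Known limitations

* The clustering is a faithful greedy-identity algorithm of the CD-HIT
  family, not a bit-exact emulation of any specific external tool; absolute
  missing-KOI counts from published runs of those tools are inputs, not
  targets.
* Gap-free identity understates similarity for sequences differing by
  indels; contigs of the same transcript differing by an internal indel may
  fail to merge at high c. For transcript redundancy removal this is
  conservative (too many representatives, never silent loss), and the
  recovery step is indifferent to it.
* Fold coverage as reads-per-contig is scale-dependent (it grows with read
  depth and shrinks with contig count); the base-level alternative is
  provided for cross-assembly comparison.
* `pairwiseMissingMatrix` is quadratic in the number of assemblies and KOI
  set sizes; at realistic scales (tens of assemblies, 10⁴ KOIs) this is
  negligible.
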