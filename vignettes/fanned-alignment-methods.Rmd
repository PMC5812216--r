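---
title: "Fanned multi-reference alignment for fusion breakpoint evaluation"
author: "fanalign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fanned multi-reference alignment for fusion breakpoint evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanalign)
```

## The problem

RNA-seq fusion detectors disagree: run on the same library, different tools
report different breakpoints with different supporting reads, and their false
positive rates vary by orders of magnitude. The most reliable way to triage a
candidate junction is to look at the read-level evidence itself: realign every
read from the neighborhood of the putative breakpoint against *all* plausible
explanations at once — the fused transcript, both normal partner transcripts,
and unspliced genomic sequence from either locus — and inspect which
references the reads actually choose.

`fanalign` implements that realignment as a three-dimensional variant of
Smith-Waterman. A candidate junction splits reference space into a 5' side
and a 3' side, each holding an arbitrary number of reference sequences
(genomic and exonic flanks of both partners by default, or any custom panel).
One score matrix is built per reference; all 5'-side matrices converge into a
single shared *breakpoint column*, and every 3'-side matrix is seeded from
that column. A single local alignment can therefore begin in any 5' reference,
cross the junction, and end in any 3' reference — or stay entirely on one
side, whichever scores best.

## Scoring model

For a read $A = a_1 \dots a_m$ and a reference $B = b_1 \dots b_n$ the
similarity is the unit scheme

$$\sigma(a_i, b_j) = \begin{cases} +1 & a_i = b_j \\ -1 & a_i \ne b_j
\end{cases}, \qquad W = -1,$$

with a linear gap penalty $W$ per gapped base. `N` and any other ambiguity
symbol mismatches everything, including another `N` — the conservative
reading of $\sigma$'s two-case definition. Scores are kept as integers; the
normalized score is only rounded for display.

The classic local recurrence, with entries floored at zero, fills each matrix:

$$H(i,j) = \max\{0,\; H(i-1,j-1)+\sigma(a_i,b_j),\; H(i,j-1)+W,\;
H(i-1,j)+W\}.$$

**Left stack.** Each 5'-side matrix is filled over its reference's columns
$1..n_f-1$ only; the *last* base of every left reference is withheld and
consumed by the breakpoint column. References may have unequal lengths — each
matrix carries its own $n_f$, and a length-1 left reference degenerates to an
initialized column whose single base feeds the junction directly.

**Breakpoint column.** Entry $i$ is the maximum over every move out of the
penultimate column of *any* left matrix: a diagonal move pairing $a_i$ with
the withheld last base of left reference $f$, a gap-in-read move from the
same row of matrix $f$, and a gap-in-reference move down the column itself.
The diagonal and deletion candidates pair each matrix with *its own* last
base. One can show (and the test suite verifies exhaustively on randomized
instances) that this column equals, entry-wise, the best corresponding column
over all single-reference computations, which yields the key correctness
property below.

**Right stack.** Column 0 of every 3'-side matrix is a copy of the breakpoint
column; the remaining columns follow the classic recurrence.

**Strand.** The whole construction is repeated for the reverse complement of
the read; the orientation with the larger global maximum wins and is reported
as strand `+` or `-`. Ties go to the forward strand.

**Score.** The alignment score is normalized per read,
$\alpha = H_s(i_0, j_0; f_0) / m \times 100$, where the numerator is the
matrix element at which backtracking commenced. A read matching some
reference (or some left$\oplus$right concatenation across the junction)
exactly scores 100; in local mode $\alpha \in [0, 100]$.

## Backtracking and tie-breaking

Backtracking starts at the global maximum over all matrices and the
breakpoint column and stops at the first zero entry. Inside a right matrix a
trace that reaches column 0 continues at the breakpoint column; a diagonal or
gap-in-read move out of the breakpoint column jointly selects one left matrix
and its withheld last base, and the trace then continues in that matrix. A
read is **spanning** when its trace consumes at least one read base strictly
on each side of the junction; read bases consumed *at* the breakpoint column
count as 5'-side bases, since that column represents the last base of the 5'
references.

The recurrences leave genuine ties, so the package fixes a total order to
make results reproducible:

* **Moves**: the trace follows neighboring elements in descending order of
  element score — among moves that explain the current cell, the one whose
  predecessor element is largest wins. This is what makes the trace extend
  through a gap whose predecessor sits higher than the diagonal's, as in the
  documented single-reference worked example. Remaining ties prefer diagonal,
  then gap-in-read, then gap-in-reference; candidate left matrices are taken
  in panel order.
* **Start cell**: side preference right > breakpoint column > left (starting
  on the right is what permits junction-crossing traces), lowest matrix index
  within a side, then largest read index and largest reference index within a
  matrix.
* **Gap placement** (single-reference alignment): among equal-scoring optima
  that differ only in which member of a run of identical bases is gapped, the
  leftmost placement is reported — the same convention used when normalizing
  indels.

## Semi-global mode

Local alignment may clip read ends. Semi-global mode instead guarantees that
every read base appears in the reported alignment: the floor is removed from
all recurrences, column 0 of the left matrices is initialized to $i \cdot W$
(every skipped leading read base costs a gap), backtracking starts at the
bottom-row maximum and terminates only at the top row. The normalized score
uses the bottom-row start element and may be negative; it is reported as
computed (a display layer may clamp at zero). Strand selection in this mode
compares bottom-row maxima, since that is the quantity the score is based on.

## Correctness property

The central invariant tying the fanned construction to ordinary alignment:
for every read and panel, the fanned global maximum equals
$$\max_{f_L, f_R} \mathrm{SW}(A,\; L_{f_L} \oplus R_{f_R}),$$
the best classic local score over all concatenations of one left and one
right reference, with the breakpoint column playing the role of each left
reference's final column. The suite checks this exhaustively on hundreds of
randomized instances (references up to 10 nt, reads up to 12 nt, up to 3
references per side), alongside an independent chained-pair enumeration
oracle for classic alignment itself and a cross-check against
`Biostrings::pairwiseAlignment`.

## Reference retrieval

Given a breakpoint `chrom:pos:strand > chrom:pos:strand` and a search radius
$r$ (default 200 bp, a typical choice for short-read fusion review), the
builder retrieves per partner:

* a **genomic** flank of exactly $r$ bp on each side (truncated only at
  contig ends, with a warning), and
* an **exonic** flank assembled by walking the merged exon annotation away
  from the coordinate, collecting exon sub-intervals until their aggregate
  length reaches $r$ or the annotation is exhausted.

The partner's breakpoint base belongs to the side matching its role (5'
partner → left reference, 3' partner → right reference); the walk for the
other side starts one base further on. An intronic start snaps to the nearest
exon boundary in the search direction. For a `-`-strand partner the search
directions swap and the assembled sequence is reverse complemented, so all
references read in transcript orientation. Overlapping exons from different
isoforms are flattened before walking; identical genomic/exonic references
are deliberately *not* deduplicated (both appear in the panel and the
legend). With annotation on both partners this yields 8 references, 4 per
side. All retrieval is from a local indexed FASTA plus a BED/refFlat exon
table — the package performs no network access.

## Read extraction

From coordinate-sorted indexed BAMs, a read qualifies when its alignment
start (leftmost mapped position, soft clips excluded) lies within $r$ of
either partner coordinate, or when its alignment overlaps an exon fragment
within exonic distance $r$ of a coordinate. Mates are fetched regardless of
their own alignment; placed unmapped mates are recovered through the index,
while mates with no coordinates at all cannot be and produce a warning.
Secondary/supplementary records may qualify a read, but each name/mate emits
one FASTQ record (primary preferred), with minus-strand records restored to
sequencing orientation. Pooling a normal and a chimeric alignment file
double-counts reads present in both; an opt-in name-based dedupe addresses
this, and it is off by default to mirror the pooling behavior users see with
chimeric-capable aligners.

## Filtering and display

Filtering is inclusive at the threshold (`alpha >= min_alpha`), so the
conventional review threshold of 95 retains reads scoring exactly 95. For
pairs, *both* mates must pass the score filter; under spanning-only display a
pair survives when at least one mate spans. Raising the threshold never adds
reads (a property the suite checks directly).

The evidence plot assigns each panel reference a deterministic color keyed to
its sorted label, draws each read (or pair, joined by a connector on one row)
as junction-relative segments — a spanning read takes its two references'
colors — and orders tracks: spanning first, then 5'-only, then 3'-only, each
by descending score. Output is a standalone SVG plus an HTML report with the
alignment table, and TSV/JSON tables; rendering is byte-stable so reports
diff cleanly.

## The synthetic locus generator

The generator exists so every layer is testable without downloads. Its
defaults are the conditions the package is validated under: two 24-kb random
chromosomes, partners mid-chromosome on `+` and `-` strands (exercising the
reverse-complement path end to end), 140-bp exons with 60-bp introns phased
so each coordinate is exonic, radius 200 bp, 50-nt reads (anchors of up to
~25 bp per side, the short-read regime fusion review targets), 0.5%
substitution errors, and 30/30/30/10 fusion/normal-5'/normal-3'/genomic
reads; paired mode draws 180±20 bp fragments with mate 2 reverse
complemented.

Two design points deserve emphasis:

* **Normal reads are drawn strictly on one side of their partner's
  coordinate.** The panel carries both partners' references on both sides of
  the junction, so a normal read crossing its own coordinate legitimately
  traces across the breakpoint column (taking the same partner's color on
  both sides) and is flagged spanning. One-sided draws keep the truth labels
  unambiguous, at the cost of not emulating coordinate-crossing normal
  coverage; the round-trip tests therefore show that labeled classes are
  recovered exactly, not that spanning status alone separates fusion from
  normal transcription in real libraries.
* **The decoy class models homology-driven false positives.** A shared 25-mer
  is planted at the junction-adjacent ends of both partners' 5' references,
  and decoy reads are normal 3'-partner reads crossing their own coordinate
  with a left anchor short enough to fit inside the shared k-mer. The
  realigner then attributes the anchor to the wrong partner — the
  characteristic "nonsense alignment" signature of reference homology, with
  a small and consistent anchor — deterministically, because the 5' partner
  precedes the 3' partner in panel order and ties resolve to the lowest
  matrix index.

What the generator does **not** emulate: indel sequencing errors, quality
score structure, coverage biases, alternative splicing near the junction,
and multi-isoform annotation. Passing round-trip tests demonstrate
correctness of the machinery under controlled conditions, not detector-grade
performance on real libraries.

Fixture BAMs are emitted directly from the generator's known fragment
layouts (`N`-gapped CIGARs across introns; junction-crossing reads as
soft-clipped records on the longer-anchor side in a separate chimeric file),
so no external aligner is required; a user can substitute real
chimeric-aligner output at the same interface.

## Numerical and degenerate-input choices

* Matrix fills are exact integer dynamic programming; the per-row gap
  recursion is unrolled with a running-maximum identity, so no tolerance
  enters anywhere.
* Empty read: raw score 0, normalized score undefined (`NA`); scoring an
  empty read explicitly is an error.
* Empty reference: an error when loading panels (every reference must have
  length ≥ 1).
* All-`N` reads score 0 in local mode.
* Reference panels larger than the 12-color palette cycle with progressive
  darkening and a warning.
* Worked problem sizes throughout the suite — references ≤ 10 nt and reads
  ≤ 12 nt for the oracle comparisons, a ~100-read locus for round-trips —
  were chosen so each oracle stays exhaustively checkable.

## Known limitations

* Linear gap penalties only; affine gaps, banding and vectorized
  acceleration are out of scope, as are protein alphabets.
* The breakpoint-column recurrence's gap-in-reference term references only
  the column itself (`H_bkpt(i-1) + W`), never re-entering a left matrix
  vertically at the junction; the implementation follows that definition
  as stated, and the backtrack may likewise sit in the column across
  several vertical moves.
* Exon walking is gene-agnostic: exons of unrelated overlapping genes are
  flattened together.
* Mates lacking coordinates entirely (unplaced unmapped) are not
  retrievable through a coordinate-sorted index.
* CRAM input and streaming SAM are unsupported.
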