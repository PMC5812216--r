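# fanalign

Realignment-based review of candidate gene fusions.

RNA-seq fusion detectors frequently disagree about where a breakpoint lies
and which reads support it, and their false-positive rates differ by orders
of magnitude. The most informative triage step is to go back to the reads:
realign everything near the candidate junction against *all* plausible
explanations simultaneously — the fused transcript, both normal partner
transcripts, and unspliced genomic sequence from either locus — and look at
which references the reads choose, how evenly they span the junction, and
whether short shared anchors betray reference homology rather than a real
rearrangement.

`fanalign` implements the alignment core for this as a fanned variant of
Smith-Waterman. Given a junction, any number of 5′-side references and any
number of 3′-side references, it builds one score matrix per reference; all
5′ matrices converge into a shared **breakpoint column** (fed by each
reference's withheld final base) and every 3′ matrix fans out from that
column. A single local (or semi-global) alignment may therefore start in any
5′ reference and continue across the junction into any 3′ reference. Each
read gets a normalized score

    alpha = H(i0, j0; f0) / m * 100

(the starting matrix element over the read length), so a read that aligns
perfectly anywhere along the panel scores exactly 100. Both strands are
scored and the better orientation is reported. Around that core the package
provides:

* **Reference building** — genomic flanks plus exon-walked exonic flanks for
  both partners (8 references for a typical annotated breakpoint), honoring
  strand, search radius, and the convention that each partner's breakpoint
  base belongs to the side matching its role. Local indexed FASTA +
  BED/refFlat input; no network access.
* **Read extraction** — pulls reads near the breakpoint (genomic start
  distance or exonic-distance overlap) with their mates from
  coordinate-sorted indexed BAMs, writing FASTQ.
* **Filtering and display** — inclusive minimum-score and spanning-read
  filters with paired-end both-mates semantics, and a deterministic,
  color-coded SVG/HTML evidence plot plus TSV/JSON tables.
* **Simulation** — a seeded generator for complete toy fusion loci (genome,
  exons, reads with truth labels, normal + chimeric BAM fixtures), including
  a homology-decoy class that reproduces the "nonsense alignment" signature
  of false positives.

## A worked example

Align a read that crosses from one gene's 5′ side into the *other* gene's 3′
side — the signature of a fusion-supporting read:

```r
library(fanalign)

panel <- reference_panel(
  left  = c("ACACA|exonic"  = "TGGAGAAGCTTCCAGGGAATGGTC",
            "STAC2|exonic"  = "CATTGGCACTAGGGTCCTGGAAAC"),
  right = c("ACACA3|exonic" = "GGTTCAAGGCCTATGTGATGGATC",
            "STAC23|exonic" = "CAGCGGTGGCAGCAGCTTCTTCAG"))

read <- paste0("GGGAATGGTC", "CAGCGGTGGCAGCA")
res <- align_read(read, panel)
res
#> read [local, strand +]: alpha 100.00 (raw 24 over 24 nt), spanning
#>   read: GGGAATGGTCCAGCGGTGGCAGCA
#>   ref:  GGGAATGGTCCAGCGGTGGCAGCA
#>   5' ref: ACACA|exonic
#>   3' ref: STAC23|exonic
```

The read realigns perfectly (`alpha` 100), is flagged `spanning`, and names
the two references its trace used: the last 10 bases of the first 5′
reference and the first 14 bases of the second 3′ reference — 10- and 14-bp
anchors on either side of the junction. `results_table()` flattens a list of
such results into one row per read (strand, alpha, references, spanning
flag, CIGAR-like operation string) for filtering and export.

The same machinery scales up through `build_reference_panel()` (genome +
exons + breakpoint), `extract_reads()` (BAM), `apply_filters()` /
`layout_tracks()` / `render_report()` (evidence plot), or in one step:

```sh
fanalign simulate --seed 9 --out-dir sim
fanalign run --genome sim/genome.fa --exons sim/exons.bed \
    --breakpoint "chrA:12000:+>chrB:12000:-" \
    --bam sim/normal.bam,sim/chimeric.bam --min-score 95 --out-dir report
```

(the `fanalign` script is installed under the package's `exec/` directory).

## Layout

```
R/                      core alignment, reference building, extraction,
                        filtering/visualization, simulator, pipeline
exec/fanalign           command-line interface
scripts/acceptance.R    headline-quantity recomputation
tests/testthat/         unit, property and end-to-end suites
vignettes/              methods vignette (model, conventions, limitations)
```
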