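# End-to-end orchestration: references -> (extraction) -> alignment ->
# filtering -> report. This is the function the command-line wrapper calls.

#' Run the full breakpoint evaluation pipeline
#'
#' Builds (or loads) the reference panel, reads candidate reads from FASTQ,
#' realigns every read across the breakpoint, applies the score/spanning
#' filters, and writes the SVG/HTML evidence report plus TSV/JSON tables.
#'
#' @param fastq character vector of 1 (single-end) or 2 (paired) FASTQ paths.
#' @param out_dir output directory for the report artifacts.
#' @param breakpoint a [breakpoint_spec()] (required unless a custom `panel`
#'   is given).
#' @param genome a [genome_source()] (with `breakpoint`).
#' @param exons an [exon_table()] (with `breakpoint`).
#' @param panel optionally, a ready-made [reference_panel()] instead of
#'   automatic retrieval.
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` or `"semiglobal"`.
#' @param min_alpha,spanning_only filter settings (see [filter_settings()]);
#'   pairing is inferred from the number of FASTQ files.
#' @param basename file stem for the report artifacts.
#' @return Invisibly, a list with `results` (all alignments), `retained`
#'   (post-filter), `panel`, and `paths`.
#' @export
run_candidate <- function(fastq, out_dir,
                          breakpoint = NULL, genome = NULL, exons = NULL,
                          panel = NULL,
                          scheme = scoring_scheme(),
                          mode = c("local", "semiglobal"),
                          min_alpha = 0, spanning_only = FALSE,
                          basename = "fusion_report") {
  mode <- match.arg(mode)
  if (is.null(panel)) {
    if (is.null(breakpoint) || is.null(genome))
      stop("either a panel or (breakpoint + genome [+ exons]) must be supplied")
    if (is.null(exons))
      exons <- exon_table(data.frame(chrom = character(0),
                                     start = integer(0), end = integer(0)))
    panel <- build_reference_panel(genome, exons, breakpoint)
  }
  paired <- length(fastq) == 2L
  reads <- if (paired) {
    c(read_fastq_reads(fastq[[1L]], mate = 1L),
      read_fastq_reads(fastq[[2L]], mate = 2L))
  } else {
    read_fastq_reads(fastq[[1L]])
  }
  results <- align_reads(reads, panel, scheme = scheme, mode = mode)
  settings <- filter_settings(min_alpha = min_alpha,
                              spanning_only = spanning_only,
                              paired = paired)
  retained <- apply_filters(results, settings)
  plot <- layout_tracks(retained, panel, settings)
  paths <- render_report(plot, retained, out_dir, basename = basename)
  invisible(list(results = results, retained = retained, panel = panel,
                 paths = paths))
}
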