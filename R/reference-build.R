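# Reference retrieval around a fusion breakpoint: genomic flanks and
# exon-walked exonic flanks for both fusion partners, honoring strand, search
# radius and the convention that each partner's breakpoint base belongs to
# the reference side matching its role (5' partner -> left, 3' partner ->
# right).

#' Open a genome sequence source
#'
#' Wraps either an indexed FASTA file (random access through its `.fai`
#' index) or an in-memory named set of sequences. All retrieval is local; no
#' network access is ever performed.
#'
#' @param x path to a FASTA file, a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param create_index for a FASTA path without a `.fai` index: create one
#'   (default `FALSE`, in which case a missing index is an error).
#' @return An object of class `"genome_source"`.
#' @export
genome_source <- function(x, create_index = FALSE) {
  if (is.character(x) && !is.null(names(x))) {
    seqs <- lapply(x, normalize_bases, what = "genome sequence")
    obj <- list(type = "memory", seqs = seqs,
                lengths = vapply(seqs, nchar, 0L))
  } else if (inherits(x, "DNAStringSet")) {
    seqs <- as.list(as.character(x))
    obj <- list(type = "memory", seqs = seqs,
                lengths = vapply(seqs, nchar, 0L))
  } else if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("genome FASTA not found: %s", x))
    fai <- paste0(x, ".fai")
    if (!file.exists(fai)) {
      if (create_index) Rsamtools::indexFa(x)
      else stop(sprintf("index not found: %s (run samtools faidx or set create_index = TRUE)", fai))
    }
    # .fai is a plain-text table: name, length, offset, linebases, linewidth
    idx <- utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE)
    obj <- list(type = "fasta", file = Rsamtools::FaFile(x),
                lengths = stats::setNames(as.integer(idx[[2L]]),
                                          as.character(idx[[1L]])))
  } else {
    stop("genome_source() expects a FASTA path, a named character vector, or a DNAStringSet")
  }
  structure(obj, class = "genome_source")
}

#' @export
print.genome_source <- function(x, ...) {
  cat(sprintf("genome source (%s): %d sequence(s)\n", x$type,
              length(x$lengths)))
  invisible(x)
}

genome_seqlen <- function(genome, chrom) {
  if (!chrom %in% names(genome$lengths))
    stop(sprintf("chromosome '%s' not present in genome source", chrom))
  genome$lengths[[chrom]]
}

#' Fetch a genomic subsequence
#'
#' 1-based inclusive coordinates. Ranges extending past a contig end are
#' truncated with a warning, so the returned sequence can be shorter than
#' requested only at contig boundaries.
#'
#' @param genome a [genome_source()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive range.
#' @return The requested sequence (uppercase).
#' @export
get_genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_source"))
  len <- genome_seqlen(genome, chrom)
  if (start > end) stop("start must be <= end")
  if (start < 1L || end > len) {
    warning(sprintf("range %s:%d-%d truncated to contig bounds [1, %d]",
                    chrom, start, end, len))
    start <- max(1L, start)
    end <- min(len, end)
    if (start > end) return("")
  }
  if (genome$type == "memory") {
    toupper(substr(genome$seqs[[chrom]], start, end))
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    toupper(as.character(Rsamtools::scanFa(genome$file, param = gr)[[1L]]))
  }
}

#' Build an exon table
#'
#' Flattens exon intervals (1-based, inclusive) into a merged,
#' strand-agnostic interval set per chromosome. Overlapping exons from
#' different transcripts are merged before any exon walking.
#'
#' @param df a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return An object of class `"exon_table"`: a data.frame of merged,
#'   sorted intervals.
#' @export
exon_table <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    class(out) <- c("exon_table", "data.frame")
    return(out)
  }
  if (any(df$start > df$end)) stop("exon start > end")
  if (any(df$start < 1L)) stop("exon coordinates must be >= 1")
  pieces <- lapply(split(df, df$chrom), function(d) {
    merged <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(chrom = d$chrom[[1L]], start = IRanges::start(merged),
               end = IRanges::end(merged))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exon_table", "data.frame")
  out
}

#' Read an exon annotation file
#'
#' Supports 3+ column BED (0-based half-open, converted to 1-based inclusive
#' on load) and refFlat-style tables (with `exonStarts`/`exonEnds` comma
#' lists, 0-based half-open). Intervals are merged per chromosome.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension: `.bed` vs anything else),
#'   `"bed"`, or `"refflat"`.
#' @return An [exon_table()].
#' @export
read_exon_table <- function(path, format = c("auto", "bed", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "refflat"
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             comment.char = "#")
    exon_table(data.frame(chrom = as.character(tab[[1L]]),
                          start = as.integer(tab[[2L]]) + 1L,
                          end = as.integer(tab[[3L]])))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             comment.char = "#")
    # refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
    #          exonCount exonStarts exonEnds
    if (ncol(tab) < 11L) stop("refFlat table needs 11 columns")
    rows <- lapply(seq_len(nrow(tab)), function(r) {
      starts <- as.integer(strsplit(tab[r, 10L], ",")[[1L]]) + 1L
      ends <- as.integer(strsplit(tab[r, 11L], ",")[[1L]])
      data.frame(chrom = tab[r, 3L], start = starts, end = ends)
    })
    exon_table(do.call(rbind, rows))
  }
}

chrom_exons <- function(exons, chrom) {
  d <- exons[exons$chrom == chrom, , drop = FALSE]
  d[order(d$start), , drop = FALSE]
}

#' Walk exons outward from a coordinate
#'
#' Starting at `from` (1-based; the caller has already applied the
#' breakpoint-base inclusion convention), accumulates exon sub-intervals in
#' the given genomic direction until their aggregate length reaches `radius`
#' or the annotation is exhausted. If `from` is intronic the walk starts at
#' the nearest exon boundary in the search direction.
#'
#' @param exons an [exon_table()].
#' @param chrom chromosome name.
#' @param from first candidate base of the walk.
#' @param direction `"3prime"` (increasing coordinates) or `"5prime"`
#'   (decreasing).
#' @param radius aggregate length to collect, in bp.
#' @return A data.frame of fragments (`start`, `end`), in ascending genomic
#'   order, with aggregate length `<= radius`. Zero rows (with a warning) if
#'   no exonic sequence exists in the search direction.
#' @export
exonic_walk <- function(exons, chrom, from, direction = c("3prime", "5prime"),
                        radius) {
  direction <- match.arg(direction)
  radius <- as.integer(radius)
  stopifnot(radius >= 1L)
  ex <- chrom_exons(exons, chrom)
  frags_start <- integer(0)
  frags_end <- integer(0)
  remaining <- radius
  cur <- as.integer(from)
  if (direction == "3prime") {
    while (remaining > 0L) {
      cand <- ex[ex$end >= cur, , drop = FALSE]
      if (nrow(cand) == 0L) break
      seg_start <- max(cur, cand$start[[1L]])
      take <- min(cand$end[[1L]] - seg_start + 1L, remaining)
      frags_start <- c(frags_start, seg_start)
      frags_end <- c(frags_end, seg_start + take - 1L)
      remaining <- remaining - take
      cur <- cand$end[[1L]] + 1L
    }
  } else {
    while (remaining > 0L) {
      cand <- ex[ex$start <= cur, , drop = FALSE]
      if (nrow(cand) == 0L) break
      last <- nrow(cand)
      seg_end <- min(cur, cand$end[[last]])
      take <- min(seg_end - cand$start[[last]] + 1L, remaining)
      frags_start <- c(frags_start, seg_end - take + 1L)
      frags_end <- c(frags_end, seg_end)
      remaining <- remaining - take
      cur <- cand$start[[last]] - 1L
    }
    ord <- order(frags_start)
    frags_start <- frags_start[ord]
    frags_end <- frags_end[ord]
  }
  if (length(frags_start) == 0L)
    warning(sprintf("no exonic sequence %s of %s:%d", direction, chrom, from))
  data.frame(start = frags_start, end = frags_end)
}

# Side geometry shared by genomic and exonic flank retrieval.
#
# For each reference side (left = transcript-upstream of the junction,
# right = transcript-downstream), work out the genomic walk direction and the
# first base of the walk. The partner's breakpoint base is included on the
# side matching its role; the other side starts one base further along the
# walk direction.
flank_geometry <- function(pos, strand, role, side) {
  # genomic direction of this side's walk
  inc <- if (strand == "+") side == "right" else side == "left"
  include_pos <- (role == "5prime_partner" && side == "left") ||
                 (role == "3prime_partner" && side == "right")
  from <- if (include_pos) pos else if (inc) pos + 1L else pos - 1L
  list(increasing = inc, from = from)
}

#' Genomic flanking references for one fusion partner
#'
#' Retrieves the two genomic (unspliced) references for a partner: the
#' left-of-junction sequence and the right-of-junction sequence, each of
#' length `radius` (truncated only at contig ends, with a warning). For a
#' `"-"`-strand partner the search directions swap and both sequences are
#' reverse complemented, so that the returned strings read in transcript
#' orientation. The partner's breakpoint base is included on the side
#' matching its role.
#'
#' @param genome a [genome_source()].
#' @param chrom,pos,strand partner coordinate.
#' @param role `"5prime_partner"` or `"3prime_partner"`.
#' @param radius flank length in bp.
#' @return A list with entries `left` and `right`, each a list
#'   `(seq, span, strand)` where `span` is the 1-based genomic interval
#'   string.
#' @export
genomic_flanks <- function(genome, chrom, pos, strand,
                           role = c("5prime_partner", "3prime_partner"),
                           radius) {
  role <- match.arg(role)
  radius <- as.integer(radius)
  stopifnot(radius >= 1L)
  one_side <- function(side) {
    g <- flank_geometry(pos, strand, role, side)
    if (g$increasing) {
      start <- g$from; end <- g$from + radius - 1L
    } else {
      start <- g$from - radius + 1L; end <- g$from
    }
    seq <- get_genome_seq(genome, chrom, start, end)
    if (strand == "-") seq <- reverse_complement(seq)
    list(seq = seq,
         span = sprintf("%s:%d-%d", chrom, max(1L, start),
                        min(end, genome_seqlen(genome, chrom))),
         strand = strand)
  }
  list(left = one_side("left"), right = one_side("right"))
}

#' Exonic flanking references for one fusion partner
#'
#' Walks the (merged) exon annotation outward from the partner coordinate in
#' both directions ([exonic_walk()]), fetches the fragments, concatenates
#' them in genomic order, and reverse complements the concatenation for a
#' `"-"`-strand partner. The aggregate length is `radius` when enough exonic
#' sequence exists, less when the annotation is exhausted, and the result is
#' empty (with a warning) when no exon lies in the search direction.
#'
#' @inheritParams genomic_flanks
#' @param exons an [exon_table()].
#' @return A list with entries `left` and `right`, each
#'   `(seq, span, fragments)`; `seq` is `""` when no exonic sequence was
#'   found.
#' @export
exonic_flanks <- function(genome, exons, chrom, pos, strand,
                          role = c("5prime_partner", "3prime_partner"),
                          radius) {
  role <- match.arg(role)
  radius <- as.integer(radius)
  one_side <- function(side) {
    g <- flank_geometry(pos, strand, role, side)
    frags <- exonic_walk(exons, chrom, g$from,
                         direction = if (g$increasing) "3prime" else "5prime",
                         radius = radius)
    if (nrow(frags) == 0L)
      return(list(seq = "", span = "", fragments = frags))
    seq <- paste(vapply(seq_len(nrow(frags)), function(k)
      get_genome_seq(genome, chrom, frags$start[[k]], frags$end[[k]]), ""),
      collapse = "")
    if (strand == "-") seq <- reverse_complement(seq)
    list(seq = seq,
         span = paste(sprintf("%s:%d-%d", chrom, frags$start, frags$end),
                      collapse = "+"),
         fragments = frags)
  }
  list(left = one_side("left"), right = one_side("right"))
}

#' Build the full reference panel for a breakpoint
#'
#' For each fusion partner, retrieves one genomic and one exonic reference on
#' each side of the junction: up to 8 references in total, 4 per side. Empty
#' exonic retrievals (no exon in the search direction) reduce the count with
#' a warning. Left-side references are ordered 5' partner first, then 3'
#' partner, genomic before exonic; likewise on the right.
#'
#' @param genome a [genome_source()].
#' @param exons an [exon_table()] (may have zero rows: genomic-only panel).
#' @param bp a [breakpoint_spec()].
#' @return A [reference_panel()] whose labels encode partner, origin and
#'   genomic span, e.g. `"5p|chr1:9901-10000|genomic"`.
#' @export
build_reference_panel <- function(genome, exons, bp) {
  stopifnot(inherits(bp, "breakpoint_spec"))
  radius <- bp$radius
  collect <- function(partner, role, tag) {
    gflank <- genomic_flanks(genome, partner$chrom, partner$pos,
                             partner$strand, role, radius)
    eflank <- exonic_flanks(genome, exons, partner$chrom, partner$pos,
                            partner$strand, role, radius)
    make <- function(side) {
      out <- list()
      out[[1L]] <- list(
        label = sprintf("%s|%s|genomic", tag, gflank[[side]]$span),
        origin = "genomic", seq = gflank[[side]]$seq, partner = tag,
        span = gflank[[side]]$span)
      if (nzchar(eflank[[side]]$seq)) {
        out[[2L]] <- list(
          label = sprintf("%s|%s|exonic", tag, eflank[[side]]$span),
          origin = "exonic", seq = eflank[[side]]$seq, partner = tag,
          span = eflank[[side]]$span)
      } else {
        warning(sprintf("no exonic reference for %s side '%s'", tag, side))
      }
      out
    }
    list(left = make("left"), right = make("right"))
  }
  p5 <- collect(bp$partner5, "5prime_partner", "5p")
  p3 <- collect(bp$partner3, "3prime_partner", "3p")
  reference_panel(left = c(p5$left, p3$left),
                  right = c(p5$right, p3$right))
}
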