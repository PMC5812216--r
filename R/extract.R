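# Extraction of breakpoint-proximal reads (and their mates) from
# coordinate-sorted, indexed BAM files.

#' Target regions around a breakpoint
#'
#' The union, per fusion partner, of (a) the genomic window extending
#' `radius` bp on each side of the partner coordinate and (b) the exon
#' fragments reached by walking the annotation outward from the coordinate in
#' both directions to an aggregate (exonic) distance of `radius`. Overlapping
#' intervals are merged.
#'
#' @param exons an [exon_table()].
#' @param bp a [breakpoint_spec()].
#' @param radius search radius in bp; defaults to `bp$radius`.
#' @return A [GenomicRanges::GRanges] of merged target intervals.
#' @export
target_regions <- function(exons, bp, radius = bp$radius) {
  stopifnot(inherits(bp, "breakpoint_spec"))
  radius <- as.integer(radius)
  per_partner <- function(partner) {
    chrom <- partner$chrom
    pos <- partner$pos
    win <- data.frame(start = max(1L, pos - radius), end = pos + radius)
    up <- suppressWarnings(
      exonic_walk(exons, chrom, pos, direction = "5prime", radius = radius))
    down <- suppressWarnings(
      exonic_walk(exons, chrom, pos + 1L, direction = "3prime",
                  radius = radius))
    d <- rbind(win, up, down)
    d$chrom <- chrom
    d
  }
  d <- rbind(per_partner(bp$partner5), per_partner(bp$partner3))
  GenomicRanges::reduce(
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end)))
}

#' Configuration for read extraction
#'
#' @param sources character vector of BAM paths (each must have a `.bai`
#'   index).
#' @param radius search radius in bp.
#' @param include_mates fetch the mate of every qualifying read, regardless
#'   of where (or whether) the mate aligned (default `TRUE`).
#' @param dedupe_by_name emit each read name/mate combination at most once
#'   across all sources (default `FALSE`, mirroring the behavior of pooling a
#'   normal and a chimeric alignment file, where reads present in both are
#'   counted twice).
#' @return An object of class `"extraction_config"`.
#' @export
extraction_config <- function(sources, radius = 200L, include_mates = TRUE,
                              dedupe_by_name = FALSE) {
  radius <- as.integer(radius)
  if (length(sources) < 1L) stop("at least one BAM source is required")
  if (is.na(radius) || radius < 1L) stop("radius must be >= 1")
  structure(list(sources = sources, radius = radius,
                 include_mates = isTRUE(include_mates),
                 dedupe_by_name = isTRUE(dedupe_by_name)),
            class = "extraction_config")
}

bam_scan_fields <- c("qname", "flag", "rname", "strand", "pos", "cigar",
                     "seq", "qual", "mrnm", "mpos")

# Scan one BAM over a set of ranges, returning a flat data.frame of records.
scan_bam_regions <- function(bam, which) {
  param <- Rsamtools::ScanBamParam(what = bam_scan_fields, which = which)
  res <- Rsamtools::scanBam(bam, param = param)
  pieces <- lapply(res, function(chunk) {
    n <- length(chunk$qname)
    if (n == 0L) return(NULL)
    data.frame(qname = chunk$qname,
               flag = chunk$flag,
               rname = as.character(chunk$rname),
               strand = as.character(chunk$strand),
               pos = chunk$pos,
               cigar = chunk$cigar,
               seq = as.character(chunk$seq),
               qual = as.character(chunk$qual),
               mrnm = as.character(chunk$mrnm),
               mpos = chunk$mpos,
               stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), strand = character(0),
                      pos = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      mrnm = character(0), mpos = integer(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, pieces))
}

flag_bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

# Mate index from the flag: 1/2 for paired reads, 0 for single-end.
mate_index <- function(flag) {
  ifelse(flag_bit(flag, 0x1L),
         ifelse(flag_bit(flag, 0x40L), 1L, 2L), 0L)
}

record_key <- function(df) paste(df$qname, mate_index(df$flag), sep = "\r")

#' Extract reads near a breakpoint from BAM files
#'
#' A read qualifies when its alignment start (leftmost mapped position, soft
#' clips excluded) lies within `radius` bp of either partner coordinate, or
#' when its alignment overlaps one of the exonic target regions
#' ([target_regions()]). With `include_mates`, the mate of every qualifying
#' read is fetched as well, regardless of its own alignment (placed unmapped
#' mates included; mates without coordinates cannot be reached through the
#' index and produce a warning). Secondary and supplementary alignments may
#' qualify a read, but each read name/mate emits at most one record, with
#' primary alignments preferred.
#'
#' Sequences are reported in original sequencing orientation (reverse-strand
#' alignments are reverse complemented back); missing base qualities are
#' filled with a constant placeholder. Output order is deterministic
#' (name-sorted, then mate index).
#'
#' @param cfg an [extraction_config()].
#' @param bp a [breakpoint_spec()].
#' @param exons an [exon_table()] (zero rows for genomic-only extraction).
#' @return A data.frame of FASTQ-ready records: `name`, `mate`, `seq`,
#'   `qual`, `source`, `qualifying` (`TRUE` for reads meeting the distance
#'   rule themselves, `FALSE` for records present only as mates).
#' @export
extract_reads <- function(cfg, bp, exons = exon_table(data.frame(
                            chrom = character(0), start = integer(0),
                            end = integer(0)))) {
  stopifnot(inherits(cfg, "extraction_config"), inherits(bp, "breakpoint_spec"))
  # The overlap criterion applies to the exon-derived intervals only; the
  # plain +/- radius windows enter through the alignment-start rule.
  exonic <- exonic_target_regions(exons, bp, cfg$radius)
  out <- lapply(cfg$sources, function(bam)
    extract_from_bam(bam, bp, exonic, cfg))
  records <- do.call(rbind, out)
  if (cfg$dedupe_by_name && nrow(records) > 0L) {
    records <- records[!duplicated(paste(records$name, records$mate)), ,
                       drop = FALSE]
  }
  if (nrow(records) > 0L) {
    records <- records[order(records$name, records$mate, records$source), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

extract_from_bam <- function(bam, bp, regions, cfg) {
  if (!file.exists(bam)) stop(sprintf("BAM file not found: %s", bam))
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop(sprintf("index not found: %s", bai))
  header_chroms <- names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)

  radius <- cfg$radius
  partners <- list(bp$partner5, bp$partner3)
  wins <- NULL
  for (p in partners) {
    if (!p$chrom %in% header_chroms) {
      warning(sprintf("chromosome '%s' absent from BAM header of %s; partner skipped",
                      p$chrom, bam))
      next
    }
    wins <- rbind(wins, data.frame(chrom = p$chrom,
                                   start = max(1L, p$pos - radius),
                                   end = p$pos + radius))
  }
  regions <- regions[as.character(GenomicRanges::seqnames(regions)) %in%
                       header_chroms]
  wins <- rbind(wins,
                data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                           start = GenomicRanges::start(regions),
                           end = GenomicRanges::end(regions)))
  if (is.null(wins) || nrow(wins) == 0L) return(empty_extraction())
  which <- GenomicRanges::reduce(
    GenomicRanges::GRanges(wins$chrom, IRanges::IRanges(wins$start, wins$end)))
  hits <- scan_bam_regions(bam, which)
  hits <- hits[!is.na(hits$pos) | flag_bit(hits$flag, 0x4L), , drop = FALSE]

  qualifying <- qualifies(hits, partners, header_chroms, regions, radius)
  kept <- hits[qualifying, , drop = FALSE]

  mates <- NULL
  if (cfg$include_mates && nrow(kept) > 0L) {
    paired <- kept[flag_bit(kept$flag, 0x1L), , drop = FALSE]
    want <- unique(data.frame(qname = paired$qname,
                              mate = 3L - mate_index(paired$flag),
                              mrnm = paired$mrnm, mpos = paired$mpos,
                              stringsAsFactors = FALSE))
    have <- paste(record_key(kept))
    want <- want[!paste(want$qname, want$mate, sep = "\r") %in% have, ,
                 drop = FALSE]
    # mates that fell inside the scanned regions (including placed unmapped
    # mates, whose stored mate coordinates are masked) are already in hand
    if (nrow(want) > 0L) {
      in_hits <- paste(record_key(hits)) %in%
        paste(want$qname, want$mate, sep = "\r")
      if (any(in_hits)) {
        mates <- hits[in_hits, , drop = FALSE]
        want <- want[!paste(want$qname, want$mate, sep = "\r") %in%
                       paste(record_key(mates)), , drop = FALSE]
      }
    }
    if (nrow(want) > 0L) {
      reachable <- !is.na(want$mrnm) & !is.na(want$mpos) &
        want$mrnm %in% header_chroms
      if (any(!reachable))
        warning(sprintf("%d mate(s) without usable coordinates could not be fetched from %s",
                        sum(!reachable), bam))
      want <- want[reachable, , drop = FALSE]
      if (nrow(want) > 0L) {
        mate_rng <- GenomicRanges::reduce(GenomicRanges::GRanges(
          want$mrnm, IRanges::IRanges(want$mpos, want$mpos)))
        cand <- scan_bam_regions(bam, mate_rng)
        sel <- paste(record_key(cand)) %in%
          paste(want$qname, want$mate, sep = "\r")
        mates <- rbind(mates, cand[sel, , drop = FALSE])
      }
    }
  }

  finalize_records(kept, mates, bam)
}

empty_extraction <- function() {
  data.frame(name = character(0), mate = integer(0), seq = character(0),
             qual = character(0), source = character(0),
             qualifying = logical(0), stringsAsFactors = FALSE)
}

# Exon fragments within exonic distance `radius` of either partner
# coordinate, walked in both directions.
exonic_target_regions <- function(exons, bp, radius) {
  per_partner <- function(p) {
    up <- suppressWarnings(
      exonic_walk(exons, p$chrom, p$pos, direction = "5prime",
                  radius = radius))
    down <- suppressWarnings(
      exonic_walk(exons, p$chrom, p$pos + 1L, direction = "3prime",
                  radius = radius))
    d <- rbind(up, down)
    if (nrow(d) == 0L) return(NULL)
    d$chrom <- p$chrom
    d
  }
  d <- rbind(per_partner(bp$partner5), per_partner(bp$partner3))
  if (is.null(d) || nrow(d) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end)))
}

# Reference-space width of an alignment from its CIGAR (M/D/N/=/X consume
# reference bases).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    ops <- substring(toks, nchar(toks))
    lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
}

# Distance rule: alignment start within `radius` of either coordinate, or
# alignment overlapping one of the exon-derived target regions.
qualifies <- function(hits, partners, header_chroms, regions, radius) {
  if (nrow(hits) == 0L) return(logical(0))
  ok <- rep(FALSE, nrow(hits))
  mapped_rec <- !flag_bit(hits$flag, 0x4L)  # placed-unmapped never qualifies
  for (p in partners) {
    if (!p$chrom %in% header_chroms) next
    ok <- ok | (mapped_rec & !is.na(hits$pos) & hits$rname == p$chrom &
                  abs(hits$pos - p$pos) <= radius)
  }
  if (length(regions) > 0L) {
    mapped <- which(!is.na(hits$pos) & !is.na(hits$cigar) & hits$cigar != "*")
    if (length(mapped) > 0L) {
      spans <- GenomicRanges::GRanges(
        hits$rname[mapped],
        IRanges::IRanges(hits$pos[mapped],
                         width = pmax(1L, cigar_ref_width(hits$cigar[mapped]))))
      hit_ov <- GenomicRanges::countOverlaps(spans, regions) > 0L
      ok[mapped] <- ok[mapped] | hit_ov
    }
  }
  ok
}

finalize_records <- function(kept, mates, bam) {
  all_rec <- rbind(kept, mates)
  if (is.null(all_rec) || nrow(all_rec) == 0L) return(empty_extraction())
  all_rec$mate_idx <- mate_index(all_rec$flag)
  all_rec$primary <- !flag_bit(all_rec$flag, 0x100L) &
    !flag_bit(all_rec$flag, 0x800L)
  # one record per name/mate, primary preferred
  all_rec <- all_rec[order(all_rec$qname, all_rec$mate_idx,
                           !all_rec$primary), , drop = FALSE]
  all_rec <- all_rec[!duplicated(paste(all_rec$qname, all_rec$mate_idx)), ,
                     drop = FALSE]
  qualifying <- rep(TRUE, nrow(all_rec))
  if (!is.null(mates) && nrow(mates) > 0L) {
    mate_keys <- setdiff(paste(record_key(mates)), paste(record_key(kept)))
    qualifying <- !(paste(record_key(all_rec)) %in% mate_keys)
  }
  seq <- all_rec$seq
  qual <- all_rec$qual
  rev_sel <- !is.na(all_rec$strand) & all_rec$strand == "-"
  if (any(rev_sel)) {
    seq[rev_sel] <- vapply(seq[rev_sel], reverse_complement, "")
    qual[rev_sel] <- vapply(qual[rev_sel], function(q)
      paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "")
  }
  # missing quality comes back as "*", empty, or space filler (below the
  # Sanger range, which starts at "!")
  no_qual <- is.na(qual) | qual == "*" | grepl("^ *$", qual)
  qual[no_qual] <- strrep("I", nchar(seq[no_qual]))
  data.frame(name = all_rec$qname, mate = all_rec$mate_idx, seq = seq,
             qual = qual, source = basename(bam), qualifying = qualifying,
             stringsAsFactors = FALSE)
}

#' Write extracted reads as FASTQ
#'
#' Single-end records (mate index 0) go to `<prefix>.fastq`; paired records
#' go to `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#'
#' @param records output of [extract_reads()].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_extracted_fastq <- function(records, prefix) {
  paths <- character(0)
  single <- records[records$mate == 0L, , drop = FALSE]
  if (nrow(single) > 0L || all(records$mate == 0L)) {
    p <- paste0(prefix, ".fastq")
    write_fastq(single, p)
    paths <- c(paths, p)
  }
  for (k in 1:2) {
    part <- records[records$mate == k, , drop = FALSE]
    if (nrow(part) > 0L) {
      p <- sprintf("%s_%d.fastq", prefix, k)
      part$name <- paste0(part$name, "/", k)
      write_fastq(part, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Dump target regions as BED for audit
#'
#' @param regions a `GRanges` from [target_regions()].
#' @param path output BED path (0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
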