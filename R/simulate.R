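# Synthetic fusion-locus generator: a toy multi-chromosome genome with exon
# structures, a fusion junction joining two loci (any strand combination),
# and reads drawn from the fusion transcript, both normal partner
# transcripts, unspliced genomic sequence, and an optional homology decoy
# class. Everything is derived from one seed so the full output byte stream
# is reproducible; BAM fixtures are produced by emitting the pre-computed
# alignments directly, with no external aligner.

#' Configuration for the synthetic fusion locus
#'
#' Defaults describe the study conditions the package is exercised under: two
#' 24-kb chromosomes with the junction mid-chromosome and opposite partner
#' strands (so the reverse-complement path is exercised), a 200-bp search
#' radius, 50-nt reads, a 0.5% per-base substitution error rate, and class
#' counts of 30/30/30/10 fusion / normal 5' / normal 3' / genomic reads.
#'
#' Normal and genomic reads are drawn strictly on one side of their partner's
#' coordinate: the reference panel carries both partners' references on both
#' sides of the junction, so a normal read crossing its own partner
#' coordinate would legitimately trace across the breakpoint column and be
#' flagged spanning. Keeping those classes one-sided keeps the truth labels
#' unambiguous. The decoy class instead crosses deliberately: a shared
#' `decoy_k`-mer planted at the junction-adjacent ends of both partners' 5'
#' references lets the realigner attribute a short left anchor to the wrong
#' partner, reproducing the homology-driven "nonsense alignments" that
#' mislead fusion detectors.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param partner5,partner3 lists `(chrom, pos, strand)` for the two fusion
#'   partners.
#' @param radius search radius in bp (also the flank length of the simulated
#'   transcripts).
#' @param exons exon data.frame (`chrom`, `start`, `end`) or `NULL` to tile
#'   140-bp exons with 60-bp introns around each partner coordinate.
#' @param read_length read length in nt.
#' @param counts named integer vector with entries `fusion`, `normal5`,
#'   `normal3`, `genomic`, `decoy`.
#' @param error_rate per-base substitution probability in `[0, 0.5)`.
#' @param paired generate read pairs (insert size `insert_mean` +/-
#'   `insert_sd`, mate 2 reverse complemented).
#' @param insert_mean,insert_sd fragment length distribution for pairs.
#' @param decoy_k length of the shared terminus k-mer planted for the decoy
#'   class.
#' @param seed integer seed fixing the entire output byte stream.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(chrom_lengths = c(chrA = 24000L, chrB = 24000L),
                              partner5 = list(chrom = "chrA", pos = 12000L,
                                              strand = "+"),
                              partner3 = list(chrom = "chrB", pos = 12000L,
                                              strand = "-"),
                              radius = 200L,
                              exons = NULL,
                              read_length = 50L,
                              counts = c(fusion = 30L, normal5 = 30L,
                                         normal3 = 30L, genomic = 10L,
                                         decoy = 0L),
                              error_rate = 0.005,
                              paired = FALSE,
                              insert_mean = 180L, insert_sd = 20L,
                              decoy_k = 25L,
                              seed = 42L) {
  full <- c(fusion = 0L, normal5 = 0L, normal3 = 0L, genomic = 0L,
            decoy = 0L)
  counts <- as.integer(counts)[match(names(full), names(c(counts)))]
  counts[is.na(counts)] <- 0L
  names(counts) <- names(full)
  if (any(counts < 0L)) stop("class counts must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (read_length < 2L) stop("read_length must be >= 2")
  if (radius < read_length)
    stop("radius must be at least the read length")
  structure(list(chrom_lengths = chrom_lengths, partner5 = partner5,
                 partner3 = partner3, radius = as.integer(radius),
                 exons = exons, read_length = as.integer(read_length),
                 counts = counts, error_rate = error_rate,
                 paired = isTRUE(paired),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 decoy_k = as.integer(decoy_k),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                              collapse = "")

# Per-base substitution errors to a uniformly chosen different base.
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- seq_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  for (k in hit) {
    chars[[k]] <- sample(setdiff(DNA_BASES, chars[[k]]), 1L)
  }
  paste(chars, collapse = "")
}

# Default exon tiling: 140-bp exons / 60-bp introns phased so that the
# partner coordinate falls inside an exon.
default_exons <- function(partner, radius) {
  period <- 200L
  first <- partner$pos - 70L - 5L * period
  starts <- first + period * (0:10)
  data.frame(chrom = partner$chrom, start = starts, end = starts + 139L)
}

# Transcript-ordered genomic blocks for one flank side: `frags` ascending
# genomic fragments, reversed for a "-"-strand partner.
side_blocks <- function(frags, chrom, strand) {
  if (nrow(frags) == 0L) return(NULL)
  ord <- if (strand == "+") seq_len(nrow(frags)) else rev(seq_len(nrow(frags)))
  data.frame(chrom = chrom, gstart = frags$start[ord], gend = frags$end[ord],
             strand = strand, stringsAsFactors = FALSE)
}

# Map a transcript interval [t0, t1] (1-based) to ascending genomic
# intervals through the transcript's block list.
map_interval <- function(blocks, t0, t1) {
  widths <- blocks$gend - blocks$gstart + 1L
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out <- NULL
  for (b in seq_len(nrow(blocks))) {
    lo <- max(t0, starts[[b]])
    hi <- min(t1, ends[[b]])
    if (lo > hi) next
    o0 <- lo - starts[[b]]
    o1 <- hi - starts[[b]]
    if (blocks$strand[[b]] == "+") {
      g0 <- blocks$gstart[[b]] + o0
      g1 <- blocks$gstart[[b]] + o1
    } else {
      g0 <- blocks$gend[[b]] - o1
      g1 <- blocks$gend[[b]] - o0
    }
    out <- rbind(out, data.frame(gstart = g0, gend = g1))
  }
  out <- out[order(out$gstart), , drop = FALSE]
  # merge genomically adjacent pieces (e.g. contiguous blocks split only by
  # transcript bookkeeping)
  if (nrow(out) > 1L) {
    keep_start <- out$gstart[[1L]]
    merged <- NULL
    cur_end <- out$gend[[1L]]
    for (b in 2:nrow(out)) {
      if (out$gstart[[b]] <= cur_end + 1L) {
        cur_end <- max(cur_end, out$gend[[b]])
      } else {
        merged <- rbind(merged, data.frame(gstart = keep_start, gend = cur_end))
        keep_start <- out$gstart[[b]]
        cur_end <- out$gend[[b]]
      }
    }
    out <- rbind(merged, data.frame(gstart = keep_start, gend = cur_end))
  }
  out
}

blocks_to_cigar <- function(iv, pre_clip = 0L, post_clip = 0L) {
  parts <- character(0)
  if (pre_clip > 0L) parts <- c(parts, sprintf("%dS", pre_clip))
  for (b in seq_len(nrow(iv))) {
    if (b > 1L) {
      gap <- iv$gstart[[b]] - iv$gend[[b - 1L]] - 1L
      if (gap > 0L) parts <- c(parts, sprintf("%dN", gap))
    }
    parts <- c(parts, sprintf("%dM", iv$gend[[b]] - iv$gstart[[b]] + 1L))
  }
  if (post_clip > 0L) parts <- c(parts, sprintf("%dS", post_clip))
  paste(parts, collapse = "")
}

#' Simulate a fusion locus with reads, truth labels and alignment fixtures
#'
#' Generates (deterministically from `cfg$seed`) a toy genome FASTA (with
#' `.fai` index), an exon BED, FASTQ reads with per-read truth labels, and
#' two coordinate-sorted indexed BAMs: `normal.bam` holding the non-fusion
#' classes aligned to their true loci (with `N`-gapped CIGARs across
#' introns), and `chimeric.bam` holding junction-crossing reads as
#' soft-clipped single-end records on the side with the longer anchor.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param write_bam also emit the BAM fixtures (default `TRUE`; the FASTQ and
#'   truth table alone suffice for alignment-only studies).
#' @return A list of class `"sim_locus"`: `paths` (named file paths),
#'   `truth` (per-read truth table), `breakpoint` (a [breakpoint_spec()]),
#'   `genome` (named character vector), `exons` (an [exon_table()]), and
#'   `transcripts` (the simulated transcript sequences and junction offsets).
#' @export
simulate_locus <- function(cfg, out_dir, write_bam = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p5 <- cfg$partner5
  p3 <- cfg$partner3
  r <- cfg$radius
  len <- cfg$read_length

  genome <- vapply(cfg$chrom_lengths, rand_dna, "")
  if (cfg$counts[["decoy"]] > 0L) {
    # Plant homology: the junction-adjacent end of the 3' partner's LEFT
    # (5'-side) reference must equal that of the 5' partner's left
    # reference. For a "-"-strand 3' partner that left flank is
    # revcomp(genome[pos+1 .. pos+k]); for "+" it is genome[pos-k+1 .. pos].
    k <- cfg$decoy_k
    shared <- substr(genome[[p5$chrom]], p5$pos - k + 1L, p5$pos)
    if (p3$strand == "-") {
      substr(genome[[p3$chrom]], p3$pos + 1L, p3$pos + k) <-
        reverse_complement(shared)
    } else {
      substr(genome[[p3$chrom]], p3$pos - k + 1L, p3$pos) <- shared
    }
  }
  g <- genome_source(genome)
  exdf <- cfg$exons
  if (is.null(exdf))
    exdf <- rbind(default_exons(p5, r), default_exons(p3, r))
  exons <- exon_table(exdf)

  ef5 <- exonic_flanks(g, exons, p5$chrom, p5$pos, p5$strand,
                       "5prime_partner", r)
  ef3 <- exonic_flanks(g, exons, p3$chrom, p3$pos, p3$strand,
                       "3prime_partner", r)
  gf5 <- genomic_flanks(g, p5$chrom, p5$pos, p5$strand, "5prime_partner", r)
  gf3 <- genomic_flanks(g, p3$chrom, p3$pos, p3$strand, "3prime_partner", r)

  txs <- list(
    fusion = list(seq = paste0(ef5$left$seq, ef3$right$seq),
                  junction = nchar(ef5$left$seq),
                  blocks = rbind(side_blocks(ef5$left$fragments, p5$chrom, p5$strand),
                                 side_blocks(ef3$right$fragments, p3$chrom, p3$strand)),
                  chimeric = TRUE),
    normal5 = list(seq = paste0(ef5$left$seq, ef5$right$seq),
                   junction = nchar(ef5$left$seq),
                   blocks = rbind(side_blocks(ef5$left$fragments, p5$chrom, p5$strand),
                                  side_blocks(ef5$right$fragments, p5$chrom, p5$strand)),
                   chimeric = FALSE),
    normal3 = list(seq = paste0(ef3$left$seq, ef3$right$seq),
                   junction = nchar(ef3$left$seq),
                   blocks = rbind(side_blocks(ef3$left$fragments, p3$chrom, p3$strand),
                                  side_blocks(ef3$right$fragments, p3$chrom, p3$strand)),
                   chimeric = FALSE),
    genomic5 = list(seq = paste0(gf5$left$seq, gf5$right$seq),
                    junction = r,
                    blocks = genomic_blocks(gf5, p5, r),
                    chimeric = FALSE),
    genomic3 = list(seq = paste0(gf3$left$seq, gf3$right$seq),
                    junction = r,
                    blocks = genomic_blocks(gf3, p3, r),
                    chimeric = FALSE)
  )

  reads <- list()
  add_read <- function(class, source, t_start, crosses, flip) {
    id <- length(reads) + 1L
    nm <- sprintf("%s_%04d", class, id)
    tx <- txs[[source]]
    raw <- substr(tx$seq, t_start, t_start + len - 1L)
    seq <- mutate_seq(raw, cfg$error_rate)
    if (flip) seq <- reverse_complement(seq)
    reads[[id]] <<- list(name = nm, mate = 0L, class = class,
                         source = source, t_start = t_start,
                         crosses = crosses, flip = flip, seq = seq)
  }
  add_pair <- function(class, source, frag_start, frag_len, crosses_fun) {
    id <- length(reads) + 1L
    nm <- sprintf("%s_%04d", class, id)
    tx <- txs[[source]]
    t1 <- frag_start
    t2 <- frag_start + frag_len - len
    for (m in 1:2) {
      ts <- if (m == 1L) t1 else t2
      raw <- substr(tx$seq, ts, ts + len - 1L)
      seq <- mutate_seq(raw, cfg$error_rate)
      if (m == 2L) seq <- reverse_complement(seq)
      reads[[length(reads) + 1L]] <<- list(
        name = nm, mate = m, class = class, source = source, t_start = ts,
        crosses = crosses_fun(ts), flip = m == 2L, seq = seq)
    }
  }
  crossing <- function(tx) {
    force(tx)
    function(ts) ts <= tx$junction && ts + len - 1L > tx$junction
  }
  frag_len_draw <- function(max_len) {
    fl <- round(stats::rnorm(1L, cfg$insert_mean, cfg$insert_sd))
    max(len, min(as.integer(fl), max_len))
  }

  emit_class <- function(class, n, source_picker, start_picker) {
    for (q in seq_len(n)) {
      source <- source_picker(q)
      tx <- txs[[source]]
      if (cfg$paired) {
        sp <- start_picker(q, source, paired = TRUE)
        add_pair(class, source, sp$frag_start, sp$frag_len, crossing(tx))
      } else {
        sp <- start_picker(q, source, paired = FALSE)
        add_read(class, source, sp$t_start, crossing(tx)(sp$t_start),
                 flip = stats::runif(1L) < 0.5)
      }
    }
  }

  # fusion: junction-crossing by construction (anchor 1..len-1 on the left)
  emit_class("fusion", cfg$counts[["fusion"]],
             function(q) "fusion",
             function(q, source, paired) {
               tx <- txs[[source]]
               o <- sample(seq_len(len - 1L), 1L)
               start <- tx$junction - o + 1L
               if (paired) {
                 fl <- frag_len_draw(nchar(tx$seq) - start + 1L)
                 list(frag_start = start, frag_len = fl)
               } else list(t_start = start)
             })
  # normal / genomic: strictly one-sided
  one_sided <- function(q, source, paired) {
    tx <- txs[[source]]
    left_side <- q %% 2L == 0L
    lo <- if (left_side) 1L else tx$junction + 1L
    hi <- if (left_side) tx$junction else nchar(tx$seq)
    if (paired) {
      fl <- frag_len_draw(hi - lo + 1L)
      fs <- lo + sample(max(1L, hi - lo + 1L - fl + 1L), 1L) - 1L
      list(frag_start = fs, frag_len = fl)
    } else {
      ts <- lo + sample(hi - lo + 1L - len + 1L, 1L) - 1L
      list(t_start = ts)
    }
  }
  emit_class("normal5", cfg$counts[["normal5"]], function(q) "normal5",
             one_sided)
  emit_class("normal3", cfg$counts[["normal3"]], function(q) "normal3",
             one_sided)
  emit_class("genomic", cfg$counts[["genomic"]],
             function(q) if (q %% 2L == 0L) "genomic5" else "genomic3",
             one_sided)
  # decoy: crosses the 3' partner's own coordinate with a left anchor that
  # fits inside the planted homology k-mer
  emit_class("homology_decoy", cfg$counts[["decoy"]],
             function(q) "normal3",
             function(q, source, paired) {
               tx <- txs[[source]]
               a_max <- max(3L, min(cfg$decoy_k - 3L, len - 2L))
               a <- sample(3:a_max, 1L)
               start <- tx$junction - a + 1L
               if (paired) {
                 fl <- frag_len_draw(nchar(tx$seq) - start + 1L)
                 list(frag_start = start, frag_len = fl)
               } else list(t_start = start)
             })

  truth <- do.call(rbind, lapply(reads, function(rd)
    data.frame(name = rd$name, mate = rd$mate, class = rd$class,
               source = rd$source, t_start = rd$t_start,
               crosses_junction = rd$crosses, flipped = rd$flip,
               stringsAsFactors = FALSE)))
  if (is.null(truth)) truth <- data.frame(name = character(0))

  paths <- write_sim_outputs(cfg, out_dir, genome, exdf, reads, truth, txs,
                             write_bam)
  structure(list(paths = paths, truth = truth,
                 breakpoint = breakpoint_spec(p5$chrom, p5$pos, p5$strand,
                                              p3$chrom, p3$pos, p3$strand,
                                              radius = r),
                 genome = genome, exons = exons, transcripts = txs),
            class = "sim_locus")
}

genomic_blocks <- function(gf, partner, r) {
  span_bounds <- function(span) {
    m <- regmatches(span, regexec("^([^:]+):(\\d+)-(\\d+)$", span))[[1L]]
    c(as.integer(m[[3L]]), as.integer(m[[4L]]))
  }
  lb <- span_bounds(gf$left$span)
  rb <- span_bounds(gf$right$span)
  frags <- data.frame(start = c(lb[[1L]], rb[[1L]]),
                      end = c(lb[[2L]], rb[[2L]]))
  frags <- frags[order(frags$start), , drop = FALSE]
  # contiguous genomic window: merge into transcript-ordered blocks
  side_blocks(frags, partner$chrom, partner$strand)
}

write_sim_outputs <- function(cfg, out_dir, genome, exdf, reads, truth, txs,
                              write_bam) {
  paths <- list()
  # genome FASTA + index
  fa_path <- file.path(out_dir, "genome.fa")
  gset <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(gset, fa_path, width = 70L)
  Rsamtools::indexFa(fa_path)
  paths$genome <- fa_path
  # exon BED (0-based half-open)
  bed_path <- file.path(out_dir, "exons.bed")
  utils::write.table(
    data.frame(exdf$chrom, exdf$start - 1L, exdf$end,
               sprintf("exon%03d", seq_len(nrow(exdf))), 0L, "+"),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths$exons <- bed_path
  # FASTQ
  recs <- data.frame(
    name = vapply(reads, function(x)
      if (x$mate > 0L) paste0(x$name, "/", x$mate) else x$name, ""),
    mate = vapply(reads, `[[`, 0L, "mate"),
    seq = vapply(reads, `[[`, "", "seq"),
    stringsAsFactors = FALSE)
  recs$qual <- strrep("I", nchar(recs$seq))
  if (cfg$paired) {
    for (m in 1:2) {
      p <- file.path(out_dir, sprintf("reads_%d.fastq", m))
      write_fastq(recs[recs$mate == m, , drop = FALSE], p)
      paths[[sprintf("fastq_%d", m)]] <- p
    }
  } else {
    p <- file.path(out_dir, "reads.fastq")
    write_fastq(recs, p)
    paths$fastq <- p
  }
  # truth table
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- truth_path
  if (write_bam) {
    paths <- c(paths, write_sim_bams(cfg, out_dir, genome, reads, txs))
  }
  paths
}

# SAM/BAM fixture emission. Non-chimeric reads are written with their true
# (possibly N-gapped) alignment; junction-crossing reads from the fusion
# transcript go to the chimeric file as soft-clipped single-end records on
# the side with the longer anchor.
write_sim_bams <- function(cfg, out_dir, genome, reads, txs) {
  len <- cfg$read_length
  sq_lines <- sprintf("@SQ\tSN:%s\tLN:%d", names(cfg$chrom_lengths),
                      cfg$chrom_lengths)
  header <- c("@HD\tVN:1.6\tSO:unsorted", sq_lines)

  sam_record <- function(rd, aligned_t0, aligned_t1, clip_sides = FALSE) {
    tx <- txs[[rd$source]]
    iv <- map_interval(tx$blocks, aligned_t0, aligned_t1)
    strand <- tx$blocks$strand[[1L]]
    chrom <- tx$blocks$chrom[[1L]]
    t_read0 <- rd$t_start
    t_read1 <- rd$t_start + len - 1L
    # position of the aligned portion within the stored (genome-orientation)
    # sequence decides where soft clips go
    q0 <- aligned_t0 - t_read0 + 1L
    q1 <- aligned_t1 - t_read0 + 1L
    if (strand == "-") {
      tmp <- c(len - q1 + 1L, len - q0 + 1L)
      q0 <- tmp[[1L]]; q1 <- tmp[[2L]]
    }
    pre <- q0 - 1L
    post <- len - q1
    tx_orient <- if (rd$flip) reverse_complement(rd$seq) else rd$seq
    stored <- if (strand == "-") reverse_complement(tx_orient) else tx_orient
    rev_flag <- xor(strand == "-", rd$flip)
    flag <- if (rev_flag) 16L else 0L
    list(qname = rd$name, flag = flag, rname = chrom,
         pos = iv$gstart[[1L]],
         cigar = blocks_to_cigar(iv, pre_clip = pre, post_clip = post),
         seq = stored, mate = rd$mate)
  }

  normal_lines <- character(0)
  chimeric_lines <- character(0)
  normal_recs <- list()
  for (rd in reads) {
    tx <- txs[[rd$source]]
    t0 <- rd$t_start
    t1 <- rd$t_start + len - 1L
    if (isTRUE(tx$chimeric) && rd$crosses) {
      left_len <- tx$junction - t0 + 1L
      right_len <- t1 - tx$junction
      rec <- if (left_len >= right_len)
        sam_record(rd, t0, tx$junction) else sam_record(rd, tx$junction + 1L, t1)
      chimeric_lines <- c(chimeric_lines, sprintf(
        "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
        rec$qname, rec$flag, rec$rname, rec$pos, rec$cigar, rec$seq,
        strrep("I", nchar(rec$seq))))
    } else if (isTRUE(tx$chimeric)) {
      # fully one-sided read of the fusion transcript (possible for pairs)
      rec <- if (t1 <= tx$junction) sam_record(rd, t0, t1)
             else sam_record(rd, max(t0, tx$junction + 1L), t1)
      chimeric_lines <- c(chimeric_lines, sprintf(
        "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
        rec$qname, rec$flag, rec$rname, rec$pos, rec$cigar, rec$seq,
        strrep("I", nchar(rec$seq))))
    } else {
      rec <- sam_record(rd, t0, t1)
      normal_recs[[length(normal_recs) + 1L]] <- rec
    }
  }
  # pair up mate information for the normal file
  if (length(normal_recs) > 0L) {
    by_name <- split(seq_along(normal_recs),
                     vapply(normal_recs, `[[`, "", "qname"))
    for (nm in names(by_name)) {
      ix <- by_name[[nm]]
      if (length(ix) == 2L) {
        a <- normal_recs[[ix[[1L]]]]
        b <- normal_recs[[ix[[2L]]]]
        a_rev <- bitwAnd(a$flag, 16L) > 0L
        b_rev <- bitwAnd(b$flag, 16L) > 0L
        a$flag <- a$flag + 1L + 2L + 64L + (if (b_rev) 32L else 0L)
        b$flag <- b$flag + 1L + 2L + 128L + (if (a_rev) 32L else 0L)
        a$rnext <- "="; a$pnext <- b$pos
        b$rnext <- "="; b$pnext <- a$pos
        normal_recs[[ix[[1L]]]] <- a
        normal_recs[[ix[[2L]]]] <- b
      }
    }
    for (rec in normal_recs) {
      normal_lines <- c(normal_lines, sprintf(
        "%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
        rec$qname, rec$flag, rec$rname, rec$pos, rec$cigar,
        rec$rnext %||% "*", rec$pnext %||% 0L, rec$seq,
        strrep("I", nchar(rec$seq))))
    }
  }

  emit_bam <- function(lines, stem) {
    sam <- file.path(out_dir, paste0(stem, ".sam"))
    writeLines(c(header, lines), sam)
    bam <- Rsamtools::asBam(sam, file.path(out_dir, stem), overwrite = TRUE,
                            indexDestination = TRUE)
    bam
  }
  list(normal_bam = emit_bam(normal_lines, "normal"),
       chimeric_bam = emit_bam(chimeric_lines, "chimeric"))
}
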