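# Hand-built SAM fixtures, converted to sorted+indexed BAM in a temp dir.
make_bam <- function(lines, dir, stem,
                     header = c("@HD\tVN:1.6\tSO:unsorted",
                                "@SQ\tSN:chrT\tLN:100000")) {
  sam <- file.path(dir, paste0(stem, ".sam"))
  writeLines(c(header, lines), sam)
  Rsamtools::asBam(sam, file.path(dir, stem), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_line <- function(qname, flag, pos, cigar = "10M", rname = "chrT",
                     seq = "ACGTACGTAC", rnext = "*", pnext = 0) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
          qname, flag, rname, pos, cigar, rnext, pnext, seq,
          strrep("I", nchar(seq)))
}

no_exons <- exon_table(data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0)))

test_that("the alignment-start distance rule keeps exactly the in-window reads", {
  dir <- withr::local_tempdir()
  pos <- 50000L
  r <- 100L
  offsets <- c(-r - 1L, -r, 0L, r, r + 1L)
  lines <- vapply(seq_along(offsets), function(k)
    sam_line(sprintf("off%+05d", offsets[[k]]), 0L, pos + offsets[[k]]), "")
  bam <- make_bam(lines, dir, "starts")
  bp <- breakpoint_spec("chrT", pos, "+", "chrT", 90000L, "+", radius = r)
  recs <- extract_reads(extraction_config(bam, radius = r,
                                          include_mates = FALSE),
                        bp, no_exons)
  expect_equal(sort(recs$name),
               sort(sprintf("off%+05d", c(-r, 0L, r))))
})

test_that("reads overlapping exonic target regions qualify without starting nearby", {
  dir <- withr::local_tempdir()
  pos <- 50000L
  exons <- exon_table(data.frame(chrom = "chrT",
                                 start = c(49951L, 60001L),
                                 end = c(50050L, 60040L)))
  # distant exon within exonic distance 100 of the breakpoint (50 bp remain
  # after the first exon's 50 downstream bases)
  lines <- c(sam_line("in_distant_exon", 0L, 60005L),
             sam_line("far_no_exon", 0L, 70000L))
  bam <- make_bam(lines, dir, "exonic")
  bp <- breakpoint_spec("chrT", pos, "+", "chrT", 90000L, "+", radius = 100L)
  recs <- extract_reads(extraction_config(bam, radius = 100L,
                                          include_mates = FALSE),
                        bp, exons)
  expect_true("in_distant_exon" %in% recs$name)
  expect_false("far_no_exon" %in% recs$name)
})

test_that("mates are fetched regardless of their alignment, including unmapped", {
  dir <- withr::local_tempdir()
  pos <- 50000L
  lines <- c(
    # pair A: both mapped, mate far outside the window
    sam_line("pairA", 0x1 + 0x40, pos, rnext = "=", pnext = 80000L),
    sam_line("pairA", 0x1 + 0x80, 80000L, rnext = "=", pnext = pos),
    # pair B: mate unmapped, placed at the mapped read's position
    sam_line("pairB", 0x1 + 0x40 + 0x8, pos + 5L, rnext = "=",
             pnext = pos + 5L),
    sprintf("pairB\t%d\tchrT\t%d\t0\t*\t=\t%d\t0\tGGGGGGGGGG\t*",
            0x1 + 0x80 + 0x4, pos + 5L, pos + 5L))
  bam <- make_bam(lines, dir, "mates")
  bp <- breakpoint_spec("chrT", pos, "+", "chrT", 90000L, "+", radius = 100L)
  recs <- extract_reads(extraction_config(bam, radius = 100L,
                                          include_mates = TRUE),
                        bp, no_exons)
  expect_setequal(paste(recs$name, recs$mate),
                  c("pairA 1", "pairA 2", "pairB 1", "pairB 2"))
  # the unmapped mate keeps its sequence and gets placeholder qualities
  unm <- recs[recs$name == "pairB" & recs$mate == 2L, ]
  expect_equal(unm$seq, "GGGGGGGGGG")
  expect_equal(unm$qual, "IIIIIIIIII")
  expect_false(unm$qualifying)
  # without mates, only the qualifying reads emerge
  recs2 <- extract_reads(extraction_config(bam, radius = 100L,
                                           include_mates = FALSE),
                         bp, no_exons)
  expect_setequal(recs2$name, c("pairA", "pairB"))
})

test_that("reads present in several sources obey the dedupe switch", {
  dir <- withr::local_tempdir()
  pos <- 50000L
  line <- sam_line("shared", 0L, pos)
  bam1 <- make_bam(line, dir, "src1")
  bam2 <- make_bam(line, dir, "src2")
  bp <- breakpoint_spec("chrT", pos, "+", "chrT", 90000L, "+", radius = 50L)
  dup <- extract_reads(extraction_config(c(bam1, bam2), radius = 50L,
                                         include_mates = FALSE),
                       bp, no_exons)
  expect_equal(nrow(dup), 2L)  # double-counted, as when pooling normal+chimeric
  ded <- extract_reads(extraction_config(c(bam1, bam2), radius = 50L,
                                         include_mates = FALSE,
                                         dedupe_by_name = TRUE),
                       bp, no_exons)
  expect_equal(nrow(ded), 1L)
})

test_that("minus-strand records are restored to sequencing orientation", {
  dir <- withr::local_tempdir()
  pos <- 50000L
  bam <- make_bam(sam_line("rev1", 0x10, pos, seq = "AACCGGTTAA"), dir, "rev")
  bp <- breakpoint_spec("chrT", pos, "+", "chrT", 90000L, "+", radius = 50L)
  recs <- extract_reads(extraction_config(bam, radius = 50L,
                                          include_mates = FALSE),
                        bp, no_exons)
  expect_equal(recs$seq, reverse_complement("AACCGGTTAA"))
})

test_that("missing indexes and unknown chromosomes are surfaced", {
  dir <- withr::local_tempdir()
  bam <- make_bam(sam_line("x", 0L, 100L), dir, "noidx")
  file.remove(paste0(bam, ".bai"))
  bp <- breakpoint_spec("chrT", 100L, "+", "chrT", 200L, "+", radius = 50L)
  expect_error(extract_reads(extraction_config(bam, radius = 50L), bp,
                             no_exons),
               "index not found")
  bam2 <- make_bam(sam_line("y", 0L, 100L), dir, "okidx")
  bp2 <- breakpoint_spec("chrT", 100L, "+", "chrMISSING", 200L, "+",
                         radius = 50L)
  expect_warning(recs <- extract_reads(extraction_config(bam2, radius = 50L),
                                       bp2, no_exons),
                 "absent from BAM header")
  expect_equal(recs$name, "y")
})

test_that("target regions match a per-base exonic-distance scan", {
  set.seed(71)
  for (k in 1:10) {
    n_ex <- sample(2:5, 1L)
    starts <- sort(sample(seq(100L, 4000L, by = 10L), n_ex))
    widths <- sample(30:200, n_ex, replace = TRUE)
    exons <- exon_table(data.frame(chrom = "cZ", start = starts,
                                   end = starts + widths))
    pos <- sample(500:3500, 1L)
    r <- sample(50:150, 1L)
    bp <- breakpoint_spec("cZ", pos, "+", "cZ", pos, "+", radius = r)
    regions <- target_regions(exons, bp, r)
    member <- rep(FALSE, 5000L)
    for (i in seq_along(regions)) {
      member[GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]] <- TRUE
    }
    # oracle: genomic window plus the nearest `r` exonic bases on each side
    expect_member <- rep(FALSE, 5000L)
    expect_member[max(1L, pos - r):(pos + r)] <- TRUE
    exonic_pos <- unlist(lapply(seq_len(nrow(exons)), function(e)
      exons$start[[e]]:exons$end[[e]]))
    up <- sort(exonic_pos[exonic_pos <= pos], decreasing = TRUE)
    down <- sort(exonic_pos[exonic_pos >= pos + 1L])
    expect_member[utils::head(up, r)] <- TRUE
    expect_member[utils::head(down, r)] <- TRUE
    expect_equal(member, expect_member, info = sprintf("case %d", k))
  }
})
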