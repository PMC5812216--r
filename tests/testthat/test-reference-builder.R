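test_that("genomic flanks reproduce the documented spans on both strands", {
  loc <- worked_example_locus()
  g <- loc$source
  gf5 <- genomic_flanks(g, "chr1", 10000L, "+", "5prime_partner", 100L)
  expect_equal(gf5$left$span, "chr1:9901-10000")
  expect_equal(gf5$right$span, "chr1:10001-10100")
  expect_equal(gf5$left$seq, substr(loc$genome[["chr1"]], 9901, 10000))
  gf3 <- genomic_flanks(g, "chr2", 20000L, "-", "3prime_partner", 100L)
  expect_equal(gf3$left$span, "chr2:20001-20100")
  expect_equal(gf3$right$span, "chr2:19901-20000")
  # minus-strand partner: both sequences reverse complemented
  expect_equal(gf3$left$seq,
               reverse_complement(substr(loc$genome[["chr2"]], 20001, 20100)))
  expect_equal(gf3$right$seq,
               reverse_complement(substr(loc$genome[["chr2"]], 19901, 20000)))
  # radius 1: the left reference is exactly the breakpoint base
  gf1 <- genomic_flanks(g, "chr1", 10000L, "+", "5prime_partner", 1L)
  expect_equal(gf1$left$seq, substr(loc$genome[["chr1"]], 10000, 10000))
  expect_equal(nchar(gf1$left$seq), 1L)
})

test_that("the exon walk collects fragments to the aggregate radius", {
  loc <- worked_example_locus()
  # 3' direction from the base after the breakpoint: skips the intron, takes
  # all of the 70-bp exon, then 30 bp of the next exon
  w <- exonic_walk(loc$exons, "chr1", 10001L, "3prime", 100L)
  expect_equal(w$start, c(10031L, 10201L))
  expect_equal(w$end, c(10100L, 10230L))
  # 5' direction including the breakpoint base stays within the 200-bp exon
  w2 <- exonic_walk(loc$exons, "chr1", 10000L, "5prime", 100L)
  expect_equal(w2, data.frame(start = 9901L, end = 10000L))
  # no exon in the search direction: empty result with a warning
  expect_warning(w3 <- exonic_walk(loc$exons, "chr1", 10400L, "3prime", 50L),
                 "no exonic sequence")
  expect_equal(nrow(w3), 0L)
})

test_that("exonic flanks concatenate fragments and honor strand", {
  loc <- worked_example_locus()
  ef <- exonic_flanks(loc$source, loc$exons, "chr1", 10000L, "+",
                      "5prime_partner", 100L)
  expect_equal(ef$right$span, "chr1:10031-10100+chr1:10201-10230")
  expect_equal(nchar(ef$right$seq), 100L)
  expect_equal(ef$right$seq,
               paste0(substr(loc$genome[["chr1"]], 10031, 10100),
                      substr(loc$genome[["chr1"]], 10201, 10230)))
  # a coordinate inside an exon longer than the radius degenerates to the
  # genomic flank
  gf <- genomic_flanks(loc$source, "chr1", 10000L, "+", "5prime_partner",
                       100L)
  expect_equal(ef$left$seq, gf$left$seq)
})

test_that("minus-strand panels equal plus-strand panels on the mirrored genome", {
  set.seed(61)
  n <- 4000L
  fwd <- rand_seq(n)
  pos <- 2000L
  exdf <- data.frame(chrom = "c", start = c(1701L, 1901L, 2101L),
                     end = c(1860L, 2060L, 2260L))
  exons <- exon_table(exdf)
  # mirror: reverse-complemented chromosome, coordinates flipped
  mirror <- reverse_complement(fwd)
  mpos <- n - pos + 1L
  mexons <- exon_table(data.frame(chrom = "c",
                                  start = n - exdf$end + 1L,
                                  end = n - exdf$start + 1L))
  for (role in c("5prime_partner", "3prime_partner")) {
    a <- exonic_flanks(genome_source(c(c = fwd)), exons, "c", pos, "-",
                       role, 120L)
    b <- exonic_flanks(genome_source(c(c = mirror)), mexons, "c", mpos, "+",
                       role, 120L)
    expect_equal(a$left$seq, b$left$seq, info = role)
    expect_equal(a$right$seq, b$right$seq, info = role)
    ga <- genomic_flanks(genome_source(c(c = fwd)), "c", pos, "-", role, 120L)
    gb <- genomic_flanks(genome_source(c(c = mirror)), "c", mpos, "+", role,
                         120L)
    expect_equal(ga$left$seq, gb$left$seq, info = role)
    expect_equal(ga$right$seq, gb$right$seq, info = role)
  }
})

test_that("automatic retrieval assembles the full panel", {
  loc <- worked_example_locus()
  panel <- build_reference_panel(loc$source, loc$exons, loc$bp)
  expect_length(panel$left, 4L)
  expect_length(panel$right, 4L)
  origins <- vapply(panel$left, `[[`, "", "origin")
  expect_equal(sort(unique(origins)), c("exonic", "genomic"))
  # empty annotation: genomic-only panel with warnings
  empty_ex <- exon_table(data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0)))
  w <- testthat::capture_warnings(
    p2 <- build_reference_panel(loc$source, empty_ex, loc$bp))
  expect_true(any(grepl("no exonic", w)))
  expect_length(p2$left, 2L)
  expect_length(p2$right, 2L)
})

test_that("exonic references equal genomic ones when exons tile the flanks", {
  set.seed(67)
  genome <- c(cA = rand_seq(3000L), cB = rand_seq(3000L))
  exons <- exon_table(data.frame(chrom = c("cA", "cB"), start = c(1L, 1L),
                                 end = c(3000L, 3000L)))
  bp <- breakpoint_spec("cA", 1500L, "+", "cB", 1500L, "+", radius = 150L)
  panel <- build_reference_panel(genome_source(genome), exons, bp)
  seqs <- vapply(panel$left, `[[`, "", "seq")
  expect_equal(unname(seqs[c(2, 4)]), unname(seqs[c(1, 3)]))
})

test_that("ranges beyond contig ends are truncated with a warning", {
  g <- genome_source(c(tiny = "ACGTACGTAC"))
  expect_warning(s <- get_genome_seq(g, "tiny", 8L, 15L), "truncated")
  expect_equal(s, "TAC")
  expect_warning(gf <- genomic_flanks(g, "tiny", 2L, "+", "5prime_partner",
                                      5L),
                 "truncated")
  expect_equal(gf$left$seq, "AC")
})

test_that("custom panels load with origin suffixes and validation", {
  dir <- withr::local_tempdir()
  left_fa <- file.path(dir, "left.fa")
  right_fa <- file.path(dir, "right.fa")
  writeLines(c(">geneA|genomic", "ACGTACGTAC", ">geneA|exonic", "ACGTAC",
               ">custom1", "ttggcc"), left_fa)
  writeLines(c(">geneB|genomic", "GGCCAATT", ">geneB|exonic", "GGCCAA"),
             right_fa)
  panel <- load_custom_panel(left_fa, right_fa)
  expect_length(panel$left, 3L)
  expect_length(panel$right, 2L)
  expect_equal(vapply(panel$left, `[[`, "", "origin"),
               c("genomic", "exonic", "custom"))
  # lowercase input is normalized and alignment is unchanged
  expect_equal(panel$left[[3]]$seq, "TTGGCC")
  res_lower <- align_read("ttggcc", panel)
  res_upper <- align_read("TTGGCC", panel)
  expect_equal(res_lower$alpha, res_upper$alpha)
  expect_equal(res_lower$alpha, 100)
  # duplicate IDs are rejected by name
  writeLines(c(">dup", "ACGT", ">dup", "AACC"), left_fa)
  expect_error(load_custom_panel(left_fa, right_fa), "dup")
  # empty file is an error
  writeLines(character(0), left_fa)
  expect_error(load_custom_panel(left_fa, right_fa), "")
})

test_that("annotation files parse into merged 1-based exon tables", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "ex.bed")
  writeLines(c("chr1\t100\t200\te1\t0\t+", "chr1\t150\t260\te2\t0\t-",
               "chr2\t0\t50\te3\t0\t+"), bed)
  ex <- read_exon_table(bed)
  expect_equal(ex$start, c(101L, 1L))
  expect_equal(ex$end, c(260L, 50L))
  rf <- file.path(dir, "genes.refflat")
  writeLines(paste(c("G1", "tx1", "chr3", "+", 999, 2000, 999, 2000, 2,
                     "1000,1500,", "1200,2000"), collapse = "\t"), rf)
  ex2 <- read_exon_table(rf)
  expect_equal(ex2$start, c(1001L, 1501L))
  expect_equal(ex2$end, c(1200L, 2000L))
})

test_that("breakpoint strings parse and validate", {
  bp <- parse_breakpoint("chr1:10,000:+>chr2:20,000:-", radius = 100L)
  expect_equal(bp$partner5$pos, 10000L)
  expect_equal(bp$partner3$strand, "-")
  bp2 <- parse_breakpoint("c1:5:+ -> c2:9:-")
  expect_equal(bp2$partner3$chrom, "c2")
  expect_error(parse_breakpoint("chr1:100:+"), "malformed")
  expect_error(parse_breakpoint("chr1:100:*>chr2:5:+"), "malformed")
  expect_error(breakpoint_spec("a", 0L, "+", "b", 5L, "+"), ">= 1")
})
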