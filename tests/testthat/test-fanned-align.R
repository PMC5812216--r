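make_panel <- function() {
  set.seed(77)
  reference_panel(
    left = c(l1 = rand_seq(20L), l2 = rand_seq(20L)),
    right = c(r1 = rand_seq(20L), r2 = rand_seq(20L)))
}

test_that("a junction-crossing read spans and identifies both references", {
  panel <- make_panel()
  left2 <- panel$left[[2]]$seq
  right1 <- panel$right[[1]]$seq
  read <- paste0(substr(left2, 15, 20), substr(right1, 1, 6))
  res <- align_read(read, panel)
  expect_true(res$spanning)
  expect_equal(res$left_ref_index, 2L)
  expect_equal(res$right_ref_index, 1L)
  expect_equal(res$alpha, 100)
  expect_equal(res$strand, "+")
  # junction-relative offsets: left segment ends at -1, right starts at 0
  expect_equal(res$left_offsets, c(-6L, -1L))
  expect_equal(res$right_offsets, c(0L, 5L))
})

test_that("a read contained in one reference does not span", {
  panel <- make_panel()
  read <- substr(panel$right[[2]]$seq, 3, 14)
  res <- align_read(read, panel)
  expect_false(res$spanning)
  expect_true(is.na(res$left_ref_index))
  expect_equal(res$right_ref_index, 2L)
  expect_equal(res$alpha, 100)
})

test_that("strand selection recovers reverse-complemented reads", {
  panel <- make_panel()
  frag <- substr(panel$left[[1]]$seq, 1, 20)
  res <- align_read(reverse_complement(frag), panel)
  expect_equal(res$strand, "-")
  expect_equal(res$alpha, 100)
  # palindromic read scores identically both ways: forward wins the tie
  pal <- "ACGCGT"  # reverse complement of itself
  expect_identical(reverse_complement(pal), pal)
  res2 <- align_read(pal, panel)
  expect_equal(res2$strand, "+")
})

test_that("the returned maximum matches independently recomputed orientations", {
  set.seed(19)
  for (k in 1:30) {
    panel <- random_panel()
    read <- rand_seq(sample(4:12, 1L))
    ch <- choose_strand(read, panel)
    fwd <- fanalign:::fan_fill(read, panel, scoring_scheme(), "local")
    rev <- fanalign:::fan_fill(reverse_complement(read), panel,
                               scoring_scheme(), "local")
    expect_equal(ch$max, max(fanalign:::fan_strand_max(fwd),
                             fanalign:::fan_strand_max(rev)))
  }
})

test_that("fanned maxima equal the best pairwise concatenation (small suite)", {
  set.seed(23)
  for (k in 1:60) {
    panel <- random_panel()
    read <- rand_seq(sample(12L, 1L))
    fm <- fanalign:::fan_fill(read, panel, scoring_scheme(), "local")
    expect_equal(fanalign:::fan_strand_max(fm),
                 oracle_concat_max(read, panel_seqs(panel, "left"),
                                   panel_seqs(panel, "right")),
                 info = sprintf("case %d: read %s", k, read))
  }
})

test_that("backtrack results agree with the concatenation oracle's argmax", {
  set.seed(29)
  for (k in 1:40) {
    panel <- random_panel()
    read <- rand_seq(sample(6:12, 1L))
    fm <- fanalign:::fan_fill(read, panel, scoring_scheme(), "local")
    res <- fan_backtrack(fm, panel)
    lefts <- panel_seqs(panel, "left")
    rights <- panel_seqs(panel, "right")
    expect_equal(res$score_raw, oracle_concat_max(read, lefts, rights))
    if (res$spanning) {
      hits <- oracle_concat_argmax(read, lefts, rights)
      expect_true(any(hits[, 1] == res$left_ref_index &
                        hits[, 2] == res$right_ref_index),
                  info = sprintf("case %d", k))
    }
  }
})

test_that("degenerate reads are scored per contract", {
  panel <- make_panel()
  allN <- align_read("NNNNNNNN", panel)
  expect_equal(allN$alpha, 0)
  expect_false(allN$spanning)
  empty <- align_read("", panel)
  expect_equal(empty$score_raw, 0)
  expect_true(is.na(empty$alpha))
})

test_that("semi-global and local agree on perfect full-length reads", {
  panel <- make_panel()
  set.seed(31)
  for (k in 1:10) {
    e <- panel$left[[sample(2L, 1L)]]$seq
    start <- sample(10L, 1L)
    read <- substr(e, start, start + 9L)
    loc <- align_read(read, panel, mode = "local")
    sg <- align_read(read, panel, mode = "semiglobal")
    expect_equal(loc$alpha, 100)
    expect_equal(sg$alpha, loc$alpha)
  }
})

test_that("semi-global mode traces every read base", {
  panel <- make_panel()
  set.seed(37)
  for (k in 1:25) {
    read <- rand_seq(sample(4:15, 1L))
    res <- align_read(read, panel, mode = "semiglobal")
    consumed <- nchar(gsub("-", "", res$aligned_read, fixed = TRUE))
    expect_equal(consumed, nchar(read))
  }
})

test_that("semi-global alpha may be negative and is reported as computed", {
  panel <- reference_panel(left = c(l1 = "AAAA"), right = c(r1 = "AAAA"))
  res <- align_read("GGGGGGGG", panel, mode = "semiglobal")
  expect_lt(res$alpha, 0)
})

test_that("identical inputs give byte-identical results", {
  panel <- make_panel()
  read <- paste0(substr(panel$left[[1]]$seq, 12, 20),
                 substr(panel$right[[2]]$seq, 1, 7))
  r1 <- align_read(read, panel)
  r2 <- align_read(read, panel)
  expect_identical(r1, r2)
})

test_that("spanning status, reference indices and path side-counts are consistent", {
  set.seed(41)
  for (k in 1:40) {
    panel <- random_panel()
    read <- rand_seq(sample(4:12, 1L))
    res <- align_read(read, panel)
    expect_identical(res$spanning,
                     !is.na(res$left_ref_index) && !is.na(res$right_ref_index))
    if (!is.null(res$path) && nrow(res$path) > 0) {
      consumed <- res$path$op %in% c("M", "I")
      left_bases <- sum(consumed & res$path$side %in% c("left", "bkpt"))
      right_bases <- sum(consumed & res$path$side == "right")
      expect_identical(res$spanning, left_bases >= 1 && right_bases >= 1)
    }
  }
})
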