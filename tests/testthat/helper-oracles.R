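# Independent oracles and fixture builders used across the suite. These are
# deliberately written as different algorithms from the package code paths
# they check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force local alignment score by chaining aligned base pairs: an
# optimal gapped local alignment (linear gaps, no trailing gaps) is a chain
# of aligned pairs (i1,j1) < (i2,j2) < ... ; the gap cost between consecutive
# pairs depends only on the index differences. Memoized recursion over "best
# chain ending at (i, j)".
oracle_local_score <- function(read, ref, match = 1, mismatch = -1,
                               gap = -1) {
  a <- strsplit(read, "")[[1L]]
  b <- strsplit(ref, "")[[1L]]
  m <- length(a)
  n <- length(b)
  if (m == 0L || n == 0L) return(0)
  memo <- matrix(NA_real_, m, n)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    s <- if (a[[i]] == b[[j]] && a[[i]] %in% BASES) match else mismatch
    best_prev <- 0
    if (i > 1L && j > 1L) {
      for (i2 in 1:(i - 1L)) for (j2 in 1:(j - 1L)) {
        v <- rec(i2, j2) + gap * ((i - i2 - 1L) + (j - j2 - 1L))
        if (v > best_prev) best_prev <- v
      }
    }
    memo[i, j] <<- s + best_prev
    memo[i, j]
  }
  best <- 0
  for (i in 1:m) for (j in 1:n) best <- max(best, rec(i, j))
  best
}

# Plain double-loop Smith-Waterman maximum (independent of the package's
# vectorized fill), used as the classic-SW side of the concatenation oracle.
helper_sw_max <- function(read, ref, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(read, "")[[1L]]
  b <- strsplit(ref, "")[[1L]]
  m <- length(a)
  n <- length(b)
  if (m == 0L || n == 0L) return(0)
  H <- matrix(0, m + 1L, n + 1L)
  for (i in 1:m) for (j in 1:n) {
    s <- if (a[[i]] == b[[j]] && a[[i]] %in% BASES) match else mismatch
    H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i + 1L, j] + gap,
                             H[i, j + 1L] + gap)
  }
  max(H)
}

# Concatenation oracle: the fanned global maximum must equal the best classic
# local score over all pairings of one left with one right reference.
oracle_concat_max <- function(read, left_refs, right_refs) {
  best <- 0
  for (L in left_refs) for (R in right_refs) {
    best <- max(best, helper_sw_max(read, paste0(L, R)))
  }
  best
}

# All (left, right) pairs attaining the concatenation maximum.
oracle_concat_argmax <- function(read, left_refs, right_refs) {
  scores <- outer(seq_along(left_refs), seq_along(right_refs),
                  Vectorize(function(L, R)
                    helper_sw_max(read, paste0(left_refs[[L]], right_refs[[R]]))))
  best <- max(scores)
  which(scores == best, arr.ind = TRUE)
}

random_panel <- function(max_refs = 3L, max_len = 10L) {
  nl <- sample(max_refs, 1L)
  nr <- sample(max_refs, 1L)
  left <- vapply(seq_len(nl), function(i) rand_seq(sample(max_len, 1L)), "")
  right <- vapply(seq_len(nr), function(i) rand_seq(sample(max_len, 1L)), "")
  names(left) <- paste0("L", seq_len(nl))
  names(right) <- paste0("R", seq_len(nr))
  reference_panel(left = left, right = right)
}

panel_seqs <- function(panel, side) {
  vapply(panel[[side]], `[[`, "", "seq")
}

# The printed worked-example locus: a deterministic two-chromosome synthetic
# genome with the documented exon structure around chr1:10,000 and exons
# around chr2:20,000 so that all 8 references can be retrieved.
worked_example_locus <- function(seed = 101L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  genome <- c(chr1 = rand_seq(10400L), chr2 = rand_seq(20400L))
  exons <- exon_table(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(9801L, 10031L, 10201L, 19801L, 20061L),
    end   = c(10000L, 10100L, 10270L, 20050L, 20200L)))
  list(genome = genome,
       source = genome_source(genome),
       exons = exons,
       bp = breakpoint_spec("chr1", 10000L, "+", "chr2", 20000L, "-",
                            radius = 100L))
}

# Minimal hand-rolled alignment result for filter/layout tests.
mock_result <- function(name, alpha, spanning, mate = NA_integer_,
                        left = if (spanning) "L1" else NA_character_,
                        right = if (spanning || is.na(left)) "R1" else NA_character_,
                        left_off = c(-10L, -1L), right_off = c(0L, 9L)) {
  fanalign:::new_fan_alignment(
    read_name = name, read_len = 50L, mode = "local", strand = "+",
    score_raw = alpha / 2, alpha = alpha, spanning = spanning,
    left_ref = left, right_ref = right,
    left_ref_index = if (is.na(left)) NA_integer_ else 1L,
    right_ref_index = if (is.na(right)) NA_integer_ else 1L,
    left_offsets = if (is.na(left)) c(NA_integer_, NA_integer_) else left_off,
    right_offsets = if (is.na(right)) c(NA_integer_, NA_integer_) else right_off,
    mate = mate)
}
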