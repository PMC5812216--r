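# Core dynamic-programming machinery shared by classic Smith-Waterman and the
# fanned multi-reference variant.
#
# Matrices are stored with an explicit row 0 and column 0, so H[i + 1, j + 1]
# holds the score for read prefix a_1..a_i against reference prefix b_1..b_j.

# Fill a score matrix over reference columns `ref` (character vector of bases)
# for read `read` (character vector), given the values of column 0 (`col0`,
# length m + 1). Row 0 is 0 in both modes. In local mode every entry is
# floored at 0.
#
# The per-row recurrence has a serial dependency through the gap-in-read term
# H(i, j-1) + W; with a linear gap penalty it unrolls to a running maximum,
#   H(i, j) = W*j + max_{0 <= k <= j} (C_k - W*k),
# where C_0 is the column-0 value of row i and C_j = max(floor, diag_j, up_j),
# which cummax() evaluates in one vectorized pass per row.
sw_fill <- function(read, ref, scheme, col0, local = TRUE) {
  m <- length(read)
  nc <- length(ref)
  H <- matrix(0, nrow = m + 1L, ncol = nc + 1L)
  H[, 1L] <- col0
  if (nc == 0L || m == 0L) return(H)
  W <- scheme$gap_score
  wj <- W * (0:nc)
  for (i in seq_len(m)) {
    sig <- sigma_vec(scheme, read[[i]], ref)
    prev <- H[i, ]
    M <- pmax(prev[1:nc] + sig, prev[2:(nc + 1L)] + W)
    if (local) M <- pmax(M, 0)
    r <- cummax(c(H[i + 1L, 1L], M) - wj) + wj
    H[i + 1L, 2:(nc + 1L)] <- r[-1L]
  }
  H
}

sigma1 <- function(scheme, a, b) {
  if (a == b && a %in% DNA_BASES) scheme$match_score else scheme$mismatch_score
}

# Locate the maximum cell of a classic matrix over i >= 1, j >= 1 with the
# declared tie-break: largest i, then largest j.
sw_argmax <- function(H) {
  m <- nrow(H) - 1L
  n <- ncol(H) - 1L
  sub <- H[-1L, -1L, drop = FALSE]
  v <- max(sub)
  hits <- which(sub == v, arr.ind = TRUE)
  i <- max(hits[, 1L])
  j <- max(hits[hits[, 1L] == i, 2L])
  list(value = v, i = i, j = j)
}

# Pick the backtrack move out of cell value `v` given the valid candidate
# moves. The trace follows the neighboring element in descending order of
# element score: among predecessors that explain v (pred + move cost == v),
# the one with the LARGEST predecessor value wins; remaining ties break
# diagonal > gap-in-read > gap-in-reference (and lowest matrix index f at
# the breakpoint column). `cand` is a list of lists (move, pred, ...).
pick_move <- function(cand, v) {
  valid <- Filter(function(x) x$ok, cand)
  if (length(valid) == 0L) return(NULL)
  preds <- vapply(valid, `[[`, 0, "pred")
  valid[[which.max(preds)]]  # which.max keeps the first (preferred) on ties
}

# Backtrack within one classic matrix from (i, j), local mode: stops at the
# first element equal to 0. Returns reversed emission vectors plus the final
# cursor.
sw_trace_classic <- function(H, read, ref, scheme, i, j) {
  W <- scheme$gap_score
  ar <- character(0)
  af <- character(0)
  ops <- character(0)
  repeat {
    v <- H[i + 1L, j + 1L]
    if (v == 0) break
    cand <- list(
      list(move = "M", ok = i >= 1L && j >= 1L &&
             H[i, j] + sigma1(scheme, read[[i]], ref[[j]]) == v,
           pred = if (i >= 1L && j >= 1L) H[i, j] else -Inf),
      list(move = "D", ok = j >= 1L && H[i + 1L, j] + W == v,
           pred = if (j >= 1L) H[i + 1L, j] else -Inf),
      list(move = "I", ok = i >= 1L && H[i, j + 1L] + W == v,
           pred = if (i >= 1L) H[i, j + 1L] else -Inf)
    )
    mv <- pick_move(cand, v)
    if (is.null(mv))
      stop("internal error: inconsistent score matrix during backtrack")
    if (mv$move == "M") {
      ar <- c(ar, read[[i]]); af <- c(af, ref[[j]]); ops <- c(ops, "M")
      i <- i - 1L; j <- j - 1L
    } else if (mv$move == "D") {
      ar <- c(ar, "-"); af <- c(af, ref[[j]]); ops <- c(ops, "D")
      j <- j - 1L
    } else {
      ar <- c(ar, read[[i]]); af <- c(af, "-"); ops <- c(ops, "I")
      i <- i - 1L
    }
  }
  list(ar = ar, af = af, ops = ops, end_i = i, end_j = j)
}

# Canonicalize gap placement: among equally scoring optima that differ only
# in which member of a run of identical bases is gapped, report the leftmost
# placement (the convention used when normalizing indels). A gap-in-read
# column may swap with a preceding match/mismatch column when the two
# reference bases are identical; a gap-in-reference column when the two read
# bases are identical. Scores, consumed bases and ranges are unaffected.
left_align_gaps <- function(ar, af, ops) {
  n <- length(ops)
  if (n < 2L) return(list(ar = ar, af = af, ops = ops))
  repeat {
    moved <- FALSE
    for (k in 2:n) {
      if (ops[[k]] == "D" && ops[[k - 1L]] == "M" &&
          af[[k]] == af[[k - 1L]]) {
        ar[c(k - 1L, k)] <- ar[c(k, k - 1L)]
        ops[c(k - 1L, k)] <- ops[c(k, k - 1L)]
        moved <- TRUE
      } else if (ops[[k]] == "I" && ops[[k - 1L]] == "M" &&
                 ar[[k]] == ar[[k - 1L]]) {
        af[c(k - 1L, k)] <- af[c(k, k - 1L)]
        ops[c(k - 1L, k)] <- ops[c(k, k - 1L)]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(ar = ar, af = af, ops = ops)
}

ops_to_cigar <- function(ops) {
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Classic Smith-Waterman local alignment
#'
#' Aligns a read against a single reference under a match/mismatch similarity
#' and a linear gap penalty, returning the maximal local alignment. Backtrack
#' starts at the maximum matrix element (ties: largest read index, then
#' largest reference index) and ends at the first element equal to zero. The
#' trace follows neighboring elements in descending order of element score:
#' when several moves explain a cell, the move whose predecessor element is
#' largest wins, with remaining ties preferring diagonal, then gap-in-read,
#' then gap-in-reference. Gap placement is canonicalized to the leftmost
#' position within runs of identical bases.
#'
#' @param read a [read_sequence()] or a plain nucleotide string.
#' @param ref a single reference sequence (string).
#' @param scheme a [scoring_scheme()].
#' @return An object of class `"fan_alignment"`; for this single-reference
#'   case `spanning` is always `FALSE` and the reference indices are `NA`.
#' @examples
#' res <- classic_sw_align("ACGTGAT", "ACCGTCAT")
#' res$aligned_read  # "A-CGTGAT"
#' res$aligned_ref   # "ACCGTCAT"
#' @export
classic_sw_align <- function(read, ref, scheme = scoring_scheme()) {
  read <- as_read_sequence(read)
  ref <- normalize_bases(ref, what = "reference")
  if (nchar(ref) == 0L) stop("empty reference")
  m <- nchar(read$bases)
  if (m == 0L) {
    return(new_fan_alignment(read_name = read$name, read_len = 0L,
                             mode = "local", strand = "+",
                             score_raw = 0, alpha = NA_real_))
  }
  rc <- seq_chars(read$bases)
  fc <- seq_chars(ref)
  H <- sw_fill(rc, fc, scheme, col0 = rep(0, m + 1L), local = TRUE)
  mx <- sw_argmax(H)
  if (mx$value <= 0) {
    return(new_fan_alignment(read_name = read$name, read_len = m,
                             mode = "local", strand = "+",
                             score_raw = 0, alpha = 0))
  }
  tr <- sw_trace_classic(H, rc, fc, scheme, mx$i, mx$j)
  can <- left_align_gaps(rev(tr$ar), rev(tr$af), rev(tr$ops))
  new_fan_alignment(
    read_name = read$name, read_len = m, mode = "local", strand = "+",
    score_raw = mx$value, alpha = alignment_score(mx$value, m),
    aligned_read = paste(can$ar, collapse = ""),
    aligned_ref = paste(can$af, collapse = ""),
    cigar = ops_to_cigar(can$ops),
    read_start = tr$end_i + 1L, read_end = mx$i,
    right_ref_range = c(tr$end_j + 1L, mx$j)
  )
}

#' Normalized 0-100 alignment score
#'
#' Converts the raw score of the starting matrix element into the per-read
#' normalized score `alpha = score_raw / m * 100`, where `m` is the read
#' length. A read that aligns perfectly somewhere along the references under
#' the default unit scoring scheme receives exactly 100. In local mode alpha
#' lies in `[0, 100]`; in semi-global mode it may be negative and is reported
#' as computed.
#'
#' @param score_raw value of the matrix element where backtracking commenced.
#' @param read_length read length `m` (must be >= 1).
#' @return Numeric alpha.
#' @export
alignment_score <- function(score_raw, read_length) {
  if (read_length == 0L) stop("cannot score empty read")
  score_raw / read_length * 100
}

# Shared result constructor. Unset fields default to the empty-alignment
# state so that degenerate cases (empty read, all-mismatch read) are uniform.
new_fan_alignment <- function(read_name, read_len, mode, strand,
                              score_raw, alpha,
                              aligned_read = "", aligned_ref = "",
                              cigar = "",
                              spanning = FALSE,
                              left_ref_index = NA_integer_,
                              right_ref_index = NA_integer_,
                              left_ref = NA_character_,
                              right_ref = NA_character_,
                              read_start = NA_integer_,
                              read_end = NA_integer_,
                              left_ref_range = c(NA_integer_, NA_integer_),
                              right_ref_range = c(NA_integer_, NA_integer_),
                              left_offsets = c(NA_integer_, NA_integer_),
                              right_offsets = c(NA_integer_, NA_integer_),
                              mate = NA_integer_,
                              path = NULL) {
  structure(
    list(read_name = read_name, read_len = as.integer(read_len), mode = mode,
         strand = strand, score_raw = score_raw, alpha = alpha,
         aligned_read = aligned_read, aligned_ref = aligned_ref,
         cigar = cigar, spanning = spanning,
         left_ref_index = left_ref_index, right_ref_index = right_ref_index,
         left_ref = left_ref, right_ref = right_ref,
         read_start = read_start, read_end = read_end,
         left_ref_range = left_ref_range, right_ref_range = right_ref_range,
         left_offsets = left_offsets, right_offsets = right_offsets,
         mate = mate, path = path),
    class = "fan_alignment"
  )
}

#' @export
print.fan_alignment <- function(x, ...) {
  cat(sprintf("%s [%s, strand %s]: alpha %.2f (raw %g over %d nt)%s\n",
              x$read_name, x$mode, x$strand,
              if (is.na(x$alpha)) NaN else x$alpha,
              x$score_raw, x$read_len,
              if (isTRUE(x$spanning)) ", spanning" else ""))
  if (nzchar(x$aligned_read)) {
    cat("  read: ", x$aligned_read, "\n  ref:  ", x$aligned_ref, "\n", sep = "")
    if (!is.na(x$left_ref))  cat("  5' ref: ", x$left_ref, "\n", sep = "")
    if (!is.na(x$right_ref)) cat("  3' ref: ", x$right_ref, "\n", sep = "")
  }
  invisible(x)
}
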