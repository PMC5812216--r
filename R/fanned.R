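# Fanned multi-reference Smith-Waterman: one score matrix per reference on
# each side of the junction, all left matrices converging into a shared
# breakpoint column from which all right matrices fan out.

#' Score the left-side matrix stack
#'
#' Fills one Smith-Waterman score matrix per 5' reference. The final
#' reference column is withheld from each matrix: the last base of every left
#' reference is instead consumed by the breakpoint column
#' ([fill_breakpoint_column()]), which is where all left matrices converge.
#' Each reference carries its own length, so matrices in the stack may have
#' different widths; a length-1 left reference yields a matrix consisting of
#' only the initialized column 0 and contributes solely through the
#' breakpoint column.
#'
#' Initialization: in local mode row 0 and column 0 are 0 and all entries are
#' floored at 0; in semi-global mode column 0 of row `i` is `i * W` (every
#' skipped leading read base costs a gap), row 0 stays 0, and entries may be
#' negative.
#'
#' @param read a [read_sequence()] or nucleotide string.
#' @param panel a [reference_panel()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` or `"semiglobal"`.
#' @return A list with one element per left reference: `H` (score matrix with
#'   explicit row/column 0), `chars` (scored reference bases, i.e. all but the
#'   last), `last_base`, `n` (full reference length) and `label`.
#' @export
fill_left_stack <- function(read, panel, scheme = scoring_scheme(),
                            mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  read <- as_read_sequence(read)
  rc <- seq_chars(read$bases)
  m <- length(rc)
  local <- mode == "local"
  col0 <- if (local) rep(0, m + 1L) else scheme$gap_score * (0:m)
  lapply(panel$left, function(entry) {
    bases <- seq_chars(entry$seq)
    n <- length(bases)
    scored <- if (n > 1L) bases[seq_len(n - 1L)] else character(0)
    list(H = sw_fill(rc, scored, scheme, col0 = col0, local = local),
         chars = scored, last_base = bases[[n]], n = n, label = entry$label)
  })
}

#' Score the breakpoint column
#'
#' The breakpoint column is the shared column where all left-side matrices
#' converge. Entry `i` is the maximum over every move that leaves the
#' penultimate column of any left matrix: a diagonal move pairing read base
#' `a_i` with the last base of left reference `f`, a gap-in-read move from the
#' same row of matrix `f`, and a gap-in-reference move down the column itself
#' (`H_bkpt(i-1) + W`). In local mode the column is floored at 0.
#' `H_bkpt(0) = 0` in both modes.
#'
#' @param read a [read_sequence()] or nucleotide string.
#' @param left_stack result of [fill_left_stack()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` or `"semiglobal"`.
#' @return Numeric vector of length `m + 1` (entries for read rows 0..m).
#' @export
fill_breakpoint_column <- function(read, left_stack,
                                   scheme = scoring_scheme(),
                                   mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  read <- as_read_sequence(read)
  rc <- seq_chars(read$bases)
  m <- length(rc)
  local <- mode == "local"
  W <- scheme$gap_score
  if (m == 0L) return(0)
  # Best single-row candidate D_i over all left matrices (diagonal and
  # gap-in-read moves); the serial gap-in-reference term unrolls with the
  # same running-maximum identity as the row fill.
  D <- rep(-Inf, m)
  for (entry in left_stack) {
    pen <- entry$H[, ncol(entry$H)]  # penultimate reference column, rows 0..m
    sig <- sigma_vec(scheme, entry$last_base, rc)
    D <- pmax(D, pen[1:m] + sig, pen[2:(m + 1L)] + W)
  }
  if (local) D <- pmax(D, 0)
  wi <- W * (0:m)
  cummax(c(0, D) - wi) + wi
}

#' Score the right-side matrix stack
#'
#' Column 0 of every right-side matrix is initialized with the breakpoint
#' column, so each right matrix fans out from the shared junction; remaining
#' columns follow the classic recurrence (floored at 0 in local mode).
#'
#' @param read a [read_sequence()] or nucleotide string.
#' @param panel a [reference_panel()].
#' @param bkpt breakpoint column from [fill_breakpoint_column()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` or `"semiglobal"`.
#' @return A list with one element per right reference: `H`, `chars`, `n`,
#'   `label`.
#' @export
fill_right_stack <- function(read, panel, bkpt, scheme = scoring_scheme(),
                             mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  read <- as_read_sequence(read)
  rc <- seq_chars(read$bases)
  local <- mode == "local"
  lapply(panel$right, function(entry) {
    bases <- seq_chars(entry$seq)
    list(H = sw_fill(rc, bases, scheme, col0 = bkpt, local = local),
         chars = bases, n = length(bases), label = entry$label)
  })
}

# Build the full fanned matrix set for one read orientation.
fan_fill <- function(read_chars_string, panel, scheme, mode) {
  left <- fill_left_stack(read_chars_string, panel, scheme, mode)
  bkpt <- fill_breakpoint_column(read_chars_string, left, scheme, mode)
  right <- fill_right_stack(read_chars_string, panel, bkpt, scheme, mode)
  structure(list(left = left, bkpt = bkpt, right = right, mode = mode,
                 read = read_chars_string,
                 read_chars = seq_chars(read_chars_string)),
            class = "fan_matrices")
}

# Maximum used for strand selection. Local mode: global maximum over every
# matrix entry and the breakpoint column. Semi-global mode: maximum over the
# bottom row (the candidates the backtrack may start from), since that is the
# quantity the reported score is based on.
fan_strand_max <- function(fm) {
  if (fm$mode == "local") {
    max(vapply(fm$left, function(e) max(e$H), 0),
        max(fm$bkpt),
        vapply(fm$right, function(e) max(e$H), 0))
  } else {
    m <- length(fm$read_chars)
    bottom <- function(e, drop0 = TRUE) {
      row <- e$H[m + 1L, ]
      if (drop0 && length(row) > 1L) row <- row[-1L]
      if (drop0 && length(row) == 1L && ncol(e$H) == 1L) return(-Inf)
      max(row)
    }
    max(vapply(fm$left, bottom, 0), fm$bkpt[[m + 1L]],
        vapply(fm$right, bottom, 0))
  }
}

#' Choose the best read strand
#'
#' Scores the full fanned matrix set for the read as given and for its
#' reverse complement, and keeps the orientation with the larger maximum
#' (global maximum in local mode; bottom-row maximum in semi-global mode,
#' where the reported score is the bottom-row start element). Ties go to the
#' forward strand.
#'
#' @param read a [read_sequence()] or nucleotide string.
#' @param panel a [reference_panel()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` or `"semiglobal"`.
#' @return A list: `read` (oriented base string actually used), `strand`
#'   (`"+"` or `"-"`), `matrices` (the winning `fan_matrices`), and
#'   `max` (the winning maximum).
#' @export
choose_strand <- function(read, panel, scheme = scoring_scheme(),
                          mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  read <- as_read_sequence(read)
  fwd <- fan_fill(read$bases, panel, scheme, mode)
  rev <- fan_fill(reverse_complement(read$bases), panel, scheme, mode)
  vf <- fan_strand_max(fwd)
  vr <- fan_strand_max(rev)
  if (vr > vf) {
    list(read = rev$read, strand = "-", matrices = rev, max = vr)
  } else {
    list(read = fwd$read, strand = "+", matrices = fwd, max = vf)
  }
}

# Locate the cell where backtracking commences.
#
# Local mode: the global maximum over right matrices (columns >= 1), the
# breakpoint column (rows >= 1) and left matrices (columns >= 1). Column 0 of
# each right matrix duplicates the breakpoint column and is credited to the
# breakpoint column itself. Semi-global mode: the maximum over the bottom row
# (i = m) of the same candidates.
#
# Tie-break (documented package convention): side preference right >
# breakpoint > left; within a side, lowest matrix index f; within a matrix,
# largest i, then largest j.
fan_start <- function(fm) {
  m <- length(fm$read_chars)
  local <- fm$mode == "local"
  best <- NULL
  consider <- function(v, side, f, i, j) {
    if (is.null(best) || v > best$value)
      best <<- list(value = v, side = side, f = f, i = i, j = j)
  }
  scan_matrix <- function(H, side, f) {
    if (ncol(H) < 2L) return()
    if (local) {
      sub <- H[-1L, -1L, drop = FALSE]
      v <- max(sub)
      hits <- which(sub == v, arr.ind = TRUE)
      i <- max(hits[, 1L])
      j <- max(hits[hits[, 1L] == i, 2L])
      consider(v, side, f, i, j)
    } else {
      row <- H[m + 1L, -1L]
      v <- max(row)
      consider(v, side, f, m, max(which(row == v)))
    }
  }
  # Scan in preference order (right, bkpt, left; f ascending); consider()
  # uses strict '>' so the earliest candidate wins ties.
  for (f in seq_along(fm$right)) scan_matrix(fm$right[[f]]$H, "right", f)
  if (local) {
    if (m >= 1L) {
      v <- max(fm$bkpt[-1L])
      consider(v, "bkpt", NA_integer_, max(which(fm$bkpt[-1L] == v)), 0L)
    }
  } else {
    consider(fm$bkpt[[m + 1L]], "bkpt", NA_integer_, m, 0L)
  }
  for (f in seq_along(fm$left)) scan_matrix(fm$left[[f]]$H, "left", f)
  best
}

#' Backtrack a fanned alignment
#'
#' Traces the alignment path from the start element back through the right
#' matrices, the breakpoint column and the left matrices. In local mode the
#' trace begins at the global maximum and stops at the first element equal to
#' zero; in semi-global mode it begins at the bottom-row maximum and stops
#' only at the top row, so every read base is traced. A trace that reaches
#' column 0 of a right matrix continues at the breakpoint column; a diagonal
#' or gap-in-read move out of the breakpoint column selects (jointly) one
#' left matrix and its withheld last base, after which the trace continues in
#' that matrix. The trace follows neighboring elements in descending order of
#' element score: among moves that explain a cell, the one with the largest
#' predecessor element wins; remaining ties prefer diagonal, then
#' gap-in-read, then gap-in-reference, and candidate left matrices in panel
#' order.
#'
#' A read base consumed at the breakpoint column counts toward the left side
#' of the junction (the column represents the last base of the left
#' references). `spanning` is `TRUE` iff the path consumes at least one read
#' base strictly on each side and commits a reference on each side.
#'
#' @param matrices a `fan_matrices` object (from [choose_strand()] or
#'   `fanalign:::fan_fill`).
#' @param panel the [reference_panel()] the matrices were built from.
#' @param scheme the [scoring_scheme()] used to fill them.
#' @param read_name,strand,mate metadata copied into the result.
#' @return A `"fan_alignment"` object.
#' @export
fan_backtrack <- function(matrices, panel, scheme = scoring_scheme(),
                          read_name = "read", strand = "+",
                          mate = NA_integer_) {
  fm <- matrices
  stopifnot(inherits(fm, "fan_matrices"))
  rc <- fm$read_chars
  m <- length(rc)
  local <- fm$mode == "local"
  W <- scheme$gap_score
  empty <- function(score, alpha) {
    new_fan_alignment(read_name = read_name, read_len = m, mode = fm$mode,
                      strand = strand, score_raw = score, alpha = alpha,
                      mate = mate)
  }
  if (m == 0L) return(empty(0, NA_real_))
  start <- fan_start(fm)
  if (local && start$value <= 0) return(empty(0, 0))

  side <- start$side; f <- start$f; i <- start$i; j <- start$j
  ar <- character(0); af <- character(0); ops <- character(0)
  path_side <- character(0); path_f <- integer(0)
  path_i <- integer(0); path_j <- integer(0)
  consumed_left <- 0L; consumed_right <- 0L
  left_f <- NA_integer_; right_f <- NA_integer_
  left_pos <- integer(0); right_pos <- integer(0)
  min_i <- NA_integer_; max_i <- NA_integer_
  note_read_base <- function(ii) {
    if (is.na(min_i) || ii < min_i) min_i <<- ii
    if (is.na(max_i) || ii > max_i) max_i <<- ii
  }
  emit <- function(a, b, op) {
    ar <<- c(ar, a); af <<- c(af, b); ops <<- c(ops, op)
    path_side <<- c(path_side, side); path_f <<- c(path_f, f)
    path_i <<- c(path_i, i); path_j <<- c(path_j, j)
  }

  repeat {
    if (side == "right") {
      e <- fm$right[[f]]
      v <- e$H[i + 1L, j + 1L]
      if (local && v == 0) break
      if (!local && i == 0L) break
      if (j == 0L) { side <- "bkpt"; f <- NA_integer_; next }
      mv <- pick_move(list(
        list(move = "M", ok = i >= 1L &&
               e$H[i, j] + sigma1(scheme, rc[[i]], e$chars[[j]]) == v,
             pred = if (i >= 1L) e$H[i, j] else -Inf),
        list(move = "D", ok = e$H[i + 1L, j] + W == v,
             pred = e$H[i + 1L, j]),
        list(move = "I", ok = i >= 1L && e$H[i, j + 1L] + W == v,
             pred = if (i >= 1L) e$H[i, j + 1L] else -Inf)), v)
      if (is.null(mv)) stop("internal error: inconsistent right-stack matrices")
      if (mv$move == "M") {
        emit(rc[[i]], e$chars[[j]], "M")
        consumed_right <- consumed_right + 1L; right_f <- f
        right_pos <- c(right_pos, j); note_read_base(i)
        i <- i - 1L; j <- j - 1L
      } else if (mv$move == "D") {
        emit("-", e$chars[[j]], "D")
        right_f <- f; right_pos <- c(right_pos, j)
        j <- j - 1L
      } else {
        emit(rc[[i]], "-", "I")
        consumed_right <- consumed_right + 1L; note_read_base(i)
        i <- i - 1L
      }
    } else if (side == "bkpt") {
      v <- fm$bkpt[[i + 1L]]
      if (local && v == 0) break
      if (!local && i == 0L) break
      # Candidate moves: a diagonal or gap-in-read move into any left matrix
      # (pairing that matrix with its own withheld last base), or a
      # gap-in-reference move down the breakpoint column itself.
      cand <- list()
      for (f2 in seq_along(fm$left)) {
        e2 <- fm$left[[f2]]
        pen_prev <- if (i >= 1L) e2$H[i, ncol(e2$H)] else -Inf
        cand[[length(cand) + 1L]] <- list(
          move = "M", f2 = f2,
          ok = i >= 1L &&
            pen_prev + sigma1(scheme, rc[[i]], e2$last_base) == v,
          pred = pen_prev)
      }
      for (f2 in seq_along(fm$left)) {
        e2 <- fm$left[[f2]]
        cand[[length(cand) + 1L]] <- list(
          move = "D", f2 = f2,
          ok = e2$H[i + 1L, ncol(e2$H)] + W == v,
          pred = e2$H[i + 1L, ncol(e2$H)])
      }
      cand[[length(cand) + 1L]] <- list(
        move = "I", f2 = NA_integer_,
        ok = i >= 1L && fm$bkpt[[i]] + W == v,
        pred = if (i >= 1L) fm$bkpt[[i]] else -Inf)
      mv <- pick_move(cand, v)
      if (is.null(mv)) stop("internal error: inconsistent breakpoint column")
      if (mv$move == "M") {
        e2 <- fm$left[[mv$f2]]
        emit(rc[[i]], e2$last_base, "M")
        consumed_left <- consumed_left + 1L; left_f <- mv$f2
        left_pos <- c(left_pos, e2$n); note_read_base(i)
        side <- "left"; f <- mv$f2; i <- i - 1L; j <- e2$n - 1L
      } else if (mv$move == "D") {
        e2 <- fm$left[[mv$f2]]
        emit("-", e2$last_base, "D")
        left_f <- mv$f2; left_pos <- c(left_pos, e2$n)
        side <- "left"; f <- mv$f2; j <- e2$n - 1L
      } else {
        emit(rc[[i]], "-", "I")
        consumed_left <- consumed_left + 1L; note_read_base(i)
        i <- i - 1L
      }
    } else {  # left matrix
      e <- fm$left[[f]]
      v <- e$H[i + 1L, j + 1L]
      if (local && v == 0) break
      if (!local && i == 0L) break
      mv <- pick_move(list(
        list(move = "M", ok = i >= 1L && j >= 1L &&
               e$H[i, j] + sigma1(scheme, rc[[i]], e$chars[[j]]) == v,
             pred = if (i >= 1L && j >= 1L) e$H[i, j] else -Inf),
        list(move = "D", ok = j >= 1L && e$H[i + 1L, j] + W == v,
             pred = if (j >= 1L) e$H[i + 1L, j] else -Inf),
        list(move = "I", ok = i >= 1L && e$H[i, j + 1L] + W == v,
             pred = if (i >= 1L) e$H[i, j + 1L] else -Inf)), v)
      if (is.null(mv)) stop("internal error: inconsistent left-stack matrices")
      if (mv$move == "M") {
        emit(rc[[i]], e$chars[[j]], "M")
        consumed_left <- consumed_left + 1L; left_f <- f
        left_pos <- c(left_pos, j); note_read_base(i)
        i <- i - 1L; j <- j - 1L
      } else if (mv$move == "D") {
        emit("-", e$chars[[j]], "D")
        left_f <- f; left_pos <- c(left_pos, j)
        j <- j - 1L
      } else {
        emit(rc[[i]], "-", "I")
        consumed_left <- consumed_left + 1L; note_read_base(i)
        i <- i - 1L
      }
    }
  }

  spanning <- consumed_left >= 1L && consumed_right >= 1L &&
    !is.na(left_f) && !is.na(right_f)
  n_left <- if (!is.na(left_f)) fm$left[[left_f]]$n else NA_integer_
  left_range <- if (length(left_pos)) range(left_pos) else c(NA_integer_, NA_integer_)
  right_range <- if (length(right_pos)) range(right_pos) else c(NA_integer_, NA_integer_)
  rev_idx <- rev(seq_along(ar))
  new_fan_alignment(
    read_name = read_name, read_len = m, mode = fm$mode, strand = strand,
    score_raw = start$value, alpha = alignment_score(start$value, m),
    aligned_read = paste(ar[rev_idx], collapse = ""),
    aligned_ref = paste(af[rev_idx], collapse = ""),
    cigar = ops_to_cigar(ops[rev_idx]),
    spanning = spanning,
    left_ref_index = left_f, right_ref_index = right_f,
    left_ref = if (!is.na(left_f)) fm$left[[left_f]]$label else NA_character_,
    right_ref = if (!is.na(right_f)) fm$right[[right_f]]$label else NA_character_,
    read_start = min_i, read_end = max_i,
    left_ref_range = left_range, right_ref_range = right_range,
    # Offsets relative to the junction: the last base of a left reference sits
    # at offset -1, the first base of a right reference at offset 0.
    left_offsets = if (is.na(left_range[[1L]])) c(NA_integer_, NA_integer_)
                   else left_range - n_left - 1L,
    right_offsets = if (is.na(right_range[[1L]])) c(NA_integer_, NA_integer_)
                    else right_range - 1L,
    mate = mate,
    path = data.frame(side = path_side[rev_idx], f = path_f[rev_idx],
                      i = path_i[rev_idx], j = path_j[rev_idx],
                      op = ops[rev_idx])
  )
}

#' Align one read against a reference panel across a breakpoint
#'
#' The authoritative single-read entry point: chooses the best strand
#' ([choose_strand()]), fills the fanned matrix stacks, backtracks
#' ([fan_backtrack()]) and attaches the normalized alignment score
#' ([alignment_score()]). Deterministic given identical inputs.
#'
#' @param read a [read_sequence()] or nucleotide string.
#' @param panel a [reference_panel()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"local"` (default) or `"semiglobal"`. Semi-global mode forces
#'   every read base into the reported alignment (free reference ends,
#'   penalized read ends) and its alpha may be negative.
#' @return A `"fan_alignment"` object.
#' @examples
#' panel <- reference_panel(left = c(gA = "ACGTACGTACGT"),
#'                          right = c(gB = "TTGCAGGCATCA"))
#' res <- align_read("ACGTTTGCAG", panel)  # crosses the junction
#' res$spanning
#' res$alpha
#' @export
align_read <- function(read, panel, scheme = scoring_scheme(),
                       mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "reference_panel"))
  read <- as_read_sequence(read)
  if (nchar(read$bases) == 0L) {
    return(new_fan_alignment(read_name = read$name, read_len = 0L,
                             mode = mode, strand = "+",
                             score_raw = 0, alpha = NA_real_,
                             mate = read$mate))
  }
  ch <- choose_strand(read, panel, scheme, mode)
  fan_backtrack(ch$matrices, panel, scheme,
                read_name = read$name, strand = ch$strand, mate = read$mate)
}

#' Align a set of reads against a reference panel
#'
#' @param reads a list of [read_sequence()] objects or a named character
#'   vector of base strings.
#' @inheritParams align_read
#' @return A list of `"fan_alignment"` objects (class
#'   `"fan_alignment_list"`).
#' @export
align_reads <- function(reads, panel, scheme = scoring_scheme(),
                        mode = c("local", "semiglobal")) {
  mode <- match.arg(mode)
  if (is.character(reads)) {
    nm <- names(reads) %||% paste0("read", seq_along(reads))
    reads <- lapply(seq_along(reads), function(i)
      read_sequence(reads[[i]], name = nm[[i]]))
  }
  out <- lapply(reads, align_read, panel = panel, scheme = scheme, mode = mode)
  class(out) <- "fan_alignment_list"
  out
}

#' Tabulate alignment results
#'
#' One row per aligned read with the fields used by the filtering and
#' reporting layer.
#'
#' @param results a list of `"fan_alignment"` objects.
#' @return A `data.frame`.
#' @export
results_table <- function(results) {
  grab_chr <- function(field) vapply(results, function(r) as.character(r[[field]]), "")
  grab_num <- function(field) vapply(results, function(r) as.numeric(r[[field]]), 0)
  data.frame(
    read = grab_chr("read_name"),
    mate = vapply(results, function(r) as.integer(r$mate), 0L),
    strand = grab_chr("strand"),
    alpha = grab_num("alpha"),
    score_raw = grab_num("score_raw"),
    left_ref = grab_chr("left_ref"),
    right_ref = grab_chr("right_ref"),
    spanning = vapply(results, function(r) isTRUE(r$spanning), FALSE),
    cigar = grab_chr("cigar"),
    read_len = vapply(results, function(r) as.integer(r$read_len), 0L),
    stringsAsFactors = FALSE
  )
}
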