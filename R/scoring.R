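#' Scoring scheme for read-versus-reference alignment
#'
#' Defines the similarity function \eqn{\sigma} and the linear gap penalty
#' \eqn{W} used by both classic Smith-Waterman and the fanned multi-reference
#' variant. \eqn{\sigma(a, b)} equals `match_score` when `a == b` and both are
#' unambiguous nucleotides, and `mismatch_score` otherwise; in particular `"N"`
#' (or any non-ACGT symbol) scores as a mismatch against everything, including
#' another `"N"`. Every gap base costs `gap_score`.
#'
#' @param match_score integer > 0, score for a matching base pair (default +1).
#' @param mismatch_score integer < 0, score for a mismatching pair (default -1).
#' @param gap_score integer < 0, linear per-base gap penalty W (default -1).
#'
#' @return An object of class `"scoring_scheme"`.
#' @examples
#' sc <- scoring_scheme()
#' sc$match_score
#' @export
scoring_scheme <- function(match_score = 1L, mismatch_score = -1L,
                           gap_score = -1L) {
  match_score <- as.integer(match_score)
  mismatch_score <- as.integer(mismatch_score)
  gap_score <- as.integer(gap_score)
  if (is.na(match_score) || match_score <= 0L)
    stop("match_score must be a positive integer")
  if (is.na(mismatch_score) || mismatch_score >= 0L)
    stop("mismatch_score must be a negative integer")
  if (is.na(gap_score) || gap_score >= 0L)
    stop("gap_score must be a negative integer")
  structure(
    list(match_score = match_score, mismatch_score = mismatch_score,
         gap_score = gap_score),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: match %+d, mismatch %+d, gap %+d\n",
              x$match_score, x$mismatch_score, x$gap_score))
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_ALPHABET <- c(DNA_BASES, "N")

#' Normalize a nucleotide string
#'
#' Uppercases and validates a sequence over the alphabet `{A, C, G, T, N}`.
#'
#' @param seq a single character string.
#' @param what label used in error messages.
#' @return Uppercased string.
#' @keywords internal
normalize_bases <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), DNA_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' in %s", bad[[1L]], what))
  seq
}

# Split a (validated) sequence into a character vector of bases.
seq_chars <- function(seq) {
  if (nchar(seq) == 0L) character(0) else strsplit(seq, "", fixed = TRUE)[[1L]]
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick complement with `N -> N`, applied to an uppercased
#' copy of the input. The operation is an involution:
#' `reverse_complement(reverse_complement(x)) == toupper(x)`.
#'
#' @param seq a single nucleotide string over `{A, C, G, T, N}`
#'   (case-insensitive).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AACGN") # "NCGTT"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_bases(seq)
  if (nchar(seq) == 0L) return(seq)
  paste(rev(seq_chars(chartr("ACGTN", "TGCAN", seq))), collapse = "")
}

# Per-column similarity sigma(a_i, b_j) of one read base against a vector of
# reference bases. Ambiguous symbols always mismatch (even N vs N).
sigma_vec <- function(scheme, read_base, ref_bases) {
  ifelse(ref_bases == read_base & read_base %in% DNA_BASES,
         scheme$match_score, scheme$mismatch_score)
}

#' A named read sequence
#'
#' Light container pairing a read name with its uppercased base string and an
#' optional mate index for paired-end data.
#'
#' @param bases nucleotide string over `{A, C, G, T, N}` (case-insensitive).
#' @param name read name.
#' @param mate mate index: `1L`, `2L`, or `NA` for single-end reads.
#' @return An object of class `"read_sequence"`.
#' @export
read_sequence <- function(bases, name = "read", mate = NA_integer_) {
  bases <- normalize_bases(bases, what = sprintf("read '%s'", name))
  structure(list(name = as.character(name), bases = bases,
                 mate = as.integer(mate)),
            class = "read_sequence")
}

# Accept either a read_sequence or a plain string everywhere the aligner
# takes a read.
as_read_sequence <- function(read, name = "read") {
  if (inherits(read, "read_sequence")) return(read)
  read_sequence(read, name = name)
}
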