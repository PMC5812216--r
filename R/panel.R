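#' Reference panel for fanned alignment
#'
#' An ordered collection of 5' (left-of-junction) and 3' (right-of-junction)
#' reference sequences. Each entry carries a unique label, an origin tag
#' (`"genomic"`, `"exonic"`, or `"custom"`) and its uppercased sequence. The
#' fanned aligner builds one score matrix per reference on each side, all
#' converging into a shared breakpoint column.
#'
#' @param left,right lists of reference entries; each entry is a list with
#'   elements `label`, `seq`, and optionally `origin` (default `"custom"`).
#'   A named character vector is also accepted (names become labels).
#' @return An object of class `"reference_panel"` with elements `left` and
#'   `right`, each a list of validated entries.
#' @examples
#' panel <- reference_panel(
#'   left = c(geneA = "ACGTACGTAC"),
#'   right = c(geneB = "TTGCATGCAA")
#' )
#' panel
#' @export
reference_panel <- function(left, right) {
  left <- normalize_panel_side(left, "left")
  right <- normalize_panel_side(right, "right")
  if (length(left) < 1L) stop("panel needs at least one left (5') reference")
  if (length(right) < 1L) stop("panel needs at least one right (3') reference")
  labels <- c(vapply(left, `[[`, "", "label"),
              vapply(right, `[[`, "", "label"))
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate reference label '%s' in panel", dup[[1L]]))
  structure(list(left = left, right = right), class = "reference_panel")
}

normalize_panel_side <- function(side, side_name) {
  if (is.character(side)) {
    if (is.null(names(side)) || any(names(side) == ""))
      stop(sprintf("%s references given as a character vector must be named",
                   side_name))
    side <- lapply(seq_along(side), function(i)
      list(label = names(side)[[i]], seq = side[[i]]))
  }
  lapply(side, function(entry) {
    if (is.null(entry$label) || !nzchar(entry$label))
      stop(sprintf("every %s reference needs a non-empty label", side_name))
    origin <- entry$origin %||% "custom"
    if (!origin %in% c("genomic", "exonic", "custom"))
      stop(sprintf("unknown reference origin '%s'", origin))
    seq <- normalize_bases(entry$seq,
                           what = sprintf("reference '%s'", entry$label))
    if (nchar(seq) < 1L)
      stop(sprintf("reference '%s' has an empty sequence", entry$label))
    list(label = as.character(entry$label), origin = origin, seq = seq,
         partner = entry$partner %||% NA_character_,
         span = entry$span %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference panel: %d left (5') / %d right (3') references\n",
              length(x$left), length(x$right)))
  for (side in c("left", "right")) {
    for (entry in x[[side]]) {
      cat(sprintf("  %-5s %-9s %5d nt  %s\n", side, entry$origin,
                  nchar(entry$seq), entry$label))
    }
  }
  invisible(x)
}

panel_labels <- function(panel) {
  c(vapply(panel$left, `[[`, "", "label"),
    vapply(panel$right, `[[`, "", "label"))
}

#' Load a custom reference panel from two FASTA files
#'
#' Record IDs become reference labels. An optional `|genomic` or `|exonic`
#' suffix on a record ID sets the origin tag (the suffix is kept as part of
#' the label so that labels stay unique); records without a recognized suffix
#' are tagged `"custom"`. Sequences are uppercased and validated.
#'
#' @param left_fasta,right_fasta paths to FASTA files with the 5' and 3'
#'   references respectively.
#' @return A [reference_panel()].
#' @export
load_custom_panel <- function(left_fasta, right_fasta) {
  reference_panel(read_panel_fasta(left_fasta),
                  read_panel_fasta(right_fasta))
}

read_panel_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 1L)
    stop(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate record ID '%s' in %s", dup[[1L]], path))
  lapply(seq_along(seqs), function(i) {
    origin <- if (grepl("\\|genomic$", ids[[i]])) "genomic"
              else if (grepl("\\|exonic$", ids[[i]])) "exonic"
              else "custom"
    list(label = ids[[i]], origin = origin,
         seq = as.character(seqs[[i]]))
  })
}

#' Write a reference panel as FASTA, one file per side
#'
#' @param panel a [reference_panel()].
#' @param left_path,right_path output FASTA paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_panel_fasta <- function(panel, left_path, right_path) {
  stopifnot(inherits(panel, "reference_panel"))
  write_side <- function(entries, path) {
    seqs <- Biostrings::DNAStringSet(vapply(entries, `[[`, "", "seq"))
    names(seqs) <- vapply(entries, `[[`, "", "label")
    Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  }
  write_side(panel$left, left_path)
  write_side(panel$right, right_path)
  invisible(c(left_path, right_path))
}

#' Parse a breakpoint string
#'
#' Accepts the format `"chrom:pos:strand>chrom:pos:strand"` (also with `"->"`
#' as separator); commas in positions are ignored. The first triple is the 5'
#' partner, the second the 3' partner.
#'
#' @param x breakpoint string, e.g. `"chr1:10,000:+>chr2:20,000:-"`.
#' @param radius positive search radius in bp.
#' @return A [breakpoint_spec()].
#' @export
parse_breakpoint <- function(x, radius = 200L) {
  stopifnot(is.character(x), length(x) == 1L)
  halves <- strsplit(gsub("->", ">", x, fixed = TRUE), ">", fixed = TRUE)[[1L]]
  if (length(halves) != 2L)
    stop(sprintf("malformed breakpoint string '%s' (expected 'chrom:pos:strand>chrom:pos:strand')", x))
  parse_half <- function(h) {
    parts <- strsplit(trimws(h), ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L || !parts[[3L]] %in% c("+", "-"))
      stop(sprintf("malformed breakpoint coordinate '%s'", h))
    pos <- suppressWarnings(as.integer(gsub(",", "", parts[[2L]], fixed = TRUE)))
    if (is.na(pos)) stop(sprintf("malformed breakpoint position in '%s'", h))
    list(chrom = parts[[1L]], pos = pos, strand = parts[[3L]])
  }
  p5 <- parse_half(halves[[1L]])
  p3 <- parse_half(halves[[2L]])
  breakpoint_spec(p5$chrom, p5$pos, p5$strand,
                  p3$chrom, p3$pos, p3$strand, radius = radius)
}

#' Breakpoint specification
#'
#' The two genomic coordinates plus strands defining a candidate fusion
#' junction, together with the search radius used for reference retrieval and
#' read extraction. Coordinates are 1-based.
#'
#' @param chrom5,pos5,strand5 5' partner chromosome, position, strand.
#' @param chrom3,pos3,strand3 3' partner chromosome, position, strand.
#' @param radius positive search radius in bp (default 200).
#' @return An object of class `"breakpoint_spec"`.
#' @export
breakpoint_spec <- function(chrom5, pos5, strand5,
                            chrom3, pos3, strand3, radius = 200L) {
  pos5 <- as.integer(pos5); pos3 <- as.integer(pos3)
  radius <- as.integer(radius)
  stopifnot(is.character(chrom5), is.character(chrom3))
  if (is.na(pos5) || pos5 < 1L || is.na(pos3) || pos3 < 1L)
    stop("breakpoint positions must be >= 1")
  if (!strand5 %in% c("+", "-") || !strand3 %in% c("+", "-"))
    stop("strands must be '+' or '-'")
  if (is.na(radius) || radius < 1L) stop("radius must be >= 1")
  structure(
    list(partner5 = list(chrom = chrom5, pos = pos5, strand = strand5),
         partner3 = list(chrom = chrom3, pos = pos3, strand = strand3),
         radius = radius),
    class = "breakpoint_spec"
  )
}

#' @export
print.breakpoint_spec <- function(x, ...) {
  cat(sprintf("breakpoint %s:%d:%s > %s:%d:%s (radius %d bp)\n",
              x$partner5$chrom, x$partner5$pos, x$partner5$strand,
              x$partner3$chrom, x$partner3$pos, x$partner3$strand, x$radius))
  invisible(x)
}

#' @export
format.breakpoint_spec <- function(x, ...) {
  sprintf("%s:%d:%s>%s:%d:%s",
          x$partner5$chrom, x$partner5$pos, x$partner5$strand,
          x$partner3$chrom, x$partner3$pos, x$partner3$strand)
}
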