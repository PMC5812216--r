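# Reading reads and writing result artifacts.

#' Read a FASTQ file into a list of read sequences
#'
#' Gzip-transparent. Quality strings are ignored by the aligner and are not
#' retained. A trailing `/1` or `/2` on the read name, or a `mate` argument,
#' sets the mate index.
#'
#' @param path FASTQ file.
#' @param mate optional mate index (1 or 2) to assign to every read; by
#'   default inferred from a `/1` / `/2` name suffix when present.
#' @return A list of [read_sequence()] objects.
#' @export
read_fastq_reads <- function(path, mate = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i) {
    nm <- ids[[i]]
    mt <- mate
    if (is.na(mt) && grepl("/[12]$", nm)) {
      mt <- as.integer(sub("^.*/", "", nm))
      nm <- sub("/[12]$", "", nm)
    }
    read_sequence(as.character(seqs[[i]]), name = nm, mate = mt)
  })
}

# Write plain FASTQ records. `records` is a data.frame with columns
# name, seq, qual.
write_fastq <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", records$name),
                           records$seq,
                           "+",
                           records$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write alignment results as TSV and JSON
#'
#' The TSV holds one row per read (name, strand, alpha, references, spanning
#' flag, CIGAR-like operation string); the JSON additionally carries the full
#' alignment strings and junction-relative offsets.
#'
#' @param results a list of `"fan_alignment"` objects.
#' @param tsv_path,json_path output paths (`NULL` to skip one of them).
#' @return Invisibly, the [results_table()] data.frame.
#' @export
write_results <- function(results, tsv_path = NULL, json_path = NULL) {
  tab <- results_table(results)
  if (!is.null(tsv_path)) {
    out <- tab
    out$alpha <- sprintf("%.2f", out$alpha)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- lapply(results, function(r) {
      r$path <- NULL  # cursor trace is an internal detail
      unclass(r)
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(tab)
}
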