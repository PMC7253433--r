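#' Write transcript sequences as FASTA
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!is(sequences, "XStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read or write the transcript region table
#'
#' Tab-separated with columns `transcript_id`, `utr5_end`, `cds_end`,
#' `length` (0-based half-open region boundaries).
#'
#' @param path TSV path.
#' @return `read_transcript_table`: the validated data.frame.
#' @export
read_transcript_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "utr5_end", "cds_end", "length")
  if (!all(need %in% names(d))) {
    stop("transcript table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname read_transcript_table
#' @param regions Transcript table data.frame.
#' @export
write_transcript_table <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write an LFQ protein-group table
#'
#' Tab-separated MaxQuant-style flat table: `protein_id`,
#' `contaminant_flag`, `reverse_flag`, then raw intensity columns
#' `WT_1..WT_n`, `7dG_1..7dG_n` (0 or empty = missing). Column names are
#' taken verbatim (`7dG_1` is not syntactic R, so names are not checked).
#'
#' @param path TSV path.
#' @return `read_lfq_table`: the data.frame.
#' @export
read_lfq_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_lfq_table
#' @param tab LFQ data.frame.
#' @export
write_lfq_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
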