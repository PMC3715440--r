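# Readers and writers for the plain-text formats the package exchanges:
# FASTA genomes and site sets, BED6 scan hits and truth tables, TSV
# insertion catalogs and Cq tables.

#' Read a (multi-contig) FASTA file
#'
#' Order-preserving, uppercase-normalizing, tolerant of CRLF endings and
#' arbitrary line wrapping.
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet` named by header (first token).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) {
    stop("no FASTA records in ", path)
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param x `Biostrings::DNAStringSet` or named character vector.
#' @param path Output file.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write scan hits as BED6
#'
#' Columns: contig, start, end (0-based half-open), name = mismatch
#' count, score = 17 - mismatches, strand.
#'
#' @param hits Data.frame from [scan_genome()] or a truth table from
#'   [make_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$end,
                    hits$mismatches, CORE_WIDTH - hits$mismatches,
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of scan hits
#'
#' @param path BED6 file as written by [write_bed()].
#' @return Data.frame with columns contig, start, end, strand, mismatches.
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) {
    stop("expected >= 6 BED columns in ", path)
  }
  data.frame(contig = as.character(bed[[1L]]),
             start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]),
             strand = as.character(bed[[6L]]),
             mismatches = as.integer(bed[[4L]]),
             stringsAsFactors = FALSE)
}

#' Read an insertion catalog TSV
#'
#' Expected header: `locus`, `orientation`, optional `core_sequence`,
#' `occurrences`.
#'
#' @param path TSV file.
#' @return Data.frame of insertion records.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "orientation") %in% names(df))) {
    stop("catalog must have 'locus' and 'orientation' columns: ", path)
  }
  if (is.null(df$occurrences)) {
    df$occurrences <- 1L
  }
  df
}

#' Write an insertion catalog TSV
#'
#' @param records Data.frame of insertion records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Cq table TSV
#'
#' Expected header: `sample_id`, `target`, `replicate`, `cq`.
#'
#' @param path TSV file.
#' @return Data.frame of Cq measurements.
#' @export
read_cq_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "cq")
  if (!all(need %in% names(df))) {
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a Cq table TSV
#'
#' @param cq Data.frame of Cq measurements.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path) {
  utils::write.table(cq, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dilution-series TSV
#'
#' Expected header: `target`, `log10_copies`, `cq`.
#'
#' @param path TSV file.
#' @return Data.frame of dilution points.
#' @export
read_dilution_series <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("log10_copies", "cq")
  if (!all(need %in% names(df))) {
    stop("dilution series must have columns: ",
         paste(need, collapse = ", "))
  }
  df
}
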