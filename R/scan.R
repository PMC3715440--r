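# Mismatch-tolerant scanning of a genome for candidate attachment-site
# cores.  Known secondary sites were found experimentally; scanning is
# the in-silico counterpart: report every 17-mer on either strand within
# a Hamming-distance threshold of a reference core.

#' Scan a genome for candidate attachment sites
#'
#' Slides the 17 bp reference core over both strands of each contig and
#' reports every window whose Hamming distance to the reference is at most
#' `max_mismatch`.  Windows containing non-ACGT characters (e.g. N runs in
#' draft genomes) are skipped, not errors.  Coordinates are 0-based
#' half-open on the reference (forward) strand; strand `"-"` means the
#' core is read on the reverse strand, and `core` is reported in that
#' reading (the reverse complement of the forward-strand window).
#'
#' The scan is a vectorized shift-and-compare over byte codes, so the full
#' threshold range 0..17 is supported at the same cost (at 17 every
#' ACGT-clean window is a hit by construction).
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   contig sequences, or a single string.
#' @param reference The reference core (`att_core` or 17-base string).
#' @param max_mismatch Maximum Hamming distance, 0..17.
#' @return A data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `core`, `mismatches`, sorted by contig, start,
#'   strand.
#' @examples
#' g <- c(chr = paste0(strrep("A", 30), "GGGGGCCCCCCCTTTTT", strrep("A", 30)))
#' scan_genome(g, "GGGGGCCCCCCCTTTTT", max_mismatch = 0)
#' @export
scan_genome <- function(genome, reference, max_mismatch) {
  ref <- att_core(reference)
  if (!is.numeric(max_mismatch) || length(max_mismatch) != 1L ||
      is.na(max_mismatch) || max_mismatch < 0 || max_mismatch > CORE_WIDTH) {
    stop("max_mismatch must be a single value in 0..", CORE_WIDTH)
  }
  seqs <- genome_as_character(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("empty genome")
  }
  hits <- lapply(seq_along(seqs), function(i) {
    scan_one_contig(names(seqs)[i], seqs[[i]], ref, max_mismatch)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      core = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Coerce supported genome representations to a named character vector.
genome_as_character <- function(genome) {
  if (methods::is(genome, "XStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("genome must be a DNAStringSet or character vector")
  }
  if (length(seqs) == 0L) {
    stop("empty genome")
  }
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- if (length(seqs) == 1L) "seq1" else
      paste0("seq", seq_along(seqs))
  }
  # FASTA headers: keep the first whitespace-delimited token as the contig id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

scan_one_contig <- function(contig, seq, ref, max_mismatch) {
  len <- nchar(seq)
  if (len < CORE_WIDTH) {
    return(NULL)
  }
  gi <- as.integer(charToRaw(seq))
  acgt <- as.integer(charToRaw("ACGT"))
  n_win <- len - CORE_WIDTH + 1L

  rf <- as.integer(charToRaw(ref$sequence))
  rr <- as.integer(charToRaw(revcomp(ref$sequence)))
  mm_f <- integer(n_win)
  mm_r <- integer(n_win)
  for (j in seq_len(CORE_WIDTH)) {
    seg <- gi[j:(j + n_win - 1L)]
    mm_f <- mm_f + (seg != rf[j])
    mm_r <- mm_r + (seg != rr[j])
  }

  # windows touching any non-ACGT byte are skipped
  bad_cum <- cumsum(c(0L, !(gi %in% acgt)))
  win_ok <- (bad_cum[seq_len(n_win) + CORE_WIDTH] -
               bad_cum[seq_len(n_win)]) == 0L

  rows <- list()
  i_f <- which(win_ok & mm_f <= max_mismatch)
  if (length(i_f)) {
    rows[[1L]] <- data.frame(
      contig = contig, start = i_f - 1L, end = i_f + CORE_WIDTH - 1L,
      strand = "+",
      core = substring(seq, i_f, i_f + CORE_WIDTH - 1L),
      mismatches = mm_f[i_f], stringsAsFactors = FALSE)
  }
  i_r <- which(win_ok & mm_r <= max_mismatch)
  if (length(i_r)) {
    rows[[2L]] <- data.frame(
      contig = contig, start = i_r - 1L, end = i_r + CORE_WIDTH - 1L,
      strand = "-",
      core = revcomp(substring(seq, i_r, i_r + CORE_WIDTH - 1L)),
      mismatches = mm_r[i_r], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
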