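# Independent oracles and small generators used across the suite.
# These stay deliberately naive (character-by-character, window-by-window)
# so they check the vectorized implementations from outside.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_core <- function() random_seq(17)

# position-by-position Hamming oracle
naive_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force sliding-window scanner: loops every start on both strands,
# skips windows with non-ACGT characters
naive_scan <- function(seq, contig, ref, max_mismatch) {
  len <- nchar(seq)
  rows <- list()
  ref_rc <- naive_revcomp(ref)
  for (i in seq_len(max(len - 16L, 0L))) {
    win <- substr(seq, i, i + 16L)
    if (grepl("[^ACGT]", win)) next
    mf <- naive_hamming(win, ref)
    if (mf <= max_mismatch) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = i - 1L, end = i + 16L, strand = "+",
        core = win, mismatches = mf, stringsAsFactors = FALSE)
    }
    mr <- naive_hamming(win, ref_rc)
    if (mr <= max_mismatch) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = i - 1L, end = i + 16L, strand = "-",
        core = naive_revcomp(win), mismatches = mr,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), core = character(),
               mismatches = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# per-column Shannon entropy oracle from raw character columns
naive_column_entropy <- function(chars) {
  f <- table(factor(chars, levels = BASES)) / length(chars)
  f <- f[f > 0]
  -sum(f * log2(f))
}

# a reference core used throughout the synthetic tests; arms form a
# perfect inverted repeat like the primary site (synthetic, not the real
# attB sequence, which is an experimental input)
SYN_REF <- "ACCGTTTTCAATACGGT"
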