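# Sequence-logo statistics over aligned site contexts.  Secondary
# attachment sites are compared by aligning a fixed-width window (26 bases
# by convention: the 17 bp core plus flanking bases) and summarizing
# per-position base frequencies and information content in bits.

#' Build a position frequency / information-content matrix
#'
#' For an ungapped alignment of equal-length A/C/G/T sequences, computes
#' per-position base counts and frequencies, Shannon entropy
#' \eqn{H_i = -\sum_b f_{ib} \log_2 f_{ib}} (with 0 log 0 = 0), and
#' information content \eqn{R_i = 2 - H_i} bits.  With
#' `correction = TRUE` the small-sample correction
#' \eqn{e(n) = 3 / (2 \ln(2) n)} is subtracted (floored at 0), the
#' convention used by standard logo tools; the default is the uncorrected
#' value so that figures are reproducible either way.  Letter heights in a
#' rendered logo are \eqn{f_{ib} R_i}.
#'
#' @param contexts Character vector or `Biostrings::DNAStringSet` of
#'   aligned sequences, all of length `width`, A/C/G/T only (gaps are
#'   rejected: the window is ungapped by construction).
#' @param correction Apply the small-sample information correction?
#'   Default FALSE.
#' @param width Required alignment width (default 26, the conventional
#'   site-context window).
#' @return An object of class `logo_matrix`: list with `counts` and
#'   `frequencies` (4 x width matrices, rows A/C/G/T), `entropy` and
#'   `information` (length-width vectors, bits), `heights` (4 x width),
#'   `n_sequences`, `width`, `correction_applied`.
#' @examples
#' logo <- build_logo(rep("ACGTACGTACGTACGTACGTACGTAC", 5))
#' all(logo$information == 2)  # identical sequences: 2 bits everywhere
#' @export
build_logo <- function(contexts, correction = FALSE, width = 26L) {
  if (methods::is(contexts, "XStringSet")) {
    contexts <- as.character(contexts)
  }
  if (length(contexts) < 1L) {
    stop("build_logo() needs at least one sequence")
  }
  contexts <- toupper(contexts)
  if (any(nchar(contexts) != width)) {
    stop("all sequences must have length ", width,
         " (found widths: ",
         paste(unique(nchar(contexts)), collapse = ", "), ")")
  }
  if (any(grepl("[^ACGT]", contexts))) {
    stop("sequences must contain only A/C/G/T (gaps and ambiguity codes ",
         "are rejected)")
  }
  n <- length(contexts)
  counts <- Biostrings::consensusMatrix(
    Biostrings::DNAStringSet(contexts))[c("A", "C", "G", "T"), ,
                                        drop = FALSE]
  storage.mode(counts) <- "integer"
  freq <- counts / n
  entropy <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  e_n <- if (correction) 3 / (2 * log(2) * n) else 0
  information <- pmax(2 - entropy - e_n, 0)
  structure(
    list(counts = counts,
         frequencies = freq,
         entropy = unname(entropy),
         information = unname(information),
         heights = sweep(freq, 2L, information, `*`),
         n_sequences = n,
         width = as.integer(width),
         correction_applied = correction),
    class = "logo_matrix"
  )
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("logo_matrix:", x$n_sequences, "sequences x", x$width, "positions",
      if (x$correction_applied) "(small-sample corrected)" else
        "(uncorrected)", "\n")
  cat("information (bits):",
      paste(sprintf("%.2f", x$information), collapse = " "), "\n")
  invisible(x)
}

#' Plot per-position information content
#'
#' Stacked-bar rendering of letter heights (frequency times information),
#' the quantitative content of a sequence logo.
#'
#' @param x A `logo_matrix`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.logo_matrix <- function(x, ...) {
  graphics::barplot(x$heights, names.arg = seq_len(x$width),
                    legend.text = rownames(x$heights),
                    xlab = "position", ylab = "bits",
                    ylim = c(0, 2), border = NA, ...)
  invisible(x)
}

#' Degenerate consensus string from a logo matrix
#'
#' Per position, the most frequent base; ties are broken alphabetically.
#' The base is uppercase when its frequency reaches `threshold`, lowercase
#' otherwise.
#'
#' @param logo A `logo_matrix`.
#' @param threshold Frequency in (0, 1] above which a base is reported
#'   uppercase.  Default 0.5.
#' @return A single character string of length `logo$width`.
#' @export
consensus_seq <- function(logo, threshold = 0.5) {
  if (!inherits(logo, "logo_matrix")) {
    stop("consensus_seq() expects a logo_matrix")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  bases <- rownames(logo$frequencies)
  chars <- vapply(seq_len(logo$width), function(i) {
    f <- logo$frequencies[, i]
    b <- bases[which.max(f)]  # which.max takes the first, i.e. A<C<G<T
    if (max(f) >= threshold) b else tolower(b)
  }, character(1))
  paste(chars, collapse = "")
}

#' Write a logo matrix as TSV
#'
#' One row per position: position (1-based), A/C/G/T frequencies, entropy
#' and information in bits.
#'
#' @param logo A `logo_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = seq_len(logo$width),
                   t(logo$frequencies),
                   entropy_bits = logo$entropy,
                   information_bits = logo$information)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
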