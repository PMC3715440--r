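# Synthetic-data generators.  Every input class the analysis functions
# consume can be produced with exact, recorded ground truth: genomes with
# planted attachment-site cores at specified mismatch counts, Cq panels
# drawn from known true copy numbers through a log-linear curve, and
# multinomial transconjugant catalogs.  All generators are pure functions
# of (spec, seed).

#' Mutate a core at exactly k positions
#'
#' Positions are drawn uniformly without replacement.  When
#' `spacer_divergent` is FALSE, mutations are confined to the 10 arm
#' positions (so k <= 10 and the heteroduplex truth label is exactly
#' FALSE); when TRUE, at least one mutated position falls in the 7 bp
#' spacer (so the label is exactly TRUE).  Each chosen position is changed
#' to a different base drawn uniformly.
#'
#' @param reference Reference core (`att_core` or 17-base string).
#' @param k Number of mismatches to introduce, 0..17.
#' @param spacer_divergent Must the mutated core differ from the reference
#'   within the spacer?
#' @return A 17-base string at Hamming distance exactly `k` from the
#'   reference.  Uses the current RNG state; seed upstream.
#' @export
mutate_core <- function(reference, k, spacer_divergent = FALSE) {
  ref <- att_core(reference)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > CORE_WIDTH) {
    stop("k must lie in 0..", CORE_WIDTH)
  }
  if (spacer_divergent && k < 1L) {
    stop("a spacer-divergent core needs k >= 1")
  }
  if (!spacer_divergent && k > length(ARM_POSITIONS)) {
    stop("k > ", length(ARM_POSITIONS),
         " mismatches cannot avoid the spacer; set spacer_divergent = TRUE")
  }
  if (spacer_divergent) {
    first <- sample(SPACER_POSITIONS, 1L)
    rest <- if (k > 1L) sample(setdiff(1:CORE_WIDTH, first), k - 1L) else
      integer()
    pos <- c(first, rest)
  } else {
    pos <- sample(ARM_POSITIONS, k)
  }
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted attachment sites
#'
#' Background bases are i.i.d. at the requested GC fraction; each planted
#' core is the reference mutated at exactly the requested number of
#' positions (touching the spacer iff its divergent flag is set) and is
#' placed at a random position, non-overlapping with other planted sites.
#' After planting, the genome is checked for accidental exact copies of
#' the reference core on either strand outside planted exact sites; any
#' such window is disrupted by a point change (vanishingly rare for
#' genomes far below 4^17 bases, but guaranteed by construction).
#'
#' @param length Genome length in bases (>= 1000).
#' @param planted Data.frame with columns `mismatches` (0..17),
#'   `spacer_divergent` (logical) and `strand` (`"+"`/`"-"`); NULL plants
#'   nothing.
#' @param reference Reference core (`att_core` or 17-base string).
#' @param gc_fraction Background GC content (default 0.435, typical of
#'   the *B. subtilis* chromosome).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param contig Contig name for outputs.
#' @return A list with `genome` (a single-contig
#'   `Biostrings::DNAStringSet`) and `truth` (data.frame: contig, start,
#'   end in 0-based half-open coordinates, strand, core, mismatches,
#'   spacer_divergent), plus `seed`.
#' @examples
#' g <- make_genome(5000, data.frame(mismatches = 0,
#'                                   spacer_divergent = FALSE,
#'                                   strand = "+"),
#'                  reference = "AAGGGTTTCAATCGGCA", seed = 1)
#' nrow(g$truth)
#' @export
make_genome <- function(length, planted = NULL, reference,
                        gc_fraction = 0.435, seed, contig = "synthetic_1") {
  ref <- att_core(reference)
  length <- as.integer(length)
  if (is.na(length) || length < 1000L) {
    stop("genome length must be >= 1000")
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must lie in (0, 1)")
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    need <- c("mismatches", "spacer_divergent", "strand")
    if (!all(need %in% names(planted))) {
      stop("planted must have columns: ", paste(need, collapse = ", "))
    }
    if ((nrow(planted) + 1L) * 2L * CORE_WIDTH > length) {
      stop("planted sites do not fit without overlap in ", length, " bases")
    }
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  g <- sample(bases, length, replace = TRUE, prob = probs)

  truth <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      core = character(), mismatches = integer(),
                      spacer_divergent = logical(),
                      stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0L) {
    starts <- place_nonoverlapping(nrow(planted), length)
    for (i in seq_len(nrow(planted))) {
      core <- mutate_core(ref, planted$mismatches[i],
                          planted$spacer_divergent[i])
      strand <- as.character(planted$strand[i])
      if (!strand %in% c("+", "-")) {
        stop("strand must be '+' or '-'")
      }
      inserted <- if (strand == "+") core else revcomp(core)
      g[starts[i]:(starts[i] + CORE_WIDTH - 1L)] <-
        strsplit(inserted, "", fixed = TRUE)[[1L]]
      truth[i, ] <- list(contig, starts[i] - 1L,
                         starts[i] + CORE_WIDTH - 1L, strand, core,
                         as.integer(planted$mismatches[i]),
                         as.logical(planted$spacer_divergent[i]))
    }
  }

  seq <- paste(g, collapse = "")
  seq <- disrupt_accidental_exact(seq, ref, truth)
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, contig))
  list(genome = genome, truth = truth, seed = seed)
}

# Draw n start positions (1-based) so that planted cores neither overlap
# each other nor run off the sequence.
place_nonoverlapping <- function(n, len) {
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    cand <- sample.int(len - CORE_WIDTH + 1L, 1L)
    if (all(abs(cand - starts) >= CORE_WIDTH)) {
      starts <- c(starts, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("could not place ", n, " non-overlapping sites in ", len,
           " bases")
    }
  }
  starts
}

# Any exact occurrence of the reference core (either strand) outside the
# planted 0-mismatch intervals would corrupt scan truth tables; disrupt it
# with a point change in its central base.
disrupt_accidental_exact <- function(seq, ref, truth) {
  planted_exact <- truth[truth$mismatches == 0L, , drop = FALSE]
  for (iter in 1:20) {
    hits <- scan_genome(c(x = seq), ref, max_mismatch = 0)
    allowed <- paste(planted_exact$start, planted_exact$strand)
    stray <- hits[!(paste(hits$start, hits$strand) %in% allowed), ,
                  drop = FALSE]
    if (nrow(stray) == 0L) {
      return(seq)
    }
    for (i in seq_len(nrow(stray))) {
      overlaps <- nrow(truth) > 0L &&
        any(stray$start[i] < truth$end & stray$end[i] > truth$start)
      if (overlaps) {
        stop("accidental exact reference copy overlaps a planted site; ",
             "use a different seed")
      }
      mid <- stray$start[i] + 9L  # 1-based central position of the window
      cur <- substr(seq, mid, mid)
      substr(seq, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                      1L)
    }
  }
  stop("could not remove accidental exact reference copies")
}

#' Generate a synthetic qPCR Cq panel from known copy numbers
#'
#' Per replicate, Cq = slope * log10(copies) + intercept +
#' Normal(0, noise_sd_cq).
#'
#' @param truths Data.frame with columns `sample`, `target`, `copies`
#'   (> 0): the true copy number of each target in each sample.
#' @param curve A `standard_curve` providing slope and intercept.
#' @param noise_sd_cq Gaussian Cq noise SD in cycles (default 0.15,
#'   ordinary technical-replicate scatter).
#' @param replicates Technical replicates per measurement (default 3).
#' @param seed Integer seed.
#' @return A list with `cq` (data.frame: sample_id, target, replicate,
#'   cq), `truth` (the input), and `seed`.
#' @export
make_qpcr_panel <- function(truths, curve, noise_sd_cq = 0.15,
                            replicates = 3L, seed) {
  truths <- as.data.frame(truths)
  need <- c("sample", "target", "copies")
  if (!all(need %in% names(truths))) {
    stop("truths must have columns: ", paste(need, collapse = ", "))
  }
  if (any(truths$copies <= 0)) {
    stop("true copy numbers must be positive")
  }
  if (!inherits(curve, "standard_curve")) {
    stop("curve must be a standard_curve")
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) {
    stop("replicates must be >= 1")
  }
  set.seed(seed)
  n <- nrow(truths)
  cq <- data.frame(
    sample_id = rep(truths$sample, each = replicates),
    target = rep(truths$target, each = replicates),
    replicate = rep(seq_len(replicates), times = n),
    cq = rep(curve$slope * log10(truths$copies) + curve$intercept,
             each = replicates) +
      stats::rnorm(n * replicates, 0, noise_sd_cq),
    stringsAsFactors = FALSE
  )
  list(cq = cq, truth = truths, seed = seed)
}

#' Simulate an excision-assay panel at a known true frequency
#'
#' Builds the four-measurement design of the excision assay (empty site
#' and reference gene in both the induced sample and the cured
#' normalizer) with the sample's empty site planted at
#' `true_frequency` times the cured level, then generates Cq values with
#' [make_qpcr_panel()].  The two samples sit at unrelated absolute scales
#' to exercise the scale invariance of the normalization.
#'
#' @param true_frequency Planted excision frequency (> 0).
#' @param curve A `standard_curve`.
#' @param noise_sd_cq,replicates,seed Passed to [make_qpcr_panel()].
#' @param cured_copies Absolute copies per target in the cured strain.
#' @param sample_scale Scale factor applied to the induced sample's
#'   absolute copies.
#' @return As [make_qpcr_panel()]; sample ids are `"sample"` and
#'   `"cured"`, targets `"empty"` and `"reference"`.
#' @export
make_excision_panel <- function(true_frequency, curve, noise_sd_cq = 0.15,
                                replicates = 3L, seed,
                                cured_copies = 1e5, sample_scale = 0.35) {
  if (!is.numeric(true_frequency) || true_frequency <= 0) {
    stop("true_frequency must be positive")
  }
  truths <- data.frame(
    sample = c("sample", "sample", "cured", "cured"),
    target = c("empty", "reference", "empty", "reference"),
    copies = c(true_frequency * cured_copies * sample_scale,
               cured_copies * sample_scale,
               cured_copies, cured_copies),
    stringsAsFactors = FALSE
  )
  make_qpcr_panel(truths, curve, noise_sd_cq = noise_sd_cq,
                  replicates = replicates, seed = seed)
}

#' Draw a synthetic transconjugant catalog
#'
#' Multinomial draw of `n_isolates` independent insertions over a set of
#' sites with planted usage probabilities, emulating a pool of independent
#' transconjugants at desk scale (proportions are exact; sampling noise is
#' controlled by `n_isolates`).
#'
#' @param sites Data.frame with columns `locus`, `orientation` and `prob`
#'   (non-negative, summing to 1 within 1e-8).
#' @param n_isolates Number of independent isolates to draw (>= 1).
#' @param seed Integer seed.
#' @return A data.frame of insertion records (sites drawn zero times are
#'   dropped); occurrences sum to `n_isolates`.
#' @export
make_transconjugants <- function(sites, n_isolates, seed) {
  sites <- as.data.frame(sites)
  need <- c("locus", "orientation", "prob")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  if (any(sites$prob < 0) || abs(sum(sites$prob) - 1) > 1e-8) {
    stop("site probabilities must be non-negative and sum to 1")
  }
  n_isolates <- as.integer(n_isolates)
  if (is.na(n_isolates) || n_isolates < 1L) {
    stop("n_isolates must be >= 1")
  }
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, n_isolates, sites$prob))
  keep <- counts > 0L
  insertion_records(locus = sites$locus[keep],
                    orientation = sites$orientation[keep],
                    occurrences = counts[keep])
}

#' Site-usage probabilities of the reference catalog
#'
#' The observed 27-isolate occurrence proportions of
#' [secondary_site_catalog()] as a probability vector, for use with
#' [make_transconjugants()].
#'
#' @return Data.frame with columns `locus`, `orientation`, `prob`.
#' @export
catalog_site_probabilities <- function() {
  cat <- secondary_site_catalog()
  data.frame(locus = cat$locus, orientation = cat$orientation,
             prob = cat$occurrences / sum(cat$occurrences),
             stringsAsFactors = FALSE)
}
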