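test_that("mutate_core hits the requested distance and region constraints", {
  set.seed(101)
  for (k in 0:10) {
    core <- mutate_core(SYN_REF, k, spacer_divergent = FALSE)
    expect_equal(mismatch_count(core, SYN_REF), k)
    expect_equal(att_core(core)$spacer, att_core(SYN_REF)$spacer)
  }
  for (k in c(1, 5, 17)) {
    core <- mutate_core(SYN_REF, k, spacer_divergent = TRUE)
    expect_equal(mismatch_count(core, SYN_REF), k)
    expect_false(att_core(core)$spacer == att_core(SYN_REF)$spacer)
  }
  expect_error(mutate_core(SYN_REF, 18), "0..17")
  expect_error(mutate_core(SYN_REF, 11, spacer_divergent = FALSE),
               "spacer_divergent")
  expect_error(mutate_core(SYN_REF, 0, spacer_divergent = TRUE), ">= 1")
})

test_that("make_genome is a pure function of (spec, seed)", {
  spec <- data.frame(mismatches = c(0, 3), spacer_divergent = c(FALSE, TRUE),
                     strand = c("+", "-"))
  a <- make_genome(3000, spec, SYN_REF, seed = 9)
  b <- make_genome(3000, spec, SYN_REF, seed = 9)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  # byte-identical FASTA output
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a$genome, fa)
  write_fasta(b$genome, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  c <- make_genome(3000, spec, SYN_REF, seed = 10)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("planted sites are recovered by scanning at the planted counts", {
  spec <- data.frame(mismatches = c(2, 3, 7, 8, 11, 12),
                     spacer_divergent = c(FALSE, FALSE, FALSE, FALSE,
                                          TRUE, TRUE),
                     strand = c("+", "-", "+", "-", "+", "-"))
  g <- make_genome(20000, spec, SYN_REF, seed = 13)
  expect_equal(nrow(g$truth), 6)
  hits <- scan_genome(g$genome, SYN_REF, max_mismatch = 12)
  key <- function(df) paste(df$contig, df$start, df$strand)
  expect_true(all(key(g$truth) %in% key(hits)))
  merged <- merge(g$truth, hits, by = c("contig", "start", "strand"))
  expect_equal(merged$mismatches.y, merged$mismatches.x)
  expect_equal(merged$core.y, merged$core.x)
  # truth intervals are in bounds and the genome really carries the cores
  expect_true(all(g$truth$start >= 0))
  expect_true(all(g$truth$end <= nchar(as.character(g$genome))))
})

test_that("no accidental exact copy of the reference survives generation", {
  # short genome + permissive placement makes strays plausible over many
  # seeds; every genome must come out clean
  for (seed in 1:5) {
    g <- make_genome(50000, NULL, SYN_REF, seed = seed)
    hits <- scan_genome(g$genome, SYN_REF, max_mismatch = 0)
    expect_equal(nrow(hits), 0)
  }
})

test_that("make_genome input validation", {
  expect_error(make_genome(500, NULL, SYN_REF, seed = 1), ">= 1000")
  expect_error(make_genome(2000, data.frame(mismatches = 18,
                                            spacer_divergent = TRUE,
                                            strand = "+"),
                           SYN_REF, seed = 1), "0..17")
  big <- data.frame(mismatches = rep(1, 100),
                    spacer_divergent = FALSE, strand = "+")
  expect_error(make_genome(1000, big, SYN_REF, seed = 1), "fit")
})

test_that("noiseless qPCR panels round-trip exactly through quantify", {
  curve <- standard_curve(-1 / log10(2), 33)
  truths <- data.frame(sample = c("s1", "s1", "s2"),
                       target = c("empty", "reference", "empty"),
                       copies = c(120, 4.5e4, 3e6))
  panel <- make_qpcr_panel(truths, curve, noise_sd_cq = 0, seed = 17)
  for (i in seq_len(nrow(truths))) {
    cq <- panel$cq$cq[panel$cq$sample_id == truths$sample[i] &
                        panel$cq$target == truths$target[i]]
    expect_equal(length(cq), 3)
    expect_equal(quantify(cq, curve)$copies, truths$copies[i],
                 tolerance = 1e-9)
  }
  expect_error(make_qpcr_panel(transform(truths, copies = -1), curve,
                               seed = 1), "positive")
})

test_that("planted excision frequencies are recovered end to end", {
  curve <- standard_curve(-1 / log10(2), 33)
  for (f in c(0.06, 5e-4)) {
    ests <- vapply(1:30, function(i) {
      panel <- make_excision_panel(f, curve, noise_sd_cq = 0.15,
                                   seed = 1000 * f * 1e4 + i)
      estimate_excision(panel$cq, curve, "sample", "cured")$frequency
    }, numeric(1))
    expect_lt(abs(median(ests) - f) / f, 0.1)
  }
})

test_that("a planted integration ratio is recovered within the noise band", {
  curve <- standard_curve(-1 / log10(2), 30)
  truths <- data.frame(
    sample = c("pool", "pool", "control", "control"),
    target = c("junction", "reference", "junction", "reference"),
    copies = c(5e-4 * 2e5, 1e5, 2e5, 1e5))
  ests <- vapply(1:30, function(i) {
    panel <- make_qpcr_panel(truths, curve, noise_sd_cq = 0.15, seed = i)
    q <- function(s, t) quantify(
      panel$cq$cq[panel$cq$sample_id == s & panel$cq$target == t], curve)
    integration_ratio(q("pool", "junction"), q("pool", "reference"),
                      q("control", "junction"),
                      q("control", "reference"))$ratio
  }, numeric(1))
  expect_lt(abs(median(ests) - 5e-4) / 5e-4, 0.1)
  # inside the observed-in-the-field window of 1e-4 to 1e-3 of the control
  expect_true(all(ests > 1e-4 & ests < 1e-3))
})

test_that("transconjugant draws are multinomial with exact bookkeeping", {
  single <- make_transconjugants(
    data.frame(locus = "only", orientation = "head-on", prob = 1),
    n_isolates = 12, seed = 19)
  expect_equal(nrow(single), 1)
  expect_equal(single$occurrences, 12L)
  expect_equal(tally_sites(single)$sites$percent, 100)

  probs <- catalog_site_probabilities()
  expect_equal(sum(probs$prob), 1)
  draw <- make_transconjugants(probs, n_isolates = 27, seed = 23)
  expect_equal(sum(draw$occurrences), 27)
  expect_lte(tally_sites(draw)$n_sites, 15)

  # chi-square goodness of fit of a large draw against the planted vector
  # (single fixed-seed run; a multiple-run campaign would need alpha
  # adjustment)
  big <- make_transconjugants(probs, n_isolates = 10000, seed = 29)
  counts <- merge(probs, big, all.x = TRUE)
  counts$occurrences[is.na(counts$occurrences)] <- 0L
  gof <- suppressWarnings(chisq.test(counts$occurrences, p = counts$prob))
  expect_gt(gof$p.value, 0.01)

  expect_error(make_transconjugants(
    data.frame(locus = "a", orientation = "head-on", prob = 0.5), 5,
    seed = 1), "sum to 1")
  expect_error(make_transconjugants(probs, 0, seed = 1), ">= 1")
})
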