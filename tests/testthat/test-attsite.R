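test_that("core decomposition follows the fixed 5+7+5 partition", {
  core <- att_core(paste0("AAAAA", "TTTTTTT", "GGGGG"))
  expect_equal(core$left_arm, "AAAAA")
  expect_equal(core$spacer, "TTTTTTT")
  expect_equal(core$right_arm, "GGGGG")
  expect_false(core$perfect_stem)

  # TTTTT is the reverse complement of AAAAA: a perfect stem
  stem <- att_core(paste0("AAAAA", "CCCCCCC", "TTTTT"))
  expect_true(stem$perfect_stem)

  set.seed(11)
  for (i in 1:50) {
    s <- random_core()
    core <- att_core(s)
    expect_equal(core$left_arm, substr(s, 1, 5))
    expect_equal(core$spacer, substr(s, 6, 12))
    expect_equal(core$right_arm, substr(s, 13, 17))
    expect_equal(paste0(core$left_arm, core$spacer, core$right_arm), s)
    expect_equal(core$perfect_stem,
                 core$right_arm == naive_revcomp(core$left_arm))
  }
})

test_that("core validation rejects wrong lengths and ambiguity codes", {
  expect_error(att_core("ACGT"), "17")
  expect_error(att_core(strrep("A", 18)), "17")
  expect_error(att_core(paste0("AAAAA", "TTTNTTT", "GGGGG")), "A/C/G/T")
  expect_error(att_core(c("A", "B")), "single")
  # lowercase is normalized, not rejected
  expect_equal(att_core(tolower(SYN_REF))$sequence, SYN_REF)
})

test_that("mismatch_count is the Hamming metric on 17-mers", {
  expect_equal(mismatch_count(SYN_REF, SYN_REF), 0)
  altered <- paste0("TG", substr(SYN_REF, 3, 16), "A")  # 3 changed positions
  expect_equal(mismatch_count(altered, SYN_REF), 3)

  set.seed(21)
  for (i in 1:200) {
    a <- random_core(); b <- random_core(); c <- random_core()
    expect_equal(mismatch_count(a, b), naive_hamming(a, b))
    expect_equal(mismatch_count(a, b), mismatch_count(b, a))
    expect_identical(mismatch_count(a, b) == 0L, a == b)
    expect_lte(mismatch_count(a, c),
               mismatch_count(a, b) + mismatch_count(b, c))
  }
})

test_that("heteroduplex prediction depends only on the spacer", {
  element <- att_core(SYN_REF)
  # arms differ at 4 positions, spacer identical: no heteroduplex
  chars <- strsplit(SYN_REF, "")[[1]]
  for (p in c(1, 2, 13, 14)) chars[p] <- setdiff(BASES, chars[p])[1]
  arms_only <- paste(chars, collapse = "")
  expect_equal(mismatch_count(arms_only, element), 4)
  expect_false(predict_heteroduplex(arms_only, element))
  # a single spacer difference triggers it
  sp <- element$spacer
  substr(sp, 4, 4) <- setdiff(BASES, substr(sp, 4, 4))[1]
  one_spacer <- paste0(element$left_arm, sp, element$right_arm)
  expect_true(predict_heteroduplex(one_spacer, element))
})

test_that("planted spacer-divergent cores are exactly those flagged", {
  set.seed(31)
  for (i in 1:50) {
    divergent <- i %% 2 == 0
    k <- if (divergent) sample(1:17, 1) else sample(0:10, 1)
    core <- mutate_core(SYN_REF, k, spacer_divergent = divergent)
    expect_equal(mismatch_count(core, SYN_REF), k)
    expect_equal(predict_heteroduplex(core, SYN_REF), divergent)
  }
})

test_that("integration and excision compose correctly", {
  element <- att_core(SYN_REF)

  # homoduplex round trip: target == element att
  jp <- integrate_site(element, element)
  expect_equal(jp$attL$sequence, element$sequence)
  expect_equal(jp$attR$sequence, element$sequence)
  ex <- excise_site(jp)
  expect_false(ex$heteroduplex)
  expect_equal(ex$circle_att$sequence, element$sequence)
  expect_equal(ex$empty_site$sequence, element$sequence)

  set.seed(41)
  for (i in 1:100) {
    target <- att_core(random_core())
    jp <- integrate_site(target, element)
    ex <- excise_site(jp)
    # spacer-divergent targets give junctions with different crossovers
    expect_equal(jp$attL$spacer != jp$attR$spacer,
                 predict_heteroduplex(target, element))
    # excision flags a heteroduplex iff the target spacer diverged
    expect_equal(ex$heteroduplex, predict_heteroduplex(target, element))
    # the default convention restores chromosome and element exactly
    expect_equal(ex$empty_site$sequence, target$sequence)
    expect_equal(ex$circle_att$sequence, element$sequence)
  }

  # the spacer-assignment switch flips provenance but not the flag
  target <- att_core(mutate_core(SYN_REF, 3, spacer_divergent = TRUE))
  jp2 <- integrate_site(target, element, attL_spacer = "element")
  expect_equal(jp2$attL$spacer, element$spacer)
  expect_equal(excise_site(jp2)$heteroduplex,
               predict_heteroduplex(target, element))
})

test_that("tally_sites reproduces the reference catalog statistics", {
  tal <- tally_sites(secondary_site_catalog())
  expect_equal(tal$n_sites, 15)
  expect_equal(tal$total_insertions, 27)
  expect_equal(tal$modal_site$locus, "yrkM")
  expect_equal(tal$modal_site$percent, 41)
  expect_equal(tal$sites$percent[2], 11)
  expect_equal(tal$sites$locus[2], "mmsA")
  # the yqhG pair counts as two sites (one per orientation)
  yqhg <- tal$sites[tal$sites$locus == "yqhG", ]
  expect_equal(nrow(yqhg), 2)
  expect_setequal(yqhg$orientation, c("co-directional", "head-on"))
})

test_that("tally_sites conserves occurrences and bounds rounding error", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    rec <- insertion_records(
      locus = paste0("locus", seq_len(n)),
      orientation = sample(c("co-directional", "head-on"), n,
                           replace = TRUE),
      occurrences = sample(1:20, n, replace = TRUE))
    tal <- tally_sites(rec)
    expect_equal(tal$total_insertions, sum(rec$occurrences))
    expect_equal(sum(tal$sites$occurrences), sum(rec$occurrences))
    expect_lte(abs(sum(tal$sites$percent) - 100), 0.5 * tal$n_sites)
  }
  # duplicate (locus, orientation) rows merge into one site
  dup <- insertion_records(locus = c("a", "a", "a"),
                           orientation = c("head-on", "head-on",
                                           "co-directional"),
                           occurrences = c(2L, 3L, 1L))
  tal <- tally_sites(dup)
  expect_equal(tal$n_sites, 2)
  expect_equal(tal$modal_site$occurrences, 5)

  single <- insertion_records("x", "head-on", occurrences = 5L)
  tal1 <- tally_sites(single)
  expect_equal(tal1$n_sites, 1)
  expect_equal(tal1$sites$percent, 100)

  expect_error(tally_sites(data.frame()), "nonempty")
  expect_error(tally_sites(insertion_records("x", "head-on",
                                             occurrences = 1L)[0, ]),
               "nonempty")
})
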