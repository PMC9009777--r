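test_that("pseudo-counted frequencies blend counts with the background", {
  g <- one_col_grouped("A", "A", "A", "C")
  raw <- column_profile(g, 1, pc = NULL)
  expect_equal(unname(raw$freq$Xa["A"]), 1)
  expect_equal(sum(raw$freq$Xa), 1)
  # beta = 0 is identical to raw frequencies
  pc0 <- pseudocount_config(beta = 0)
  expect_equal(column_profile(g, 1, pc0)$freq, raw$freq)
  # hand value: n = 2 residues {A, C}, beta = 5, uniform background
  pcu <- pseudocount_config(beta = 5, background = rep(1 / 20, 20))
  g2 <- toy_grouped()
  f <- column_profile(g2, 2, pcu)$freq$Xa  # Xa column 2 holds A and C
  expect_equal(unname(f["A"]), (2 * 0.5 + 5 / 20) / 7, tolerance = 1e-12)
  expect_equal(unname(f["A"]), 0.1785714, tolerance = 1e-6)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # smoothing keeps scores away from the extremes
  pr <- column_profile(g, 1, pseudocount_config())
  expect_gt(inversion_score(pr), 0)
  expect_lt(inversion_score(pr), 1)
  expect_error(pseudocount_config(beta = -1), "non-negative")
  expect_error(pseudocount_config(background = rep(1, 20)), "summing to 1")
})

test_that("smoothed frequencies converge to raw as the cell grows", {
  pc <- pseudocount_config()
  for (n in c(4L, 40L, 400L)) {
    seqs <- stats::setNames(rep(c("A", "C", "A", "C"), each = n),
                            paste0(rep(c("X", "Y"), each = 2 * n),
                                   seq_len(4 * n), "_",
                                   rep(rep(c("a", "b"), each = n), 2)))
    g <- toy_grouped(seqs)
    f <- column_profile(g, 1, pc)$freq$Xa
    expect_lt(abs(f[["A"]] - 1), 5 * pc$beta / n)
  }
})

test_that("profile match is the dot product of frequency arrays", {
  p <- c(1, rep(0, 19)); q <- c(0.5, 0.5, rep(0, 18))
  expect_equal(profile_match(p, p), 1)
  expect_equal(profile_match(p, q), 0.5)
  expect_equal(profile_match(q, q), 0.5)
  expect_error(profile_match(p[1:5], q), "length-20")
  expect_error(profile_match(p * 2, q), "summing to 1")
})

test_that("inversion and adaptation scores hit their anchors", {
  # perfectly conserved column: both scores zero
  cons <- column_profile(one_col_grouped("C", "C", "C", "C"), 1, pc = NULL)
  expect_equal(inversion_score(cons), 0)
  expect_equal(ssa_score(cons), 0)
  # perfect inversion pattern without smoothing: inversion 1, adaptation 0
  inv <- column_profile(one_col_grouped("F", "H", "H", "F"), 1, pc = NULL)
  expect_equal(inversion_score(inv), 1)
  expect_equal(ssa_score(inv), 0)
  # perfect adaptation pattern: mirrored anchors
  ssa <- column_profile(one_col_grouped("F", "H", "F", "H"), 1, pc = NULL)
  expect_equal(inversion_score(ssa), 0)
  expect_equal(ssa_score(ssa), 1)
  # hand-verified toy values
  g <- toy_grouped()
  expect_equal(inversion_score(column_profile(g, 1, pc = NULL)), 0.5)
  expect_equal(inversion_score(column_profile(g, 2, pc = NULL)), 0.25)
  expect_equal(ssa_score(column_profile(g, 2, pc = NULL)), 0)
  expect_equal(inversion_score(column_profile(g, 3, pc = NULL)), 0)
})

test_that("division-free score equals the two-step conditional formula", {
  set.seed(21)
  for (i in 1:1000) {
    f <- random_profile()
    direct <- invphy:::score_from_arrays(f$Xa, f$Ya, f$Xb, f$Yb)
    expect_equal(direct, two_step_inversion(f), tolerance = 1e-12)
    expect_gte(direct, 0)
    expect_lte(direct, 1)
  }
})

test_that("adaptation score is the inversion score of the copy-swapped column", {
  set.seed(5)
  for (i in 1:50) {
    f <- random_profile()
    swapped <- list(Xa = f$Xa, Ya = f$Ya, Xb = f$Yb, Yb = f$Xb)
    expect_equal(invphy:::score_from_arrays(f$Xa, f$Ya, f$Yb, f$Xb),
                 invphy:::score_from_arrays(swapped$Xa, swapped$Ya,
                                            swapped$Xb, swapped$Yb),
                 tolerance = 1e-15)
  }
})

test_that("scores are invariant to sequence order within cells", {
  g1 <- toy_grouped()
  reordered <- c(X2_a = "ACC", X1_a = "AAC", Y2_a = "CCC", Y1_a = "ACC",
                 X2_b = "CCC", X1_b = "CCC", Y2_b = "ACC", Y1_b = "AAC")
  g2 <- toy_grouped(reordered)
  s1 <- scan_alignment(g1, pc = NULL)
  s2 <- scan_alignment(g2, pc = NULL)
  expect_equal(s1$inversion_score, s2$inversion_score)
  expect_equal(s1$ssa_score, s2$ssa_score)
})

test_that("gap-heavy columns are excluded from the scan", {
  # 8 of 12 grouped sequences gapped in column 2 (2 per cell) ->
  # gap fraction 2/3 >= 0.60, yet every scoring cell keeps one residue
  seqs <- c(X1_a = "AA", X2_a = "A-", X3_a = "A-",
            Y1_a = "AA", Y2_a = "A-", Y3_a = "A-",
            X1_b = "CC", X2_b = "C-", X3_b = "C-",
            Y1_b = "CC", Y2_b = "C-", Y3_b = "C-")
  g <- toy_grouped(seqs)
  sc <- scan_alignment(g, pc = NULL)
  expect_identical(sc$column, 1L)
  # relaxing the threshold brings the column back
  sc2 <- scan_alignment(g, pc = NULL, gap_threshold = 0.90)
  expect_identical(sc2$column, c(1L, 2L))
  expect_equal(sc2$gap_fraction[2], 2 / 3)
})

test_that("columns with an empty scoring cell are skipped and reported", {
  seqs <- c(X1_a = "A-", Y1_a = "AA", X1_b = "CC", Y1_b = "CC")
  g <- toy_grouped(seqs)
  expect_message(sc <- scan_alignment(g, pc = NULL, gap_threshold = 0.99),
                 "skipped")
  expect_identical(sc$column, 1L)
  expect_identical(attr(sc, "skipped"), 2L)
})

test_that("planted signal columns dominate a neutral background scan", {
  cfg <- synth_config(n_sites = 100L, n_planted_inversions = 5L, noise = 0,
                      seed = 42)
  ds <- synth_dataset(cfg)
  g <- grouped_alignment(ds$msa, ds$groups)
  sc <- scan_alignment(g)
  top5 <- sc$column[order(sc$inversion_score, decreasing = TRUE)][1:5]
  expect_setequal(top5, ds$truth$column)
})

test_that("percentile thresholds use linear interpolation", {
  scores <- seq(0, 0.99, by = 0.01)
  expect_equal(percentile_threshold(scores, 99), 0.9801)
  expect_equal(percentile_threshold(rep(0.3, 10)), 0.3)
  expect_equal(percentile_threshold(scores, 100), 0.99)
  expect_equal(percentile_threshold(scores, 0), 0)
  expect_equal(percentile_threshold(c(NA, 0.5)), 0.5)
  expect_error(percentile_threshold(numeric(0)), "no scores")
  expect_error(percentile_threshold(1, 101), "0, 100")
})

test_that("ortholog/paralog matching separates conserved from inverted columns", {
  g <- toy_grouped()
  op <- ortholog_paralog_matching(g, pc = NULL)
  # column 3 is fully conserved: both coordinates 1
  expect_equal(op$ortholog_match[op$column == 3], 1)
  expect_equal(op$paralog_match[op$column == 3], 1)
  # a perfect inversion column: orthologs mismatch, paralogs match
  inv <- toy_grouped(c(X1_a = "F", X2_a = "F", Y1_a = "H", Y2_a = "H",
                       X1_b = "H", X2_b = "H", Y1_b = "F", Y2_b = "F"))
  op2 <- ortholog_paralog_matching(inv, pc = NULL)
  expect_equal(op2$ortholog_match, 0)
  expect_equal(op2$paralog_match, 1)
})

test_that("alignment columns map to ungapped reference coordinates", {
  msa <- invphy:::as_msa(c(ref = "A-CD", other = "AACD"))
  m <- map_column_to_reference(msa, "ref", 3)
  expect_equal(m$position, 2)
  expect_identical(m$residue, "C")
  expect_false(m$at_gap)
  m2 <- map_column_to_reference(msa, "ref", 2)
  expect_true(m2$at_gap)
  expect_equal(m2$position, 1)   # nearest preceding residue
  msa2 <- invphy:::as_msa(c(ref = "MKV"))
  m3 <- map_column_to_reference(msa2, "ref", 1)
  expect_equal(m3$position, 1)
  expect_identical(m3$residue, "M")
  expect_error(map_column_to_reference(msa, "nope", 1), "unknown reference")
  expect_error(map_column_to_reference(msa, "ref", 9), "out of range")
})

test_that("multi-grouping scans report the best-scoring grouping per site", {
  inv <- c(X1_a = "F", X2_a = "F", Y1_a = "H", Y2_a = "H",
           X1_b = "H", X2_b = "H", Y1_b = "F", Y2_b = "F")
  msa <- invphy:::as_msa(inv)
  ids <- names(inv)
  species <- sub("_[ab]$", "", ids)
  paralog <- sub("^.*_", "", ids)
  right <- group_assignment(ids, species, paralog,
                            ifelse(startsWith(species, "X"), "group1", "group2"),
                            grouping_id = "true_split")
  # wrong split mixes the two species groups -> no inversion signal
  wrong_sg <- ifelse(species %in% c("X1", "Y1"), "group1", "group2")
  wrong <- group_assignment(ids, species, paralog, wrong_sg,
                            grouping_id = "wrong_split")
  sc <- scan_alignment(msa, pc = NULL, groupings = list(wrong, right))
  expect_identical(sc$grouping_id, "true_split")
  expect_equal(sc$inversion_score, 1)
})

test_that("logo frequency export is tidy and normalised", {
  g <- toy_grouped()
  lf <- logo_frequencies(g, columns = c(1, 3))
  expect_identical(nrow(lf), 2L * 4L * 20L)
  sums <- tapply(lf$frequency, interaction(lf$column, lf$cell), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
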