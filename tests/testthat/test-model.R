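test_that("substitution probability follows 1 - exp(-t)", {
  expect_equal(substitution_probability(0), 0)
  expect_equal(substitution_probability(log(2)), 0.5)
  expect_gt(substitution_probability(20), 1 - 1e-8)
  t <- seq(0, 4, by = 0.25)
  expect_true(all(diff(substitution_probability(t)) > 0))
  expect_error(substitution_probability(-0.1), "finite and >= 0")
  expect_error(substitution_probability(Inf), "finite and >= 0")
})

test_that("configuration enumeration is complete and normalised", {
  set.seed(4)
  for (i in 1:5) {
    t1 <- runif(1, 0, 5); t2 <- runif(1, 0, 5)
    bc <- branch_configurations(t1, t2)
    expect_identical(nrow(bc$states), 64L)
    expect_lt(abs(sum(bc$probability) - 1), 1e-12)
  }
  bc0 <- branch_configurations(0, 0)
  zero <- rowSums(bc0$states) == 0
  expect_equal(bc0$probability[zero], 1)
  expect_equal(bc0$probability[!zero], rep(0, 63))
  bch <- branch_configurations(log(2), log(2))
  expect_equal(bch$probability, rep(0.5^6, 64))
})

test_that("leaf states and pair counts follow the quartet topology", {
  bc <- branch_configurations(0.5, 0.5)
  s <- bc$states
  expect_equal(bc$leaf_states[, "Xa"], unname(s[, "b1"] + s[, "b3"]))
  expect_equal(bc$leaf_states[, "Yb"], unname(s[, "b2"] + s[, "b6"]))
  # inner pairs count only the branches below the speciation ancestor
  expect_equal(bc$pair_counts$k_u[, "Xa:Ya"], unname(s[, "b3"]))
  expect_equal(bc$pair_counts$k_v[, "Xa:Ya"], unname(s[, "b4"]))
  # outer pairs count each leaf's full path from the duplication
  expect_equal(bc$pair_counts$k_u[, "Ya:Xb"], unname(bc$leaf_states[, "Ya"]))
  expect_equal(bc$pair_counts$k_v[, "Ya:Xb"], unname(bc$leaf_states[, "Xb"]))
})

test_that("match probabilities equal brute-force path enumeration", {
  for (A in c(2L, 4L, 20L)) {
    for (ku in 0:2) {
      for (kv in 0:2) {
        expect_equal(match_probability(ku, kv, A), brute_match(ku, kv, A),
                     tolerance = 1e-12,
                     label = sprintf("A=%d k=(%d,%d)", A, ku, kv))
      }
    }
  }
  expect_equal(match_probability(0, 0), 1)
  expect_equal(match_probability(1, 0), 0)
  expect_equal(match_probability(1, 1), 1 / 19)
  expect_equal(match_probability(2, 1), 18 / 361)
  expect_error(match_probability(3, 0), "0, 1 or 2")
  expect_error(match_probability(0, -1), "0, 1 or 2")
})

test_that("category probabilities are a proper distribution", {
  p0 <- category_probabilities(0, 0)
  expect_equal(unname(p0[["conserved"]]), 1)
  expect_equal(sum(p0), 1)
  expect_true(all(p0[setdiff(names(p0), "conserved")] == 0))
  set.seed(8)
  for (i in 1:10) {
    p <- category_probabilities(runif(1, 0, 5), runif(1, 0, 5))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("category probabilities agree with the Monte-Carlo quartet", {
  mc <- mc_categories(0.3, 0.1, n = 2e5, seed = 31)
  exact <- category_probabilities(0.3, 0.1)[names(mc)]
  expect_true(all(abs(mc - exact) < 0.02))
})

test_that("inversion and adaptation exchange when Xb and Yb roles swap", {
  set.seed(12)
  for (i in 1:5) {
    bc <- branch_configurations(runif(1, 0, 3), runif(1, 0, 3))
    m <- bc$match
    swapped <- m
    swapped[, "Xa:Ya"] <- m[, "Xa:Ya"]
    swapped[, "Xb:Yb"] <- m[, "Xb:Yb"]
    swapped[, "Xa:Xb"] <- m[, "Xa:Yb"]
    swapped[, "Xa:Yb"] <- m[, "Xa:Xb"]
    swapped[, "Ya:Xb"] <- m[, "Ya:Yb"]
    swapped[, "Ya:Yb"] <- m[, "Ya:Xb"]
    pc <- invphy:::category_given_configuration(m)
    ps <- invphy:::category_given_configuration(swapped)
    expect_equal(as.numeric(bc$probability %*% ps[, "inversion"]),
                 as.numeric(bc$probability %*% pc[, "species_specific"]),
                 tolerance = 1e-12)
    expect_equal(as.numeric(bc$probability %*% ps[, "species_specific"]),
                 as.numeric(bc$probability %*% pc[, "inversion"]),
                 tolerance = 1e-12)
  }
})

test_that("heatmap shows the expected qualitative regimes", {
  hm0 <- category_heatmap(0, 0)
  expect_equal(hm0$conserved, matrix(1, 1, 1), ignore_attr = TRUE)
  g <- seq(0.1, 5, length.out = 10)
  hm <- category_heatmap(g, g)
  # type 1 / type 2 divergence peak when the pre-speciation branch dominates
  w2 <- which(hm$type2 == max(hm$type2), arr.ind = TRUE)
  expect_gt(g[w2[1]], g[w2[2]])
  w1 <- which(hm$type1 == max(hm$type1), arr.ind = TRUE)
  expect_gt(g[w1[1]], g[w1[2]])
  # the inversion optimum needs short pre-speciation branches but enough
  # post-speciation change: its argmax has t2 > t1
  wi <- which(hm$inversion == max(hm$inversion), arr.ind = TRUE)
  expect_lt(g[wi[1]], g[wi[2]])
  # inversions are everywhere rarer than conservation at the origin corner
  expect_true(all(hm$inversion < hm$conserved[1, 1]))
  expect_error(category_heatmap(numeric(0), 1), "non-empty")
  expect_error(category_heatmap(-1, 1), ">= 0")
})

test_that("expected inversion probability matches the model on a known tree", {
  cfg <- synth_config(n_species_group1 = 2, n_species_group2 = 2,
                      t1 = 0.3, t2 = 0.1, seed = 9)
  td <- make_duplication_tree(cfg)
  p <- expected_inversion_probability(td$tree, td$groups)
  expect_equal(attr(p, "t1"), 0.3, tolerance = 1e-9)
  expect_equal(attr(p, "t2"), 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(p),
               unname(category_probabilities(0.3, 0.1)[["inversion"]]),
               tolerance = 1e-12)
  expect_lt(as.numeric(p), 0.01)
  # degenerate tree: all branch lengths zero
  cfg0 <- synth_config(n_species_group1 = 2, n_species_group2 = 2,
                       t1 = 0, t2 = 0, seed = 9)
  td0 <- make_duplication_tree(cfg0)
  expect_equal(as.numeric(expected_inversion_probability(td0$tree, td0$groups)), 0)
})
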