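test_that("the covariance ratio matches its closed forms", {
  nm <- c("a1", "a2", "b1", "b2")
  part <- list(m1 = c("a1", "a2"), m2 = c("b1", "b2"))
  S <- matrix(0.3, 4, 4, dimnames = list(nm, nm))  # a = b = c = 0.3
  diag(S) <- 1
  expect_equal(cr_statistic(S, part), sqrt(2), tolerance = 1e-10)

  # general a, b, c: CR = sqrt(2) |c| / sqrt(|a| |b|)
  a <- 0.5; b <- 0.2; cc <- 0.3
  S2 <- S
  S2["a1", "a2"] <- S2["a2", "a1"] <- a
  S2["b1", "b2"] <- S2["b2", "b1"] <- b
  S2[part$m1, part$m2] <- cc; S2[part$m2, part$m1] <- cc
  expect_equal(cr_statistic(S2, part), sqrt(2) * cc / sqrt(a * b),
               tolerance = 1e-12)

  S0 <- S2
  S0[part$m1, part$m2] <- 0; S0[part$m2, part$m1] <- 0
  expect_equal(cr_statistic(S0, part), 0)

  # invariant to reordering traits within modules
  part_r <- list(m1 = c("a2", "a1"), m2 = c("b2", "b1"))
  expect_equal(cr_statistic(S2, part_r), cr_statistic(S2, part))

  Sz <- S0
  Sz["a1", "a2"] <- Sz["a2", "a1"] <- 0
  Sz["b1", "b2"] <- Sz["b2", "b1"] <- 0
  expect_error(cr_statistic(Sz, part), "zero within-module")
})

test_that("CR equals a brute-force element-wise computation", {
  set.seed(13)
  part <- default_partition()
  for (i in 1:10) {
    S <- random_cov(7, default_trait_names())
    m1 <- match(part$LEAF, colnames(S))
    m2 <- match(part$LIFEFORM, colnames(S))
    expect_equal(cr_statistic(S, part), brute_cr(S, m1, m2),
                 tolerance = 1e-10)
  }
  # exact homogeneity: scaling every trait by k leaves CR unchanged
  S <- random_cov(7, default_trait_names())
  expect_equal(cr_statistic(4 * S, part), cr_statistic(S, part),
               tolerance = 1e-12)
})

test_that("contrast covariance equals the GLS quadratic form", {
  ds <- make_fixture(sim_config(seed = 23))
  X <- preprocess_traits(ds$traits, log = FALSE)
  S <- contrasts_covariance(ds$tree, X)
  C <- phylo_covariance(ds$tree)
  expect_equal(unname(S), unname(evolutionary_vcv(X, C)), tolerance = 1e-8)
  # bilinearity: doubling one trait doubles its row and column
  X2 <- X; X2[, "PH"] <- 2 * X2[, "PH"]
  S2 <- contrasts_covariance(ds$tree, X2)
  expect_equal(S2["PH", "LA"], 2 * S["PH", "LA"], tolerance = 1e-10)
  expect_equal(S2["PH", "PH"], 4 * S["PH", "PH"], tolerance = 1e-10)
})

test_that("the permutation test enumerates small assignment spaces", {
  ds <- make_fixture(sim_config(seed = 25))
  X <- preprocess_traits(ds$traits, log = FALSE)
  res <- cr_test(ds$tree, X, seed = 1)
  expect_identical(res$method, "exact")
  expect_equal(res$n_permutations, 21L)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$p_value,
               sum(res$null_cr <= res$cr_observed + 1e-12) / 21)
  # deterministic regardless of seed (exact path)
  res2 <- cr_test(ds$tree, X, seed = 99)
  expect_equal(res$p_value, res2$p_value)
  expect_equal(res$cr_observed, res2$cr_observed)

  # 2+2 partition of four traits: 3 distinct assignments, warns
  X4 <- X[, c("PH", "LA", "LMA", "LT")]
  p4 <- list(m1 = c("PH", "LA"), m2 = c("LMA", "LT"))
  expect_warning(r4 <- cr_test(ds$tree, X4, p4), "distinct")
  expect_equal(r4$n_permutations, 3L)
})

test_that("sampled permutations apply the +1/+1 rule reproducibly", {
  tr <- simulate_yule(20, seed = 41)
  nm <- paste0("x", 1:10)
  R <- modular_cov(nm, list(a = nm[1:5], b = nm[6:10]),
                   within = 0.7, between = 0.1)
  X <- simulate_traits(tr, R, seed = 5)
  part <- list(a = nm[1:5], b = nm[6:10])  # C(10,5)/2 = 126 > 99 -> sampled
  r1 <- cr_test(tr, X, part, n_permutations = 99, seed = 7)
  expect_identical(r1$method, "sampled")
  expect_equal(r1$p_value,
               (1 + sum(r1$null_cr <= r1$cr_observed + 1e-12)) / 100)
  expect_gt(r1$p_value, 0)
  r2 <- cr_test(tr, X, part, n_permutations = 99, seed = 7)
  expect_identical(r1$null_cr, r2$null_cr)
})

test_that("clade-wise modularity recomputes contrasts inside clades", {
  ds <- make_fixture(sim_config(seed = 27))
  X <- preprocess_traits(ds$traits, log = FALSE)
  whole <- suppressWarnings(
    modularity_by_clade(ds$tree, X,
                        clades = list(all = ds$tree$tip.label), seed = 3))
  direct <- cr_test(ds$tree, X, seed = 4)
  expect_equal(whole$all$cr_observed, direct$cr_observed, tolerance = 1e-12)

  res <- modularity_by_clade(ds$tree, X, clades = ds$clades, seed = 5)
  expect_named(res, c("I", "II", "III"))
  for (r in res) expect_true(r$cr_observed >= 0)
  # clade CR differs from the whole-tree CR (computed within the subtree)
  expect_false(isTRUE(all.equal(res$I$cr_observed, direct$cr_observed)))

  tiny <- modularity_by_clade(ds$tree, X,
                              clades = list(t = ds$clades$I[1:3]), seed = 1)
  expect_true(is.na(tiny$t$cr_observed))
  expect_match(tiny$t$reason, "fewer than 4")
})
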