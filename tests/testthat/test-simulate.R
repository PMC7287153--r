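test_that("Yule simulator meets its structural contract", {
  tr <- simulate_yule(34, seed = 1)
  expect_equal(ape::Ntip(tr), 34L)
  expect_true(ape::is.binary(tr))
  d <- ape::node.depth.edgelength(tr)[1:34]
  expect_lt(max(d) - min(d), 1e-9 * max(d))
  expect_identical(write_newick(simulate_yule(10, seed = 7)),
                   write_newick(simulate_yule(10, seed = 7)))
  expect_error(simulate_yule(1), "n_taxa")
})

test_that("Yule tree depths match a brute-force waiting-time oracle", {
  nrep <- 600
  depths <- vapply(seq_len(nrep), function(i) {
    tr <- simulate_yule(5, birth_rate = 1, seed = 5000 + i)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  set.seed(99)
  oracle <- vapply(seq_len(5000), function(i) brute_yule_depth(5, 1), 0)
  se <- sqrt(stats::var(depths) / nrep + stats::var(oracle) / 5000)
  expect_lt(abs(mean(depths) - mean(oracle)), 3 * se)
})

test_that("Mk simulation follows the ER transition kernel", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  sim0 <- simulate_mk(tr, q = 0, seed = 1)
  expect_equal(length(unique(sim0$node_states)), 1L)
  expect_equal(sim0$n_changes, 0L)

  s1 <- simulate_mk(tr, 0.5, seed = 3)
  s2 <- simulate_mk(tr, 0.5, seed = 3)
  expect_identical(s1$tip_states, s2$tip_states)

  # high rate: tip frequencies indistinguishable from uniform
  two <- parse_newick("(A:1,B:1);")
  tips <- vapply(seq_len(2000), function(i)
    simulate_mk(two, q = 100, seed = 20000 + i)$tip_states[["A"]], "")
  tab <- table(factor(tips, levels = c("CS", "HF", "WA")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # tip-pair agreement matches the analytic two-tip probability
  t_depth <- 0.4; q <- 0.8
  agree <- vapply(seq_len(4000), function(i) {
    s <- simulate_mk(parse_newick(sprintf("(A:%f,B:%f);", t_depth, t_depth)),
                     q = q, seed = 50000 + i)$tip_states
    s[["A"]] == s[["B"]]
  }, TRUE)
  P <- mk_transition_matrix(q, "ER", t_depth)
  expected <- sum(P[1, ]^2)  # rows identical in symmetry: sum_s P(r,s)^2
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(mean(agree) - expected), 3 * se)
})

test_that("trait simulation reproduces the Brownian covariance structure", {
  # star tree: i.i.d. tips with variance = depth
  star <- parse_newick("(A:2,B:2,C:2,D:2,E:2,F:2,G:2,H:2);")
  vals <- vapply(seq_len(1500), function(i)
    simulate_traits(star, matrix(1, dimnames = list("x", "x")),
                    seed = 700 + i)[, 1], numeric(8))
  v <- stats::var(as.vector(vals))
  se <- sqrt(2 / (length(vals) - 1)) * 2   # var of sample variance, sigma2=2
  expect_lt(abs(v - 2), 3 * se)

  # lambda = 0 kills among-taxa covariance
  tr <- simulate_yule(8, seed = 31)
  xs <- t(vapply(seq_len(800), function(i)
    simulate_traits(tr, matrix(1, dimnames = list("x", "x")),
                    lambda = 0, seed = 3000 + i)[, 1], numeric(8)))
  offdiag <- stats::cov(xs); diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 4 * sqrt(1 / 800) * max(diag(stats::cov(xs))))

  # contrasts of two traits with generating correlation 0.9 correlate at 0.9
  R <- matrix(c(1, .9, .9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cors <- vapply(seq_len(300), function(i) {
    X <- simulate_traits(tr, R, seed = 8000 + i)
    stats::cor(pic_contrasts(tr, X[, 1])$contrasts,
               pic_contrasts(tr, X[, 2])$contrasts)
  }, 0)
  expect_lt(abs(mean(cors) - 0.9), 3 * stats::sd(cors) / sqrt(300))

  expect_error(simulate_traits(tr, matrix(c(1, 2, 2, 1), 2)), "definite")
})

test_that("single-trait lambda-1 simulation is distributionally Brownian", {
  tr <- simulate_yule(8, seed = 77)
  mine <- vapply(seq_len(2000), function(i)
    simulate_traits(tr, matrix(1, dimnames = list("x", "x")),
                    seed = 40000 + i)[1, 1], 0)
  set.seed(123)
  brute <- vapply(seq_len(2000), function(i) brute_bm(tr)[[1]], 0)
  expect_gt(suppressWarnings(stats::ks.test(mine, brute)$p.value), 0.01)
})

test_that("the default fixture satisfies its invariants deterministically", {
  ds <- make_fixture(sim_config(seed = 4))
  expect_setequal(ds$tree$tip.label, rownames(ds$traits))
  expect_setequal(ds$tree$tip.label, names(ds$habitat))
  expect_setequal(ds$tree$tip.label, ds$climate$taxon)
  expect_equal(lengths(ds$clades), c(I = 10L, II = 12L, III = 12L))
  expect_true(ds$truth$n_changes >= 5 && ds$truth$n_changes <= 9)
  expect_true(ape::is.binary(ds$tree))
  d <- ape::node.depth.edgelength(ds$tree)[1:34]
  expect_lt(max(d) - min(d), 1e-8)
  expect_true(all(ds$traits_raw > 0))

  ds2 <- make_fixture(sim_config(seed = 4))
  expect_identical(ds$traits, ds2$traits)
  expect_identical(ds$habitat, ds2$habitat)
  expect_identical(write_newick(ds$tree), write_newick(ds2$tree))

  # impossible change-count target errors out with advice
  expect_error(make_fixture(sim_config(q = 0, target_changes = c(5, 9),
                                       max_retries = 5, seed = 1)),
               "different q")
})

test_that("dataset round-trips through its on-disk format", {
  ds <- make_fixture(sim_config(seed = 9))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "tree.nwk", "traits.tsv", "habitat.tsv", "climate.tsv", "truth.json")))))
  back <- read_dataset(dir)
  expect_tree_equal(ds$tree, back$tree, tol = 1e-8)
  expect_equal(back$traits_raw[rownames(ds$traits_raw), ],
               ds$traits_raw, tolerance = 1e-9)
  expect_identical(back$habitat[names(ds$habitat)], ds$habitat)
})

test_that("modular_cov builds the requested block structure", {
  R <- modular_cov(letters[1:4], list(m1 = c("a", "b"), m2 = c("c", "d")),
                   within = 0.8, between = 0.1)
  expect_equal(R["a", "b"], 0.8)
  expect_equal(R["a", "c"], 0.1)
  expect_equal(diag(R), stats::setNames(rep(1, 4), letters[1:4]))
  expect_gt(min(eigen(R, only.values = TRUE)$values), 0)
})
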