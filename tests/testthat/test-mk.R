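test_that("transition matrices obey the ER closed form and limits", {
  expect_equal(mk_transition_matrix(1, "ER", 0), diag(3))
  expect_equal(mk_transition_matrix(c(1, 2, 3), "SYM", 0), diag(3))
  P <- mk_transition_matrix(1, "ER", 50)
  expect_lt(max(abs(P - 1 / 3)), 1e-12)
  # closed form against a series-expansion matrix exponential
  for (t in c(0.1, 1, 2.5)) {
    for (q in c(0.2, 1)) {
      expect_lt(max(abs(mk_transition_matrix(q, "ER", t) -
                          enum_pmatrix(q, "ER", t, 3))), 1e-9)
    }
    r <- c(0.3, 1.1, 0.6)
    expect_lt(max(abs(mk_transition_matrix(r, "SYM", t) -
                        enum_pmatrix(r, "SYM", t, 3))), 1e-9)
  }
  expect_equal(mk_transition_matrix(1, "ER", 1)[1, 1], 1 / 3 + 2 / 3 * exp(-3))
  expect_equal(rowSums(mk_transition_matrix(c(2, 1, 5), "SYM", 0.7)),
               rep(1, 3))
})

test_that("pruning log-likelihood equals exhaustive enumeration", {
  # two-tip worked case, root prior 1/3
  two <- parse_newick("(A:1,B:1);")
  st <- c(A = "CS", B = "CS")
  P <- mk_transition_matrix(1, "ER", 1)
  direct <- log(sum(sapply(1:3, function(r) (1 / 3) * P[r, 1]^2)))
  expect_equal(mk_loglik(two, st, "ER", 1), direct, tolerance = 1e-12)

  # q = 0, monomorphic data: only the matching root state contributes
  expect_equal(mk_loglik(two, st, "ER", 0), log(1 / 3))

  set.seed(21)
  for (i in 1:12) {
    tr <- simulate_yule(sample(4:6, 1), seed = 900 + i)
    st <- random_states(tr, c("CS", "HF", "WA"))
    if (i %% 2 == 0) {
      rates <- stats::runif(1, 0.1, 2); model <- "ER"
    } else {
      rates <- stats::runif(3, 0.1, 2); model <- "SYM"
    }
    expect_equal(mk_loglik(tr, st, model, rates),
                 enum_mk(tr, st, model, rates, c("CS", "HF", "WA"))$loglik,
                 tolerance = 1e-10)
  }
})

test_that("pruning likelihood is invariant to tip order and ER relabeling", {
  tr <- simulate_yule(8, seed = 3)
  st <- random_states(tr, c("CS", "HF", "WA"))
  ll <- mk_loglik(tr, st, "ER", 0.7)
  expect_equal(mk_loglik(tr, st[sample(names(st))], "ER", 0.7), ll)
  relab <- c(CS = "WA", HF = "CS", WA = "HF")[st]
  names(relab) <- names(st)
  expect_equal(mk_loglik(tr, relab, "ER", 0.7), ll)
})

test_that("ML fitting recovers rates and respects model nesting", {
  ds <- make_fixture(sim_config(seed = 6))
  er <- fit_mk(ds$tree, ds$habitat, "ER")
  sym <- fit_mk(ds$tree, ds$habitat, "SYM")
  expect_true(er$converged)
  expect_lte(er$log_likelihood, sym$log_likelihood + 1e-6)
  expect_equal(er$AIC, 2 * 1 - 2 * er$log_likelihood)
  expect_equal(sym$AIC, 2 * 3 - 2 * sym$log_likelihood)

  mono <- stats::setNames(rep("CS", 34), ds$tree$tip.label)
  flat <- fit_mk(ds$tree, mono, "ER", state_levels = c("CS", "HF", "WA"))
  expect_lt(flat$rates, 1e-6)
  expect_true(flat$boundary)

  # parameter recovery at moderate size
  tr <- simulate_yule(120, birth_rate = 3, seed = 55)
  qhat <- vapply(1:12, function(i) {
    sim <- simulate_mk(tr, 0.5, seed = 7000 + i)
    fit_mk(tr, sim$tip_states, "ER",
           state_levels = c("CS", "HF", "WA"))$rates
  }, 0)
  expect_lt(abs(stats::median(qhat) - 0.5), 0.25 * 0.5)
})

test_that("the likelihood-ratio test matches its definition", {
  out <- mk_lrt(-29.7, -27.5, df = 2)
  expect_equal(out$statistic, 4.4)
  expect_equal(out$p_value, stats::pchisq(4.4, 2, lower.tail = FALSE))

  ds <- make_fixture(sim_config(seed = 6))
  er <- fit_mk(ds$tree, ds$habitat, "ER")
  sym <- fit_mk(ds$tree, ds$habitat, "SYM")
  lrt <- mk_lrt(er, sym)
  expect_equal(lrt$df, 2L)
  expect_gte(lrt$statistic, 0)

  same <- mk_lrt(er$log_likelihood, er$log_likelihood, df = 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(mk_lrt(-5, -9, df = 2), "lower likelihood")
})

test_that("marginal ancestral states equal exact conditional probabilities", {
  # symmetric two-tip case: CS favoured, HF and WA tied by symmetry
  two <- parse_newick("(A:1,B:1);")
  asr <- ancestral_states(two, c(A = "CS", B = "CS"), "ER", rates = 0.5,
                          state_levels = c("CS", "HF", "WA"))
  root <- asr$prob[3, ]
  expect_equal(sum(root), 1)
  expect_equal(unname(root["HF"]), unname(root["WA"]), tolerance = 1e-12)
  expect_gt(root["CS"], root["HF"])
  # tips are indicators
  expect_equal(unname(asr$prob["A", ]), c(1, 0, 0))

  set.seed(31)
  for (i in 1:10) {
    tr <- simulate_yule(sample(4:6, 1), seed = 400 + i)
    st <- random_states(tr, c("CS", "HF", "WA"))
    model <- if (i %% 2) "ER" else "SYM"
    rates <- if (model == "ER") stats::runif(1, 0.2, 1.5)
             else stats::runif(3, 0.2, 1.5)
    asr <- ancestral_states(tr, st, model, rates,
                            state_levels = c("CS", "HF", "WA"))
    oracle <- enum_mk(tr, st, model, rates, c("CS", "HF", "WA"))$marginals
    internal <- asr$prob[-seq_len(ape::Ntip(tr)), , drop = FALSE]
    expect_lt(max(abs(internal - oracle)), 1e-9)
    expect_equal(rowSums(asr$prob), rep(1, nrow(asr$prob)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("transition counting works on assignments and reconstructions", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  const <- rep("CS", 5)
  expect_equal(sum(count_transitions(tr, const,
                                     state_levels = c("CS", "HF", "WA"))), 0L)

  ds <- make_fixture(sim_config(seed = 12))
  truth_counts <- count_transitions(ds$tree, ds$truth$node_states,
                                    state_levels = c("CS", "HF", "WA"))
  expect_equal(sum(truth_counts), ds$truth$n_changes)

  asr <- ancestral_states(ds$tree, ds$habitat, "ER")
  rec <- count_transitions(ds$tree, asr)
  expect_true(sum(rec) >= 1)
  expect_equal(diag(rec), stats::setNames(rep(0L, 3), c("CS", "HF", "WA")),
               ignore_attr = TRUE)
})
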