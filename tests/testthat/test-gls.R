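test_that("the lambda transform rescales only the off-diagonal", {
  C <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(C, 0.5), matrix(c(2, .5, .5, 2), 2))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
})

test_that("GLS likelihood reduces to the i.i.d. closed form and is invariant", {
  set.seed(5)
  y <- stats::rnorm(20, 3, 2)
  X <- matrix(1, 20, 1)
  out <- gls_loglik(y, X, diag(20))
  s2 <- mean((y - mean(y))^2)
  expect_equal(out$logLik, -10 * log(2 * pi * s2) - 20 / 2)
  expect_equal(unname(out$beta), mean(y))

  V <- crossprod(matrix(stats::rnorm(400), 20)) / 20 + diag(20)
  ref <- gls_loglik(y, X, V, beta = 1.5, sigma2 = 2)
  sc <- gls_loglik(y, X, 4 * V, beta = 1.5, sigma2 = 0.5)
  expect_equal(ref$logLik, sc$logLik, tolerance = 1e-10)

  # MLEs maximize: random perturbations never improve
  at_mle <- gls_loglik(y, X, V)
  for (i in 1:30) {
    worse <- gls_loglik(y, X, V, beta = at_mle$beta + stats::rnorm(1, 0, .3))
    expect_lte(worse$logLik, at_mle$logLik + 1e-10)
  }
  expect_error(gls_loglik(y, cbind(X, X), V), "rank deficient")
})

test_that("lambda endpoints match a dense-algebra likelihood oracle", {
  tr <- simulate_yule(15, seed = 61)
  x <- simulate_traits(tr, matrix(1, dimnames = list("x", "x")),
                       seed = 3)[, 1]
  C <- phylo_covariance(tr)
  dense_ll <- function(V, y) {
    n <- length(y)
    one <- rep(1, n)
    Vi <- solve(V)
    mu <- drop(t(one) %*% Vi %*% y) / drop(t(one) %*% Vi %*% one)
    r <- y - mu
    s2 <- drop(t(r) %*% Vi %*% r) / n
    -0.5 * (n * log(2 * pi * s2) +
              determinant(V)$modulus[1] + n)
  }
  f <- fit_lambda(tr, x)
  y <- x[rownames(C)]
  expect_equal(f$logLik_0, dense_ll(lambda_transform(C, 0), y),
               tolerance = 1e-8)
  expect_equal(f$logLik_1, dense_ll(C, y), tolerance = 1e-8)
  expect_gte(f$logLik, max(f$logLik_0, f$logLik_1) - 1e-6)
  # one extra parameter: AIC at the optimum within 2 of the endpoint AICs
  expect_lte(f$AIC, min(f$AIC_0, f$AIC_1) + 2 + 1e-9)
})

test_that("PGLS equals OLS on identity-like covariance structures", {
  star <- parse_newick(paste0("(", paste(sprintf("s%d:1", 1:12),
                                         collapse = ","), ");"))
  set.seed(9)
  df <- data.frame(y = stats::rnorm(12), x = stats::rnorm(12),
                   row.names = star$tip.label)
  a <- pgls(y ~ x, df, star)
  b <- pgls(y ~ x, df, star, method = "ols")
  expect_equal(coef(a), coef(b), tolerance = 1e-8)
  expect_equal(a$coef_table$se, b$coef_table$se, tolerance = 1e-8)

  # identity covariance reproduces lm() exactly
  lmfit <- stats::lm(y ~ x, df)
  expect_equal(coef(b), coef(lmfit), tolerance = 1e-10)
  s <- summary(lmfit)
  expect_equal(b$coef_table$t, unname(s$coefficients[, "t value"]),
               tolerance = 1e-9)
  expect_equal(b$F, unname(s$fstatistic["value"]), tolerance = 1e-9)
  expect_equal(b$R2, s$r.squared, tolerance = 1e-10)
})

test_that("PGLS with fixed lambda matches nlme::gls on an ultrametric tree", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule(16, seed = 13)
  X <- simulate_traits(tr, matrix(c(1, .5, .5, 1), 2,
                                  dimnames = list(c("y", "x"),
                                                  c("y", "x"))), seed = 2)
  df <- data.frame(y = X[, "y"], x = X[, "x"], row.names = rownames(X))
  mine <- pgls(y ~ x, df, tr)
  ref <- suppressWarnings(nlme::gls(y ~ x, df, correlation = ape::corPagel(
    mine$lambda, tr, form = ~1, fixed = TRUE), method = "ML"))
  expect_equal(coef(mine), coef(ref), tolerance = 1e-7)
  expect_equal(mine$logLik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-7)
  expect_equal(mine$coef_table$se,
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
})

test_that("lambda is recovered from Brownian and from star-noise data", {
  tr <- simulate_yule(80, seed = 29)
  bm_hat <- vapply(1:25, function(i)
    fit_lambda(tr, simulate_traits(tr, matrix(1, dimnames = list("x", "x")),
                                   seed = 1500 + i)[, 1])$lambda, 0)
  expect_gte(stats::median(bm_hat), 0.85)
  noise_hat <- vapply(1:25, function(i) {
    x <- stats::setNames(stats::rnorm(80), tr$tip.label)
    fit_lambda(tr, x)$lambda
  }, 0)
  expect_lte(stats::median(noise_hat), 0.15)
})

test_that("pgls fit objects expose the standard modelling methods", {
  ds <- make_fixture(sim_config(seed = 15))
  X <- preprocess_traits(ds$traits, log = FALSE)
  p <- phylo_pca(ds$tree, X)
  df <- data.frame(PC1 = p$scores[, 1],
                   habitat = factor(ds$habitat[rownames(p$scores)],
                                    levels = c("CS", "HF", "WA")),
                   row.names = rownames(p$scores))
  fit <- pgls(PC1 ~ habitat, df, ds$tree)
  expect_s3_class(fit, "pgls_fit")
  expect_named(coef(fit), c("(Intercept)", "habitatHF", "habitatWA"))
  expect_equal(fit$df_F, c(2L, 31L))
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(df$PC1),
               tolerance = 1e-10)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_equal(attr(stats::logLik(fit), "df"), fit$k)
  expect_equal(stats::AIC(fit), fit$AIC)
  nd <- data.frame(habitat = factor("HF", levels = c("CS", "HF", "WA")))
  expect_equal(unname(predict(fit, nd)),
               unname(coef(fit)[1] + coef(fit)[2]))
  expect_output(print(fit), "PGLS")
  expect_error(pgls(PC1 ~ habitat + as.factor(rownames(df)), df, ds$tree))
})
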