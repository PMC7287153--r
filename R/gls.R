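#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` is the Brownian covariance, `lambda = 0` a star
#' phylogeny (no phylogenetic signal).
#'
#' @param C Phylogenetic covariance matrix (see [phylo_covariance()]).
#' @param lambda Scalar in \[0, 1\].
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1], got ", lambda)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Gaussian GLS log-likelihood
#'
#' Log-density of `y ~ N(X beta, sigma2 V)`. When `beta` or `sigma2` are
#' omitted they are profiled out at their maximum-likelihood values
#' `beta_hat = (X' V^-1 X)^-1 X' V^-1 y` and
#' `sigma2_hat = (y - X beta_hat)' V^-1 (y - X beta_hat) / n`.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank).
#' @param V Positive-definite covariance structure.
#' @param beta,sigma2 Optional fixed parameter values.
#' @return A list with `logLik`, `beta`, `sigma2`, `rss` (whitened residual
#'   sum of squares at `beta`).
#' @export
gls_loglik <- function(y, X, V, beta = NULL, sigma2 = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n) stop("dimension mismatch")
  L <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite: ", conditionMessage(e)))
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(beta)) beta <- qr.coef(qrx, yw)
  if (!is.null(colnames(X))) names(beta) <- colnames(X)
  resw <- yw - Xw %*% beta
  rss <- sum(resw^2)
  if (is.null(sigma2)) sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + rss / sigma2)
  list(logLik = ll, beta = drop(beta), sigma2 = sigma2, rss = rss)
}

# Profile log-likelihood of lambda for response y, design X on tree cov C.
lambda_profile <- function(y, X, C, lambda) {
  gls_loglik(y, X, lambda_transform(C, lambda))$logLik
}

#' Phylogenetic signal: maximum-likelihood Pagel's lambda for one trait
#'
#' Profiles the intercept-only GLS likelihood over `lambda` in \[0, 1\]
#' (golden-section search plus explicit endpoint checks) and reports AIC at
#' the optimum (3 parameters: mean, sigma2, lambda) and at the fixed
#' endpoints `lambda = 0` and `lambda = 1` (2 parameters each), the
#' comparison used to judge whether a trait carries phylogenetic signal.
#'
#' @param tree A rooted `"phylo"` with branch lengths (>= 4 taxa).
#' @param x Named numeric vector of tip values.
#' @return An object of class `"lambda_fit"`: `lambda`, `logLik`,
#'   `logLik_0`, `logLik_1`, `AIC`, `AIC_0`, `AIC_1`.
#' @export
fit_lambda <- function(tree, x) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 4) stop("need at least 4 taxa")
  C <- phylo_covariance(tree)
  y <- x[rownames(C)]
  if (anyNA(y)) stop("missing tip values")
  X <- matrix(1, length(y), 1)
  f <- function(l) lambda_profile(y, X, C, l)
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  ll0 <- f(0); ll1 <- f(1)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll0), c(1, ll1))
  best <- cand[which.max(cand[, 2]), ]
  structure(list(lambda = best[1], logLik = best[2],
                 logLik_0 = ll0, logLik_1 = ll1,
                 AIC = 2 * 3 - 2 * best[2],
                 AIC_0 = 2 * 2 - 2 * ll0,
                 AIC_1 = 2 * 2 - 2 * ll1,
                 n = length(y)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda fit: lambda =", format(x$lambda, digits = 4),
      " logLik =", format(x$logLik, digits = 7), "\n")
  cat("  AIC(lambda-hat) =", format(x$AIC, digits = 6),
      " AIC(0) =", format(x$AIC_0, digits = 6),
      " AIC(1) =", format(x$AIC_1, digits = 6), "\n")
  invisible(x)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `formula` by GLS with error covariance given by the lambda-transformed
#' Brownian covariance of `tree` (`method = "pgls"`), or by ordinary least
#' squares with identity covariance (`method = "ols"`). With
#' `lambda = "ML"` the transform parameter is profiled jointly with the
#' regression by maximum likelihood on \[0, 1\]. Factor predictors are
#' dummy-coded against their first level (set the reference by releveling).
#'
#' Reported alongside the coefficients: per-coefficient t tests on
#' `n - p - 1` degrees of freedom (p = non-intercept columns), the overall F
#' against the intercept-only model on the GLS-whitened problem with df
#' `(p, n - p - 1)`, `R2 = 1 - RSS_w / TSS_w` on the whitened scale, and AIC
#' counting one parameter per coefficient, one for sigma2 and one for lambda
#' when it is estimated.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data A data.frame whose rownames are taxon labels.
#' @param tree A rooted `"phylo"`; tips are matched to rownames of `data`
#'   and both are reduced to their intersection.
#' @param lambda `"ML"` or a fixed value in \[0, 1\]. Ignored for
#'   `method = "ols"`.
#' @param method `"pgls"` or `"ols"`.
#' @return An object of class `"pgls_fit"`.
#' @export
pgls <- function(formula, data, tree, lambda = "ML",
                 method = c("pgls", "ols")) {
  method <- match.arg(method)
  validate_tree(tree)
  taxa <- intersect(tree$tip.label, rownames(data))
  if (length(taxa) < 3) stop("fewer than 3 taxa shared by tree and data")
  if (length(taxa) < ape::Ntip(tree)) tree <- prune_to(tree, taxa)
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- droplevels(stats::model.frame(formula, data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p_tot <- ncol(X)
  if (n <= p_tot) stop("n (", n, ") must exceed number of coefficients (",
                       p_tot, ")")
  if (qr(X)$rank < p_tot) stop("design matrix is rank deficient")
  C <- phylo_covariance(tree)
  lambda_estimated <- FALSE
  if (method == "ols") {
    V <- diag(n)
    lam <- NA_real_
  } else if (identical(lambda, "ML")) {
    f <- function(l) lambda_profile(y, X, C, l)
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(opt$maximum, opt$objective), c(0, f(0)), c(1, f(1)))
    lam <- cand[which.max(cand[, 2]), 1]
    V <- lambda_transform(C, lam)
    lambda_estimated <- TRUE
  } else {
    lam <- as.numeric(lambda)
    V <- lambda_transform(C, lam)
  }
  fit <- gls_loglik(y, X, V)
  fit0 <- gls_loglik(y, matrix(1, n, 1), V)
  p <- p_tot - 1L                       # non-intercept predictors
  df_res <- n - p_tot
  sigma2_res <- fit$rss / df_res
  L <- chol(V)
  Xw <- backsolve(L, X, transpose = TRUE)
  XtX_inv <- chol2inv(qr.R(qr(Xw)))
  vcov_beta <- sigma2_res * XtX_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  Fstat <- if (p > 0) ((fit0$rss - fit$rss) / p) / (fit$rss / df_res)
           else NA_real_
  pF <- if (p > 0) stats::pf(Fstat, p, df_res, lower.tail = FALSE)
        else NA_real_
  R2 <- 1 - fit$rss / fit0$rss
  k <- p_tot + 1L + as.integer(lambda_estimated)
  coefs <- data.frame(estimate = fit$beta, se = se, t = tval, p = pval,
                      row.names = colnames(X))
  structure(list(call = match.call(), formula = formula, method = method,
                 coefficients = fit$beta, coef_table = coefs,
                 vcov = vcov_beta, sigma2 = fit$sigma2,
                 F = Fstat, df_F = c(p, df_res), p_F = pF, R2 = R2,
                 lambda = lam, lambda_estimated = lambda_estimated,
                 logLik = fit$logLik, AIC = 2 * k - 2 * fit$logLik,
                 k = k, n = n,
                 fitted = drop(X %*% fit$beta),
                 residuals = y - drop(X %*% fit$beta),
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 taxa = tree$tip.label),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(if (x$method == "ols") "OLS" else "PGLS", "fit:",
      deparse(x$formula), "\n")
  if (x$method != "ols")
    cat("  lambda =", format(x$lambda, digits = 4),
        if (x$lambda_estimated) "(ML)" else "(fixed)", "\n")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 7),
      " AIC =", format(x$AIC, digits = 6), "\n")
  if (!is.na(x$F))
    cat("  F(", x$df_F[1], ",", x$df_F[2], ") = ",
        format(x$F, digits = 4), ", p = ", format(x$p_F, digits = 3),
        ", R2 = ", format(x$R2, digits = 3), "\n", sep = "")
  print(signif(as.matrix(x$coef_table), 4))
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
vcov.pgls_fit <- function(object, ...) object$vcov

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
fitted.pgls_fit <- function(object, ...) {
  stats::setNames(object$fitted, object$taxa)
}

#' @export
residuals.pgls_fit <- function(object, ...) {
  stats::setNames(object$residuals, object$taxa)
}

#' @export
predict.pgls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}
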