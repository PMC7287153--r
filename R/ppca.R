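#' GLS phylogenetic mean of a trait matrix
#'
#' The generalized-least-squares estimate of the root (ancestral) mean,
#' `a = (1' C^-1 1)^-1 1' C^-1 X`, one entry per trait.
#'
#' @param X Taxa x traits matrix.
#' @param C Phylogenetic covariance matrix aligned with `X` rows.
#' @return Named numeric vector over traits.
#' @export
phylo_mean <- function(X, C) {
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    if (!setequal(rownames(X), rownames(C))) stop("taxa mismatch")
    X <- X[rownames(C), , drop = FALSE]
  }
  L <- chol(C)
  onew <- backsolve(L, rep(1, nrow(X)), transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  stats::setNames(drop(crossprod(onew, Xw) / sum(onew^2)), colnames(X))
}

#' Evolutionary (GLS) trait covariance matrix
#'
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, the among-trait covariance with
#' phylogenetic structure removed; reduces to the ordinary sample covariance
#' when `C` is the identity.
#'
#' @param X Taxa x traits matrix.
#' @param C Phylogenetic covariance.
#' @param a Phylogenetic mean vector (computed if omitted).
#' @return Symmetric positive semi-definite trait covariance matrix.
#' @export
evolutionary_vcv <- function(X, C, a = NULL) {
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !is.null(rownames(C)))
    X <- X[rownames(C), , drop = FALSE]
  if (is.null(a)) a <- phylo_mean(X, C)
  Xc <- sweep(X, 2, a)
  L <- chol(C)
  Xw <- backsolve(L, Xc, transpose = TRUE)
  crossprod(Xw) / (nrow(X) - 1)
}

#' Phylogenetic principal components analysis
#'
#' Eigen-decomposition of the evolutionary covariance matrix
#' [evolutionary_vcv()]; scores are the centered data projected on the
#' eigenvectors, `(X - 1a) V`. Components are oriented deterministically so
#' that each column's largest-magnitude loading is positive. Run on
#' standardized traits (see [preprocess_traits()]) this is covariance-mode
#' PCA.
#'
#' @param tree A rooted `"phylo"` with branch lengths.
#' @param X Taxa x traits matrix (no missing values, >= 2 traits).
#' @return An object of class `"phylo_pca"`: `loadings` (trait x component),
#'   `eigenvalues`, `proportion`, `scores` (taxon x component), `mean`.
#' @export
phylo_pca <- function(tree, X) {
  validate_tree(tree)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 traits")
  if (nrow(X) < 3) stop("need at least 3 taxa")
  if (anyNA(X)) stop("missing trait values")
  C <- phylo_covariance(tree)
  X <- X[rownames(C), , drop = FALSE]
  a <- phylo_mean(X, C)
  R <- evolutionary_vcv(X, C, a)
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  cn <- paste0("PC", seq_len(ncol(V)))
  dimnames(V) <- list(colnames(X), cn)
  ev <- pmax(eig$values, 0)
  scores <- sweep(X, 2, a) %*% V
  structure(list(loadings = V, eigenvalues = ev,
                 proportion = ev / sum(ev),
                 scores = scores, mean = a, n = nrow(X)),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, digits = 3, ...) {
  cat("Phylogenetic PCA:", x$n, "taxa,", nrow(x$loadings), "traits\n")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", 100 * x$proportion), collapse = " "), "\n")
  cat("  loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' @export
summary.phylo_pca <- function(object, ...) {
  tab <- rbind(eigenvalue = object$eigenvalues,
               proportion = object$proportion,
               cumulative = cumsum(object$proportion))
  colnames(tab) <- colnames(object$loadings)
  print(round(tab, 4))
  invisible(tab)
}

#' Scatter of the first two phylogenetic PC scores
#'
#' @param x A `"phylo_pca"` object.
#' @param groups Optional named factor/character (taxon -> group) used to
#'   color points, e.g. the habitat states.
#' @param axes Which two components to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phylo_pca <- function(x, groups = NULL, axes = c(1, 2), ...) {
  s <- x$scores[, axes, drop = FALSE]
  col <- 1
  if (!is.null(groups)) {
    g <- factor(groups[rownames(s)])
    col <- as.integer(g) + 1L
  }
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * x$proportion[axes])
  graphics::plot(s, col = col, pch = 19, xlab = lab[1], ylab = lab[2], ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(g), col = seq_along(
      levels(g)) + 1L, pch = 19, bty = "n")
  invisible(x)
}
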