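#' Covariance ratio between two trait modules
#'
#' `CR = sqrt( tr(S12 S21) / sqrt( tr(S11* S11*) tr(S22* S22*) ) )`, where
#' `S12` is the between-module block of the trait covariance matrix `S` and
#' `S11*`, `S22*` are the within-module blocks with their diagonals set to
#' zero. CR near zero means modules covary less with each other than traits
#' covary within modules.
#'
#' @param S Symmetric trait covariance matrix with trait dimnames.
#' @param partition Named list of two character vectors assigning every
#'   trait of `S` to one of two modules (each >= 2 traits).
#' @return The CR value (non-negative scalar).
#' @export
cr_statistic <- function(S, partition) {
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  if (length(partition) != 2) stop("exactly 2 modules required")
  m1 <- match(partition[[1]], colnames(S))
  m2 <- match(partition[[2]], colnames(S))
  if (anyNA(m1) || anyNA(m2)) stop("partition names not in S")
  if (length(m1) < 2 || length(m2) < 2) stop("each module needs >= 2 traits")
  if (length(intersect(m1, m2)) || length(c(m1, m2)) != ncol(S))
    stop("partition must split the traits of S exactly")
  S12 <- S[m1, m2, drop = FALSE]
  S11 <- S[m1, m1, drop = FALSE]; diag(S11) <- 0
  S22 <- S[m2, m2, drop = FALSE]; diag(S22) <- 0
  denom <- sqrt(sum(S11^2) * sum(S22^2))
  if (denom == 0)
    stop("zero within-module covariance; CR undefined")
  sqrt(sum(S12^2) / sqrt(sum(S11^2) * sum(S22^2)))
}

#' Trait covariance matrix from independent contrasts
#'
#' Stacks the per-trait standardized contrasts into an `(n-1) x p` matrix and
#' returns its covariance. By default the contrasts are not mean-centered
#' (their expectation is zero under Brownian motion); divisor `n - 1`.
#'
#' @param tree A bifurcating rooted `"phylo"`.
#' @param X Taxa x traits matrix (complete).
#' @param center Center the contrasts before taking cross-products?
#' @return A `p x p` covariance matrix with trait dimnames.
#' @export
contrasts_covariance <- function(tree, X, center = FALSE) {
  X <- as.matrix(X)
  cm <- pic_matrix(tree, X)
  if (center) cm <- sweep(cm, 2, colMeans(cm))
  crossprod(cm) / nrow(cm)
}

# (n-1) x p matrix of contrasts, one column per trait.
pic_matrix <- function(tree, X) {
  out <- vapply(colnames(X), function(tr)
    pic_contrasts(tree, stats::setNames(X[, tr], rownames(X)))$contrasts,
    numeric(ape::Ntip(tree) - 1L))
  colnames(out) <- colnames(X)
  out
}

#' Permutation test of modularity via the covariance ratio
#'
#' Computes the observed CR from the contrasts covariance and builds a null
#' by reassigning traits to modules at random with module sizes fixed. The
#' test is one-tailed for low CR (modularity = less between-module covariance
#' than expected): `p = (1 + #null <= observed) / (1 + n_permutations)`.
#'
#' When the number of distinct assignments is no larger than
#' `n_permutations` the full assignment space is enumerated instead and the
#' p-value is the exact rank of the observed CR (the observed assignment is
#' one of the enumerated ones, so p >= 1/N); a warning is emitted when that
#' space is smaller than 10.
#'
#' @param tree A bifurcating rooted `"phylo"`.
#' @param X Taxa x traits matrix (standardized).
#' @param partition Named list of two trait sets (default
#'   [default_partition()]).
#' @param n_permutations Number of random permutations (>= 99).
#' @param seed Optional integer seed.
#' @param center Passed to [contrasts_covariance()].
#' @return An object of class `"cr_test"`: `cr_observed`, `p_value`,
#'   `null_cr`, `n_permutations`, `method` ("exact" or "sampled"), `seed`.
#' @export
cr_test <- function(tree, X, partition = default_partition(),
                    n_permutations = 999, seed = NULL, center = FALSE) {
  stopifnot(n_permutations >= 99)
  X <- as.matrix(X)
  S <- contrasts_covariance(tree, X, center = center)
  traits <- colnames(S)
  sizes <- lengths(partition)
  obs <- cr_statistic(S, partition)
  n_distinct <- choose(length(traits), min(sizes))
  if (sizes[1] == sizes[2]) n_distinct <- n_distinct / 2
  if (n_distinct <= n_permutations) {
    if (n_distinct < 10)
      warning("only ", n_distinct, " distinct module assignments; ",
              "exact enumeration used")
    small <- which.min(sizes)
    combs <- utils::combn(traits, sizes[small], simplify = FALSE)
    if (sizes[1] == sizes[2])
      combs <- combs[vapply(combs, function(s) traits[1] %in% s, TRUE)]
    null_cr <- vapply(combs, function(s) {
      part <- list(a = setdiff(traits, s), b = s)
      cr_statistic(S, part)
    }, 0)
    p <- sum(null_cr <= obs + 1e-12) / length(null_cr)
    method <- "exact"
    nperm <- length(null_cr)
  } else {
    null_cr <- with_local_seed(seed, vapply(seq_len(n_permutations),
      function(i) {
        s <- sample(traits)
        part <- list(a = s[seq_len(sizes[1])], b = s[-seq_len(sizes[1])])
        cr_statistic(S, part)
      }, 0))
    p <- (1 + sum(null_cr <= obs + 1e-12)) / (1 + n_permutations)
    method <- "sampled"
    nperm <- n_permutations
  }
  structure(list(cr_observed = obs, p_value = p, null_cr = null_cr,
                 n_permutations = nperm, method = method, seed = seed,
                 partition = partition, n_taxa = ape::Ntip(tree)),
            class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat("Covariance-ratio modularity test (", x$method, " null, ",
      x$n_permutations, " assignments)\n", sep = "")
  cat("  CR =", format(x$cr_observed, digits = 4),
      " p =", format(x$p_value, digits = 3),
      " (one-tailed, low CR = modular)\n")
  invisible(x)
}

#' Modularity test per clade
#'
#' Runs [cr_test()] on each clade's extracted subtree, recomputing the
#' contrasts inside the clade. Clades with fewer than 4 taxa yield an `NA`
#' entry with the reason recorded.
#'
#' @param tree A bifurcating rooted `"phylo"`.
#' @param X Taxa x traits matrix.
#' @param partition Module partition.
#' @param clades Named list of taxon vectors.
#' @param n_permutations,seed,center As in [cr_test()].
#' @return Named list of `"cr_test"` objects (or `NA` records).
#' @export
modularity_by_clade <- function(tree, X, partition = default_partition(),
                                clades, n_permutations = 999, seed = NULL,
                                center = FALSE) {
  out <- vector("list", length(clades))
  names(out) <- names(clades)
  for (i in seq_along(clades)) {
    tx <- clades[[i]]
    if (length(tx) < 4) {
      out[[i]] <- list(cr_observed = NA_real_, p_value = NA_real_,
                       reason = "fewer than 4 taxa")
      next
    }
    st <- extract_clade(tree, tx)
    out[[i]] <- cr_test(st, X[st$tip.label, , drop = FALSE], partition,
                        n_permutations = n_permutations,
                        seed = if (is.null(seed)) NULL else seed + i,
                        center = center)
  }
  out
}
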