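# Independent brute-force oracles used across the test files. These are
# deliberately naive (enumeration, recursion, dense algebra) and share no
# code with the package internals they check.

# Exhaustive Mk likelihood: sum over every joint assignment of states to the
# internal nodes, using transition probabilities computed from the generator
# by scaled Taylor series (squaring), not the package's eigen/closed forms.
enum_pmatrix <- function(rates, model, t, k) {
  Q <- matrix(0, k, k)
  if (model == "ER") Q[] <- rates[1] else {
    Q[upper.tri(Q)] <- rates; Q <- Q + t(Q)
  }
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  A <- Q * t
  s <- max(0, ceiling(log2(max(1, max(abs(A))))) + 4)
  A <- A / 2^s
  P <- diag(k); term <- diag(k)
  for (i in 1:25) { term <- term %*% A / i; P <- P + term }
  for (i in seq_len(s)) P <- P %*% P
  P
}

enum_mk <- function(tree, states, model, rates, levels) {
  k <- length(levels)
  ntip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  tipc <- match(states[tree$tip.label], levels)
  Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
    enum_pmatrix(rates, model, tree$edge.length[i], k))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  total <- 0
  node_post <- matrix(0, n_int, k)
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(tipc, grid[g, ])
    pr <- 1 / k   # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_all[tree$edge[e, 1]]
      b <- assign_all[tree$edge[e, 2]]
      pr <- pr * Ps[[e]][a, b]
    }
    total <- total + pr
    for (v in seq_len(n_int)) node_post[v, grid[g, v]] <-
        node_post[v, grid[g, v]] + pr
  }
  list(loglik = log(total), marginals = node_post / total)
}

# Recursive single-trait BM simulator (per-branch normal increments).
brute_bm <- function(tree, sigma2 = 1) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  x <- numeric(n_all)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    e <- pre$edge[i, ]
    x[e[2]] <- x[e[1]] + stats::rnorm(1, 0, sqrt(sigma2 * pre$edge.length[i]))
  }
  stats::setNames(x[seq_len(ape::Ntip(tree))], tree$tip.label)
}

# Depth of a Yule tree under the package's convention, simulated directly.
brute_yule_depth <- function(n, birth) {
  t <- 0; k <- 2
  while (k < n) { t <- t + stats::rexp(1, k * birth); k <- k + 1 }
  t + stats::rexp(1, n * birth)
}

# Element-wise covariance-ratio computation via explicit loops.
brute_cr <- function(S, m1, m2) {
  num <- 0
  for (i in m1) for (j in m2) num <- num + S[i, j]^2
  d1 <- 0
  for (i in m1) for (j in m1) if (i != j) d1 <- d1 + S[i, j]^2
  d2 <- 0
  for (i in m2) for (j in m2) if (i != j) d2 <- d2 + S[i, j]^2
  sqrt(num / sqrt(d1 * d2))
}

# Random PSD trait covariance with dimnames.
random_cov <- function(p, names_ = paste0("x", seq_len(p))) {
  A <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(A) / p
  dimnames(S) <- list(names_, names_)
  S
}

# Random tip states guaranteed to include >= 2 distinct states.
random_states <- function(tree, levels) {
  repeat {
    s <- sample(levels, ape::Ntip(tree), replace = TRUE)
    if (length(unique(s)) >= 2) break
  }
  stats::setNames(s, tree$tip.label)
}

expect_tree_equal <- function(a, b, tol = 1e-8) {
  testthat::expect_setequal(a$tip.label, b$tip.label)
  da <- ape::cophenetic.phylo(a); db <- ape::cophenetic.phylo(b)
  db <- db[rownames(da), colnames(da)]
  testthat::expect_lt(max(abs(da - db)), tol)
}
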