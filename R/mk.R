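#' Mk transition probability matrix
#'
#' For the equal-rates (ER) model the closed form is used:
#' `P_ii = 1/K + (1 - 1/K) exp(-K q t)`, `P_ij = 1/K - (1/K) exp(-K q t)`.
#' For the symmetric (SYM) model the generator `Q` (off-diagonal `q_ij`,
#' diagonal minus the row sum) is exponentiated through its symmetric
#' eigendecomposition.
#'
#' @param rates ER: a single rate `q`. SYM: `K(K-1)/2` rates in the order of
#'   the upper triangle (1,2), (1,3), ..., (2,3), ...
#' @param model `"ER"` or `"SYM"`.
#' @param t Branch length (>= 0).
#' @param k Number of states.
#' @return A `k x k` row-stochastic matrix.
#' @export
mk_transition_matrix <- function(rates, model = c("ER", "SYM"), t, k = 3) {
  model <- match.arg(model)
  stopifnot(t >= 0, all(rates >= 0))
  if (model == "ER") {
    stopifnot(length(rates) == 1L)
    q <- rates
    e <- exp(-k * q * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- 1 / k + (1 - 1 / k) * e
    return(P)
  }
  Q <- mk_generator(rates, model, k)
  eig <- eigen(Q, symmetric = TRUE)
  P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  P[P < 0] <- 0                     # clip tiny negative round-off
  P / rowSums(P)
}

# Generator matrix for ER/SYM. SYM rates fill the upper triangle by column
# (pair order (1,2), (1,3), (2,3), ...), mirrored below; ER uses one rate.
mk_generator <- function(rates, model, k) {
  Q <- matrix(0, k, k)
  if (model == "ER") {
    Q[] <- rates[1]
  } else {
    if (length(rates) != k * (k - 1) / 2)
      stop("SYM needs ", k * (k - 1) / 2, " rates")
    Q[upper.tri(Q)] <- rates
    Q <- Q + t(Q)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Align a named character state vector with tree tips; returns integer codes.
check_states <- function(tree, states, state_levels) {
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips missing from the character: ", paste(miss, collapse = ", "))
  st <- states[tree$tip.label]
  bad <- setdiff(unique(st), state_levels)
  if (length(bad))
    stop("states not in the declared list: ", paste(bad, collapse = ", "))
  match(st, state_levels)
}

# Felsenstein pruning: per-node conditional (down) partials, each node's
# vector rescaled to max 1 with the log scaling factor accumulated, so deep
# trees cannot underflow.
mk_partials <- function(tree, tip_codes, Plist, k) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  down <- matrix(0, n_all, k)
  down[cbind(seq_len(ntip), tip_codes)] <- 1
  logscale <- numeric(n_all)
  post <- ape::reorder.phylo(tree, "postorder")
  eidx <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  # ape postorder lists all edges of a parent consecutively, children first
  parents <- unique(post$edge[, 1])
  edges_of <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  for (v in parents) {
    d <- rep(1, k)
    ls <- 0
    for (r in edges_of[[as.character(v)]]) {
      chi <- post$edge[r, 2]
      d <- d * drop(Plist[[eidx[r]]] %*% down[chi, ])
      ls <- ls + logscale[chi]
    }
    m <- max(d)
    if (m <= 0) stop("likelihood underflow: data impossible under model")
    down[v, ] <- d / m
    logscale[v] <- ls + log(m)
  }
  list(down = down, logscale = logscale)
}

# Transition matrices for every edge of the tree under (model, rates).
# The generator is shared by all edges, so it is decomposed once.
edge_pmatrices <- function(tree, rates, model, k) {
  if (model == "ER") {
    return(lapply(tree$edge.length, function(t)
      mk_transition_matrix(rates, "ER", t, k)))
  }
  eig <- eigen(mk_generator(rates, model, k), symmetric = TRUE)
  U <- eig$vectors
  lapply(tree$edge.length, function(t) {
    P <- U %*% (exp(eig$values * t) * t(U))
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Tip partial likelihoods are indicator vectors; the root is weighted by a
#' uniform prior `1/K`. Returned in nats.
#'
#' @param tree A bifurcating (or multifurcating) rooted `"phylo"`.
#' @param states Named character vector: taxon -> state.
#' @param model `"ER"` or `"SYM"`.
#' @param rates Rate parameter(s), see [mk_transition_matrix()].
#' @param state_levels Ordered state labels (default: the habitat states
#'   CS, HF, WA, or the sorted observed states if others are present).
#' @return The log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, states, model = c("ER", "SYM"), rates,
                      state_levels = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(state_levels)) state_levels <- infer_levels(states)
  k <- length(state_levels)
  codes <- check_states(tree, states, state_levels)
  Plist <- edge_pmatrices(tree, rates, model, k)
  pr <- mk_partials(tree, codes, Plist, k)
  root <- ape::Ntip(tree) + 1L
  log(sum(pr$down[root, ] / k)) + pr$logscale[root]
}

infer_levels <- function(states) {
  if (all(unique(states) %in% default_states())) default_states()
  else sort(unique(as.character(states)))
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale within `[1e-8, 1e3]`. The ER model
#' uses a 10-point log-spaced start grid refined by golden-section search;
#' SYM uses L-BFGS-B from the same grid of equal-rates starts plus the ER
#' solution, so the SYM optimum can never fall below the ER optimum.
#'
#' @param tree A rooted `"phylo"` with branch lengths.
#' @param states Named character vector taxon -> state.
#' @param model `"ER"` or `"SYM"`.
#' @param state_levels Ordered state labels.
#' @return An object of class `"mk_fit"`: fields `model`, `rates`,
#'   `log_likelihood`, `n_param`, `AIC`, `converged`, `boundary`,
#'   `state_levels`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "SYM"),
                   state_levels = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(state_levels)) state_levels <- infer_levels(states)
  k <- length(state_levels)
  lo <- log(1e-8); hi <- log(1e3)
  nll <- function(logr) -mk_loglik(tree, states, model, exp(logr),
                                   state_levels)
  n_obs_states <- length(unique(states[tree$tip.label]))
  if (model == "ER") {
    grid <- seq(lo, hi, length.out = 10)
    vals <- vapply(grid, nll, 0)
    b <- which.min(vals)
    lower <- grid[max(1, b - 1)]; upper <- grid[min(length(grid), b + 1)]
    opt <- stats::optimize(nll, c(lower, upper), tol = 1e-10)
    # guard against a better endpoint
    cand <- rbind(c(opt$minimum, opt$objective), cbind(grid, vals))
    best <- cand[which.min(cand[, 2]), ]
    rates <- exp(best[1]); ll <- -best[2]; conv <- TRUE
  } else {
    np <- k * (k - 1) / 2
    starts <- lapply(seq(lo, log(10), length.out = 9),
                     function(g) rep(g, np))
    er <- fit_mk(tree, states, "ER", state_levels)
    starts <- c(starts, list(rep(log(max(er$rates, 1e-8)), np)))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(s, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("SYM optimization failed from every start")
    rates <- exp(best$par); ll <- -best$value
    conv <- best$convergence == 0
    if (ll < er$log_likelihood - 1e-6) {  # nested model safety net
      rates <- rep(er$rates, np); ll <- er$log_likelihood
    }
  }
  n_param <- if (model == "ER") 1L else as.integer(k * (k - 1) / 2)
  boundary <- any(rates <= 2e-8 | rates >= 0.9e3) || n_obs_states < 2
  structure(list(model = model, rates = unname(rates),
                 log_likelihood = ll, n_param = n_param,
                 AIC = 2 * n_param - 2 * ll,
                 converged = conv, boundary = boundary,
                 state_levels = state_levels, n_tips = ape::Ntip(tree)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, ", K = ", length(x$state_levels), ")\n",
      sep = "")
  cat("  rates:", paste(signif(x$rates, 5), collapse = " "), "\n")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 7),
      "  AIC:", format(x$AIC, digits = 7), "\n")
  if (x$boundary) cat("  note: estimate at parameter boundary\n")
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_param, class = "logLik")
}

#' Likelihood-ratio test between nested Mk fits
#'
#' `statistic = 2 (lnL_general - lnL_restricted)`; small negative values
#' (within 1e-8) are clipped to zero, larger ones raise an error since they
#' signal optimizer failure. Degrees of freedom come from the difference in
#' free parameter counts; the p-value is the chi-square upper tail.
#'
#' @param restricted,general `"mk_fit"` objects, or bare log-likelihoods (in
#'   which case `df` must be supplied).
#' @param df Optional explicit degrees of freedom.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
mk_lrt <- function(restricted, general, df = NULL) {
  ll <- function(f) if (inherits(f, "mk_fit")) f$log_likelihood
                    else as.numeric(f)
  np <- function(f) if (inherits(f, "mk_fit")) f$n_param else NA_integer_
  stat <- 2 * (ll(general) - ll(restricted))
  if (stat < -1e-8)
    stop("general model has lower likelihood than restricted (", stat,
         "); optimizer failure")
  stat <- max(stat, 0)
  if (is.null(df)) {
    df <- np(general) - np(restricted)
    if (is.na(df)) stop("df must be supplied for non-fit inputs")
  }
  if (df <= 0) stop("restricted model must have fewer parameters")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Marginal ancestral state probabilities
#'
#' Computes, for every node, `P(state | all tip data)` under the fitted Mk
#' model with a uniform root prior, holding the rates fixed (empirical
#' Bayes). The computation is the two-pass message-passing form of the
#' re-rooting method: downward pruning partials are combined with upward
#' messages, which for the symmetric ER/SYM generators is exactly equivalent
#' to re-rooting the tree at each node and reading off the root marginals.
#' Tip rows are the observed indicator vectors.
#'
#' @param tree A rooted `"phylo"` with branch lengths.
#' @param states Named character vector taxon -> state.
#' @param model `"ER"` or `"SYM"`.
#' @param rates Fitted rates; if `NULL` the model is fitted first.
#' @param state_levels Ordered state labels.
#' @return An object of class `"ancestral_states"`: `prob` (rows = all nodes
#'   in ape numbering, tips first; columns = states), `states` (most probable
#'   state per node, ties broken by state order with a warning), `fit`.
#' @export
ancestral_states <- function(tree, states, model = c("ER", "SYM"),
                             rates = NULL, state_levels = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(state_levels)) state_levels <- infer_levels(states)
  k <- length(state_levels)
  fit <- NULL
  if (is.null(rates)) {
    fit <- fit_mk(tree, states, model, state_levels)
    rates <- fit$rates
  }
  codes <- check_states(tree, states, state_levels)
  Plist <- edge_pmatrices(tree, rates, model, k)
  pr <- mk_partials(tree, codes, Plist, k)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  root <- ntip + 1L
  # upward messages, preorder; up[root] = uniform prior
  up <- matrix(0, n_all, k)
  up[root, ] <- 1 / k
  child_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  ord <- reorder_edges_preorder(tree)
  msg <- vector("list", nrow(tree$edge))   # P(t_c) %*% down[c] per edge
  for (i in seq_len(nrow(tree$edge)))
    msg[[i]] <- drop(Plist[[i]] %*% pr$down[tree$edge[i, 2], ])
  for (kk in ord) {
    par <- tree$edge[kk, 1]; chi <- tree$edge[kk, 2]
    sibs <- setdiff(child_of[[as.character(par)]], kk)
    G <- up[par, ]
    for (s in sibs) G <- G * msg[[s]]
    u <- drop(crossprod(Plist[[kk]], G))
    tot <- sum(u)
    up[chi, ] <- if (tot > 0) u / tot else u
  }
  prob <- pr$down * up
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list(c(tree$tip.label,
                           (ntip + 1L):n_all), state_levels)
  mx <- apply(prob, 1, max)
  ties <- rowSums(abs(prob - mx) < 1e-12) > 1
  if (any(ties[(ntip + 1L):n_all]))
    warning("tied marginal probabilities at ",
            sum(ties[(ntip + 1L):n_all]),
            " node(s); broken by state order")
  best <- state_levels[apply(prob, 1, which.max)]
  structure(list(prob = prob, states = stats::setNames(best, rownames(prob)),
                 model = model, rates = rates, state_levels = state_levels,
                 fit = fit, n_tips = ntip),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, digits = 3, ...) {
  cat("Marginal ancestral states (", x$model, " model, rates ",
      paste(signif(x$rates, 4), collapse = " "), ")\n", sep = "")
  internal <- x$prob[-seq_len(x$n_tips), , drop = FALSE]
  print(round(utils::head(internal, 8), digits))
  if (nrow(internal) > 8) cat("  ... ", nrow(internal) - 8, " more nodes\n")
  invisible(x)
}

#' Count state transitions along a tree
#'
#' Given a state assignment for every node (for instance the most probable
#' states from [ancestral_states()], or the true states of a simulation),
#' counts parent -> child changes along every edge, keyed by ordered state
#' pair.
#'
#' @param tree A rooted `"phylo"`.
#' @param node_states Character vector of states for all nodes (tips first,
#'   ape numbering), or an `"ancestral_states"` object.
#' @param state_levels Ordered state labels.
#' @return A `K x K` matrix of counts (`from` in rows, `to` in columns;
#'   diagonal zero).
#' @export
count_transitions <- function(tree, node_states, state_levels = NULL) {
  validate_tree(tree)
  if (inherits(node_states, "ancestral_states")) {
    if (is.null(state_levels)) state_levels <- node_states$state_levels
    node_states <- node_states$states
  }
  if (is.null(state_levels)) state_levels <- infer_levels(node_states)
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (length(node_states) != n_all)
    stop("need one state per node (", n_all, "), got ", length(node_states))
  K <- length(state_levels)
  out <- matrix(0L, K, K, dimnames = list(from = state_levels,
                                          to = state_levels))
  from <- match(node_states[tree$edge[, 1]], state_levels)
  to <- match(node_states[tree$edge[, 2]], state_levels)
  for (i in seq_along(from))
    if (from[i] != to[i]) out[from[i], to[i]] <- out[from[i], to[i]] + 1L
  out
}
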