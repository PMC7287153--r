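#' Log-transform and z-standardize a trait matrix
#'
#' Natural log followed by a per-column z-score (mean 0, SD 1 across taxa),
#' the scale on which contrasts, rates and the PCA are computed. Set
#' `log = FALSE` for data already on a log scale.
#'
#' @param x Taxa x traits numeric matrix with row and column names; raw
#'   values must be strictly positive when `log = TRUE`.
#' @param log Apply the natural log first?
#' @return A matrix of the same shape, attribute `scale = "log-z"`.
#' @export
preprocess_traits <- function(x, log = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("trait matrix needs row (taxon) and column (trait) names")
  if (log) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive trait value: taxon ", rownames(x)[bad[1, 1]],
           ", trait ", colnames(x)[bad[1, 2]])
    x <- base::log(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scale") <- "log-z"
  out
}

#' Phylogenetically independent contrasts for one trait
#'
#' Felsenstein's pruning algorithm: at an internal node with children values
#' `(x_i, x_j)` on working branch lengths `(b_i, b_j)` the standardized
#' contrast is `(x_i - x_j) / sqrt(b_i + b_j)`, the node estimate is the
#' branch-length-weighted average, and the node's parent branch is lengthened
#' by `b_i b_j / (b_i + b_j)`.
#'
#' @param tree A strictly bifurcating rooted `"phylo"` with branch lengths
#'   (resolve polytomies first, see [resolve_polytomies()]).
#' @param x Named numeric vector of tip values (all tips present).
#' @return A list of class `"contrast_set"`: `contrasts` (n-1 values, named
#'   by internal node number), `node_values`, `adjusted_bl`, `n_taxa`.
#' @export
pic_contrasts <- function(tree, x) {
  validate_tree(tree)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree has polytomies; run resolve_polytomies() first")
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("tips without a value: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  val <- numeric(n_all)
  val[seq_len(ntip)] <- x[tree$tip.label]
  wbl <- numeric(n_all)                    # working branch length above node
  wbl[tree$edge[, 2]] <- tree$edge.length
  contrasts <- numeric(tree$Nnode)
  names(contrasts) <- (ntip + 1L):n_all
  post <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(post$edge[, 1])
  kids <- split(post$edge[, 2], post$edge[, 1])
  for (v in parents) {
    ch <- kids[[as.character(v)]]
    bi <- wbl[ch[1]]; bj <- wbl[ch[2]]
    if (bi + bj <= 0)
      stop("zero summed sibling branch lengths at node ", v)
    contrasts[as.character(v)] <-
      (val[ch[1]] - val[ch[2]]) / sqrt(bi + bj)
    val[v] <- (val[ch[1]] / bi + val[ch[2]] / bj) / (1 / bi + 1 / bj)
    wbl[v] <- wbl[v] + bi * bj / (bi + bj)
  }
  structure(list(contrasts = contrasts,
                 node_values = stats::setNames(val[(ntip + 1L):n_all],
                                               (ntip + 1L):n_all),
                 adjusted_bl = stats::setNames(wbl, seq_len(n_all)),
                 n_taxa = ntip),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Independent contrasts:", length(x$contrasts), "contrasts from",
      x$n_taxa, "taxa\n")
  print(summary(unname(x$contrasts)))
  invisible(x)
}

#' Brownian-motion evolutionary rate from contrasts
#'
#' The rate statistic `beta = sum(c_i^2) / (n - 1)`, where the `c_i` are the
#' n - 1 standardized contrasts and n the number of taxa. Under Brownian
#' motion with rate sigma^2 this is an unbiased estimator of sigma^2.
#'
#' @param contrasts A `"contrast_set"` (or numeric vector of contrasts).
#' @param n_taxa Taxa count; taken from the contrast set when omitted.
#' @return The rate estimate (numeric scalar, trait units^2 per unit branch
#'   length).
#' @export
bm_rate <- function(contrasts, n_taxa = NULL) {
  if (inherits(contrasts, "contrast_set")) {
    n_taxa <- contrasts$n_taxa
    contrasts <- contrasts$contrasts
  }
  if (is.null(n_taxa)) n_taxa <- length(contrasts) + 1L
  if (length(contrasts) < 2) stop("need at least 2 contrasts")
  sum(contrasts^2) / (n_taxa - 1)
}

#' F test for a rate difference between two contrast sets
#'
#' `F = beta_a / beta_b` with degrees of freedom `(n_a - 1, n_b - 1)`. The
#' p-value is two-tailed: `2 min(P(F <= f), P(F >= f))`, capped at 1. Under
#' Brownian motion the contrasts are i.i.d. normal so F is exactly
#' F-distributed when the rates are equal.
#'
#' @param a,b `"contrast_set"` objects from disjoint trees (clades) or for
#'   different traits.
#' @return A list with `F`, `df`, `p_value`, `rates`.
#' @export
rate_ratio_test <- function(a, b) {
  ba <- bm_rate(a); bb <- bm_rate(b)
  if (bb == 0) stop("zero rate in denominator")
  f <- ba / bb
  df <- c(a$n_taxa - 1L, b$n_taxa - 1L)
  p <- 2 * min(stats::pf(f, df[1], df[2]),
               stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, df = df, p_value = min(p, 1), rates = c(ba, bb))
}

#' Evolutionary rates per trait, overall and per clade
#'
#' For each trait, the contrast rate on the full tree and inside each clade
#' subtree (contrasts recomputed within the clade). Clades are compared
#' pairwise with [rate_ratio_test()] at level `alpha` and summarized with
#' shared/distinct group letters (clades that are not significantly different
#' share a letter); no multiplicity correction is applied.
#'
#' @param tree A bifurcating rooted `"phylo"`.
#' @param traits Taxa x traits matrix (already standardized, see
#'   [preprocess_traits()]; standardization happens on the full taxon set so
#'   clade rates are comparable).
#' @param clades Named list of taxon vectors (each >= 4 taxa; smaller clades
#'   yield NA entries).
#' @param alpha Significance level for the letters.
#' @return A data.frame with one row per trait: total rate, per-clade rates,
#'   and per-clade letters.
#' @export
rates_table <- function(tree, traits, clades, alpha = 0.05) {
  traits <- as.matrix(traits)
  subtrees <- lapply(clades, function(tx)
    if (length(tx) >= 4) extract_clade(tree, tx) else NULL)
  rows <- lapply(colnames(traits), function(tr) {
    x <- stats::setNames(traits[, tr], rownames(traits))
    cs_all <- pic_contrasts(tree, x)
    cs_clade <- lapply(subtrees, function(st)
      if (is.null(st)) NULL else pic_contrasts(st, x[st$tip.label]))
    betas <- vapply(cs_clade, function(cs)
      if (is.null(cs)) NA_real_ else bm_rate(cs), 0)
    ok <- !vapply(cs_clade, is.null, TRUE)
    pmat <- matrix(NA_real_, length(clades), length(clades))
    for (i in seq_along(clades)) for (j in seq_along(clades))
      if (i < j && ok[i] && ok[j])
        pmat[i, j] <- pmat[j, i] <-
          rate_ratio_test(cs_clade[[i]], cs_clade[[j]])$p_value
    letters_ <- group_letters(pmat, alpha)
    letters_[!ok] <- NA_character_
    out <- data.frame(trait = tr, total = bm_rate(cs_all),
                      stringsAsFactors = FALSE)
    for (i in seq_along(clades)) {
      out[[paste0("rate_", names(clades)[i])]] <- betas[i]
      out[[paste0("letter_", names(clades)[i])]] <- letters_[i]
    }
    out
  })
  do.call(rbind, rows)
}

# Compact letter display from a pairwise p-value matrix: groups are the
# maximal cliques of the "not significantly different" graph, lettered in
# order of appearance.
group_letters <- function(pmat, alpha) {
  k <- nrow(pmat)
  adj <- !is.na(pmat) & pmat >= alpha
  diag(adj) <- TRUE
  # enumerate maximal cliques (k is tiny: the number of clades)
  subsets <- lapply(seq_len(2^k) - 1L, function(m) which(bitwAnd(
    m, 2^(seq_len(k) - 1L)) > 0))
  is_clique <- vapply(subsets, function(s)
    length(s) > 0 && all(adj[s, s, drop = FALSE]), TRUE)
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(cliques, function(s)
    !any(vapply(cliques, function(t)
      length(t) > length(s) && all(s %in% t), TRUE)), TRUE)]
  out <- rep("", k)
  for (i in seq_along(maximal))
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  out
}
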