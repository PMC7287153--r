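#' Simulate a pure-birth (Yule) tree
#'
#' Lineages start at the root split (two lineages at time 0). While k
#' lineages are extant the waiting time to the next split is
#' Exponential(k * birth_rate) and the splitting lineage is chosen uniformly;
#' after the n-th tip appears a final Exponential(n * birth_rate) interval
#' runs to the present, so every tip ends at the same time and the tree is
#' ultrametric and strictly bifurcating.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param tip_prefix Prefix for tip labels (`t1`, `t2`, ...).
#' @return An ultrametric `"phylo"` object with `n_taxa` tips.
#' @export
simulate_yule <- function(n_taxa, birth_rate = 1, seed = NULL,
                          tip_prefix = "t") {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  with_local_seed(seed, {
    maxid <- 2L
    parent <- c(0L, 0L)       # parent lineage id (0 = root)
    btime <- c(0, 0)          # time the branch leading to this id started
    split_time <- c(NA_real_, NA_real_)
    children <- list(NULL, NULL)
    active <- c(1L, 2L)
    t <- 0
    k <- 2L
    while (k < n_taxa) {
      t <- t + stats::rexp(1, rate = k * birth_rate)
      j <- active[sample.int(k, 1L)]
      c1 <- maxid + 1L; c2 <- maxid + 2L; maxid <- maxid + 2L
      parent[c(c1, c2)] <- j
      btime[c(c1, c2)] <- t
      split_time[c(c1, c2)] <- NA_real_
      children[[j]] <- c(c1, c2)
      children[c1] <- list(NULL); children[c2] <- list(NULL)
      split_time[j] <- t
      active <- c(setdiff(active, j), c1, c2)
      k <- k + 1L
    }
    present <- t + stats::rexp(1, rate = k * birth_rate)
    # assemble Newick from the recorded splits
    lab <- character(maxid)
    lab[active] <- paste0(tip_prefix, seq_len(n_taxa))
    nk <- function(id) {
      len <- if (is.null(children[[id]])) present - btime[id]
             else split_time[id] - btime[id]
      body <- if (is.null(children[[id]])) lab[id]
              else paste0("(", nk(children[[id]][1]), ",",
                          nk(children[[id]][2]), ")")
      paste0(body, ":", format(len, digits = 15))
    }
    txt <- paste0("(", nk(1L), ",", nk(2L), ");")
    parse_newick(txt)
  })
}

#' Simulate a discrete character under an equal-rates Mk process
#'
#' The root state is drawn uniformly; along each branch of length t the child
#' state is sampled exactly from the analytic ER transition matrix
#' (off-diagonal rate `q`, diagonal `-(K-1) q`), so no branch discretization
#' is involved.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param q ER transition rate per unit branch length (>= 0).
#' @param states Ordered state labels (default the three habitat classes).
#' @param seed Optional integer seed.
#' @return A list with `tip_states` (named character vector over tips),
#'   `node_states` (true states of all nodes, tips first, ape numbering),
#'   `n_changes` (number of edges on which the state changed), `q`, `states`.
#' @export
simulate_mk <- function(tree, q, states = c("CS", "HF", "WA"), seed = NULL) {
  validate_tree(tree)
  stopifnot(q >= 0, length(states) >= 2)
  K <- length(states)
  with_local_seed(seed, {
    n_all <- ape::Ntip(tree) + tree$Nnode
    st <- integer(n_all)
    root <- ape::Ntip(tree) + 1L
    st[root] <- sample.int(K, 1L)
    ord <- reorder_edges_preorder(tree)
    for (kk in ord) {
      e <- tree$edge[kk, ]
      P <- mk_transition_matrix(q, model = "ER", t = tree$edge.length[kk],
                                k = K)
      st[e[2]] <- sample.int(K, 1L, prob = P[st[e[1]], ])
    }
    tips <- seq_len(ape::Ntip(tree))
    tip_states <- stats::setNames(states[st[tips]], tree$tip.label)
    n_changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    list(tip_states = tip_states,
         node_states = states[st],
         n_changes = n_changes, q = q, states = states)
  })
}

#' Simulate correlated traits under Brownian motion with per-trait lambda
#'
#' Tip values for trait j are `L_j w_j`, where `L_j` is the Cholesky factor of
#' the lambda-transformed phylogenetic covariance `C_lambda_j` and the columns
#' `w_j` are standard normal vectors carrying the among-trait covariance `R`
#' (`cov(w_j, w_k) = R[j,k] I`). Each trait's marginal among-taxa covariance
#' is therefore exactly `R[j,j] * C_lambda_j`; with all lambda equal to 1 this
#' is the usual matrix-normal Brownian model with Kronecker covariance.
#'
#' @param tree A rooted `"phylo"` object.
#' @param R Trait evolutionary covariance (p x p, symmetric positive
#'   definite), units of squared log-trait per unit branch length.
#' @param lambda Per-trait Pagel's lambda in \[0, 1\] (recycled if length 1).
#' @param seed Optional integer seed.
#' @return A taxa x traits numeric matrix (log-trait scale), rows named by
#'   tip label, columns by `colnames(R)`.
#' @export
simulate_traits <- function(tree, R, lambda = 1, seed = NULL) {
  validate_tree(tree)
  R <- as.matrix(R)
  p <- ncol(R)
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("R must be symmetric")
  A <- tryCatch(chol(R), error = function(e)
    stop("R must be positive definite: ", conditionMessage(e)))
  lambda <- rep_len(lambda, p)
  if (any(lambda < 0 | lambda > 1)) stop("lambda entries must be in [0, 1]")
  C <- phylo_covariance(tree)
  n <- nrow(C)
  with_local_seed(seed, {
    W <- matrix(stats::rnorm(n * p), n, p) %*% A
    X <- matrix(0, n, p, dimnames = list(rownames(C), colnames(R)))
    for (j in seq_len(p)) {
      Cl <- lambda_transform(C, lambda[j])
      X[, j] <- t(chol(Cl)) %*% W[, j]
    }
    X
  })
}

# Recursive BM simulator with a branch-specific rate matrix: edges inside a
# named clade use that clade's R, all other (backbone) edges use R_backbone.
# Used for scenarios in which clades differ in their integration structure.
simulate_traits_by_clade <- function(tree, clade_R, clades,
                                     R_backbone, seed = NULL) {
  validate_tree(tree)
  p <- ncol(R_backbone)
  chol_back <- chol(R_backbone)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  # nodes belonging to each clade = all nodes strictly below the clade MRCA
  edge_chol <- vector("list", nrow(tree$edge))
  member <- rep(NA_character_, n_all)
  for (nm in names(clades)) {
    mrca <- if (length(clades[[nm]]) == 1L)
      match(clades[[nm]], tree$tip.label) else ape::getMRCA(tree, clades[[nm]])
    desc <- descendant_nodes(tree, mrca)
    member[desc] <- nm
  }
  chol_by_clade <- lapply(clade_R, chol)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    edge_chol[[k]] <- if (!is.na(member[child]))
      chol_by_clade[[member[child]]] else chol_back
  }
  with_local_seed(seed, {
    x <- matrix(0, n_all, p)
    ord <- reorder_edges_preorder(tree)
    for (k in ord) {
      e <- tree$edge[k, ]
      z <- stats::rnorm(p) * sqrt(tree$edge.length[k])
      x[e[2], ] <- x[e[1], ] + drop(crossprod(edge_chol[[k]], z))
    }
    out <- x[seq_len(ntip), , drop = FALSE]
    dimnames(out) <- list(tree$tip.label, colnames(R_backbone))
    out
  })
}

# All nodes (tips + internals) in the subtree rooted at `node`, inclusive
# of node itself except when node is the tree root.
descendant_nodes <- function(tree, node) {
  post <- ape::reorder.phylo(tree, "postorder")
  inset <- logical(ape::Ntip(tree) + tree$Nnode)
  inset[node] <- TRUE
  ord <- rev(seq_len(nrow(post$edge)))  # preorder over postorder-stored edges
  for (k in ord) {
    e <- post$edge[k, ]
    if (inset[e[1]]) inset[e[2]] <- TRUE
  }
  which(inset)
}

#' Build a modular trait covariance matrix
#'
#' Block covariance: unit variances, correlation `within` between traits of
#' the same module, `between` across modules.
#'
#' @param trait_names Character vector of trait names.
#' @param modules Named list of two character vectors partitioning
#'   `trait_names`.
#' @param within,between Correlations inside / across modules.
#' @param var Common trait variance (rate per unit branch length).
#' @return A p x p covariance matrix with dimnames.
#' @export
modular_cov <- function(trait_names, modules, within = 0.6, between = 0,
                        var = 1) {
  stopifnot(setequal(unlist(modules), trait_names))
  p <- length(trait_names)
  R <- matrix(between * var, p, p,
              dimnames = list(trait_names, trait_names))
  for (m in modules) {
    idx <- match(m, trait_names)
    R[idx, idx] <- within * var
  }
  diag(R) <- var
  R
}

default_trait_names <- function() c("PH", "LA", "LMA", "LT", "LD", "AR", "RSR")
default_states <- function() c("CS", "HF", "WA")
slow_traits <- function() c("LMA", "LT", "LD", "RSR")

#' Default module partition used in the modularity analyses
#'
#' `LEAF` holds the five leaf traits (LA, LMA, LT, LD, AR); `LIFEFORM` holds
#' plant height and root-to-shoot ratio.
#' @return Named list of two character vectors.
#' @export
default_partition <- function() {
  list(LEAF = c("LA", "LMA", "LT", "LD", "AR"),
       LIFEFORM = c("PH", "RSR"))
}

#' Simulation configuration for the synthetic study fixture
#'
#' Defaults emulate the study design the pipeline targets: 34 taxa in three
#' clades (10/12/12), a three-state habitat evolving under an equal-rates Mk
#' process calibrated to show a handful of transitions, and seven log-scale
#' traits evolving under modular multivariate Brownian motion (blocks
#' LMA/LT/LD/RSR and PH/LA/AR, zero covariance between blocks) with an
#' additive "slow strategy" shift on LMA, LT, LD and RSR for cold-steppe (CS)
#' taxa. AR evolves with lambda = 0, all other traits with lambda = 1.
#'
#' @param n_taxa Total number of taxa.
#' @param clade_sizes Sizes of the three clades (must sum to `n_taxa`).
#' @param birth_rate Yule rate for the clade subtrees.
#' @param q ER habitat transition rate per unit branch length.
#' @param states Habitat state labels.
#' @param trait_names Trait labels.
#' @param R Trait evolutionary covariance; default modular as described.
#' @param lambda Per-trait lambda; default 0 for AR, 1 otherwise.
#' @param habitat_effects states x traits matrix of additive log-trait shifts;
#'   default +`delta_cs` on the slow-strategy traits for CS.
#' @param delta_cs Size of the CS shift (log-trait units).
#' @param target_changes Acceptable range for the number of true habitat
#'   changes (the habitat history is redrawn until it lands in this range).
#' @param max_retries Redraw budget for the habitat history.
#' @param clade_R Optional named list of per-clade trait covariances (clades
#'   "I", "II", "III"); when given, traits are simulated branch-wise with the
#'   clade's R inside each clade and `R` on the backbone, and `lambda` must
#'   be all 1.
#' @param seed Integer seed for the whole fixture.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 34, clade_sizes = c(10, 12, 12),
                       birth_rate = 1, q = 0.35,
                       states = default_states(),
                       trait_names = default_trait_names(),
                       R = NULL, lambda = NULL, habitat_effects = NULL,
                       delta_cs = 3, target_changes = c(5, 9),
                       max_retries = 500, clade_R = NULL, seed = 1) {
  stopifnot(sum(clade_sizes) == n_taxa, length(clade_sizes) == 3,
            n_taxa >= 4, all(clade_sizes >= 2))
  if (is.null(R))
    R <- modular_cov(trait_names,
                     list(slow = intersect(slow_traits(), trait_names),
                          fast = setdiff(trait_names, slow_traits())),
                     within = 0.6, between = 0)
  if (is.null(lambda))
    lambda <- stats::setNames(ifelse(trait_names == "AR", 0, 1), trait_names)
  if (is.null(habitat_effects)) {
    habitat_effects <- matrix(0, length(states), length(trait_names),
                              dimnames = list(states, trait_names))
    habitat_effects["CS", intersect(slow_traits(), trait_names)] <- delta_cs
  }
  structure(list(n_taxa = n_taxa, clade_sizes = clade_sizes,
                 birth_rate = birth_rate, q = q, states = states,
                 trait_names = trait_names, R = R, lambda = lambda,
                 habitat_effects = habitat_effects,
                 target_changes = target_changes, max_retries = max_retries,
                 clade_R = clade_R, seed = seed),
            class = "sim_config")
}

#' Generate a complete synthetic dataset
#'
#' Builds a 34-taxon (by default) three-clade ultrametric tree of unit depth,
#' simulates the habitat character under ER (redrawing until the true number
#' of changes falls in `target_changes`), simulates modular Brownian traits
#' with per-trait lambda, applies the additive habitat effects, and draws
#' per-taxon climate summaries (wMAT in deg C, wMAP in mm) around
#' habitat-specific means with Brownian noise. All randomness derives from
#' `config$seed`.
#'
#' @param config A `"sim_config"` object (see [sim_config()]).
#' @return A list of class `"synthetic_dataset"` with elements `tree`,
#'   `habitat` (named character), `traits` (log scale), `traits_raw`
#'   (exponentiated), `climate` (data.frame), `clades` (named list of taxa),
#'   and `truth` (generating parameters and true node states).
#' @export
make_fixture <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(config$seed)
  # --- tree: three Yule clades of depth 0.6 on a fixed backbone, depth 1 ---
  sizes <- config$clade_sizes
  offs <- c(0, cumsum(sizes))[1:3]
  subs <- lapply(1:3, function(i) {
    st <- simulate_yule(sizes[i], config$birth_rate, seed = seed + i,
                        tip_prefix = "z")
    st$tip.label <- sprintf("t%02d", offs[i] + seq_len(sizes[i]))
    d <- max(node_depths(st)[seq_len(ape::Ntip(st))])
    st$edge.length <- st$edge.length * (0.6 / d)
    st
  })
  body <- vapply(subs, function(s) sub(";$", "", write_newick(s)), "")
  tree <- parse_newick(paste0(
    "(", body[1], ":0.4,(", body[2], ":0.2,", body[3], ":0.2):0.2);"))
  clades <- list(I = subs[[1]]$tip.label, II = subs[[2]]$tip.label,
                 III = subs[[3]]$tip.label)
  # --- habitat: redraw until the true change count is in range ---
  mk <- NULL
  for (i in seq_len(config$max_retries)) {
    cand <- simulate_mk(tree, config$q, config$states, seed = seed + 1000 + i)
    if (cand$n_changes >= config$target_changes[1] &&
        cand$n_changes <= config$target_changes[2]) { mk <- cand; break }
  }
  if (is.null(mk))
    stop("no habitat history with ", config$target_changes[1], "-",
         config$target_changes[2], " changes in ", config$max_retries,
         " draws; try a different q")
  # --- traits ---
  if (is.null(config$clade_R)) {
    X <- simulate_traits(tree, config$R, config$lambda, seed = seed + 2)
  } else {
    if (any(config$lambda != 1))
      warning("clade_R simulation ignores lambda (all traits lambda = 1)")
    X <- simulate_traits_by_clade(tree, config$clade_R, clades,
                                  R_backbone = config$R, seed = seed + 2)
  }
  X <- X + config$habitat_effects[mk$tip_states[rownames(X)], , drop = FALSE]
  # --- climate: habitat means + Brownian noise ---
  mat_mean <- c(CS = 4, HF = 10, WA = 14)
  map_mean <- c(CS = 550, HF = 1000, WA = 250)
  noise <- simulate_traits(tree, diag(2), lambda = 1, seed = seed + 3)
  hab <- mk$tip_states[tree$tip.label]
  climate <- data.frame(
    taxon = tree$tip.label,
    wMAT = unname(mat_mean[hab]) + 1.5 * noise[, 1],
    wMAP = pmax(unname(map_mean[hab]) + 120 * noise[, 2], 20),
    stringsAsFactors = FALSE)
  structure(list(
    tree = tree,
    habitat = mk$tip_states,
    traits = X,
    traits_raw = exp(X),
    climate = climate,
    clades = clades,
    truth = list(config = config, node_states = mk$node_states,
                 n_changes = mk$n_changes, R = config$R,
                 lambda = config$lambda,
                 habitat_effects = config$habitat_effects)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic comparative dataset\n")
  cat("  taxa:", ape::Ntip(x$tree),
      " clades:", paste(lengths(x$clades), collapse = "/"), "\n")
  cat("  habitat states:", paste(sprintf(
    "%s=%d", names(table(x$habitat)), table(x$habitat)), collapse = " "),
    " (", x$truth$n_changes, "true changes )\n")
  cat("  traits:", paste(colnames(x$traits), collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `tree.nwk`, `traits.tsv` (raw, i.e. exponentiated, trait values),
#' `habitat.tsv`, `climate.tsv` and `truth.json`.
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("tree.nwk", "traits.tsv", "habitat.tsv",
                            "climate.tsv", "truth.json"))
  writeLines(write_newick(dataset$tree), paths[1])
  tr <- data.frame(taxon = rownames(dataset$traits_raw),
                   signif(dataset$traits_raw, 12), check.names = FALSE)
  utils::write.table(tr, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(taxon = names(dataset$habitat),
               habitat = unname(dataset$habitat)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- dataset$climate
  cl$wMAT <- signif(cl$wMAT, 12); cl$wMAP <- signif(cl$wMAP, 12)
  utils::write.table(cl, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    n_changes = dataset$truth$n_changes,
    node_states = dataset$truth$node_states,
    lambda = as.list(dataset$truth$lambda),
    clades = dataset$clades,
    seed = dataset$truth$config$seed)
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `tree.nwk`, `traits.tsv`, `habitat.tsv`
#'   and optionally `climate.tsv`.
#' @return A list with `tree`, `traits_raw`, `habitat`, `climate` (or NULL).
#' @export
read_dataset <- function(dir) {
  tree <- parse_newick(paste(readLines(file.path(dir, "tree.nwk")),
                             collapse = ""))
  tr <- utils::read.table(file.path(dir, "traits.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  traits_raw <- as.matrix(tr[, -1, drop = FALSE])
  rownames(traits_raw) <- tr$taxon
  hb <- utils::read.table(file.path(dir, "habitat.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  habitat <- stats::setNames(hb$habitat, hb$taxon)
  cpath <- file.path(dir, "climate.tsv")
  climate <- if (file.exists(cpath))
    utils::read.table(cpath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  list(tree = tree, traits_raw = traits_raw, habitat = habitat,
       climate = climate)
}
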