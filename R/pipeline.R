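#' Pipeline configuration
#'
#' @param data_dir Directory holding `tree.nwk`, `traits.tsv`, `habitat.tsv`
#'   and optionally `climate.tsv` (see [write_dataset()]); alternatively pass
#'   a `"synthetic_dataset"` via `dataset`.
#' @param out_dir Directory for result tables and the manifest.
#' @param dataset Optional in-memory `"synthetic_dataset"`.
#' @param habitat_ref Reference habitat level for the PGLS dummy coding.
#' @param clades Named list of taxon vectors, or `NULL` /
#'   `"auto:3-deepest"` to cut the three deepest splits ([auto_clades()]).
#' @param n_permutations Permutations for the modularity test.
#' @param seed Master seed; every stage derives its seed from it.
#' @param ultrametric_method Passed to [force_ultrametric()].
#' @param epsilon Branch length for polytomy resolution.
#' @param stages Character vector of stages to run after tree and trait
#'   preparation (`"asr"`, `"pca"`, `"pgls"`, `"signal"`, `"rates"`,
#'   `"modularity"`), or `"all"`.
#' @param traits_on_log_scale Set `TRUE` if `traits.tsv` already holds
#'   log-scale values (the default expects raw positive measurements).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(data_dir = NULL, out_dir, dataset = NULL,
                            habitat_ref = "CS", clades = NULL,
                            n_permutations = 999, seed = 1,
                            ultrametric_method = "extend", epsilon = 1e-4,
                            stages = "all", traits_on_log_scale = FALSE) {
  if (is.null(data_dir) && is.null(dataset))
    stop("either data_dir or dataset is required")
  if (!is.null(data_dir)) {
    need <- file.path(data_dir, c("tree.nwk", "traits.tsv", "habitat.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("missing input files: ", paste(miss, collapse = ", "))
  }
  all_stages <- c("asr", "pca", "pgls", "signal", "rates", "modularity")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(data_dir = data_dir, out_dir = out_dir, dataset = dataset,
                 habitat_ref = habitat_ref, clades = clades,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 ultrametric_method = ultrametric_method, epsilon = epsilon,
                 stages = stages,
                 traits_on_log_scale = traits_on_log_scale),
            class = "pipeline_config")
}

#' Cut a tree into its three deepest clades
#'
#' Deterministically splits at the two deepest internal nodes: the root's
#' two children, then the two children of the root child with more tips
#' (ties resolved toward the first child in edge order). Errors if any
#' resulting clade has fewer than 3 taxa.
#'
#' @param tree A bifurcating rooted `"phylo"` (>= 9 taxa).
#' @return Named list (`I`, `II`, `III`) of taxon vectors; `I` is the
#'   uncut root child.
#' @export
auto_clades <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 9) stop("need at least 9 taxa")
  if (!ape::is.binary(tree)) stop("resolve polytomies first")
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  tipset <- function(v) {
    if (v <= ape::Ntip(tree)) return(tree$tip.label[v])
    tree$tip.label[intersect(descendant_nodes(tree, v),
                             seq_len(ape::Ntip(tree)))]
  }
  sizes <- vapply(kids, function(v) length(tipset(v)), 0L)
  big <- kids[which.max(sizes)]
  small <- setdiff(kids, big)[1]
  if (big <= ape::Ntip(tree))
    stop("deepest split is a single tip; provide explicit clade lists")
  gkids <- tree$edge[tree$edge[, 1] == big, 2]
  out <- list(I = tipset(small), II = tipset(gkids[1]),
              III = tipset(gkids[2]))
  if (any(lengths(out) < 3))
    stop("auto clades smaller than 3 taxa (sizes ",
         paste(lengths(out), collapse = "/"),
         "); provide explicit clade lists")
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative analysis pipeline
#'
#' Stage order: tree preparation (prune to the common taxon set, resolve
#' polytomies, force ultrametric) and trait preprocessing, then ancestral
#' state reconstruction (ER and SYM fits, LRT, re-rooting marginals,
#' transition counts), phylogenetic PCA, PGLS of PC1/PC2 on habitat and
#' climate (with OLS comparison and a CS-versus-rest contrast on the
#' orientation-anchored PC1), per-trait lambda signal, the clade rates
#' table, and the modularity tests (all taxa + per clade). Each stage writes
#' TSV/JSON files into `config$out_dir`; a manifest records status, files
#' and timing. Failures abort with the failing stage named (the partial
#' manifest is still written).
#'
#' @param config A `"pipeline_config"`.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "dataset")],
                   package_version =
                     as.character(utils::packageVersion("cladeshift")),
                   stages = list())
  t_all <- proc.time()[3]
  files <- character()
  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, config$out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[3] - t0, 3),
      files = if (is.character(res)) basename(res) else character())
    if (is.character(res)) files <<- c(files, res)
    res
  }

  # ---- load + tree prep (always runs) ----
  env <- new.env()
  stage("prepare", function() {
    d <- if (!is.null(config$dataset)) {
      ds <- config$dataset
      list(tree = ds$tree, traits_raw = ds$traits_raw, habitat = ds$habitat,
           climate = ds$climate)
    } else read_dataset(config$data_dir)
    taxa <- Reduce(intersect, list(d$tree$tip.label, rownames(d$traits_raw),
                                   names(d$habitat)))
    if (!is.null(d$climate)) taxa <- intersect(taxa, d$climate$taxon)
    if (length(taxa) < 10)
      stop("only ", length(taxa), " taxa shared across inputs (need >= 10)")
    tree <- prune_to(d$tree, taxa)
    tree <- resolve_polytomies(tree, config$epsilon, seed = config$seed)
    tree <- force_ultrametric(tree, config$ultrametric_method)
    env$tree <- tree
    env$habitat <- d$habitat[tree$tip.label]
    log_scale <- if (!is.null(config$dataset)) FALSE else
      config$traits_on_log_scale
    env$traits <- preprocess_traits(
      d$traits_raw[tree$tip.label, , drop = FALSE], log = !log_scale)
    env$climate <- if (!is.null(d$climate)) {
      cl <- d$climate[match(tree$tip.label, d$climate$taxon), , drop = FALSE]
      rownames(cl) <- cl$taxon
      cl
    } else NULL
    env$clades <- if (is.null(config$clades) ||
                      identical(config$clades, "auto:3-deepest"))
      auto_clades(tree) else lapply(config$clades, intersect, y = taxa)
    character()
  })
  res <- list(tree = env$tree, clades = env$clades)

  if ("asr" %in% config$stages) stage("asr", function() {
    er <- fit_mk(env$tree, env$habitat, "ER")
    sym <- fit_mk(env$tree, env$habitat, "SYM")
    lrt <- mk_lrt(er, sym)
    asr <- ancestral_states(env$tree, env$habitat, "ER", rates = er$rates)
    trans <- count_transitions(env$tree, asr)
    res$mk <<- list(er = er, sym = sym, lrt = lrt, asr = asr,
                    transitions = trans)
    f1 <- file.path(config$out_dir, "mk_fits.json")
    jsonlite::write_json(list(
      ER = er[c("rates", "log_likelihood", "n_param", "AIC", "boundary")],
      SYM = sym[c("rates", "log_likelihood", "n_param", "AIC", "boundary")],
      LRT = lrt,
      transitions = as.data.frame.table(trans, stringsAsFactors = FALSE)),
      f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f2 <- write_tsv(data.frame(node = rownames(asr$prob),
                               state = unname(asr$states),
                               as.data.frame(asr$prob)),
                    file.path(config$out_dir, "ancestral_states.tsv"))
    tr <- env$tree
    tr$node.label <- asr$states[-seq_len(ape::Ntip(tr))]
    f3 <- file.path(config$out_dir, "ancestral_tree.nwk")
    writeLines(write_newick(tr), f3)
    c(f1, f2, f3)
  })

  if (any(c("pca", "pgls") %in% config$stages)) stage("pca", function() {
    p <- phylo_pca(env$tree, env$traits)
    res$pca <<- p
    f1 <- write_tsv(data.frame(trait = rownames(p$loadings),
                               as.data.frame(p$loadings)),
                    file.path(config$out_dir, "pca_loadings.tsv"))
    f2 <- write_tsv(data.frame(component = colnames(p$loadings),
                               eigenvalue = p$eigenvalues,
                               proportion = p$proportion),
                    file.path(config$out_dir, "pca_variance.tsv"))
    f3 <- write_tsv(data.frame(taxon = rownames(p$scores),
                               as.data.frame(p$scores)),
                    file.path(config$out_dir, "pca_scores.tsv"))
    c(f1, f2, f3)
  })

  if ("pgls" %in% config$stages) stage("pgls", function() {
    res$pgls <<- pgls_stage(env, res$pca, config)
    write_tsv(res$pgls, file.path(config$out_dir, "pgls.tsv"))
  })

  if ("signal" %in% config$stages) stage("signal", function() {
    tab <- do.call(rbind, lapply(colnames(env$traits), function(tr) {
      lf <- fit_lambda(env$tree,
                       stats::setNames(env$traits[, tr],
                                       rownames(env$traits)))
      data.frame(trait = tr, lambda = lf$lambda, logLik = lf$logLik,
                 AIC_hat = lf$AIC, AIC_lambda0 = lf$AIC_0,
                 AIC_lambda1 = lf$AIC_1)
    }))
    res$signal <<- tab
    write_tsv(tab, file.path(config$out_dir, "signal.tsv"))
  })

  if ("rates" %in% config$stages) stage("rates", function() {
    tab <- rates_table(env$tree, env$traits, env$clades)
    res$rates <<- tab
    write_tsv(tab, file.path(config$out_dir, "rates.tsv"))
  })

  if ("modularity" %in% config$stages) stage("modularity", function() {
    all_res <- cr_test(env$tree, env$traits,
                       n_permutations = config$n_permutations,
                       seed = config$seed + 100)
    by_clade <- modularity_by_clade(env$tree, env$traits,
                                    clades = env$clades,
                                    n_permutations = config$n_permutations,
                                    seed = config$seed + 200)
    rows <- c(list(all = all_res), by_clade)
    tab <- do.call(rbind, lapply(names(rows), function(nm) {
      r <- rows[[nm]]
      data.frame(scope = nm, CR = r$cr_observed, p_value = r$p_value,
                 n_assignments = if (is.null(r$n_permutations)) NA_integer_
                                 else r$n_permutations,
                 method = if (is.null(r$method)) NA_character_ else r$method)
    }))
    res$modularity <<- tab
    write_tsv(tab, file.path(config$out_dir, "modularity.tsv"))
  })

  manifest$total_seconds <- round(proc.time()[3] - t_all, 3)
  manifest$files <- basename(files)
  write_manifest(manifest, config$out_dir)
  res$manifest <- manifest
  invisible(res)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

# PGLS stage: PC1 and PC2 against habitat and (when present) climate, each
# fitted by ML-lambda PGLS and OLS for the AIC comparison; plus the
# CS-versus-rest contrast on PC1 oriented so the LMA loading is negative
# (low PC1 = resource-conservative strategy).
pgls_stage <- function(env, pca_fit, config) {
  sc <- pca_fit$scores
  orient <- if ("LMA" %in% rownames(pca_fit$loadings) &&
                pca_fit$loadings["LMA", "PC1"] > 0) -1 else 1
  hab_levels <- c(config$habitat_ref,
                  setdiff(sort(unique(env$habitat)), config$habitat_ref))
  df <- data.frame(habitat = factor(env$habitat, levels = hab_levels),
                   PC1 = sc[, "PC1"], PC2 = sc[, "PC2"],
                   PC1_oriented = orient * sc[, "PC1"],
                   row.names = rownames(sc))
  if (!is.null(env$climate)) {
    df$wMAT <- env$climate[rownames(df), "wMAT"]
    df$wMAP <- env$climate[rownames(df), "wMAP"]
  }
  rows <- list()
  add <- function(response, design, fit) {
    ct <- fit$coef_table
    rows[[length(rows) + 1]] <<- data.frame(
      response = response, design = design, method = fit$method,
      term = c("_model_", rownames(ct)),
      estimate = c(NA, ct$estimate), se = c(NA, ct$se),
      t = c(NA, ct$t), p = c(fit$p_F, ct$p),
      F = c(fit$F, rep(NA, nrow(ct))),
      df1 = c(fit$df_F[1], rep(NA, nrow(ct))),
      df2 = c(fit$df_F[2], rep(NA, nrow(ct))),
      R2 = c(fit$R2, rep(NA, nrow(ct))),
      lambda = c(fit$lambda, rep(NA, nrow(ct))),
      AIC = c(fit$AIC, rep(NA, nrow(ct))), n = fit$n)
    fit
  }
  for (resp in c("PC1", "PC2")) {
    fh <- add(resp, "habitat",
              pgls(stats::reformulate("habitat", resp), df, env$tree))
    add(resp, "habitat", pgls(stats::reformulate("habitat", resp), df,
                              env$tree, method = "ols"))
    if (!is.null(env$climate)) {
      add(resp, "climate",
          pgls(stats::reformulate(c("wMAT", "wMAP"), resp), df, env$tree))
      add(resp, "climate", pgls(stats::reformulate(c("wMAT", "wMAP"), resp),
                                df, env$tree, method = "ols"))
    }
  }
  # CS-vs-rest contrast on orientation-anchored PC1
  fo <- pgls(PC1_oriented ~ habitat, df, env$tree)
  ctr <- cs_vs_rest_contrast(fo, config$habitat_ref)
  rows[[length(rows) + 1]] <- data.frame(
    response = "PC1_oriented", design = "habitat", method = "pgls",
    term = "CS_vs_rest", estimate = ctr$estimate, se = ctr$se, t = ctr$t,
    p = ctr$p, F = NA, df1 = NA, df2 = NA, R2 = NA, lambda = fo$lambda,
    AIC = NA, n = fo$n)
  do.call(rbind, rows)
}

#' Contrast of the reference habitat against the mean of the others
#'
#' For a PGLS fit of a response on a habitat factor, estimates
#' `mu_ref - mean(mu_other)` with its GLS standard error and t test
#' (negative = the reference habitat sits lower on the response).
#'
#' @param fit A `"pgls_fit"` whose design is a single factor with the
#'   reference as first level.
#' @param ref Reference level name (used only for labeling).
#' @return A list with `estimate`, `se`, `t`, `p`, `df`.
#' @export
cs_vs_rest_contrast <- function(fit, ref = "CS") {
  b <- coef(fit)
  other <- setdiff(names(b), "(Intercept)")
  if (!length(other)) stop("fit has no factor coefficients")
  cvec <- stats::setNames(rep(0, length(b)), names(b))
  cvec[other] <- -1 / length(other)
  est <- sum(cvec * b)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  tv <- est / se
  df <- fit$df_F[2]
  list(estimate = est, se = se, t = tv,
       p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE), df = df,
       reference = ref)
}
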