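## End-to-end orchestration: a structured run configuration, a synthetic
## scenario generator producing every pipeline input, and the staged analysis
## (filter -> decompose -> split/heterogeneity -> flux -> correlate -> report)
## with deterministic seeding and per-stage TSV outputs.

#' Build a validated run configuration
#'
#' Aggregates every tunable constant of the pipeline. Exactly one of
#' `input` (paths to existing tables) or `scenario` (a synthetic-scenario
#' block, see [synthetic_scenario()]) must be supplied.
#'
#' @param input Optional list of input paths: `matrix` (dN/dS TSV),
#'   `covariates` (TSV: lineage_id, covariate, optional clade), `lineage_tree`
#'   (Newick). Estimate-level inputs may be added as `estimates` (TSV).
#' @param scenario Optional list of synthetic-scenario settings.
#' @param min_mutations,min_fraction Retention-filter thresholds.
#' @param tol,max_iter,outlier_alpha Decomposition settings.
#' @param min_tips,min_depth Split settings.
#' @param heterogeneity_bootstrap,bca_bootstrap,subsample_draws,subsample_n
#'   Bootstrap counts.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, scenario = NULL,
                       min_mutations = 32, min_fraction = 0.7,
                       tol = 1e-6, max_iter = 1000, outlier_alpha = 0.05,
                       min_tips = 20, min_depth = 0.2,
                       heterogeneity_bootstrap = 100, bca_bootstrap = 1000,
                       subsample_draws = 10000, subsample_n = 19,
                       seed = 1) {
  if (is.null(input) == is.null(scenario))
    stop_invalid("exactly one of input or scenario must be given")
  stopifnot(min_mutations >= 0, min_fraction >= 0, min_fraction <= 1,
            tol > 0, max_iter >= 1, outlier_alpha > 0, outlier_alpha < 1,
            min_tips >= 2, min_depth >= 0, heterogeneity_bootstrap >= 1,
            bca_bootstrap >= 10, subsample_draws >= 1, subsample_n >= 3)
  structure(list(input = input, scenario = scenario,
                 min_mutations = min_mutations, min_fraction = min_fraction,
                 tol = tol, max_iter = max_iter, outlier_alpha = outlier_alpha,
                 min_tips = min_tips, min_depth = min_depth,
                 heterogeneity_bootstrap = heterogeneity_bootstrap,
                 bca_bootstrap = bca_bootstrap,
                 subsample_draws = subsample_draws, subsample_n = subsample_n,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Describe a synthetic analysis scenario
#'
#' Settings for the synthetic world the pipeline can run on end-to-end.
#' Lineages are organized into clades (monophyletic in the lineage tree),
#' each with its own planted rank correlation between the lineage constraint
#' and the covariate (synthetic genome size).
#'
#' @param clades List of clade blocks `list(name, n_lineages, covariate_rho)`;
#'   the default is a single 100-lineage clade with rho 0.3.
#' @param n_genes Number of gene families in the dN/dS matrix.
#' @param sd_F,sd_R,residual_sd,missing_fraction,outlier_fraction,
#'   outlier_shift Passed to [generate_dnds_matrix()].
#' @param flux List: `n_genomes`, `n_families`, `gain_meanlog`, `loss_meanlog`,
#'   `rate_sdlog` controlling per-lineage gain/loss simulations.
#' @param split List: `n_genomes`, `tree_depth_scale`, `n_lineages`,
#'   `het_fraction`, `het_delta` controlling splittable genome trees and
#'   planted subtree heterogeneity.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(clades = list(list(name = "cladeA",
                                                  n_lineages = 100,
                                                  covariate_rho = 0.3)),
                               n_genes = 200, sd_F = 0.5, sd_R = 0.5,
                               residual_sd = 0.3, missing_fraction = 0.2,
                               outlier_fraction = 0.005, outlier_shift = 3,
                               flux = list(n_genomes = 8, n_families = 100,
                                           gain_meanlog = log(2),
                                           loss_meanlog = log(2),
                                           rate_sdlog = 0.5),
                               split = list(n_genomes = 50,
                                            tree_depth_scale = 3,
                                            n_lineages = 5,
                                            het_fraction = 0.4,
                                            het_delta = 0.5)) {
  structure(list(clades = clades, n_genes = n_genes, sd_F = sd_F, sd_R = sd_R,
                 residual_sd = residual_sd, missing_fraction = missing_fraction,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift, flux = flux, split = split),
            class = c("synthetic_scenario", "list"))
}

## Generate every pipeline input for a scenario. Returns in-memory objects;
## run_full_analysis serializes them alongside its outputs.
generate_scenario_inputs <- function(scenario, seed) {
  sc <- scenario
  n_lineages <- sum(vapply(sc$clades, `[[`, numeric(1), "n_lineages"))
  gen <- generate_dnds_matrix(
    n_lineages = n_lineages, n_genes = sc$n_genes, sd_F = sc$sd_F,
    sd_R = sc$sd_R, residual_sd = sc$residual_sd,
    missing_fraction = sc$missing_fraction,
    outlier_fraction = sc$outlier_fraction,
    outlier_shift = sc$outlier_shift, seed = derive_seed(seed, "matrix"))
  mat <- gen$matrix
  truth <- gen$truth

  ## clade assignment follows lineage order; the lineage tree joins one
  ## random subtree per clade so clades are monophyletic
  clade_sizes <- vapply(sc$clades, `[[`, numeric(1), "n_lineages")
  clade_names <- vapply(sc$clades, `[[`, character(1), "name")
  clade_of <- rep(clade_names, clade_sizes)
  subtrees <- list()
  offset <- 0L
  for (k in seq_along(sc$clades)) {
    nk <- clade_sizes[k]
    if (nk < 2) stop_invalid("each clade needs at least 2 lineages")
    sub <- random_tree(nk, 1.0, derive_seed(seed, "clade-tree", k))
    sub$tip.label <- mat$lineage_ids[offset + seq_len(nk)]
    subtrees[[k]] <- sub
    offset <- offset + nk
  }
  lineage_tree <- join_clades(subtrees)

  ## per-clade covariates with the planted rank correlation to true F
  covariate <- numeric(n_lineages)
  offset <- 0L
  for (k in seq_along(sc$clades)) {
    nk <- clade_sizes[k]
    idx <- offset + seq_len(nk)
    covariate[idx] <- generate_lineage_covariates(
      truth$true_F[idx], sc$clades[[k]]$covariate_rho,
      derive_seed(seed, "covariate", k))
    offset <- offset + nk
  }
  names(covariate) <- mat$lineage_ids

  ## synthetic per-family estimate records feeding the retention filter:
  ## mutation counts drawn lognormal around ~10x the threshold, with a small
  ## fraction of shallow families below it
  est <- with_seed(derive_seed(seed, "estimates"), {
    cells <- which(mat$observed, arr.ind = TRUE)
    n_sites <- sample(300:3000, nrow(cells), replace = TRUE)
    tl <- stats::rlnorm(nrow(cells), log(0.15), 0.9)
    data.frame(lineage_id = mat$lineage_ids[cells[, 1]],
               gene_id = mat$gene_ids[cells[, 2]],
               dnds = exp(mat$values[cells]),
               kappa = stats::runif(nrow(cells), 1, 4),
               n_sequences = sample(4:40, nrow(cells), replace = TRUE),
               n_sites_nt = n_sites, tree_length = tl,
               mutation_count = tl * n_sites,
               log_likelihood = NA_real_, boundary_flag = FALSE,
               stringsAsFactors = FALSE)
  })

  ## per-lineage gain/loss worlds for the flux stage
  flux_truth <- with_seed(derive_seed(seed, "flux-rates"), {
    data.frame(lineage_id = mat$lineage_ids,
               gain = stats::rlnorm(n_lineages, sc$flux$gain_meanlog,
                                    sc$flux$rate_sdlog),
               loss = stats::rlnorm(n_lineages, sc$flux$loss_meanlog,
                                    sc$flux$rate_sdlog),
               stringsAsFactors = FALSE)
  })

  ## genome trees for the split stage, a few with planted subtree
  ## heterogeneity in the lineage constraint
  n_split <- min(sc$split$n_lineages, n_lineages)
  split_lineages <- mat$lineage_ids[seq_len(n_split)]
  het_planted <- with_seed(derive_seed(seed, "het"),
                           stats::runif(n_split) < sc$split$het_fraction)
  genome_trees <- lapply(seq_len(n_split), function(k)
    random_tree(sc$split$n_genomes, sc$split$tree_depth_scale,
                derive_seed(seed, "genome-tree", k)))
  names(genome_trees) <- split_lineages

  list(matrix = mat, truth = truth, clade_of = clade_of,
       lineage_tree = lineage_tree, covariate = covariate,
       estimates = est, flux_truth = flux_truth,
       genome_trees = genome_trees, het_planted = het_planted,
       split_lineages = split_lineages)
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on a synthetic scenario or on loaded inputs:
#' retention filtering, decomposition with outlier removal, split detection
#' and subtree heterogeneity, gene-flux estimation, and the correlation layer
#' (global and per-clade Spearman with BCa CIs, per-node correlations on the
#' lineage tree, and the subsampling null). Every stage writes a TSV into
#' `out_dir` and the machine-readable `report.json` summarizes the run.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("selscape pipeline, master seed %d\n", config$seed),
      file = log_path)
  stage <- function(name, expr) {
    logf("[stage %s] start", name)
    r <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("[stage %s] done", name)
    r
  }

  inputs <- stage("inputs", {
    if (!is.null(config$scenario))
      generate_scenario_inputs(config$scenario, config$seed)
    else load_run_inputs(config$input)
  })
  mat <- inputs$matrix

  ## stage: retention filter on the estimate table
  filt <- stage("filter", {
    f <- apply_retention_filters(inputs$estimates,
                                 min_mutations = config$min_mutations,
                                 min_fraction = config$min_fraction)
    write_tsv_file(f$exclusion_log, file.path(out_dir, "exclusions.tsv"))
    f
  })
  keep <- matrix(FALSE, nrow(mat$values), ncol(mat$values),
                 dimnames = dimnames(mat$values))
  keep[cbind(match(filt$retained$lineage_id, mat$lineage_ids),
             match(filt$retained$gene_id, mat$gene_ids))] <- TRUE
  keep <- keep & mat$observed
  keep_lin <- rowSums(keep) > 0
  keep_gene <- colSums(keep[keep_lin, , drop = FALSE]) > 0
  mat_f <- dnds_matrix(mat$values[keep_lin, keep_gene, drop = FALSE],
                       keep[keep_lin, keep_gene, drop = FALSE],
                       mat$lineage_ids[keep_lin], mat$gene_ids[keep_gene])

  ## stage: decomposition with one outlier-removal pass
  fit <- stage("decompose", {
    first <- decompose(mat_f, tol = config$tol, max_iter = config$max_iter)
    final <- remove_outliers_and_refit(mat_f, first,
                                       alpha = config$outlier_alpha,
                                       tol = config$tol,
                                       max_iter = config$max_iter)
    write_tsv_file(data.frame(lineage_id = names(final$F),
                              F = fmt_num(final$F),
                              exp_F = fmt_num(exp(final$F))),
                   file.path(out_dir, "lineage_constraints.tsv"))
    write_tsv_file(data.frame(gene_id = names(final$R),
                              R = fmt_num(final$R)),
                   file.path(out_dir, "gene_constraints.tsv"))
    write_tsv_file(final$removed_cells, file.path(out_dir, "removed_cells.tsv"))
    final
  })

  ## stage: split detection + planted-heterogeneity comparison
  split_report <- stage("split", {
    rows <- NULL
    for (lid in names(inputs$genome_trees %||% list())) {
      tr <- inputs$genome_trees[[lid]]
      cand <- find_split_branch(tr, min_tips = config$min_tips,
                                min_depth = config$min_depth)
      if (is.null(cand)) {
        rows <- rbind(rows, data.frame(
          lineage_id = lid, splittable = FALSE, branch_id = NA_integer_,
          n_A = NA_integer_, n_B = NA_integer_, depth_A = NA_real_,
          depth_B = NA_real_, difference = NA_real_, flagged = NA))
        next
      }
      het <- subtree_heterogeneity_for(inputs, lid, fit, config)
      rows <- rbind(rows, data.frame(
        lineage_id = lid, splittable = TRUE, branch_id = cand$branch_id,
        n_A = length(cand$tips_A), n_B = length(cand$tips_B),
        depth_A = cand$depth_A, depth_B = cand$depth_B,
        difference = het$difference_measure, flagged = het$flagged))
    }
    rows <- rows %||% data.frame(lineage_id = character(0),
                                 splittable = logical(0))
    write_tsv_file(rows, file.path(out_dir, "splits.tsv"))
    rows
  })

  ## stage: per-lineage gene flux from simulated presence/absence worlds
  flux_tab <- stage("flux", {
    rows <- NULL
    if (!is.null(inputs$flux_truth)) {
      for (k in seq_len(nrow(inputs$flux_truth))) {
        lid <- inputs$flux_truth$lineage_id[k]
        tr <- random_tree(config$scenario$flux$n_genomes, 2.0,
                          derive_seed(config$seed, "flux-tree", k))
        sim <- simulate_presence_absence(tr, gain_loss_params(
          inputs$flux_truth$gain[k], inputs$flux_truth$loss[k],
          root_presence_prob = 0.5,
          n_families = config$scenario$flux$n_families,
          seed = derive_seed(config$seed, "flux-sim", k)))
        anc <- reconstruct_ancestral_states(tr, sim$pam)
        fl <- compute_flux(tr, anc)
        rows <- rbind(rows, data.frame(
          lineage_id = lid, gains = fl$total_gains, losses = fl$total_losses,
          tree_length = fl$tree_length, gain_rate = fl$gain_rate,
          loss_rate = fl$loss_rate,
          flux_ratio = if (fl$flux_defined) fl$flux_ratio else NA_real_))
      }
    }
    rows <- rows %||% data.frame(lineage_id = character(0))
    write_tsv_file(rows, file.path(out_dir, "flux.tsv"))
    rows
  })

  ## stage: correlation layer
  corr <- stage("correlate", {
    lins <- names(fit$F)
    covar <- inputs$covariate[lins]
    global <- correlate_with_ci(covar, fit$F[lins],
                                n_bootstrap = config$bca_bootstrap,
                                seed = derive_seed(config$seed, "bca-global"))
    clade_rows <- NULL
    clade_of <- inputs$clade_of
    names(clade_of) <- inputs$matrix$lineage_ids
    for (cl in unique(clade_of)) {
      ids <- intersect(lins, names(clade_of)[clade_of == cl])
      if (length(ids) < 8) next
      cc <- correlate_with_ci(inputs$covariate[ids], fit$F[ids],
                              n_bootstrap = config$bca_bootstrap,
                              seed = derive_seed(config$seed, "bca", cl))
      clade_rows <- rbind(clade_rows, data.frame(
        clade = cl, n = cc$n, rho = cc$rho, ci_low = cc$ci_low,
        ci_high = cc$ci_high, p_value = cc$p_value))
    }
    clade_rows <- clade_rows %||% data.frame(clade = character(0))
    write_tsv_file(clade_rows, file.path(out_dir, "clade_correlations.tsv"))

    per_node <- if (!is.null(inputs$lineage_tree)) {
      tr <- ape::keep.tip(inputs$lineage_tree,
                          intersect(inputs$lineage_tree$tip.label, lins))
      per_node_correlations(tr, inputs$covariate, fit$F)
    } else data.frame()
    write_tsv_file(per_node, file.path(out_dir, "node_correlations.tsv"))

    ## subsampling null drawn from the largest clade
    sizes <- table(clade_of[lins])
    big <- names(sizes)[which.max(sizes)]
    ids <- intersect(lins, names(clade_of)[clade_of == big])
    sub <- if (length(ids) > config$subsample_n)
      subsample_null(inputs$covariate[ids], fit$F[ids],
                     subsample_size = config$subsample_n,
                     n_draws = config$subsample_draws,
                     seed = derive_seed(config$seed, "subsample"))
    else NULL
    ## flux vs constraint across lineages
    flux_corr <- NULL
    if (nrow(flux_tab) >= 8) {
      ok <- !is.na(flux_tab$flux_ratio) & flux_tab$lineage_id %in% lins
      if (sum(ok) >= 8)
        flux_corr <- spearman(flux_tab$flux_ratio[ok],
                              fit$F[flux_tab$lineage_id[ok]])
    }
    list(global = global, clades = clade_rows, per_node = per_node,
         subsample = sub, big_clade = big, flux_corr = flux_corr)
  })

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_lineages_input = length(mat$lineage_ids),
    n_genes_input = length(mat$gene_ids),
    retained = list(n_lineages = length(filt$retained_lineages),
                    n_families_total = nrow(filt$retained)),
    decomposition = list(E = fit$E, n_iterations = fit$n_iterations,
                         converged = fit$converged,
                         n_removed_cells = nrow(fit$removed_cells)),
    split = list(n_examined = nrow(split_report),
                 n_splittable = sum(split_report$splittable %in% TRUE),
                 n_flagged = sum(split_report$flagged %in% TRUE)),
    flux = list(n_lineages = nrow(flux_tab),
                flux_vs_constraint_rho =
                  if (!is.null(corr$flux_corr)) corr$flux_corr$rho else NA),
    correlations = list(
      global = corr$global[c("rho", "ci_low", "ci_high", "p_value", "n")],
      subsample_null = if (!is.null(corr$subsample))
        list(clade = corr$big_clade, n_draws = config$subsample_draws,
             subsample_n = config$subsample_n,
             minimum = corr$subsample$minimum,
             mean = mean(corr$subsample$rhos)) else NULL))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

## Planted subtree heterogeneity: per splittable lineage, the scenario
## evolves the lineage's genes in the two subtrees around F_L +/- delta/2
## and the pipeline recovers F_A, F_B by decomposing the stacked 2 x G
## matrix (shared gene effects), then compares the constraints.
subtree_heterogeneity_for <- function(inputs, lid, fit, config) {
  sc <- config$scenario
  if (is.null(sc)) return(list(difference_measure = NA_real_, flagged = NA))
  k <- match(lid, inputs$split_lineages)
  delta <- if (isTRUE(inputs$het_planted[k])) sc$split$het_delta else 0
  iL <- match(lid, inputs$matrix$lineage_ids)
  FL <- inputs$truth$true_F[iL]
  R <- inputs$truth$true_R
  vals <- with_seed(derive_seed(config$seed, "het-values", k), {
    rbind(FL + delta / 2 + R + stats::rnorm(length(R), 0, sc$residual_sd),
          FL - delta / 2 + R + stats::rnorm(length(R), 0, sc$residual_sd))
  })
  sub <- dnds_matrix(vals, lineage_ids = c("subtreeA", "subtreeB"),
                     gene_ids = inputs$matrix$gene_ids)
  f2 <- decompose(sub, tol = config$tol, max_iter = config$max_iter)
  compare_subtree_constraints(f2$F[["subtreeA"]], f2$F[["subtreeB"]])
}

## Input-mode loader: reads the dN/dS matrix, covariate table (lineage_id,
## covariate, optional clade), optional lineage tree, and optional estimate
## table; synthesizes a pass-all estimate table when none is given so the
## filter stage stays uniform.
load_run_inputs <- function(input) {
  if (is.null(input$matrix)) stop_invalid("input$matrix (TSV path) is required")
  mat <- read_dnds_matrix_tsv(input$matrix)
  cov_df <- if (!is.null(input$covariates))
    utils::read.table(input$covariates, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else data.frame(lineage_id = mat$lineage_ids, covariate = NA_real_)
  covariate <- stats::setNames(cov_df$covariate, cov_df$lineage_id)
  clade_of <- if (!is.null(cov_df$clade))
    stats::setNames(cov_df$clade, cov_df$lineage_id)[mat$lineage_ids]
  else stats::setNames(rep("all", length(mat$lineage_ids)), mat$lineage_ids)
  est <- if (!is.null(input$estimates))
    utils::read.table(input$estimates, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else {
    cells <- which(mat$observed, arr.ind = TRUE)
    data.frame(lineage_id = mat$lineage_ids[cells[, 1]],
               gene_id = mat$gene_ids[cells[, 2]],
               mutation_count = Inf, stringsAsFactors = FALSE)
  }
  tree <- if (!is.null(input$lineage_tree)) ape::read.tree(input$lineage_tree)
  list(matrix = mat, truth = NULL, clade_of = unname(clade_of),
       lineage_tree = tree, covariate = covariate, estimates = est,
       flux_truth = NULL, genome_trees = NULL, het_planted = NULL,
       split_lineages = character(0))
}

#' Simulation-based recovery experiment for the ML estimator
#'
#' Simulates codon alignments on a fixed tree with per-alignment parameters
#' drawn from stated ranges, re-estimates omega and kappa by maximum
#' likelihood, and reports rank correlations between true and estimated
#' values plus error quantiles. Mirrors, at desk scale, validating the
#' estimator on alignments with known parameters.
#'
#' @param n_alignments Number of simulated alignments (default 200).
#' @param tree Tree to simulate on; default is a seeded 10-tip random tree
#'   of total length 1.
#' @param n_codons Codons per alignment (default 300).
#' @param omega_range Log-uniform sampling range for omega
#'   (default `c(0.02, 0.8)`).
#' @param kappa_range Uniform sampling range for kappa (default `c(1, 4)`).
#' @param seed Master seed (default 7).
#' @return A list with `results` (data.frame: true/estimated omega and kappa,
#'   boundary flags), `omega_spearman`, `kappa_spearman`, `error_quantiles`,
#'   `n_usable`, `n_failed`.
#' @export
validate_recovery_experiment <- function(n_alignments = 200, tree = NULL,
                                         n_codons = 300,
                                         omega_range = c(0.02, 0.8),
                                         kappa_range = c(1, 4), seed = 7) {
  if (is.null(tree))
    tree <- random_tree(10, 1.0, derive_seed(seed, "recovery-tree"))
  draws <- with_seed(derive_seed(seed, "recovery-params"), {
    data.frame(
      omega = exp(stats::runif(n_alignments, log(omega_range[1]),
                               log(omega_range[2]))),
      kappa = stats::runif(n_alignments, kappa_range[1], kappa_range[2]))
  })
  res <- draws
  res$omega_hat <- NA_real_; res$kappa_hat <- NA_real_
  res$boundary <- NA; res$logL <- NA_real_
  n_failed <- 0L
  for (i in seq_len(n_alignments)) {
    aln <- simulate_alignment(tree,
                              codon_model_params(draws$omega[i], draws$kappa[i]),
                              n_codons, derive_seed(seed, "recovery-aln", i))
    fit <- try(estimate_dnds_ml(aln, tree), silent = TRUE)
    if (inherits(fit, "try-error")) { n_failed <- n_failed + 1L; next }
    res$omega_hat[i] <- fit$params$omega
    res$kappa_hat[i] <- fit$params$kappa
    res$boundary[i] <- fit$boundary_flag
    res$logL[i] <- fit$log_likelihood
  }
  ok <- !is.na(res$omega_hat)
  out <- list(results = res, n_usable = sum(ok), n_failed = n_failed)
  if (sum(ok) >= 3) {
    out$omega_spearman <- spearman(res$omega[ok], res$omega_hat[ok])$rho
    out$kappa_spearman <- spearman(res$kappa[ok], res$kappa_hat[ok])$rho
    out$error_quantiles <- list(
      omega_rel = stats::quantile(abs(res$omega_hat[ok] / res$omega[ok] - 1),
                                  c(0.5, 0.9, 0.95), names = TRUE),
      kappa_rel = stats::quantile(abs(res$kappa_hat[ok] / res$kappa[ok] - 1),
                                  c(0.5, 0.9, 0.95), names = TRUE))
  }
  out
}
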