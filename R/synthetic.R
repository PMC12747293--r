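## Synthetic-data generators: every input the pipeline consumes can be
## simulated with the statistical structure the downstream analysis assumes,
## so all stages are testable without external data.

#' Generate a random rooted binary tree with a fixed total length
#'
#' Coalescent-style random topology (via [ape::rcoal()]) with
#' exponentially-spaced internode depths, rescaled so the sum of all branch
#' lengths equals `total_length` exactly. Tips are labelled `t1 ... tn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param total_length Target sum of branch lengths.
#' @param seed Integer seed; identical arguments give identical trees.
#' @return An [ape] `phylo` object, rooted and binary.
#' @export
#' @examples
#' tr <- random_tree(10, 1.0, seed = 1)
#' sum(tr$edge.length)
random_tree <- function(n_tips, total_length, seed) {
  if (!(is.numeric(n_tips) && n_tips >= 2))
    stop_invalid("n_tips must be >= 2")
  if (!(is.numeric(total_length) && total_length > 0))
    stop_invalid("total_length must be > 0")
  n_tips <- as.integer(n_tips)
  with_seed(seed, {
    tr <- ape::rcoal(n_tips, tip.label = paste0("t", seq_len(n_tips)))
    tr$edge.length <- tr$edge.length * (total_length / sum(tr$edge.length))
    tr
  })
}

#' Join subtrees as monophyletic sister clades under a new root
#'
#' @param trees List of `phylo` objects with disjoint tip labels.
#' @param stem_length Branch length from the new root to each clade root.
#' @return A rooted `phylo` tree in which every input tree is a clade.
#' @export
join_clades <- function(trees, stem_length = 0.2) {
  stopifnot(length(trees) >= 1)
  if (length(trees) == 1) return(trees[[1]])
  parts <- vapply(trees, function(tr)
    sub(";$", "", ape::write.tree(tr)), character(1))
  nwk <- paste0("(", paste0(parts, ":", stem_length, collapse = ","), ");")
  out <- ape::read.tree(text = nwk)
  if (!ape::is.binary(out)) out <- ape::multi2di(out, random = FALSE)
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}

#' Truth record for a planted lineage-by-gene matrix
#' @keywords internal
planted_matrix_truth <- function(true_F, true_R, residual_sd, missing_fraction,
                                 outlier_cells, seed) {
  structure(list(true_F = true_F, true_R = true_R, residual_sd = residual_sd,
                 missing_fraction = missing_fraction,
                 outlier_cells = outlier_cells, seed = seed),
            class = "planted_matrix_truth")
}

#' Simulate a lineage-by-gene log dN/dS matrix with planted structure
#'
#' Generates observed cells as `true_F[L] + true_R[G] + N(0, residual_sd)`,
#' optionally shifted by `outlier_shift` (random sign) in a fraction of cells,
#' with a uniformly random missingness mask that is guaranteed to leave every
#' lineage and every gene with at least one observed cell. The gene factors
#' are recentred to mean zero (the decomposition's gauge), so planted and
#' fitted factors are directly comparable.
#'
#' @param n_lineages,n_genes Matrix dimensions.
#' @param sd_F,sd_R Standard deviations of the planted lineage and gene
#'   factors (log scale).
#' @param residual_sd Residual standard deviation.
#' @param missing_fraction Fraction of cells masked, in `[0, 1)`.
#' @param outlier_fraction Fraction of observed cells shifted, in `[0, 1)`.
#' @param outlier_shift Absolute shift applied to outlier cells (sign random).
#' @param mean_F Mean of the planted lineage factors; defaults to -1.5
#'   (median dN/dS around 0.2, typical of purifying selection).
#' @param seed Integer seed.
#' @param max_mask_retries Retries for a feasible mask before failing.
#' @return A list with elements `matrix` (a [dnds_matrix()]) and `truth`
#'   (a `planted_matrix_truth`).
#' @export
generate_dnds_matrix <- function(n_lineages, n_genes, sd_F = 0.5, sd_R = 0.5,
                                 residual_sd = 0.3, missing_fraction = 0,
                                 outlier_fraction = 0, outlier_shift = 0,
                                 mean_F = -1.5, seed = 1,
                                 max_mask_retries = 100) {
  stopifnot(n_lineages >= 1, n_genes >= 1,
            missing_fraction >= 0, missing_fraction < 1,
            outlier_fraction >= 0, outlier_fraction < 1)
  with_seed(seed, {
    nL <- as.integer(n_lineages); nG <- as.integer(n_genes)
    F <- stats::rnorm(nL, mean_F, sd_F)
    R <- stats::rnorm(nG, 0, sd_R)
    R <- R - mean(R)  # gauge: mean(true_R) = 0
    vals <- outer(F, R, "+") +
      matrix(stats::rnorm(nL * nG, 0, residual_sd), nL, nG)

    observed <- matrix(TRUE, nL, nG)
    if (missing_fraction > 0) {
      n_mask <- floor(missing_fraction * nL * nG)
      ok <- FALSE
      for (try in seq_len(max_mask_retries)) {
        m <- matrix(TRUE, nL, nG)
        m[sample.int(nL * nG, n_mask)] <- FALSE
        if (all(rowSums(m) > 0) && all(colSums(m) > 0)) { observed <- m; ok <- TRUE; break }
      }
      if (!ok)
        stop_invalid(paste0("could not draw a mask leaving every row and column",
                            " observed after %d retries (%.2f missing on %dx%d)"),
                     max_mask_retries, missing_fraction, nL, nG)
    }

    outlier_cells <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("lineage", "gene")))
    if (outlier_fraction > 0 && outlier_shift != 0) {
      obs_idx <- which(observed)
      n_out <- max(1L, floor(outlier_fraction * length(obs_idx)))
      pick <- sample(obs_idx, n_out)
      signs <- sample(c(-1, 1), n_out, replace = TRUE)
      vals[pick] <- vals[pick] + signs * outlier_shift
      outlier_cells <- cbind(lineage = ((pick - 1L) %% nL) + 1L,
                             gene = ((pick - 1L) %/% nL) + 1L)
    }

    lineage_ids <- sprintf("L%03d", seq_len(nL))
    gene_ids <- sprintf("G%04d", seq_len(nG))
    mat <- dnds_matrix(vals, observed, lineage_ids, gene_ids)
    list(matrix = mat,
         truth = planted_matrix_truth(F, R, residual_sd, missing_fraction,
                                      outlier_cells, seed))
  })
}

#' Parameters of the two-state gene gain/loss process
#'
#' @param gain_rate_per_unit_length Rate of 0 -> 1 transitions per unit branch
#'   length.
#' @param loss_rate_per_unit_length Rate of 1 -> 0 transitions.
#' @param root_presence_prob Probability a family is present at the root.
#' @param n_families Number of independently evolving gene families.
#' @param seed Integer seed.
#' @return An object of class `gain_loss_params`.
#' @export
gain_loss_params <- function(gain_rate_per_unit_length,
                             loss_rate_per_unit_length,
                             root_presence_prob = 0.5,
                             n_families = 100, seed = 1) {
  if (gain_rate_per_unit_length < 0 || loss_rate_per_unit_length < 0)
    stop_invalid("gain/loss rates must be nonnegative")
  if (gain_rate_per_unit_length == 0 && loss_rate_per_unit_length == 0)
    stop_invalid("at least one of the gain/loss rates must be positive")
  if (root_presence_prob < 0 || root_presence_prob > 1)
    stop_invalid("root_presence_prob must be in [0, 1]")
  stopifnot(n_families >= 1)
  structure(list(gain_rate_per_unit_length = gain_rate_per_unit_length,
                 loss_rate_per_unit_length = loss_rate_per_unit_length,
                 root_presence_prob = root_presence_prob,
                 n_families = as.integer(n_families), seed = seed),
            class = "gain_loss_params")
}

## Exact (Gillespie) simulation of the two-state process for a vector of
## families along one branch; returns end states and true event counts.
## Waiting-time sampling (rather than a transition-probability draw) gives
## the per-branch event counts the oracles need.
sim_gainloss_branch <- function(states, len, gain, loss) {
  n <- length(states)
  gains <- 0L; losses <- 0L
  remaining <- rep(len, n)
  active <- seq_len(n)
  rates <- c(gain, loss)  # rate out of state 0 is gain, out of state 1 is loss
  while (length(active)) {
    r <- rates[states[active] + 1L]
    idx <- active[r > 0]
    if (!length(idx)) break
    w <- stats::rexp(length(idx), rates[states[idx] + 1L])
    remaining[idx] <- remaining[idx] - w
    flip <- idx[remaining[idx] > 0]
    if (length(flip)) {
      gains <- gains + sum(states[flip] == 0L)
      losses <- losses + sum(states[flip] == 1L)
      states[flip] <- 1L - states[flip]
    }
    active <- flip
  }
  list(states = states, gains = gains, losses = losses)
}

#' Simulate gene presence/absence evolution on a tree
#'
#' Each family evolves independently down the rooted tree under a two-state
#' continuous-time Markov process (0 -> 1 at the gain rate, 1 -> 0 at the
#' loss rate), simulated by exact waiting-time (Gillespie) sampling per
#' branch. Both the tip matrix and the true internal states are returned,
#' together with the realized per-tree event counts.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param params A [gain_loss_params()] object.
#' @return A list with `pam` (a [presence_absence_matrix()]), `ancestral`
#'   (an [ancestral_states()] covering all nodes, tips included),
#'   `true_gains`, `true_losses` (realized event totals over the whole tree).
#' @export
simulate_presence_absence <- function(tree, params) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "gain_loss_params"))
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")
  with_seed(params$seed, {
    nf <- params$n_families
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    states <- matrix(0L, nnode, nf)
    states[root, ] <- as.integer(stats::runif(nf) < params$root_presence_prob)
    gains <- 0L; losses <- 0L
    ord <- rev(ape::postorder(tree))  # preorder over edges
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      res <- sim_gainloss_branch(states[par, ], tree$edge.length[e],
                                 params$gain_rate_per_unit_length,
                                 params$loss_rate_per_unit_length)
      states[child, ] <- res$states
      gains <- gains + res$gains; losses <- losses + res$losses
    }
    fam_ids <- sprintf("F%05d", seq_len(nf))
    node_ids <- node_id_labels(tree)
    pam <- presence_absence_matrix(states[seq_len(ntip), , drop = FALSE],
                                   tree$tip.label, fam_ids)
    anc <- ancestral_states(states, node_ids, fam_ids)
    list(pam = pam, ancestral = anc, true_gains = gains, true_losses = losses)
  })
}

#' Generate lineage covariates with a target rank correlation
#'
#' Produces positive covariate values (synthetic genome sizes, in Mb) whose
#' Spearman correlation with `true_F` converges to `target_rho` as the number
#' of lineages grows. Construction: a Gaussian copula on the normal scores of
#' `true_F`'s ranks, using the Pearson correlation `2*sin(pi*rho_s/6)`
#' equivalent to the requested Spearman rho, mapped through a lognormal
#' quantile so values are positive and span realistic genome sizes.
#'
#' @param true_F Numeric vector of lineage factors (length >= 3).
#' @param target_rho Target Spearman correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal parameters of the covariate marginal;
#'   defaults give a median of ~3 Mb spanning roughly 0.1-12 Mb.
#' @return Numeric vector of positive covariate values.
#' @export
generate_lineage_covariates <- function(true_F, target_rho, seed,
                                        meanlog = log(3), sdlog = 0.8) {
  n <- length(true_F)
  if (n < 3) stop_invalid("true_F must have length >= 3")
  if (abs(target_rho) > 1) stop_invalid("target_rho must be in [-1, 1]")
  with_seed(seed, {
    if (abs(target_rho) == 1) {
      u <- (rank(sign(target_rho) * true_F, ties.method = "average") - 0.5) / n
      return(stats::qlnorm(u, meanlog, sdlog))
    }
    ## normal scores of the observed ranks, then a correlated Gaussian draw
    z <- stats::qnorm((rank(true_F, ties.method = "average") - 0.5) / n)
    r_pearson <- 2 * sin(pi * target_rho / 6)
    y <- r_pearson * z + sqrt(1 - r_pearson^2) * stats::rnorm(n)
    stats::qlnorm(stats::pnorm(y), meanlog, sdlog)
  })
}
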