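## Maximum-likelihood estimation of dN/dS (omega), the transition/transversion
## ratio (kappa), and a global branch-length scale on a fixed topology, by
## Felsenstein pruning under the codon model. Plus the Nei-Gojobori counting
## estimator used as an independent cross-check, and the mutation-count
## retention filters applied to per-gene estimates.

## Collapse alignment columns to unique site patterns with weights.
site_patterns <- function(idx) {
  keys <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(keys)
  w <- as.numeric(table(keys)[keys[u]])
  list(patterns = idx[, u, drop = FALSE], weights = w)
}

## Negative log-likelihood of the alignment under (omega, kappa, scale).
## `prep` carries the postorder tree structure and tip pattern states.
codon_nll <- function(par_log, prep) {
  omega <- exp(par_log[1]); kappa <- exp(par_log[2]); scale <- exp(par_log[3])
  params <- codon_model_params(omega, kappa, prep$pi, branch_scale = scale)
  Q <- build_codon_rate_matrix(params)
  eig <- codon_eigen(Q, prep$pi)
  ntip <- prep$ntip
  npat <- ncol(prep$tip_states)
  partial <- vector("list", ntip + prep$nnode)
  logscale <- numeric(npat)
  ## postorder over edges: children processed before parents
  edges <- prep$edge
  elen <- prep$edge.length * scale
  Pmats <- lapply(elen, function(t) codon_pmat(eig, t))
  acc <- vector("list", ntip + prep$nnode)
  for (k in seq_len(nrow(edges))) {
    child <- edges[k, 2]; par <- edges[k, 1]
    P <- Pmats[[k]]
    contrib <- if (child <= ntip) {
      P[, prep$tip_states[child, ], drop = FALSE]
    } else {
      P %*% partial[[child]]
    }
    acc[[par]] <- if (is.null(acc[[par]])) contrib else acc[[par]] * contrib
    ## when all children of `par` are folded in, finalize; rescaling columns
    ## is only needed when underflow actually threatens (deep/large trees)
    if (k == prep$last_edge_of_parent[par]) {
      A <- acc[[par]]
      if (min(A) < 1e-150) {
        m <- apply(A, 2, max)
        m[m <= 0] <- 1
        A <- A / rep(m, each = nrow(A))
        logscale <- logscale + log(m)
      }
      partial[[par]] <- A
      acc[par] <- list(NULL)  # drop the reference without shrinking the list
    }
  }
  root <- ntip + 1L
  site_l <- as.numeric(prep$pi %*% partial[[root]])
  if (any(site_l <= 0) || any(!is.finite(site_l))) return(1e10)
  -sum(prep$weights * (log(site_l) + logscale))
}

ml_prepare <- function(alignment, tree) {
  idx <- alignment_codon_indices(alignment)
  idx <- idx[match(tree$tip.label, rownames(idx)), , drop = FALSE]
  sp <- site_patterns(idx)
  tree_po <- stats::setNames(ape::postorder(tree), NULL)
  edge <- tree$edge[tree_po, , drop = FALSE]
  last_edge <- integer(length(tree$tip.label) + tree$Nnode)
  for (k in seq_len(nrow(edge))) last_edge[edge[k, 1]] <- k
  list(ntip = length(tree$tip.label), nnode = tree$Nnode,
       edge = edge, edge.length = tree$edge.length[tree_po],
       last_edge_of_parent = last_edge,
       tip_states = sp$patterns, weights = sp$weights,
       pi = rep(1 / codon_tables()$n, codon_tables()$n))
}

#' Estimate dN/dS by maximum likelihood on a fixed topology
#'
#' Maximizes the Felsenstein pruning likelihood of the alignment under the
#' package's codon model over `omega` (dN/dS), `kappa`
#' (transition/transversion ratio), and a single global branch-length scale,
#' with the topology held fixed. Optimization is bounded quasi-Newton
#' (L-BFGS-B) on log-transformed parameters within
#' `omega in [1e-4, 20]`, `kappa in [1e-2, 1e2]`, `scale in [1e-3, 1e3]`,
#' from a deterministic start plus two seeded perturbed restarts.
#'
#' @param alignment A `codon_alignment` whose taxa equal the tree's tips.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param restarts Number of additional perturbed starts (default 2).
#' @param seed Seed for the restart perturbations (deterministic default 0).
#' @return A list with `params` (a [codon_model_params()] with the fitted
#'   values), `log_likelihood`, `boundary_flag` (TRUE if any estimate is
#'   within tolerance of an optimizer bound), and `convergence`.
#' @export
estimate_dnds_ml <- function(alignment, tree, restarts = 2, seed = 0) {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(tree, "phylo"))
  if (!setequal(alignment$taxa, tree$tip.label))
    stop_invalid("alignment taxa and tree tips differ")
  idx <- alignment_codon_indices(alignment)
  n_var <- sum(apply(idx, 2, function(col) length(unique(col)) > 1L))
  if (n_var < 2)
    stop_invalid("degenerate alignment: fewer than 2 variable codon columns")
  prep <- ml_prepare(alignment, tree)

  lower <- log(c(1e-4, 1e-2, 1e-3))
  upper <- log(c(20, 1e2, 1e3))
  tol <- 1e-4
  at_bound <- function(par) any(par < lower + tol) || any(par > upper - tol)
  starts <- list(log(c(0.5, 2, 1)))
  if (restarts > 0) {
    pert <- with_seed(derive_seed(seed, "ml-restarts"),
                      matrix(stats::runif(3 * restarts, -1.5, 1.5), ncol = 3))
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- pmin(pmax(starts[[1]] + pert[r, ], lower), upper)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, codon_nll, prep = prep, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e7, maxit = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    ## restarts guard against boundary traps; once an interior optimum has
    ## converged cleanly, further starts would re-find it
    if (best$convergence == 0 && !at_bound(best$par)) break
  }
  if (is.null(best)) stop_invalid("likelihood optimization failed")
  est <- exp(best$par)
  boundary <- at_bound(best$par)
  list(params = codon_model_params(est[1], est[2], branch_scale = est[3]),
       log_likelihood = -best$value,
       boundary_flag = boundary,
       convergence = best$convergence)
}

## ---- Nei-Gojobori (1986) counting estimator -------------------------------

## Synonymous site count of one codon: for each position, fraction of the
## three single-nucleotide changes (to sense codons) that are synonymous.
ng86_site_counts <- function() {
  tab <- codon_tables()
  if (!is.null(.codon_env$ng_sites)) return(.codon_env$ng_sites)
  n <- tab$n
  S <- numeric(n)
  bases <- c("T", "C", "A", "G")
  for (i in seq_len(n)) {
    s <- 0
    for (p in 1:3) {
      alt_syn <- 0; alt_tot <- 0
      for (b in bases) {
        if (b == tab$cmat[i, p]) next
        cod <- tab$cmat[i, ]; cod[p] <- b
        j <- match(paste(cod, collapse = ""), tab$codons)
        alt_tot <- alt_tot + 1
        if (!is.na(j) && tab$syn[i, j]) alt_syn <- alt_syn + 1
      }
      s <- s + alt_syn / 3
    }
    S[i] <- s
  }
  .codon_env$ng_sites <- list(S = S, N = 3 - S)
  .codon_env$ng_sites
}

## Average synonymous/nonsynonymous differences between two codons over all
## orderings of the changed positions, skipping pathways through stop codons.
ng86_codon_diffs <- function(i, j) {
  tab <- codon_tables()
  pos <- which(tab$cmat[i, ] != tab$cmat[j, ])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- if (length(pos) == 1) list(pos) else
    lapply(seq_len(nrow(perms <- permutations_of(pos))), function(r) perms[r, ])
  tot_s <- 0; tot_n <- 0; n_ok <- 0
  for (ord in paths) {
    cur <- i; s <- 0; nn <- 0; ok <- TRUE
    for (p in ord) {
      nxt_cod <- tab$cmat[cur, ]; nxt_cod[p] <- tab$cmat[j, p]
      nxt <- match(paste(nxt_cod, collapse = ""), tab$codons)
      if (is.na(nxt)) { ok <- FALSE; break }  # pathway through a stop codon
      if (tab$syn[cur, nxt]) s <- s + 1 else nn <- nn + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + nn; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(sd = 0, nd = length(pos)))  # all paths blocked
  c(sd = tot_s / n_ok, nd = tot_n / n_ok)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (k in seq_along(x))
    out <- rbind(out, cbind(x[k], permutations_of(x[-k])))
  out
}

#' Nei-Gojobori pairwise dN/dS estimate
#'
#' Counting estimator: synonymous and nonsynonymous sites per codon,
#' equal-pathway averaging of differences for codons differing at more than
#' one position (pathways through stop codons excluded), and Jukes-Cantor
#' correction of the proportions. Serves as an independent cross-check of
#' the likelihood estimator.
#'
#' @param seq_a,seq_b Codon sequences (strings) of equal length, no stops.
#' @return A list with `dN`, `dS`, and `ratio` (`NA` when `dS` is 0 or a
#'   proportion exceeds the Jukes-Cantor domain).
#' @export
estimate_dnds_ng86 <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop_invalid("sequences differ in length")
  ia <- alignment_codon_indices_chr(toupper(c(seq_a, seq_b)))
  if (anyNA(ia)) stop_invalid("sequences contain stop codons or invalid bases")
  sites <- ng86_site_counts()
  S_sites <- mean(c(sum(sites$S[ia[1, ]]), sum(sites$S[ia[2, ]])))
  N_sites <- mean(c(sum(sites$N[ia[1, ]]), sum(sites$N[ia[2, ]])))
  sd_tot <- 0; nd_tot <- 0
  for (k in seq_len(ncol(ia))) {
    if (ia[1, k] == ia[2, k]) next
    d <- ng86_codon_diffs(ia[1, k], ia[2, k])
    sd_tot <- sd_tot + d[["sd"]]; nd_tot <- nd_tot + d[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S_sites > 0) sd_tot / S_sites else 0
  pN <- if (N_sites > 0) nd_tot / N_sites else 0
  dS <- jc(pS); dN <- jc(pN)
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(dN = dN, dS = dS, ratio = ratio)
}

## ---- Mutation-count retention filters -------------------------------------

#' Approximate mutation count of a gene alignment
#'
#' The expected number of substitutions in the alignment: total tree length
#' (substitutions per nucleotide site) times the number of nucleotide columns.
#'
#' @param tree_length Total tree length (>= 0).
#' @param n_sites_nt Number of nucleotide columns (> 0).
#' @return `tree_length * n_sites_nt`.
#' @export
#' @examples
#' count_mutations(0.2, 300)  # 60
count_mutations <- function(tree_length, n_sites_nt) {
  if (tree_length < 0 || n_sites_nt < 0) stop_invalid("inputs must be >= 0")
  tree_length * n_sites_nt
}

#' Per-gene-family estimate record
#'
#' @param lineage_id,gene_id Identifiers.
#' @param dnds,kappa Point estimates.
#' @param n_sequences Number of sequences in the family.
#' @param n_sites_nt Nucleotide columns in the alignment.
#' @param tree_length Total tree length (substitutions per nt site).
#' @param log_likelihood Maximized log-likelihood.
#' @param boundary_flag TRUE if the estimate sits at an optimizer bound.
#' @return A one-row `data.frame` with a `mutation_count` column.
#' @export
gene_family_estimate <- function(lineage_id, gene_id, dnds, kappa,
                                 n_sequences, n_sites_nt, tree_length,
                                 log_likelihood = NA_real_,
                                 boundary_flag = FALSE) {
  data.frame(lineage_id = lineage_id, gene_id = gene_id, dnds = dnds,
             kappa = kappa, n_sequences = as.integer(n_sequences),
             n_sites_nt = as.integer(n_sites_nt), tree_length = tree_length,
             mutation_count = count_mutations(tree_length, n_sites_nt),
             log_likelihood = log_likelihood, boundary_flag = boundary_flag,
             stringsAsFactors = FALSE)
}

#' Apply the mutation-count retention filters
#'
#' A gene family is retained iff its mutation count is at least
#' `min_mutations`; a lineage is retained iff the fraction of its families
#' passing that condition is at least `min_fraction`. Within a retained
#' lineage only passing families propagate downstream.
#'
#' @param estimates A `data.frame` of [gene_family_estimate()] rows.
#' @param min_mutations Family-level threshold (default 32).
#' @param min_fraction Lineage-level threshold (default 0.7).
#' @return A list with `retained` (filtered data.frame), `retained_lineages`,
#'   `retained_families` (per retained lineage), and `exclusion_log`
#'   (data.frame of exclusions with reasons).
#' @export
apply_retention_filters <- function(estimates, min_mutations = 32,
                                    min_fraction = 0.7) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0)
    stop_invalid("estimates must be a non-empty data.frame")
  stopifnot(all(c("lineage_id", "gene_id", "mutation_count") %in%
                  names(estimates)))
  pass_fam <- estimates$mutation_count >= min_mutations
  frac <- tapply(pass_fam, estimates$lineage_id, mean)
  keep_lin <- names(frac)[frac >= min_fraction]
  keep_row <- estimates$lineage_id %in% keep_lin & pass_fam
  log_df <- data.frame(
    lineage_id = estimates$lineage_id[!keep_row],
    gene_id = estimates$gene_id[!keep_row],
    reason = ifelse(estimates$lineage_id[!keep_row] %in% keep_lin,
                    "family_below_min_mutations", "lineage_below_min_fraction"),
    stringsAsFactors = FALSE)
  retained <- estimates[keep_row, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       retained_lineages = sort(unique(retained$lineage_id)),
       retained_families = split(retained$gene_id, retained$lineage_id),
       exclusion_log = log_df)
}

#' Pick one representative family per cross-lineage gene group
#'
#' Within each group the family with the largest number of sequences is
#' retained; ties are broken by the lexicographically smallest family ID.
#'
#' @param families A `data.frame` with columns `group_id`, `family_id`,
#'   `n_sequences`.
#' @return A `data.frame` with one row per group.
#' @export
select_representative_paralog <- function(families) {
  if (!is.data.frame(families) || nrow(families) == 0)
    stop_invalid("families must be a non-empty data.frame")
  stopifnot(all(c("group_id", "family_id", "n_sequences") %in% names(families)))
  pick <- function(df) {
    df <- df[order(-df$n_sequences, df$family_id), , drop = FALSE]
    df[1, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(families, families$group_id), pick))
  rownames(out) <- NULL
  out[order(out$group_id), , drop = FALSE]
}
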