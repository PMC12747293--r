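## Additive decomposition of a lineage x gene matrix of log dN/dS values,
## r[L,G] = F[L] + R[G] + e[G,L], fitted by iterative backfitting (alternating
## row/column mean updates of the residuals) minimizing the sum of squared
## residuals E, with Bonferroni-corrected outlier removal and per-class refits.

#' Lineage-by-gene log dN/dS matrix
#'
#' @param values Numeric matrix (lineages x genes) of log dN/dS (natural log).
#' @param observed Logical matrix of the same shape marking observed cells;
#'   defaults to non-`NA` cells of `values`.
#' @param lineage_ids,gene_ids Unique identifiers (default from dimnames or
#'   generated).
#' @return An object of class `dnds_matrix`.
#' @export
dnds_matrix <- function(values, observed = NULL, lineage_ids = NULL,
                        gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!all(dim(values) == dim(observed)))
    stop_invalid("values and observed must have identical dimensions")
  if (nrow(values) == 0 || ncol(values) == 0)
    stop_invalid("matrix must be non-empty")
  lineage_ids <- lineage_ids %||% rownames(values) %||%
    sprintf("L%03d", seq_len(nrow(values)))
  gene_ids <- gene_ids %||% colnames(values) %||%
    sprintf("G%04d", seq_len(ncol(values)))
  if (anyDuplicated(lineage_ids) || anyDuplicated(gene_ids))
    stop_invalid("lineage and gene ids must be unique")
  if (any(rowSums(observed) == 0))
    stop_invalid("every lineage needs at least one observed cell")
  if (any(colSums(observed) == 0))
    stop_invalid("every gene needs at least one observed cell")
  if (any(!is.finite(values[observed])))
    stop_invalid("observed values must be finite")
  values[!observed] <- NA_real_
  dimnames(values) <- list(lineage_ids, gene_ids)
  dimnames(observed) <- dimnames(values)
  structure(list(lineage_ids = as.character(lineage_ids),
                 gene_ids = as.character(gene_ids),
                 values = values, observed = observed),
            class = "dnds_matrix")
}

#' @export
print.dnds_matrix <- function(x, ...) {
  cat(sprintf("dnds_matrix: %d lineages x %d genes, %.1f%% observed\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  invisible(x)
}

#' Decompose log dN/dS into lineage and gene constraints
#'
#' Fits `r[L,G] = F[L] + R[G] + e[G,L]` by iterative backfitting: starting
#' from zero, each iteration adds the mean residual over observed genes to
#' each lineage factor `F[L]`, then the mean residual over observed lineages
#' to each gene factor `R[G]`. Iteration stops when the change in the sum of
#' squared residuals `E` falls below `tol` or after `max_iter` iterations.
#' The fit is only identified up to a constant, so the gauge `mean(R) = 0`
#' is applied afterwards (the shift is absorbed into `F`).
#'
#' @param matrix A [dnds_matrix()].
#' @param tol Convergence tolerance on the change in `E` (default `1e-6`).
#' @param max_iter Maximum number of iterations (default 1000).
#' @return An object of class `decomposition_result` with fields `F`
#'   (named lineage factors), `R` (named gene factors), `residuals`
#'   (matrix, `NA` off-mask), `E`, `E_trajectory`, `n_iterations`,
#'   `converged`, `removed_cells`, and `gauge`.
#' @export
decompose <- function(matrix, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(matrix, "dnds_matrix"))
  V <- matrix$values
  obs <- matrix$observed
  nL <- nrow(V); nG <- ncol(V)
  F <- numeric(nL); R <- numeric(nG)  # initialized at zero
  E_prev <- Inf
  E_traj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    resid <- V - outer(F, R, "+")
    F <- F + rowMeans(resid, na.rm = TRUE)
    resid <- V - outer(F, R, "+")
    R <- R + colMeans(resid, na.rm = TRUE)
    resid <- V - outer(F, R, "+")
    E <- sum(resid[obs]^2)
    E_traj <- c(E_traj, E)
    if (E > E_prev + 1e-9)
      stop("internal error: objective increased during backfitting")
    if (is.finite(E_prev) && abs(E_prev - E) < tol) { converged <- TRUE }
    E_prev <- E
    if (converged || iter >= max_iter) break
  }
  shift <- mean(R)
  R <- R - shift
  F <- F + shift
  resid <- V - outer(F, R, "+")
  resid[!obs] <- NA_real_
  structure(list(F = stats::setNames(F, matrix$lineage_ids),
                 R = stats::setNames(R, matrix$gene_ids),
                 residuals = resid,
                 E = sum(resid[obs]^2),
                 E_trajectory = E_traj,
                 n_iterations = iter,
                 converged = converged,
                 removed_cells = data.frame(lineage_id = character(0),
                                            gene_id = character(0),
                                            z = numeric(0)),
                 gauge = "mean(R) = 0"),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(paste0("decomposition_result: %d lineages, %d genes, E = %.6g, ",
                     "%d iterations (%sconverged), %d cells removed\n"),
              length(x$F), length(x$R), x$E, x$n_iterations,
              if (x$converged) "" else "NOT ", nrow(x$removed_cells)))
  invisible(x)
}

#' Remove outlier cells and refit the decomposition
#'
#' Residuals from `first_fit` are standardized by their sample standard
#' deviation; cells whose two-sided normal tail probability falls below
#' `alpha / N` (Bonferroni over the `N` observed cells) are masked, and the
#' decomposition is rerun once on the reduced mask. Removals that would
#' empty a lineage row or gene column are skipped and logged.
#'
#' @param matrix The [dnds_matrix()] that produced `first_fit`.
#' @param first_fit A [decompose()] result for `matrix`.
#' @param alpha Familywise false-removal level (default 0.05).
#' @param tol,max_iter Passed through to the refit.
#' @return A `decomposition_result` with `removed_cells` filled in; attribute
#'   `skipped_removals` lists flagged cells that were kept to preserve
#'   coverage.
#' @export
remove_outliers_and_refit <- function(matrix, first_fit, alpha = 0.05,
                                      tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(matrix, "dnds_matrix"),
            inherits(first_fit, "decomposition_result"))
  obs <- matrix$observed
  res <- first_fit$residuals
  N <- sum(obs)
  s <- stats::sd(res[obs])
  ## an (almost) exact fit leaves only roundoff residuals: nothing to remove
  if (!is.finite(s) || s < 1e-8) return(first_fit)
  z <- res / s
  p <- 2 * stats::pnorm(-abs(z))
  flag <- which(obs & p < alpha / N, arr.ind = TRUE)
  if (nrow(flag) == 0) return(first_fit)
  ## most extreme first, so coverage-preserving skips drop the mildest cells
  flag <- flag[order(-abs(z[flag])), , drop = FALSE]
  new_obs <- obs
  removed <- NULL; skipped <- NULL
  for (k in seq_len(nrow(flag))) {
    i <- flag[k, 1]; j <- flag[k, 2]
    trial <- new_obs; trial[i, j] <- FALSE
    if (sum(trial[i, ]) == 0 || sum(trial[, j]) == 0) {
      skipped <- rbind(skipped, data.frame(
        lineage_id = matrix$lineage_ids[i], gene_id = matrix$gene_ids[j],
        z = z[i, j], stringsAsFactors = FALSE))
      next
    }
    new_obs <- trial
    removed <- rbind(removed, data.frame(
      lineage_id = matrix$lineage_ids[i], gene_id = matrix$gene_ids[j],
      z = z[i, j], stringsAsFactors = FALSE))
  }
  if (is.null(removed)) return(first_fit)
  m2 <- dnds_matrix(ifelse(new_obs, matrix$values, NA_real_), new_obs,
                    matrix$lineage_ids, matrix$gene_ids)
  refit <- decompose(m2, tol = tol, max_iter = max_iter)
  refit$removed_cells <- removed
  attr(refit, "skipped_removals") <-
    skipped %||% data.frame(lineage_id = character(0), gene_id = character(0),
                            z = numeric(0))
  refit
}

#' Decompose per functional class of genes
#'
#' Splits the gene set by `class_of_gene`, drops (per class) lineages with
#' fewer than `min_genes_per_lineage` observed genes in that class, runs
#' [decompose()] on each qualifying submatrix, and reports the pairwise
#' Spearman concordance of the class-specific lineage factors over shared
#' lineages.
#'
#' @param matrix A [dnds_matrix()].
#' @param class_of_gene Named character vector mapping every gene id to a
#'   class label.
#' @param min_genes_per_lineage Minimum observed genes per lineage per class
#'   (default 10).
#' @param tol,max_iter Passed to [decompose()].
#' @return A list with `fits` (named list of `decomposition_result`) and
#'   `concordance` (data.frame: class_a, class_b, n_shared, rho).
#' @export
decompose_by_class <- function(matrix, class_of_gene,
                               min_genes_per_lineage = 10,
                               tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(matrix, "dnds_matrix"))
  if (!all(matrix$gene_ids %in% names(class_of_gene)))
    stop_invalid("class_of_gene must cover every gene id")
  classes <- split(matrix$gene_ids,
                   as.character(class_of_gene[matrix$gene_ids]))
  fits <- list()
  for (cl in names(classes)) {
    genes <- classes[[cl]]
    jj <- match(genes, matrix$gene_ids)
    sub_obs <- matrix$observed[, jj, drop = FALSE]
    keep_lin <- rowSums(sub_obs) >= min_genes_per_lineage
    keep_gene <- colSums(sub_obs[keep_lin, , drop = FALSE]) > 0
    if (!any(keep_lin) || !any(keep_gene)) {
      warning(sprintf("class '%s' has no qualifying lineage; skipped", cl))
      next
    }
    vals <- matrix$values[keep_lin, jj[keep_gene], drop = FALSE]
    fits[[cl]] <- decompose(
      dnds_matrix(vals, matrix$observed[keep_lin, jj[keep_gene], drop = FALSE],
                  matrix$lineage_ids[keep_lin], genes[keep_gene]),
      tol = tol, max_iter = max_iter)
  }
  cls <- names(fits)
  conc <- NULL
  if (length(cls) >= 2) {
    for (a in seq_along(cls)) for (b in seq_along(cls)) {
      if (b <= a) next
      shared <- intersect(names(fits[[cls[a]]]$F), names(fits[[cls[b]]]$F))
      rho <- if (length(shared) >= 3)
        spearman(fits[[cls[a]]]$F[shared], fits[[cls[b]]]$F[shared])$rho
      else NA_real_
      conc <- rbind(conc, data.frame(class_a = cls[a], class_b = cls[b],
                                     n_shared = length(shared), rho = rho,
                                     stringsAsFactors = FALSE))
    }
  }
  list(fits = fits,
       concordance = conc %||% data.frame(class_a = character(0),
                                          class_b = character(0),
                                          n_shared = integer(0),
                                          rho = numeric(0)))
}

#' Read / write a dN/dS matrix as TSV
#'
#' Lineages are rows, genes are columns; the first column holds lineage ids
#' and empty cells mark missing values.
#'
#' @param path File path.
#' @param matrix A [dnds_matrix()].
#' @return `read_dnds_matrix_tsv` returns a `dnds_matrix`;
#'   `write_dnds_matrix_tsv` returns `path` invisibly.
#' @export
read_dnds_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1, na.strings = "",
                          stringsAsFactors = FALSE)
  dnds_matrix(as.matrix(df), lineage_ids = rownames(df),
              gene_ids = colnames(df))
}

#' @rdname read_dnds_matrix_tsv
#' @export
write_dnds_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "dnds_matrix"))
  chr <- matrix(fmt_num(matrix$values), nrow = nrow(matrix$values))
  out <- cbind(lineage_id = matrix$lineage_ids,
               as.data.frame(chr, optional = TRUE))
  colnames(out) <- c("lineage_id", matrix$gene_ids)
  write_tsv_file(out, path)
}
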