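## Correlation layer: Spearman rank correlation with asymptotic p-values,
## BCa bootstrap confidence intervals, the subsampling null used to rule out
## sample-size artifacts, and per-node correlations mapped onto a phylogeny.

#' Spearman rank correlation with asymptotic p-value
#'
#' Rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation with `n - 2` degrees of freedom (the "asymptotic p-value").
#' For `n <= 8` an exact permutation p-value can be requested.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @param exact If TRUE and `n <= 8`, compute the exact permutation p-value.
#' @return A list with `rho`, `p_value`, `n`, and `method`.
#' @export
#' @examples
#' spearman(1:10, (1:10)^2)$rho  # 1
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("values must be finite")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_invalid("Spearman correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (exact && n <= 8) {
    perms <- permutations_of(seq_len(n))
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "spearman-exact"
  } else {
    if (abs(rho) >= 1) {
      p_value <- .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
      p_value <- max(min(p_value, 1), .Machine$double.xmin)
    }
    method <- "spearman-t"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}

#' BCa bootstrap confidence interval for a paired statistic
#'
#' Resamples `(x_i, y_i)` pairs with replacement, computes the statistic on
#' each resample, and applies the bias-corrected and accelerated adjustment:
#' the bias correction `z0` comes from the fraction of bootstrap statistics
#' below the point estimate (ties counted half), and the acceleration `a`
#' from the jackknife third-moment formula. Resamples on which the statistic
#' fails are redrawn up to a retry budget.
#'
#' @param x,y Paired numeric vectors (length >= 8).
#' @param statistic Function of `(x, y)` returning a scalar; defaults to
#'   Spearman's rho.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A list with `ci_low`, `ci_high`, `z0`, `acceleration`,
#'   `n_bootstrap`, and the `point` estimate.
#' @export
bca_ci <- function(x, y, statistic = function(x, y) spearman(x, y)$rho,
                   n_bootstrap = 1000, level = 0.95, seed = 1) {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y must have equal length")
  if (n < 8) stop_invalid("need at least 8 pairs for a BCa interval")
  point <- statistic(x, y)
  safe_stat <- function(xi, yi) {
    v <- try(statistic(xi, yi), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) NA_real_ else v
  }
  boot <- with_seed(derive_seed(seed, "bca-boot"), {
    out <- numeric(n_bootstrap)
    fails <- 0L
    budget <- 10L * n_bootstrap
    b <- 0L
    while (b < n_bootstrap && fails < budget) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- safe_stat(x[idx], y[idx])
      if (is.na(v)) { fails <- fails + 1L; next }
      b <- b + 1L
      out[b] <- v
    }
    if (b < n_bootstrap)
      stop_invalid("statistic failed on too many bootstrap resamples (%d failures)",
                   fails)
    attr(out, "n_failed") <- fails
    out
  })
  if (attr(boot, "n_failed") > 0.1 * n_bootstrap)
    stop_invalid("statistic failed on more than 10%% of resamples")
  if (max(boot) - min(boot) < 1e-12)
    return(list(ci_low = point, ci_high = point, z0 = 0, acceleration = 0,
                n_bootstrap = n_bootstrap, point = point))
  prop <- (sum(boot < point) + 0.5 * sum(boot == point)) / n_bootstrap
  prop <- min(max(prop, 1 / (2 * n_bootstrap)), 1 - 1 / (2 * n_bootstrap))
  z0 <- stats::qnorm(prop)
  ## jackknife acceleration
  jack <- vapply(seq_len(n),
                 function(i) safe_stat(x[-i], y[-i]), numeric(1))
  jack <- jack[is.finite(jack)]
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / denom else 0
  alpha <- (1 - level) / 2
  adj <- function(q) {
    zq <- stats::qnorm(q)
    stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  qs <- stats::quantile(boot, probs = c(adj(alpha), adj(1 - alpha)),
                        names = FALSE, type = 6)
  list(ci_low = qs[1], ci_high = qs[2], z0 = z0, acceleration = a,
       n_bootstrap = n_bootstrap, point = point)
}

#' Full correlation result with BCa confidence interval
#'
#' Convenience wrapper combining [spearman()] and [bca_ci()].
#'
#' @inheritParams bca_ci
#' @return A list of class `correlation_result` with `rho`, `p_value`, `n`,
#'   `ci_low`, `ci_high`, `n_bootstrap`, `method`.
#' @export
correlate_with_ci <- function(x, y, n_bootstrap = 1000, level = 0.95,
                              seed = 1) {
  sp <- spearman(x, y)
  ci <- bca_ci(x, y, n_bootstrap = n_bootstrap, level = level, seed = seed)
  structure(list(rho = sp$rho, p_value = sp$p_value, n = sp$n,
                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n_bootstrap = n_bootstrap,
                 method = "spearman-t + BCa"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman R = %.3f, 95%% CI = %.3f - %.3f, p = %.3g (n = %d)\n",
              x$rho, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Subsampling null distribution of a correlation
#'
#' Repeatedly draws `subsample_size` observations without replacement and
#' computes Spearman's rho on each draw — the reference distribution for
#' judging whether a correlation seen in a small group could arise from
#' subsampling a larger one.
#'
#' @param x,y Paired numeric vectors (`length > subsample_size`).
#' @param subsample_size Draw size (default 19).
#' @param n_draws Number of draws (default 10000).
#' @param seed Integer seed.
#' @return A list with `rhos` (length `n_draws`), `minimum`, and
#'   `fraction_at_or_below(threshold)` (an empirical CDF function).
#' @export
subsample_null <- function(x, y, subsample_size = 19, n_draws = 10000,
                           seed = 1) {
  n <- length(x)
  if (length(y) != n) stop_invalid("x and y must have equal length")
  if (subsample_size < 3) stop_invalid("subsample_size must be >= 3")
  if (n <= subsample_size)
    stop_invalid("need more observations than subsample_size")
  rhos <- with_seed(derive_seed(seed, "subsample-null"),
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(n, subsample_size)
      spearman(x[idx], y[idx])$rho
    }, numeric(1)))
  list(rhos = rhos, minimum = min(rhos),
       fraction_at_or_below = function(threshold) mean(rhos <= threshold))
}

#' Per-node correlations mapped onto a phylogeny
#'
#' For every internal node with strictly more than `min_descendants`
#' descendant tips, computes Spearman's correlation between the two lineage
#' variables over the node's descendants. Nodes at or below the threshold
#' are reported as absent (`NA`).
#'
#' @param lineage_tree A `phylo` tree whose tips are lineages.
#' @param covariate,constraint Named numeric vectors covering all tips.
#' @param min_descendants Strict descendant-count threshold (default 15).
#' @return A `data.frame`: `node`, `n_descendants`, `rho`, `p_value`
#'   (rows for qualifying nodes only).
#' @export
per_node_correlations <- function(lineage_tree, covariate, constraint,
                                  min_descendants = 15) {
  stopifnot(inherits(lineage_tree, "phylo"))
  tips <- lineage_tree$tip.label
  if (!all(tips %in% names(covariate)) || !all(tips %in% names(constraint)))
    stop_invalid("covariate and constraint must cover every tip")
  ntip <- length(tips)
  desc <- descendant_tips(lineage_tree)
  rows <- NULL
  for (node in (ntip + 1L):(ntip + lineage_tree$Nnode)) {
    labs <- tips[desc[[node]]]
    if (length(labs) <= min_descendants) next
    sp <- try(spearman(covariate[labs], constraint[labs]), silent = TRUE)
    if (inherits(sp, "try-error")) next
    rows <- rbind(rows, data.frame(node = node, n_descendants = length(labs),
                                   rho = sp$rho, p_value = sp$p_value))
  }
  rows %||% data.frame(node = integer(0), n_descendants = integer(0),
                       rho = numeric(0), p_value = numeric(0))
}
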