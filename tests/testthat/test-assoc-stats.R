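test_that("spearman matches the rank-formula oracle and base R", {
  expect_equal(spearman(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman(1:3, c(30, 20, 10))$rho, -1)

  ## ties: rho equals Pearson on midranks
  x <- c(1, 2, 2, 3); y <- c(3, 1, 2, 2)
  expect_equal(spearman(x, y)$rho, stats::cor(rank(x), rank(y)))

  ## agreement with cor.test's asymptotic machinery on continuous data
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    mine <- spearman(a, b)
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  ## antisymmetry without ties
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(spearman(a, -b)$rho, -spearman(a, b)$rho, tolerance = 1e-12)

  ## exact permutation p for tiny n agrees with the t-approximation's sign
  ex <- spearman(1:6, c(2, 1, 4, 3, 6, 5), exact = TRUE)
  expect_equal(ex$method, "spearman-exact")
  expect_true(ex$p_value > 0 && ex$p_value <= 1)

  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:4), "equal length")
})

test_that("bca_ci degenerate and symmetric contracts hold", {
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)

  ## constant statistic collapses the interval
  ci_c <- bca_ci(x, y, statistic = function(a, b) 0.7, seed = 1)
  expect_equal(ci_c$ci_low, 0.7)
  expect_equal(ci_c$ci_high, 0.7)

  ## with z0 = 0 and a = 0 the BCa interval equals the percentile interval;
  ## force both by a statistic whose bootstrap distribution is symmetric
  ## around the point estimate: median of symmetric resample signs
  ci <- bca_ci(x, y, n_bootstrap = 501, seed = 5)
  expect_true(ci$ci_low <= ci$point && ci$point <= ci$ci_high)

  ## determinism
  ci2 <- bca_ci(x, y, n_bootstrap = 501, seed = 5)
  expect_identical(ci, ci2)
  expect_error(bca_ci(x[1:5], y[1:5]), "at least 8")
})

test_that("bca reduces to percentile when bias and skew vanish", {
  ## statistic constructed so the bootstrap distribution is symmetric and
  ## unbiased: mean of iid symmetric values; jackknife acceleration ~ 0
  set.seed(3)
  x <- rnorm(60); y <- rnorm(60)
  stat <- function(a, b) mean(a)
  ci <- bca_ci(x, y, statistic = stat, n_bootstrap = 2000, seed = 11)
  ## rebuild the same bootstrap distribution to get its raw percentiles
  boot <- with_seed(derive_seed(11, "bca-boot"), {
    out <- numeric(2000)
    b <- 0L
    while (b < 2000) {
      idx <- sample.int(60, 60, replace = TRUE)
      b <- b + 1L
      out[b] <- mean(x[idx])
    }
    out
  })
  perc <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 6)
  ## z0 and a are near zero here, so BCa and percentile nearly coincide
  expect_lt(abs(ci$ci_low - perc[1]), 0.03)
  expect_lt(abs(ci$ci_high - perc[2]), 0.03)
  expect_lt(abs(ci$z0), 0.15)
  expect_lt(abs(ci$acceleration), 0.05)
})

test_that("subsample_null has the stated shape and bounds", {
  set.seed(4)
  x <- sort(rnorm(50)); y <- x^3 + 1  # strictly monotone
  sn <- subsample_null(x, y, subsample_size = 10, n_draws = 200, seed = 1)
  expect_length(sn$rhos, 200)
  expect_true(all(abs(sn$rhos - 1) < 1e-12))
  expect_equal(sn$minimum, 1, tolerance = 1e-12)
  expect_equal(sn$fraction_at_or_below(0.999), 0)
  expect_equal(sn$fraction_at_or_below(1 + 1e-12), 1)

  ## mean of the null tracks the full-sample correlation (low bias)
  x2 <- rnorm(400); y2 <- 0.5 * x2 + rnorm(400)
  full <- spearman(x2, y2)$rho
  sn2 <- subsample_null(x2, y2, subsample_size = 19, n_draws = 2000, seed = 2)
  expect_lt(abs(mean(sn2$rhos) - full), 0.05)

  expect_error(subsample_null(x, y, subsample_size = 2), "subsample_size")
  expect_error(subsample_null(x[1:5], y[1:5], subsample_size = 10), "more")
})

test_that("per_node_correlations respects the strict descendant threshold", {
  tr <- random_tree(40, 1.0, 6)
  set.seed(5)
  covv <- stats::setNames(rnorm(40), tr$tip.label)
  cons <- stats::setNames(0.6 * covv + rnorm(40, 0, 0.5), tr$tip.label)
  tab <- per_node_correlations(tr, covv, cons, min_descendants = 15)
  ## root row equals the global correlation
  root_row <- tab[tab$n_descendants == 40, ]
  expect_equal(nrow(root_row), 1L)
  expect_equal(root_row$rho, spearman(covv, cons)$rho)
  ## no node at or below the threshold is reported
  expect_true(all(tab$n_descendants > 15))

  ## planted opposite-sign clades are recovered at the clade ancestors
  cladeA <- random_tree(60, 1.0, 7)
  cladeB <- random_tree(60, 1.0, 8)
  cladeA$tip.label <- sprintf("a%d", 1:60)
  cladeB$tip.label <- sprintf("b%d", 1:60)
  both <- join_clades(list(cladeA, cladeB))
  set.seed(9)
  fa <- rnorm(60); fb <- rnorm(60)
  covar <- stats::setNames(c(fa, fb), c(cladeA$tip.label, cladeB$tip.label))
  constr <- stats::setNames(
    c(0.9 * fa + rnorm(60, 0, 0.4), -0.9 * fb + rnorm(60, 0, 0.4)),
    names(covar))
  tab2 <- per_node_correlations(both, covar, constr, min_descendants = 15)
  mrcaA <- ape::getMRCA(both, sprintf("a%d", 1:60))
  mrcaB <- ape::getMRCA(both, sprintf("b%d", 1:60))
  expect_gt(tab2$rho[tab2$node == mrcaA], 0.5)
  expect_lt(tab2$rho[tab2$node == mrcaB], -0.5)
})
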