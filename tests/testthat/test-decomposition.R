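test_that("decompose solves hand-checkable matrices exactly", {
  m <- dnds_matrix(matrix(c(1, 3, 2, 4), 2, 2))
  fit <- decompose(m)
  expect_equal(unname(fit$F), c(1.5, 3.5))
  expect_equal(unname(fit$R), c(-0.5, 0.5))
  expect_equal(fit$E, 0)
  expect_true(all(abs(fit$residuals) < 1e-12))

  ## single lineage: gauge forces F = row mean
  m1 <- dnds_matrix(matrix(c(0.1, 0.5, 0.9), 1, 3))
  f1 <- decompose(m1)
  expect_equal(unname(f1$F), 0.5)
  expect_equal(unname(f1$R), c(-0.4, 0, 0.4))
  expect_equal(f1$E, 0)
})

test_that("backfitting equals the normal-equations solution (oracle)", {
  ## small matrices with 30% missing cells and noise, varied shapes
  set.seed(3)
  for (rep in 1:12) {
    nL <- sample(3:12, 1); nG <- sample(4:15, 1)
    vals <- outer(rnorm(nL), rnorm(nG), "+") + rnorm(nL * nG, 0, 0.4)
    obs <- matrix(TRUE, nL, nG)
    drop <- sample(nL * nG, floor(0.3 * nL * nG))
    obs[drop] <- FALSE
    if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) next
    m <- dnds_matrix(ifelse(obs, vals, NA), obs)
    fit <- decompose(m, tol = 1e-13, max_iter = 20000)
    ref <- oracle_two_way_ls(vals, obs)
    expect_equal(unname(fit$F), ref$F, tolerance = 1e-6)
    expect_equal(unname(fit$R), ref$R, tolerance = 1e-6)
  }
})

test_that("decompose invariants: monotone E, gauge, equivariance", {
  g <- generate_dnds_matrix(8, 15, residual_sd = 0.4, missing_fraction = 0.25,
                            seed = 5)
  fit <- decompose(g$matrix)
  ## E non-increasing along the trajectory
  expect_true(all(diff(fit$E_trajectory) <= 1e-9))
  ## gauge
  expect_lt(abs(mean(fit$R)), 1e-9)
  ## E consistency with residuals
  expect_equal(fit$E, sum(fit$residuals[g$matrix$observed]^2),
               tolerance = 1e-9)
  ## residual row/column means vanish at convergence
  expect_lt(max(abs(rowMeans(fit$residuals, na.rm = TRUE))), 1e-5)
  expect_lt(max(abs(colMeans(fit$residuals, na.rm = TRUE))), 1e-5)

  ## permutation equivariance
  pi_r <- sample(8); pi_c <- sample(15)
  mp <- dnds_matrix(g$matrix$values[pi_r, pi_c],
                    g$matrix$observed[pi_r, pi_c],
                    g$matrix$lineage_ids[pi_r], g$matrix$gene_ids[pi_c])
  fitp <- decompose(mp)
  expect_equal(unname(fitp$F), unname(fit$F[pi_r]), tolerance = 1e-7)
  expect_equal(unname(fitp$R), unname(fit$R[pi_c]), tolerance = 1e-7)

  ## gauge: a constant added to the data lands entirely in F, R untouched
  mshift <- dnds_matrix(g$matrix$values + 2.5, g$matrix$observed,
                        g$matrix$lineage_ids, g$matrix$gene_ids)
  fits <- decompose(mshift)
  expect_equal(unname(fits$F), unname(fit$F) + 2.5, tolerance = 1e-7)
  expect_equal(unname(fits$R), unname(fit$R), tolerance = 1e-7)

  expect_error(dnds_matrix(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("outlier removal flags exactly the gross outliers", {
  ## exactly additive: nothing removed, same object back
  g0 <- generate_dnds_matrix(6, 8, residual_sd = 0, seed = 1)
  f0 <- decompose(g0$matrix)
  expect_identical(remove_outliers_and_refit(g0$matrix, f0), f0)

  ## single gross outlier in an otherwise additive 10x10 matrix
  vals <- outer(seq(-1, 1, length.out = 10), seq(-0.5, 0.5, length.out = 10),
                "+")
  vals[4, 7] <- vals[4, 7] + 10
  m <- dnds_matrix(vals)
  first <- decompose(m)
  refit <- remove_outliers_and_refit(m, first)
  expect_equal(nrow(refit$removed_cells), 1L)
  expect_equal(refit$removed_cells$lineage_id, m$lineage_ids[4])
  expect_equal(refit$removed_cells$gene_id, m$gene_ids[7])
  expect_lt(refit$E, 1e-8)

  ## planted-shift recovery at scale (z-score oracle scale)
  g <- generate_dnds_matrix(50, 200, residual_sd = 0.3,
                            outlier_fraction = 0.01, outlier_shift = 3,
                            seed = 9)
  fit <- decompose(g$matrix)
  refit <- remove_outliers_and_refit(g$matrix, fit)
  planted <- paste(g$truth$outlier_cells[, 1], g$truth$outlier_cells[, 2])
  removed <- paste(match(refit$removed_cells$lineage_id, g$matrix$lineage_ids),
                   match(refit$removed_cells$gene_id, g$matrix$gene_ids))
  sens <- mean(planted %in% removed)
  expect_gte(sens, 0.9)
  expect_lte(sum(!(removed %in% planted)), 2)  # ~Bonferroni-controlled
})

test_that("per-class decomposition honors thresholds and recovers shared F", {
  ## partition identity: one class equals the global fit on qualifying rows
  g <- generate_dnds_matrix(10, 30, residual_sd = 0.2, seed = 4)
  one <- stats::setNames(rep("all", 30), g$matrix$gene_ids)
  bc <- decompose_by_class(g$matrix, one, min_genes_per_lineage = 10)
  expect_named(bc$fits, "all")
  global <- decompose(g$matrix)
  expect_equal(bc$fits$all$F, global$F, tolerance = 1e-9)

  ## class-independent F: concordance across classes
  g2 <- generate_dnds_matrix(20, 400, residual_sd = 0.3, seed = 6)
  classes <- stats::setNames(rep(c("info", "cellular", "metabolism", "poor"),
                                 each = 100), g2$matrix$gene_ids)
  bc2 <- decompose_by_class(g2$matrix, classes)
  expect_length(bc2$fits, 4L)
  expect_true(all(bc2$concordance$rho >= 0.9))

  ## lineages below the per-class gene threshold are dropped
  obs <- matrix(TRUE, 5, 20)
  obs[1, 1:12] <- FALSE  # lineage 1 has only 8 observed genes in classA
  vals <- outer(rnorm(5), rnorm(20), "+")
  m <- dnds_matrix(ifelse(obs, vals, NA), obs,
                   sprintf("L%d", 1:5), sprintf("G%02d", 1:20))
  cls <- stats::setNames(rep("classA", 20), m$gene_ids)
  bc3 <- decompose_by_class(m, cls, min_genes_per_lineage = 10)
  expect_false("L1" %in% names(bc3$fits$classA$F))
  expect_true(all(sprintf("L%d", 2:5) %in% names(bc3$fits$classA$F)))
})

test_that("dnds matrix TSV round-trips with missing cells", {
  g <- generate_dnds_matrix(5, 7, missing_fraction = 0.2, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dnds_matrix_tsv(g$matrix, path)
  back <- read_dnds_matrix_tsv(path)
  expect_identical(back$lineage_ids, g$matrix$lineage_ids)
  expect_identical(back$gene_ids, g$matrix$gene_ids)
  expect_identical(back$observed, g$matrix$observed)
  expect_equal(back$values, g$matrix$values, tolerance = 1e-10)
})
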