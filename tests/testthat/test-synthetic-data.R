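test_that("random_tree honors its contract and is seed-deterministic", {
  tr2 <- random_tree(2, 1.0, 7)
  expect_s3_class(tr2, "phylo")
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(sum(tr2$edge.length), 1.0, tolerance = 1e-12)

  a <- ape::write.tree(random_tree(20, 1.0, 42))
  b <- ape::write.tree(random_tree(20, 1.0, 42))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(random_tree(20, 1.0, 43))))

  tr50 <- random_tree(50, 2.0, 1)
  expect_equal(length(tr50$tip.label), 50L)
  expect_equal(tr50$Nnode, 49L)          # rooted binary: n - 1 internal nodes
  expect_equal(nrow(tr50$edge), 98L)     # 2n - 2 edges
  expect_equal(sum(tr50$edge.length), 2.0, tolerance = 1e-9)
  ## binary: every internal node has exactly two children
  kids <- table(tr50$edge[, 1])
  expect_true(all(kids == 2))

  expect_error(random_tree(1, 1.0, 1), "n_tips")
})

test_that("random_tree does not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(random_tree(10, 1.0, 5))
  expect_identical(before, .Random.seed)
})

test_that("generate_dnds_matrix plants the declared structure", {
  ## noiseless additive case: decomposition recovers truth exactly
  g <- generate_dnds_matrix(6, 9, residual_sd = 0, missing_fraction = 0,
                            seed = 2)
  fit <- decompose(g$matrix)
  expect_equal(fit$E, 0, tolerance = 1e-18)
  expect_equal(unname(fit$F), g$truth$true_F, tolerance = 1e-9)
  expect_equal(unname(fit$R), g$truth$true_R, tolerance = 1e-9)

  ## gauge: planted gene factors always have mean zero
  for (s in 1:5) {
    g2 <- generate_dnds_matrix(5, 40, seed = s)
    expect_lt(abs(mean(g2$truth$true_R)), 1e-12)
  }

  ## masking never empties a row or column
  g3 <- generate_dnds_matrix(8, 10, missing_fraction = 0.4, seed = 3)
  expect_true(all(rowSums(g3$matrix$observed) > 0))
  expect_true(all(colSums(g3$matrix$observed) > 0))
  expect_equal(sum(!g3$matrix$observed), floor(0.4 * 80))

  ## determinism
  a <- generate_dnds_matrix(10, 20, missing_fraction = 0.3, seed = 11)
  b <- generate_dnds_matrix(10, 20, missing_fraction = 0.3, seed = 11)
  expect_identical(a$matrix$values, b$matrix$values)

  ## observed cells equal truth + residual (+shift): reconstruct residuals
  g4 <- generate_dnds_matrix(10, 20, residual_sd = 0.3, outlier_fraction = 0.05,
                             outlier_shift = 2, seed = 4)
  res <- g4$matrix$values - outer(g4$truth$true_F, g4$truth$true_R, "+")
  out_idx <- g4$truth$outlier_cells
  expect_gt(nrow(out_idx), 0)
  expect_true(all(abs(res[out_idx]) > 1))  # shifted cells stand out
})

test_that("presence/absence simulation matches its generative process", {
  tr <- random_tree(6, 1.0, 5)

  ## no-event limit
  p0 <- gain_loss_params(0, 1e-12, root_presence_prob = 1, n_families = 20,
                         seed = 1)
  sim0 <- simulate_presence_absence(tr, p0)
  expect_true(all(sim0$ancestral$states == 1L))
  expect_identical(sim0$true_gains + sim0$true_losses, 0L)

  ## tip states in the ancestral table equal the pam
  p1 <- gain_loss_params(2, 2, n_families = 50, seed = 3)
  sim1 <- simulate_presence_absence(tr, p1)
  expect_identical(sim1$ancestral$states[seq_len(6), ], sim1$pam$states)

  ## determinism
  sim1b <- simulate_presence_absence(tr, p1)
  expect_identical(sim1$ancestral$states, sim1b$ancestral$states)

  ## realized gain totals agree with a Monte-Carlo oracle
  mk <- function(seed) simulate_presence_absence(
    tr, gain_loss_params(2, 2, n_families = 1000, seed = seed))$true_gains
  obs <- mk(101)
  ref <- vapply(1:25, mk, integer(1))
  expect_lt(abs(obs - mean(ref)), 4 * stats::sd(ref))

  ## generative asymmetry shows up in flux computed from TRUE states
  tr2 <- random_tree(8, 3.0, 9)
  sim2 <- simulate_presence_absence(tr2, gain_loss_params(3, 1,
                                                          root_presence_prob = 0.5,
                                                          n_families = 400,
                                                          seed = 7))
  fl <- compute_flux(tr2, sim2$ancestral)
  expect_true(fl$flux_defined)
  expect_gt(fl$flux_ratio, 1)
})

test_that("tip presence frequency approaches the stationary probability", {
  ## two tips at the end of branches of length 10 each: essentially stationary
  tr <- random_tree(2, 20, 1)
  gain <- 1.2; loss <- 0.8
  sim <- simulate_presence_absence(tr, gain_loss_params(gain, loss,
                                                        root_presence_prob = 0,
                                                        n_families = 10000,
                                                        seed = 5))
  p_stat <- gain / (gain + loss)
  freq <- mean(sim$pam$states)
  se <- sqrt(p_stat * (1 - p_stat) / (2 * 10000))
  expect_lt(abs(freq - p_stat), 3 * se + 1e-3)
})

test_that("generate_lineage_covariates couples ranks as requested", {
  set.seed(1)
  F1 <- rnorm(50)
  ## monotone coupling at rho = 1
  cov1 <- generate_lineage_covariates(F1, 1, seed = 1)
  expect_equal(spearman(F1, cov1)$rho, 1)
  expect_true(all(cov1 > 0))

  ## independence at rho = 0, large n
  F2 <- stats::rnorm(1000)
  cov2 <- generate_lineage_covariates(F2, 0, seed = 2)
  expect_lt(abs(spearman(F2, cov2)$rho), 0.1)

  ## Monte-Carlo mean near the target at n = 19
  F3 <- stats::rnorm(19)
  rhos <- vapply(1:2000, function(s)
    spearman(F3, generate_lineage_covariates(F3, -0.82, seed = s))$rho,
    numeric(1))
  expect_lt(abs(mean(rhos) - (-0.82)), 0.05)

  expect_error(generate_lineage_covariates(F1, 1.2, seed = 1), "target_rho")
  expect_error(generate_lineage_covariates(rnorm(2), 0.5, seed = 1), "length")
})
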