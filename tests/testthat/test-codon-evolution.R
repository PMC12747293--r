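test_that("codon rate matrix has the stated structure", {
  tab <- selscape:::codon_tables()
  expect_equal(tab$n, 61L)

  p_eq <- codon_model_params(omega = 1, kappa = 1)
  Q <- build_codon_rate_matrix(p_eq)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  ## omega = kappa = 1, equal frequencies: all permitted rates identical
  off <- Q[tab$single]
  expect_equal(max(off), min(off))
  ## multi-step pairs have rate zero
  expect_true(all(Q[!tab$single & !diag(61) > 0] == 0))

  ## stationary distribution equals the codon frequencies (eigenvector oracle)
  p <- codon_model_params(0.3, 2.5)
  Q2 <- build_codon_rate_matrix(p)
  pi_hat <- selscape:::stationary_distribution(Q2)
  expect_equal(pi_hat, p$codon_frequencies, tolerance = 1e-10)

  ## omega = 0 kills every nonsynonymous entry
  Q0 <- build_codon_rate_matrix(codon_model_params(0, 2))
  nonsyn <- tab$single & !tab$syn
  expect_true(all(Q0[nonsyn] == 0))

  ## detailed balance under equal frequencies: Q symmetric
  expect_lt(max(abs(Q2 - t(Q2))), 1e-12)

  ## normalization: expected rate is 3 per codon (1 per nucleotide site)
  expect_equal(-sum(p$codon_frequencies * diag(Q2)), 3, tolerance = 1e-12)
})

test_that("simulate_alignment respects limits and the event-count oracle", {
  tr <- random_tree(5, 1.0, 3)
  p <- codon_model_params(0.3, 2)

  tr0 <- tr; tr0$edge.length[] <- 0
  aln0 <- simulate_alignment(tr0, p, 50, seed = 1)
  expect_equal(length(unique(aln0$sequences)), 1L)
  expect_identical(attr(aln0, "n_events"), 0L)

  ## omega = 0: all tips translate to the same protein
  aln_cons <- simulate_alignment(tr, codon_model_params(0, 2), 100, seed = 2)
  prot <- vapply(aln_cons$sequences, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(Biostrings::GENETIC_CODE[cods], collapse = "")
  }, character(1))
  expect_equal(length(unique(prot)), 1L)

  ## Poisson expectation: tree length 1, 1000 codons -> ~3000 substitutions
  tr1 <- random_tree(10, 1.0, 8)
  aln <- simulate_alignment(tr1, codon_model_params(0.3, 2), 1000, seed = 5)
  expect_lt(abs(attr(aln, "n_events") - 3000), 3 * sqrt(3000))

  ## determinism and truncation
  a <- simulate_alignment(tr, p, 30, seed = 9)
  b <- simulate_alignment(tr, p, 30, seed = 9)
  expect_identical(a$sequences, b$sequences)
  short <- truncate_alignment(a, 10)
  expect_equal(short$length_codons, 10L)
  expect_identical(short$sequences, substr(a$sequences, 1, 30))

  expect_error(simulate_alignment(tr, p, 0, seed = 1), "n_codons")
})

test_that("estimate_dnds_ml recovers simulation parameters", {
  tr <- random_tree(10, 1.0, 21)
  aln <- simulate_alignment(tr, codon_model_params(0.2, 2.0), 500, seed = 31)
  fit <- estimate_dnds_ml(aln, tr)
  expect_gt(fit$params$omega, 0.15)
  expect_lt(fit$params$omega, 0.27)
  expect_false(fit$boundary_flag)
  expect_true(is.finite(fit$log_likelihood))

  ## degenerate input contract
  same <- codon_alignment(stats::setNames(rep(strrep("ATG", 20), 10),
                                          tr$tip.label))
  expect_error(estimate_dnds_ml(same, tr), "degenerate")

  ## taxa mismatch
  bad <- aln; bad$taxa[1] <- "nope"
  expect_error(estimate_dnds_ml(bad, tr), "taxa")
})

test_that("likelihood is maximized near the simulating parameters", {
  tr <- random_tree(8, 1.0, 77)
  truth <- c(0.3, 2, 1)
  aln <- simulate_alignment(tr, codon_model_params(truth[1], truth[2]), 400,
                            seed = 13)
  prep <- selscape:::ml_prepare(aln, tr)
  nll_true <- selscape:::codon_nll(log(truth), prep)
  fit <- estimate_dnds_ml(aln, tr)
  expect_lte(-fit$log_likelihood, nll_true + 1e-6)
  ## and not absurdly better: truth lies within the typical LRT range
  expect_lt(nll_true + fit$log_likelihood, 10)
})

test_that("NG86 matches the brute-force pathway enumeration oracle", {
  ## hand-checkable cases
  r0 <- estimate_dnds_ng86("TTTAAA", "TTTAAA")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))

  ## one synonymous difference in a context long enough for the JC domain
  r1 <- estimate_dnds_ng86("TTTAAAGGGCCC", "TTCAAAGGGCCC")
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)

  ## random simulated pairs vs the independent enumeration oracle
  tr2 <- random_tree(2, 0.6, 5)
  for (s in 1:4) {
    aln <- simulate_alignment(tr2, codon_model_params(0.5, 2), 100, seed = s)
    mine <- estimate_dnds_ng86(aln$sequences[1], aln$sequences[2])
    ref <- oracle_ng86_pair(aln$sequences[1], aln$sequences[2])
    expect_equal(mine$dN, ref$dN, tolerance = 1e-10)
    expect_equal(mine$dS, ref$dS, tolerance = 1e-10)
  }

  expect_error(estimate_dnds_ng86("TTT", "TTTAAA"), "length")
})

test_that("ML and NG86 estimators rank alignments consistently", {
  ## moderate divergence: high enough for signal, below JC saturation
  tr2 <- random_tree(2, 0.3, 17)
  omegas <- rep(c(0.1, 0.5, 1.0), length.out = 36)
  est <- t(vapply(seq_along(omegas), function(i) {
    aln <- simulate_alignment(tr2, codon_model_params(omegas[i], 2), 500,
                              seed = 1000 + i)
    ml <- estimate_dnds_ml(aln, tr2)$params$omega
    ng <- estimate_dnds_ng86(aln$sequences[1], aln$sequences[2])$ratio
    c(ml = ml, ng = ng)
  }, c(ml = 0, ng = 0)))
  ok <- stats::complete.cases(est)
  expect_gt(sum(ok), 30)
  expect_gte(spearman(est[ok, "ml"], est[ok, "ng"])$rho, 0.9)
})

test_that("mutation counting and retention filters follow the stated rules", {
  expect_equal(count_mutations(0.2, 300), 60)
  expect_equal(count_mutations(0, 500), 0)
  expect_lt(count_mutations(0.1, 300), 32)  # fails the retention threshold

  mk <- function(lineage, n, n_pass) {
    do.call(rbind, lapply(seq_len(n), function(i)
      gene_family_estimate(lineage, sprintf("%s_g%02d", lineage, i),
                           dnds = 0.2, kappa = 2, n_sequences = 10,
                           n_sites_nt = 100,
                           tree_length = if (i <= n_pass) 0.4 else 0.1)))
  }
  est <- rbind(mk("L1", 10, 7), mk("L2", 10, 6))
  f <- apply_retention_filters(est)
  expect_identical(f$retained_lineages, "L1")      # 0.7 inclusive, 0.6 not
  expect_equal(nrow(f$retained), 7L)
  expect_true(all(f$retained$mutation_count >= 32))
  expect_equal(sum(f$exclusion_log$reason == "lineage_below_min_fraction"), 10L)

  ## boundary: exactly 32 mutations everywhere is retained
  est32 <- mk("L3", 5, 0)
  est32$mutation_count <- 32
  f32 <- apply_retention_filters(est32)
  expect_equal(nrow(f32$retained), 5L)

  ## idempotence
  f2 <- apply_retention_filters(f$retained)
  expect_identical(f2$retained, f$retained)

  expect_error(apply_retention_filters(est[0, ]), "non-empty")
})

test_that("representative paralog selection is deterministic", {
  fams <- data.frame(group_id = c("C1", "C1", "C2", "C2", "C3"),
                     family_id = c("famA", "famB", "famB", "famA", "famZ"),
                     n_sequences = c(10, 7, 5, 5, 3))
  rep1 <- select_representative_paralog(fams)
  expect_equal(rep1$family_id[rep1$group_id == "C1"], "famA")  # max count
  expect_equal(rep1$family_id[rep1$group_id == "C2"], "famA")  # lexicographic
  expect_equal(rep1$family_id[rep1$group_id == "C3"], "famZ")  # singleton
  expect_error(select_representative_paralog(fams[0, ]), "non-empty")
})

test_that("alignment FASTA round-trips", {
  tr <- random_tree(4, 0.5, 2)
  aln <- simulate_alignment(tr, codon_model_params(0.3, 2), 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".fna")
  write_alignment_fasta(aln, path)
  back <- read_alignment_fasta(path)
  expect_identical(back$sequences, aln$sequences)
  expect_identical(back$taxa, aln$taxa)
})
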