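test_that("demography validates its parameters", {
  expect_s3_class(demography("constant", 2, 2, n = 10), "demography")
  expect_error(demography("constant", 1, 2, n = 10), class = "molexpand_input_error")
  expect_error(demography("sudden_expansion", -1, 10, 1, n = 10),
    class = "molexpand_input_error"
  )
  expect_error(demography("sudden_expansion", 1, 10, -1, n = 10),
    class = "molexpand_input_error"
  )
  expect_error(demography("constant", 1, 1, n = 1), class = "molexpand_input_error")
})

test_that("theta = 0 gives monomorphic samples; same seed reproduces the sample", {
  sims <- simulate(demography("constant", 0, 0, n = 8), nsim = 5, seed = 42)
  expect_true(all(vapply(sims, function(s) ncol(s$genotypes) == 0L, logical(1))))
  aln <- as_alignment(sims[[1]])
  expect_equal(nrow(unique(aln$seq)), 1L)

  # determinism: same config + seed -> identical panel; replicate i does
  # not depend on nsim
  cfg <- demography("sudden_expansion", 1, 100, 3, n = 12)
  a <- simulate(cfg, nsim = 3, seed = 7)
  b <- simulate(cfg, nsim = 3, seed = 7)
  expect_identical(
    lapply(a, function(s) s$genotypes),
    lapply(b, function(s) s$genotypes)
  )
  c1 <- simulate(cfg, nsim = 1, seed = 7)[[1]]
  expect_identical(c1$genotypes, a[[1]]$genotypes)
})

test_that("constant-size simulator matches coalescent expectations", {
  # n = 2, theta = 1: E[pairwise difference] = theta = 1
  sims <- simulate(demography("constant", 1, 1, n = 2), nsim = 6000, seed = 11)
  d <- vapply(sims, function(s) ncol(s$genotypes), numeric(1)) # n=2: every site separates the pair
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1), 3 * se)

  # n = 10, theta = 2: E[S] = theta * a1, E[k_bar] = theta (Watterson)
  a1 <- sum(1 / (1:9))
  sims <- simulate(demography("constant", 2, 2, n = 10), nsim = 6000, seed = 13)
  S <- vapply(sims, function(s) ncol(s$genotypes), numeric(1))
  expect_lt(abs(mean(S) - 2 * a1), 3 * stats::sd(S) / sqrt(length(S)))
  kb <- vapply(sims, function(s) mean(molexpand:::.genotype_diffs(s$genotypes)), numeric(1))
  expect_lt(abs(mean(kb) - 2), 3 * stats::sd(kb) / sqrt(length(kb)))

  # and again at n = 5 (scaling of the Watterson factor with n)
  a1 <- sum(1 / (1:4))
  sims <- simulate(demography("constant", 2, 2, n = 5), nsim = 4000, seed = 17)
  S <- vapply(sims, function(s) ncol(s$genotypes), numeric(1))
  expect_lt(abs(mean(S) - 2 * a1), 3 * stats::sd(S) / sqrt(length(S)))
})

test_that("sudden-expansion panel collapses to the constant model at tau = 0", {
  pan <- simulate_expansion_panel(2, 2, 0, n = 10, reps = 3000, seed = 19)
  kb1 <- vapply(pan, function(s) mean(molexpand:::.genotype_diffs(s$genotypes)), numeric(1))
  con <- simulate(demography("constant", 2, 2, n = 10), nsim = 3000, seed = 23)
  kb2 <- vapply(con, function(s) mean(molexpand:::.genotype_diffs(s$genotypes)), numeric(1))
  se <- sqrt(stats::var(kb1) / length(kb1) + stats::var(kb2) / length(kb2))
  expect_lt(abs(mean(kb1) - mean(kb2)), 3 * se)
})

test_that("Poisson limit: theta0 = 0, huge theta1 puts the mismatch mean at tau", {
  pan <- simulate_expansion_panel(0, 1e4, 3, n = 50, reps = 800, seed = 29)
  pooled <- unlist(lapply(pan, function(s) {
    as.vector(molexpand:::.genotype_diffs(s$genotypes))
  }))
  # pairs within a replicate are correlated; use a generous Monte-Carlo band
  expect_lt(abs(mean(pooled) - 3), 0.15)
})

test_that("fixed-S null conditions exactly on S", {
  # S = 0 -> monomorphic
  sims <- fixed_s_null(6, 0, reps = 10, seed = 31)
  expect_true(all(vapply(sims, function(s) ncol(s$genotypes) == 0L, logical(1))))

  # n = 2, S = 5 -> the pair differs at exactly 5 sites, every replicate
  sims <- fixed_s_null(2, 5, reps = 20, seed = 37)
  d <- vapply(sims, function(s) as.vector(molexpand:::.genotype_diffs(s$genotypes)), numeric(1))
  expect_true(all(d == 5))

  # n = 10, S = 10: mean Tajima's D over the null is close to zero
  sims <- fixed_s_null(10, 10, reps = 4000, seed = 41)
  D <- vapply(sims, function(s) {
    G <- s$genotypes
    tajimas_d(10, ncol(G), mean(molexpand:::.genotype_diffs(G)))
  }, numeric(1))
  expect_gt(mean(D), -0.3)
  expect_lt(mean(D), 0.3)
})

test_that("downstream statistics are exchangeable under relabelling", {
  sim <- simulate(demography("sudden_expansion", 1, 1000, 3, n = 20), nsim = 1, seed = 43)[[1]]
  G <- sim$genotypes
  perm <- sample(nrow(G))
  sim2 <- sim
  sim2$genotypes <- G[perm, , drop = FALSE]
  expect_equal(observed_mismatch(sim)$counts, observed_mismatch(sim2)$counts)
  expect_equal(diversity(sim)$k_bar, diversity(sim2)$k_bar)
})

test_that("alignment export is reproducible and respects the site budget", {
  sim <- simulate(demography("sudden_expansion", 1, 1000, 3, n = 10, k = 60), nsim = 1, seed = 47)[[1]]
  a1 <- as_alignment(sim)
  a2 <- as_alignment(sim)
  expect_identical(a1$seq, a2$seq)
  expect_equal(a1$k, 60)
  # the exported alignment carries exactly the simulated differences
  expect_equal(
    as.vector(pairwise_differences(a1)$diffs),
    as.vector(molexpand:::.genotype_diffs(sim$genotypes))
  )
  # more segregating sites than positions is refused
  big <- sim
  big$genotypes <- matrix(0L, 10, 61)
  expect_error(as_alignment(big, k = 60), class = "molexpand_input_error")
})

test_that("finite-sites Jukes-Cantor export produces valid sequences", {
  cfg <- demography("sudden_expansion", 1, 500, 3, n = 8, k = 200, sites = "jc")
  sim <- simulate(cfg, nsim = 1, seed = 53)[[1]]
  aln <- as_alignment(sim)
  expect_equal(aln$n, 8)
  expect_equal(aln$k, 200)
  expect_true(all(aln$seq %in% c("A", "C", "G", "T")))
  # same seed, same sequences
  sim2 <- simulate(cfg, nsim = 1, seed = 53)[[1]]
  expect_identical(sim$seqs, sim2$seqs)
})
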