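# Independent oracle for Tajima's D: a literal, standalone transcription of
# the constant cascade, kept separate from the package implementation.
oracle_tajima <- function(n, S, kbar) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (kbar - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

test_that("diversity matches exhaustive pair enumeration", {
  # two sequences differing at one of ten sites
  dv <- diversity(fix_aln("ACGTACGTAC", "ACGTACGTAA"))
  expect_equal(dv$S, 1)
  expect_equal(dv$k_bar, 1)
  expect_equal(dv$pi, 0.1)

  # monomorphic sample
  dv0 <- diversity(fix_aln("ACGT", "ACGT", "ACGT"))
  expect_equal(dv0$S, 0)
  expect_equal(dv0$k_bar, 0)
  expect_equal(dv0$pi, 0)

  # four sequences, three variable columns: brute force over all 6 pairs
  seqs <- c("AAAAACGTAC", "AATAACGTAC", "AATAACGTCC", "AAAAACTTAC")
  aln <- fix_aln(seqs[1], seqs[2], seqs[3], seqs[4])
  dv4 <- diversity(aln)
  expect_equal(dv4$S, 3)
  expect_equal(dv4$k_bar, mean(brute_all_pairs(seqs)))

  expect_error(diversity(fix_aln("ACGT")), class = "molexpand_input_error")
})

test_that("Tajima's D reproduces the formula cascade and boundary behaviour", {
  # numerator vanishes when k_bar equals the Watterson estimate
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(10, 5, 5 / a1), 0)

  # frozen fixture (n = 4, S = 3, k_bar = 1.5), checked against the
  # independent transcription above
  expect_equal(tajimas_d(4, 3, 1.5), oracle_tajima(4, 3, 1.5))
  expect_equal(round(tajimas_d(4, 3, 1.5), 3), -0.754)

  # a handful of (n, S, kbar) combinations against the oracle
  for (n in c(5, 20, 60)) {
    for (S in c(1, 7, 30)) {
      kbar <- S / sum(1 / seq_len(n - 1)) * 0.7
      expect_equal(tajimas_d(n, S, kbar), oracle_tajima(n, S, kbar))
    }
  }

  # S = 0 is undefined, not silently zero
  expect_error(tajimas_d(10, 0, 0), class = "molexpand_undefined_statistic")
})

test_that("duplicating every haplotype leaves the sign of D stable", {
  # star-like fixture: one common haplotype plus rare one-step derivatives,
  # a clear negative-D signal (far from the D = 0 boundary)
  seqs <- c(
    "AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "AAAAAAAA",
    "TAAAAAAA", "ACAAAAAA", "AAGAAAAA"
  )
  aln1 <- do.call(fix_aln, as.list(seqs))
  dv1 <- diversity(aln1)
  aln2 <- do.call(fix_aln, as.list(c(seqs, seqs)))
  dv2 <- diversity(aln2)
  d1 <- tajimas_d(dv1$n, dv1$S, dv1$k_bar)
  d2 <- tajimas_d(dv2$n, dv2$S, dv2$k_bar)
  expect_equal(sign(d1), sign(d2))
})

test_that("Ewens distribution: hand-enumerated case, normalization, monotone tail", {
  # n = 3, theta = 1: |s(3, k)| = (2, 3, 1), denominator 6
  expect_equal(ewens_k_pmf(3, 1), c(2, 3, 1) / 6)
  expect_equal(fus_fs(3, 1, 2), log(2))

  # k_obs = 1 -> S' = 1 -> +Inf (finite with a cap)
  expect_identical(fus_fs(10, 2, 1), Inf)
  expect_equal(fus_fs(10, 2, 1, cap = 999), 999)

  # log-space Stirling recurrence keeps the distribution normalized far
  # beyond integer overflow
  for (n in c(10, 50, 130, 200)) {
    expect_lt(abs(sum(ewens_k_pmf(n, 3.7)) - 1), 1e-12)
  }

  # Fs is non-increasing in k_obs for fixed n and theta
  fs <- vapply(1:20, function(k) fus_fs(20, 2.5, k), numeric(1))
  expect_true(all(diff(fs) <= 1e-12))

  expect_error(fus_fs(10, 0, 3), class = "molexpand_undefined_statistic")
})

test_that("Fs = 0 when the tail and head probabilities are equal", {
  # binary search theta so that P(K >= k) = 0.5; Fs must then vanish
  n <- 12
  k <- 5
  f <- function(th) sum(ewens_k_pmf(n, th)[k:n]) - 0.5
  th <- uniroot(f, c(0.01, 50), tol = 1e-14)$root
  expect_lt(abs(fus_fs(n, th, k)), 1e-6)
})

test_that("neutrality p-values respect the add-one rule and determinism", {
  aln <- fix_aln("AAAAA", "AAAAT", "AATAT", "CAAAT", "AAAAA", "TAAAT")
  nt1 <- neutrality_test(aln, reps = 100, seed = 5)
  nt2 <- neutrality_test(aln, reps = 100, seed = 5)
  expect_identical(nt1$p_D, nt2$p_D)
  expect_identical(nt1$p_Fs, nt2$p_Fs)
  # add-one: p in [1/(reps+1), 1]
  expect_gte(nt1$p_D, 1 / 101)
  expect_lte(nt1$p_D, 1)
  expect_gte(nt1$p_Fs, 1 / 101)

  # fixed-S null is accepted as an alternative
  nt3 <- neutrality_test(aln, reps = 100, seed = 5, null = "fixed_s")
  expect_s3_class(nt3, "neutrality_summary")
  expect_gte(nt3$p_D, 1 / 101)

  # degenerate observed data: NA p-values with a reason
  mono <- fix_aln("ACGT", "ACGT", "ACGT", "ACGT")
  ntm <- neutrality_test(mono, reps = 100, seed = 5)
  expect_true(is.na(ntm$D))
  expect_true(is.na(ntm$p_D))
  expect_match(attr(ntm, "reason"), "monomorphic")
})

test_that("expansion samples give strongly negative Fu's Fs on average", {
  pan <- simulate_expansion_panel(1, 1000, 3, n = 50, reps = 40, seed = 59)
  fs <- vapply(pan, function(s) {
    G <- s$genotypes
    fus_fs(nrow(G), mean(molexpand:::.genotype_diffs(G)), nrow(unique(G)), cap = 50)
  }, numeric(1))
  expect_lt(mean(fs), 0)
})
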