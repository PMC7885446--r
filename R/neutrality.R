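## popgen_stats: diversity summaries and neutrality tests.

#' Diversity summary of an alignment
#'
#' Computes the number of segregating sites S (columns with at least two
#' distinct unambiguous states), the mean number of pairwise nucleotide
#' differences k_bar (pairwise deletion, averaged over all n(n-1)/2 pairs)
#' and the nucleotide diversity per site pi = k_bar normalised by the mean
#' number of usable sites per pair.
#'
#' @param aln A [hap_alignment] (or `coalsim_sample`).
#' @return Object of class `diversity_summary`: list with `n`, `S`,
#'   `k_bar`, `pi`, `mean_usable`.
#' @export
diversity <- function(aln) {
  if (inherits(aln, "coalsim_sample")) {
    G <- aln$genotypes
    if (is.null(G)) {
      return(diversity(as_alignment(aln)))
    }
    n <- nrow(G)
    if (n < 2L) abort_input("diversity needs n >= 2")
    d <- .genotype_diffs(G)
    k <- aln$config$k
    out <- list(
      n = n, S = ncol(G), k_bar = mean(d),
      pi = mean(d) / k, mean_usable = k
    )
    return(structure(out, class = "diversity_summary"))
  }
  stopifnot(inherits(aln, "hap_alignment"))
  if (aln$n < 2L) abort_input("diversity needs n >= 2")
  code <- .encode(aln$seq)
  S <- sum(apply(code, 2L, function(z) {
    z <- z[!is.na(z)]
    length(z) > 0L && any(z != z[1L])
  }))
  pd <- pairwise_differences(aln)
  k_bar <- mean(pd$diffs)
  mu <- mean(pd$usable)
  structure(
    list(
      n = aln$n, S = S, k_bar = k_bar,
      pi = if (mu > 0) k_bar / mu else 0, mean_usable = mu
    ),
    class = "diversity_summary"
  )
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, S = %d, mean pairwise differences = %.4g, pi = %.4g\n",
    x$n, x$S, x$k_bar, x$pi
  ))
  invisible(x)
}

#' Tajima's D
#'
#' The classical contrast between the mean number of pairwise differences
#' and the Watterson estimate S/a1, normalised by its estimated standard
#' deviation. Negative values indicate an excess of rare variants, the
#' signature of population growth.
#'
#' @param n Sample size.
#' @param S Number of segregating sites; the statistic is undefined for
#'   S = 0 and a classed condition (`molexpand_undefined_statistic`) is
#'   signalled rather than silently returning 0.
#' @param k_bar Mean pairwise differences.
#' @return Tajima's D (numeric scalar).
#' @export
#' @examples
#' tajimas_d(n = 4, S = 3, k_bar = 1.5)
tajimas_d <- function(n, S, k_bar) {
  if (n < 2) abort_input("tajimas_d needs n >= 2")
  if (S == 0) abort_undefined("Tajima's D is undefined when S = 0")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## --- Ewens sampling distribution -----------------------------------------

## Cache of log unsigned Stirling numbers of the first kind, one row per n.
.stirling_cache <- new.env(parent = emptyenv())

#' Log unsigned Stirling numbers of the first kind, |s(n, k)| for k = 1..n
#'
#' Computed by the recurrence |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|
#' carried entirely in log space, so that sample sizes in the hundreds
#' (where the integers overflow) remain exact to double precision.
#'
#' @param n Row to return (n >= 1).
#' @return Numeric vector of length n: log |s(n, k)|.
#' @export
log_stirling1 <- function(n) {
  n <- as.integer(n)
  if (n < 1L) abort_input("n must be >= 1")
  key <- as.character(n)
  hit <- .stirling_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- 0 # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      a <- c(log(m) + r, -Inf) # n |s(m, k)|, k = 1..m+1
      b <- c(-Inf, r) #   |s(m, k-1)|
      r <- lse2(a, b)
    }
  }
  .stirling_cache[[key]] <- r
  r
}

#' Ewens distribution of the number of distinct haplotypes
#'
#' P(K = k) = |s(n, k)| theta^k / (theta (theta + 1) ... (theta + n - 1)),
#' the sampling distribution of the number of alleles in a neutral sample
#' of size n with scaled mutation rate theta.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @param log Return log-probabilities?
#' @return Numeric vector of length n (probabilities for k = 1..n).
#' @export
ewens_k_pmf <- function(n, theta, log = FALSE) {
  if (theta <= 0) abort_input("theta must be > 0")
  lst <- log_stirling1(n)
  k <- seq_len(n)
  logdenom <- sum(base::log(theta + 0:(n - 1)))
  lp <- lst + k * base::log(theta) - logdenom
  if (log) lp else exp(lp)
}

#' Fu's Fs
#'
#' With S' = P(K >= k_obs | theta) under the Ewens sampling distribution,
#' Fs = ln(S') - ln(1 - S'). Strongly negative values arise when far more
#' haplotypes are observed than theta (estimated from the mean pairwise
#' differences) predicts -- the signature of recent expansion. Computed in
#' log space; S' numerically 0 or 1 yields +/-Inf unless `cap` is given.
#'
#' @param n Sample size.
#' @param theta_hat Scaled mutation parameter, conventionally the mean
#'   number of pairwise differences (> 0; 0 is undefined and signalled).
#' @param k_obs Observed number of distinct haplotypes (1..n).
#' @param cap Optional finite magnitude at which to clamp +/-Inf results.
#' @return Fu's Fs (numeric scalar, possibly +/-Inf).
#' @export
#' @examples
#' fus_fs(n = 3, theta_hat = 1, k_obs = 2) # = log(2)
fus_fs <- function(n, theta_hat, k_obs, cap = NULL) {
  if (n < 2) abort_input("fus_fs needs n >= 2")
  if (k_obs < 1 || k_obs > n) abort_input("k_obs must be in 1..n")
  if (theta_hat <= 0) abort_undefined("Fu's Fs is undefined for theta_hat = 0")
  lp <- ewens_k_pmf(n, theta_hat, log = TRUE)
  if (k_obs == 1L) {
    fs <- Inf # K >= 1 always: S' = 1
  } else {
    ltail <- logsumexp(lp[k_obs:n]) # log S'
    lhead <- logsumexp(lp[1:(k_obs - 1L)]) # log(1 - S')
    ## renormalise against round-off so Fs = 0 exactly when tail == head
    tot <- lse2(ltail, lhead)
    fs <- (ltail - tot) - (lhead - tot)
  }
  if (!is.null(cap) && is.infinite(fs)) fs <- sign(fs) * cap
  fs
}

## Statistics of one simulated replicate, with the degenerate conventions
## used for null distributions: S = 0 gives D := 0 and Fs := +Inf (a
## monomorphic sample has exactly one haplotype).
.null_stats <- function(G) {
  n <- nrow(G)
  S <- ncol(G)
  if (S == 0L) {
    return(c(D = 0, Fs = Inf))
  }
  d <- .genotype_diffs(G)
  kb <- mean(d)
  kobs <- nrow(unique(G))
  D <- tajimas_d(n, S, kb)
  Fs <- if (kb > 0) fus_fs(n, kb, kobs) else Inf
  c(D = D, Fs = Fs)
}

#' Neutrality tests with coalescent-simulation p-values
#'
#' Computes Tajima's D and Fu's Fs for the observed data and their
#' one-sided (lower-tail) p-values from replicates of a constant-size
#' coalescent simulation: either with theta fixed at the observed mean
#' pairwise differences (`null = "fixed_theta"`, the default) or
#' conditional on the observed number of segregating sites
#' (`null = "fixed_s"`). P-values use the add-one rule
#' p = (1 + #(sim <= obs)) / (1 + reps), so they are never zero.
#' Simulated replicates with S = 0 contribute D = 0 and Fs = +Inf.
#'
#' @param x A [hap_alignment], `coalsim_sample`, or a list with elements
#'   `n`, `S`, `k_bar`, `k_obs`.
#' @param reps Number of null replicates (>= 100; the conventional choice
#'   is 1000).
#' @param seed Integer master seed for the null simulation.
#' @param null `"fixed_theta"` or `"fixed_s"`.
#' @param two_sided_d Also report a two-sided p-value for D (proportion of
#'   replicates with |D| >= |obs|)?
#' @return Object of class `neutrality_summary`: list with `D`, `p_D`,
#'   `Fs`, `p_Fs`, `reps`, `null` (and `p_D_two_sided` on request).
#'   Degenerate observed statistics (S = 0 or k_bar = 0) are reported as
#'   `NA` with a `reason` attribute.
#' @export
neutrality_test <- function(x, reps = 1000, seed = NULL,
                            null = c("fixed_theta", "fixed_s"),
                            two_sided_d = FALSE) {
  null <- match.arg(null)
  if (reps < 100) abort_input("reps must be >= 100 for stable p-values")
  if (inherits(x, "hap_alignment")) {
    dv <- diversity(x)
    obs <- list(
      n = dv$n, S = dv$S, k_bar = dv$k_bar,
      k_obs = collapse_haplotypes(x)$k_obs
    )
  } else if (inherits(x, "coalsim_sample")) {
    G <- x$genotypes
    obs <- list(
      n = nrow(G), S = ncol(G),
      k_bar = mean(.genotype_diffs(G)), k_obs = nrow(unique(G))
    )
  } else {
    obs <- x
    stopifnot(all(c("n", "S", "k_bar", "k_obs") %in% names(obs)))
  }

  degenerate <- obs$S == 0 || obs$k_bar == 0
  D_obs <- if (obs$S > 0) tajimas_d(obs$n, obs$S, obs$k_bar) else NA_real_
  Fs_obs <- if (obs$k_bar > 0) fus_fs(obs$n, obs$k_bar, obs$k_obs) else NA_real_

  sims <- if (null == "fixed_theta") {
    theta <- max(obs$k_bar, 1e-8)
    simulate(demography("constant", theta0 = theta, theta1 = theta, n = obs$n),
      nsim = reps, seed = seed
    )
  } else {
    fixed_s_null(obs$n, obs$S, reps, seed = seed)
  }
  stats <- vapply(sims, function(s) .null_stats(s$genotypes), numeric(2))

  p_D <- if (is.na(D_obs)) NA_real_ else (1 + sum(stats["D", ] <= D_obs)) / (1 + reps)
  p_Fs <- if (is.na(Fs_obs)) NA_real_ else (1 + sum(stats["Fs", ] <= Fs_obs)) / (1 + reps)
  out <- list(
    D = D_obs, p_D = p_D, Fs = Fs_obs, p_Fs = p_Fs,
    reps = reps, null = null, n = obs$n, S = obs$S,
    k_bar = obs$k_bar, k_obs = obs$k_obs
  )
  if (two_sided_d) {
    out$p_D_two_sided <- if (is.na(D_obs)) NA_real_ else (1 + sum(abs(stats["D", ]) >= abs(D_obs))) / (1 + reps)
  }
  if (degenerate) attr(out, "reason") <- "observed sample is monomorphic; D and Fs undefined"
  structure(out, class = "neutrality_summary")
}

#' @export
print.neutrality_summary <- function(x, ...) {
  cat(sprintf(
    "Tajima's D = %.4g (p = %.4g), Fu's Fs = %.4g (p = %.4g) [%s null, %d reps]\n",
    x$D, x$p_D, x$Fs, x$p_Fs, x$null, x$reps
  ))
  cat("  (Fu's Fs is conventionally called significant at p < 0.02.)\n")
  invisible(x)
}
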