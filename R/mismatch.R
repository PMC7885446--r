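## mismatch: observed and model-expected mismatch distributions,
## least-squares sudden-expansion fitting, parametric bootstrap.

#' Observed mismatch distribution
#'
#' The histogram of pairwise nucleotide differences over all n(n-1)/2
#' unordered pairs (pairwise-deletion distances). For a haplotype table the
#' pairs are frequency-weighted, which reproduces exactly the distribution
#' of the underlying sample.
#'
#' @param x A [hap_alignment], `hap_table`, `coalsim_sample`, or a numeric
#'   vector of pairwise difference counts.
#' @param ... Unused.
#' @return Object of class `mismatch_dist`: list with `counts` (named
#'   vector over d = 0..d_max), `freqs`, `n_pairs` and `n` (sample size
#'   when known).
#' @export
observed_mismatch <- function(x, ...) UseMethod("observed_mismatch")

.mk_mismatch <- function(d, weights = NULL, n = NA_integer_) {
  if (!length(d)) abort_input("mismatch distribution needs at least one pair (n >= 2)")
  dmax <- max(d)
  counts <- numeric(dmax + 1)
  if (is.null(weights)) weights <- rep(1, length(d))
  for (i in seq_along(d)) counts[d[i] + 1] <- counts[d[i] + 1] + weights[i]
  names(counts) <- 0:dmax
  structure(
    list(
      counts = counts, freqs = counts / sum(counts),
      n_pairs = sum(counts), n = n
    ),
    class = "mismatch_dist"
  )
}

#' @rdname observed_mismatch
#' @export
observed_mismatch.hap_alignment <- function(x, ...) {
  if (x$n < 2L) abort_input("mismatch distribution needs n >= 2")
  pd <- pairwise_differences(x)
  .mk_mismatch(as.vector(pd$diffs), n = x$n)
}

#' @rdname observed_mismatch
#' @export
observed_mismatch.hap_table <- function(x, ...) {
  if (x$n < 2L) abort_input("mismatch distribution needs n >= 2")
  f <- x$frequency
  m <- x$k_obs
  d0 <- sum(choose(f, 2)) # identical pairs within haplotypes
  if (m == 1L) {
    return(.mk_mismatch(0L, weights = d0, n = x$n))
  }
  D <- as.matrix(pairwise_differences(x)$diffs)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  w <- f[ut[, 1]] * f[ut[, 2]]
  .mk_mismatch(c(0L, d), weights = c(d0, w), n = x$n)
}

#' @rdname observed_mismatch
#' @export
observed_mismatch.coalsim_sample <- function(x, ...) {
  if (is.null(x$genotypes)) {
    return(observed_mismatch(as_alignment(x)))
  }
  n <- nrow(x$genotypes)
  if (n < 2L) abort_input("mismatch distribution needs n >= 2")
  .mk_mismatch(as.vector(.genotype_diffs(x$genotypes)), n = n)
}

#' @rdname observed_mismatch
#' @export
observed_mismatch.numeric <- function(x, ...) .mk_mismatch(as.integer(x))

#' @export
print.mismatch_dist <- function(x, ...) {
  cat(sprintf(
    "Mismatch distribution: %g pairs, d = 0..%d, mean = %.3g\n",
    x$n_pairs, length(x$counts) - 1L, mismatch_mean(x)
  ))
  invisible(x)
}

#' Mean of a mismatch distribution
#' @param x A `mismatch_dist` (or frequency vector over d = 0, 1, ...).
#' @return Mean number of pairwise differences.
#' @export
mismatch_mean <- function(x) {
  f <- if (inherits(x, "mismatch_dist")) x$freqs else x / sum(x)
  sum((seq_along(f) - 1) * f)
}

#' Equilibrium mismatch distribution
#'
#' F_d(theta) = theta^d / (theta + 1)^(d + 1), the geometric distribution
#' of pairwise differences in a stationary population with scaled mutation
#' parameter theta.
#'
#' @param theta Scaled mutation parameter (>= 0).
#' @param d_max Largest difference class to return.
#' @return Numeric probability vector over d = 0..d_max. The truncated tail
#'   mass is (theta / (theta + 1))^(d_max + 1).
#' @export
equilibrium_mismatch <- function(theta, d_max) {
  if (theta < 0) abort_input("theta must be >= 0")
  .expected_mismatch_cpp(0, theta, max(theta, 1e-12), as.integer(d_max))
}

#' Transient mismatch distribution of the sudden-expansion model
#'
#' Distribution of pairwise differences tau mutational time units after an
#' instantaneous change of the scaled mutation parameter from theta0 to
#' theta1:
#' \deqn{F_d = \hat F_d(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{i=0}^{d} \frac{\tau^i}{i!}
#'   [\hat F_{d-i}(\theta_0) - \hat F_{d-i}(\theta_1)]}
#' with \eqn{\hat F} the equilibrium distribution. Limits: tau = 0 gives
#' the theta0 equilibrium; tau -> Inf the theta1 equilibrium; theta0 = 0
#' with theta1 -> Inf the Poisson(tau) distribution.
#'
#' @param tau Expansion age in mutational time units (>= 0).
#' @param theta0,theta1 Parameters before/after the expansion.
#' @param d_max Largest difference class to return.
#' @return Numeric probability vector over d = 0..d_max (the full
#'   distribution over d = 0..Inf sums to 1; the returned vector omits the
#'   truncated tail).
#' @export
#' @examples
#' round(expected_mismatch(3, 1, 1000, d_max = 6), 4)
expected_mismatch <- function(tau, theta0, theta1, d_max) {
  if (tau < 0 || theta0 < 0 || theta1 < 0) abort_input("parameters must be >= 0")
  .expected_mismatch_cpp(tau, theta0, theta1, as.integer(d_max))
}

#' Raggedness index of a mismatch distribution
#'
#' r = sum over i = 1..d_max+1 of (x_i - x_{i-1})^2, with x the relative
#' frequencies and x_{d_max+1} := 0. Smooth unimodal (expansion-like)
#' distributions have small r; multimodal equilibrium distributions are
#' ragged.
#'
#' @param x A `mismatch_dist` or a frequency vector over d = 0, 1, ...
#' @return The raggedness index (>= 0).
#' @export
#' @examples
#' raggedness(c(0.5, 0.5)) # 0.25
raggedness <- function(x) {
  f <- if (inherits(x, "mismatch_dist")) x$freqs else x / sum(x)
  sum(diff(c(f, 0))^2)
}

## SSD with the model tail folded into an extra empty bin; cpp kernel.
.ssd <- function(tau, theta0, theta1, obs_freq) {
  .ssd_sudden_cpp(tau, theta0, theta1, obs_freq)
}

#' Least-squares fit of the sudden-expansion model
#'
#' Estimates the expansion parameters by minimising the sum of squared
#' deviations (SSD) between the observed mismatch frequencies on their
#' support 0..d_max and the model expectation (model mass beyond d_max is
#' collected in a tail bin compared against zero). A fixed coarse grid over
#' tau in [0, 2 mean] and theta0 in [0, mean] (plus, in free mode, theta1
#' in {mean, 10 mean, 1e4}) seeds Nelder-Mead refinements from the best
#' grid points; the fit is deterministic (no RNG).
#'
#' By default theta1 is held at the "effectively infinite" ceiling rather
#' than estimated: a population sampled shortly (in coalescent time) after
#' a strong expansion carries almost no information about its new size, and
#' leaving theta1 free lets it absorb sampling variance while theta0
#' collapses to zero, inflating tau. Fixing theta1 = Inf when fitting fresh
#' expansions is the standard recommendation for exactly this reason. Set
#' `theta1 = "free"` to estimate it (capped at `theta1_max` and reported as
#' effectively infinite at the ceiling), or pass a number to fix it at a
#' chosen value.
#'
#' @param obs A `mismatch_dist` (see [observed_mismatch]), or anything it
#'   accepts.
#' @param theta1 `"infinite"` (default; fixed at `theta1_max`), `"free"`
#'   (estimated), or a positive number (fixed).
#' @param theta1_max Ceiling for theta1 (default 1e5, "effectively
#'   infinite").
#' @param n_starts Number of grid points refined by Nelder-Mead.
#' @return Object of class `expansion_fit`: list with `tau`, `theta0`,
#'   `theta1`, `theta1_infinite` (logical), `theta1_mode`, `ssd`,
#'   `raggedness`, `d_max`, `obs`, `degenerate`; bootstrap fields
#'   (`p_ssd`, `p_raggedness`, `tau_ci`, `reps`) are filled in by
#'   [parametric_bootstrap()].
#' @export
fit_sudden_expansion <- function(obs, theta1 = c("infinite", "free"),
                                 theta1_max = 1e5, n_starts = 3L) {
  if (!inherits(obs, "mismatch_dist")) obs <- observed_mismatch(obs)
  if (is.character(theta1)) theta1 <- match.arg(theta1)
  mode <- if (identical(theta1, "free")) "free" else "fixed"
  th1_fix <- if (identical(theta1, "infinite")) {
    theta1_max
  } else if (is.numeric(theta1)) {
    if (theta1 <= 0) abort_input("fixed theta1 must be > 0")
    min(theta1, theta1_max)
  } else {
    NA_real_
  }
  freqs <- obs$freqs
  dmax <- length(freqs) - 1L
  mk <- function(tau, th0, th1, ssd, degenerate = FALSE) {
    structure(
      list(
        tau = tau, theta0 = th0, theta1 = th1,
        theta1_infinite = is.finite(th1) && th1 >= 0.99 * theta1_max,
        theta1_mode = if (mode == "fixed") th1_fix else "free",
        ssd = ssd, raggedness = raggedness(obs), d_max = dmax,
        obs = obs, degenerate = degenerate,
        p_ssd = NA_real_, p_raggedness = NA_real_,
        tau_ci = c(NA_real_, NA_real_), reps = NA_integer_
      ),
      class = "expansion_fit"
    )
  }
  if (dmax == 0L) {
    ## monomorphic sample: no expansion signal at all
    return(mk(0, 0, if (mode == "fixed") th1_fix else NA_real_, 0, degenerate = TRUE))
  }
  mbar <- mismatch_mean(obs)
  obj <- if (mode == "fixed") {
    function(p) .ssd(p[1]^2, p[2]^2, th1_fix, freqs)
  } else {
    function(p) .ssd(p[1]^2, p[2]^2, min(p[3]^2, theta1_max), freqs)
  }
  tau_grid <- seq(0, max(2 * mbar, 1), length.out = 9)
  th0_grid <- c(0, mbar / 4, mbar / 2, mbar)
  th1_grid <- if (mode == "fixed") th1_fix else c(max(mbar, 1), 10 * max(mbar, 1), 1e4)
  grid <- expand.grid(tau = tau_grid, th0 = th0_grid, th1 = th1_grid)
  gssd <- vapply(
    seq_len(nrow(grid)),
    function(i) .ssd(grid$tau[i], grid$th0[i], grid$th1[i], freqs),
    numeric(1)
  )
  ord <- order(gssd)
  starts <- utils::head(ord, n_starts)
  best <- NULL
  for (s in starts) {
    p0 <- sqrt(c(grid$tau[s], grid$th0[s], if (mode == "fixed") NULL else grid$th1[s]))
    fit <- stats::optim(p0, obj,
      method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-12)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  mk(
    tau = p[1]^2, th0 = p[2]^2,
    th1 = if (mode == "fixed") th1_fix else min(p[3]^2, theta1_max),
    ssd = best$value
  )
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit: tau = %.4g, theta0 = %.4g, theta1 = %s\n",
    x$tau, x$theta0,
    if (isTRUE(x$theta1_infinite)) sprintf("%.3g (effectively infinite)", x$theta1) else sprintf("%.4g", x$theta1)
  ))
  cat(sprintf("  SSD = %.4g, raggedness r = %.4g\n", x$ssd, x$raggedness))
  if (!is.na(x$p_ssd)) {
    cat(sprintf(
      "  bootstrap (%d reps): p_SSD = %.4g, p_r = %.4g, tau 95%% CI = (%.3g, %.3g)\n",
      x$reps, x$p_ssd, x$p_raggedness, x$tau_ci[1], x$tau_ci[2]
    ))
  }
  if (isTRUE(x$degenerate)) cat("  [degenerate fit: monomorphic sample]\n")
  invisible(x)
}

#' Parametric bootstrap for a sudden-expansion fit
#'
#' For each replicate, simulates n sequences under the fitted
#' (tau, theta0, theta1) with the coalescent simulator, recomputes the
#' mismatch distribution, re-fits the model, and records the replicate SSD
#' (simulated vs its own re-fitted expectation), raggedness and tau. The
#' SSD and raggedness p-values are upper-tail with the add-one rule
#' p = (1 + #(stat_b >= stat_obs)) / (1 + reps); the tau confidence
#' interval is the 2.5/97.5 percentile interval of the bootstrap tau
#' estimates.
#'
#' @param fit An `expansion_fit` from [fit_sudden_expansion()].
#' @param n Sample size of the original data (defaults to the size recorded
#'   in the fitted mismatch distribution).
#' @param reps Bootstrap replicates (the conventional choice is 1000; a
#'   warning is issued below 100).
#' @param seed Integer master seed.
#' @param ci_level Confidence level for the percentile interval.
#' @return The completed `expansion_fit` (fields `p_ssd`, `p_raggedness`,
#'   `tau_ci`, `reps`, `boot_tau`, `n_failed`). A note is attached when the
#'   percentile CI excludes the point estimate.
#' @export
parametric_bootstrap <- function(fit, n = fit$obs$n, reps = 1000, seed = NULL,
                                 ci_level = 0.95) {
  stopifnot(inherits(fit, "expansion_fit"))
  if (is.na(n) || n < 2) abort_input("sample size n is required")
  if (reps < 100) warning("fewer than 100 bootstrap replicates; p-values will be coarse")
  if (isTRUE(fit$degenerate)) {
    abort_input("cannot bootstrap a degenerate (monomorphic) fit")
  }
  th1 <- if (is.finite(fit$theta1)) fit$theta1 else 1e5
  cfg <- demography("sudden_expansion",
    theta0 = fit$theta0, theta1 = max(th1, 1e-6),
    tau = fit$tau, n = n
  )
  ssd_b <- tau_b <- r_b <- rep(NA_real_, reps)
  failed <- 0L
  ## replicates are re-fitted under the same theta1 setting as the parent fit
  refit_theta1 <- if (identical(fit$theta1_mode, "free")) "free" else fit$theta1_mode
  for (b in seq_len(reps)) {
    sim <- simulate(cfg, nsim = 1, seed = if (is.null(seed)) NULL else derive_seed(seed, b))[[1]]
    ok <- tryCatch(
      {
        ob <- observed_mismatch(sim)
        rf <- fit_sudden_expansion(ob, theta1 = refit_theta1, n_starts = 2L)
        ssd_b[b] <- rf$ssd
        tau_b[b] <- rf$tau
        r_b[b] <- raggedness(ob)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) failed <- failed + 1L
  }
  keep <- !is.na(ssd_b)
  B <- sum(keep)
  alpha <- (1 - ci_level) / 2
  fit$p_ssd <- (1 + sum(ssd_b[keep] >= fit$ssd)) / (1 + B)
  fit$p_raggedness <- (1 + sum(r_b[keep] >= fit$raggedness)) / (1 + B)
  fit$tau_ci <- unname(stats::quantile(tau_b[keep], c(alpha, 1 - alpha), type = 7))
  fit$reps <- B
  fit$n_failed <- failed
  fit$boot_tau <- tau_b[keep]
  if (fit$tau < fit$tau_ci[1] || fit$tau > fit$tau_ci[2]) {
    attr(fit, "note") <- "percentile CI excludes the point estimate"
  }
  fit
}
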