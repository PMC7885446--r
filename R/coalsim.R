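## coalsim: seedable coalescent simulator for constant-size and
## sudden-expansion demographies.
##
## Time scaling. Genealogies are drawn from the n-coalescent with time in
## units such that a pair of lineages in the *current* (post-expansion)
## population coalesces at rate 1, and mutations fall on every lineage at
## rate theta1/2 per time unit. Under the sudden-expansion model the
## population switches (backward in time) from scaled size theta1 to theta0
## at time tau/theta1, so that a non-coalescing pair accumulates on average
## 2 * (theta1/2) * (tau/theta1) = tau differences since the expansion --
## the conversion that makes tau = 2*u*t mutational time. Before the switch
## pairs coalesce at rate theta1/theta0 (size ratio), while the mutation
## rate is unchanged. With theta0 = 0 all lineages surviving to the switch
## coalesce instantaneously (star genealogy).

#' Demography configuration for the coalescent simulator
#'
#' @param model `"constant"` or `"sudden_expansion"`.
#' @param theta0 Scaled mutation parameter (2Nu per sequence) before the
#'   expansion, looking forward in time. Must equal `theta1` for the
#'   constant model.
#' @param theta1 Parameter after the expansion (the present-day value).
#' @param tau Expansion age in mutational time units (tau = 2ut); 0 for the
#'   constant model.
#' @param n Sample size (number of sequences), at least 2.
#' @param k Number of sites available when exporting sequences (default
#'   1140, a complete cytochrome b gene).
#' @param sites Mutation model used when sequences are exported:
#'   `"infinite"` (default; every mutation hits a fresh site) or `"jc"`
#'   (finite-sites Jukes-Cantor: mutations land uniformly on the k sites,
#'   possibly repeatedly).
#' @return An object of class `demography`.
#' @export
#' @examples
#' demography("sudden_expansion", theta0 = 1, theta1 = 1000, tau = 3, n = 50)
demography <- function(model = c("sudden_expansion", "constant"),
                       theta0, theta1 = theta0, tau = 0, n,
                       k = 1140, sites = c("infinite", "jc")) {
  model <- match.arg(model)
  sites <- match.arg(sites)
  if (!is.numeric(theta0) || theta0 < 0) abort_input("theta0 must be >= 0")
  if (!is.numeric(theta1) || theta1 < 0) abort_input("theta1 must be >= 0")
  if (!is.numeric(tau) || tau < 0) abort_input("tau must be >= 0")
  if (!is.numeric(n) || n < 2) abort_input("sample size n must be >= 2")
  if (model == "constant") {
    if (theta0 != theta1) abort_input("constant model requires theta0 == theta1")
    if (tau != 0) abort_input("constant model requires tau == 0")
  } else {
    if (theta1 <= 0) abort_input("sudden_expansion requires theta1 > 0")
  }
  structure(
    list(
      model = model, theta0 = theta0, theta1 = theta1, tau = tau,
      n = as.integer(n), k = as.integer(k), sites = sites
    ),
    class = "demography"
  )
}

## Draw one genealogy; returns branches as (length, leaf set) pairs plus
## the parent-pointer tree used by the finite-sites exporter.
## Nodes 1..n are tips; internal nodes are numbered in coalescence order.
.sim_genealogy <- function(n, theta0, theta1, tau, model) {
  texp <- if (model == "sudden_expansion") tau / theta1 else Inf
  rel <- 1 # current relative population size (vs theta1)
  if (texp <= 0 && model == "sudden_expansion") {
    ## expansion "now": whole history under the ancestral size
    rel <- if (theta1 > 0) theta0 / theta1 else 1
    texp <- Inf
    if (theta0 == 0) {
      ## degenerate: everything coalesces at time 0
      root <- 2L * n - 1L
      return(list(
        node = seq_len(n), len = numeric(n),
        leafsets = lapply(seq_len(n), identity),
        parent = c(rep(root, n), rep(NA_integer_, n - 1L)),
        blen = c(rep(0, n), rep(0, n - 1L)), n = n
      ))
    }
  }
  active <- as.list(seq_len(n)) # leaf sets of active lineages
  anode <- seq_len(n) # node ids of active lineages
  birth <- numeric(n)
  nn <- 2L * n - 1L
  parent <- rep(NA_integer_, nn)
  blen <- rep(0, nn)
  br_len <- numeric(0)
  br_sets <- list()
  br_node <- integer(0)
  t <- 0
  nextnode <- n + 1L
  kk <- n
  while (kk > 1L) {
    rate <- kk * (kk - 1) / 2 / rel
    w <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (t < texp && t + w > texp) {
      ## hit the epoch boundary before the next coalescence
      t <- texp
      texp <- Inf
      if (theta0 == 0) {
        ## star collapse: all remaining lineages coalesce now
        root <- nn
        for (j in seq_len(kk)) {
          L <- t - birth[j]
          br_len <- c(br_len, L)
          br_sets <- c(br_sets, active[j])
          br_node <- c(br_node, anode[j])
          parent[anode[j]] <- root
          blen[anode[j]] <- L
        }
        kk <- 1L
        break
      }
      rel <- theta0 / theta1
      next
    }
    t <- t + w
    ij <- sample.int(kk, 2L)
    i <- min(ij)
    j <- max(ij)
    for (m in c(i, j)) {
      L <- t - birth[m]
      br_len <- c(br_len, L)
      br_sets <- c(br_sets, active[m])
      br_node <- c(br_node, anode[m])
      parent[anode[m]] <- nextnode
      blen[anode[m]] <- L
    }
    active[[i]] <- c(active[[i]], active[[j]])
    anode[i] <- nextnode
    birth[i] <- t
    active[[j]] <- NULL
    anode <- anode[-j]
    birth <- birth[-j]
    nextnode <- nextnode + 1L
    kk <- kk - 1L
  }
  list(
    node = br_node, len = br_len, leafsets = br_sets,
    parent = parent, blen = blen, n = n
  )
}

## Infinite-sites genotype matrix (n x S, 0/1) from a genealogy.
.drop_mutations <- function(gen, theta1) {
  m <- stats::rpois(length(gen$len), theta1 / 2 * gen$len)
  S <- sum(m)
  G <- matrix(0L, gen$n, S)
  if (S > 0L) {
    col <- 1L
    for (b in seq_along(m)) {
      if (m[b] > 0L) {
        for (s in seq_len(m[b])) {
          G[gen$leafsets[[b]], col] <- 1L
          col <- col + 1L
        }
      }
    }
  }
  G
}

## Finite-sites Jukes-Cantor sequences from a genealogy: the root sequence
## is uniform over ACGT; each mutation picks a uniform site and a uniform
## different base, applied from root to tips.
.jc_sequences <- function(gen, theta1, k) {
  n <- gen$n
  nn <- 2L * n - 1L
  m <- integer(nn)
  has <- !is.na(gen$parent)
  m[has] <- stats::rpois(sum(has), theta1 / 2 * gen$blen[has])
  seqs <- vector("list", nn)
  root <- which(!has)[length(which(!has))] # highest-numbered parentless node
  seqs[[root]] <- sample(.BASES, k, replace = TRUE)
  ## children have lower node ids than parents, so descend in id order
  for (node in rev(seq_len(nn))) {
    if (node == root || is.na(gen$parent[node])) next
    s <- seqs[[gen$parent[node]]]
    if (m[node] > 0L) {
      for (mu in seq_len(m[node])) {
        pos <- sample.int(k, 1L)
        s[pos] <- sample(setdiff(.BASES, s[pos]), 1L)
      }
    }
    seqs[[node]] <- s
  }
  do.call(rbind, seqs[seq_len(n)])
}

#' Simulate samples from a demography
#'
#' Draws `nsim` independent coalescent samples. Each replicate runs under
#' its own deterministically derived seed, so the same `(object, seed)`
#' always reproduces the same panel, and replicate `i` is invariant to
#' `nsim`.
#'
#' @param object A [demography].
#' @param nsim Number of replicates.
#' @param seed Integer master seed (or `NULL` to use the ambient RNG).
#' @param ... Unused.
#' @return A list of `coalsim_sample` objects (length `nsim`). Each holds
#'   `genotypes`, an n x S 0/1 matrix of segregating sites (infinite-sites
#'   model), or `seqs`, an n x k base matrix (finite-sites model), plus the
#'   generating `config` and `seed`.
#' @export
#' @examples
#' cfg <- demography("constant", theta0 = 2, theta1 = 2, n = 10)
#' sims <- simulate(cfg, nsim = 3, seed = 1)
#' sapply(sims, function(s) ncol(s$genotypes)) # segregating sites
simulate.demography <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i) {
    si <- if (is.null(seed)) NULL else derive_seed(seed, i)
    run_seeded(si, {
      gen <- .sim_genealogy(object$n, object$theta0, object$theta1, object$tau, object$model)
      out <- list(config = object, seed = si)
      if (object$sites == "infinite") {
        out$genotypes <- .drop_mutations(gen, object$theta1)
      } else {
        out$seqs <- .jc_sequences(gen, object$theta1, object$k)
      }
      structure(out, class = "coalsim_sample")
    })
  })
}

#' Simulate a panel of sudden-expansion samples
#'
#' Convenience wrapper used by the parametric bootstrap: `reps` independent
#' samples under the sudden-expansion demography, with per-replicate seeds
#' derived from the master seed.
#'
#' @param theta0,theta1,tau Sudden-expansion parameters (see [demography]).
#' @param n Sample size per replicate.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param k,sites Passed to [demography].
#' @return List of `coalsim_sample` objects.
#' @export
simulate_expansion_panel <- function(theta0, theta1, tau, n, reps, seed = NULL,
                                     k = 1140, sites = "infinite") {
  if (reps < 1) abort_input("reps must be >= 1")
  cfg <- demography("sudden_expansion",
    theta0 = theta0, theta1 = theta1,
    tau = tau, n = n, k = k, sites = sites
  )
  simulate(cfg, nsim = reps, seed = seed)
}

#' Constant-size samples conditional on the number of segregating sites
#'
#' Simulates standard-coalescent genealogies and places exactly `S`
#' mutations on the tree, each branch chosen with probability proportional
#' to its length. This is the fixed-S null for neutrality tests.
#'
#' @param n Sample size.
#' @param S Number of segregating sites (>= 0).
#' @param reps Number of replicates.
#' @param seed Integer master seed.
#' @return List of `coalsim_sample` objects (infinite-sites genotypes).
#' @export
fixed_s_null <- function(n, S, reps, seed = NULL) {
  if (S < 0) abort_input("S must be >= 0")
  cfg <- demography("constant", theta0 = 1, theta1 = 1, n = n)
  lapply(seq_len(reps), function(i) {
    si <- if (is.null(seed)) NULL else derive_seed(seed, i)
    run_seeded(si, {
      gen <- .sim_genealogy(n, 1, 1, 0, "constant")
      G <- matrix(0L, n, S)
      if (S > 0L) {
        b <- sample.int(length(gen$len), S, replace = TRUE, prob = gen$len)
        for (s in seq_len(S)) G[gen$leafsets[[b[s]]], s] <- 1L
      }
      structure(list(genotypes = G, config = cfg, seed = si),
        class = "coalsim_sample"
      )
    })
  })
}

#' Export a simulated sample as a haplotype alignment
#'
#' Under the infinite-sites model the S segregating sites are mapped onto
#' `k` alignment positions without collision; monomorphic positions carry a
#' random ancestral base, and each segregating site a random derived base.
#' The mapping is seeded from the sample's own seed, so export is
#' reproducible.
#'
#' @param x A `coalsim_sample`.
#' @param k Alignment length (default from the sample's config).
#' @param ids Sample identifiers (default `sim1`, `sim2`, ...).
#' @param seed Override the derived export seed.
#' @param ... Unused.
#' @return A [hap_alignment].
#' @export
as_alignment <- function(x, ...) UseMethod("as_alignment")

#' @rdname as_alignment
#' @export
as_alignment.coalsim_sample <- function(x, k = NULL, ids = NULL, seed = NULL, ...) {
  k <- k %||% x$config$k
  if (!is.null(x$seqs)) {
    mat <- x$seqs
    rownames(mat) <- ids %||% paste0("sim", seq_len(nrow(mat)))
    return(hap_alignment(mat))
  }
  G <- x$genotypes
  n <- nrow(G)
  S <- ncol(G)
  if (S > k) {
    abort_input(sprintf(
      "cannot place %d segregating sites on %d positions without collision", S, k
    ))
  }
  seed <- seed %||% (if (is.null(x$seed)) NULL else derive_seed(x$seed, 777L))
  run_seeded(seed, {
    anc <- sample(.BASES, k, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n)
    if (S > 0L) {
      pos <- sample.int(k, S)
      for (s in seq_len(S)) {
        der <- sample(setdiff(.BASES, anc[pos[s]]), 1L)
        mat[G[, s] == 1L, pos[s]] <- der
      }
    }
    rownames(mat) <- ids %||% paste0("sim", seq_len(n))
    hap_alignment(mat)
  })
}

## Fast pairwise-difference counts for infinite-sites genotype matrices:
## d(i, j) = S_i + S_j - 2 <x_i, x_j>.
.genotype_diffs <- function(G) {
  n <- nrow(G)
  if (ncol(G) == 0L) {
    return(stats::as.dist(matrix(0L, n, n)))
  }
  cp <- tcrossprod(G)
  s <- diag(cp)
  stats::as.dist(outer(s, s, "+") - 2 * cp)
}

#' @export
print.coalsim_sample <- function(x, ...) {
  cfg <- x$config
  S <- if (!is.null(x$genotypes)) ncol(x$genotypes) else NA_integer_
  cat(sprintf(
    "Coalescent sample: n = %d, model = %s (theta0 = %g, theta1 = %g, tau = %g), S = %s\n",
    cfg$n, cfg$model, cfg$theta0, cfg$theta1, cfg$tau,
    ifelse(is.na(S), sprintf("finite-sites (%d bp)", cfg$k), S)
  ))
  invisible(x)
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf(
    "Demography: %s, theta0 = %g, theta1 = %g, tau = %g, n = %d, %s sites (k = %d)\n",
    x$model, x$theta0, x$theta1, x$tau, x$n, x$sites, x$k
  ))
  invisible(x)
}
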