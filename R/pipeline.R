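## pipeline: per-group orchestration of diversity, neutrality, mismatch
## fitting, optional network export, and chronology; plus the synthetic
## multi-group fixture generator.

#' Expansion decision rule
#'
#' A haplotype group is flagged as a sudden expansion when the
#' sudden-expansion model is NOT rejected (both the SSD and raggedness
#' bootstrap tests above `alpha_ssd`) AND at least one neutrality test is
#' significant (Fu's Fs below `alpha_fs`, the conventional 0.02 threshold,
#' or Tajima's D below `alpha_d`). The rule is pure: the same p-values
#' always give the same flag.
#'
#' @param p_ssd,p_raggedness Bootstrap p-values of the model-fit tests.
#' @param p_D,p_Fs Lower-tail neutrality p-values.
#' @param alpha_ssd,alpha_d,alpha_fs Thresholds (defaults 0.05, 0.05,
#'   0.02).
#' @return Logical (NA when any needed p-value is NA).
#' @export
expansion_flag <- function(p_ssd, p_raggedness, p_D, p_Fs,
                           alpha_ssd = 0.05, alpha_d = 0.05, alpha_fs = 0.02) {
  model_ok <- p_ssd > alpha_ssd & p_raggedness > alpha_ssd
  neut <- (p_Fs < alpha_fs) | (p_D < alpha_d)
  model_ok & neut
}

.na_report <- function(group, n, note) {
  data.frame(
    group = group, n = n, failed = TRUE, note = note,
    S = NA_integer_, k_obs = NA_integer_, pi = NA_real_, k_bar = NA_real_,
    D = NA_real_, p_D = NA_real_, Fs = NA_real_, p_Fs = NA_real_,
    tau = NA_real_, tau_lo = NA_real_, tau_hi = NA_real_,
    theta0 = NA_real_, theta1 = NA_real_,
    ssd = NA_real_, p_ssd = NA_real_, raggedness = NA_real_,
    p_raggedness = NA_real_, expansion = NA, T_years = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run the full expansion-detection pipeline
#'
#' For every group in the alignment: diversity summary, neutrality tests
#' with coalescent p-values, sudden-expansion mismatch fit with parametric
#' bootstrap, expansion flag, and (when a rate is supplied) the expansion
#' time in years. All randomness flows from one master seed (recorded in
#' the result attributes); per-group and per-stage seeds are derived
#' deterministically, so reruns with the same seed are identical and each
#' stage can be reproduced by calling the module functions directly with
#' the same derived seed. A failing stage marks the group as failed and the
#' pipeline continues.
#'
#' @param x A [hap_alignment], or a path to a FASTA file.
#' @param groups Optional path to a group TSV (when `x` is a path) or a
#'   named group vector. When the alignment has no groups, all samples are
#'   analysed as one group called `"all"`.
#' @param reps Replicates for both the neutrality null and the parametric
#'   bootstrap (conventional choice 1000).
#' @param fast Use `reps = 200` (quick exploratory runs).
#' @param seed Master seed.
#' @param mu Optional substitution rate (substitutions/site/myr) used to
#'   date each group's expansion (`T_years = tau / (2 mu k)`).
#' @param min_n Groups smaller than this are reported with statistics NA
#'   (default 4).
#' @param network Also build the median-joining network and attach star
#'   summaries?
#' @param out_dir Optional directory for artifacts: a JSON report and a TSV
#'   summary table (plus GraphML networks when `network = TRUE`).
#' @return Data frame with one row per group (class `group_report`);
#'   attributes `seed`, `reps`, and (when requested) `networks` and
#'   `star` (named lists by group).
#' @export
run_pipeline <- function(x, groups = NULL, reps = 1000, fast = FALSE,
                         seed = 1, mu = NULL, min_n = 4L,
                         network = FALSE, out_dir = NULL) {
  if (fast) reps <- 200
  aln <- if (inherits(x, "hap_alignment")) {
    x
  } else {
    read_alignment(x, groups = if (is.character(groups) && length(groups) == 1) groups else NULL)
  }
  if (!is.null(groups) && !(is.character(groups) && length(groups) == 1)) {
    aln <- hap_alignment(aln$seq, ids = aln$ids, groups = groups)
  }
  if (is.null(aln$groups)) {
    aln <- hap_alignment(aln$seq,
      ids = aln$ids,
      groups = stats::setNames(rep("all", aln$n), aln$ids)
    )
  }
  glv <- group_levels(aln)
  nets <- list()
  stars <- list()
  rows <- lapply(seq_along(glv), function(g) {
    grp <- glv[g]
    sub <- subset_by_group(aln, grp)
    if (sub$n < min_n) {
      return(.na_report(grp, sub$n, sprintf("n < %d; statistics not computed", min_n)))
    }
    tryCatch(
      {
        dv <- diversity(sub)
        tab <- collapse_haplotypes(sub)
        nt <- neutrality_test(sub,
          reps = reps,
          seed = derive_seed(seed, 1000L + g)
        )
        obs <- observed_mismatch(tab)
        fit <- fit_sudden_expansion(obs)
        if (!fit$degenerate) {
          fit <- parametric_bootstrap(fit,
            n = sub$n, reps = reps,
            seed = derive_seed(seed, 2000L + g)
          )
        }
        if (network) {
          net <- median_joining(tab)
          nets[[grp]] <<- net
          stars[[grp]] <<- star_summary(net)
        }
        flag <- expansion_flag(fit$p_ssd, fit$p_raggedness, nt$p_D, nt$p_Fs)
        data.frame(
          group = grp, n = sub$n, failed = FALSE, note = "",
          S = dv$S, k_obs = tab$k_obs, pi = dv$pi, k_bar = dv$k_bar,
          D = nt$D, p_D = nt$p_D, Fs = nt$Fs, p_Fs = nt$p_Fs,
          tau = fit$tau, tau_lo = fit$tau_ci[1], tau_hi = fit$tau_ci[2],
          theta0 = fit$theta0, theta1 = fit$theta1,
          ssd = fit$ssd, p_ssd = fit$p_ssd, raggedness = fit$raggedness,
          p_raggedness = fit$p_raggedness, expansion = flag,
          T_years = if (!is.null(mu)) expansion_time(fit$tau, mu, sub$k) else NA_real_,
          stringsAsFactors = FALSE
        )
      },
      error = function(e) .na_report(grp, sub$n, conditionMessage(e))
    )
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "seed") <- seed
  attr(report, "reps") <- reps
  if (network) {
    attr(report, "networks") <- nets
    attr(report, "star") <- stars
  }
  class(report) <- c("group_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, reps = reps, report = report),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    utils::write.table(report, file.path(out_dir, "report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (network) {
      for (grp in names(nets)) {
        write_network(nets[[grp]],
          graphml = file.path(out_dir, paste0("network_", gsub("[^A-Za-z0-9_.-]", "_", grp), ".graphml"))
        )
      }
    }
  }
  report
}

#' Default configuration of the synthetic multi-group panel
#'
#' Emulates the structure of a two-species mole cytochrome b survey: ten
#' haplotype groups of 14-36 sequences, 1140 bp, with expansion ages
#' spanning tau = 1.32 (mid-Holocene) to tau = 8.61 (penultimate glacial),
#' theta0 = 1 and theta1 = 1000 (expansion to an effectively infinite
#' population, the regime the sudden-expansion model targets).
#'
#' @return Data frame with columns `group`, `n`, `tau`, `theta0`,
#'   `theta1`.
#' @export
default_panel_config <- function() {
  data.frame(
    group = c(
      "Mwo-III", "Mwo-Ia", "Mim-Ia", "Mwo-IIIa", "Mim-Ia-1",
      "Mwo-IV", "Mwo-IIa", "Mwo-IIIa-1", "Mwo-IIIb", "Mwo-Ia-1"
    ),
    n = c(34L, 24L, 36L, 30L, 28L, 14L, 20L, 22L, 16L, 18L),
    tau = c(8.61, 5.48, 3.51, 3.32, 2.69, 2.89, 2.14, 2.55, 3.08, 1.32),
    theta0 = rep(1, 10),
    theta1 = rep(1000, 10),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic multi-group haplotype panel
#'
#' Simulates one sudden-expansion coalescent sample per configured group
#' and assembles them into a single alignment with group labels -- a
#' stand-in, generated in code, for a deposited multi-haplogroup alignment.
#' Deterministic given the seed.
#'
#' @param config Data frame as in [default_panel_config()].
#' @param seed Master seed.
#' @param k Alignment length in base pairs.
#' @param out_fasta,out_groups Optional output paths (FASTA alignment and
#'   TSV group table).
#' @return The combined [hap_alignment], invisibly when files are written.
#' @export
make_fixture_panel <- function(config = default_panel_config(), seed = 1,
                               k = 1140, out_fasta = NULL, out_groups = NULL) {
  seqs <- character(0)
  ids <- character(0)
  grp <- character(0)
  for (g in seq_len(nrow(config))) {
    cfg <- demography("sudden_expansion",
      theta0 = config$theta0[g], theta1 = config$theta1[g],
      tau = config$tau[g], n = config$n[g], k = k
    )
    sim <- simulate(cfg, nsim = 1, seed = derive_seed(seed, 100L + g))[[1]]
    gid <- gsub("[^A-Za-z0-9]", "", config$group[g])
    sub <- as_alignment(sim, ids = sprintf("%s_s%02d", gid, seq_len(config$n[g])))
    seqs <- c(seqs, apply(sub$seq, 1, paste0, collapse = ""))
    ids <- c(ids, sub$ids)
    grp <- c(grp, rep(config$group[g], config$n[g]))
  }
  aln <- hap_alignment(seqs, ids = ids, groups = stats::setNames(grp, ids))
  if (!is.null(out_fasta)) write_alignment(aln, out_fasta)
  if (!is.null(out_groups)) write_group_table(aln, out_groups)
  if (is.null(out_fasta) && is.null(out_groups)) aln else invisible(aln)
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf(
    "Group report (%d groups, reps = %s, seed = %s)\n",
    nrow(x), attr(x, "reps") %||% "?", attr(x, "seed") %||% "?"
  ))
  cols <- c("group", "n", "S", "pi", "D", "p_D", "Fs", "p_Fs", "tau", "p_ssd", "expansion")
  print.data.frame(x[, intersect(cols, names(x))], digits = 3, row.names = FALSE)
  invisible(x)
}
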