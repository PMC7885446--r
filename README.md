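# molexpand

Demographic inference and rate calibration from mitochondrial mismatch
distributions.

## What this is for

Phylogeographers screening aligned mtDNA haplotypes (the motivating system
is the 1140-bp cytochrome *b* gene of Japanese moles, analysed per
haplotype group) for **sudden demographic expansions**, and converting the
fitted expansion ages into calendar times and substitution rates against
biogeographic calibration points. The package covers the whole chain:

* **Alignment handling** — FASTA + group-table input, haplotype collapsing
  with an explicit ambiguity rule (N/`-` never separate haplotypes,
  pairwise deletion for all distances).
* **Diversity and neutrality** — segregating sites, mean pairwise
  differences, nucleotide diversity π; Tajima's *D* and Fu's *Fs* with
  one-sided p-values from a constant-size coalescent null (fixed-θ or
  fixed-S), using the add-one rule.
* **Mismatch-distribution fitting** — the sudden-expansion model

  F̂_d(θ) = θ^d/(θ+1)^(d+1),
  F_d(τ,θ₀,θ₁) = F̂_d(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i≤d} (τ^i/i!)[F̂_{d−i}(θ₀) − F̂_{d−i}(θ₁)]

  fitted by least squares (SSD), with a parametric bootstrap giving
  p(SSD), p(raggedness *r*), and a 95% percentile CI for τ.
* **Median-joining networks** — Bandelt-style construction (ε-relaxed
  minimum spanning network, cost-reducing median vectors, degree pruning)
  with a star-shape summary.
* **Chronology** — T = τ/(2μk), μ = τ/(2Tk), u = μg, t = τ/(2uk), with a
  calibration table over the late-Quaternary anchors (130 ka, 53 ka,
  15 ka, 11.5 ka).
* **Coalescent simulator** — seedable constant-size and sudden-expansion
  demographies (infinite-sites by default, finite-sites Jukes–Cantor
  export available); it powers the neutrality nulls, the parametric
  bootstrap, and fully synthetic multi-group test panels.

## Worked example

```r
library(molexpand)

# a synthetic two-group panel: one recent, one old expansion
cfg <- data.frame(group = c("young", "old"), n = c(30L, 30L),
                  tau = c(1.5, 8), theta0 = 1, theta1 = 1000)
aln <- make_fixture_panel(cfg, seed = 42)

rep_ <- run_pipeline(aln, reps = 200, seed = 1, mu = 0.10)
df <- as.data.frame(rep_)[, c("group", "n", "S", "tau", "tau_lo", "tau_hi",
                              "p_ssd", "p_Fs", "expansion", "T_years")]
print(df, digits = 3)
#>   group  n   S  tau tau_lo tau_hi p_ssd    p_Fs expansion T_years
#> 1 young 30  26 1.87  0.563   2.63 0.358 0.00498      TRUE    8195
#> 2   old 30 114 8.19  5.629   9.71 0.423 0.00498      TRUE   35924
```

Both groups are flagged as expansions (sudden-expansion model not rejected
by the SSD bootstrap, Fu's *Fs* significant at its 0.02 convention); the
fitted τ of the young group, at a rate of 0.10 substitutions/site/myr over
1140 bp, dates its expansion to roughly 8200 years before present — note
the wide bootstrap CI (0.56–2.63 in τ units): for a single locus the CI,
not the point estimate, is the honest summary.

Converting the published mole τ estimates into time-dependent rates:

```r
calibration_table(mole_tau_table())
#>        calibration T_years n_groups mean_tau mu_site_myr mu_report
#> 1          PGM_end  130000        1    8.610  0.02904858     0.029
#> 2           MIS4_3   53000        1    5.480  0.04534922     0.045
#> 3 last_glacial_end   15000        2    3.415  0.09985380     0.100
#> 4           YD_end   11500        5    2.670  0.10183066     0.100

signif_report(expansion_time(1.32, mu = 0.10))  # tau = 1.32 at 0.10 subs/site/myr
#> [1] 5800
```

A thin command-line wrapper over the same functions lives at
`inst/cli/molexpand.R` (verbs: `simulate`, `collapse`, `stats`,
`mismatch`, `network`, `date`, `pipeline`).

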