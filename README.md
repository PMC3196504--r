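# comdemog

Comparative demographic inference for codistributed taxa, built around the
Joshua tree (*Yucca brevifolia*) / yucca moth study design: did a plant and
its obligate pollinators expand together after the last glacial period?

The package asks that question the way a population geneticist would, with
every step seeded and testable:

* **Simulate** coalescent genealogies under a piecewise-constant history
  with one instantaneous size change at a known time (or under smooth
  exponential growth), and evolve sequences along them under HKY, TrN or
  K81 substitution models with discrete-Γ rate heterogeneity.
* **Detect and date expansions**: Fu's *Fs* computed exactly from the Ewens
  sampling distribution (log-space Stirling numbers, stable to n ≥ 80),
  Tajima's *D*, and the mismatch-distribution expansion parameter τ with
  its conversion to calendar years, `t = τ/µ_locus` (the published-table
  convention; the classical `τ/(2µ)` is also provided).
* **Test histories**: coalescent-null *p*-values and a four-scenario power
  analysis for *Fs* — the proportion of datasets simulated under a
  candidate history whose *Fs* falls below the observed value — with the
  scenarios anchored to palaeodistribution range-cell counts
  (`Ne = Θ/(2µ)`; ancestral:present ratio = past cells / current cells).
  A simplified exponential-growth coalescent likelihood estimates (Θ, g)
  from a single genealogy, and the posterior count of size-change events
  from skyline output gives the probability of demographic constancy.
* **Quantify structure**: hierarchical AMOVA with Φ statistics and
  permutation tests, pairwise Φ_ST, Mantel tests of isolation by distance
  on great-circle distances, the F_ST > 0.2 + significant-Mantel gating
  rule, and the McDonald–Kreitman test.
* **Evaluate distribution models**: equal-sensitivity/specificity and
  max-sum thresholds, Cohen's κ, rank-based AUC, strict range-cell counts,
  non-analogue climate masks, and fossil-cell hindcast validation, with
  ESRI ASCII grid I/O.
* **Generate synthetic communities** matching the study's sampling design
  (5 taxa, 9 locus datasets, published models and effective sizes), with a
  stepping-stone structured coalescent for the plant that reproduces its
  high F_ST and isolation-by-distance pattern.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` visualisations.

## Worked example

Convert a diversity estimate to an effective size, simulate an expansion,
and ask whether the signal would be detected:

```r
library(comdemog)

# Theta = 0.03 at mu = 1.5e-8 per site per generation -> haploid Ne
ne_from_theta(0.03, 1.5e-8)
#> [1] 1e+06

# simulate a 100-fold expansion at 13 KYA and summarise the alignment
tr  <- simulate_genealogy(25, demographic_scenario(1e6, ratio_ancestral = 0.01),
                          seed = 7)
aln <- evolve_sequences(tr, substitution_model("HKY", kappa = 25.9, alpha = 0.04),
                        mu = 1.5e-8, n_sites = 1800, seed = 7)
summary_stats(aln)
#> # A tibble: 1 × 8
#>   locus     n     S k_hap    pi theta_w    fs tajima_d
#>   <chr> <int> <int> <int> <dbl>   <dbl> <dbl>    <dbl>
#> 1 locus    25     6     7  0.62    1.59 -4.99    -1.82
```

*Fs* = −4.99 is strongly negative and *D* = −1.82: the haplotype excess and
singleton excess both flag the expansion. Dating it from the mismatch
distribution:

```r
fit <- mismatch_tau(aln)
fit
#> <mismatch_fit> tau = 0.7652, theta0 = 1e-06, theta1 = 1000, SSD = 0.01228
tau_to_years(fit$tau_hat, mu_locus_per_year = 1.5e-8 * 1800)
#> [1] 28300
```

τ ≈ 0.77 converts to ≈ 28 KYA — the right order for a change placed at
13 KYA, given one locus and a small τ. How often would a constant-size
population produce an *Fs* as extreme as a published observation of −8.206?

```r
mod <- substitution_model("TrN", rate_AG = 65.95, rate_CT = 24.28, alpha = 0.04)
fs_null_pvalue(-8.206, n = 25, theta_match = 0.03, model = mod,
               mu = 1.5e-8, n_sites = 1800, n_reps = 200, seed = 1)
#> <power_result> scenario constant: Pr(sim < -8.206) = 0 (200 reps, 0 redrawn)
```

None of 200 constant-size replicates reached it. And the plant-like
structured data show the pattern that gates a dataset into phylogeographic
analysis — high global F_ST *and* a significant distance–divergence
correlation:

```r
community <- generate_community(default_community_config(seed = 99))
aln_p <- community$Y_brevifolia$cpDNA
global_fst(aln_p)
#> [1] 0.8241151
ibd_mantel(aln_p, n_perms = 199, seed = 1)
#> # A tibble: 1 × 4
#>       r r_squared     p n_populations
#>   <dbl>     <dbl> <dbl>         <int>
#> 1 0.622     0.387 0.005            10
```

Global F_ST ≈ 0.82 with a significant distance–divergence correlation
(r² ≈ 0.39) — the chloroplast-like pattern that passes
`structure_gate()`, while the panmictic moth datasets fail it.

`run_pipeline(pipeline_config(seed = 1))` chains all of these per species
and locus and writes TSV/JSON reports stamped with the configuration hash.

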