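---
title: "Comparative demographic inference for codistributed taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative demographic inference for codistributed taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comdemog)
```

## The scientific problem

Mutualist communities — here, the Joshua tree (*Yucca brevifolia*) and its
obligate yucca moth pollinators and parasites — are expected to respond to
late-Quaternary climate change in concert: if the plant's range expanded
after the last glacial period, its specialist insects should carry matching
genetic signatures of population growth. `comdemog` implements the pieces of
that comparative test as reusable, seeded, tested components:

1. **Coalescent simulation** of genealogies under piecewise-constant
   histories with one instantaneous size change (and, separately, smooth
   exponential growth), plus sequence evolution under the substitution
   models fitted to each locus.
2. **Expansion diagnostics**: Fu's *Fs* from the Ewens sampling
   distribution, Tajima's *D*, and the mismatch-distribution expansion
   parameter τ with its conversion to calendar years.
3. **Inference engines**: coalescent-null *p*-values and a four-scenario
   power analysis for *Fs*; a simplified exponential-growth coalescent
   likelihood for (Θ, *g*); and the posterior-count constancy test applied
   to Bayesian skyline output.
4. **Population structure**: hierarchical AMOVA with Φ statistics,
   pairwise Φ~ST~, great-circle Mantel tests, the F~ST~ > 0.2 + significant-
   Mantel gating rule, and the McDonald–Kreitman test.
5. **Distribution-model evaluation**: threshold selection (equal
   sensitivity/specificity; maximum of their sum), Cohen's κ, rank-based
   AUC, range-cell counting and non-analogue climate masking.
6. **A synthetic community generator** emulating the study design, so every
   stage can be exercised end-to-end without the original sequence data.

## Models and their assumptions

### The demographic model

A history is `demographic_scenario(ne_present, ratio_ancestral,
t_change_years, generations_per_year)`: constant haploid size
N~0~ back to the change time (13 000 years by default, roughly the end of
rapid post-glacial community turnover in the Mojave region), then constant
N~0~ · *ratio* beyond it. Moths are simulated at one generation per year,
the plant at 30 years per generation, so the change sits at 13 000 vs ~433
generations. The coalescent is the continuous-time Kingman approximation
with pairwise coalescence rate 1/N(t) per generation; the tabulated sizes
are haploid N~e~ used directly (inheritance scaling is folded into each
locus's Θ), and no recombination is modelled at any locus.

The four alternative histories are anchored to the palaeodistribution
reconstructions through range-cell counts: `scenario_ratio_from_cells(past,
current)` treats suitable-cell counts as proportional to population size.
`scenario_ratios()` exposes decline (693/657 ≈ 1.055), slight growth
(434/509 ≈ 0.853) and doubling (240/432 ≈ 0.556). The "constant" label is
simulated at ratio exactly 1, although the cell counts of the reconstruction
that motivated it imply ≈ 1.13 — we keep the literal null because the power
analysis is defined against demographic constancy.

### Sequence evolution

`substitution_model()` supports HKY, TrN and K81 with optional
discrete-gamma rate heterogeneity. Choices worth knowing:

* **Base frequencies** default to equal; the source study does not report
  empirical compositions. This affects realism, not any calibration here.
* **K81** is printed with a single κ; we interpret it as the transition
  rate against both transversion classes held equal, with a second class
  rate exposed (`rate_tv2`) for the full three-parameter form.
* **Discrete gamma** uses 4 equal-probability categories represented by
  category *means*, renormalised to average exactly 1 (mean-preserving; at
  α = 0.04 the categories are ≈ {5·10⁻¹⁶, 3·10⁻⁸, 1.3·10⁻³, 4.0}, i.e.
  three-quarters of sites are effectively frozen). Site rates are drawn
  once per alignment and shared across branches.
* Rate matrices are scaled to one expected substitution per unit time at
  stationarity and satisfy detailed balance; transition probabilities come
  from the symmetrised eigendecomposition, which is exact and stable for
  reversible generators.

### Fu's Fs, exactly

*Fs* is the logit of the Ewens tail probability S′ = P(K ≥ k~obs~ | θ̂ = π,
n). We compute the unsigned Stirling numbers of the first kind by recurrence
in log space, so n = 80 is handled without overflow; the test suite checks
the implementation against exact polynomial-expansion Stirling numbers for
n ≤ 12 to 10⁻⁶. When S′ underflows below 10⁻³⁰⁰ (or saturates at 1) a
signed infinity is returned with a warning — those values still order
correctly in the power analysis.

### Mismatch distributions and τ

The expected pairwise-difference distribution under sudden expansion has a
closed form: conditioning on the pair's coalescence epoch gives two
regularised-incomplete-gamma terms (see `expected_mismatch()`), with the
equilibrium geometric distributions at θ₀ and θ₁ as its τ → 0 and τ → ∞
limits. `mismatch_tau()` fits (τ, θ₀) by least squares with θ₁ pinned at
10³ · max(θ₀, 1) — the "infinite post-expansion size" configuration in
which τ dates the expansion — using a bounded grid refined by L-BFGS-B. The
tests compare it against a dense independent grid search and against star
genealogies with known τ (median recovery within 25%).

τ is converted to years by **two deliberately coexisting conventions**. The
classical definition τ = 2µt gives t = τ/(2µ). The study's own table is
internally consistent only under t = τ/µ. Both are implemented
(`tau_to_years(..., convention =)`); `paper_table` is the default because it
reproduces the published dates. We do not silently reconcile the factor of
two — callers doing fresh analyses should use `classical`.

### The growth likelihood

`fit_growth()` maximises the exponential-growth coalescent log-likelihood of
the inter-coalescent intervals (hazard k(k−1)e^{gu}/Θ in mutational time u)
over (Θ, g). This is a *single-genealogy* simplification of
genealogy-sampling MCMC estimators: with one genealogy, g is interpretable
for sign and magnitude class only, and carries a known upward bias (at
n = 30 under g = 0 the median of ĝ sits a few standard errors above zero,
well within one null standard deviation — the property the tests assert).
With g fixed at 0, Θ̂ has the closed form Σ k(k−1)w~k~/(n−1), used as an
exact oracle. Sequence mode first builds a UPGMA tree from p-distances;
pairing simulated truths with their reconstructions confirms the
reconstruction costs accuracy (higher RMSE), which is why genealogy mode is
preferred when trees are available. Profile-likelihood intervals for g use
the Δlog-likelihood = 1.92 cutoff.

### Power analysis

`power_analysis()` runs the full generative chain per replicate (genealogy →
sequences → statistic) and reports the proportion of simulated statistics
*strictly below* the observed value; ties count as not extreme.
Monomorphic replicates, on which *Fs* is undefined, are redrawn from a
disjoint seed stream and counted — they carry no information for a
lower-tail test. `fs_null_pvalue()` is the constant-size special case and
shares seed streams with `power_analysis()` so the two are replicate-for-
replicate identical at ratio 1.

A calibration note: reproducing the published constant-scenario proportion
for the most diverse mitochondrial locus (0.074 below *Fs* = −8.206) is not
possible from the printed information. Our chain — and an infinite-sites
check, and DNAsp's own published simulation p-value of 0.001 for the same
observed value — all put that tail near 0.002–0.008; the published
simulation table's null is an order of magnitude heavier-tailed than its
own DNAsp null for every mitochondrial locus, which points to unreported
settings in the original simulation tool. The package therefore documents
the ordering property instead (under paired seeds, the doubling scenario's
extreme proportion is ≥ the constant scenario's), which holds in ≥ 90% of
paired runs.

### AMOVA, Mantel, and the structure gate

The hierarchical AMOVA decomposes squared pairwise nucleotide differences
(no model correction — the "haplotypic format") into among-region,
among-population-within-region and within-population components with
unequal-sample-size coefficients. Negative variance components are
**retained**, matching published practice; a consequence worth knowing is
that truly exchangeable populations do not give Φ~ST~ = 0 but a small
negative value (exact duplicates give −1/(n~c~ − 1)). Permutation tests use
the statistic-appropriate scheme (haplotypes among populations for Φ~ST~,
within regions for Φ~SC~, whole populations among regions for Φ~CT~) and
report (extreme + 1)/(permutations + 1) so no p-value is exactly zero.

Mantel tests (via `vegan`, which implements precisely the one-tailed,
ties-extreme convention) correlate pairwise Φ~ST~ with great-circle
distances (haversine, 6371 km radius) between population centroids. The
gating rule is literal: global F~ST~ > 0.2 **and** Mantel p < 0.05. Global
F~ST~ defaults to the AMOVA Φ~ST~; the mean of pairwise values is exposed
as an alternative since summary texts sometimes average.

### Distribution-model evaluation

Thresholds are chosen from data-driven candidates (midpoints of adjacent
unique scores plus sentinels beyond both ends); presence is *strictly
greater than* the threshold throughout, so boundary cells are absences —
this matters when comparing cell counts at a printed threshold. AUC is the
rank-based Mann–Whitney statistic with ties at one half (checked to 10⁻¹⁰
against trapezoidal ROC integration and against `pROC`). Non-analogue
masking computes each variable's global min/max over non-NODATA current
cells and flags past cells outside the closed interval for *any* variable;
NODATA is never imputed.

## The synthetic community

`default_community_config()` encodes the study design: four moth species
with a ~1800 bp mitochondrial locus (n = 24–32) and a 490 bp nuclear locus
(43–58 phased haplotypes), and the plant with a 2000 bp chloroplast locus
(n = 79; the real total length is unpublished, so 2000 bp is a configurable
default). Substitution models, Γ shapes, per-site rates and haploid sizes
follow the published per-locus values; moths are panmictic
(their observed F~ST~ ≈ 0.12), the plant evolves on a 1-D stepping-stone
chain of ten demes.

The stepping-stone parameters are the one place the emulator deliberately
departs from the species-wide tabulated N~e~: with demes of
2.27 × 10⁷/10 individuals and weak migration, between-deme coalescence is
so ancient that every pair saturates mutationally and the
isolation-by-distance gradient disappears. Real chloroplast data are the
opposite: little variation within demes, a clean distance gradient between
them. Setting the per-deme size to 5 × 10⁴ with migration 10⁻⁵ per lineage
per generation reproduces the published *pattern* — global F~ST~ ≈ 0.8–0.9
and a strongly significant Mantel correlation — while the species-wide N~e~
remains what the panmictic power analyses use. The structured coalescent
handles the size change piecewise, and vanishing migration drives F~ST~
toward 1, which the tests exercise.

What the generator does **not** emulate: indels and sequencing error (the
readers accept gaps and `N`; the generator never emits them), PHASE-style
ambiguity (haplotypes are emitted resolved), recombination, and selection.
Tests passing on synthetic data therefore validate the *statistical
machinery*, not the biological fidelity of any particular locus.

## Reproducibility and numerical choices

* All randomness flows from explicit integer seeds; community generation
  derives disjoint per-entry streams from one master seed and stamps each
  alignment with provenance (seed, scenario, model). Identical seeds give
  byte-identical FASTA output.
* Replicated studies in the tests are scaled to keep the whole suite fast:
  e.g. 1000 replicates for the headline power cell, 200 for estimator
  calibrations, 12 paired runs at n = 12 × 600 bp × 300 replicates for the
  scenario-ordering property, 5000 draws for distribution-equality checks.
  These sizes are the package's choices; the underlying functions accept
  arbitrary sizes.
* Degenerate inputs are first-class: monomorphic alignments flag *Fs*/*D*
  as undefined rather than returning numbers; τ on monomorphic data is 0
  with SSD 0; AMOVA on identical haplotypes reports zero components and
  flagged statistics; Mantel on zero-variance matrices returns `NA` with a
  warning; κ with degenerate marginals is `NA`.
* `run_pipeline()` stamps every output table with a configuration hash and
  the master seed, isolates per-entry failures, and writes TSV/JSON
  reports.

## Known limitations

* The growth estimator is not a genealogy-sampling MCMC; its ĝ values are
  not comparable to published genealogy-sampler point estimates and are
  used for sign/class statements only.
* The mismatch fit pins θ₁ large rather than estimating it; data from
  genuinely bounded expansions will show inflated SSD.
* AMOVA distances are raw difference counts; no substitution-model
  correction is applied (by design, to match the published tables).
* Species-distribution model *fitting* (boosted regression trees, maximum
  entropy) is out of scope; surfaces and climate stacks are inputs, with
  `generate_sdm_fixture()` supplying synthetic ones for testing.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_reps = 200)
report <- run_pipeline(cfg)
report$sumstats
report$power
```
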