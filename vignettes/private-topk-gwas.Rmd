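---
title: "Private release of top-K GWAS SNPs: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private release of top-K GWAS SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpsnp)
```

## The problem

A case–control GWAS summarizes each SNP as a 2×3 contingency table: case
counts `(r0, r1, r2)` and control counts `(s0, s1, s2)` by the number of
minor alleles an individual carries. Publishing the identities of the K
most associated SNPs leaks information about the case participants, so the
selection must be randomized under ε-differential privacy: for any two
databases differing in one individual's record, the output distribution of
the release mechanism may change by at most a factor `exp(ε)`.

Throughout, the control data are treated as public (in the motivating
setting the controls come from a public reference panel, and their genotype
row is derived from allele frequencies under Hardy–Weinberg equilibrium);
privacy is owed to the case group, so a "neighbouring database" re-genotypes
exactly one **case** individual.

## The allelic test and its x-parametrization

Association strength is the allelic test statistic (Cochran–Armitage trend
test under the additive model), the Pearson χ² with 1 df on the collapsed
2×2 allelic table:

$$Y_A = \frac{2N\,[(2r_0+r_1)S - (2s_0+s_1)R]^2}
             {R\,S\,(2n_0+n_1)(n_1+2n_2)},$$

with $n_i = r_i + s_i$, $N = R + S$. `allelic_chi2()` implements this
formula; the test suite checks it against an independently coded Pearson
χ² on the allelic table (and against `chisq.test`) to 1e-9 on a thousand
random tables.

Fixing the control row and `R` defines a space of `(R+1)(R+2)/2` case rows
— lattice points of the triangle `r0, r1 ≥ 0, r0 + r1 ≤ R`. On that space
the statistic depends on the case row only through the case major-allele
count `x = 2r0 + r1`:

$$Y_A(x) = \frac{2N(xS - n_{10}R)^2}{R\,S\,(x+n_{10})(2N-x-n_{10})},
\qquad n_{10} = 2s_0 + s_1 .$$

`Y_A(x)` is zero at the vertex `x* = n10·R/S`, strictly decreasing left of
it and strictly increasing right of it. The insignificant region
`{x : Y_A(x) < c}` at a χ² threshold `c` is therefore one contiguous band
of `x` values straddling the vertex. This unimodality is what the fast
Hamming-score algorithm and its correctness proof-by-audit rest on; it is
asserted as a property test over random `(n10, R, S)` configurations.

## The Hamming distance score

Re-genotyping one case individual moves the case row by one of six moves
(`legal_moves()`), changing `x` by ±1 or ±2. The shortest Hamming distance
of a table `D` is the minimum number of such moves needed to flip its
significance status (`Y_A ≥ c` counts as significant, ties included); the
score is

$$h = \begin{cases} -\,d & Y_A(D) < c \\ d - 1 & Y_A(D) \ge c ,\end{cases}$$

so `h ≥ 0` exactly for significant tables, and one move across the
boundary changes `h` by exactly 1. The score's sensitivity is 1, which
lets the exponential mechanism run at exponent `ε·h/(2K)` rather than
being deflated by the χ² statistic's much larger sensitivity.

### The fast algorithm

`hamming_distance()` never searches the lattice:

* **Insignificant table.** Two directional walks in `x`. Downward: `r0`
  steps of −2 (moving `r0 → r2`), then `r1` steps of −1 (`r1 → r2`);
  upward: `r2` steps of +2, then `r1` steps of +1. Each walk's step
  sequence achieves the maximum possible |Δx| at every prefix, so the
  first step at which `Y_A ≥ c` is the minimal move count in that
  direction; the distance is the smaller of the two. If the whole space is
  insignificant the distance is defined as one step past the nearer
  extreme corner: `1 + min(r0 + r1, R − r0)`.
* **Significant table.** A significant table lies strictly on one side of
  the vertex (at the vertex `Y_A = 0 < c`). Only the walk toward the
  vertex can reach insignificance — the opposite walk only increases
  `Y_A` and is discarded. The algorithm locates the nearest insignificant
  integer `x` by scanning from the table toward the vertex, then lands on
  it exactly in `max(⌈δ/2⌉, δ − doubles)` moves, where `δ` is the `x`-gap
  and `doubles` the number of ±2 moves the lattice allows (`r0` going
  down, `r2` going up). The exact landing matters: a greedy −2 walk could
  jump over an insignificant band that contains a single integer, so the
  band edge is computed first and the move count in closed form.

Degenerate inputs are refused rather than scored: monomorphic control rows
(`n10 = 0` or `2S`) put a zero-margin table inside the walk space, and a
threshold below the grid minimum of `Y_A` leaves no insignificant table to
cross to. `allelic_chi2()` itself returns 0 with a warning on
zero-margin tables so that plain panel scoring never crashes; only the
Hamming geometry refuses them.

### The oracle and the audits

`hamming_distance_bfs()` implements the distance directly from its
definition by breadth-first search over the triangle and is the package's
independent oracle: the central test sweeps every table of every space for
`R = 2..12`, three control rows and three thresholds (about four thousand
tables) and requires exact agreement. `hamming_sensitivity()` enumerates a
space and takes the maximum |Δh| over all one-move neighbour pairs; it
returns exactly 1 on every crossable space tested, which is the package's
headline structural claim, recomputed from scratch by
`scripts/acceptance.R`.

## Release mechanisms

`release_laplace()` adds i.i.d. Laplace(0, `2Ks/ε`) noise to all M scores
and takes the top K perturbed SNPs (ties broken by ascending panel index —
a probability-zero event under continuous noise, fixed for determinism).
Noise is sampled exactly as the difference of two unit exponentials scaled
by `b`.

`release_exponential()` draws K SNPs sequentially without replacement,
each round with probability ∝ `exp(ε·q_i/(2Ks))` over the remaining SNPs;
"remove" is implemented as weight exactly 0, not a large negative score,
avoiding NaN arithmetic. Softmax weights are computed after subtracting
the maximum exponent, so arbitrarily large χ² scores cannot overflow.
`selection_probabilities()` exposes the exact K = 1 output distribution;
the privacy test uses it to verify `Pr/Pr' ≤ exp(ε)` analytically over
every one-move neighbour combination of a small three-SNP panel — no
sampling, no tolerance beyond float round-off.

The budget split across the K draws uses the factor `2K` in both
mechanisms; no alternative composition is offered.

**χ² score sensitivity is a required input.** The allelic χ² has no
universally valid small bound (it grows with the table's geometry), so the
χ²-score mechanisms refuse to run without an explicit `sensitivity`.
`chi2_sensitivity()` computes the exact maximum one-move change over an
enumerated space so users can justify a value for spaces shaped like their
data; values around 7–15 are typical for the sample sizes used here. The
Hamming score needs no such input: its sensitivity is 1 by construction,
and `release` defaults to it for that score.

## The synthetic panel generator

`simulate_panel()` emulates the shape of a processed case–control panel:
`m` SNPs, control MAF drawn uniformly (default `[0.05, 0.5]` — the lower
bound sits safely above the 1% common-SNP floor so that allelic margins
stay positive even at small `R`, `S`), control row expanded exactly under
HWE, case row drawn trinomially from HWE probabilities at the case MAF.
Associated SNPs shift the case MAF by `effect`. One global seed expands
into per-SNP substreams, so growing `m` leaves earlier SNPs bit-identical.

Two consequences worth knowing:

* Because the control row is an exact expectation (no sampling noise), the
  null distribution of `Y_A` is approximately `(S/N)·χ²(1)`, mean `S/N`
  rather than 1; the calibration test asserts exactly that. Real data with
  sampled controls would be calibrated to mean ≈ 1 — a feature of this
  generator, not of the statistic.
* The generator has no linkage disequilibrium, population structure or
  covariates — the statistic is single-SNP, and so are all claims tested
  here. Passing tests say nothing about confounding in real cohorts.

## Risk–utility evaluation

Utility of a release is `u = |S0 ∩ S|/K` against the true χ² top-K
(`true_top_k()`, ties by panel index). `risk_utility_sweep()` averages it
over repeated mechanism draws per grid cell (default 200 repetitions,
mean ± sd reported; per-cell, per-repetition seeds derive deterministically
from one base seed) with the default grid `K ∈ {3, 5, 10}`,
`ε ∈ {1, 2, 5, 10, 20, 50}`, `p* ∈ {0.1/M, 0.01/M}`.

The acceptance tests reproduce three qualitative signatures on synthetic
panels (M = 80–100, R = S = 100–150 — sizes chosen so 200 repetitions per
cell stay cheap while the score separations are comparable to the
motivating data):

1. the χ²-score mechanisms' utility is non-decreasing in ε and reaches 1
   at large ε;
2. the Hamming-score mechanism's utility plateaus below 1 on a panel
   engineered so its ranking disagrees with the χ² ranking (two strongly
   significant SNPs whose χ² and Hamming orders invert: a steep profile at
   low MAF gives a high χ² with a short walk, a shallower profile a lower
   χ² with a longer one). The plateau is a property of ranking
   inconsistency, not of the privacy noise;
3. at ε = 1 the Hamming-score exponential mechanism beats both χ²-score
   mechanisms by a wide margin on a panel with well-separated significant
   SNPs — unit sensitivity keeps the exponent scale large where the χ²
   score's sensitivity (≈ 15 audited on that panel's spaces) crushes it.

## Numerical conventions

* All cross-formula equivalences (tabular χ² vs Pearson, vs
  x-parametrization) are tested at 1e-9 relative tolerance, absorbing
  float accumulation at realistic N.
* `Y_A ≥ c` is compared exactly in floating point — both sides come from
  deterministic closed forms, and an epsilon band would itself create a
  boundary-classification ambiguity.
* HWE-derived control cells stay real-valued by default; only the case row
  must be integral (moves re-genotype cases only). Largest-remainder
  rounding is available for users who want integer control tables.
* Thresholds map `p*` to `c` via the χ²(1) upper-tail quantile; the
  round-trip is tested to 1e-10.

## Limitations

* Single invocation only: no composition accounting across repeated
  releases, no Gaussian mechanism or Rényi variants.
* Genotype-count input only (TSV); VCF/PLINK conversion is out of scope.
* The Hamming geometry covers the allelic (2×2) test with public controls;
  the 2×3 Pearson test and non-public controls would need a different
  boundary analysis.
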