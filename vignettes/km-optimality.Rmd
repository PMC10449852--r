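---
title: "Methods: free-energy landscapes, optimal substrate affinity, and the Km–[S] consistency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy landscapes, optimal substrate affinity, and the Km-[S] consistency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepmm)
```

## The model and its assumptions

`bepmm` treats one enzyme as a two-step catalytic cycle, E + S ⇌ ES → E + P,
summarized by two free energies: the binding free energy ΔG₁ (E + S → ES) and
the total reaction free energy ΔG_T (S → P). The second step's free energy is
always the remainder, ΔG₂ = ΔG_T − ΔG₁, so the additivity constraint holds by
construction and ΔG₁ is the single degree of freedom an enzyme can tune at
fixed chemistry.

Kinetics enter through two empirical assumptions:

1. **BEP relation** — each elementary step's activation barrier changes
   linearly with its driving force, `Ea = Ea⁰ + α ΔG`, with sensitivity
   α ∈ (0, 1). Microscopic reversibility forces the reverse barrier to move
   with coefficient 1 − α, which is why the reverse coefficient is never an
   independent parameter in this package.
2. **Arrhenius equation** — `k = A exp(−Ea/RT)`. The pre-exponential factor
   and the zero-driving-force barrier are not separately identifiable from
   rate data, so they are folded into a single reference rate constant
   `k⁰ = A exp(−Ea⁰/RT)`, one per step. `A` and `Ea⁰` are deliberately not
   exposed.

With `g1 = exp(ΔG1/RT)` and `gT = exp(ΔGT/RT)` this yields

```
k1 = k1⁰ g1^(−α1)      k1r = k1⁰ g1^(1−α1)
k2 = k2⁰ (g1/gT)^(α2)  k2r = k2⁰ (g1/gT)^(α2−1)
```

Two consistency properties follow algebraically and are enforced as tested
invariants rather than assumptions: per-step detailed balance
(`k1/k1r = exp(−ΔG1/RT)`) and the Haldane identity around the cycle
(`k1k2/(k1r k2r) = exp(−ΔGT/RT)`). The Michaelis constant is the composite
`Km = (k1r + k2)/k1 = g1(1 + K)` with
`K = k2⁰ g1^(α1+α2−1)/(k1⁰ gT^α2)`; the package computes it from the
landscape form and tests agreement with the rate-constant ratio to 1e−12
relative over randomized landscapes.

The steady-state assumption underlying `v = k2[S][E_T]/(Km + [S])` requires
[S] to be approximately constant on the timescale of interest (small [E_T] in
batch, or continuous substrate supply in vivo). Only steady-state rate laws
are implemented; there is no time-course ODE integration.

## Optimality

At fixed ΔG_T, `v` depends on ΔG₁ only through the denominator
`f(g1) = [S] g1^(−α2) + g1^(1−α2) + k2⁰ g1^(α1)/(k1⁰ gT^(α2))`, which is
smooth and single-troughed. Setting `df/dg1 = 0` gives
`[S] = g1((1−α2)/α2 + (α1/α2)K)`.

* **Closed form** (`optimal_dG1_closed()`): when α1 + α2 = 1, `K` does not
  depend on `g1` and the stationarity condition solves explicitly, giving
  `Km* = (α2/(1−α2))·[S]` — and `Km* = [S]` at α1 = α2 = 0.5. We treat the
  closed form as exact *only* in this regime: for general coefficients `K`
  itself contains `g1^(α1+α2−1)`, the condition is implicit, and the numeric
  path is authoritative.
* **Numeric path** (`optimize_numeric()`): derivative-free bounded (Brent)
  maximization of the rate over ΔG₁ on `[ΔG_T − 60, +60]` kJ/mol, absolute
  tolerance 1e−9 kJ/mol, followed by one parabolic-vertex polish using a
  ±1e−4 kJ/mol stencil. The polish matters because Brent's practical argmax
  accuracy saturates near √ε·|x|; with it, the optimizer reproduces the
  closed form to better than 1e−6 kJ/mol, which is what the agreement tests
  assert. Results carry a local-maximum certificate (the rate at ±1e−5
  kJ/mol displacements may not exceed the optimum) and a `boundary` flag when
  the maximum sits on the bracket edge, in which case the boundary solution
  is returned with a warning rather than an error.

`activity_grid()` evaluates the rate on a uniform (ΔG₁, ΔG_T) grid (default
400×400 over ΔG₁ ∈ [−60, 20], ΔG_T ∈ [−80, 0] kJ/mol — the physically
meaningful forward-reaction window for biochemical reactions) and extracts
the ridge as the per-column argmax, ties broken toward more negative ΔG₁ so
the output is deterministic. `volcano_curve()` reports `v` against `Km` along
a ΔG₁ sweep and refines the apex by the same parabolic-vertex step, so the
apex location is resolved well below the sweep spacing; single-peakedness is
verified by counting sign changes of the discrete differences. The apex
depends only on [S] and the α's — not on ΔG_T, k1⁰, k2⁰ or [E_T] — which the
tests check by recomputing sweeps across those parameters.

`scaling_relation()` exposes the flip side of optimality: along any ΔG₁
sweep, `log k2 = α2 log Km − α2 log((1+K) gT) + log k2⁰`. When α1 + α2 = 1
the intercept is constant and an ordinary least-squares fit recovers the
slope α2 exactly (asserted to 1e−9); otherwise the intercept drifts with `K`,
the function warns, and per-point values of `K` are attached.

## Mechanistic deviations

Three deviations from the standard mechanism are implemented:

* **Reverse reaction** (`net_rate_reversible()`): the steady-state net rate
  of E + S ⇌ ES ⇌ E + P,
  `v = [E_T](k1k2[S] − k1r k2r[P]) / (k1[S] + k2r[P] + k1r + k2)`. This is
  the unique steady-state solution of the two-step scheme with BEP rate
  constants; its Haldane consistency is the acceptance check — the net rate
  vanishes identically at `[P]/[S] = exp(−ΔGT/RT)` and reduces to the
  standard law at [P] = 0. Grid cells where the net rate is non-positive
  (possible at ΔG_T > 0) are *flagged* in `activity_grid()$feasible`, not
  overwritten with placeholder values: masking is a plotting decision, not a
  model feature.
* **Competitive / uncompetitive inhibition** (`rate_inhibited()`): the
  textbook forms `v = k2[S][E_T]/(Km(1+γ) + [S])` and
  `v = k2[S][E_T]/(Km + (1+γ)[S])`, with the degree of inhibition
  γ = [I]/Ki as the only inhibitor parameter. The default γ = 10 in
  `true_optimal_km()` is the representative upper decile of measured
  inhibitor loads in intracellular data. The numerically located optima
  confirm the candidate closed forms `Km* = [S]/(1+γ)` (competitive) and
  `Km* = [S](1+γ)` (uncompetitive) rather than assuming them: the test suite
  compares both against the optimizer and a dense grid-scan oracle.

### How "the cost of the rule" is quantified

`km_rule_penalty()` compares the rate at the ΔG₁ that realizes `Km = [S]`
(obtained by inverting `Km(ΔG₁)`, a strictly monotone map, in closed form
when α1 + α2 = 1 and by bisection otherwise) with the rate at the true
optimum, for each ΔG_T on a scan grid. Two summaries are reported, because
"percent difference between two activities" is ambiguous:

* the one-sided shortfall `(v* − v_rule)/v* × 100`, and
* the **symmetric relative difference** `2|v* − v_rule|/(v* + v_rule) × 100`,
  which treats the two rates on equal footing and does not depend on which is
  the reference.

For competitive inhibition at α = 0.5 both are independent of ΔG_T and have
closed forms in γ alone: `v_rule/v* = 2√(1+γ)/(2+γ)`, giving a shortfall of
44.7% and a symmetric relative difference of 57.6% at γ = 10. The package's
headline robustness figure uses the symmetric definition; both numbers are
computed, printed, and covered by the acceptance machinery, so readers can
use either. Against the ten-decade span of the activity landscape, a
half-order-of-magnitude penalty is small — that is the robustness claim the
tests encode (`v_rule` stays within a factor 10 of `v*` across the scanned
regimes, including α1 = α2 = 0.2).

## The Km–[S] consistency analysis

`km_consistency()` asks whether measured wild-type Michaelis constants match
in-vivo substrate concentrations, via the per-entry statistic
`log10(Km/[S])` (zero means affinity matched to concentration).

* **Loading** (`load_km_dataset()`): CSV/TSV with columns `substrate`, `Km`,
  `S`, `organism`. Units must be declared explicitly per concentration column
  and are converted to µM — kinetics databases conventionally report Km in
  mM while metabolomic concentrations are often µM, and a silent mixup
  shifts every log-ratio by 3 decades, which is the main corruption risk for
  this analysis. Rows with missing or non-positive values are dropped and
  counted in a load report; log-ratios are always recomputed, never read
  from the file. Duplicate (enzyme, substrate) rows are retained: the
  analysis counts entries, not unique pairs.
* **Categorization** (`categorize_substrates()`): occurrence count per
  substrate name over the whole dataset, as a proxy for how strongly a
  substrate is shared between enzymes (shared substrates — cofactors, ATP —
  are the ones expected to deviate from single-enzyme kinetics). Boundary
  convention, since the class limits are quoted loosely in the field:
  ≤ 50 → major metabolite, 51–299 → cofactor class, ≥ 300 → ATP class.
* **Histogram fit** (`fit_gaussian_histogram()`): fixed-width binning
  (default 0.25 log10 units, edges aligned to multiples of the width) and an
  unweighted least-squares Gaussian fit to the bin counts via
  Levenberg–Marquardt (`minpack.lm::nlsLM`), with a Nelder–Mead fallback.
  Sample mean and SD are always reported alongside the fit. Degenerate input
  (zero variance) returns the sample statistics with an `NA` fit and a
  warning. The bin width is a choice, not a published protocol; the
  downstream tolerances (±0.1 on centers) absorb its effect.
* **Fractions**: per category, the fraction with |log10(Km/[S])| ≤ 1
  (consistency within one order of magnitude), the fraction with Km < [S],
  and the fraction with log-ratio > 3 (the far tail where the steady-state
  picture likely breaks, e.g. diffusion-limited enzymes).

## The synthetic generator: what it emulates, and what it does not

`generate_km_dataset()` produces tables with the statistical structure of the
published wild-type compilation: 980 major-metabolite entries over 25
substrates (≤ 50 each), 410 cofactor entries over 5 substrates, 313 entries
of a single high-occurrence substrate (1703 total); per-category log-ratios
Gaussian with centers (−0.18, −0.43, −1.64). Choices the published statistics
do not pin down, made once:

* **Spreads**: only the major-metabolite SD (1.3) is published. The cofactor
  and ATP spreads (1.2 and 0.8) were obtained by inverting the published
  fraction statistics under the Gaussian model — 57% within one order of
  magnitude for a Gaussian centered at −0.43 implies σ ≈ 1.2, and 98% below
  zero for a center of −1.64 implies σ ≈ 0.8.
* **[S] marginal**: log-uniform over 10⁻² to 10⁴ µM, because in-vivo
  concentrations span about six decades; only the *ratio* statistics carry
  scientific weight, so the marginal is a convenience.
* **Occurrence profile**: entries split as evenly as possible across the
  substrates of a category, with a feasibility check against the
  categorization thresholds (so a profile that cannot respect its own class
  boundaries is an error, not a silent mislabeling).

The generator draws from a single seeded RNG stream in row order and restores
the caller's RNG state, so fixed seeds give byte-identical CSVs.

What passing tests on synthetic data do **not** show: real log-ratio
histograms are heavier-tailed than a Gaussian (the published major-metabolite
histogram has its empirical within-one-order fraction *below* the
Gaussian-implied one), category composition reflects biology rather than an
even split, and [S] values correlate with organism and pathway. Pipeline
correctness (categorization, fitting, fraction computation) transfers to real
tables; distributional fine structure does not.

## Numerical choices

* R = 8.314×10⁻³ kJ/(mol·K); default temperature 298.15 K (25 °C), the
  conventional biochemical reference.
* All exponentials are evaluated in log space (including `log(1+K)` via a
  stable `log1p(exp(·))`), and landscapes with |ΔG|/RT > 500 are rejected at
  construction instead of silently saturating to `Inf`/0.
* Defaults mirror the simulation conditions used throughout:
  [E_T] = 0.01 µM, k1⁰ = k2⁰ = 1 (1/(µM·s) and 1/s), α1 = α2 = 0.5.
* Problem sizes: the test suite uses 400×400 grids for the ridge checks,
  10⁴ randomized landscapes for the Haldane property, 10⁵-point grid scans
  as the optimizer oracle, and 10⁵ draws for Gaussian-fit recovery; the
  whole suite runs in about a minute.
* Parameter-recovery assertions for the generator average over five seeded
  replicates: a single binned fit of σ at n ≈ 300 has sampling noise
  comparable to the ±0.1 recovery band, and the property under test is the
  estimator's accuracy, not one draw's luck.

## Known limitations

* The BEP relation is empirical; enzymes that break it (e.g. via Marcus
  inverted-region behavior) are outside the model, as are diffusion-limited
  enzymes for which the steady-state Michaelis-Menten picture itself fails.
* Substrate inhibition and allosteric (Hill-type) mechanisms are not
  implemented.
* The optimizer treats only ΔG₁ as a decision variable; the α's and k⁰'s are
  inputs, never optimized over.
* No live database queries; the dataset analysis works on local tables only,
  and organism information is carried through but not stratified on.
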