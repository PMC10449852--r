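# bepmm — thermodynamically constrained Michaelis–Menten kinetics

`bepmm` answers a practical question in enzyme engineering and systems
biology: **given a fixed total driving force, how should an enzyme allocate
free energy between substrate binding and turnover to maximize its activity?**

The two-step Michaelis–Menten mechanism

```
E + S  <--k1/k1r-->  ES  --k2-->  E + P
```

is described by a free-energy landscape: the binding free energy ΔG₁ of
E + S → ES and the total reaction free energy ΔG_T of S → P, with
ΔG₂ = ΔG_T − ΔG₁. The Brønsted–Evans–Polanyi (BEP) relation
E_a = E_a⁰ + αΔG, combined with the Arrhenius equation, couples the
elementary rate constants to the landscape:

```
k1  = k1⁰ g1^(−α1)          k1r = k1⁰ g1^(1−α1)        g1 = exp(ΔG1/RT)
k2  = k2⁰ (g1/gT)^(α2)      k2r = k2⁰ (g1/gT)^(α2−1)   gT = exp(ΔGT/RT)
```

so that the Michaelis constant Km = (k1r + k2)/k1 = g1(1 + K) with
K = k2⁰ g1^(α1+α2−1)/(k1⁰ gT^α2), and the steady-state rate is
v = k2[S][E_T]/(Km + [S]). Because k2 and Km are tied to the same landscape,
they cannot be improved independently: log k2 = α2·log Km + const. Maximizing
v over ΔG₁ at fixed ΔG_T gives the optimality rule

> **Km = [S]** for symmetric BEP coefficients (α1 = α2 = 0.5), and more
> generally **Km\* = (α2/(1−α2))·[S]** whenever α1 + α2 = 1.

The package provides:

* the kinetic core (`thermo_landscape()`, `rate_constants()`,
  `michaelis_constant()`, `activity()`), with Haldane-consistent reversible
  and competitive/uncompetitive rate laws (`reaction_rate()`);
* closed-form and derivative-free numerical optimization of the landscape
  (`optimal_dG1_closed()`, `optimize_numeric()`, `true_optimal_km()`),
  activity landscapes with ridge extraction (`activity_grid()`), volcano
  curves (`volcano_curve()`), the k2–Km scaling law (`scaling_relation()`),
  and the cost of the Km = [S] rule under mechanistic deviations
  (`km_rule_penalty()`);
* the bioinformatic consistency analysis of measured Km versus in-vivo
  substrate concentrations (`load_km_dataset()`, `km_consistency()`), which
  categorizes substrates by occurrence, fits Gaussians to log10(Km/[S])
  histograms and reports fraction statistics;
* seeded synthetic-data generators for the whole pipeline
  (`generate_km_dataset()`, `generate_landscapes()`).

Units are fixed: concentrations in µM, free energies in kJ/mol, time in s.

## Worked example

```r
library(bepmm)

enzyme <- thermo_landscape(dG1 = -25, dGT = -40)
enzyme
#> Two-step free-energy landscape (E + S <-> ES -> E + P)
#>   dG1 = -25 kJ/mol, dG2 = -15 kJ/mol, dGT = -40 kJ/mol
#>   alpha1 = 0.5, alpha2 = 0.5 (alpha1r = 0.5)
#>   k1_0 = 1 1/(uM s), k2_0 = 1 1/s, T = 298.15 K
#>   Km = 0.133084 uM

round(coef(enzyme), 4)
#>       k1      k1r       k2      k2r       Km     kcat
#> 154.8913   0.0065  20.6071   0.0485   0.1331  20.6071
```

This enzyme binds strongly (Km ≈ 0.13 µM): excellent at scavenging scarce
substrate, but its turnover k2 is capped by the little driving force left for
the second step. At [S] = 10 µM a weaker binder does better — and the optimum
is exactly at Km = [S]:

```r
optimize_numeric(S = 10, dGT = -40)
#> Optimal free-energy allocation (numeric, standard mechanism)
#>   dG1* = -14.293085 kJ/mol
#>   Km*  = 10 uM  (substrate [S] = 10 uM)
#>   v*   = 0.89314849 uM/s
```

The BEP coupling forces turnover and affinity onto a scaling line with slope
α2 (here the experimentally motivated α2 = 0.74):

```r
scaling_relation(dGT = -40, alpha1 = 0.26, alpha2 = 0.74)
#> log10(k2) vs log10(Km) scaling along a dG1 sweep
#>   slope = 0.74 (alpha2 = 0.74), intercept = 1.34835, R^2 = 1
```

How robust is the Km = [S] rule when an inhibitor competes for the enzyme
(degree of inhibition γ = [I]/Ki = 10)? The truly optimal Km drops to
[S]/(1+γ), an order of magnitude below [S], yet the activity lost by staying
at Km = [S] stays bounded:

```r
km_rule_penalty(S = 10, mechanism = "competitive", gamma = 10,
                dGT = seq(-80, 0, by = 2))
#> Penalty of the Km = [S] rule (competitive mechanism, gamma = 10, [S] = 10 uM)
#>   max shortfall vs optimum: 44.72 %
#>   max relative difference : 57.6 %
```

Finally, the dataset side: a synthetic Km–[S] table with the structure of the
published wild-type compilation (1703 entries; major metabolites, five
high-occurrence cofactors, ATP) is analyzed end-to-end:

```r
fit <- km_consistency(generate_km_dataset(seed = 1))
fit
#> Km vs in-vivo [S] consistency analysis: 1703 entries, 31 substrates
#>             label n_entries gauss_mu gauss_sigma frac_within_one_order
#>  major_metabolite       980   -0.231       1.368                 0.531
#>          cofactor       410   -0.443       1.213                 0.559
#>               ATP       313   -1.617       0.737                 0.192
#>  frac_km_below_S
#>            0.561
#>            0.649
#>            0.990
#> Overall: 0.29% of entries have log10(Km/[S]) > 3 (5 entries)
```

Major metabolites center near log10(Km/[S]) = 0 — wild-type affinities match
in-vivo concentrations to within an order of magnitude for about half the
entries — while ATP sits far below (Km ≪ [ATP]), as expected when many
enzymes compete for one substrate. `plot(fit)` draws the per-category
histograms with their fitted Gaussians.

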