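# oxex

Stochastic kinetics of the intermediate Pi–HOH oxygen exchange that
accompanies ATP hydrolysis by F₁-ATPase.

When F₁-ATPase hydrolyses MgATP, oxygen atoms of the enzyme-bound
phosphate (or of the γ-phosphoryl group of bound ATP) exchange with water
oxygens before the product Pi is released. The ¹⁸O record imprinted on
the released Pi — the mean ¹⁸O/P ratio and the full isotopomer
distribution (species with 3, 2, 1, 0 heavy oxygens, resolved by GC-MS) —
is a time-resolved probe of events inside the catalytic sites. `oxex` is
for enzymologists and modellers who want to analyse such data
quantitatively: estimate the apparent exchange rate constant, decide how
many catalytic sites exchange simultaneously, and confront trisite vs
bisite occupancy models with activity data.

## The model

**Uptake configuration** (label enters Pi from H₂¹⁸O). The fractional
extent X of labeling of released Pi obeys `dX/dt = k (1 − X)`. One of the
four Pi oxygens always comes from a water molecule in the hydrolysis
step itself, so `X(0) = Xᵢ = 1/4` and

```
ln[ 0.75 / (1 − X) ] = k t ,      X = ¹⁸O/P ÷ 4 ,      t = n / v
```

where `k` is the apparent exchange rate constant, `v` the steady-state
hydrolysis velocity (so `1/v` is the time available for exchange per
catalytic cycle) and `n ∈ {1,2,3}` the number of simultaneously
exchanging catalytic sites. The same X results whether exchange precedes
or follows bond cleavage (pathway independence; `extent_prehydrolysis_pathway`).

**Washout configuration** (labeled γ-phosphoryl ATP, unlabeled water).
Exchange events at a site form a chain A₁→A₂→A₃→A₄ (3→2→1→0 labels), all
steps at the same rate k — a Poisson process in the event count. With
initial percentages A₁₀…A₄₀ the closed forms are

```
A₁ = A₁₀ e^{−kt}
A₂ = (A₁₀ kt + A₂₀) e^{−kt}
A₃ = (A₁₀ (kt)²/2 + A₂₀ kt + A₃₀) e^{−kt}
A₄ = 100 − A₁ − A₂ − A₃
```

**Inference.** `fit_rate_constant()` regresses `ln[0.75/(1−X)]` on
`t = 1/v` through the origin (the law has no intercept);
`select_site_count()` scans n ∈ {1,2,3} by least squares against the
closed-form washout prediction at `kt = k·n/v`; `detect_transition()`
locates the switch from three exchanging sites (short times) to two
(long times). `species_fractions()` computes equilibrium occupancy
fractions of the eight site-filling patterns from three site-specific
dissociation constants (independent-site partition function), giving the
trisite `f(111)` and bisite activity curves that are compared with
Michaelis–Menten-normalised rates.

A seeded simulator (`simulate_dataset()`) generates GC-MS-style synthetic
observations — Michaelis–Menten velocities, the 33 ms regime switch,
Poisson-chain washout, multinomial counting noise — so every stage of the
analysis can be validated by parameter recovery.

## Worked example

```r
library(oxex)

ds <- simulate_dataset(simulation_config(seed = 1))   # 12 conditions, 1e4 molecules
fit <- fit_rate_constant(ds$observations)
fit
#> oxex fit: rate_constant
#>   estimate std_error
#> k  10.4818    0.0184
#> R-squared (about origin): 0.999972  (n = 10)
```

The generating rate constant (10.5 s⁻¹) is recovered to 0.2 %, with the
two fully saturated low-ATP conditions (¹⁸O/P at the 3.98 assay ceiling)
excluded automatically. The regime transition:

```r
trans <- detect_transition(ds$observations, fit$estimates[["k"]],
                           label_distribution(57, 17, 2, 24))
trans$transition_time_s   #> 0.0535 s
trans$bracket_atp_uM      #> 5.43 2.05  (µM, bracketing the 3-to-2-site switch)
```

Occupancy fractions from the mitochondrial-enzyme dissociation constants
(Kd = 0.018, 1, 150 µM):

```r
round(occupancy_table(c(1, 10, 100, 1000, 5000), mf1_binding_model()), 4)
#>   atp_conc_uM   f111   f110 f_bisite_all
#> 1           1 0.0033 0.4879       0.4912
#> 2          10 0.0567 0.8507       0.8565
#> 3         100 0.3960 0.5940       0.5980
#> 4        1000 0.8687 0.1303       0.1312
#> 5        5000 0.9707 0.0291       0.0293
```

`f111` — the fraction of enzyme with all three catalytic sites filled —
rises monotonically with [ATP] and dominates at saturating substrate,
while every bisite species decays; `run_pipeline()` chains all of the
above from a single JSON/YAML configuration into a report document.

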