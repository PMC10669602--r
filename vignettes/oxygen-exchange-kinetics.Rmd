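---
title: "Modelling intermediate Pi-HOH oxygen exchange in F1-ATPase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intermediate Pi-HOH oxygen exchange in F1-ATPase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxex)
```

## The process being modelled

F1-ATPase hydrolyses MgATP at three beta-catalytic sites. While the
phosphate (or the gamma-phosphoryl group of bound ATP) sits in a
catalytic site, its oxygen ligands exchange with water oxygens; the
released Pi therefore carries a record of how long it was exposed to
exchange and at how many sites. Two experimental configurations probe
this record:

* **Uptake**: heavy-oxygen water, unlabeled ATP. The observable is the
  mean number of heavy oxygens per released Pi (the 18O/P ratio, 0-4),
  summarised as the fractional extent `X = 18O/P / 4`.
* **Washout**: ATP labeled on the gamma-phosphoryl group, unlabeled
  water. The observable is the full isotopomer distribution - the
  percentages of Pi with 3, 2, 1, 0 heavy oxygens resolved by GC-MS.

Both configurations are driven by the same two quantities: an apparent
exchange rate constant `k` (first-order, per site) and the time `t`
available for exchange, which is set by the steady-state hydrolysis
velocity (`t = n / v`, with `n` the number of simultaneously exchanging
catalytic sites). Only the product `kt` ever enters the equations, and
every function in the package takes it in that composite form.

### Uptake kinetics

Exchange of a Pi oxygen pool with water follows `dX/dt = k (1 - X)`.
Because exactly one of the four oxygens of each released Pi is
incorporated from a water molecule by the hydrolysis step itself, the
pre-exchange extent is `Xi = 1/4` (`hydrolysis_initial_fraction()`), and

$$\ln\!\left[\frac{0.75}{1 - X}\right] = kt .$$

The same X results if the exchange happens on the gamma-phosphoryl group
*before* cleavage: three quarters of the oxygens then carry the
pre-hydrolysis extent `1 - e^{-kt}` and one quarter is the water oxygen
from the cleavage step. `extent_prehydrolysis_pathway()` implements this
weighted sum, and the test-suite verifies its identity with
`extent_from_kt()` to 1e-12 over 1000 random exposures - the model's
pathway-independence property, which is what licenses fitting a single
`k` without committing to an order of elementary steps.

### Washout kinetics

Washout of the (at most three) heavy labels proceeds as a chain
`A1 -> A2 -> A3 -> A4` of single-label losses. The package commits to the
constant-rate special case - every step at the same `k` - under which the
event count over an exposure is Poisson with mean `kt` and the chain
integrates in closed form (`isotopomer_distribution()`):

$$A_1 = A_{10}e^{-kt},\quad
A_2 = (A_{10}kt + A_{20})e^{-kt},\quad
A_3 = \left(A_{10}\tfrac{(kt)^2}{2} + A_{20}kt + A_{30}\right)e^{-kt},$$

with the zero-label class taken by normalisation closure,
`A4 = 100 - A1 - A2 - A3` (the chain is absorbing at zero labels, so no
fourth closed form is needed). A general-rate chain would add three
parameters the data cannot constrain; the constant-rate form is also the
one the stochastic simulator realises, so the two can be checked against
each other exactly.

Distributions are carried as percentages (the convention of the
literature and of GC-MS reports) by the `label_distribution` class, which
enforces non-negativity and closure to 100. An 18O4 channel exists in the
mass spectra but has no state in the theory (the gamma-phosphoryl group
carries at most three labels); it is accepted on input only up to a 0.5%
validation tolerance.

Note the deliberate asymmetry of conventions: `Xi = 0.25` belongs to the
uptake direction, while the washout chain starts from a measured initial
distribution. The two share the single rate constant `k`, which the
package - like the theory it implements - treats as one phenomenological
parameter rather than attempting a microscopic reconciliation of the
per-oxygen uptake law with the single-event washout chain.

## Inference

### The rate constant

`fit_rate_constant()` transforms each observation to
`y = ln[0.75/(1 - X)]` and regresses `y` on `t = n/v` by ordinary least
squares **through the origin**: the uptake law has no intercept, so a
free intercept would spend a degree of freedom absorbing exactly the
signal being tested. The reported R-squared is correspondingly computed
about the origin (`1 - SS_res / sum(y^2)`). A free-intercept mode exists
for diagnostics and reports the conventional R-squared. Weighting is
uniform: per-point uncertainties are generally only available as figure
error bars, not numbers.

The default time axis is `t = 1/v` (`n = 1`). The site-count multiplier
deliberately enters only the *distribution* predictions: the extent data
are conventionally plotted and fitted against the reciprocal velocity,
and the selection stage is where multisite structure is actually
identified.

**Saturation guard.** Observations with `18O/P` above `o18_max = 3.98`
(default) are excluded with a warning. The ceiling of the measurement is
4 labels per Pi; readings at or near it pin `X` to 1, where the log
transform diverges and a single point - carrying weight proportional to
`t^2` in the through-origin fit - can dominate the slope while containing
no information about `kt`. The default matches the largest resolvable
reading of the GC-MS assay. With 10^4 molecules per condition the
simulator's lowest-concentration conditions saturate with probability
close to 1, so the guard is exercised routinely.

### Site-count selection and the regime transition

`select_site_count()` compares a measured distribution with the
closed-form prediction at `kt = k n / v` for each candidate
`n` in {1,2,3} and picks the smallest sum of squared differences over
the four percentage components. The criterion is deliberately simple -
the alternative chi-square-on-counts criterion (available via
`criterion = "chisq"`) needs the molecule count behind the measurement,
which real GC-MS tables rarely state. Exact ties are broken toward the
smaller n (parsimony) and surfaced via a `tie` flag; the fully degenerate
no-exchange case (`kt = 0`, reachable as `velocity = Inf`) ties all
candidates and returns n = 1 flagged.

`detect_transition()` orders observations by exchange time `1/v`, labels
each by its selected n, and reports the midpoint between the largest
time labelled n = 3 and the smallest labelled n = 2, with the bracketing
ATP concentrations. A label sequence that returns from 2 to 3 sites as
time grows is physically unexpected and yields a warning plus the full
label vector - not an error, because at low molecule counts the shortest
exposures genuinely produce noisy labels.

### Michaelis-Menten support

`fit_michaelis_menten()` (Levenberg-Marquardt, started from the
double-reciprocal linearisation) exists to normalise activities for the
occupancy comparison, not as a contribution: `normalized_activity()`
divides velocities by Vmax, warning - not failing - on values up to 5%
above it (measurement scatter). A design with all concentrations far
above Km leaves Km unidentified; this surfaces as a large standard
error rather than an error, matching how practitioners read such fits.

## Occupancy model

The study's occupancy question - trisite vs bisite filling - needs the
fraction of enzyme in each of the 8 site-filling patterns as a function
of [ATP], given three site dissociation constants. No formula is printed
in the source literature, so the package makes the model explicit:
**independent sites**, i.e. per-site occupancy `theta_i = S/(S + Kd_i)`
and pattern weight equal to the product of `theta_i` over filled and
`1 - theta_i` over empty sites (the grand partition function over the 8
patterns). This choice is forced by the fact that the doubly-occupied
species (110), (101) and (011) are all given weight in the bisite
comparison - a strictly sequential filling model would zero two of them.
A sequential (Adair-ordered) mode is nevertheless provided
(`mode = "sequential"`) for sensitivity analysis.

Two literature parameter sets ship as constructors:
`mf1_binding_model()` (0.018, 1, 150 uM, mitochondrial enzyme) and
`ef1_binding_model()` (0.02, 1.4 uM for the two tight sites of the
E. coli enzyme, with the weak site approximated by the Michaelis
constant, 99 uM by default). MgATP is the only ligand considered;
MgADP competition is out of scope (no constants are available for it).

The factorisation `f(111) = theta1 theta2 theta3`, normalisation at
every concentration, monotonicity of the trisite curve, unimodality of
the partial-occupancy species, and the large-S limit
`f(111) -> S/(S + Kd3)` are all verified in the test-suite against a
brute-force enumeration of the partition function.

## The synthetic-data generator

`simulate_dataset()` produces the kind of dataset the analysis assumes,
with ground truth attached. Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `k` | 10.5 1/s | apparent exchange rate constant |
| `initial` | 57/17/2/24 % | measured gamma-phosphoryl label distribution |
| `atp_concs` | 12 points, 0.11-5000 uM (log-spaced) | substrate grid |
| `vmax`, `km` | 640 1/s, 99 uM | Michaelis-Menten velocity law |
| `switch_time` | 0.033 s | hard 3-to-2-site switch on the per-site time |
| `molecules_per_condition` | 10^4 | multinomial GC-MS counting noise |

Per condition: `v = Vmax S/(Km + S)`, `t = 1/v`, `n = 3` if
`t < 0.033 s` else `2`, washout exposure `kt = k n t`, and an isotopomer
distribution sampled molecule-by-molecule (`simulate_population()`,
built on the Poisson event chain `simulate_molecule_washout()`). The
18O/P column is by default simulated from the uptake configuration at
exposure `k/v` (`simulate_uptake_extent()`: each Pi carries
`1 + Binomial(3, 1 - e^{-kt})` labels), because that is the observable
the rate-constant fit consumes and the scale (1-4) on which it is
reported; `o18_source = "washout"` instead sets the column to the mean
label count of the sampled distribution (0-3 scale) for strict internal
consistency with the distribution columns.

What the generator emulates: the velocity law, the regime switch, the
absorbing washout chain, and molecule-counting noise. What it does not:
instrument-level GC-MS noise (peak integration, derivatisation
artifacts), per-condition biological replicates (figure error bars
conflate both), smooth crossover of the site count around 33 ms, 18O4
species, and any rotary-dwell fine structure. Passing recovery tests
therefore demonstrate statistical identifiability under idealised
counting noise - not robustness to instrument systematics.

The molecule count (10^4) was chosen as a realistic per-measurement
scale that reproduces percent-level scatter in the distribution
components; recovery tests in the suite use 10^2-10^4 (consistency
scan), 10^5 (goodness-of-fit screen) and 10^6 (Monte-Carlo oracle for
the closed forms, compared at three standard errors).

## Numerical choices and degenerate inputs

* **Clamping near X = 1**: `kt_from_extent()` clamps extents within
  1e-12 of 1 (with a warning) before the log; measured 18O/P near 4
  otherwise produces infinities.
* **Round-trip precision**: `kt -> X -> kt` is exact to 1e-10 for
  `kt <= 12`. Beyond that, `1 - X` (about `e^{-kt}`) falls below what a
  double stored near 1 can represent, and the inverse degrades to the
  representation limit (about 1e-4 relative by `kt = 24`). This is a
  property of storing X, not of the algorithm; the experimentally
  accessible range (`18O/P <= 3.98`, i.e. `kt <= 5.3`) is far inside the
  exact regime.
* **Ties** in site selection: broken toward smaller n, always flagged.
* **All-equal exchange times**: rejected as a singular design by
  `fit_rate_constant()` even though a through-origin slope would be
  formally identifiable - a single-time design cannot support the
  linearity claim the fit is used to make.
* **Empty or header-only tables**: detected before any computation with
  a usage error; malformed cells and row-sum violations are reported
  with row and column names.
* **Seeding**: `simulate_dataset()` seeds R's RNG from its config, so a
  config fully determines the dataset bytes; lower-level simulators use
  the ambient RNG state and are composable under a caller's seed.

## Interface

The package's interface is its functions; `run_pipeline()` chains the
stages (observations or simulation, rate-constant fit or fixed value,
per-observation site selection, transition detection, Michaelis-Menten
normalisation, occupancy tables) from a single validated JSON/YAML
configuration and writes a JSON report whose only non-deterministic
field is the timestamp in its provenance block. Observation tables are
plain delimited text with named columns (`read_observations()` /
`write_observations()`), percentages on the printed 0-100 scale.

```{r example, eval = FALSE}
report <- run_pipeline(list(
  simulation = list(molecules_per_condition = 1e4),
  seed = 1,
  output_dir = "exchange-report"
))
```

## Known limitations

* The apparent rate constant is treated as concentration-independent;
  the package tests that hypothesis through the quality of a single
  global fit rather than fitting per-condition rate constants.
* Selection among n in {1,2,3} assumes `k` is known (fitted first); no
  joint (k, n) fit is attempted, mirroring the fixed-k-then-scan-n
  analysis the data support.
* The occupancy model is an equilibrium description; kinetic occupancy
  dynamics during turnover are out of scope.
* Only molecule-level multinomial noise is simulated; recovery rates
  quoted by the test-suite are therefore upper bounds on what real
  instrument noise would allow.
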