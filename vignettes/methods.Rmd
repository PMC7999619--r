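---
title: "Models and methods: line-tailored diet optimization with bio-economic and LCA assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: line-tailored diet optimization with bio-economic and LCA assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porkopt)
```

`porkopt` evaluates how genetic selection for feed efficiency and
line-tailored diet formulation combine to affect the profitability and the
environmental footprint of producing a 120-kg live pig. This vignette
documents the models, their assumptions, the tunable parameters and the
choices made where the design was genuinely open.

## The study design

Two lines divergently selected on residual feed intake (RFI) — the
efficient LRFI line and the inefficient HRFI line, 57 fattening pigs each —
are simulated on four diets: a shared reference diet and three diets
tailored to each line's nutritional requirements, formulated for least
cost (LC), least environmental-impact score under a cost cap, and a joint
cost–environment objective. Each of the eight line-by-diet scenarios is
pushed through an individual trait-based profit model and a simplified
cradle-to-farm-gate LCA, and the line contrasts are summarised by t-tests,
correlations, zero-profit market sensitivities and relative line gaps.

## Growth model

The body is tracked as protein mass $P$ and lipid mass $L$ (kg). Live
weight follows a standard allometry with body water $w_c P^{0.855}$
($w_c = 5.42$), ash $0.15\,P$ and a 95 % empty-body fraction (5 % gut
fill). With the default initial protein fraction (16 % of a 30-kg pig)
this maps a finishing pig with $P \approx 19.5$, $L \approx 24$ kg to
about 121 kg live weight — the neighbourhood reported for the selection
experiment at slaughter.

Daily potential protein deposition is the Gompertz differential form
$dP/dt = b\,P\ln(P_{mat}/P)$. Ad libitum NE intake follows the
gamma-shaped curve $NE(BW) = s\,BW\,e^{-c\,BW}$ (MJ/d); pigs adjust feed
intake to the diet's NE density, so feed mass is $NE(BW)$ divided by the
density. The population simulator of the original study is external
software whose internal parameterisation is not published; these
two-parameter forms are this package's own stand-ins and are not claimed
to be numerically equivalent to it.

Energy partition per day: maintenance $0.75\,BW^{0.60}$ MJ NE, retained
energy 23.6 MJ/kg protein and 39.7 MJ/kg lipid — conventional NE-system
constants, all exposed in `growth_config()`. Realised protein deposition
is the minimum of the Gompertz potential, the energy-allowed rate and the
crude-protein- and amino-acid-allowed rates (marginal efficiency 0.72 for
amino acids, 0.78 for CP; body protein contains 7 % lysine with ideal
ratios 0.65/0.19/0.30 for threonine/tryptophan/methionine). Lipid takes
the residual NE, so daily NE is conserved exactly — a property the test
suite asserts at 1e-6 relative tolerance. Integration is an explicit daily
Euler step; the first day ending at or above the 120-kg target counts
fully, which keeps every finishing weight within one day's gain of the
target.

Carcass outputs are linear maps chosen so an adequately fed reference pig
lands in the reported trait region: lean meat percentage
$35 + 57\,P/(P+L)$, back fat $7 + 0.375\,L$ mm, carcass weight
$0.793\,BW$.

Calibration (`calibrate_profile()`) inverts the simulator from daily
records in two stages: the intake curve is linear in
$\log(NE/BW) = \log s - c\,BW$ and is fitted by ordinary least squares;
$(P_{mat}, b)$ are then fitted by Levenberg–Marquardt on the simulated
body-weight trajectory (log-parameterised to keep both positive). On
noise-free records generated by the simulator itself the loop closes to
machine precision; with 1 % multiplicative weighing noise the mature
protein mass — the weakest-identified parameter, since fattening pigs stay
far from maturity — is recovered to a few percent.

## Nutritional requirements and diet formulation

A pig's requirement for each nutrient on each day is the intake that lets
it express its Gompertz potential: potential deposition times the body
content of the nutrient divided by the marginal efficiency, standardized
to that day's NE intake (g/MJ NE). The indicators peak early in fattening,
when intake is still low; the per-pig summary is the maximum over a
28-day early-growth window, and line requirements are the per-nutrient
means over the line — LRFI pigs, eating less for similar protein growth,
end up with systematically higher g/MJ requirements.

Formulation optimises the non-additive incorporation rates $q_i$ under a
mass balance (1 kg minus 32.5 g/kg of fixed additives, split 4.5/11/12/5 g
between salt, calcium carbonate, dicalcium phosphate and a vitamin-mineral
premix) and five requirement rows
$\sum_i q_i (X_i - R\,NE_i) = 0$. The rows are equalities by default — the
diet supplies exactly R g/MJ — with an `at_least` switch because equality
can be infeasible with few ingredients. Incorporation bounds are
$[0, 1-\text{additives}]$; no milling constraints.

The three objectives are:

* least cost: $\sum_i q_i\,p_i/NE_i$ — each ingredient's price normalized
  to its own NE, which penalises energy-poor ingredients;
* least EI score: $\sum_k w_k\,(\text{impact}_k/NE)/(\text{impact}_k^{LC}/NE^{LC})$
  with unit weights, subject to the diet's price per MJ NE staying within
  110 % of the LC diet's;
* joint: $w_t \cdot EI + (1-w_t)\cdot$ price ratio, swept for
  $w_t \in [0,1]$ in steps of 0.01 (no cost cap in the sweep).

The cost measure differs deliberately between the LC objective
(per-ingredient $p_i/NE_i$, the literal least-cost formulation) and the
score/cap/joint terms (diet-level price per MJ NE); the source equations
mix both notations and the diet-level form is the one that makes the
score a well-defined ratio.

Two solvers implement every objective. The exact route is a dense
two-phase simplex; the EI and joint objectives are ratios of linear forms
in $q$ and are solved exactly after the Charnes–Cooper substitution
$y = tq$, $t = 1/(NE^\top q)$, which keeps every constraint linear
(homogeneous rows pick up a $-b_i t$ term, the cost cap becomes
$p^\top y + p_{add}t \le \text{cap}$). The evolutionary route is a
real-coded genetic algorithm in the spirit of the constrained NSGA-II
usage it mirrors (defaults: population 340, 3,500 generations, both
configurable): individuals are repaired by alternating projection onto
the equality rows and the non-negative orthant followed by a mass
rescale, varied by blend crossover with extrapolation and decaying
Gaussian mutation plus an occasional coordinate-zeroing move (optima sit
on polytope vertices), and selected by objective value plus a large
penalty on any residual violation. Because the exact optimum is available,
the test suite holds the evolutionary solver to within 0.5 % of the LP
objective on twenty seeded 14-ingredient instances.

The selected $w_t$ maximises the ratio of the score reduction (relative to
the LC diet) to the price increase over the grid, with ties broken toward
smaller $w_t$; a discrete-slope alternative is exposed
(`select = "slope"`), and a price-flat degenerate curve falls back to the
smallest $w_t$ attaining the minimal score, with a warning.

## Bio-economic model

A linear profit model per pig: revenue minus itemized costs. Costs cover
the weaned-piglet market price (which absorbs the whole sow-litter stage),
postweaning feed/water/energy/labor/capital from line-mean intake and
gain, the fattening components driven by the pig's own simulated traits
(feed = diet price × ADFI × duration; water at 2.7 L/kg feed, 2.5 L/kg
postweaning; energy at 0.42 kWh/kg gain; labor from 2.3 workers per
200-sow farm, 25 weaned piglets/sow/year, 1,600 h/year at 1.5 × 10.03 €/h,
half attributed to the growing phase over a 163-day cycle; capital at 6 %
interest on a 2,500 €/sow investment) and a fixed health/insurance term.
Manure is assumed cost-neutral. Revenue prices the carcass
(0.793 × BW) on a configurable grid: base price 1.28 €/kg at the 100-kg /
56 %-lean reference point, ±0.02 €/kg per lean point, a flat 90–105 kg
band with a penalty outside. The actual French grid is not published with
the study, so the default is a monotone-in-leanness stand-in; piglet
price (33 €), postweaning means and fixed costs are likewise package
defaults in French-farm magnitudes.

Zero-profit sensitivity is linear: a euro of extra fattening feed cost or
of lost revenue removes a euro of profit, so the tolerable diet-price
increase is $100\,\pi/\text{feed cost}$ and the tolerable pig-price drop
$100\,\pi/\text{revenue}$, computed on line means. The package bundles
the reported line-by-diet means of the selection experiment
(`reported_line_means()`) as inputs for these worked examples; feeding
them through `zero_profit_sensitivity()` and `derived_line_metrics()`
reproduces the published 15.2 / 38.2 / 32.6 % sensitivities and the
23.4 → 7.6 % profit-gap narrowing, which the acceptance script recomputes.

## LCA model

Functional unit: 1 kg of live pig at the farm gate, cradle-to-farm-gate.
Four categories: GWP (kg CO₂ eq), AP (g SO₂ eq), EP (g P eq, freshwater)
and LO (m²a crop eq). Per pig:

* feed chain: incorporation-weighted ingredient impacts × total feed
  intake, plus transport at 100 km farm→factory, 500 km extra for the
  cereal share, 30 km factory→farm, with per-t·km factors;
* excreta: nutrient mass balance, intake − retention. N intake derives
  from digestible CP via a configurable digestibility (0.85) and N =
  CP/6.25; N retention is protein gain × 0.16. The ingredient library
  carries no P or K, so P/K intakes use config-level per-kg-feed contents
  and per-kg-gain retentions. Conservation (intake = retention + excreta)
  is exact by construction and asserted in the tests;
* emissions: housing fractions of excreted N to NH₃/N₂O/NOx/N₂, field
  fractions for the remainder, enteric and manure CH₄, and P leaching,
  characterised by per-kg factors (N₂O × 265, CH₄ × 28, NH₃ × 1.88 g
  SO₂/g). The published emission-factor tables behind the original study
  are deliberately replaced by this config-driven set with
  order-of-magnitude defaults; every factor is a YAML key;
* fertilizer credits: field-applied N (75 % equivalence) and P, K (100 %)
  offset synthetic fertilizer production at configured per-kg impacts.
  With equivalences capped at 1 a credit can never exceed the substituted
  fertilizer's gross impact;
* upstream: one configurable impact vector per weaned piglet stands in
  for the sow-litter and postweaning stages, whose mechanistic profiles
  are out of scope.

Land occupation receives feed-chain and upstream contributions only. The
farm-gate score normalises a scenario's impact vector to the same line's
LC baseline; the default is the mean of per-category ratios (baseline
scores 1), because the literal sum of the four categories mixes
incommensurable units — that literal mode is still available
(`mode = "literal_sum"`).

## Synthetic data: what it emulates and what it does not

The generator draws ingredient nutrient contents, prices and impacts from
truncated normals around anchors of published magnitude (cereals near
9–11 MJ NE/kg, soybean meal near 450 g digestible CP/kg, amino acids
expensive and impact-intensive per kg), so formulation problems are
realistic without copying any database row. Line defaults were set so the
simulated reference-diet traits land near the reported fattening means
(ADFI ≈ 2.0 vs 2.2 kg/d, FCR ≈ 2.5 vs 2.6, duration ≈ 116 vs 111 d,
lean ≈ 61 vs 58 %); the line contrast is mechanistic — a lower intake
curve for LRFI with similar protein growth — so higher NE-standardized
requirements for the efficient line emerge rather than being imposed.

What passing tests on these data do **not** show: agreement with any real
herd's absolute profits or impacts (prices and impacts are synthetic
draws; the reported-mean worked examples are the only quantities tied to
published numbers), sow-stage biology, multiphase feeding, health or
thermal perturbations, or slaughter in batches (slaughter weight is fixed
at 120 kg, which inflates trait–profit correlations relative to field
conditions, a limitation the original analysis shares).

## Numerical choices and problem sizes

Equality residual tolerances: 1e-6 for the exact solver, 1e-3 for the
evolutionary one (reported via `check_diet()`). The simplex uses Bland's
rule with a 1e-9 pivot tolerance; phase-1 feasibility is accepted below
1e-7; infeasibility reports name requirement rows that no non-trivial mix
can satisfy. The Charnes–Cooper back-substitution is safe because the
normalisation row forces $t > 0$ whenever the system admits a diet with
positive NE. Gompertz fitting runs on log-parameters with
Levenberg–Marquardt (200 iterations, 1e-12 tolerances). Measurement noise
for calibration-robustness studies is multiplicative with CV 1 %, seeded.

The default study uses the full 57 pigs per line and the 0.01-step
trade-off grid (101 exact solves per line) and completes in about a
minute; the test suite exercises the evolutionary solver at population
150–220 and 600–1,500 generations, which already matches the exact
optimum to a fraction of a percent on these 14-ingredient problems, and
keeps the heavier paper-scale defaults (340 × 3,500) configurable rather
than routine. Every stage seed derives deterministically from the master
seed, so a study run is byte-reproducible.
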