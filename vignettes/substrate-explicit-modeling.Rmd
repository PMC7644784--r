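---
title: "Substrate-explicit modeling of organic matter oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-explicit modeling of organic matter oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxm)
```

## The modeling problem

Ultra-high-resolution mass spectrometry (FTICR-MS and kin) characterizes
natural organic matter as thousands of assigned molecular formulae per
sample, with no structures and no concentrations. Conventional
biogeochemical models cannot use this information: they lump the organic
pool into one or a few state variables and parameterize kinetics per pool.
`sxm` takes the opposite, substrate-explicit route: every detected formula
gets its own oxidative degradation reaction, thermodynamic profile and rate
expression, and the entire reaction system is governed by just two kinetic
parameters — a maximal specific growth rate $\mu^{max}$ and a harvest
volume $V_h$ (the volume a microbe can access for harvesting energy) — no
matter how many compounds are present.

## From a formula to a balanced metabolic reaction

All reactions live on a fixed basis of ten chemical species: the organic
compound (OC), H$_2$O, HCO$_3^-$, NH$_4^+$, HPO$_4^{2-}$, HS$^-$, H$^+$,
e$^-$, O$_2$ and biomass (CH$_{1.8}$N$_{0.2}$O$_{0.5}$). For a compound
C$_a$H$_b$N$_c$O$_d$P$_e$S$_f$ with net charge $z$, the electron-donor half
reaction oxidizes all carbon to bicarbonate, releasing nitrogen as
ammonium, phosphorus as hydrogen phosphate and sulfur as bisulfide. Its
electron coefficient is

$$n_{e^-} = -z + 4a + b - 3c - 2d + 5e - 2f,$$

and the nominal oxidation state of carbon is $\mathrm{NOSC} = 4 - n_{e^-}/a$.
Aerobic catabolism combines the donor half reaction with the oxygen couple
(O$_2$ + 4H$^+$ + 4e$^-$ $\rightarrow$ 2H$_2$O) at ratio $n_{e^-}/4$.
Anabolism forms one C-mol of biomass from the compound with ammonium as
nitrogen source. The metabolic reaction couples the two energetically:

$$y = \lambda\, y^{Cat} + y^{An},$$

where $\lambda$ is the number of catabolic turnovers needed to pay for one
C-mol of biomass — the package's central thermodynamic index of substrate
quality (lower $\lambda$, more favorable growth).

Every constructed vector is checked against the element/charge balance
operator (`balance_residual()`); the property suites require residuals
below $10^{-9}$ across thousands of random CHNOPS formulae.

### The anabolic electron-closure convention

How the anabolic reaction balances its electrons is a genuine design
choice, so it is isolated in one function with two selectable conventions.
The default (`"donor_scaled"`) scales the carbon-source donor half reaction
by $x = n_B/(n_{e^-}/a)$ (with $n_B = 4.2$ electrons per C-mol biomass) so
that electrons close without any terminal acceptor; the classic
heterotrophic construction follows, with $y_{HCO_3} = x - 1$ turning
negative (net carbon fixation into biomass) for compounds more reduced than
biomass (NOSC $< -0.2$). The alternative (`"acceptor_balanced"`) feeds
exactly $1/a$ mol of compound per C-mol biomass and closes the electron
mismatch with the O$_2$ couple. Both conventions balance exactly and are
tested; results in this package default to the acceptor-free construction
because it keeps anabolism purely synthetic and the O$_2$ demand entirely
attributable to catabolism.

## The Gibbs-energy chain

Formation energies of nine of the ten species are tabulated constants
(kJ/mol, 25&nbsp;°C, 1&nbsp;bar): H$_2$O $-237.2$, HCO$_3^-$ $-586.9$,
NH$_4^+$ $-79.5$, HPO$_4^{2-}$ $-1089.1$, HS$^-$ $+12.0$, O$_2$ $+16.5$,
biomass $-67$, with H$^+$ and e$^-$ zero by convention. The compound's own
formation energy is unobtainable from a formula alone (group-contribution
methods need structures), so it is back-calculated from the per-C-mol
linear NOSC relation for oxidation half reactions,

$$\Delta G^0_{Cox}\,[\mathrm{kJ/C\text{-}mol}] = 60.3 - 28.5\,\mathrm{NOSC},
\qquad \Delta G^0_{r,D} = a\,\Delta G^0_{Cox},$$

by inverting the donor half reaction's energy sum. This inversion is exact
by construction and is verified to $10^{-9}$ in the tests.

Energies are reported at two reference states: the standard state (pH 0,
unit activities) and the biological standard state (pH 7), related by
$\Delta G^{0'} = \Delta G^0 + RT\,y_{H^+}\ln 10^{-7}$ (about $-39.95$ kJ
per mol of protons produced at 298.15 K). The coupling parameter is
computed from a thermodynamic electron equivalents balance,

$$\lambda\,(\eta\,\Delta G_{r,Cat}) + \eta^m\,\Delta G_{r,Block} +
\Delta G_{r,Syn} = 0,$$

with energy-transfer efficiency $\eta = 0.43$, building-block-to-biomass
cost $\Delta G_{r,Syn} = 200$ kJ/C-mol, and $m = +1$ when forming building
blocks releases energy ($\Delta G_{r,Block} \le 0$) or $-1$ when it costs
energy. Because building blocks share the biomass composition,
$\Delta G_{r,Block}$ is identified with the anabolic energy. The
dissipation energy follows as
$\Delta G_{r,Dis} = \lambda(-\Delta G_{r,Cat}) - \Delta G_{r,Ana}$.

Numerical edge cases are handled explicitly rather than silently:

* $m$ at $\Delta G_{r,Block} = 0$ uses $+1$; the term vanishes either way,
  and fixing the branch removes an undefined case.
* Endergonic catabolism ($\Delta G_{r,Cat} \ge 0$) makes $\lambda$
  undefined; the row gets `NA` and an `endergonic_catabolism` flag.
* Negative $\lambda$ (conceivable for extremely favorable anabolism) is
  retained with a `nonpositive_lambda` flag instead of being clamped, so
  distributions are not biased; flagged compounds are excluded from
  kinetics by default.
* Compounds with $n_{e^-} \le 0$ cannot act as electron donors here and
  are flagged `not_oxidizable`; batch processing never aborts on a bad row.

Which pH feeds $\lambda$, the metabolic vector and the kinetics is a
configuration switch (`thermo_config(ph = )`). The default is the
biological standard state (pH 7), the conventional choice for redox
thermodynamics of circumneutral aquatic systems; both values are always
reported so analyses can be run either way. Temperature is fixed at
298.15 K with no enthalpy-based correction — the formation-energy table is
a 25 °C table, and extrapolating it would suggest an accuracy the inputs
do not have.

## Growth kinetics

Rates use the energy-harvest exponential form. Under carbon and oxygen
co-limitation,

$$\mu_i = \mu^{max}
\exp\!\left(-\frac{|y_{OC,i}|}{V_h\,[OC_i]}\right)
\exp\!\left(-\frac{|y_{O_2,i}|}{V_h\,[O_2]}\right),$$

and single-limitation scenarios drop the other factor. The exponent is the
metabolic coefficient *divided by* the dimensionless harvest product
$V_h[S]$: a smaller harvest product means stronger limitation and a slower
rate, and $\mu \to \mu^{max}$ as the products grow without bound. This
quotient reading is the single most consequential interpretation in the
package and is therefore isolated in one internal function; the harvest
products at 1 (moderate) and 0.2 (severe) are the conventional comparison
levels. Only the product $V_h[S]$ enters the law, so scenario analyses
parameterize it directly and treat it as dimensionless; the dynamic
simulator composes a global $V_h$ with evolving concentrations instead.
Chemical rates are coefficients times $\mu$: $r_{OC} = y_{OC}\,\mu$,
$r_C = a\,r_{OC}$, $r_{O_2} = y_{O_2}\,\mu$, $r_{HCO_3} = y_{HCO_3}\,\mu$,
all per C-mol of biomass. $\mu^{max}$ defaults to 1 in comparative
analyses, which it cannot affect.

## Dynamic simulation and regulation

`simulate_batch()` integrates the batch mass balances with `deSolve`
(lsoda, relative tolerance $10^{-8}$, absolute $10^{-12}$) on a fixed
output grid for reproducibility. Exponential kinetics vanish smoothly with
the substrate, so trajectories approach zero without crossing it and no
event handling is required. Three modes share one right-hand side:

* **sxm** — every compound reacts at its unregulated rate and all growth
  contributions feed a single biomass pool (the minimal multi-compound
  extension of the per-compound balances).
* **sxm_exm** — simplified cybernetic regulation: allocation weights
  $u_i = \mu_i^{kin}/\sum_j \mu_j^{kin}$ are recomputed algebraically from
  the current state at every evaluation and multiply the kinetic rates.
  The full enzyme balance (constitutive/inductive synthesis, degradation)
  is deliberately not integrated; the algebraic form is the stated
  simplification this package adopts.
* **sxm_mxm** — multiple guilds differing only in $\mu^{max}_j$ and their
  biomass pools; one guild reproduces plain sxm to solver tolerance
  (tested), and $V_h$ stays global, preserving the two-parameter claim.

Total carbon ($\sum_i a_i[OC_i] + [HCO_3^-] + \sum_j [B_j]$) is conserved
to below $10^{-6}$ relative drift in the test trajectories, and regulated
consumption never exceeds unregulated consumption at any time point.

The compound-count scaling analysis (`scaling_experiment()`) evaluates
aggregate specific respiration at a fixed harvest state for seeded random
subsets of a compound pool. Without regulation the aggregate rate is a sum
over compounds and grows linearly with subset size — a structural artifact
of unregulated substrate-explicit kinetics; with cybernetic weights it
stays nearly constant. The test conditions (a 500-compound synthetic pool,
subset sizes 10–100) reproduce this contrast: a line through the origin
with $R^2 > 0.98$ without regulation, a max/min ratio under 1.5 with it.

## What the synthetic generator emulates — and what it does not

`generate_formulas()` emulates the *composition space* of assigned FTICR
formulae: CHNOPS only, carbon counts 5–40, H/C in 0.3–2.2 and O/C in
0–1.2 (typical van Krevelen coverage of natural organic matter),
occasional heteroatoms (N up to 3 with per-atom probability 0.1, S up to 2
at 0.05, P at 0.05 — most natural-OM assignments are plain CHO), and a
controllable NOSC distribution (default location $-0.3$, scale 0.5,
matching the mildly reduced character of riverine organic matter).
Heteroatoms and carbon are drawn first, hydrogen via the H/C ratio, and
oxygen is then solved per row from a Gaussian NOSC target, with rejection
at the bounds and an iterative nudge of the sampling location so the
achieved mean lands within 0.15 of the target. Everything is a pure
function of (spec, seed).

`generate_cohort()` emulates a two-zone field design: samples from a
high-activity zone draw more reduced formula pools (NOSC location $-0.6$)
than low-activity samples ($0.0$), and the measured respiration proxy is
constructed as
$\mathrm{resp}_s = \alpha - \beta\,\bar\lambda_s + \varepsilon$ with
$\varepsilon \sim N(0, \sigma)$. The default noise ($\sigma = 0.005$) was
chosen once, by Monte-Carlo against the across-sample spread of
$\bar\lambda$ (about 0.006 under the default zones), to give a moderate
but reliably detectable signal; with 30 samples the recovered Pearson
correlation is about $-0.8$ and falls below $-0.4$ in essentially every
seed.

The generator deliberately does **not** emulate instrument reality: no
intensity/abundance structure (compounds are presence/absence, which is
also why cohort aggregation defaults to the unweighted mean), no
isotopologues, no m/z calibration error, no peak-assignment ambiguity, and
no correlation structure between co-occurring compounds. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers a
thermodynamic signal *when one exists and the formula table is clean*;
they say nothing about assignment quality or matrix effects in real data.

## Sizes, tolerances and other fixed choices

* Property suites run on 1000 seeded random CHNOPS formulae (balance and
  energy-chain identities at $10^{-9}$), the scaling analysis on a
  500-compound pool, and the cohort recovery on 20 seeds of 30 samples
  with 40 compounds each — sizes chosen to exercise the vectorized batch
  paths well beyond typical per-sample workloads while keeping the whole
  suite interactive.
* Charged compounds: formula strings carry no charge, so charge is an
  explicit argument; it enters $n_{e^-}$ as $-z$, which is exactly what
  charge balance of the donor half reaction requires. Assigned FTICR
  tables are effectively neutral, but the convention generalizes cleanly.
* Elements outside CHNOPS are rejected, not dropped: silently removing
  atoms would corrupt every downstream balance.
* Mean vs median per-sample aggregation are both provided (`stat=`);
  field practice varies and the choice is observable in the output.
* Reaction quotients never include the electron (not a solution species);
  explicit activities must be positive and default to 1.

## Limitations

Oxygen is the only terminal electron acceptor — nitrate, sulfate, iron
reduction, fermentation and disproportionation are out of scope, as are
activity-coefficient corrections, temperature/pressure corrections,
reactive-transport coupling and raw spectral processing (the package
starts from assigned formula tables). Concentrations of individual
compounds are generally unknown in FTICR data; analyses here treat
detection as presence and evaluate *carbon quality*, not quantity.
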