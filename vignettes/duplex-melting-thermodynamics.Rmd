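---
title: "Two-state melting thermodynamics of short DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state melting thermodynamics of short DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmelt)
```

## The model

A short non-self-complementary DNA duplex is assumed to melt in a single
bimolecular two-state equilibrium: strands are either fully duplexed or fully
dissociated, with no populated intermediates. With total strand concentration
$C_t$ (both strands summed, each at $C_t/2$ — this convention matters, see
below) and association constant $K(T) = \exp(-\Delta G^\circ(T)/RT)$, the
duplexed fraction $f$ solves

$$K C_t (1-f)^2 = 2f,$$

and the UV absorbance at 260 nm is a population-weighted mix of two linear
baselines,

$$A(T) = f(T)\,(b_{ds} + m_{ds}T) + (1-f(T))\,(b_{ss} + m_{ss}T),$$

the upper (single-strand) baseline lying above the lower one because melting
is hyperchromic. $\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$ with
no heat-capacity correction ($\Delta C_p = 0$), the usual approximation for
oligonucleotide work over the 0–95 °C window. All energies are in
kcal·mol⁻¹ (entropies cal·mol⁻¹·K⁻¹) with $R = 1.987$ cal·mol⁻¹·K⁻¹; the
"2.303" appearing in the field's log₁₀-based equations is carried internally
at full precision as $\ln 10$.

At the melting temperature, $f = 1/2$ and $K(T_m) = 4/C_t$, giving the
closed form

$$T_m = \frac{1000\,\Delta H^\circ}{\Delta S^\circ + R\ln(C_t/4)}.$$

**The $C_t$ convention is a classic factor-of-two trap.** Everywhere in this
package $C_t$ is the *total* single-strand concentration; the $C_t/4$ form
above is only correct under that convention. Self-complementary sequences
obey a different molecularity and are rejected explicitly rather than
silently mis-analysed.

## Parameter estimation

Two independent routes are implemented and then consolidated:

* `fit_two_state()` fits $(\Delta H^\circ, T_m)$ plus four baseline
  coefficients to one curve by Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`). The fit is parameterised in $(\Delta H^\circ, T_m)$
  rather than $(\Delta H^\circ, \Delta S^\circ)$, which decorrelates the
  parameters; $\Delta S^\circ$ is recovered from the closed form.
  Initialisation: $T_m$ from the smoothed-derivative locator,
  $\Delta H^\circ_0 = -80$ kcal·mol⁻¹, baselines from linear fits to the
  lowest and highest 15% of the temperature range. Convergence: relative SSE
  change below $10^{-10}$ or 500 iterations; non-convergence is reported via
  a flag, never silently, and never raised as an error so batch runs
  continue.
* `vant_hoff_regression()` regresses $T_m^{-1}$ on $\log_{10}(C_t/4)$ over a
  concentration series; the slope is $\ln 10 \cdot R/\Delta H^\circ$
  (negative for a melting duplex — a non-negative slope implies
  $\Delta H^\circ \ge 0$ and is flagged). On noiseless generator output this
  estimator is an exact algebraic inverse, which the tests assert to 1e-9.

`consolidate_parameters()` averages the per-curve fits (converged ones only),
then averages that with the van't Hoff estimate; $\Delta G^\circ_{37}$ is
recomputed from the averaged $\Delta H^\circ, \Delta S^\circ$ rather than
averaged directly (the two choices differ only in the third decimal here, but
recomputation keeps the triple self-consistent). Agreement of the two
$\Delta H^\circ$ estimates within 15% — a community rule of thumb,
configurable via `dh_agreement_tol` — is the operational indicator of
two-state melting.

### The derivative-based $T_m$ and its intrinsic offset

`tm_from_derivative()` locates the maximum of $dA/dT$ after a centered
5-point moving average (ties break to the lowest temperature; a boundary or
zero-prominence maximum is a no-transition error). For a *bimolecular*
transition the steepest point of $f(T)$ does not coincide with $T_m$: it sits
above it by roughly 1 K at typical 13-mer enthalpies (for
$\Delta H^\circ = -92$, $C_t = 10^{-5}$ M: steepest point 325.38 K vs
$T_m$ = 324.37 K, both computed analytically). This is physics, not error —
only for unimolecular transitions do the two coincide — so the derivative
estimate is used as an initial value and as the reported midpoint for long
duplexes, never as the thermodynamic $T_m$.

## The synthetic generator

`sim_config()` / `generate_melting_curve()` run the two-state model forward
and add i.i.d. Gaussian noise per point — the simplest model consistent with
photometric noise. Defaults, chosen once as typical of 260 nm melting
experiments on 13-mers:

| parameter | default | rationale |
|---|---|---|
| baselines $b_{ds}, m_{ds}, b_{ss}, m_{ss}$ | 0.60, 2·10⁻⁴/°C, 0.75, 3·10⁻⁴/°C | ~20% hyperchromicity, gently sloping |
| `noise_sd` | 0.002 AU | realistic photometric noise |
| T grid | 0–95 °C, 0.5 °C steps | matches typical heating-rate granularity |
| `Ct_list` | 2 µM–100 µM, 6 levels | ~1.7 decades, standard van't Hoff design |
| truth $-\Delta G^\circ_{37}$ (6-duplex study) | 12.5, 11.2, 11.2, 10.4, 9.15, 8.83 | the published 1 M Na⁺ stabilities of the X·Y variants |
| truth $\Delta H^\circ$ (6-duplex study) | −98 … −86 | fixture choices in the −85 to −105 range typical of 13-mers, ordered with stability |

The salt-series generator encodes the assumed polyelectrolyte structure:
$-\Delta G^\circ_{37}$ linear in $\log_{10}[M]$ with $\Delta H^\circ$ held
constant (the entropy absorbs the salt effect). Under that construction the
$\Delta G^\circ$-based and $T_m^{-1}$-based uptake estimators agree
identically, which the tests exploit as a consistency check.

What the generator does *not* emulate — and hence what passing recovery
tests do **not** demonstrate about real data: curved or drifting baselines,
correlated (drift-like) noise, evaporation at high temperature, partially
populated intermediates (non-two-state melting), and concentration errors
between nominally identical samples. Parameter recovery on synthetic data
bounds estimator error under the model's own assumptions, nothing more.

Seeding: every stochastic entry point takes or contains an integer seed and
records it in its output; identical configurations give identical output.
Problem sizes used in the shipped tests (6 curves × 191 points per series,
50-seed recovery studies, 100-draw property checks) were chosen so the whole
suite characterises the estimators well while running in seconds.

## Salt dependence and counterion uptake

`fit_salt_slope()` is unweighted OLS of stability on $\log_{10}[M]$ (no
weighting scheme is assumed); the intercept is the value extrapolated to
1 M. Slopes convert to uptake numbers via

$$\frac{\delta(-\Delta G^\circ)}{\delta \log [M]} = 2.303\,\alpha R T\,\Delta n,
\qquad
\frac{\delta(T_m^{-1})}{\delta \log [M]} = \frac{2.303\,\alpha R\,\Delta n}{\Delta H^\circ},$$

with $\alpha = 0.9$ for NaCl and $0.88$ for MgCl₂ (overridable), $T$
defaulting to 310.15 K because the free energies are extrapolated to 37 °C.
Mg²⁺ is treated with the identical linear-in-log formalism, with no
charge-2 correction beyond $\alpha$. Reported $\Delta n$ is rounded to one
decimal (the field's presentation convention) with full precision retained
in machine output. Note that with 5 salt levels the slope's ±2·SE interval
covers the truth at the $t_3$ rate (~86%), not the normal-approximation 95%.

## Nearest-neighbor model

The embedded tables are the published unified Watson–Crick set and internal
G·T wobble set (provenance strings ship with the table; 1 M NaCl reference
state). Steps are keyed `"XY/WZ"` (top 5'→3' over bottom 3'→5'), and each
step is registered under both written forms, so predictions are invariant
under swapping the strands. `nn_predict()` sums initiation (per terminal
pair type) plus all steps; duplexes containing I or D are rejected rather
than guessed at, since no parameters are published for them — I and D remain
representable in `validate_duplex()` for labelling and discrimination
analyses.

The trinucleotide-core decomposition attributes
`measured − (initiation + all steps not touching the central pair)` to the
two central steps. The convention "two central steps, no initiation share"
was chosen because it makes the decomposition exactly additive:
`nn_trinucleotide()` applied to the CGC/GTG wobble core returns
$-\Delta G^\circ_{37} = 1.06$, $-\Delta H^\circ = 8.5$,
$-\Delta S^\circ = 24.0$, and the identity
`core(nn_predict(duplex)) == nn_trinucleotide(center)` holds to 1e-10.
(Any printed $-\Delta S^\circ$ of 23.0 alongside the 1.06/8.5 pair is
internally inconsistent with $\Delta G^\circ = \Delta H^\circ - T\Delta
S^\circ$ at 310.15 K; the package keeps the self-consistent 24.0.) Because
all six X·Y study duplexes share identical flanks, the flank subtraction is
one constant, so measured cores preserve the duplex stability ordering —
a property the tests assert.

Positions are 1-based along the top strand in this R API (R's native
convention); the CLI's JSON output uses the same 1-based positions and says
so in its schema.

## Degenerate inputs and numerical choices

* `duplex_fraction()` uses the rationalised smaller quadratic root,
  $f = 2KC_t\,/\,(2KC_t + 2 + \sqrt{(2KC_t+2)^2 - 4(KC_t)^2})$, accurate in
  relative terms down to $f \sim 10^{-18}$ (no cancellation at small
  $KC_t$); $K = 0$ maps to $f = 0$ exactly.
* Flat or baseline-only curves raise explicit no-transition errors (range
  under 3× a robust noise estimate, or no interior derivative maximum with
  ≥10% prominence).
* Fewer than 20 temperature points, fewer than 3 distinct concentrations or
  salt levels, duplicate concentrations, and non-positive temperatures or
  concentrations are all hard errors with specific messages. A
  concentration series with fewer than 4 levels or under 1.5 decades of
  span fits but warns, since the van't Hoff design is then weak.

## Limitations

Heat-capacity effects, hairpin (unimolecular) transitions, three-state
models, Poisson–Boltzmann or counterion-condensation treatments of the salt
effect, mixed Na⁺/Mg²⁺ competition, and solvent dielectric modelling are out
of scope. The ion-uptake numbers inherit the assumptions of the
stoichiometric mass-action treatment of ion binding and are comparative
quantities, not absolute site counts.
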