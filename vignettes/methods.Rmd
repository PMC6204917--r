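---
title: "Models and methods for state-dependent sodium-channel block analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for state-dependent sodium-channel block analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navblock)
```

## Scope and data model

`navblock` analyses voltage-clamp pharmacology of voltage-gated sodium
(and potassium) channel block by small molecules such as cannabidiol. Its
exchange format is a per-sweep table of peak currents with protocol
metadata (holding and test potentials, prepulse duration, time since
compound addition, temperature, compound, concentration), together with
per-cell quality-control metrics. Everything downstream — pooled
concentration–response tables, gating curves, kinetic series — is built
from that table.

Units are fixed package-wide: mV for potentials, ms for trace time, s for
recovery/onset lags, µM for concentrations, pA for currents, pF for
capacitance. Fractions live in [0, 1]; percentages appear only at I/O
boundaries. Inward sodium currents are stored negative and all block
arithmetic works on magnitudes, so results are invariant to current sign
and overall scale.

## Parametric models

**Hill–Langmuir concentration–response.** Normalized inhibition is
$Y(C) = C^h/(IC_{50}^h + C^h)$. The evaluator uses the logistic-in-log
form $Y = 1/(1+\exp[h(\ln IC_{50} - \ln C)])$, which is algebraically
identical, exactly 0.5 at $C = IC_{50}$, and numerically stable for steep
slopes. Slopes near 3, as observed for CBD on Nav channels, make the
fitted $IC_{50}$ very sensitive to concentration errors; the steep slope
is treated purely as a property of the concentration–response curve, not
as a multi-site binding mechanism.

**Boltzmann gating curves.** Activation (normalized conductance) and
steady-state fast-inactivation availability (normalized test-pulse
current) are two-state Boltzmann functions of membrane potential with
midpoint $V_{1/2}$ and slope factor $k > 0$. A `polarity` flag fixes the
sign convention — activation rises with depolarization, availability
falls — so that fitted slope factors are directly comparable between the
two conventions and to published values. With shared parameters the two
polarities are exact mirror images: $act(V) + avail(V) = 1$.

**Exponential kinetics.** Recovery from inactivation uses the
biexponential
$Y(t) = Plateau + Span_{fast}e^{-K_{fast}t} + Span_{slow}e^{-K_{slow}t}$
with the spans partitioning the total amplitude by `percent_fast`;
components are relabelled after fitting so $K_{fast} \ge K_{slow}$, which
removes the label-swap ambiguity. Block onset uses the single exponential
$Y(t) = (Y_0-Plateau)e^{-Kt}+Plateau$ with observed equilibration time
constant $\tau_{obs} = 1/K$.

**State-dependent block.** Apparent potency varies with holding potential
because the compound binds resting and inactivated channels with
different affinities. With resting fraction $f(V)$ given by an
availability Boltzmann, the model is the two-receptor-state equilibrium
$$\frac{1}{K_{app}(V)} = \frac{f(V)}{K_r} + \frac{1-f(V)}{K_i},$$
which bounds the apparent $IC_{50}$ between $K_r$ and $K_i$ and makes it
monotone in the inactivated fraction. The model accepts any availability
Boltzmann as input rather than hard-coding a channel-specific one,
because different channel preparations have different inactivation
midpoints. No equation for this model is uniquely standard in print;
this harmonic form is the classical modulated-receptor equilibrium and is
linear in inverse affinities, which is also how it is fitted (below).

## Fitting

All fitters use Levenberg–Marquardt least squares with deterministic,
data-derived initial values — no random starts — so identical inputs give
bit-identical results:

* $IC_{50}$ initialized by log-interpolating the concentration bracketing
  50% inhibition; slope starts at 1 (or is held fixed).
* Boltzmann midpoint from the half-maximum crossing; slope from the
  10–90% transition width divided by $\ln 81$.
* Exponential rates from a log-linear regression on the tail of
  $|y - plateau|$; the biexponential starts the fast rate an order of
  magnitude above the slow one with the fast fraction at 50%.

Strictly positive parameters ($IC_{50}$, $h$, $k$, rates, affinities) are
optimized on the log scale, which keeps the optimizer unconstrained and
avoids boundary sticking; the fast-component fraction uses a logit scale.
If Levenberg–Marquardt fails, a BFGS pass on the same objective is tried;
if that also fails the result is returned `converged = FALSE` with a
diagnostic, never silent garbage. Degenerate inputs (flat curves, no
concentration dependence, non-decaying "onset" signals) are detected
before or after fitting and flagged the same way. The loss is unweighted
least squares on pooled normalized means, matching how plate data are
conventionally fitted; pooled fits carry no standard errors, and a seeded
bootstrap over cells is provided instead.

Boltzmann fits include a free amplitude by default (`free_scale = TRUE`).
Max-normalized curves from protocols whose most extreme prepulse does not
fully saturate the channel are then recovered without truncation bias;
on exactly normalized input the amplitude fits to 1 and the result is
unchanged.

The state model is fitted in inverse-$IC_{50}$ space, where it is linear
in $(1/K_r, 1/K_i)$: an unconstrained linear solve provides the start and
a log-parameterized polish guarantees positive affinities. On the four
published apparent potencies between −100 and −70 mV this yields a
resting/inactivated affinity ratio of ≈7.4, consistent with the reported
order-of-magnitude (~10-fold) preference for inactivated channels; the
exact ratio depends on which availability curve and equilibration
correction underlie the published fit, so tests assert the order of
magnitude, not a precise value.

The temperature dependence of potency is summarized by an ordinary
least-squares line of $IC_{50}$ against temperature (closed form, no
iteration). Temperature-dependent rate theory (Arrhenius/Eyring) is out
of scope.

## Plate pipeline

Automated patch-clamp plates are processed in the standard order:

1. **QC filter** — exclude cells with membrane resistance ≤ 500 MΩ,
   series resistance ≥ 10 MΩ, or baseline peak magnitude ≤ 500 pA; every
   exclusion is labelled with all filters failed.
2. **Baseline** — mean magnitude of the last 5 baseline-epoch sweeps.
   (Published protocols fix the baseline timing, not the aggregation; the
   trailing-5 mean is stated here for reproducibility.)
3. **Vehicle correction** — the pooled fractional current remaining on
   vehicle wells, linearly interpolated at each drug cell's measurement
   time, multiplies the baseline. The correction's existence is standard;
   its multiplicative, time-matched form is this package's documented
   choice.
4. **Full-block reference** — the residual current in a saturating
   blocker (e.g. 300 nM TTX) is the zero of the inhibition scale, so
   leak current does not masquerade as unblocked channels.
5. **Inhibition** — $Y = (|I_{base}|d - |I_{drug}|)/(|I_{base}|d -
   |I_{full}|)$, clipped to [0, 1] (clipping can be disabled to study the
   unclipped estimator; with near-zero true inhibition the clip
   introduces a small positive bias of order $\sigma/\sqrt{2\pi}$).
6. **Pooling** — one concentration per cell; per-concentration means and
   per-cell provenance are both retained. Hill fits use the means by
   default (`use_cells = TRUE` fits all points instead); published plate
   analyses pool "data at each concentration", which is ambiguous between
   the two, and both are supported.

The conductance transform for I/V families is $G = I/(V - E_{Na})$ with
points at the reversal potential dropped with a warning. Persistent
current is the mean over the final 10% of a ≥100-ms step (the window is
not standardized in print; final-10% is common practice and is stated
explicitly), with the peak taken in the first 10 ms. Leak subtraction and
series-resistance compensation are assumed already applied during
acquisition, and liquid-junction potentials are not corrected.

## Synthetic data

The study this package is designed around deposited no raw recordings,
so a seeded generator produces every input the pipeline consumes, with
defaults equal to the published figure-legend parameter values:

* Hill: $IC_{50}$ = 2.5 µM, $h$ = 2.0 (heterologously expressed
  Nav1.1 at an inactivated-state holding potential).
* Gating: activation (−41.9, 3.6) → (−40.3, 7.2) mV; availability
  (−69.7, 5.0) → (−77.8, 5.8) mV vehicle → drug.
* Recovery (10-s prepulse): τ = 0.0715/0.696 s vehicle, 0.272/8.72 s
  drug; the fast-component percentage is published only graphically, so
  the default of 50% is an assumption and labelled as such.
* Block-onset τ map over 20/28/33 °C and 6.3–50 µM, reproducing both the
  temperature dependence and the saturation of $\tau_{obs}$ at a minimum
  at high concentration.
* State model: $K_r$ = 12 µM, $K_i$ = 1.2 µM with the (−69.7, 5.0)
  availability curve, i.e. a 10-fold inactivated-state preference.

Noise is additive Gaussian on normalized currents (σ = 0.03) plus a
multiplicative lognormal cell-size factor (σ_log = 0.2) on raw
amplitudes; these reproduce standard-error magnitudes of roughly 10% at
the published cell counts. Rundown is monoexponential at 2%/min,
motivating the vehicle correction. A leak pedestal (25 pA) is present in
every sweep and is all that remains in the full-block epoch.

Problem sizes are scaled for fast, deterministic testing: plates default
to 6 cells per concentration plus 8 vehicle wells, a 240-s drug epoch
sampled at 1 Hz with a 20-s equilibration time constant (≈12 time
constants, so the end-of-epoch current is at equilibrium to ~10⁻⁵), and
the pulse-train protocol runs the published 180 pulses at 1 Hz per
holding potential with a 30-s time constant. Equilibrium block in the
pulse-train analysis is read from the plateau of a monoexponential fit
to each train (guarded against extrapolation on noise-dominated flat
trains, where the tail mean is used instead); this removes the ~0.3%
under-equilibration that the 180th pulse alone would carry.

What the generator does **not** emulate: within-sweep kinetics of drug
binding, capacitive/leak artifacts, series-resistance error, or cell
heterogeneity in gating parameters. Passing round-trip tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every pathology of real recordings.

## Neuron simulation

The excitability model is a single-compartment conductance-based neuron
with the classic $m^3h$ sodium, $n^4$ potassium and leak structure,
modified so the gating steady states are Boltzmann functions taking the
experimentally fitted midpoints and slopes directly (activation −41.9/3.6
mV; inactivation −69.7/5.0 mV). Conductance densities and reversals
default to a regular-spiking cortical pyramidal parameter set
($g_{Na}$ = 56, $g_K$ = 6, $g_{leak}$ = 0.0205 mS/cm²; $E_{Na}$ = 50,
$E_K$ = −90, $E_{leak}$ = −70.3 mV; $C_m$ = 1 µF/cm²). Because no rate
equations accompany the published steady-state measurements, gating time
constants use bell-shaped voltage dependences
$\tau(V) = base + amp/\cosh[(V - V_{mid})/V_{scale}]$ with defaults in
the cortical-pyramidal range (τ_m ≲ 0.15 ms, τ_h ≤ ~7 ms, τ_n ≤ ~5 ms).
No adaptation (M-type) conductance is included by default, consistent
with sustained firing during 100-ms steps.

The drug condition is applied as fractional conductance block plus an
inactivation-midpoint shift; the published condition corresponds to
`apply_drug_condition(model, 0.5, 0.5, -8.1)` — both conductances halved
and inactivation hyperpolarized by 8.1 mV. The same 50% block is applied
to the potassium conductance by default (the published description
states 50% for both), but the fraction is configurable since the
potassium-channel potency differs from the sodium-channel one.

Integration is deterministic fixed-step classical Runge–Kutta at
dt = 0.01 ms (dt ≤ 0.025 ms enforced); halving dt moves spike times by
well under 0.1 ms, and the trace matches an adaptive LSODA reference
within 0.5 mV RMS in the test suite. The stimulus default mirrors the
published protocol: increasing current steps of 100 ms separated by
50-ms recovery gaps. Spikes are upward 0-mV crossings separated by at
least 1 ms; the per-spike voltage threshold is the potential at which
dV/dt first exceeds 20 mV/ms on the upstroke. The published claim that
the drug "reduced the threshold" of the first action potential is
ambiguous between voltage threshold and rheobase, so the simulator
reports both the per-spike voltage threshold and per-step spike counts
and asserts neither direction in tests.

## Numerical and design notes

* The printed form of the gating Boltzmann rises with depolarization for
  $k > 0$, yet availability curves fall; the polarity flag resolves this
  while keeping $k > 0$ comparable across conventions.
* The printed conductance transform omits parentheses; it is implemented
  as $I/(V - E_{Na})$, the only dimensionally sensible reading.
* Fit determinism: no random initialization anywhere; the only seeded
  randomness is in the synthetic generator and the optional bootstrap,
  both of which require an explicit seed.
* Steady-state fast-inactivation prepulse duration appears variously as
  100 ms and 500 ms in published protocols; it is protocol metadata
  here, never hard-coded.
* Known limitations: no global multi-curve fitting, no heteroscedastic
  error models, no Bayesian inference, no multi-compartment or stochastic
  neuron models, and no readers for proprietary acquisition formats.

## Column dictionary

Sweep tables use unit-suffixed columns, in this order: `cell_id`,
`well`, `protocol`, `sweep`, `time_s`, `holding_mV`, `test_mV`,
`prepulse_ms`, `peak_pA`, `steady_pA`, `temp_C`, `compound`, `conc_uM`,
`epoch` (`baseline`, `drug`, or `full_block`). QC tables use `cell_id`,
`rm_MOhm`, `rs_MOhm`, `cap_pF`, `baseline_peak_pA`. Unknown columns are
retained with a warning, never silently dropped.
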