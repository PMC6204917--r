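# navblock

Analysis tools for voltage-clamp pharmacology of voltage-gated sodium
(Nav) and potassium channel block — built for the kind of study that asks
how a compound such as cannabidiol inhibits Nav currents: how potent it
is, whether it prefers resting or inactivated channels, how fast block
develops, how gating shifts, and what all of that does to neuronal
excitability.

The package covers five connected pieces:

1. **Curve models** — Hill–Langmuir concentration–response
   `Y = C^h/(IC50^h + C^h)`; Boltzmann gating curves
   `1/(1 + exp[±(V − V½)/k])` for activation and steady-state
   fast-inactivation availability; mono- and biexponential kinetics for
   block onset and recovery from inactivation; and the
   resting/inactivated two-state block model
   `1/Kapp(V) = f_rest(V)/K_r + (1 − f_rest(V))/K_i`,
   which predicts how apparent IC50 falls as holding potentials
   depolarize and channels inactivate.
2. **Fitting** — deterministic nonlinear least squares for every model
   (log-scale positivity, data-derived initial values, no random starts),
   with degenerate inputs flagged rather than silently fitted.
3. **Plate pipeline** — automated patch-clamp QC filters (Rm > 500 MΩ,
   Rs < 10 MΩ, |I| > 500 pA), vehicle-rundown correction, full-block
   referencing, and pooling into concentration–response tables.
4. **Neuron simulation** — a modified Hodgkin–Huxley cortical-neuron
   model whose gating steady states take fitted Boltzmann parameters
   directly, with a drug condition applied as conductance block plus an
   inactivation-midpoint shift.
5. **Synthetic data** — a fully seeded generator for plates, gating
   families, recovery series, onset time courses, and pulse-train
   state-dependence runs, used throughout the tests for round-trip
   parameter recovery.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

Fit the state-dependent block model to apparent IC50s measured at four
holding potentials, using the availability curve fitted from the same
cells:

```r
library(navblock)

avail <- boltzmann_fit(-69.7, 5.0, "availability")
fr <- fit_state_model(holding_mV = c(-100, -90, -80, -70),
                      ic50_uM    = c(12.7, 10.3, 6.7, 2.9),
                      availability = avail)
fr
#> Converged fit (n = 4, RSS = 7.668e-05)
#> State-dependent block model: Kd(rest) = 11.87 uM, Kd(inact) = 1.603 uM (7.41-fold)
#>   availability: V1/2 = -69.7 mV, k = 5 mV
```

The compound binds inactivated channels roughly an order of magnitude
more tightly than resting ones (Kd 1.6 vs 11.9 µM), which is why its
apparent potency climbs steeply as the holding potential depolarizes
past the inactivation midpoint.

A full synthetic round trip — generate a plate, QC it, correct for
vehicle rundown, pool, and fit:

```r
cfg <- synth_config(seed = 7)          # true IC50 = 2.5 uM, slope = 2.0
res <- fit_hill(analyze_plate(gen_plate(cfg)))
res
#> Converged fit (n = 7, RSS = 0.0003855)
#> Hill-Langmuir fit: IC50 = 2.517 uM, h = 2.122
```

With the default measurement noise (σ = 0.03 on normalized currents,
6 cells per concentration) the pipeline recovers the generating IC50 to
within a few percent.

A command-line wrapper over the same functions lives at
`inst/cli/navblock.R`:

```sh
Rscript inst/cli/navblock.R gen-synth --seed 7 --out out/
Rscript inst/cli/navblock.R report --seed 7 --out out/
```

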