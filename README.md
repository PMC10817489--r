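# mycosorb

Quantitative analysis of fungal metallotolerance and heavy-metal
biosorption, for environmental microbiologists screening melanized
("black") fungi as biosorbents of toxic oxyanions such as As(V) and
Cr(VI).

The package implements the two computations such a study rests on:

1. **Dose-response on plates.** The tolerance index (TI) — colony growth
   on metal-amended agar relative to unamended controls — is modelled as a
   two-parameter Hill logistic in concentration `C`:

   `TI(C) = 1 / (1 + (C / IC50)^h)`,

   fitted to per-replicate TI points by multistart bounded least squares,
   with case-resampling bootstrap CIs, an `extrapolated` flag when the
   IC50 estimate exceeds the tested range, and a no-growth sentinel for
   strains that never grew.

2. **Batch biosorption kinetics.** From the liquid-phase mass balance
   `q_t = V (C0 - Ct) / Ma`, equilibrium loading is modelled with the
   Langmuir (`q_e = q_max K_L Ce / (1 + K_L Ce)`) or Freundlich
   (`q_e = K_F Ce^(1/n)`) isotherm, and the depletion of metal from
   solution follows the isotherm-coupled ODE

   `dCt/dt = -k_i (Ma/V) [ q_e(Ct) - (V/Ma)(C0 - Ct) ]_+^i`,  `i = 1, 2`,

   integrated numerically (lsoda, rtol 1e-8) and fitted over
   `(k_i, isotherm parameters)` by seeded multistart Levenberg-Marquardt
   in log10 space, with SSE-ranked selection across the four
   order x isotherm combinations, plus the classical linearised
   pseudo-second-order fit, half-saturation (`1/K_L`) and
   melanin-contribution summaries.

A synthetic-data module generates both input kinds (seeded, reproducible)
so the full simulate -> fit -> select pipeline is testable by parameter
recovery without any external data.

## Worked example

```r
library(mycosorb)

# --- dose-response: simulate a 5-concentration As(V) plate assay and refit
d <- simulate_tolerance(true_ic50 = 10, true_h = 2, seed = 1)
fit_hill(d, n_boot = 500, seed = 1)
#> <hill_fit> sim / AsV / day 30
#>   IC50 = 9.986 (9.56-10.3), h = 2.08, r2 = 0.977, n = 30
# 30 replicate TI points; the estimate sits inside the tested 2.5-12.5 g/L
# range, so no extrapolation flag

# --- kinetics: a Cr(VI) depletion experiment at a published parameter set
m <- kinetic_model(2, 1.32e-6, langmuir(q_max = 39.81, K_L = 0.1124))
sim <- simulate_timecourse(m, C0 = 25, V = 0.030, Ma = 0.050,
                           rel_noise_sd = 0, seed = 1)
fit_kinetics(sim, order = 2, isotherm = "langmuir", n_starts = 4, seed = 1)
#> <kinetic_fit> sim: order 2 + langmuir
#>   k_2 = 1.32e-06, q_max = 39.81 mg/g, K_L = 0.1124 L/mg
#>   SSE = 7.1e-27, r2 = 1.0000, n = 21  [weakly identifiable]
# noise-free closed loop: all three parameters come back exactly. The
# weak-identifiability flag is doing its job even here: over a 30-day
# window this system stays below saturation, so on *noisy* data q_max
# spreads widely along a flat likelihood ridge (see the methods vignette)

half_saturation(0.1124)                     # 8.8968 mg/L
melanin_contribution(0.125, 544.84, 95.26)  # 71.49381 % of cell capacity
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study-shaped analysis end to end on synthetic data, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | generates plate tables and triplicate Cr(VI) time courses |
| `02_tolerance_fits.R` | Hill/IC50 fit table with bootstrap CIs per strain |
| `03_sorption_metrics.R` | removal efficiencies, capacities, half-saturation, melanin share |
| `04_kinetic_model_selection.R` | ranked order x isotherm fits per experiment |
| `05_parameter_recovery.R` | 20-seed simulate -> refit recovery summaries |

Run them in order from the repository root with `Rscript`.

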