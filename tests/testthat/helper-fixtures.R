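# Shared fixtures: the three fitted parameter sets from the study's
# second-order + Langmuir Cr(VI) biosorption experiments, and the standard
# batch design (25 mg/L initial Cr(VI), 30 mL, 50 mg biomass dry matter).

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

study_params <- function() {
  list(
    r_similis = list(k = 1.32e-6, q_max = 39.81, K_L = 0.1124),
    e_mesophila = list(k = 1.39e-7, q_max = 95.26, K_L = 0.1964),
    melanin = list(k = 1.67e-6, q_max = 544.84, K_L = 0.0075)
  )
}

study_model <- function(which = "r_similis") {
  p <- study_params()[[which]]
  kinetic_model(2, p$k, langmuir(p$q_max, p$K_L))
}

batch_design <- function() list(C0 = 25, V = 0.030, Ma = 0.050)

# Build a noise-free tolerance dataset straight from the Hill curve.
hill_dataset <- function(ic50, h, conc = c(2.5, 5, 7.5, 10, 12.5),
                         n_rep = 6, control = 50) {
  cc <- rep(conc, each = n_rep)
  tolerance_dataset("fix", "AsV", 30, cc,
                    control * hill_ti(cc, ic50, h),
                    rep(control, n_rep))
}
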