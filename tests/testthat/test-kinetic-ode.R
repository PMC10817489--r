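# The isotherm-coupled kinetic ODE: right-hand side, integration,
# equilibrium fixed point, least-squares fitting and model selection.

test_that("sorption rate matches the hand-computed driving-force form", {
  m <- study_model("r_similis")
  d <- batch_design()
  # t = 0 state: q_t = 0, so the gap is the full equilibrium loading at C0
  qe0 <- 39.81 * 0.1124 * 25 / (1 + 0.1124 * 25)
  expect_equal(sorption_rhs(25, m, d$C0, d$Ma, d$V),
               -1.32e-6 * (0.050 / 0.030) * qe0^2, tolerance = 1e-12)
  expect_equal(sorption_rhs(25, m, d$C0, d$Ma, d$V), -1.8966e-3,
               tolerance = 1e-4)
  # equilibrium is the fixed point; no desorption below it
  ceq <- equilibrium_concentration(m, d$C0, d$Ma, d$V)
  expect_equal(sorption_rhs(ceq, m, d$C0, d$Ma, d$V), 0, tolerance = 1e-12)
  expect_equal(sorption_rhs(ceq * 0.5, m, d$C0, d$Ma, d$V), 0)
  expect_equal(sorption_rhs(25, m, d$C0, 0, d$V), 0) # no sorbent
  expect_error(sorption_rhs(26, m, d$C0, d$Ma, d$V), class = "domain_error")
})

test_that("integrated trajectory is monotone, conservative, and reaches equilibrium", {
  d <- batch_design()
  # faster variant so the 30-day window actually reaches the fixed point;
  # first order approaches equilibrium exponentially (second order only
  # algebraically), so the long-horizon consistency check uses i = 1
  m <- kinetic_model(1, 1e-3, langmuir(39.81, 0.1124))
  times <- seq(0, 43200, by = 1440)
  tc <- integrate_timecourse(m, d$C0, d$Ma, d$V, times)
  expect_equal(tc$ct[1], d$C0)
  expect_true(all(diff(tc$ct) <= 0))
  ceq <- equilibrium_concentration(m, d$C0, d$Ma, d$V)
  expect_true(all(tc$ct >= ceq - 1e-9))
  expect_lt(abs(tc$ct[nrow(tc)] - ceq), 1e-6)
  # mass balance: reconstructed loading closes the budget at every time
  qt <- specific_uptake(d$C0, tc$ct, d$V, d$Ma)
  expect_equal(d$Ma * qt + d$V * tc$ct, rep(d$V * d$C0, length(times)),
               tolerance = 1e-8)
  expect_true(all(diff(qt) >= 0))
})

test_that("k -> 0 and Ma -> 0 guards give a constant-C0 trajectory", {
  d <- batch_design()
  m <- kinetic_model(2, 1e-30, langmuir(39.81, 0.1124))
  tc <- integrate_timecourse(m, d$C0, d$Ma, d$V, c(0, 1e4, 4e4))
  expect_equal(tc$ct, rep(d$C0, 3), tolerance = 1e-9)
  m2 <- study_model("r_similis")
  tc2 <- integrate_timecourse(m2, d$C0, 0, d$V, c(0, 1e4, 4e4))
  expect_identical(tc2$ct, rep(d$C0, 3))
  expect_error(integrate_timecourse(m2, d$C0, d$Ma, d$V, c(10, 20)),
               class = "precondition_error")
})

test_that("adaptive integrator agrees with a fixed-step Euler reference", {
  d <- batch_design()
  times <- seq(0, 3 * 1440, by = 360) # 3-day horizon
  m <- study_model("r_similis")
  ref <- euler_timecourse(m, d$C0, d$Ma, d$V, times, dt = 0.1)
  tc <- integrate_timecourse(m, d$C0, d$Ma, d$V, times)
  expect_lt(max(abs(tc$ct - ref)), 1e-4)
})

test_that("equilibrium concentration solves the isotherm/mass-balance crossing", {
  d <- batch_design()
  for (nm in names(study_params())) {
    m <- study_model(nm)
    ceq <- equilibrium_concentration(m, d$C0, d$Ma, d$V)
    expect_gte(ceq, 0); expect_lte(ceq, d$C0)
    lhs <- isotherm_qe(m$isotherm, ceq)
    rhs <- (d$V / d$Ma) * (d$C0 - ceq)
    expect_lt(abs(lhs - rhs), 1e-9)
  }
  mf <- kinetic_model(1, 1e-4, freundlich(4.5, 1.3))
  ceqf <- equilibrium_concentration(mf, d$C0, d$Ma, d$V)
  expect_lt(abs(isotherm_qe(mf$isotherm, ceqf) - (d$V / d$Ma) * (d$C0 - ceqf)),
            1e-8)
  expect_equal(equilibrium_concentration(mf, d$C0, 0, d$V), d$C0)
  # sorbent excess drives the liquid phase toward exhaustion
  expect_lt(equilibrium_concentration(study_model("melanin"), d$C0, 50, d$V),
            0.01)
})

test_that("dilute-limit Langmuir and the matched linear Freundlich coincide", {
  d <- batch_design()
  C0 <- 0.01 / 0.1124 # far below half-saturation
  mL <- kinetic_model(2, 1.32e-4, langmuir(39.81, 0.1124))
  mF <- kinetic_model(2, 1.32e-4, freundlich(39.81 * 0.1124, 1))
  times <- seq(0, 43200, length.out = 25)
  tL <- integrate_timecourse(mL, C0, d$Ma, d$V, times)
  tF <- integrate_timecourse(mF, C0, d$Ma, d$V, times)
  expect_lt(max(abs(tL$ct - tF$ct)) / C0, 0.01)
})

test_that("noise-free kinetic fit recovers all three parameters", {
  d <- batch_design()
  m <- study_model("r_similis")
  sim <- simulate_timecourse(m, rel_noise_sd = 0, seed = 1)
  fit <- fit_kinetics(sim, order = 2, isotherm = "langmuir",
                      n_starts = 4, seed = 1)
  expect_lt(abs(fit$model$k - m$k) / m$k, 1e-3)
  expect_lt(abs(fit$model$isotherm$q_max - 39.81) / 39.81, 1e-3)
  expect_lt(abs(fit$model$isotherm$K_L - 0.1124) / 0.1124, 1e-3)
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-12)
})

test_that("fitting the wrong kinetic order costs squared error", {
  m <- study_model("r_similis")
  sim <- simulate_timecourse(m, seed = 5)
  f2 <- fit_kinetics(sim, order = 2, isotherm = "langmuir", n_starts = 4, seed = 5)
  f1 <- fit_kinetics(sim, order = 1, isotherm = "langmuir", n_starts = 4, seed = 5)
  expect_gt(f1$sse, f2$sse)
})

test_that("no-signal and too-short inputs are refused or flagged", {
  # constant concentration: rate constant collapses to its lower bound
  b <- batch_sorption("flat", "CrVI", 25, 0.03, 0.05,
                      time = rep(c(2880, 7200, 10080, 20160, 43200), each = 3),
                      ct = rep(25, 15), replicate = rep(1:3, 5))
  expect_warning(
    fit <- fit_kinetics(b, order = 2, isotherm = "langmuir", n_starts = 2, seed = 1),
    class = "no_signal_fit"
  )
  expect_lt(fit$sse, 1e-6)
  # all measurements censored carry no usable signal
  b2 <- batch_sorption("cens", "CrVI", 25, 0.03, 0.05,
                       time = rep(c(2880, 7200, 10080, 20160), each = 3),
                       ct = 0.01, censored = TRUE, detection_limit = 0.01)
  expect_error(fit_kinetics(b2, order = 2, isotherm = "langmuir"),
               class = "no_signal_error")
  b3 <- batch_sorption("short", "CrVI", 25, 0.03, 0.05,
                       time = rep(c(2880, 7200, 14400), each = 3),
                       ct = rep(c(20, 15, 12), each = 3))
  expect_error(fit_kinetics(b3, order = 2, isotherm = "langmuir"),
               class = "precondition_error")
})

test_that("weak-identifiability warning fires far below saturation", {
  # melanin-extract regime: observed loading is a small fraction of q_max
  m <- study_model("melanin")
  sim <- simulate_timecourse(m, rel_noise_sd = 0, seed = 1)
  fit <- fit_kinetics(sim, order = 2, isotherm = "langmuir",
                      n_starts = 2, seed = 1)
  expect_true(fit$identifiability_warning)
})

test_that("model selection ranks the generating combination first when identifiable", {
  # noise-free data separate the families cleanly (the generating SSE is at
  # machine zero while the best wrong-family fit keeps a model discrepancy)
  m <- study_model("r_similis")
  sim <- simulate_timecourse(m, rel_noise_sd = 0, seed = 3)
  ms <- suppressWarnings(model_select(sim, n_starts = 4, seed = 3))
  expect_equal(ms$table$order[1], 2L)
  expect_equal(ms$table$isotherm[1], "langmuir")
  expect_equal(nrow(ms$table), 4L)
  expect_true(all(diff(ms$table$sse[!ms$table$failed]) >= 0))
  expect_lt(ms$table$sse[1], 1e-12)
  expect_gt(ms$table$sse[2], 1e-6)
  mf <- kinetic_model(1, 1e-5, freundlich(4.5, 1.3))
  simf <- simulate_timecourse(mf, rel_noise_sd = 0, seed = 3)
  msf <- suppressWarnings(model_select(simf, n_starts = 4, seed = 3))
  expect_equal(msf$table$order[1], 1L)
  expect_equal(msf$table$isotherm[1], "freundlich")
})

test_that("fits are bit-reproducible under a fixed seed", {
  m <- study_model("r_similis")
  sim1 <- simulate_timecourse(m, seed = 9)
  sim2 <- simulate_timecourse(m, seed = 9)
  expect_identical(sim1$data, sim2$data)
  f1 <- fit_kinetics(sim1, order = 2, isotherm = "langmuir", n_starts = 4, seed = 9)
  f2 <- fit_kinetics(sim2, order = 2, isotherm = "langmuir", n_starts = 4, seed = 9)
  expect_identical(f1$model$k, f2$model$k)
  expect_identical(f1$model$isotherm$q_max, f2$model$isotherm$q_max)
  expect_identical(f1$sse, f2$sse)
})
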