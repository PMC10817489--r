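# Closed-form sorption quantities, isotherms, and the linearised
# pseudo-second-order fit.

test_that("specific uptake reproduces the batch mass balance", {
  expect_equal(specific_uptake(20, 20, 0.030, 0.050), 0)
  # complete removal (residual below detection) and the dead-cell assay
  expect_equal(specific_uptake(20, 0, 0.030, 0.05357), 11.20, tolerance = 5e-4)
  expect_equal(specific_uptake(20, 5.16, 0.030, 0.04640), 9.59, tolerance = 1e-3)
  expect_error(specific_uptake(20, 5, 0.030, 0), class = "division_domain_error")
  expect_warning(specific_uptake(20, 21, 0.030, 0.05), class = "negative_uptake")
})

test_that("removal efficiency matches the final-concentration ratios", {
  expect_equal(removal_efficiency(20, 3.48), 82.6, tolerance = 1e-6)
  expect_equal(removal_efficiency(20, 1.16), 94.2, tolerance = 1e-6)
  expect_equal(removal_efficiency(20, 20), 0)
  expect_warning(removal_efficiency(20, 25), class = "negative_uptake")
})

test_that("uptake and efficiency satisfy the exact mass-balance identity", {
  set.seed(31)
  for (i in 1:25) {
    C0 <- runif(1, 5, 200); Ct <- runif(1, 0, C0)
    V <- runif(1, 0.01, 0.5); Ma <- runif(1, 0.01, 1)
    q <- specific_uptake(C0, Ct, V, Ma)
    eff <- removal_efficiency(C0, Ct)
    expect_equal(q * Ma, V * C0 * eff / 100)
  }
})

test_that("Langmuir isotherm: origin, half-saturation, saturation, concavity", {
  m <- langmuir(q_max = 95.26, K_L = 0.1964)
  expect_equal(langmuir_qe(0, m), 0)
  expect_equal(langmuir_qe(1 / m$K_L, m), m$q_max / 2)
  expect_equal(langmuir_qe(25, m), 79.14, tolerance = 1e-4)
  ce <- seq(0, 500, length.out = 400)
  qe <- langmuir_qe(ce, m)
  expect_true(all(qe < m$q_max))
  expect_true(all(diff(qe) > 0))
  expect_true(all(diff(diff(qe)) < 0)) # concave
  expect_equal(langmuir_qe(1e6 / m$K_L, m), m$q_max, tolerance = 1e-4)
  expect_error(langmuir_qe(5, freundlich(3, 2)), class = "type_error")
  expect_error(langmuir(-1, 0.1), class = "parameter_domain_error")
})

test_that("Freundlich isotherm: power law with stored-n convention", {
  m <- freundlich(K_F = 3, n = 2)
  expect_equal(freundlich_qe(1, m), 3)
  expect_equal(freundlich_qe(4, m), 6.0)
  lin <- freundlich(K_F = 2.5, n = 1)
  ce <- c(0.5, 1, 7, 30)
  expect_equal(freundlich_qe(ce, lin), 2.5 * ce)
  # n > 1 is concave and unbounded
  qe <- freundlich_qe(seq(0.1, 100, length.out = 300), m)
  expect_true(all(diff(qe) > 0))
  expect_true(all(diff(diff(qe)) < 0))
  expect_error(freundlich_qe(5, langmuir(10, 0.1)), class = "type_error")
})

test_that("half-saturation is the reciprocal affinity", {
  expect_equal(round(half_saturation(0.1124), 2), 8.90)
  expect_equal(round(half_saturation(0.1964), 2), 5.09)
  expect_equal(half_saturation(1), 1)
  expect_error(half_saturation(0), class = "domain_error")
})

test_that("melanin mass fraction scales its capacity share of whole cells", {
  expect_equal(melanin_contribution(0.125, 544.84, 95.26), 71.5,
               tolerance = 1e-4)
  expect_equal(melanin_contribution(0, 544.84, 95.26), 0)
  expect_equal(melanin_contribution(1, 12.3, 12.3), 100)
  expect_error(melanin_contribution(1.2, 10, 10), class = "domain_error")
})

test_that("linearised pseudo-second-order fit is exact on closed-form data", {
  t <- seq(5, 60, by = 5)
  fit <- pso_linear_fit(t, pso_qt(t, q_e = 20.80, k_2 = 3.39e-2))
  expect_lt(abs(fit$q_e - 20.80) / 20.80, 1e-9)
  expect_lt(abs(fit$k_2 - 3.39e-2) / 3.39e-2, 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("pseudo-second-order fit rejects degenerate inputs", {
  t <- seq(10, 60, by = 10)
  # constant uptake: zero intercept boundary is non-physical
  expect_error(pso_linear_fit(t, rep(5, length(t))),
               class = "nonphysical_fit_error")
  expect_error(pso_linear_fit(c(10, 20), c(1, 2)), class = "precondition_error")
  # t = 0 rows are dropped, not divided by
  fit <- pso_linear_fit(c(0, t), c(0, pso_qt(t, 10, 1e-2)))
  expect_lt(abs(fit$q_e - 10) / 10, 1e-9)
})

test_that("batch_sorption validates and stores censoring as a flag", {
  b <- batch_sorption("x", "CrVI", C0 = 25, V = 0.03, Ma = 0.05,
                      time = c(10, 10, 20, 20), ct = c(20, 21, 0.01, 15),
                      replicate = c(1, 2, 1, 2),
                      censored = c(FALSE, FALSE, TRUE, FALSE),
                      detection_limit = 0.01)
  expect_s3_class(b, "batch_sorption")
  expect_equal(sum(b$data$censored), 1L)
  expect_equal(b$data$ct[b$data$censored], 0.01) # bound, not an imputed 0
  expect_error(batch_sorption("x", "CrVI", 25, 0.03, 0.05, 10, 40),
               class = "validation_error")
  expect_error(batch_sorption("x", "CrVI", -1, 0.03, 0.05, 10, 5),
               class = "validation_error")
  expect_error(batch_sorption("x", "Pb", 25, 0.03, 0.05, 10, 5),
               class = "validation_error")
})

test_that("sorption_summary reports the final-time capacity and efficiency", {
  b <- batch_sorption("x", "CrVI", C0 = 20, V = 0.030, Ma = 0.04640,
                      time = rep(c(10, 43200), each = 3),
                      ct = c(15, 15, 15, 5.16, 5.16, 5.16),
                      replicate = rep(1:3, 2))
  s <- sorption_summary(b)
  expect_equal(s$capacity_mg_g, 9.59)
  expect_equal(s$efficiency_pct, 74.2)
  expect_false(s$capacity_is_lower_bound)
  # censored final rows: capacity at the bound, flagged as a lower bound
  b2 <- batch_sorption("x", "CrVI", C0 = 20, V = 0.030, Ma = 0.05357,
                       time = rep(43200, 3), ct = rep(0.01, 3),
                       censored = TRUE, detection_limit = 0.01)
  s2 <- sorption_summary(b2)
  expect_true(s2$capacity_is_lower_bound)
  expect_equal(s2$capacity_mg_g, 11.20)
  expect_equal(s2$efficiency_pct, 100)
})
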