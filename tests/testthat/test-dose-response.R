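# Tolerance index and Hill/IC50 dose-response fitting.

test_that("tolerance index is the treated/control growth ratio, unclipped", {
  expect_equal(tolerance_index(c(6, 6, 6), c(12, 12, 12))$ti_mean, 0.5)
  expect_equal(tolerance_index(c(12, 12), c(12, 12))$ti_mean, 1.0)
  # biostimulation above the control stays above 1
  expect_equal(tolerance_index(13.8, 12.0)$ti_mean, 1.15)
  # SD propagated onto the control-mean scale; NA for a single replicate
  expect_equal(tolerance_index(c(5, 7), c(10, 10))$ti_sd, sd(c(5, 7)) / 10)
  expect_true(is.na(tolerance_index(13.8, 12.0)$ti_sd))
})

test_that("degenerate tolerance-index inputs are rejected with typed errors", {
  expect_error(tolerance_index(c(5, 5), numeric(0)),
               class = "undefined_control_error")
  expect_error(tolerance_index(c(5, 5), c(0, 0)),
               class = "undefined_control_error")
  expect_error(tolerance_index(c(-1, 5), c(10, 10)),
               class = "validation_error")
  expect_error(tolerance_index(numeric(0), c(10, 10)),
               class = "validation_error")
})

test_that("hill_ti has the logistic midpoint, control limit, and monotone decay", {
  for (h in c(0.3, 1, 3, 7.5)) {
    expect_equal(hill_ti(10, ic50 = 10, h = h), 0.5)
  }
  expect_equal(hill_ti(12.5, ic50 = 12.5, h = 3), 0.5)
  expect_identical(hill_ti(0, ic50 = 4, h = 2), 1.0)
  grid <- seq(0.01, 50, length.out = 200)
  for (p in list(c(10, 2), c(0.5, 0.7), c(25, 5))) {
    ti <- hill_ti(grid, p[1], p[2])
    expect_true(all(diff(ti) < 0))
    expect_true(all(ti > 0 & ti <= 1))
  }
  expect_error(hill_ti(5, ic50 = 0, h = 2), class = "parameter_domain_error")
  expect_error(hill_ti(5, ic50 = 10, h = -1), class = "parameter_domain_error")
  expect_error(hill_ti(-5, ic50 = 10, h = 2), class = "domain_error")
})

test_that("fit_hill recovers generating parameters exactly from noise-free data", {
  for (truth in list(c(10, 2), c(4, 0.8), c(7.5, 4))) {
    fit <- fit_hill(hill_dataset(truth[1], truth[2]))
    expect_lt(abs(fit$ic50 - truth[1]) / truth[1], 1e-6)
    expect_lt(abs(fit$h - truth[2]) / truth[2], 1e-6)
    expect_false(fit$extrapolated)
    expect_true(fit$converged)
    expect_equal(fit$n_points, 30L)
  }
})

test_that("fit_hill flags IC50 estimates beyond the tested range as extrapolated", {
  # mirrors report rows where the estimate lies well above the design maximum
  fit <- fit_hill(hill_dataset(48.26, 1.5))
  expect_true(fit$extrapolated)
  expect_lt(abs(fit$ic50 - 48.26) / 48.26, 1e-4)
})

test_that("fit_hill returns the no-growth sentinel when nothing grew", {
  conc <- rep(c(2.5, 5, 7.5), each = 3)
  ds <- tolerance_dataset("x", "CrVI", 30, conc, rep(0, 9), rep(40, 6))
  fit <- fit_hill(ds)
  expect_true(fit$no_growth)
  expect_true(is.na(fit$ic50))
})

test_that("fit_hill preconditions: at least two distinct concentrations", {
  ds <- tolerance_dataset("x", "AsV", 30, rep(2.5, 6), rep(20, 6), rep(40, 6))
  expect_error(fit_hill(ds), class = "precondition_error")
})

test_that("IC50 recovery stays within 10% under replicate TI noise", {
  # Gaussian TI noise (sd 0.05), 6 replicates, IC50 inside the design range
  cs <- c(2.5, 5, 7.5, 10, 12.5)
  errs <- vapply(1:50, function(s) {
    conc <- rep(cs, each = 6)
    ti <- with_seed_local(s, pmax(hill_ti(conc, 10, 2) + rnorm(length(conc), 0, 0.05), 0))
    ds <- tolerance_dataset("x", "AsV", 30, conc, ti * 50, rep(50, 6))
    abs(fit_hill(ds)$ic50 - 10) / 10
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("bootstrap CI is seed-reproducible and brackets the estimate", {
  ds <- with_seed_local(42, {
    conc <- rep(c(2.5, 5, 7.5, 10, 12.5), each = 6)
    ti <- pmax(hill_ti(conc, 8, 2.5) + rnorm(length(conc), 0, 0.04), 0)
    tolerance_dataset("x", "AsV", 30, conc, ti * 50, rep(50, 6))
  })
  f1 <- fit_hill(ds, n_boot = 200, seed = 7)
  f2 <- fit_hill(ds, n_boot = 200, seed = 7)
  expect_identical(f1$ci_low, f2$ci_low)
  expect_identical(f1$ci_high, f2$ci_high)
  expect_lte(f1$ci_low, f1$ic50)
  expect_gte(f1$ci_high, f1$ic50)
  expect_error(fit_hill(ds, n_boot = 10), class = "config_error")
})

test_that("fit_hill_table fits per group and carries partial failures per row", {
  d1 <- simulate_tolerance(8, 2, seed = 1, strain = "A", metal = "AsV")
  d2 <- simulate_tolerance(1.2, 1.5, seed = 2, strain = "B", metal = "CrVI",
                           concentrations = c(0.1, 0.5, 1, 1.5, 2.5))
  plates <- rbind(plate_rows(d1), plate_rows(d2))
  tab <- fit_hill_table(plates)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$status, "ok")
  expect_false(any(tab$extrapolated))
  # only-control rows degrade to the no-growth sentinel, not an error
  ctl <- plates[plates$conc_g_per_L == 0 & plates$strain == "A", ]
  tab2 <- fit_hill_table(ctl)
  expect_equal(tab2$status, "no_growth")
  expect_error(fit_hill_table(plates[0, ]), class = "no_data_error")
})
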