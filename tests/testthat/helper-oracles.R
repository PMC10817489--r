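# Independent oracles, kept free of the package's solver path.

# Fixed-step explicit-Euler integration of the liquid-phase sorption ODE.
# Recomputes the right-hand side from the model fields directly.
euler_timecourse <- function(model, C0, Ma, V, times, dt = 0.1) {
  qe <- function(C) {
    iso <- model$isotherm
    if (inherits(iso, "langmuir")) {
      iso$q_max * iso$K_L * C / (1 + iso$K_L * C)
    } else {
      iso$K_F * C^(1 / iso$n)
    }
  }
  f <- function(C) {
    gap <- qe(C) - (V / Ma) * (C0 - C)
    -model$k * (Ma / V) * max(gap, 0)^model$order
  }
  out <- numeric(length(times))
  C <- C0
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      step <- min(dt, times[i] - t)
      C <- max(min(C + step * f(C), C0), 0)
      t <- t + step
    }
    out[i] <- C
  }
  out
}

# Closed-form pseudo-second-order uptake curve (constant-q_e hypothesis).
pso_qt <- function(t, q_e, k_2) q_e^2 * k_2 * t / (1 + q_e * k_2 * t)
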