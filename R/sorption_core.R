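# Batch sorption containers, closed-form uptake/efficiency, and the
# linearised pseudo-second-order fit.
#
# Units package-wide: concentrations mg L^-1, sorbent mass g dry matter,
# volume L, time minutes. k_2 is therefore g (mg min)^-1.

#' Specific metal uptake from the liquid-phase mass balance
#'
#' q_t = V (C0 - Ct) / Ma: mass of metal removed from solution per unit
#' sorbent dry mass at the time Ct was measured.
#'
#' @param C0 initial concentration, mg L^-1.
#' @param Ct remaining concentration, mg L^-1 (vectorised).
#' @param V liquid volume, L.
#' @param Ma sorbent dry mass, g, > 0.
#' @return specific uptake q_t, mg g^-1. `Ct > C0` yields a negative value
#'   with a `negative_uptake` warning (apparent release), not an error.
#' @examples
#' specific_uptake(20, 0, 0.030, 0.05357) # 11.20 mg/g
#' @export
specific_uptake <- function(C0, Ct, V, Ma) {
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE)
  check_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  if (!is.numeric(Ma) || length(Ma) != 1L || !is.finite(Ma) || Ma <= 0) {
    ms_stop("`Ma` must be > 0 (division by sorbent mass)", "division_domain_error")
  }
  if (any(!is.finite(Ct)) || any(Ct < 0)) {
    ms_stop("`Ct` must be finite and >= 0", "domain_error")
  }
  if (any(Ct > C0)) {
    ms_warn("Ct exceeds C0: negative (apparent) uptake returned",
            "negative_uptake")
  }
  V * (C0 - Ct) / Ma
}

#' Removal efficiency
#'
#' 100 (C0 - Ct) / C0, the percentage of the initial metal load removed from
#' solution.
#'
#' @inheritParams specific_uptake
#' @return percent removal in \[0, 100\]; `Ct > C0` yields a flagged negative
#'   efficiency (warning), not an error.
#' @examples
#' removal_efficiency(20, 3.48) # 82.6 %
#' @export
removal_efficiency <- function(C0, Ct) {
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(Ct)) || any(Ct < 0)) {
    ms_stop("`Ct` must be finite and >= 0", "domain_error")
  }
  if (any(Ct > C0)) {
    ms_warn("Ct exceeds C0: negative removal efficiency returned",
            "negative_uptake")
  }
  100 * (C0 - Ct) / C0
}

#' Construct a batch sorption experiment
#'
#' One batch liquid-phase experiment: metadata (initial concentration,
#' volume, sorbent dry mass, detection limit) plus replicate residual
#' concentrations at sampled times in long format. Left-censored
#' measurements (below the detection limit) are stored at the bound with a
#' logical `censored` flag rather than an imputed number. The t = 0 state
#' Ct = C0 is implicit; t = 0 rows may be present but are not required.
#'
#' @param label experiment label.
#' @param metal `"AsV"` or `"CrVI"`.
#' @param C0 initial concentration, mg L^-1, > 0.
#' @param V liquid volume, L, > 0.
#' @param Ma sorbent dry mass, g, >= 0.
#' @param time sampling time (min) per measurement row, >= 0.
#' @param ct residual concentration (mg L^-1) per row.
#' @param replicate replicate id per row (recycled).
#' @param censored logical flag per row (recycled); `TRUE` rows record `ct`
#'   at the detection bound.
#' @param detection_limit detection limit, mg L^-1.
#' @param ct_tol relative slack above `C0` allowed for noisy measurements
#'   before validation fails (default 0.25).
#' @return object of class `batch_sorption` with element `data`, a data frame
#'   `time, replicate, ct, censored` sorted by time.
#' @export
batch_sorption <- function(label, metal, C0, V, Ma, time, ct,
                           replicate = 1L, censored = FALSE,
                           detection_limit = 0, ct_tol = 0.25) {
  check_metal(metal)
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE,
                   class = "validation_error")
  check_scalar_num(V, "V", lower = 0, strict_lower = TRUE,
                   class = "validation_error")
  check_scalar_num(Ma, "Ma", lower = 0, class = "validation_error")
  check_scalar_num(detection_limit, "detection_limit", lower = 0,
                   class = "validation_error")
  n <- length(time)
  if (length(ct) == 1L) ct <- rep(ct, n)
  if (n < 1L || length(ct) != n) {
    ms_stop("`time` and `ct` must be non-empty and of equal length",
            "validation_error")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    ms_stop("times must be finite and >= 0", "validation_error")
  }
  cens <- rep_len(as.logical(censored), n)
  # censored rows carry the detection bound, not a measurement, so only
  # uncensored values are held to the physical upper limit
  if (any(!is.finite(ct)) || any(ct < 0) ||
      any(ct[!cens] > C0 * (1 + ct_tol))) {
    ms_stop(sprintf("ct values must lie in [0, C0*(1+%.2f)]", ct_tol),
            "validation_error")
  }
  d <- data.frame(time = as.numeric(time),
                  replicate = rep_len(replicate, n),
                  ct = as.numeric(ct),
                  censored = cens)
  d <- d[order(d$time, d$replicate), , drop = FALSE]
  rownames(d) <- NULL
  structure(
    list(label = as.character(label), metal = metal, C0 = C0, V = V, Ma = Ma,
         detection_limit = detection_limit, data = d),
    class = "batch_sorption"
  )
}

#' @export
print.batch_sorption <- function(x, ...) {
  cat(sprintf("<batch_sorption> %s (%s)\n", x$label, x$metal))
  cat(sprintf("  C0 = %g mg/L, V = %g L, Ma = %g g; %d measurements at %d times (%d censored)\n",
              x$C0, x$V, x$Ma, nrow(x$data), length(unique(x$data$time)),
              sum(x$data$censored)))
  invisible(x)
}

#' Summarise a batch sorption experiment at its final sampling time
#'
#' Report-table row in the style of a biosorption summary: biomass, mean and
#' SD of the final residual concentration, specific removal capacity
#' (per-replicate uptake averaged, so the capacity is the mean of ratios),
#' and removal efficiency. Censored final measurements are evaluated at
#' Ct = 0 and flagged (capacity reported as a lower bound).
#'
#' @param x a [batch_sorption()] object.
#' @param digits decimals used for the rendered columns (default 2).
#' @return one-row data frame: `label, metal, biomass_g, final_ct_mean,
#'   final_ct_sd, capacity_mg_g, capacity_sd, capacity_is_lower_bound,
#'   efficiency_pct`.
#' @export
sorption_summary <- function(x, digits = 2) {
  stopifnot(inherits(x, "batch_sorption"))
  tmax <- max(x$data$time)
  fin <- x$data[x$data$time == tmax, , drop = FALSE]
  cens <- fin$censored
  ct_eff <- ifelse(cens, 0, fin$ct) # censored: complete removal at the bound
  q <- specific_uptake(x$C0, ct_eff, x$V, x$Ma)
  eff <- removal_efficiency(x$C0, mean(ct_eff))
  data.frame(
    label = x$label, metal = x$metal, biomass_g = x$Ma,
    final_ct_mean = round(mean(fin$ct), digits),
    final_ct_sd = round(stats::sd(fin$ct), digits),
    capacity_mg_g = round(mean(q), digits),
    capacity_sd = round(stats::sd(q), digits),
    capacity_is_lower_bound = any(cens),
    efficiency_pct = round(eff, 1),
    stringsAsFactors = FALSE
  )
}

#' Linearised pseudo-second-order kinetic fit
#'
#' Under constant equilibrium concentration the second-order rate law
#' integrates to q_t = q_e^2 k_2 t / (1 + q_e k_2 t), which linearises as
#' t/q_t = 1/(k_2 q_e^2) + t/q_e. Ordinary least squares of t/q_t on t gives
#' q_e from the slope and k_2 from the intercept.
#'
#' @param times sampling times, min; points with t <= 0 are excluded
#'   (t/q_t is undefined at 0).
#' @param q_t specific uptake at `times`, mg g^-1, > 0 at retained points.
#' @return list with `k_2` (g (mg min)^-1), `q_e` (mg g^-1), and `r2` of the
#'   linear fit.
#' @examples
#' t <- seq(5, 60, by = 5)
#' q <- 20.8^2 * 3.39e-2 * t / (1 + 20.8 * 3.39e-2 * t)
#' pso_linear_fit(t, q)
#' @export
pso_linear_fit <- function(times, q_t) {
  if (length(times) != length(q_t)) {
    ms_stop("`times` and `q_t` must have equal length", "validation_error")
  }
  keep <- is.finite(times) & times > 0
  times <- times[keep]; q_t <- q_t[keep]
  if (length(times) < 3L) {
    ms_stop("need >= 3 points with t > 0 for the linearised fit",
            "precondition_error")
  }
  if (any(!is.finite(q_t)) || any(q_t <= 0)) {
    ms_stop("q_t must be > 0 at all retained points", "domain_error")
  }
  y <- times / q_t
  fit <- stats::lm(y ~ t, data = data.frame(t = times, y = y))
  b <- stats::coef(fit)
  intercept <- unname(b[1]); slope <- unname(b[2])
  # a zero intercept means an infinite rate constant: outside the model
  if (!is.finite(slope) || !is.finite(intercept) || slope <= 0 ||
      intercept <= 1e-10 * slope * max(times)) {
    ms_stop("slope or intercept non-positive: data inconsistent with the pseudo-second-order form",
            "nonphysical_fit_error")
  }
  sst <- sum((y - mean(y))^2)
  list(k_2 = slope^2 / intercept,
       q_e = 1 / slope,
       r2 = if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1)
}
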