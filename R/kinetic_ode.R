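# Isotherm-coupled sorption kinetics: the liquid-phase ODE, its numerical
# integration, multistart least-squares fitting, and model selection.
#
# The rate law dq_t/dt = k_i (q_e - q_t)^i, with q_e evaluated by the
# isotherm at the instantaneous liquid concentration and q_t eliminated via
# the mass balance q_t = (V/Ma)(C0 - Ct), gives
#
#   dCt/dt = -k_i (Ma/V) [ q_e(Ct) - (V/Ma)(C0 - Ct) ]^i
#
# with the driving force clamped at zero (sorption only, no desorption
# branch). Time is in minutes throughout; 30 days = 43,200 min.

#' Kinetic sorption model
#'
#' A kinetic order (1 or 2), its rate constant, and an equilibrium isotherm.
#'
#' @param order kinetic order i, 1 or 2.
#' @param k rate constant: min^-1 for i = 1, g (mg min)^-1 for i = 2; > 0.
#' @param isotherm an [langmuir()] or [freundlich()] object.
#' @return object of class `kinetic_model`.
#' @examples
#' kinetic_model(2, 1.32e-6, langmuir(39.81, 0.1124))
#' @export
kinetic_model <- function(order, k, isotherm) {
  if (!order %in% c(1, 2)) {
    ms_stop("`order` must be 1 or 2", "parameter_domain_error")
  }
  check_scalar_num(k, "k", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  if (!inherits(isotherm, "isotherm")) {
    ms_stop("`isotherm` must be an isotherm object", "type_error")
  }
  structure(list(order = as.integer(order), k = k, isotherm = isotherm),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> order %d, k = %.4g\n", x$order, x$k))
  print(x$isotherm)
  invisible(x)
}

#' Right-hand side of the liquid-phase sorption ODE
#'
#' dCt/dt = -k_i (Ma/V) max(q_e(Ct) - (V/Ma)(C0 - Ct), 0)^i. The driving
#' force is the gap between the isotherm-implied equilibrium loading at the
#' instantaneous concentration and the current loading; it is clamped at
#' zero so the model never desorbs. The returned rate is always <= 0.
#'
#' @param Ct liquid concentration, mg L^-1, within \[0, C0\] (vectorised).
#' @param model a [kinetic_model()].
#' @param C0 initial concentration, mg L^-1.
#' @param Ma sorbent dry mass, g (Ma = 0 gives rate 0: no sorbent).
#' @param V liquid volume, L.
#' @return dCt/dt, mg L^-1 min^-1.
#' @export
sorption_rhs <- function(Ct, model, C0, Ma, V) {
  stopifnot(inherits(model, "kinetic_model"))
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE)
  check_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  check_scalar_num(Ma, "Ma", lower = 0)
  if (any(!is.finite(Ct)) || any(Ct < -1e-9) || any(Ct > C0 * (1 + 1e-9))) {
    ms_stop("`Ct` must lie in [0, C0]", "domain_error")
  }
  if (Ma == 0) return(rep(0, length(Ct)))
  gap <- isotherm_qe(model$isotherm, pmax(Ct, 0)) - (V / Ma) * (C0 - Ct)
  -model$k * (Ma / V) * pmax(gap, 0)^model$order
}

#' Integrate the sorption time course
#'
#' Adaptive-step integration (lsoda) of the liquid-phase ODE from Ct(0) = C0,
#' with dense output at the requested times. The returned trajectory is
#' clamped to \[0, C0\] and made non-increasing (the exact solution is; the
#' clamp only removes solver noise at the tolerance floor).
#'
#' @inheritParams sorption_rhs
#' @param times output times, min; strictly increasing, starting at 0.
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @return data frame with columns `time` and `ct`.
#' @examples
#' m <- kinetic_model(2, 1.32e-6, langmuir(39.81, 0.1124))
#' integrate_timecourse(m, C0 = 25, Ma = 0.050, V = 0.030,
#'                      times = c(0, 2, 5, 7, 14, 21, 30) * 1440)
#' @export
integrate_timecourse <- function(model, C0, Ma, V, times,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "kinetic_model"))
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE)
  check_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  check_scalar_num(Ma, "Ma", lower = 0)
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    ms_stop("`times` must be strictly increasing and start at 0",
            "precondition_error")
  }
  if (Ma == 0 || model$k == 0) {
    return(data.frame(time = times, ct = rep(C0, length(times))))
  }
  rhs <- function(t, y, parms) {
    C <- min(max(y[1], 0), C0)
    gap <- isotherm_qe(model$isotherm, C) - (V / Ma) * (C0 - C)
    list(-model$k * (Ma / V) * max(gap, 0)^model$order)
  }
  out <- tryCatch(
    deSolve::ode(y = c(ct = C0), times = times, func = rhs, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(out, "condition")) {
    ms_stop(paste("ODE integration failed:", conditionMessage(out)),
            "integration_error")
  }
  ct <- cummin(pmin(pmax(out[, "ct"], 0), C0))
  data.frame(time = times, ct = as.numeric(ct))
}

#' Equilibrium liquid concentration of a batch system
#'
#' The fixed point of the sorption ODE: the unique C in \[0, C0\] at which the
#' isotherm loading q_e(C) equals the mass-balance loading (V/Ma)(C0 - C).
#' Existence and uniqueness hold because q_e is increasing in C and the
#' mass-balance line is decreasing. For the Langmuir isotherm the admissible
#' root of the implied quadratic is returned in closed form; for the
#' Freundlich isotherm the root is bracketed on \[0, C0\] (tolerance 1e-10).
#'
#' @inheritParams sorption_rhs
#' @return equilibrium concentration, mg L^-1. `Ma = 0` returns `C0`.
#' @export
equilibrium_concentration <- function(model, C0, Ma, V) {
  stopifnot(inherits(model, "kinetic_model"))
  check_scalar_num(C0, "C0", lower = 0, strict_lower = TRUE)
  check_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  check_scalar_num(Ma, "Ma", lower = 0)
  if (Ma == 0) return(C0)
  iso <- model$isotherm
  if (inherits(iso, "langmuir")) {
    # V K_L C^2 + (V + q_max K_L Ma - V K_L C0) C - V C0 = 0
    a <- V * iso$K_L
    b <- V + iso$q_max * iso$K_L * Ma - V * iso$K_L * C0
    cc <- -V * C0
    root <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    return(min(max(root, 0), C0))
  }
  g <- function(C) isotherm_qe(iso, C) - (V / Ma) * (C0 - C)
  stats::uniroot(g, c(0, C0), tol = 1e-10)$root
}

# ---- fitting ---------------------------------------------------------------

# log10-space box bounds for the fitted parameters
kinetic_bounds <- function(isotherm_kind) {
  if (isotherm_kind == "langmuir") {
    list(lower = log10(c(k = 1e-10, q_max = 1e-2, K_L = 1e-5)),
         upper = log10(c(k = 1e2, q_max = 1e4, K_L = 1e2)))
  } else {
    list(lower = log10(c(k = 1e-10, K_F = 1e-4, n = 0.2)),
         upper = log10(c(k = 1e2, K_F = 1e4, n = 10)))
  }
}

build_model <- function(theta10, order, isotherm_kind) {
  p <- 10^theta10
  iso <- if (isotherm_kind == "langmuir") langmuir(p[2], p[3]) else freundlich(p[2], p[3])
  kinetic_model(order, p[1], iso)
}

# Predicted Ct at the observation rows (pooled replicates share times).
predict_rows <- function(theta10, order, isotherm_kind, C0, Ma, V,
                         utimes, row_time_idx, rtol) {
  m <- build_model(theta10, order, isotherm_kind)
  tc <- integrate_timecourse(m, C0, Ma, V, utimes, rtol = rtol,
                             atol = rtol * 1e-2)
  tc$ct[row_time_idx]
}

# Data-informed start: pseudo-second-order linearisation for k, loading
# scale for the isotherm parameters; clamped into the box.
heuristic_start <- function(obs, C0, Ma, V, isotherm_kind, bounds) {
  qt <- specific_uptake(C0, obs$ct, V, Ma)
  by_t <- tapply(qt, obs$time, mean)
  tt <- as.numeric(names(by_t))
  k_guess <- tryCatch(pso_linear_fit(tt, as.numeric(by_t))$k_2,
                      error = function(e) 1e-5)
  qmax_guess <- max(2 * max(qt, 0), 1e-1)
  ce_late <- mean(obs$ct[obs$time == max(obs$time)])
  KL_guess <- 1 / max(ce_late, 0.05 * C0)
  start <- if (isotherm_kind == "langmuir") {
    c(k_guess, qmax_guess, KL_guess)
  } else {
    c(k_guess, qmax_guess * KL_guess, 1)
  }
  pmin(pmax(log10(start), bounds$lower + 1e-6), bounds$upper - 1e-6)
}

#' Fit the isotherm-coupled kinetic ODE to a batch sorption time course
#'
#' Minimises the sum of squared errors between the integrated model and all
#' pooled replicate Ct measurements, over (k_i, isotherm parameters), by
#' bounded Levenberg-Marquardt least squares in log10-parameter space from
#' `n_starts` seeded Latin-hypercube starts plus one data-informed start
#' (pseudo-second-order linearisation and loading-based isotherm guesses).
#'
#' @param data a [batch_sorption()] experiment.
#' @param order kinetic order, 1 or 2.
#' @param isotherm `"langmuir"` or `"freundlich"`.
#' @param n_starts number of Latin-hypercube starts (default 8).
#' @param seed integer seed for the start design; `NULL` uses the current
#'   RNG stream.
#' @param fit_means fit per-time replicate means instead of pooled
#'   replicates (off by default).
#' @param rtol integrator relative tolerance used inside the objective.
#' @return object of class `kinetic_fit`: `model` (the fitted
#'   [kinetic_model()]), `sse`, `r2` (1 - SSE/SST about the mean of the
#'   pooled observations, negative values reported raw), `n_obs`, `n_starts`,
#'   `converged`, `at_bound` (named logicals), and `identifiability_warning`
#'   (isotherm-parameter estimate correlation above 0.99, or maximum
#'   observed loading below 0.2 q_max for a Langmuir fit).
#' @export
fit_kinetics <- function(data, order = 2,
                         isotherm = c("langmuir", "freundlich"),
                         n_starts = 8, seed = NULL, fit_means = FALSE,
                         rtol = 1e-8) {
  stopifnot(inherits(data, "batch_sorption"))
  isotherm <- match.arg(isotherm)
  if (!order %in% c(1, 2)) {
    ms_stop("`order` must be 1 or 2", "parameter_domain_error")
  }
  obs <- data$data
  pos <- obs[obs$time > 0, , drop = FALSE]
  if (nrow(pos) == 0L || all(pos$censored)) {
    ms_stop("no uncensored measurements above t = 0: nothing to fit",
            "no_signal_error")
  }
  if (fit_means) {
    agg <- stats::aggregate(ct ~ time, data = obs, FUN = mean)
    obs <- data.frame(time = agg$time, replicate = 1L, ct = agg$ct,
                      censored = FALSE)
  }
  utimes_obs <- sort(unique(obs$time))
  if (length(unique(c(0, utimes_obs))) < 5L) {
    # 3 parameters need >= 4 informative sampling times
    ms_stop("need >= 4 sampling times beyond t = 0 to fit 3 parameters",
            "precondition_error")
  }
  utimes <- unique(c(0, utimes_obs))
  row_time_idx <- match(obs$time, utimes)

  bounds <- kinetic_bounds(isotherm)
  resid_fn <- function(theta10) {
    pred <- predict_rows(theta10, order, isotherm, data$C0, data$Ma, data$V,
                         utimes, row_time_idx, rtol)
    obs$ct - pred
  }

  starts_unit <- with_preserved_seed(seed, lhs::randomLHS(n_starts, 3))
  starts <- t(apply(starts_unit, 1, function(u) {
    bounds$lower + u * (bounds$upper - bounds$lower)
  }))
  starts <- rbind(starts,
                  heuristic_start(obs, data$C0, data$Ma, data$V, isotherm,
                                  bounds))

  fits <- apply(starts, 1, function(s) {
    ms_lsq(s, resid_fn, bounds$lower, bounds$upper)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$sse) && f$sse < 1e10,
                 fits)
  if (length(fits) == 0L) {
    ms_stop("no start of the kinetic fit converged to a finite SSE",
            "fit_failure_error")
  }
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  n_bound <- vapply(fits, function(f) {
    sum(abs(f$par - bounds$lower) < 1e-6 | abs(f$par - bounds$upper) < 1e-6)
  }, integer(1))
  best <- fits[[order(sses, n_bound)[1L]]]

  theta <- best$par
  at_bound <- abs(theta - bounds$lower) < 1e-6 | abs(theta - bounds$upper) < 1e-6
  names(at_bound) <- names(bounds$lower)

  pred <- predict_rows(theta, order, isotherm, data$C0, data$Ma, data$V,
                       utimes, row_time_idx, rtol)
  if (at_bound[1] || (data$C0 - min(pred)) < 1e-6 * data$C0) {
    ms_warn("fitted trajectory is flat: data carry no sorption signal",
            "no_signal_fit")
  }
  sse <- sum((obs$ct - pred)^2)
  sst <- sum((obs$ct - mean(obs$ct))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  model <- build_model(theta, order, isotherm)
  ident <- identifiability_flag(theta, order, isotherm, data, obs, utimes,
                                row_time_idx, rtol, sse, model)

  structure(
    list(model = model, sse = sse, r2 = r2, n_obs = nrow(obs),
         n_starts = nrow(starts), converged = isTRUE(best$converged),
         at_bound = at_bound, identifiability_warning = ident,
         isotherm_kind = isotherm, order = as.integer(order),
         label = data$label),
    class = "kinetic_fit"
  )
}

# Estimate-correlation / saturation heuristics for weak identifiability.
identifiability_flag <- function(theta, order, isotherm, data, obs, utimes,
                                 row_time_idx, rtol, sse, model) {
  flag <- FALSE
  if (inherits(model$isotherm, "langmuir")) {
    qt_max <- max(specific_uptake(data$C0, obs$ct, data$V, data$Ma))
    if (qt_max < 0.2 * model$isotherm$q_max) flag <- TRUE
  }
  if (!flag) {
    corr <- tryCatch({
      f0 <- predict_rows(theta, order, isotherm, data$C0, data$Ma, data$V,
                         utimes, row_time_idx, rtol)
      hstep <- 1e-5
      J <- vapply(1:3, function(j) {
        tj <- theta; tj[j] <- tj[j] + hstep
        (predict_rows(tj, order, isotherm, data$C0, data$Ma, data$V,
                      utimes, row_time_idx, rtol) - f0) / hstep
      }, numeric(length(f0)))
      covm <- solve(crossprod(J))
      stats::cov2cor(covm)[2, 3]
    }, error = function(e) 1) # singular information: unidentifiable
    if (is.finite(corr) && abs(corr) > 0.99) flag <- TRUE
  }
  flag
}

#' @export
print.kinetic_fit <- function(x, ...) {
  iso <- x$model$isotherm
  pars <- if (inherits(iso, "langmuir")) {
    sprintf("q_max = %.4g mg/g, K_L = %.4g L/mg", iso$q_max, iso$K_L)
  } else {
    sprintf("K_F = %.4g, n = %.4g", iso$K_F, iso$n)
  }
  cat(sprintf("<kinetic_fit> %s: order %d + %s\n", x$label, x$order,
              x$isotherm_kind))
  cat(sprintf("  k_%d = %.4g, %s\n  SSE = %.4g, r2 = %.4f, n = %d%s%s\n",
              x$order, x$model$k, pars, x$sse, x$r2, x$n_obs,
              if (!x$converged) "  [not converged]" else "",
              if (x$identifiability_warning) "  [weakly identifiable]" else ""))
  invisible(x)
}

#' Fit and rank all four kinetic-order x isotherm combinations
#'
#' Fits the kinetic ODE with order in {1, 2} crossed with the Langmuir and
#' Freundlich isotherms and ranks the fits by SSE (ties broken toward fewer
#' parameters stuck at a bound, then lower order, then isotherm name).
#' Individual fit failures are kept as ranked-last placeholder entries with
#' a failure flag.
#'
#' @inheritParams fit_kinetics
#' @return object of class `model_selection`: `fits` (ranked list of
#'   [fit_kinetics()] results or failure placeholders) and `table`, a data
#'   frame with one row per combination in rank order.
#' @export
model_select <- function(data, n_starts = 8, seed = NULL) {
  combos <- expand.grid(order = c(1L, 2L),
                        isotherm = c("langmuir", "freundlich"),
                        stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(combos)), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    withCallingHandlers(
      tryCatch(
        fit_kinetics(data, order = combos$order[i],
                     isotherm = combos$isotherm[i],
                     n_starts = n_starts, seed = s),
        mycosorb_error = function(e) {
          structure(list(model = NULL, sse = Inf, r2 = NA_real_,
                         n_obs = NA_integer_, converged = FALSE,
                         at_bound = NULL, identifiability_warning = NA,
                         isotherm_kind = combos$isotherm[i],
                         order = combos$order[i], label = data$label,
                         failed = TRUE, error = conditionMessage(e)),
                    class = "kinetic_fit")
        }
      ),
      mycosorb_warning = function(w) invokeRestart("muffleWarning")
    )
  })
  failed <- vapply(fits, function(f) isTRUE(f$failed), logical(1))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  nb <- vapply(fits, function(f) if (is.null(f$at_bound)) 99L else sum(f$at_bound),
               integer(1))
  rank_idx <- order(failed, sses, nb, combos$order, combos$isotherm)
  fits <- fits[rank_idx]
  tab <- do.call(rbind, lapply(seq_along(fits), function(r) {
    f <- fits[[r]]
    iso <- f$model$isotherm
    data.frame(
      rank = r, order = f$order, isotherm = f$isotherm_kind,
      k = if (is.null(f$model)) NA_real_ else f$model$k,
      q_max = if (inherits(iso, "langmuir")) iso$q_max else NA_real_,
      K_L = if (inherits(iso, "langmuir")) iso$K_L else NA_real_,
      K_F = if (inherits(iso, "freundlich")) iso$K_F else NA_real_,
      n = if (inherits(iso, "freundlich")) iso$n else NA_real_,
      sse = f$sse, r2 = f$r2, failed = isTRUE(f$failed),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(fits = fits, table = tab, label = data$label),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %s\n", x$label))
  print(x$table, row.names = FALSE)
  invisible(x)
}
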