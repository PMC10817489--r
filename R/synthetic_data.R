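# Seeded generators for plate-tolerance datasets and batch sorption time
# courses, plus the simulate -> fit parameter-recovery harness.

#' Default plate concentration designs
#'
#' Five-concentration plate designs: 2.5-12.5 g L^-1 for As(V) and
#' 0.1-2.5 g L^-1 for Cr(VI).
#'
#' @param metal `"AsV"` or `"CrVI"`.
#' @return concentrations, g L^-1.
#' @export
default_plate_concentrations <- function(metal = c("AsV", "CrVI")) {
  metal <- match.arg(metal)
  if (metal == "AsV") c(2.5, 5, 7.5, 10, 12.5) else c(0.1, 0.5, 1.0, 1.5, 2.5)
}

#' Default batch sampling schedule
#'
#' Samples at 0, 2, 5, 7, 14, 21 and 30 days, expressed in minutes
#' (1 d = 1440 min).
#'
#' @return sampling times, min.
#' @export
default_sampling_times <- function() c(0, 2, 5, 7, 14, 21, 30) * 1440

#' Simulate a plate tolerance dataset
#'
#' Control diameters are drawn Normal(control_mean_diameter,
#' cv * control_mean_diameter), truncated at 0; treated diameters are drawn
#' around control_mean_diameter * TI(C) (Hill model) with the same relative
#' noise. With `diameter_cv = 0` the realised TI equals [hill_ti()] exactly
#' at every concentration.
#'
#' @param true_ic50,true_h generating Hill parameters.
#' @param concentrations tested concentrations, g L^-1 (default: the As(V)
#'   plate design).
#' @param n_replicates colonies per plate (default 6).
#' @param control_mean_diameter mean control colony diameter, mm (default 50).
#' @param diameter_cv relative SD of replicate diameters (default 0.05).
#' @param seed integer seed (required).
#' @param strain,metal,day labels for the generated dataset.
#' @return a [tolerance_dataset()].
#' @export
simulate_tolerance <- function(true_ic50, true_h,
                               concentrations = default_plate_concentrations("AsV"),
                               n_replicates = 6,
                               control_mean_diameter = 50,
                               diameter_cv = 0.05,
                               seed,
                               strain = "sim", metal = "AsV", day = 30) {
  check_scalar_num(true_ic50, "true_ic50", lower = 0, strict_lower = TRUE,
                   class = "validation_error")
  check_scalar_num(true_h, "true_h", lower = 0, strict_lower = TRUE,
                   class = "validation_error")
  check_scalar_num(control_mean_diameter, "control_mean_diameter", lower = 0,
                   strict_lower = TRUE, class = "validation_error")
  check_scalar_num(diameter_cv, "diameter_cv", lower = 0,
                   class = "validation_error")
  if (length(concentrations) < 2L ||
      anyDuplicated(concentrations) > 0 || any(concentrations <= 0)) {
    ms_stop("`concentrations` must be distinct and > 0", "validation_error")
  }
  if (missing(seed)) {
    ms_stop("a seed is required for stochastic generation", "config_error")
  }
  with_preserved_seed(seed, {
    draw <- function(mu, n) {
      pmax(mu + stats::rnorm(n, 0, diameter_cv * mu), 0)
    }
    control <- draw(control_mean_diameter, n_replicates)
    ti <- hill_ti(concentrations, true_ic50, true_h)
    conc <- rep(concentrations, each = n_replicates)
    diameter <- unlist(lapply(seq_along(concentrations), function(i) {
      mu <- control_mean_diameter * ti[i]
      # cv = 0: treated/control-mean reproduces the Hill TI exactly
      if (diameter_cv == 0) rep(mu, n_replicates) else draw(mu, n_replicates)
    }), use.names = FALSE)
    if (diameter_cv == 0) control <- rep(control_mean_diameter, n_replicates)
    tolerance_dataset(strain, metal, day, conc, diameter, control)
  })
}

#' Simulate a batch sorption time course
#'
#' Integrates the kinetic ODE at the given parameters and adds multiplicative
#' Gaussian measurement noise per replicate at each positive sampling time
#' (t = 0 rows stay at C0, the structural initial condition). Values are
#' truncated at 0; values below `detection_limit` are recorded at the limit
#' with the censoring flag set.
#'
#' @param model generating [kinetic_model()].
#' @param C0 initial concentration, mg L^-1 (default 25).
#' @param V liquid volume, L (default 0.030).
#' @param Ma sorbent dry mass, g (default 0.050).
#' @param times sampling times, min, including 0 (default:
#'   [default_sampling_times()]).
#' @param n_replicates replicates per time (default 3).
#' @param rel_noise_sd relative SD of the measurement noise (default 0.05).
#' @param detection_limit left-censoring bound, mg L^-1 (default 0.01).
#' @param seed integer seed (required when `rel_noise_sd > 0`).
#' @param label,metal labels for the generated experiment.
#' @return a [batch_sorption()].
#' @export
simulate_timecourse <- function(model, C0 = 25, V = 0.030, Ma = 0.050,
                                times = default_sampling_times(),
                                n_replicates = 3, rel_noise_sd = 0.05,
                                detection_limit = 0.01, seed = NULL,
                                label = "sim", metal = "CrVI") {
  stopifnot(inherits(model, "kinetic_model"))
  check_scalar_num(rel_noise_sd, "rel_noise_sd", lower = 0,
                   class = "validation_error")
  if (!0 %in% times) {
    ms_stop("`times` must include 0", "validation_error")
  }
  if (rel_noise_sd > 0 && is.null(seed)) {
    ms_stop("a seed is required for stochastic generation", "config_error")
  }
  tc <- integrate_timecourse(model, C0, Ma, V, sort(unique(times)))
  with_preserved_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(tc)), function(i) {
      t_i <- tc$time[i]
      true_ct <- tc$ct[i]
      ct <- if (t_i == 0) {
        rep(C0, n_replicates)
      } else {
        pmax(true_ct * (1 + stats::rnorm(n_replicates, 0, rel_noise_sd)), 0)
      }
      cens <- t_i > 0 & ct < detection_limit
      ct[cens] <- detection_limit
      data.frame(time = t_i, replicate = seq_len(n_replicates), ct = ct,
                 censored = cens)
    }))
    batch_sorption(label, metal, C0, V, Ma,
                   time = rows$time, ct = rows$ct,
                   replicate = rows$replicate, censored = rows$censored,
                   detection_limit = detection_limit)
  })
}

#' Simulate-and-refit parameter-recovery experiment
#'
#' Repeatedly generates a batch time course from a known kinetic model with
#' [simulate_timecourse()], refits it with [fit_kinetics()] (run r uses seed
#' `seed + r - 1` for both steps), and summarises recovery: per-parameter
#' relative bias of the median estimate, median absolute relative error, and
#' (optionally) how often [model_select()] ranks the generating
#' order x isotherm combination first.
#'
#' @inheritParams simulate_timecourse
#' @param n_runs number of simulate -> fit runs (>= 1).
#' @param seed base integer seed (required).
#' @param n_starts multistart count passed to the fitters.
#' @param select also run [model_select()] per run and record the top-ranked
#'   combination (slower; default FALSE).
#' @return list with `estimates` (one row per run: fitted parameters, sse,
#'   convergence, failure flag, and when `select = TRUE` the top-ranked
#'   combination), `summary` (per-parameter true value, median estimate,
#'   relative bias of the median, median absolute relative error), and
#'   `selection_frequency` (NA unless `select = TRUE`).
#' @export
recovery_experiment <- function(model, n_runs = 20, seed = 1,
                                C0 = 25, V = 0.030, Ma = 0.050,
                                times = default_sampling_times(),
                                n_replicates = 3, rel_noise_sd = 0.05,
                                detection_limit = 0.01,
                                n_starts = 8, select = FALSE) {
  stopifnot(inherits(model, "kinetic_model"))
  if (n_runs < 1L) ms_stop("`n_runs` must be >= 1", "validation_error")
  iso_kind <- if (inherits(model$isotherm, "langmuir")) "langmuir" else "freundlich"
  true <- c(k = model$k,
            if (iso_kind == "langmuir") {
              c(q_max = model$isotherm$q_max, K_L = model$isotherm$K_L)
            } else {
              c(K_F = model$isotherm$K_F, n = model$isotherm$n)
            })
  rows <- lapply(seq_len(n_runs), function(r) {
    s <- seed + r - 1L
    out <- data.frame(run = r, seed = s, k = NA_real_, p2 = NA_real_,
                      p3 = NA_real_, sse = NA_real_, converged = FALSE,
                      failed = FALSE, top_order = NA_integer_,
                      top_isotherm = NA_character_,
                      stringsAsFactors = FALSE)
    sim <- simulate_timecourse(model, C0 = C0, V = V, Ma = Ma, times = times,
                               n_replicates = n_replicates,
                               rel_noise_sd = rel_noise_sd,
                               detection_limit = detection_limit, seed = s)
    fit <- tryCatch(
      fit_kinetics(sim, order = model$order, isotherm = iso_kind,
                   n_starts = n_starts, seed = s),
      mycosorb_error = function(e) NULL
    )
    if (is.null(fit)) {
      out$failed <- TRUE
    } else {
      iso <- fit$model$isotherm
      out$k <- fit$model$k
      out$p2 <- if (iso_kind == "langmuir") iso$q_max else iso$K_F
      out$p3 <- if (iso_kind == "langmuir") iso$K_L else iso$n
      out$sse <- fit$sse
      out$converged <- fit$converged
    }
    if (select) {
      ms <- model_select(sim, n_starts = n_starts, seed = s)
      out$top_order <- ms$table$order[1]
      out$top_isotherm <- ms$table$isotherm[1]
    }
    out
  })
  est <- do.call(rbind, rows)
  names(est)[3:5] <- names(true)
  ok <- !est$failed
  summ <- do.call(rbind, lapply(names(true), function(p) {
    e <- est[[p]][ok]
    data.frame(parameter = p, true = unname(true[p]),
               median_estimate = stats::median(e),
               bias_rel = (stats::median(e) - true[p]) / true[p],
               mare = stats::median(abs(e - true[p]) / true[p]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  sel_freq <- if (select) {
    mean(est$top_order == model$order & est$top_isotherm == iso_kind)
  } else NA_real_
  list(estimates = est, summary = summ,
       selection_frequency = sel_freq, n_failed = sum(est$failed))
}
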