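# Plate tolerance indices and Hill/IC50 dose-response fitting.

#' Tolerance index of a treated plate relative to its unamended control
#'
#' The tolerance index (TI) is the ratio of colony radial growth on
#' metal-amended agar to growth on control plates at the same incubation day.
#' Values above 1 (biostimulation at sub-toxic doses) are reported as-is,
#' never clipped.
#'
#' @param treated replicate colony diameters (mm) on the amended plate.
#' @param control replicate colony diameters (mm) on the unamended plate.
#' @return list with `ti_mean` = mean(treated)/mean(control) and `ti_sd`,
#'   the treated replicate SD divided by the control mean (NA for a single
#'   replicate).
#' @examples
#' tolerance_index(c(6, 6, 6), c(12, 12, 12))
#' @export
tolerance_index <- function(treated, control) {
  if (length(treated) < 1L || !is.numeric(treated)) {
    ms_stop("at least one treated replicate diameter is required",
            "validation_error")
  }
  if (length(control) < 1L || !is.numeric(control)) {
    ms_stop("control diameters are empty: tolerance index is undefined",
            "undefined_control_error")
  }
  if (anyNA(treated) || anyNA(control)) {
    ms_stop("diameters must not contain NA", "validation_error")
  }
  if (any(treated < 0) || any(control < 0)) {
    ms_stop("colony diameters must be non-negative", "validation_error")
  }
  cbar <- mean(control)
  if (cbar <= 0) {
    ms_stop("control mean diameter is zero: tolerance index is undefined",
            "undefined_control_error")
  }
  list(
    ti_mean = mean(treated) / cbar,
    ti_sd = if (length(treated) > 1L) stats::sd(treated) / cbar else NA_real_
  )
}

#' Two-parameter Hill logistic tolerance-index model
#'
#' TI(C) = 1 / (1 + (C / IC50)^h), the decreasing-orientation Hill logistic:
#' TI(0) = 1, TI(IC50) = 1/2 for any slope h > 0, and TI is strictly
#' decreasing in concentration.
#'
#' @param concentration metal concentration (g L^-1), vectorised, >= 0.
#' @param ic50 concentration of half-maximal growth inhibition (g L^-1), > 0.
#' @param h dimensionless Hill slope factor, > 0.
#' @return tolerance index values in (0, 1].
#' @examples
#' hill_ti(c(0, 10, 20), ic50 = 10, h = 2)
#' @export
hill_ti <- function(concentration, ic50, h) {
  check_scalar_num(ic50, "ic50", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  check_scalar_num(h, "h", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    ms_stop("`concentration` must be finite and >= 0", "domain_error")
  }
  1 / (1 + (concentration / ic50)^h)
}

#' Construct a plate tolerance dataset
#'
#' Bundles replicate colony diameters across metal concentrations for one
#' strain x metal x incubation day, together with the unamended control
#' diameters used to normalise the tolerance index.
#'
#' @param strain strain label.
#' @param metal `"AsV"` or `"CrVI"`.
#' @param day incubation day (any positive value).
#' @param conc concentration (g L^-1) per treated replicate row.
#' @param diameter colony diameter (mm) per treated replicate row, parallel
#'   to `conc`.
#' @param control_diameter replicate diameters (mm) at concentration 0.
#' @return object of class `tolerance_dataset`.
#' @export
tolerance_dataset <- function(strain, metal, day, conc, diameter,
                              control_diameter) {
  check_metal(metal)
  check_scalar_num(day, "day", lower = 0, strict_lower = TRUE,
                   class = "validation_error")
  if (length(conc) != length(diameter)) {
    ms_stop("`conc` and `diameter` must have equal length", "validation_error")
  }
  if (length(conc) > 0) {
    if (any(!is.finite(conc)) || any(conc <= 0)) {
      ms_stop("treated concentrations must be finite and > 0 (controls go in `control_diameter`)",
              "validation_error")
    }
    if (any(!is.finite(diameter)) || any(diameter < 0)) {
      ms_stop("diameters must be finite and >= 0", "validation_error")
    }
  }
  if (length(control_diameter) < 1L || any(!is.finite(control_diameter)) ||
      any(control_diameter < 0) || mean(control_diameter) <= 0) {
    ms_stop("control diameters must be non-negative with positive mean",
            "undefined_control_error")
  }
  structure(
    list(
      strain = as.character(strain), metal = metal, day = day,
      records = data.frame(conc = as.numeric(conc),
                           diameter = as.numeric(diameter)),
      control = as.numeric(control_diameter)
    ),
    class = "tolerance_dataset"
  )
}

#' @export
print.tolerance_dataset <- function(x, ...) {
  cat(sprintf("<tolerance_dataset> %s / %s / day %g\n", x$strain, x$metal, x$day))
  cat(sprintf("  %d treated replicates at %d concentrations; %d controls (mean %.1f mm)\n",
              nrow(x$records), length(unique(x$records$conc)),
              length(x$control), mean(x$control)))
  invisible(x)
}

# Per-replicate TI points: each treated diameter over the control mean.
ti_points <- function(dataset) {
  stopifnot(inherits(dataset, "tolerance_dataset"))
  data.frame(conc = dataset$records$conc,
             ti = dataset$records$diameter / mean(dataset$control))
}

# Residuals of the Hill model at log-parameters, over per-replicate TI points.
hill_resid <- function(logpar, conc, ti) {
  p <- exp(logpar)
  ti - 1 / (1 + (conc / p[1])^p[2])
}

hill_multistart <- function(conc, ti, lower, upper) {
  cs <- sort(unique(conc))
  ic50_starts <- unique(pmin(pmax(c(min(cs), exp(mean(log(cs))), max(cs)),
                                  exp(lower[1])), exp(upper[1])))
  h_starts <- c(0.5, 1, 2, 4)
  fits <- list()
  for (i0 in ic50_starts) {
    for (h0 in h_starts) {
      f <- ms_lsq(log(c(i0, h0)),
                  function(p) hill_resid(p, conc, ti),
                  lower = lower, upper = upper, maxiter = 300)
      if (!is.null(f) && is.finite(f$sse)) fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0L) {
    ms_stop("no multistart optimisation of the Hill model converged",
            "fit_failure_error")
  }
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  ic50s <- vapply(fits, function(f) exp(f$par[1]), numeric(1))
  # lowest SSE; ties broken toward the smallest IC50
  best <- order(sses, ic50s)[1L]
  fits[[best]]
}

#' Fit the Hill logistic dose-response model to a tolerance dataset
#'
#' Minimises the squared error between [hill_ti()] and the per-replicate
#' tolerance-index points over (IC50, h), in log-parameter space with box
#' bounds and a deterministic multistart grid (IC50 starts at the minimum,
#' geometric mean and maximum tested concentration; h starts at 0.5, 1, 2, 4).
#' The unamended control only normalises TI; it is not a fitted point. An
#' optional case-resampling bootstrap (replicates resampled within each
#' concentration, controls resampled too) gives a percentile confidence
#' interval for IC50.
#'
#' @param dataset a [tolerance_dataset()].
#' @param n_boot bootstrap resamples for the IC50 CI (0 disables the CI).
#' @param seed integer seed for the bootstrap (required when `n_boot > 0`).
#' @return object of class `hill_fit` with elements `ic50`, `h`, `ci_low`,
#'   `ci_high`, `r2` (clamped to \[0, 1\] with `r2_clamped` flag; raw value in
#'   `r2_raw`), `sse`, `extrapolated` (IC50 beyond the largest tested
#'   concentration), `n_points`, `converged`, and `no_growth` (sentinel when
#'   every TI is zero and IC50 is not estimable).
#' @examples
#' d <- simulate_tolerance(true_ic50 = 10, true_h = 2,
#'                         concentrations = c(2.5, 5, 7.5, 10, 12.5),
#'                         diameter_cv = 0, seed = 1)
#' fit_hill(d)
#' @export
fit_hill <- function(dataset, n_boot = 0, seed = NULL) {
  stopifnot(inherits(dataset, "tolerance_dataset"))
  pts <- ti_points(dataset)
  cs <- unique(pts$conc)
  if (length(cs) < 2L) {
    ms_stop("need >= 2 distinct concentrations with computable TI",
            "precondition_error")
  }
  if (n_boot > 0 && is.null(seed)) {
    ms_stop("a seed is required when `n_boot` > 0", "config_error")
  }
  sentinel <- function() {
    structure(
      list(ic50 = NA_real_, h = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           r2 = NA_real_, r2_raw = NA_real_, r2_clamped = FALSE, sse = NA_real_,
           extrapolated = FALSE, n_points = nrow(pts), converged = FALSE,
           no_growth = TRUE, n_boot = 0L,
           strain = dataset$strain, metal = dataset$metal, day = dataset$day),
      class = "hill_fit"
    )
  }
  # mirrors report-table "-" rows: no measurable growth at any concentration
  if (all(pts$ti < 1e-6)) return(sentinel())

  lower <- log(c(1e-3 * min(cs), 0.05))
  upper <- log(c(1e3 * max(cs), 20))
  best <- hill_multistart(pts$conc, pts$ti, lower, upper)
  est <- exp(best$par)
  sse <- best$sse
  sst <- sum((pts$ti - mean(pts$ti))^2)
  r2_raw <- if (sst > 0) 1 - sse / sst else NA_real_
  r2 <- if (is.na(r2_raw)) NA_real_ else min(max(r2_raw, 0), 1)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_preserved_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(b) {
        ctrl <- sample(dataset$control, replace = TRUE)
        idx <- unlist(lapply(split(seq_len(nrow(dataset$records)),
                                   dataset$records$conc),
                             function(i) sample(i, replace = TRUE)),
                      use.names = FALSE)
        conc_b <- dataset$records$conc[idx]
        ti_b <- dataset$records$diameter[idx] / mean(ctrl)
        # refit from the full-data optimum (cheap, stable for resamples)
        f <- ms_lsq(best$par, function(p) hill_resid(p, conc_b, ti_b),
                    lower = lower, upper = upper, maxiter = 300)
        if (is.null(f)) NA_real_ else exp(f$par[1])
      }, numeric(1))
      stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    })
  }

  structure(
    list(ic50 = est[1], h = est[2],
         ci_low = ci[1], ci_high = ci[2],
         r2 = r2, r2_raw = r2_raw,
         r2_clamped = isTRUE(!is.na(r2_raw) && r2_raw < 0),
         sse = sse,
         extrapolated = est[1] > max(cs),
         n_points = nrow(pts),
         converged = isTRUE(best$converged),
         no_growth = FALSE, n_boot = as.integer(n_boot),
         strain = dataset$strain, metal = dataset$metal, day = dataset$day),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> %s / %s / day %g\n", x$strain, x$metal, x$day))
  if (x$no_growth) {
    cat("  no growth at any tested concentration; IC50 not estimable\n")
    return(invisible(x))
  }
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (%.3g-%.3g)", x$ci_low, x$ci_high)
  cat(sprintf("  IC50 = %.4g%s, h = %.3g, r2 = %.3f, n = %d%s\n",
              x$ic50, ci, x$h, x$r2, x$n_points,
              if (x$extrapolated) "  [extrapolated beyond tested range]" else ""))
  invisible(x)
}

#' Fit Hill models to every strain x metal x day group of a plate table
#'
#' Splits a long-format plate table (see [read_plate_table()]) into groups,
#' builds a [tolerance_dataset()] per group (rows with `conc_g_per_L == 0`
#' are the controls), and fits each with [fit_hill()]. Failures in one group
#' are reported in its `status` column; the run continues.
#'
#' @param plates data frame with columns `strain, metal, day, conc_g_per_L,
#'   replicate, diameter_mm`.
#' @inheritParams fit_hill
#' @return data frame with one row per group: `strain, metal, day, ic50, h,
#'   ci_low, ci_high, r2, extrapolated, n_points, status` (`"ok"`,
#'   `"no_growth"`, or an error message).
#' @export
fit_hill_table <- function(plates, n_boot = 0, seed = NULL) {
  required <- c("strain", "metal", "day", "conc_g_per_L", "replicate",
                "diameter_mm")
  if (!all(required %in% names(plates))) {
    ms_stop(paste("plate table must have columns:",
                  paste(required, collapse = ", ")), "parse_error")
  }
  if (nrow(plates) == 0L) {
    ms_stop("plate table contains no rows", "no_data_error")
  }
  groups <- split(plates, interaction(plates$strain, plates$metal, plates$day,
                                      drop = TRUE))
  rows <- lapply(groups, function(g) {
    out <- data.frame(strain = g$strain[1], metal = g$metal[1], day = g$day[1],
                      ic50 = NA_real_, h = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, r2 = NA_real_, extrapolated = NA,
                      n_points = NA_integer_, status = "ok",
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      ctrl <- g$diameter_mm[g$conc_g_per_L == 0]
      trt <- g[g$conc_g_per_L > 0, , drop = FALSE]
      if (nrow(trt) == 0L) {
        # a table of only control rows carries no dose-response signal
        out$status <- "no_growth"
        out$n_points <- 0L
        return(out)
      }
      ds <- tolerance_dataset(g$strain[1], g$metal[1], g$day[1],
                              trt$conc_g_per_L, trt$diameter_mm, ctrl)
      fit_hill(ds, n_boot = n_boot, seed = seed)
    }, mycosorb_error = function(e) e)
    if (inherits(fit, "error")) {
      out$status <- conditionMessage(fit)
      return(out)
    }
    if (is.data.frame(fit)) return(fit)
    out$ic50 <- fit$ic50; out$h <- fit$h
    out$ci_low <- fit$ci_low; out$ci_high <- fit$ci_high
    out$r2 <- fit$r2; out$extrapolated <- fit$extrapolated
    out$n_points <- fit$n_points
    out$status <- if (fit$no_growth) "no_growth" else "ok"
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
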