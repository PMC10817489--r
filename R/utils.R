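# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All package errors carry a condition class so callers and tests can
#' distinguish, e.g., parameter-domain violations from fit failures.
#'
#' @param msg message text.
#' @param class condition class (in addition to `"mycosorb_error"`).
#' @param ... fields attached to the condition (diagnostics).
#' @noRd
ms_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mycosorb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ms_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "mycosorb_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code under a seed without disturbing the global RNG stream
#'
#' When `seed` is NULL the code runs on the current stream. Otherwise the
#' global `.Random.seed` is saved, the seed applied, and the previous state
#' restored on exit, so seeded package functions have no hidden side effects.
#'
#' @noRd
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Bounded Levenberg-Marquardt least squares from one start
#'
#' Thin wrapper over minpack.lm::nls.lm returning the solved parameters, the
#' SSE, and a convergence flag. `resid_fn` returns the residual vector; it
#' may return NULL (or non-finite values) to signal an infeasible point,
#' which is treated as a failed start by the caller.
#'
#' @noRd
ms_lsq <- function(start, resid_fn, lower, upper, maxiter = 150) {
  nres <- NULL
  safe_resid <- function(p) {
    r <- tryCatch(resid_fn(p), error = function(e) NULL)
    if (is.null(nres) && !is.null(r)) nres <<- length(r)
    if (is.null(r) || any(!is.finite(r))) {
      # large finite penalty keeps LM moving away from infeasible regions
      return(rep(1e6, nres %||% 1L))
    }
    r
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = safe_resid,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(par = fit$par, sse = fit$deviance,
       converged = fit$info %in% 1:4)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE,
                             class = "domain_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ms_stop(sprintf("`%s` must be a finite numeric scalar", name), class)
  }
  if (strict_lower && x <= lower) {
    ms_stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), class)
  }
  if (!strict_lower && x < lower) {
    ms_stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), class)
  }
  if (x > upper) {
    ms_stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), class)
  }
  invisible(x)
}

# Supported metal labels: pentavalent arsenic and hexavalent chromium oxyanions.
check_metal <- function(metal) {
  if (!is.character(metal) || length(metal) != 1L || !metal %in% c("AsV", "CrVI")) {
    ms_stop('`metal` must be "AsV" or "CrVI"', "validation_error")
  }
  metal
}
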