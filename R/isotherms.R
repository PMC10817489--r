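# Langmuir and Freundlich equilibrium isotherms and derived summary metrics.

#' Langmuir isotherm model
#'
#' Monolayer equilibrium model q_e = q_max K_L C_e / (1 + K_L C_e): a finite
#' number of homogeneous surface sites gives a maximum capacity `q_max`
#' (mg g^-1) approached with affinity `K_L` (L mg^-1).
#'
#' @param q_max maximum sorption capacity, mg per g sorbent dry matter, > 0.
#' @param K_L affinity constant, L mg^-1, > 0.
#' @return object of class `c("langmuir", "isotherm")`.
#' @examples
#' langmuir(q_max = 39.81, K_L = 0.1124)
#' @export
langmuir <- function(q_max, K_L) {
  check_scalar_num(q_max, "q_max", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  check_scalar_num(K_L, "K_L", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  structure(list(q_max = q_max, K_L = K_L),
            class = c("langmuir", "isotherm"))
}

#' Freundlich isotherm model
#'
#' Empirical power-law equilibrium model q_e = K_F C_e^(1/n). The exponent is
#' stored as `n` with the model using `1/n` (the conventional printed form).
#'
#' @param K_F Freundlich coefficient, (mg g^-1)(L mg^-1)^(1/n), > 0.
#' @param n dimensionless heterogeneity exponent, > 0.
#' @return object of class `c("freundlich", "isotherm")`.
#' @examples
#' freundlich(K_F = 3, n = 2)
#' @export
freundlich <- function(K_F, n) {
  check_scalar_num(K_F, "K_F", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  check_scalar_num(n, "n", lower = 0, strict_lower = TRUE,
                   class = "parameter_domain_error")
  structure(list(K_F = K_F, n = n),
            class = c("freundlich", "isotherm"))
}

#' @export
print.isotherm <- function(x, ...) {
  if (inherits(x, "langmuir")) {
    cat(sprintf("<langmuir> q_max = %.4g mg/g, K_L = %.4g L/mg\n",
                x$q_max, x$K_L))
  } else {
    cat(sprintf("<freundlich> K_F = %.4g, n = %.4g\n", x$K_F, x$n))
  }
  invisible(x)
}

#' Equilibrium loading predicted by an isotherm
#'
#' @param model an [langmuir()] or [freundlich()] object.
#' @param Ce equilibrium liquid concentration (mg L^-1), vectorised, >= 0.
#' @return equilibrium specific loading q_e (mg g^-1).
#' @export
isotherm_qe <- function(model, Ce) UseMethod("isotherm_qe")

#' @export
isotherm_qe.langmuir <- function(model, Ce) {
  if (any(!is.finite(Ce)) || any(Ce < 0)) {
    ms_stop("`Ce` must be finite and >= 0", "domain_error")
  }
  model$q_max * model$K_L * Ce / (1 + model$K_L * Ce)
}

#' @export
isotherm_qe.freundlich <- function(model, Ce) {
  if (any(!is.finite(Ce)) || any(Ce < 0)) {
    ms_stop("`Ce` must be finite and >= 0", "domain_error")
  }
  model$K_F * Ce^(1 / model$n)
}

#' @export
isotherm_qe.default <- function(model, Ce) {
  ms_stop("`model` is not an isotherm object", "type_error")
}

#' Langmuir equilibrium loading
#'
#' Thin typed wrapper over [isotherm_qe()] that rejects non-Langmuir models.
#'
#' @inheritParams isotherm_qe
#' @export
langmuir_qe <- function(Ce, model) {
  if (!inherits(model, "langmuir")) {
    ms_stop("`model` must be a Langmuir isotherm", "type_error")
  }
  isotherm_qe(model, Ce)
}

#' Freundlich equilibrium loading
#'
#' @inheritParams isotherm_qe
#' @export
freundlich_qe <- function(Ce, model) {
  if (!inherits(model, "freundlich")) {
    ms_stop("`model` must be a Freundlich isotherm", "type_error")
  }
  isotherm_qe(model, Ce)
}

#' Langmuir half-saturation concentration
#'
#' The equilibrium concentration at which loading equals q_max/2, i.e. the
#' reciprocal of the affinity constant K_L.
#'
#' @param K_L Langmuir affinity constant (L mg^-1), > 0.
#' @return half-saturation concentration, mg L^-1.
#' @examples
#' half_saturation(0.1124) # 8.90 mg/L
#' @export
half_saturation <- function(K_L) {
  check_scalar_num(K_L, "K_L", lower = 0, strict_lower = TRUE,
                   class = "domain_error")
  1 / K_L
}

#' Contribution of melanin to whole-cell sorption capacity
#'
#' Given the melanin mass fraction of the biomass and the maximum capacities
#' of extracted melanin and of whole cells, returns the percentage of the
#' whole-cell capacity attributable to the melanin fraction:
#' 100 * mel_fraction * qmax_mel / qmax_cell.
#'
#' @param mel_fraction g melanin per g biomass dry matter, in \[0, 1\].
#' @param qmax_mel maximum capacity of the melanin extract (mg g^-1), > 0.
#' @param qmax_cell maximum capacity of whole cells (mg g^-1), > 0.
#' @return percent contribution.
#' @examples
#' melanin_contribution(0.125, 544.84, 95.26) # 71.5 %
#' @export
melanin_contribution <- function(mel_fraction, qmax_mel, qmax_cell) {
  check_scalar_num(mel_fraction, "mel_fraction", lower = 0, upper = 1,
                   class = "domain_error")
  check_scalar_num(qmax_mel, "qmax_mel", lower = 0, strict_lower = TRUE,
                   class = "domain_error")
  check_scalar_num(qmax_cell, "qmax_cell", lower = 0, strict_lower = TRUE,
                   class = "domain_error")
  100 * mel_fraction * qmax_mel / qmax_cell
}
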