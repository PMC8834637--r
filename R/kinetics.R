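# Kinetic laws and Arrhenius temperature dependence: the shared mathematical
# kernel used by the simulator, the global fit and the downstream analyses.

#' Gas constant (J mol^-1 K^-1)
#'
#' Module-level physical constant used everywhere the Arrhenius relation is
#' evaluated. Activation energies are carried in kJ/mol and converted to
#' J/mol at the single point of use inside [arrhenius_k()].
#' @export
GAS_CONSTANT <- 8.314

# Kelvin offset; 273.15 exactly.
KELVIN_OFFSET <- 273.15

#' Specify a degradation model
#'
#' A model specification couples a kinetic law with the exposure axis the
#' data live on. Concentration may decline linearly with exposure
#' (zero-order), exponentially (first-order), or exponentially towards a
#' non-zero plateau (fractional conversion). The exposure axis is either
#' storage time in days (dark storage) or cumulative light dose in
#' megalux-hours (illuminated storage); the axis is metadata and never
#' changes the numerics.
#'
#' @param order One of `"zero"`, `"first"`, `"fractional"`.
#' @param axis One of `"time_days"`, `"dose_Mluxh"`.
#' @return An object of class `model_spec` with elements `order`, `axis` and
#'   `n_par` (3 for zero/first order, 4 for fractional conversion).
#' @examples
#' model_spec("fractional", "dose_Mluxh")
#' @export
model_spec <- function(order = c("zero", "first", "fractional"),
                       axis = c("time_days", "dose_Mluxh")) {
  order <- match.arg(order)
  axis <- match.arg(axis)
  structure(
    list(order = order, axis = axis,
         n_par = if (order == "fractional") 4L else 3L),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s-order kinetics on axis '%s' (%d parameters)\n",
              x$order, x$axis, x$n_par))
  invisible(x)
}

#' Kinetic parameter set
#'
#' Bundles the parameters of a degradation law: the initial concentration
#' `C0` (ug/g beverage), the rate constant `kref` at the reference
#' temperature `Tref` (default 25 degrees C), the Arrhenius activation
#' energy `Ea` in kJ/mol, and, for the fractional-conversion law only, the
#' plateau concentration `Cinf` (0 <= Cinf < C0).
#'
#' Units of `kref`: per day or per Mlux-h for first-order and fractional
#' conversion; ug/g per day or ug/g per Mlux-h for zero order. The unit
#' follows the model order and the exposure axis and is carried as metadata.
#'
#' @param C0 Initial concentration, ug/g, > 0.
#' @param kref Rate constant at `Tref`, > 0 (0 permitted for degenerate
#'   no-decay inputs in simulations).
#' @param Ea Activation energy, kJ/mol, >= 0.
#' @param Cinf Plateau concentration for fractional conversion, or `NULL`.
#' @param Tref Reference temperature, degrees C (default 25).
#' @return An object of class `param_set`.
#' @examples
#' param_set(C0 = 1.15, kref = 8.40e-2, Ea = 22.55)
#' @export
param_set <- function(C0, kref, Ea, Cinf = NULL, Tref = 25) {
  stopifnot(is.numeric(C0), is.numeric(kref), is.numeric(Ea),
            length(C0) == 1, length(kref) == 1, length(Ea) == 1)
  if (!all(is.finite(c(C0, kref, Ea, Tref)))) {
    stop("param_set: all parameters must be finite", call. = FALSE)
  }
  if (C0 <= 0) stop("param_set: C0 must be > 0", call. = FALSE)
  if (kref < 0) stop("param_set: kref must be >= 0", call. = FALSE)
  if (Ea < 0) stop("param_set: Ea must be >= 0", call. = FALSE)
  if (!is.null(Cinf)) {
    stopifnot(is.numeric(Cinf), length(Cinf) == 1, is.finite(Cinf))
    if (Cinf < 0 || Cinf >= C0) {
      stop("param_set: Cinf must satisfy 0 <= Cinf < C0", call. = FALSE)
    }
  }
  structure(list(C0 = C0, Cinf = Cinf, kref = kref, Ea = Ea, Tref = Tref),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> C0 = %g, kref = %g (Tref = %g degC), Ea = %g kJ/mol%s\n",
              x$C0, x$kref, x$Tref, x$Ea,
              if (is.null(x$Cinf)) "" else sprintf(", Cinf = %g", x$Cinf)))
  invisible(x)
}

#' Arrhenius rate constant at a temperature
#'
#' Evaluates `k(T) = kref * exp[(Ea/R) * (1/Tref_K - 1/T_K)]` with
#' temperatures converted to Kelvin internally (K = degC + 273.15) and
#' `Ea` converted from kJ/mol to J/mol. Strictly increasing in `T`
#' when `Ea > 0`; equals `kref` exactly at `T = Tref`.
#'
#' @param params A [param_set()].
#' @param temp_C Temperature(s), degrees C; must exceed absolute zero.
#' @return Rate constant(s) at `temp_C`, same units as `kref`. Vectorised
#'   over `temp_C`.
#' @examples
#' p <- param_set(C0 = 1.15, kref = 8.40e-2, Ea = 22.55)
#' arrhenius_k(p, 10) # ~5.19e-2 per day
#' @export
arrhenius_k <- function(params, temp_C) {
  stopifnot(inherits(params, "param_set"), is.numeric(temp_C))
  if (any(!is.finite(temp_C)) || any(temp_C <= -KELVIN_OFFSET)) {
    stop("arrhenius_k: temperature must be finite and above absolute zero",
         call. = FALSE)
  }
  tref_K <- params$Tref + KELVIN_OFFSET
  t_K <- temp_C + KELVIN_OFFSET
  ea_J <- params$Ea * 1000
  params$kref * exp((ea_J / GAS_CONSTANT) * (1 / tref_K - 1 / t_K))
}

#' Predict concentration under a kinetic law
#'
#' Evaluates the chosen degradation law at exposure `x` and temperature
#' `temp_C`, with the rate constant obtained from the Arrhenius relation.
#' The three laws are `Ct = C0 - k*t` (zero order),
#' `Ct = C0 * exp(-k*t)` (first order) and
#' `Ct = Cinf + (C0 - Cinf) * exp(-k*t)` (fractional conversion).
#'
#' Zero-order predictions are deliberately not clamped at zero: clamping
#' during fitting would bias residuals. Callers can check
#' `any(pred < 0)` themselves; [fit_one_step()] raises a warning when the
#' fitted zero-order curve goes negative inside the observed range.
#'
#' @param model A [model_spec()].
#' @param params A [param_set()]; `Cinf` required for fractional conversion.
#' @param temp_C Temperature, degrees C (scalar or same length as `x`).
#' @param x Exposure (days or Mlux-h), >= 0. Vectorised.
#' @return Predicted concentration(s), ug/g.
#' @examples
#' m <- model_spec("zero", "time_days")
#' p <- param_set(C0 = 1.07, kref = 0.30e-2, Ea = 0)
#' predict_conc(m, p, 10, 42) # 1.07 - 0.126 = 0.944
#' @export
predict_conc <- function(model, params, temp_C, x) {
  stopifnot(inherits(model, "model_spec"), inherits(params, "param_set"),
            is.numeric(x))
  if (any(x < 0)) stop("predict_conc: exposure must be >= 0", call. = FALSE)
  if (model$order == "fractional" && is.null(params$Cinf)) {
    stop("predict_conc: fractional conversion requires Cinf", call. = FALSE)
  }
  k <- arrhenius_k(params, temp_C)
  switch(model$order,
    zero = params$C0 - k * x,
    first = params$C0 * exp(-k * x),
    fractional = params$Cinf + (params$C0 - params$Cinf) * exp(-k * x)
  )
}
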