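# Shelf-storage analyses downstream of the kinetic fits: light-dose to
# retail-day conversion, re-expression of dose-axis rate constants per day,
# Welch comparison of rate constants (e.g., with vs without added ascorbic
# acid), ascorbic-acid/oxygen stoichiometry, and simple linear association
# diagnostics (e.g., dissolved oxygen vs carotenoid loss).

# Molar masses, g/mol.
MOLAR_MASS_AA <- 176.12
MOLAR_MASS_O2 <- 32.00

#' Retail lighting schedule
#'
#' @param illuminance Light level, lux (> 0). Default 600 lux, a typical
#'   supermarket shelf.
#' @param hours_per_day Daily illumination hours in (0, 24]. Default 12.
#' @return Object of class `light_schedule` with the derived `daily_dose_Mluxh`
#'   (`illuminance * hours_per_day * 1e-6`).
#' @export
light_schedule <- function(illuminance = 600, hours_per_day = 12) {
  stopifnot(illuminance > 0, hours_per_day > 0, hours_per_day <= 24)
  structure(list(illuminance = illuminance, hours_per_day = hours_per_day,
                 daily_dose_Mluxh = illuminance * hours_per_day * 1e-6),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %g lux, %g h/day (%g Mlux-h/day)\n",
              x$illuminance, x$hours_per_day, x$daily_dose_Mluxh))
  invisible(x)
}

#' Cumulative light dose after a number of retail days
#'
#' `dose = days * lux * hours_per_day * 1e-6` Mlux-h. Linear and exactly
#' invertible by [days_from_dose()].
#'
#' @param days Storage days, >= 0. Vectorised.
#' @param schedule A [light_schedule()].
#' @return Cumulative dose, Mlux-h.
#' @examples
#' dose_from_days(180, light_schedule(600, 12)) # 1.296 Mlux-h
#' @export
dose_from_days <- function(days, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"), all(days >= 0))
  days * schedule$daily_dose_Mluxh
}

#' Retail days required to accumulate a light dose
#'
#' Exact inverse of [dose_from_days()].
#'
#' @param dose Cumulative dose, Mlux-h, >= 0. Vectorised.
#' @param schedule A [light_schedule()].
#' @return Days.
#' @export
days_from_dose <- function(dose, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"), all(dose >= 0))
  dose / schedule$daily_dose_Mluxh
}

#' Re-express a dose-axis rate constant per retail day
#'
#' `k_day = k_dose * lux * hours_per_day * 1e-6`. Composing the day-axis
#' trajectory with [dose_from_days()] reproduces the dose-axis trajectory
#' exactly, for all three kinetic laws.
#'
#' @param k_dose Rate constant on the Mlux-h axis (per Mlux-h for
#'   first-order/fractional; ug/g per Mlux-h for zero order). Vectorised.
#' @param schedule A [light_schedule()].
#' @return Rate constant on the day axis.
#' @examples
#' rate_to_perday(2.44e-2, light_schedule(600, 12)) # 1.7568e-4 per day
#' @export
rate_to_perday <- function(k_dose, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"), is.numeric(k_dose))
  k_dose * schedule$daily_dose_Mluxh
}

#' Welch comparison of two rate constants
#'
#' Tests `k1 = k2` for two independently estimated rate constants with
#' standard errors, using `t = (k1 - k2)/sqrt(se1^2 + se2^2)` and
#' Welch-Satterthwaite degrees of freedom from the supplied per-fit
#' residual degrees of freedom. Two-sided p-value; significance flagged at
#' `alpha` (default 0.05).
#'
#' @param k1,se1,df1 First estimate, its standard error (> 0) and residual
#'   degrees of freedom (`m - p` of its fit). `df1`/`df2` are required.
#' @param k2,se2,df2 Second estimate, likewise.
#' @param alpha Significance level.
#' @return Object of class `rate_comparison`: list with `k1`, `se1`, `k2`,
#'   `se2`, `t_statistic`, `degrees_of_freedom`, `p_value`, `significant`.
#' @examples
#' compare_rates(1.70, 0.20, 24, 0.39, 0.01, 24)
#' @export
compare_rates <- function(k1, se1, df1, k2, se2, df2, alpha = 0.05) {
  if (missing(df1) || missing(df2) || is.null(df1) || is.null(df2) ||
      is.na(df1) || is.na(df2)) {
    stop("compare_rates: degrees of freedom for both estimates are required",
         call. = FALSE)
  }
  stopifnot(se1 > 0, se2 > 0, df1 >= 1, df2 >= 1)
  v1 <- se1^2; v2 <- se2^2
  t_stat <- (k1 - k2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / df1 + v2^2 / df2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(k1 = k1, se1 = se1, k2 = k2, se2 = se2,
                 t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p, alpha = alpha, significant = p <= alpha),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("<rate_comparison> k1 = %g +/- %g vs k2 = %g +/- %g\n",
              x$k1, x$se1, x$k2, x$se2))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.4g (%ssignificant at alpha = %g)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Ascorbic-acid / oxygen stoichiometric accounting
#'
#' Aerobic oxidation consumes 0.5 mol O2 per mol ascorbic acid (AA).
#' Given an observed AA loss (ug per g beverage) and an observed dissolved
#' oxygen loss (mg per L), converts both to mol/L (AA via the beverage
#' density), computes the O2 required by AA oxidation alone, and reports the
#' fraction of the observed O2 consumption attributable to it. A fraction
#' near 1 means essentially all consumed oxygen went into AA oxidation.
#'
#' @param delta_AA AA consumed, ug per g beverage, >= 0.
#' @param delta_O2 Dissolved O2 consumed, mg per L, >= 0.
#' @param density Beverage density, g/mL (default 1.0, bridging ug/g and
#'   mg/L for a dilute aqueous beverage).
#' @return Object of class `stoichiometry_result`: list with
#'   `moles_AA_consumed`, `moles_O2_required` (= 0.5 x AA), and
#'   `observed_O2_consumed` (mol/L each), and `fraction_attributable`.
#' @examples
#' aa_oxygen_fraction(delta_AA = 176.12, delta_O2 = 16) # fraction = 1
#' @export
aa_oxygen_fraction <- function(delta_AA, delta_O2, density = 1.0) {
  stopifnot(delta_AA >= 0, delta_O2 >= 0, density > 0)
  # ug/g * (g/mL) * 1000 mL/L = ug/L -> g/L -> mol/L
  mol_AA <- delta_AA * density * 1000 * 1e-6 / MOLAR_MASS_AA
  mol_O2_req <- 0.5 * mol_AA
  mol_O2_obs <- delta_O2 * 1e-3 / MOLAR_MASS_O2
  if (delta_AA == 0) {
    frac <- 0
  } else if (mol_O2_obs == 0) {
    stop("aa_oxygen_fraction: observed O2 consumption is zero with nonzero AA loss; fraction undefined",
         call. = FALSE)
  } else {
    frac <- mol_O2_req / mol_O2_obs
  }
  structure(list(moles_AA_consumed = mol_AA,
                 moles_O2_required = mol_O2_req,
                 observed_O2_consumed = mol_O2_obs,
                 fraction_attributable = frac),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("<stoichiometry_result> AA consumed = %.4g mol/L, O2 required = %.4g mol/L\n",
              x$moles_AA_consumed, x$moles_O2_required))
  cat(sprintf("  O2 observed = %.4g mol/L; fraction attributable to AA oxidation = %.3f\n",
              x$observed_O2_consumed, x$fraction_attributable))
  invisible(x)
}

#' Simple linear association between two series
#'
#' Ordinary least squares of `y` on `x` with a two-sided slope test; used
#' for diagnostics such as dissolved-oxygen content vs carotenoid loss.
#'
#' @param x,y Paired numeric series, >= 3 points; `x` must not be constant.
#' @return List with `slope`, `intercept`, `r2`, `r2adj`, `p_value`, `n`.
#' @examples
#' linear_association(0:3, c(1.0, 0.8, 0.7, 0.4))
#' @export
linear_association <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) {
    stop("linear_association: need at least 3 points", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("linear_association: x is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, r2adj = sm$adj.r.squared,
       p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
       n = length(x))
}
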