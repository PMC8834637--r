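# One-step (global) nonlinear least squares: all storage temperatures are
# fitted simultaneously with k(T) replaced by the Arrhenius expression, so
# the reference rate constant and activation energy are estimated directly.
# C0 (and the fractional-conversion plateau Cinf) are shared across
# temperatures. Optimisation uses bounded Levenberg-Marquardt least squares
# (minpack.lm) with a deterministic multi-start grid.

#' Control settings for the one-step fit
#'
#' @param n_starts Number of multi-start initialisations (>= 1). Starts are
#'   spread over log-spaced rate constants and activation energies between 5
#'   and 80 kJ/mol; starts beyond the first receive a small reproducible
#'   multiplicative jitter.
#' @param seed Seed for the multi-start jitter stream. The caller's RNG
#'   state is preserved.
#' @param ftol,ptol Relative convergence tolerances on the sum of squares
#'   and on the parameter step.
#' @param maxfev Maximum number of residual evaluations per start.
#' @param average_replicates If `TRUE`, replicate extractions at the same
#'   (temperature, exposure) point are averaged before fitting; the default
#'   keeps them as independent observations, preserving degrees of freedom.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 8L, seed = 20220207L,
                        ftol = 1e-10, ptol = 1e-10, maxfev = 10000L,
                        average_replicates = FALSE) {
  stopifnot(n_starts >= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 ftol = ftol, ptol = ptol, maxfev = as.integer(maxfev),
                 average_replicates = isTRUE(average_replicates)),
            class = "fit_control")
}

# Internal parameterisation: fractional conversion is optimised as
# (amplitude A = C0 - Cinf, Cinf, kref, Ea) so the constraint Cinf < C0
# becomes the box bound A > 0; other models use (C0, kref, Ea) directly.
.to_internal <- function(order, C0, kref, Ea, Cinf = NULL) {
  if (order == "fractional") c(A = C0 - Cinf, Cinf = Cinf, kref = kref, Ea = Ea)
  else c(C0 = C0, kref = kref, Ea = Ea)
}

.from_internal <- function(order, par, Tref) {
  if (order == "fractional") {
    param_set(C0 = unname(par["A"] + par["Cinf"]), kref = unname(par["kref"]),
              Ea = unname(par["Ea"]), Cinf = unname(par["Cinf"]), Tref = Tref)
  } else {
    param_set(C0 = unname(par["C0"]), kref = unname(par["kref"]),
              Ea = unname(par["Ea"]), Tref = Tref)
  }
}

.residual_fun <- function(order, temp_C, x, y, Tref) {
  tref_K <- Tref + KELVIN_OFFSET
  t_K <- temp_C + KELVIN_OFFSET
  inv_diff <- (1 / tref_K - 1 / t_K) * 1000 / GAS_CONSTANT # per kJ/mol
  if (order == "fractional") {
    function(par) {
      k <- par["kref"] * exp(par["Ea"] * inv_diff)
      y - (par["Cinf"] + par["A"] * exp(-k * x))
    }
  } else if (order == "first") {
    function(par) {
      k <- par["kref"] * exp(par["Ea"] * inv_diff)
      y - par["C0"] * exp(-k * x)
    }
  } else {
    function(par) {
      k <- par["kref"] * exp(par["Ea"] * inv_diff)
      y - (par["C0"] - k * x)
    }
  }
}

# Data-driven starting grid for (kref, Ea); C0 from exposure-0 mean,
# Cinf from 0.8 x the smallest observation.
.start_grid <- function(order, temp_C, x, y, Tref, control) {
  C0_init <- if (any(x == 0)) mean(y[x == 0]) else max(y)
  if (C0_init <= 0) C0_init <- max(y, 1e-6)
  Cinf_init <- max(min(y) * 0.8, 0)
  if (Cinf_init >= C0_init) Cinf_init <- 0.5 * C0_init
  x_max <- max(x[x > 0], 1)
  drop <- max(C0_init - min(y), 1e-4 * C0_init)
  k_base <- if (order == "zero") drop / x_max
            else max(-log(max(min(y), 1e-3 * C0_init) / C0_init), 1e-4) / x_max
  n <- control$n_starts
  k_mult <- if (n == 1) 1 else 10^seq(-1, 1, length.out = n)
  ea_grid <- if (n == 1) 25 else seq(5, 80, length.out = n)
  jit <- matrix(1, n, 2)
  if (n > 1) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(control$seed)
    jit[-1, ] <- exp(matrix(stats::rnorm(2 * (n - 1), 0, 0.05), n - 1, 2))
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  lapply(seq_len(n), function(i) {
    kref0 <- k_base * k_mult[i] * jit[i, 1]
    ea0 <- ea_grid[i] * jit[i, 2]
    .to_internal(order, C0 = C0_init, kref = kref0, Ea = ea0,
                 Cinf = if (order == "fractional") Cinf_init else NULL)
  })
}

.bounds <- function(order) {
  if (order == "fractional") {
    list(lower = c(A = 1e-12, Cinf = 0, kref = 0, Ea = 0),
         upper = c(A = Inf, Cinf = Inf, kref = Inf, Ea = Inf))
  } else {
    list(lower = c(C0 = 1e-12, kref = 0, Ea = 0),
         upper = c(C0 = Inf, kref = Inf, Ea = Inf))
  }
}

#' Fit a degradation model jointly across temperatures
#'
#' Minimises the sum over all temperatures, exposures and replicates of
#' squared deviations between observed concentrations and the kinetic law,
#' with the rate constant at each temperature substituted by the Arrhenius
#' relation. One `C0` (and, for fractional conversion, one `Cinf`) is shared
#' across temperatures. The fit is deterministic given the data and control
#' settings, and invariant to row order.
#'
#' Standard errors come from the linearised covariance `MSE * (J'J)^-1` at
#' the optimum; per-temperature rate constants and their standard errors are
#' derived from the fitted `(kref, Ea)` by the delta method.
#'
#' @param group A [study_table()] restricted to one
#'   (carotenoid, packaging, condition) group, on a single exposure axis.
#' @param model A [model_spec()] whose `axis` matches the table.
#' @param Tref Reference temperature, degrees C.
#' @param control A [fit_control()].
#' @return An object of class `kinfit`: list with `model`, `estimates`
#'   ([param_set()]), `se` (named vector), `covariance`,
#'   `k_by_temperature` (data frame: `temperature_C`, `k`, `se`),
#'   `SSQ`, `SEE`, `r2adj`, `runs_p`, `residuals`, `fitted`, `m`, `p`,
#'   `converged`, `n_iterations`, `ssq_trace` (per-iteration objective of
#'   the winning start, non-increasing) and `data`.
#' @export
fit_one_step <- function(group, model, Tref = 25, control = fit_control()) {
  stopifnot(inherits(group, "study_table"), inherits(model, "model_spec"),
            inherits(control, "fit_control"))
  if (model$axis != table_axis(group)) {
    stop("fit_one_step: model axis '", model$axis,
         "' does not match table axis '", table_axis(group), "'",
         call. = FALSE)
  }
  rep_df <- validate_design(group)
  if (nrow(rep_df) != 1) {
    stop("fit_one_step: table must contain exactly one (carotenoid, packaging, condition) group",
         call. = FALSE)
  }
  if (!rep_df$fittable) {
    stop("fit_one_step: group not fittable: ", rep_df$findings, call. = FALSE)
  }
  df <- as.data.frame(group)
  if (control$average_replicates) {
    agg <- stats::aggregate(concentration_ug_per_g ~ temperature_C + exposure,
                            data = df, FUN = mean)
    df <- agg
  }
  temp_C <- df$temperature_C
  x <- df$exposure
  y <- df$concentration_ug_per_g
  m <- length(y)
  p <- model$n_par
  if (m <= p) {
    stop("fit_one_step: need more observations (m = ", m,
         ") than parameters (p = ", p, ")", call. = FALSE)
  }
  fn <- .residual_fun(model$order, temp_C, x, y, Tref)
  starts <- .start_grid(model$order, temp_C, x, y, Tref, control)
  bnd <- .bounds(model$order)
  best <- NULL
  n_converged <- 0L
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = bnd$lower, upper = bnd$upper,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$ftol, ptol = control$ptol,
                           maxfev = control$maxfev, maxiter = 1024)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$info %in% 1:4 && is.finite(res$deviance)
    if (conv) n_converged <- n_converged + 1L
    if (is.finite(res$deviance) &&
        (is.null(best) || res$deviance < best$deviance)) {
      res$start_converged <- conv
      best <- res
    }
  }
  if (is.null(best)) {
    stop("fit_one_step: all ", length(starts), " starts failed", call. = FALSE)
  }
  if (n_converged == 0L) {
    stop("fit_one_step: no start converged after multi-start; best SSQ = ",
         format(best$deviance), " at par = ",
         paste(format(best$par), collapse = ", "), call. = FALSE)
  }
  par <- stats::setNames(as.numeric(best$par), names(best$par))
  est <- .from_internal(model$order, par, Tref)

  resid <- as.numeric(fn(par)) # fn returns y - pred = observed - fitted
  fitted <- y - resid
  SSQ <- sum(resid^2)
  stats_out <- fit_statistics(resid, y, p,
                              order_by = order(temp_C, x, df$replicate %||% seq_len(m)))

  # Linearised covariance in the reported (C0[,Cinf],kref,Ea) space.
  J <- .numeric_jacobian(fn, par)
  MSE <- SSQ / (m - p)
  cov_int <- tryCatch(MSE * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  dimnames(cov_int) <- list(names(par), names(par))
  if (model$order == "fractional") {
    # C0 = A + Cinf: linear map from internal to reported space
    L <- rbind(C0 = c(A = 1, Cinf = 1, kref = 0, Ea = 0),
               Cinf = c(0, 1, 0, 0), kref = c(0, 0, 1, 0), Ea = c(0, 0, 0, 1))
    cov_rep <- L %*% cov_int %*% t(L)
    dimnames(cov_rep) <- list(c("C0", "Cinf", "kref", "Ea"),
                              c("C0", "Cinf", "kref", "Ea"))
  } else {
    cov_rep <- cov_int
  }
  se <- sqrt(pmax(diag(cov_rep), 0))

  temps <- sort(unique(temp_C))
  k_tab <- .k_by_temperature(est, temps, cov_rep)

  neg_warn <- FALSE
  if (model$order == "zero" && any(fitted < 0)) {
    neg_warn <- TRUE
    warning("fit_one_step: zero-order predictions negative inside the observed range",
            call. = FALSE)
  }

  structure(list(
    model = model, estimates = est, se = se, covariance = cov_rep,
    k_by_temperature = k_tab, SSQ = SSQ, SEE = stats_out$SEE,
    r2adj = stats_out$r2adj, runs_p = stats_out$runs_p,
    residuals = resid, fitted = fitted, m = m, p = p,
    converged = TRUE, n_iterations = best$niter,
    ssq_trace = best$rsstrace, n_starts_converged = n_converged,
    negative_predictions = neg_warn, Tref = Tref,
    data = df, axis = model$axis
  ), class = "kinfit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.numeric_jacobian <- function(fn, par, eps = 1e-7) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-4)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  colnames(J) <- names(par)
  J
}

.k_by_temperature <- function(est, temps, cov_rep) {
  k <- arrhenius_k(est, temps)
  tref_K <- est$Tref + KELVIN_OFFSET
  inv_diff <- (1 / tref_K - 1 / (temps + KELVIN_OFFSET)) * 1000 / GAS_CONSTANT
  se_k <- rep(NA_real_, length(temps))
  if (all(c("kref", "Ea") %in% rownames(cov_rep)) &&
      all(is.finite(cov_rep[c("kref", "Ea"), c("kref", "Ea")]))) {
    for (i in seq_along(temps)) {
      g <- c(kref = k[i] / est$kref, Ea = k[i] * inv_diff[i])
      V <- cov_rep[c("kref", "Ea"), c("kref", "Ea")]
      se_k[i] <- sqrt(max(drop(t(g) %*% V %*% g), 0))
    }
  }
  data.frame(temperature_C = temps, k = k, se = se_k)
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("<kinfit> %s-order, axis %s, m = %d, p = %d\n",
              x$model$order, x$axis, x$m, x$p))
  est <- x$estimates
  lab <- c("C0", if (!is.null(est$Cinf)) "Cinf", "kref", "Ea")
  val <- c(est$C0, if (!is.null(est$Cinf)) est$Cinf, est$kref, est$Ea)
  for (i in seq_along(lab)) {
    cat(sprintf("  %-5s = %.6g +/- %.3g\n", lab[i], val[i],
                x$se[lab[i]]))
  }
  cat(sprintf("  SSQ = %.6g, SEE = %.6g, r2adj = %.4f, runs p = %.3f\n",
              x$SSQ, x$SEE, x$r2adj, x$runs_p))
  invisible(x)
}

#' Goodness-of-fit statistics
#'
#' Computes the adjusted coefficient of determination
#' `r2adj = 1 - [SSQ/(m-p)] / [SSQtot/(m-1)]` (with `SSQtot` about the grand
#' mean of all observations in the group), the standard error of estimate
#' `SEE = sqrt(SSQ/(m-p))`, and a Wald-Wolfowitz runs test on the signs of
#' the residuals ordered by exposure within temperature — a numerical
#' stand-in for visual residual-plot inspection.
#'
#' @param residuals Residuals (observed - fitted).
#' @param observed Observed values (same length).
#' @param p Number of fitted parameters; `m - p` must be positive.
#' @param order_by Optional permutation ordering residuals by exposure
#'   within temperature for the runs test; default keeps the given order.
#' @return List with `SSQ`, `SEE`, `r2adj`, `runs_p`.
#' @export
fit_statistics <- function(residuals, observed, p, order_by = NULL) {
  m <- length(observed)
  stopifnot(length(residuals) == m, m > p)
  SSQtot <- sum((observed - mean(observed))^2)
  if (SSQtot == 0) {
    stop("fit_statistics: all observations identical; r2adj undefined",
         call. = FALSE)
  }
  SSQ <- sum(residuals^2)
  SEE <- sqrt(SSQ / (m - p))
  r2adj <- 1 - (SSQ / (m - p)) / (SSQtot / (m - 1))
  ord <- order_by %||% seq_len(m)
  list(SSQ = SSQ, SEE = SEE, r2adj = r2adj,
       runs_p = runs_test(residuals[ord]))
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Two-sided normal-approximation p-value for randomness of the sign
#' sequence. Zero residuals are dropped. Returns `NA` when fewer than two
#' residuals of either sign remain (the test is uninformative).
#'
#' @param residuals Numeric vector in the order to be tested.
#' @return p-value, or `NA_real_`.
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 < 1 || n2 < 1) return(NA_real_)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  z <- (runs - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Fit candidate models and select one
#'
#' Fits each candidate by [fit_one_step()] and ranks converged fits by SEE
#' (ascending). Fractional conversion is preferred over its nested simpler
#' model (first order) only when it lowers SEE by at least `see_margin`
#' (relative) and its plateau estimate exceeds twice its standard error;
#' otherwise the best non-fractional candidate wins. SEE ties (relative
#' difference below `tie_tol`) are broken toward fewer parameters, then
#' toward zero order.
#'
#' @param group A single-group [study_table()].
#' @param candidates Character vector of model orders, or list of
#'   [model_spec()]s. Default: all three laws on the table's axis.
#' @param Tref Reference temperature, degrees C.
#' @param see_margin Relative SEE improvement required to accept the extra
#'   plateau parameter (default 0.05).
#' @param tie_tol Relative SEE difference below which candidates are treated
#'   as tied and parsimony decides (default 1e-3).
#' @param control A [fit_control()].
#' @return Object of class `model_comparison`: list with `fits` (named list
#'   of `kinfit`), `table` (ranking data frame), `selected` (model order
#'   name) and `selected_fit`.
#' @export
select_model <- function(group, candidates = c("zero", "first", "fractional"),
                         Tref = 25, see_margin = 0.05, tie_tol = 1e-3,
                         control = fit_control()) {
  axis <- table_axis(group)
  if (is.character(candidates)) {
    candidates <- lapply(candidates, model_spec, axis = axis)
  }
  names(candidates) <- vapply(candidates, function(m) m$order, character(1))
  fits <- list()
  errs <- character()
  for (nm in names(candidates)) {
    f <- tryCatch(
      suppressWarnings(fit_one_step(group, candidates[[nm]], Tref = Tref,
                                    control = control)),
      error = function(e) e)
    if (inherits(f, "kinfit")) fits[[nm]] <- f
    else errs <- c(errs, sprintf("%s: %s", nm, conditionMessage(f)))
  }
  if (!length(fits)) {
    stop("select_model: all candidate fits failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  tab <- data.frame(
    order = names(fits),
    p = vapply(fits, function(f) f$p, integer(1)),
    SSQ = vapply(fits, function(f) f$SSQ, numeric(1)),
    SEE = vapply(fits, function(f) f$SEE, numeric(1)),
    r2adj = vapply(fits, function(f) f$r2adj, numeric(1)),
    runs_p = vapply(fits, function(f) f$runs_p, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  prefer <- c(zero = 1L, first = 2L, fractional = 3L)
  see_min <- min(tab$SEE)
  tied <- tab$SEE <= see_min + tie_tol * max(see_min, .Machine$double.eps)
  cand_tab <- tab[tied, , drop = FALSE]
  cand_tab <- cand_tab[order(cand_tab$p, prefer[cand_tab$order]), , drop = FALSE]
  selected <- cand_tab$order[1]
  if (selected == "fractional") {
    fr <- fits[["fractional"]]
    simpler <- if ("first" %in% names(fits)) "first"
               else if ("zero" %in% names(fits)) "zero" else NA_character_
    if (!is.na(simpler)) {
      see_simple <- tab$SEE[tab$order == simpler]
      cinf_ok <- is.finite(fr$se["Cinf"]) &&
        fr$estimates$Cinf > 2 * fr$se["Cinf"]
      improved <- fr$SEE <= (1 - see_margin) * see_simple
      if (!(improved && cinf_ok)) {
        alt <- tab[tab$order != "fractional", , drop = FALSE]
        alt <- alt[order(alt$SEE, alt$p, prefer[alt$order]), , drop = FALSE]
        selected <- alt$order[1]
      }
    }
  }
  tab <- tab[order(tab$SEE), ]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, selected = selected,
                 selected_fit = fits[[selected]], errors = errs),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> selected:", x$selected, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Two-step diagnostic fit
#'
#' The classical alternative to one-step estimation: fits the kinetic law
#' separately at each temperature (own `C0` per temperature), then regresses
#' `ln k` on `(1/Tref_K - 1/T_K)` to recover `kref` (intercept) and `Ea`
#' (slope x R). Provided as a diagnostic cross-check; the package's
#' estimates come from [fit_one_step()].
#'
#' @inheritParams fit_one_step
#' @return List with `kref`, `Ea` (kJ/mol), `k_by_temperature` (data frame),
#'   and `arrhenius_r2` from the secondary regression.
#' @export
fit_two_step <- function(group, model, Tref = 25, control = fit_control()) {
  stopifnot(inherits(group, "study_table"), inherits(model, "model_spec"))
  df <- as.data.frame(group)
  temps <- sort(unique(df$temperature_C))
  if (length(temps) < 2) {
    stop("fit_two_step: need >=2 temperatures", call. = FALSE)
  }
  k_t <- vapply(temps, function(T) {
    d <- df[df$temperature_C == T, ]
    .fit_single_temperature(model$order, d$exposure, d$concentration_ug_per_g)
  }, numeric(1))
  if (any(k_t <= 0)) {
    stop("fit_two_step: non-positive per-temperature rate constant; ",
         "Arrhenius log-regression undefined", call. = FALSE)
  }
  tref_K <- Tref + KELVIN_OFFSET
  z <- 1 / tref_K - 1 / (temps + KELVIN_OFFSET)
  reg <- stats::lm(log(k_t) ~ z)
  list(kref = unname(exp(stats::coef(reg)[1])),
       Ea = unname(stats::coef(reg)[2] * GAS_CONSTANT / 1000),
       k_by_temperature = data.frame(temperature_C = temps, k = k_t),
       # suppress summary.lm's perfect-fit caveat: noiseless input is valid here
       arrhenius_r2 = suppressWarnings(summary(reg)$r.squared))
}

# Per-temperature fit of one kinetic law; returns the rate constant.
.fit_single_temperature <- function(order, x, y) {
  if (order == "zero") {
    return(-unname(stats::coef(stats::lm(y ~ x))[2]))
  }
  if (order == "first") {
    ypos <- pmax(y, 1e-9 * max(y))
    return(-unname(stats::coef(stats::lm(log(ypos) ~ x))[2]))
  }
  # fractional: small bounded LM fit of (A, Cinf, k)
  C0_init <- if (any(x == 0)) mean(y[x == 0]) else max(y)
  st <- c(A = max(C0_init - min(y), 1e-3), Cinf = max(min(y) * 0.8, 0),
          k = max(1 / max(x[x > 0]), 1e-4))
  fn <- function(par) y - (par["Cinf"] + par["A"] * exp(-par["k"] * x))
  res <- minpack.lm::nls.lm(par = st, lower = c(1e-12, 0, 0),
                            upper = c(Inf, Inf, Inf), fn = fn)
  unname(res$par["k"])
}
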