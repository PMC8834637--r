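# Synthetic-data generator: concentration tables with the statistical
# structure the analysis assumes (multi-temperature design, replicate
# extractions, additive Gaussian noise), so every stage of the pipeline is
# testable without the original deposited data.

#' Noise specification for simulated observations
#'
#' Additive Gaussian noise, either with an absolute standard deviation or
#' relative to the initial concentration C0 (default: 2% of C0, a
#' realistic replicate-extraction scatter for HPLC carotenoid
#' quantification). Draws are truncated at 0, since concentrations cannot
#' be negative.
#'
#' @param mode `"relative_to_C0"` or `"absolute"`.
#' @param sd Standard deviation (> 0): a fraction of C0 in relative mode,
#'   ug/g in absolute mode.
#' @param seed Integer seed; the same seed yields an identical table.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("relative_to_C0", "absolute"), sd = 0.02,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(sd) || sd <= 0) {
    stop("noise_spec: sd must be > 0 (use generate_study(noise = NULL) for noiseless data)",
         call. = FALSE)
  }
  structure(list(mode = mode, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic concentration table
#'
#' Simulates `concentration = predict_conc(model, truth, T, x) + e`,
#' `e ~ N(0, sd^2)` i.i.d., truncated at 0, over a multi-temperature
#' [study_design()]. The caller's RNG state is preserved; the same
#' `noise$seed` reproduces the identical table. The truth parameters are
#' attached as attribute `"truth"` for recovery tests.
#'
#' @param model A [model_spec()].
#' @param truth A [param_set()] valid for the model.
#' @param design A [study_design()].
#' @param noise A [noise_spec()], or `NULL` for noiseless data.
#' @param carotenoid,packaging,condition Labels for the generated group.
#'   `condition` defaults to the one implied by the model axis.
#' @return A [study_table()] with attribute `truth`.
#' @export
generate_study <- function(model, truth, design, noise = noise_spec(),
                           carotenoid = "synthetic", packaging = "glass",
                           condition = NULL) {
  stopifnot(inherits(model, "model_spec"), inherits(truth, "param_set"),
            inherits(design, "study_design"))
  if (model$order == "fractional" && is.null(truth$Cinf)) {
    stop("generate_study: fractional-conversion truth requires Cinf",
         call. = FALSE)
  }
  if (is.null(condition)) {
    condition <- if (model$axis == "time_days") "dark" else "illuminated"
  }
  rows <- list()
  for (i in seq_along(design$temperatures)) {
    T <- design$temperatures[i]
    grid <- design$exposure_grid[[i]]
    for (x in grid) {
      for (r in seq_len(design$replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          carotenoid = carotenoid, packaging = packaging,
          condition = condition, temperature_C = T, exposure = x,
          exposure_unit = AXIS_UNIT[[model$axis]], replicate = r,
          concentration_ug_per_g = predict_conc(model, truth, T, x),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    sd_abs <- if (noise$mode == "relative_to_C0") noise$sd * truth$C0 else noise$sd
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(noise$seed)
    eps <- stats::rnorm(nrow(df), 0, sd_abs)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    df$concentration_ug_per_g <- pmax(df$concentration_ug_per_g + eps, 0)
  }
  out <- study_table(df, axis = model$axis)
  attr(out, "truth") <- truth
  attr(out, "truth_model") <- model
  out
}

#' Truth parameters attached to a generated table
#' @param table A table from [generate_study()] or [make_paper_fixture()].
#' @return The [param_set()] used as truth (or a named list of them for
#'   multi-group fixtures).
#' @export
study_truth <- function(table) attr(table, "truth")

#' The reference multi-temperature storage design
#'
#' Dark storage: 10 and 20 degC sampled over 42 days, 35 and 45 degC over
#' 36 days, seven evenly spaced sampling points from day 0, duplicate
#' extractions. Illuminated storage: four temperatures, seven dose points
#' from 0 to 1.3 Mlux-h, duplicates.
#'
#' @param scenario `"dark"` or `"illuminated"`.
#' @param replicates Replicate extractions per point (default 2).
#' @return A [study_design()].
#' @export
reference_design <- function(scenario = c("dark", "illuminated"),
                             replicates = 2L) {
  scenario <- match.arg(scenario)
  if (scenario == "dark") {
    study_design(
      temperatures = c(10, 20, 35, 45),
      exposure_grid = list(`10` = seq(0, 42, length.out = 7),
                           `20` = seq(0, 42, length.out = 7),
                           `35` = seq(0, 36, length.out = 7),
                           `45` = seq(0, 36, length.out = 7)),
      replicates = replicates)
  } else {
    study_design(
      temperatures = c(10, 20, 35, 45),
      exposure_grid = seq(0, 1.3, length.out = 7),
      replicates = replicates)
  }
}

#' Simulate the full reference storage study
#'
#' Generates a synthetic table for one or more carotenoids under the
#' reference design ([reference_design()]), with truth parameters taken
#' from the published estimates ([carotenoid_params()]) for the requested
#' scenario and packaging. Fractional-conversion truths use
#' `Cinf = cinf_frac * C0` (default 0.6) since no plateau value is
#' published.
#'
#' @param scenario `"dark"` or `"illuminated"`.
#' @param packaging `"glass"`, `"PET"`, or `"both"`.
#' @param noise A [noise_spec()] or `NULL` for noiseless data. Each group
#'   gets an independent reproducible stream derived from `noise$seed`.
#' @param carotenoids Carotenoid names to include (default: all five).
#' @param cinf_frac Plateau fraction of C0 for fractional-conversion truths.
#' @return A [study_table()]; attribute `truth` is a named list
#'   (`carotenoid/packaging`) of [param_set()]s, `truth_order` the matching
#'   model orders.
#' @export
make_paper_fixture <- function(scenario = c("dark", "illuminated"),
                               packaging = "glass", noise = noise_spec(),
                               carotenoids = NULL, cinf_frac = 0.6) {
  scenario <- match.arg(scenario)
  packs <- if (identical(packaging, "both")) c("glass", "PET") else packaging
  stopifnot(all(packs %in% c("glass", "PET")))
  design <- reference_design(scenario)
  params <- carotenoid_params(condition = scenario)
  params <- params[params$packaging %in% packs, ]
  if (!is.null(carotenoids)) {
    params <- params[params$carotenoid %in% carotenoids, ]
    if (nrow(params) == 0) {
      stop("make_paper_fixture: no parameters for requested carotenoid(s)",
           call. = FALSE)
    }
  }
  axis <- if (scenario == "dark") "time_days" else "dose_Mluxh"
  tabs <- list()
  truths <- list()
  orders <- list()
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    truth <- param_set(
      C0 = row$C0, kref = row$kref, Ea = row$Ea,
      Cinf = if (row$order == "fractional") cinf_frac * row$C0 else NULL,
      Tref = row$Tref)
    model <- model_spec(row$order, axis)
    grp_noise <- noise
    if (!is.null(noise)) {
      # independent reproducible stream per (seed, group)
      grp_noise <- noise_spec(noise$mode, noise$sd,
                              seed = noise$seed + 1000L * i)
    }
    key <- paste(row$carotenoid, row$packaging, sep = "/")
    tabs[[key]] <- generate_study(model, truth, design, grp_noise,
                                  carotenoid = row$carotenoid,
                                  packaging = row$packaging,
                                  condition = scenario)
    truths[[key]] <- truth
    orders[[key]] <- row$order
  }
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  out <- study_table(df, axis = axis)
  attr(out, "truth") <- truths
  attr(out, "truth_order") <- orders
  out
}
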