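# Observation data model: a long-format table of concentration measurements
# on a time (dark storage) or light-dose (illuminated storage) axis, with a
# fixed CSV dialect for interchange.

STUDY_COLUMNS <- c("carotenoid", "packaging", "condition", "temperature_C",
                   "exposure", "exposure_unit", "replicate",
                   "concentration_ug_per_g")

AXIS_UNIT <- c(time_days = "day", dose_Mluxh = "Mlux_h")

#' Construct a study table of concentration observations
#'
#' A `study_table` is a data frame with one row per measurement and the
#' columns `carotenoid`, `packaging` ("glass" or "PET"), `condition`
#' ("dark" or "illuminated"), `temperature_C`, `exposure` (days or Mlux-h
#' according to `axis`), `exposure_unit` ("day" or "Mlux_h"), `replicate`
#' (positive integer) and `concentration_ug_per_g`. Validation enforces
#' non-negative concentrations and exposures, a physically sane temperature
#' range, and a uniform exposure unit consistent with the declared axis.
#'
#' @param df Data frame with the columns above (`exposure_unit` optional —
#'   filled from `axis` when absent).
#' @param axis `"time_days"` or `"dose_Mluxh"`.
#' @param temp_range Permitted temperature range, degrees C.
#' @return The validated data frame with class `study_table` and attribute
#'   `axis`.
#' @export
study_table <- function(df, axis = c("time_days", "dose_Mluxh"),
                        temp_range = c(-20, 100)) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"exposure_unit" %in% names(df)) {
    df$exposure_unit <- rep(AXIS_UNIT[[axis]], nrow(df))
  }
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("study_table: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[STUDY_COLUMNS]
  df$carotenoid <- as.character(df$carotenoid)
  df$packaging <- as.character(df$packaging)
  df$condition <- as.character(df$condition)
  df$exposure_unit <- as.character(df$exposure_unit)
  for (col in c("temperature_C", "exposure", "concentration_ug_per_g")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$replicate <- as.integer(df$replicate)
  .validate_rows(df, axis, temp_range)
  structure(df, axis = axis, class = c("study_table", "data.frame"))
}

.validate_rows <- function(df, axis, temp_range) {
  if (nrow(df) == 0) return(invisible(TRUE))
  bad <- which(!df$packaging %in% c("glass", "PET"))
  if (length(bad)) {
    stop("study_table: invalid packaging at row ", bad[1], call. = FALSE)
  }
  bad <- which(!df$condition %in% c("dark", "illuminated"))
  if (length(bad)) {
    stop("study_table: invalid condition at row ", bad[1], call. = FALSE)
  }
  bad <- which(is.na(df$concentration_ug_per_g) | df$concentration_ug_per_g < 0)
  if (length(bad)) {
    stop("study_table: negative or missing concentration at row ", bad[1],
         call. = FALSE)
  }
  bad <- which(is.na(df$exposure) | df$exposure < 0)
  if (length(bad)) {
    stop("study_table: negative or missing exposure at row ", bad[1],
         call. = FALSE)
  }
  bad <- which(is.na(df$temperature_C) | df$temperature_C < temp_range[1] |
                 df$temperature_C > temp_range[2])
  if (length(bad)) {
    stop("study_table: temperature outside [", temp_range[1], ", ",
         temp_range[2], "] degC at row ", bad[1], call. = FALSE)
  }
  bad <- which(is.na(df$replicate) | df$replicate < 1)
  if (length(bad)) {
    stop("study_table: replicate must be a positive integer (row ", bad[1], ")",
         call. = FALSE)
  }
  expected_unit <- AXIS_UNIT[[axis]]
  bad <- which(df$exposure_unit != expected_unit)
  if (length(bad)) {
    stop("study_table: exposure_unit '", df$exposure_unit[bad[1]],
         "' at row ", bad[1], " does not match axis '", axis,
         "' (expected '", expected_unit, "')", call. = FALSE)
  }
  key <- paste(df$carotenoid, df$packaging, df$condition, df$temperature_C,
               df$exposure, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("study_table: duplicate (group, temperature, exposure, replicate) key at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Axis of a study table
#' @param table A [study_table()].
#' @return `"time_days"` or `"dose_Mluxh"`.
#' @export
table_axis <- function(table) {
  stopifnot(inherits(table, "study_table"))
  attr(table, "axis")
}

#' Read concentration observations from CSV
#'
#' Reads the fixed CSV dialect (UTF-8, header mandatory, decimal point) into
#' a validated [study_table()]. The per-file `exposure_unit` column is
#' cross-checked against the declared axis so that dark-storage (days) and
#' illuminated-storage (Mlux-h) tables can never silently mix.
#'
#' @param path Path to a CSV file.
#' @param axis `"time_days"` or `"dose_Mluxh"`.
#' @return A [study_table()]; row order preserved.
#' @export
read_observations <- function(path, axis = c("time_days", "dose_Mluxh")) {
  axis <- match.arg(axis)
  if (!file.exists(path)) {
    stop("read_observations: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, fileEncoding = "UTF-8")
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("read_observations: CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  study_table(df, axis = axis)
}

#' Write a study table to CSV
#'
#' Values round-trip at full double precision (15 significant digits), so
#' `read_observations(write_observations(x))` reproduces `x` exactly.
#'
#' @param table A [study_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  df <- as.data.frame(table)
  for (col in c("temperature_C", "exposure", "concentration_ug_per_g")) {
    df[[col]] <- format(df[[col]], digits = 15, scientific = FALSE, trim = TRUE)
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("write_observations: cannot write to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Describe a multi-temperature storage design
#'
#' @param temperatures Storage temperatures, degrees C.
#' @param exposure_grid Either a single numeric vector of exposures applied
#'   at every temperature, or a named list with one strictly increasing grid
#'   per temperature. Every grid must start at 0 (baseline sample).
#' @param replicates Number of replicate extractions per design point.
#' @return An object of class `study_design`.
#' @export
study_design <- function(temperatures, exposure_grid, replicates = 2L) {
  stopifnot(is.numeric(temperatures), length(temperatures) >= 1,
            replicates >= 1)
  if (!is.list(exposure_grid)) {
    exposure_grid <- stats::setNames(
      rep(list(as.numeric(exposure_grid)), length(temperatures)),
      as.character(temperatures))
  }
  if (length(exposure_grid) != length(temperatures)) {
    stop("study_design: one exposure grid per temperature required",
         call. = FALSE)
  }
  for (g in exposure_grid) {
    if (g[1] != 0) stop("study_design: first exposure must be 0", call. = FALSE)
    if (any(diff(g) <= 0)) {
      stop("study_design: exposure grid must be strictly increasing",
           call. = FALSE)
    }
  }
  structure(list(temperatures = as.numeric(temperatures),
                 exposure_grid = exposure_grid,
                 replicates = as.integer(replicates)),
            class = "study_design")
}

#' Validate the study structure of a table
#'
#' Labels each (carotenoid, packaging, condition) group fittable or
#' unfittable for a global Arrhenius regression: a fittable group has at
#' least two distinct temperatures with at least three exposure points each.
#' Groups without a baseline (exposure 0) observation draw a warning
#' finding. Purely a reporting operation — the table is never modified.
#'
#' @param table A [study_table()].
#' @return A data frame of class `design_report` with one row per group and
#'   columns `carotenoid`, `packaging`, `condition`, `n_obs`,
#'   `n_temperatures`, `min_exposures`, `n_replicates`, `fittable`,
#'   `findings` (semicolon-joined strings; empty when clean).
#' @export
validate_design <- function(table) {
  stopifnot(inherits(table, "study_table"))
  df <- as.data.frame(table)
  if (nrow(df) == 0) {
    rep0 <- data.frame(carotenoid = character(), packaging = character(),
                       condition = character(), n_obs = integer(),
                       n_temperatures = integer(), min_exposures = integer(),
                       n_replicates = integer(), fittable = logical(),
                       findings = character(), stringsAsFactors = FALSE)
    class(rep0) <- c("design_report", "data.frame")
    return(rep0)
  }
  key <- interaction(df$carotenoid, df$packaging, df$condition, drop = TRUE)
  groups <- split(df, key)
  rows <- lapply(groups, function(g) {
    temps <- unique(g$temperature_C)
    n_exp <- vapply(split(g$exposure, g$temperature_C),
                    function(e) length(unique(e)), integer(1))
    findings <- character()
    fittable <- TRUE
    if (length(temps) < 2) {
      fittable <- FALSE
      findings <- c(findings, "Arrhenius needs >=2 temperatures")
    }
    if (any(n_exp < 3)) {
      fittable <- FALSE
      findings <- c(findings, ">=3 exposure points per temperature required")
    }
    if (!any(g$exposure == 0)) {
      findings <- c(findings, "no time-0 observation")
    }
    data.frame(carotenoid = g$carotenoid[1], packaging = g$packaging[1],
               condition = g$condition[1], n_obs = nrow(g),
               n_temperatures = length(temps), min_exposures = min(n_exp),
               n_replicates = max(g$replicate), fittable = fittable,
               findings = paste(findings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("design_report", "data.frame")
  out
}

#' Extract a single fitting group from a study table
#'
#' @param table A [study_table()].
#' @param carotenoid,packaging,condition Group key values; `NULL` keeps all.
#' @return A [study_table()] restricted to the matching rows.
#' @export
subset_group <- function(table, carotenoid = NULL, packaging = NULL,
                         condition = NULL) {
  stopifnot(inherits(table, "study_table"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(carotenoid)) keep <- keep & table$carotenoid == carotenoid
  if (!is.null(packaging)) keep <- keep & table$packaging == packaging
  if (!is.null(condition)) keep <- keep & table$condition == condition
  study_table(as.data.frame(table)[keep, , drop = FALSE],
              axis = table_axis(table))
}
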