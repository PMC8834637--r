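# Published one-step kinetic parameter estimates for the five all-trans
# carotenoids of a pumpkin-coloured beverage, per packaging and storage
# condition (Tref = 25 degC). These serve as default truth values for the
# synthetic-data generator and as inputs to Arrhenius re-expression.
#
# Units of kref: dark axis is days (per day for fractional conversion,
# ug/g per day for zero order); illuminated axis is Mlux-h (per Mlux-h,
# or ug/g per Mlux-h for zero order). Cinf is never published; the
# fractional-conversion default Cinf = 0.6 * C0 reflects the ~36-38% final
# beta-carotene loss observed at the warmer dark-storage temperatures.

.CAROTENOID_PARAMS <- local({
  rows <- rbind(
    # condition, packaging, carotenoid, order, C0, kref(x1e-2), Ea, se_kref(x1e-2), se_Ea
    c("dark", "glass", "beta-carotene",  "fractional", 1.22, 7.50, 15.13, 1.10, 3.44),
    c("dark", "PET",   "beta-carotene",  "fractional", 1.15, 8.40, 22.55, 2.00, 6.91),
    c("dark", "glass", "antheraxanthin", "zero",       1.07, 0.64, 35.48, 0.06, 3.53),
    c("dark", "PET",   "antheraxanthin", "zero",       1.04, 0.78, 35.23, 0.13, 6.50),
    c("dark", "glass", "lutein",         "zero",       0.59, 0.28, 26.75, 0.01, 3.74),
    c("dark", "PET",   "lutein",         "zero",       0.59, 0.31, 41.16, 0.08, 9.67),
    c("dark", "glass", "violaxanthin",   "zero",       0.10, 0.07, 19.48, 0.01, 3.81),
    c("dark", "PET",   "violaxanthin",   "zero",       0.10, 0.11, 22.85, 0.01, 4.08),
    c("dark", "glass", "neoxanthin",     "zero",       0.10, 0.07, 12.88, 0.01, 3.31),
    c("dark", "PET",   "neoxanthin",     "zero",       0.10, 0.10, 26.20, 0.01, 3.95),
    c("illuminated", "glass", "beta-carotene",  "fractional", 1.19, 3.68, 19.25, 0.29, 2.58),
    c("illuminated", "PET",   "beta-carotene",  "fractional", 1.16, 3.69, 17.43, 0.35, 3.14),
    c("illuminated", "glass", "antheraxanthin", "fractional", 1.08, 3.79, 16.20, 0.33, 2.87),
    c("illuminated", "PET",   "antheraxanthin", "fractional", 1.06, 3.51, 11.50, 0.44, 3.94),
    c("illuminated", "glass", "lutein",         "first",      0.64, 1.21,  7.86, 0.03, 1.21),
    c("illuminated", "PET",   "lutein",         "first",      0.67, 1.50,  8.36, 0.04, 1.52),
    c("illuminated", "glass", "violaxanthin",   "first",      0.10, 2.49, 22.94, 0.11, 3.58),
    c("illuminated", "PET",   "violaxanthin",   "first",      0.10, 3.25, 27.90, 0.10, 3.96),
    c("illuminated", "glass", "neoxanthin",     "first",      0.09, 3.29, 21.44, 0.17, 3.97),
    c("illuminated", "PET",   "neoxanthin",     "first",      0.09, 3.43, 22.42, 0.17, 3.91)
  )
  df <- data.frame(condition = rows[, 1], packaging = rows[, 2],
                   carotenoid = rows[, 3], order = rows[, 4],
                   C0 = as.numeric(rows[, 5]),
                   kref = as.numeric(rows[, 6]) * 1e-2,
                   Ea = as.numeric(rows[, 7]),
                   se_kref = as.numeric(rows[, 8]) * 1e-2,
                   se_Ea = as.numeric(rows[, 9]),
                   stringsAsFactors = FALSE)
  df$Tref <- 25
  df
})

#' Published kinetic parameters for the five beverage carotenoids
#'
#' Returns the one-step parameter estimates (C0, kref, Ea with standard
#' errors; Tref = 25 degrees C) for all-trans beta-carotene,
#' antheraxanthin, lutein, violaxanthin and neoxanthin per storage
#' condition and packaging. The dark-storage axis is days; the illuminated
#' axis is cumulative light dose in Mlux-h. These values are the default
#' truth parameters of [make_paper_fixture()].
#'
#' @param condition Optional filter: `"dark"` or `"illuminated"`.
#' @param packaging Optional filter: `"glass"` or `"PET"`.
#' @param carotenoid Optional filter by carotenoid name.
#' @return Data frame with columns `condition`, `packaging`, `carotenoid`,
#'   `order`, `C0`, `kref`, `Ea`, `se_kref`, `se_Ea`, `Tref`.
#' @export
carotenoid_params <- function(condition = NULL, packaging = NULL,
                              carotenoid = NULL) {
  df <- .CAROTENOID_PARAMS
  if (!is.null(condition)) df <- df[df$condition == condition, ]
  if (!is.null(packaging)) df <- df[df$packaging == packaging, ]
  if (!is.null(carotenoid)) df <- df[df$carotenoid == carotenoid, ]
  rownames(df) <- NULL
  df
}
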