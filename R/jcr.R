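# F-based joint confidence regions for (kref, Ea): the set of parameter
# pairs whose residual sum of squares stays below an F-scaled multiple of
# the minimum SSQ. Contours are extracted by marching squares on an SSQ
# grid; overlap between two regions is decided on the contour polygons.

#' SSQ threshold of a joint confidence region
#'
#' `threshold = SSQ_min * [1 + (p/(m-p)) * F(p, m-p, 1-phi)]`, where `F` is
#' the upper `1-phi` quantile of the F distribution, `p` the number of
#' simultaneously estimated parameters and `m` the number of observations.
#' Parameter vectors whose SSQ does not exceed the threshold belong to the
#' `100*(1-phi)%` joint confidence region.
#'
#' @param ssq_min Minimum (least-squares) SSQ, >= 0.
#' @param p Number of simultaneously estimated parameters (>= 1).
#' @param m Number of observations (> p).
#' @param phi Confidence complement in (0, 1); 0.10 gives a 90% region.
#' @return The SSQ threshold.
#' @examples
#' jcr_threshold(1, p = 2, m = 14, phi = 0.10) # 1.4678
#' @export
jcr_threshold <- function(ssq_min, p, m, phi = 0.10) {
  stopifnot(ssq_min >= 0, p >= 1, phi > 0, phi < 1)
  if (m <= p) stop("jcr_threshold: m must exceed p", call. = FALSE)
  ssq_min * (1 + (p / (m - p)) * stats::qf(1 - phi, p, m - p))
}

# SSQ as a function of (kref, Ea) with nuisance parameters either fixed at
# the least-squares optimum or re-minimised (profiled). Profiling exploits
# that all three laws are linear in their concentration parameters given
# (kref, Ea): zero order in C0; first order in C0; fractional in (A, Cinf).
.ssq_evaluator <- function(fit, nuisance_mode = c("fixed_at_optimum", "profiled")) {
  nuisance_mode <- match.arg(nuisance_mode)
  df <- fit$data
  x <- df$exposure
  y <- df$concentration_ug_per_g
  tref_K <- fit$Tref + KELVIN_OFFSET
  inv_diff <- (1 / tref_K - 1 / (df$temperature_C + KELVIN_OFFSET)) *
    1000 / GAS_CONSTANT
  order <- fit$model$order
  est <- fit$estimates
  function(kref, Ea) {
    k <- kref * exp(Ea * inv_diff)
    if (order == "zero") {
      if (nuisance_mode == "fixed_at_optimum") {
        return(sum((y - (est$C0 - k * x))^2))
      }
      C0 <- max(mean(y + k * x), 1e-12)
      return(sum((y - (C0 - k * x))^2))
    }
    e <- exp(-k * x)
    if (order == "first") {
      if (nuisance_mode == "fixed_at_optimum") {
        return(sum((y - est$C0 * e)^2))
      }
      C0 <- max(sum(y * e) / sum(e^2), 1e-12)
      return(sum((y - C0 * e)^2))
    }
    # fractional: y ~ Cinf * (1 - e) + C0 * e with 0 <= Cinf < C0
    if (nuisance_mode == "fixed_at_optimum") {
      return(sum((y - (est$Cinf + (est$C0 - est$Cinf) * e))^2))
    }
    X <- cbind(e, 1 - e)
    beta <- tryCatch(stats::coef(stats::lm.fit(X, y)),
                     error = function(err) c(est$C0, est$Cinf))
    C0 <- beta[1]; Cinf <- beta[2]
    if (!is.finite(C0) || !is.finite(Cinf)) { C0 <- est$C0; Cinf <- est$Cinf }
    if (Cinf < 0) { # refit on the Cinf = 0 boundary
      Cinf <- 0
      C0 <- max(sum(y * e) / sum(e^2), 1e-12)
    }
    if (C0 <= Cinf) { C0 <- Cinf + 1e-12 }
    sum((y - (Cinf + (C0 - Cinf) * e))^2)
  }
}

#' Construct a joint confidence region for (kref, Ea)
#'
#' Evaluates the residual SSQ on a rectangular (kref, Ea) grid — with the
#' concentration parameters either fixed at their least-squares estimates
#' (default) or re-minimised per grid point (`"profiled"`) — and extracts
#' the contour at the [jcr_threshold()]. Following the threshold's
#' definition, `p` is the total number of simultaneously estimated
#' parameters of the fit (3 or 4), even though the region is drawn in the
#' two-dimensional (kref, Ea) plane.
#'
#' Default grid bounds are the estimate plus/minus `expand` linearised
#' standard errors, clipped at zero, at `resolution` points per axis.
#'
#' @param fit A converged [fit_one_step()] result.
#' @param phi Confidence complement (0.10 gives the 90% region).
#' @param nuisance_mode `"fixed_at_optimum"` or `"profiled"`.
#' @param kref_range,Ea_range Optional explicit grid bounds (length-2).
#' @param resolution Grid points per axis (>= 25).
#' @param expand Half-width of automatic bounds in linearised SEs.
#' @return Object of class `jcr_region`: list with `threshold`, `ssq_min`,
#'   `p`, `m`, `phi`, `kref`, `Ea` (grid axes), `ssq` (matrix), `inside`
#'   (logical matrix), `contours` (list of closed polygons with columns
#'   `kref`, `Ea`), `estimate`, `unit`, `nuisance_mode`.
#' @export
jcr_region <- function(fit, phi = 0.10,
                       nuisance_mode = c("fixed_at_optimum", "profiled"),
                       kref_range = NULL, Ea_range = NULL,
                       resolution = 81L, expand = 6) {
  stopifnot(inherits(fit, "kinfit"), isTRUE(fit$converged))
  nuisance_mode <- match.arg(nuisance_mode)
  if (resolution < 25) stop("jcr_region: resolution must be >= 25", call. = FALSE)
  est <- fit$estimates
  se_k <- fit$se["kref"]; se_e <- fit$se["Ea"]
  if (!is.finite(se_k) || se_k <= 0) se_k <- 0.25 * max(est$kref, 1e-8)
  if (!is.finite(se_e) || se_e <= 0) se_e <- 0.25 * max(est$Ea, 1)
  if (is.null(kref_range)) {
    kref_range <- c(max(est$kref - expand * se_k, est$kref * 1e-3),
                    est$kref + expand * se_k)
  }
  if (is.null(Ea_range)) {
    Ea_range <- c(max(est$Ea - expand * se_e, 0), est$Ea + expand * se_e)
  }
  if (est$kref < kref_range[1] || est$kref > kref_range[2] ||
      est$Ea < Ea_range[1] || est$Ea > Ea_range[2]) {
    stop("jcr_region: estimate outside grid bounds; expand kref_range/Ea_range",
         call. = FALSE)
  }
  kref_grid <- seq(kref_range[1], kref_range[2], length.out = resolution)
  Ea_grid <- seq(Ea_range[1], Ea_range[2], length.out = resolution)
  ssq_fun <- .ssq_evaluator(fit, nuisance_mode)
  ssq <- matrix(NA_real_, resolution, resolution)
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      ssq[i, j] <- ssq_fun(kref_grid[i], Ea_grid[j])
    }
  }
  thr <- jcr_threshold(fit$SSQ, fit$p, fit$m, phi)
  cl <- grDevices::contourLines(kref_grid, Ea_grid, ssq, levels = thr)
  contours <- lapply(cl, function(cc) {
    poly <- data.frame(kref = cc$x, Ea = cc$y)
    # close the polygon (contours clipped at the grid edge are closed
    # along the straight segment between their endpoints)
    if (poly$kref[1] != poly$kref[nrow(poly)] ||
        poly$Ea[1] != poly$Ea[nrow(poly)]) {
      poly <- rbind(poly, poly[1, ])
    }
    poly
  })
  unit <- if (fit$axis == "time_days") "per_day" else "per_Mluxh"
  structure(list(threshold = thr, ssq_min = fit$SSQ, p = fit$p, m = fit$m,
                 phi = phi, kref = kref_grid, Ea = Ea_grid, ssq = ssq,
                 inside = ssq <= thr, contours = contours,
                 estimate = c(kref = est$kref, Ea = est$Ea),
                 unit = unit, nuisance_mode = nuisance_mode),
            class = "jcr_region")
}

#' @export
print.jcr_region <- function(x, ...) {
  cat(sprintf("<jcr_region> %.0f%% region, p = %d, m = %d, SSQ_min = %.4g, threshold = %.4g\n",
              100 * (1 - x$phi), x$p, x$m, x$ssq_min, x$threshold))
  cat(sprintf("  estimate: kref = %.4g, Ea = %.4g kJ/mol (%s, %s nuisance)\n",
              x$estimate["kref"], x$estimate["Ea"], x$unit, x$nuisance_mode))
  cat(sprintf("  %d contour polygon(s), %d of %d grid points inside\n",
              length(x$contours), sum(x$inside), length(x$inside)))
  invisible(x)
}

#' Does a (kref, Ea) point lie inside the joint confidence region?
#'
#' Decided directly on the SSQ surface (no grid): the point is inside when
#' its SSQ — nuisance parameters handled per `nuisance_mode` — does not
#' exceed the [jcr_threshold()].
#'
#' @inheritParams jcr_region
#' @param kref,Ea Candidate parameter values.
#' @return Logical.
#' @export
jcr_contains <- function(fit, kref, Ea, phi = 0.10,
                         nuisance_mode = c("fixed_at_optimum", "profiled")) {
  stopifnot(inherits(fit, "kinfit"))
  nuisance_mode <- match.arg(nuisance_mode)
  ssq_fun <- .ssq_evaluator(fit, nuisance_mode)
  ssq_fun(kref, Ea) <= jcr_threshold(fit$SSQ, fit$p, fit$m, phi)
}

#' Test whether two joint confidence regions overlap
#'
#' True when the contour polygons of the two regions intersect or one
#' contains the other. Regions must live on commensurable rate-constant
#' units (both per day or both per Mlux-h).
#'
#' @param a,b [jcr_region()] objects.
#' @return Logical.
#' @export
regions_overlap <- function(a, b) {
  stopifnot(inherits(a, "jcr_region"), inherits(b, "jcr_region"))
  if (a$unit != b$unit) {
    stop("regions_overlap: unit mismatch (", a$unit, " vs ", b$unit, ")",
         call. = FALSE)
  }
  if (!length(a$contours) || !length(b$contours)) {
    stop("regions_overlap: a region has no extracted contour; widen its grid",
         call. = FALSE)
  }
  for (pa in a$contours) {
    for (pb in b$contours) {
      if (.polygons_intersect(pa$kref, pa$Ea, pb$kref, pb$Ea)) return(TRUE)
    }
  }
  FALSE
}

# Polygon intersection: any pair of edges crosses, or a vertex of one
# polygon lies inside the other (containment).
.polygons_intersect <- function(ax, ay, bx, by) {
  na <- length(ax); nb <- length(bx)
  for (i in seq_len(na - 1)) {
    for (j in seq_len(nb - 1)) {
      if (.segments_intersect(ax[i], ay[i], ax[i + 1], ay[i + 1],
                              bx[j], by[j], bx[j + 1], by[j + 1])) {
        return(TRUE)
      }
    }
  }
  .point_in_polygon(ax[1], ay[1], bx, by) ||
    .point_in_polygon(bx[1], by[1], ax, ay)
}

.segments_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- .cross(x3, y3, x4, y4, x1, y1)
  d2 <- .cross(x3, y3, x4, y4, x2, y2)
  d3 <- .cross(x1, y1, x2, y2, x3, y3)
  d4 <- .cross(x1, y1, x2, y2, x4, y4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && .on_segment(x3, y3, x4, y4, x1, y1)) ||
    (d2 == 0 && .on_segment(x3, y3, x4, y4, x2, y2)) ||
    (d3 == 0 && .on_segment(x1, y1, x2, y2, x3, y3)) ||
    (d4 == 0 && .on_segment(x1, y1, x2, y2, x4, y4))
}

.cross <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py) {
  px >= min(ax, bx) && px <= max(ax, bx) &&
    py >= min(ay, by) && py <= max(ay, by)
}

# Even-odd ray casting.
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
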