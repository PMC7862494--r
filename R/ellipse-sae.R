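#' Ellipse area
#'
#' Area of an ellipse with semi-minor radius `r` and semi-major radius `R`,
#' `pi * r * R`. For a fiber modeled as a cylinder of base radius `r`
#' sectioned at tilt angle theta, `R = r / cos(theta)` and the cut surface
#' is this ellipse.
#'
#' @param r Semi-minor radius (um). Must satisfy `0 < r <= R`.
#' @param R Semi-major radius (um).
#' @return Area in um^2. Vectorized over `r` and `R`.
#' @examples
#' ellipse_area(1, 2) # 2 * pi
#' @export
ellipse_area <- function(r, R) {
  check_radii(r, R)
  pi * r * R
}

#' Ellipse perimeter by the Gauss-Kummer series
#'
#' Perimeter of an ellipse from the infinite series
#' `pi * (r + R) * sum_n choose(0.5, n)^2 * h^n` with
#' `h = (R - r)^2 / (R + r)^2`, truncated after `n_terms` terms.
#' The series is non-decreasing in `n_terms` and converges to the exact
#' (complete elliptic integral) perimeter.
#'
#' @inheritParams ellipse_area
#' @param n_terms Number of series terms (>= 1). The four-term truncation
#'   is the one used by the shape-adjusted ellipse solve; see
#'   [sae_perimeter()].
#' @return Perimeter in um. Vectorized over `r` and `R`.
#' @seealso [ellipse_perimeter_exact()] for the elliptic-integral value.
#' @examples
#' ellipse_perimeter_series(1, 2, n_terms = 4)
#' @export
ellipse_perimeter_series <- function(r, R, n_terms = 4L) {
  check_radii(r, R)
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1)
    stop("`n_terms` must be a single integer >= 1", call. = FALSE)
  n_terms <- as.integer(n_terms)
  h <- ((R - r) / (R + r))^2
  n <- 0:(n_terms - 1L)
  coef <- choose(0.5, n)^2
  # outer() keeps this vectorized over (r, R) pairs
  s <- as.vector(outer(h, n, `^`) %*% coef)
  pi * (r + R) * s
}

#' Exact ellipse perimeter
#'
#' Perimeter via the complete elliptic integral of the second kind,
#' `4 * R * E(1 - (r/R)^2)`. Used as the high-accuracy reference for the
#' series truncation and for generating validation inputs.
#'
#' @inheritParams ellipse_area
#' @return Perimeter in um.
#' @export
ellipse_perimeter_exact <- function(r, R) {
  check_radii(r, R)
  m <- 1 - (r / R)^2
  vapply(seq_along(m), function(i) 4 * R[i] * pracma::ellipke(m[i])$e,
         numeric(1))
}

#' Four-term ellipse perimeter at fixed area
#'
#' The truncated perimeter of the ellipse with semi-minor radius `r` and
#' area `area`: substituting `R = area / (pi * r)` into the four-term
#' Gauss-Kummer series gives
#' `pi * (area/(pi*r) + r) * (1 + h/4 + h^2/64 + h^3/256)` with
#' `h = ((area - pi*r^2) / (area + pi*r^2))^2`.
#' This is the forward map inverted by [solve_sae()].
#'
#' @param r Semi-minor radius (um), with `pi * r^2 <= area` (r cannot
#'   exceed the semi-major radius).
#' @param area Ellipse area (um^2).
#' @return Perimeter in um. Vectorized.
#' @examples
#' sae_perimeter(1, 2 * pi) # ellipse r = 1, R = 2
#' @export
sae_perimeter <- function(r, area) {
  if (!is.numeric(r) || !is.numeric(area) || any(!is.finite(r)) ||
      any(!is.finite(area)) || any(r <= 0) || any(area <= 0))
    stop("`r` and `area` must be positive and finite", call. = FALSE)
  if (any(pi * r^2 > area * (1 + 1e-12)))
    stop("pi * r^2 exceeds `area`: r would exceed the semi-major radius",
         call. = FALSE)
  h <- ((area - pi * r^2) / (area + pi * r^2))^2
  pi * (area / (pi * r) + r) * (1 + h / 4 + h^2 / 64 + h^3 / 256)
}

#' Shape-adjusted ellipse (SAE) solve
#'
#' Recovers the semi-minor radius of the unique ellipse having a measured
#' cross-sectional area and perimeter, by solving
#' `sae_perimeter(r, area) = perimeter` for `r` with Newton's method. The
#' minor diameter `2 * r` is the tilt-corrected fiber diameter: for a
#' cylindrical fiber sectioned obliquely, the ellipse's minor axis equals
#' the diameter of the circular base regardless of tilt angle.
#'
#' A measured perimeter below the isoperimetric bound `2 * sqrt(pi * area)`
#' cannot arise from any ellipse (it is sub-circular); such records are
#' clamped to the circle-equivalent radius `sqrt(area / pi)` with tilt 0 and
#' flagged `feasible = FALSE`.
#'
#' Newton iterations start at `r0 = sqrt(area / pi)` (an upper bound for the
#' root; the residual is monotone decreasing on `(0, r0]`) and fall back to
#' bisection on that interval whenever an iterate leaves it.
#'
#' @param area Measured areas (um^2), positive.
#' @param perimeter Measured perimeters (um), positive.
#' @param tolerance Relative convergence tolerance on `r`.
#' @param max_iter Maximum Newton iterations per record.
#' @return A data frame with one row per input:
#'   `minor_radius`, `minor_diameter` (= 2 * minor_radius), `major_radius`,
#'   `h`, `tilt_angle` (degrees, `acos(r/R)`), `rho` (= R/r = 1/cos(tilt),
#'   the area overestimation factor), `iterations`, `converged`, `feasible`.
#' @examples
#' solve_sae(pi, 2 * pi)               # circle: diameter 2, tilt 0
#' solve_sae(2 * pi, 9.688446)         # ellipse r = 1, R = 2, tilt 60 deg
#' @export
solve_sae <- function(area, perimeter, tolerance = 1e-10, max_iter = 100L) {
  if (!is.numeric(area) || !is.numeric(perimeter) ||
      any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop("`area` and `perimeter` must be positive and finite", call. = FALSE)
  if (length(area) != length(perimeter))
    stop("`area` and `perimeter` must have equal length", call. = FALSE)
  n <- length(area)
  if (n == 0L)
    stop("`area` and `perimeter` must be non-empty", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- sae_solve_one(area[i], perimeter[i], tolerance, max_iter)
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cl) unlist(lapply(rows, `[[`, cl)))
  names(out) <- cols
  as.data.frame(out)
}

# Scalar Newton solve with bisection fallback; returns the row as a list.
sae_solve_one <- function(area, perimeter, tolerance, max_iter) {
  r0 <- sqrt(area / pi)
  iso <- 2 * sqrt(pi * area)
  if (perimeter <= iso * (1 + 1e-12)) {
    feas <- perimeter >= iso * (1 - 1e-12)  # circle to numeric precision
    return(list(minor_radius = r0, minor_diameter = 2 * r0,
                major_radius = r0, h = 0, tilt_angle = 0, rho = 1,
                iterations = 0L, converged = TRUE, feasible = feas))
  }
  f <- function(r) sae_perimeter(r, area) - perimeter
  # residual derivative of the four-term form, by finite analytic parts
  fp <- function(r) {
    A <- area
    g <- (A - pi * r^2) / (A + pi * r^2)
    h <- g^2
    S <- 1 + h / 4 + h^2 / 64 + h^3 / 256
    dS_dh <- 1 / 4 + h / 32 + 3 * h^2 / 256
    dg_dr <- -4 * pi * r * A / (A + pi * r^2)^2
    dh_dr <- 2 * g * dg_dr
    base <- A / (pi * r) + r
    pi * ((1 - A / (pi * r^2)) * S + base * dS_dh * dh_dr)
  }
  lo <- r0 * 1e-12
  hi <- r0
  r <- r0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fr <- f(r)
    # maintain the bracket: residual is decreasing in r
    if (fr > 0) lo <- max(lo, r) else hi <- min(hi, r)
    step <- fr / fp(r)
    r_new <- r - step
    if (!is.finite(r_new) || r_new <= lo || r_new > hi)
      r_new <- (lo + hi) / 2  # bisection fallback
    if (abs(r_new - r) <= tolerance * r_new) {
      r <- r_new
      converged <- TRUE
      break
    }
    r <- r_new
  }
  R <- area / (pi * r)
  list(minor_radius = r, minor_diameter = 2 * r, major_radius = R,
       h = ((R - r) / (R + r))^2,
       tilt_angle = tilt_angle(r, R), rho = R / r,
       iterations = iter, converged = converged, feasible = TRUE)
}

#' Tilt (dispersion) angle from the ellipse axes
#'
#' For a cylinder of base radius `r` sectioned at tilt angle theta, the cut
#' ellipse has semi-major radius `R = r / cos(theta)`; inverting,
#' `theta = acos(r / R)`.
#'
#' @inheritParams ellipse_area
#' @return Angle in degrees, in `[0, 90)`. Vectorized.
#' @export
tilt_angle <- function(r, R) {
  check_radii(r, R)
  acos(pmin(1, r / R)) * 180 / pi
}

#' Area overestimation factor rho
#'
#' `rho = 1 / cos(theta)`, the factor by which oblique sectioning at tilt
#' angle theta inflates the cut area relative to the cylinder's circular
#' base (`Ae = rho * Ac`). At tilt 0 the section is the base circle and
#' `rho = 1`. The relationship is strictly increasing and convex in theta.
#'
#' @param tilt Tilt angle in degrees, in `[0, 90)`.
#' @return Dimensionless factor >= 1. Vectorized.
#' @export
overestimation_factor <- function(tilt) {
  if (!is.numeric(tilt) || any(!is.finite(tilt)) ||
      any(tilt < 0) || any(tilt >= 90))
    stop("`tilt` must be in [0, 90) degrees", call. = FALSE)
  1 / cos(tilt * pi / 180)
}

#' Traditional circle-based diameters
#'
#' The two classical estimators that treat the cross-section as a circle:
#' `circle_diameter_from_area(A) = 2 * sqrt(A / pi)` and
#' `circle_diameter_from_perimeter(p) = p / pi`. Both overestimate the true
#' base diameter for obliquely sectioned fibers.
#'
#' @param area Cross-sectional area (um^2), positive.
#' @return Diameter in um. Vectorized.
#' @export
circle_diameter_from_area <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0))
    stop("`area` must be positive and finite", call. = FALSE)
  2 * sqrt(area / pi)
}

#' @rdname circle_diameter_from_area
#' @param perimeter Cross-sectional perimeter (um), positive.
#' @export
circle_diameter_from_perimeter <- function(perimeter) {
  if (!is.numeric(perimeter) || any(!is.finite(perimeter)) ||
      any(perimeter <= 0))
    stop("`perimeter` must be positive and finite", call. = FALSE)
  perimeter / pi
}

check_radii <- function(r, R) {
  if (!is.numeric(r) || !is.numeric(R) || any(!is.finite(r)) ||
      any(!is.finite(R)) || any(r <= 0) || any(R <= 0))
    stop("radii must be positive and finite", call. = FALSE)
  if (any(r > R * (1 + 1e-12)))
    stop("semi-minor radius `r` must not exceed semi-major radius `R`",
         call. = FALSE)
  invisible(TRUE)
}
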