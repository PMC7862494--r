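#' Polygon contour of a segmented structure
#'
#' A contour is an ordered, implicitly closed polygon (the last vertex
#' connects back to the first) traced around one segmented structure in a
#' micrograph cross-section. Coordinates are continuous, in micrometres
#' (use [scale_contour()] for pixel inputs); y increases downward by image
#' convention, which does not affect any measured quantity.
#'
#' @param x,y Numeric vertex coordinates (um), length >= 3.
#' @param id Structure label (coerced to character).
#' @param structure_type One of `"fiber_outer"` (outer myelin contour),
#'   `"axon_inner"` (inner contour / axon proper), `"unmyelinated"`.
#' @return An object of class `"contour"`.
#' @export
contour <- function(x, y, id = "1",
                    structure_type = c("fiber_outer", "axon_inner",
                                       "unmyelinated")) {
  structure_type <- match.arg(structure_type)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("`x` and `y` must be numeric vectors of equal length",
         call. = FALSE)
  if (length(x) < 3L)
    stop("a contour needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("contour vertices must be finite", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 id = as.character(id)[1L],
                 structure_type = structure_type),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> id=%s type=%s vertices=%d\n",
              x$id, x$structure_type, length(x$x)))
  invisible(x)
}

#' Measure a contour
#'
#' Computes the measurements the morphometric pipeline consumes: area by the
#' shoelace formula (absolute value, so vertex orientation is irrelevant),
#' perimeter as the sum of edge lengths, the area-weighted polygon centroid,
#' and the maximum/minimum Feret (caliper) diameters via rotating calipers
#' over the convex hull.
#'
#' @param contour A [contour()], or a list of contours (then one row each).
#' @return A data frame with columns `id`, `structure_type`, `area`,
#'   `perimeter`, `centroid_x`, `centroid_y`, `feret_min`, `feret_max`
#'   (lengths um, areas um^2).
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' measure_contour(sq)
#' @export
measure_contour <- function(contour) {
  if (inherits(contour, "contour")) contour <- list(contour)
  if (!all(vapply(contour, inherits, logical(1), "contour")))
    stop("`contour` must be a contour or a list of contours", call. = FALSE)
  rows <- lapply(contour, measure_one)
  do.call(rbind, rows)
}

measure_one <- function(ct) {
  x <- ct$x; y <- ct$y
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a2 <- sum(cross)                       # signed, twice the area
  area <- abs(a2) / 2
  if (area <= 0)
    stop(sprintf("contour '%s' has zero area", ct$id), call. = FALSE)
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  cx <- sum((x + xn) * cross) / (3 * a2)
  cy <- sum((y + yn) * cross) / (3 * a2)
  fer <- feret_diameters(ct)
  data.frame(id = ct$id, structure_type = ct$structure_type,
             area = area, perimeter = perimeter,
             centroid_x = cx, centroid_y = cy,
             feret_min = fer[["feret_min"]], feret_max = fer[["feret_max"]],
             stringsAsFactors = FALSE)
}

#' Feret (caliper) diameters of a contour
#'
#' The maximum Feret diameter is the largest distance between two parallel
#' tangent lines (equivalently the polygon diameter, attained on the convex
#' hull); the minimum Feret diameter is the smallest width over hull-edge
#' directions, computed exactly by rotating calipers. The minimum Feret is a
#' classical caliper estimator of nerve-fiber size; for an ellipse section
#' of a tilted cylinder it equals the base diameter at every tilt.
#'
#' @param contour A [contour()].
#' @return Named numeric vector `c(feret_min, feret_max)` in um.
#' @export
feret_diameters <- function(contour) {
  if (!inherits(contour, "contour"))
    stop("`contour` must be a contour", call. = FALSE)
  hidx <- grDevices::chull(contour$x, contour$y)
  hx <- contour$x[hidx]; hy <- contour$y[hidx]
  m <- length(hx)
  if (m < 3L)
    stop(sprintf("contour '%s' is degenerate (collinear vertices)",
                 contour$id), call. = FALSE)
  # chull() returns clockwise order; reverse to counter-clockwise
  hx <- rev(hx); hy <- rev(hy)
  # max Feret: max pairwise distance over hull vertices. Hull sizes here are
  # modest (<= contour vertex count), so the vectorized O(m^2) form is fine
  # for m up to ~2000; fall back to antipodal pairs beyond that.
  if (m <= 2048L) {
    dmax <- sqrt(max(outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2))
  } else {
    dmax <- hull_diameter_calipers(hx, hy)
  }
  # min Feret: for each hull edge, the width is the max distance of hull
  # vertices from the edge's supporting line; the minimum width over all
  # edges is attained at an edge direction (exact for polygons).
  ex <- c(hx[-1L], hx[1L]) - hx
  ey <- c(hy[-1L], hy[1L]) - hy
  elen <- sqrt(ex^2 + ey^2)
  keep <- elen > 0
  widths <- vapply(which(keep), function(i) {
    # distance of all hull vertices from line through vertex i along edge i
    max(abs((hx - hx[i]) * (-ey[i]) + (hy - hy[i]) * ex[i]) / elen[i])
  }, numeric(1))
  c(feret_min = min(widths), feret_max = dmax)
}

# Antipodal-pair walk for the hull diameter, O(m); hull is counter-clockwise.
hull_diameter_calipers <- function(hx, hy) {
  m <- length(hx)
  nxt <- function(i) if (i == m) 1L else i + 1L
  area2 <- function(i, j, k)
    (hx[j] - hx[i]) * (hy[k] - hy[i]) - (hy[j] - hy[i]) * (hx[k] - hx[i])
  best <- 0
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    while (abs(area2(i, i2, nxt(j))) > abs(area2(i, i2, j))) j <- nxt(j)
    best <- max(best,
                (hx[i] - hx[j])^2 + (hy[i] - hy[j])^2,
                (hx[i2] - hx[j])^2 + (hy[i2] - hy[j])^2)
  }
  sqrt(best)
}

#' Rescale a contour from pixels to micrometres
#'
#' Multiplies all vertex coordinates by `um_per_pixel`. Lengths scale by the
#' factor, areas by its square.
#'
#' @param contour A [contour()].
#' @param um_per_pixel Positive scale factor (um per pixel).
#' @return The rescaled contour.
#' @export
scale_contour <- function(contour, um_per_pixel) {
  if (!inherits(contour, "contour"))
    stop("`contour` must be a contour", call. = FALSE)
  if (!is.numeric(um_per_pixel) || length(um_per_pixel) != 1L ||
      !is.finite(um_per_pixel) || um_per_pixel <= 0)
    stop("`um_per_pixel` must be a single positive number", call. = FALSE)
  contour$x <- contour$x * um_per_pixel
  contour$y <- contour$y * um_per_pixel
  contour
}
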