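#' Circularity shape descriptors
#'
#' Five dimensionless descriptors of how far a cross-sectional profile
#' departs from a circle, computed from tabulated measurements (no vertices
#' needed):
#'
#' * shape factor = `perimeter / sqrt(area)` (circle: `2*sqrt(pi)` ~ 3.54)
#' * form factor = `4*pi*area / perimeter^2` (circle: 1)
#' * aspect ratio = `feret_min / feret_max` (circle: 1)
#' * compactness = `sqrt(4*area/pi) / feret_max` (circle: 1)
#' * roundness = `4*area / (pi * feret_max^2)` (circle: 1)
#'
#' The Feret-dependent descriptors (aspect ratio, compactness, roundness)
#' are returned as `NA` when Feret columns are absent or missing — they are
#' never imputed.
#'
#' @param measurements A data frame with columns `area` and `perimeter`
#'   (and optionally `feret_min`, `feret_max`), e.g. from
#'   [measure_contour()] or [read_measurements()]; or a numeric vector of
#'   areas together with `perimeter` etc. given as separate arguments.
#' @param perimeter,feret_min,feret_max Used only when `measurements` is a
#'   numeric vector of areas.
#' @return A data frame with columns `shape_factor`, `form_factor`,
#'   `aspect_ratio`, `compactness`, `roundness`.
#' @examples
#' # ideal circle of radius 1
#' shape_metrics(data.frame(area = pi, perimeter = 2 * pi,
#'                          feret_min = 2, feret_max = 2))
#' @export
shape_metrics <- function(measurements, perimeter = NULL,
                          feret_min = NULL, feret_max = NULL) {
  if (is.numeric(measurements)) {
    measurements <- data.frame(area = measurements, perimeter = perimeter)
    measurements$feret_min <- if (is.null(feret_min)) NA_real_ else feret_min
    measurements$feret_max <- if (is.null(feret_max)) NA_real_ else feret_max
  }
  m <- measurements
  if (!all(c("area", "perimeter") %in% names(m)))
    stop("`measurements` needs `area` and `perimeter` columns",
         call. = FALSE)
  if (any(!is.finite(m$area)) || any(m$area <= 0))
    stop("areas must be positive", call. = FALSE)
  if (any(!is.finite(m$perimeter)) || any(m$perimeter <= 0))
    stop("perimeters must be positive", call. = FALSE)
  fmin <- if ("feret_min" %in% names(m)) m$feret_min else NA_real_
  fmax <- if ("feret_max" %in% names(m)) m$feret_max else NA_real_
  if (any(!is.na(fmax) & fmax <= 0))
    stop("feret_max must be positive where present", call. = FALSE)
  data.frame(
    shape_factor = m$perimeter / sqrt(m$area),
    form_factor  = 4 * pi * m$area / m$perimeter^2,
    aspect_ratio = fmin / fmax,
    compactness  = sqrt(4 * m$area / pi) / fmax,
    roundness    = 4 * m$area / (pi * fmax^2)
  )
}
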