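#' Fiber size classes
#'
#' Counts diameters in the three conventional ventral-root size bands:
#' 0-4 um (myelinated autonomic / preganglionic parasympathetic range),
#' > 4-10 um (gamma-motor range) and > 10 um (alpha-motor range). Bins are
#' right-closed, matching the printed band labels. Non-positive diameters
#' are rejected and counted, never binned.
#'
#' @param diameters Numeric vector (um).
#' @return A data frame with columns `class` (`"0-4"`, `">4-10"`,
#'   `">10"`), `count` and `fraction` (of accepted records); the attribute
#'   `rejected` counts non-positive inputs.
#' @examples
#' size_class_counts(c(2, 4, 5, 10, 12))
#' @export
size_class_counts <- function(diameters) {
  if (!is.numeric(diameters))
    stop("`diameters` must be numeric", call. = FALSE)
  bad <- !is.finite(diameters) | diameters <= 0
  d <- diameters[!bad]
  counts <- c(sum(d <= 4), sum(d > 4 & d <= 10), sum(d > 10))
  out <- data.frame(class = c("0-4", ">4-10", ">10"),
                    count = counts,
                    fraction = if (length(d)) counts / length(d)
                               else rep(NA_real_, 3),
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- sum(bad)
  out
}

#' Fiber diameter frequency distribution
#'
#' Histogram of diameters on right-closed bins of width `bin_width`
#' starting at 0, optionally with a Gaussian kernel-smoothed density
#' (normal-reference/Silverman bandwidth, the nonparametric smoothing
#' behind interpolation-curve frequency displays). The density integrates
#' to 1 on its grid.
#'
#' @param diameters Numeric vector (um), `n >= 1`.
#' @param bin_width Positive bin width (um).
#' @param smooth Also return the kernel density.
#' @return A list with `histogram` (data frame: `bin_lo`, `bin_hi`,
#'   `count`) and, when `smooth`, `density` (data frame: `x`, `y`) plus
#'   `bandwidth`.
#' @export
frequency_distribution <- function(diameters, bin_width = 0.5,
                                   smooth = TRUE) {
  if (!is.numeric(diameters) || length(diameters) < 1L ||
      any(!is.finite(diameters)))
    stop("`diameters` must be a non-empty finite numeric vector",
         call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  lo <- 0
  hi <- bin_width * ceiling(max(diameters) / bin_width)
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- pmin(pmax(ceiling((diameters - lo) / bin_width), 1L),
              length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                     bin_hi = breaks[-1L],
                                     count = counts))
  if (smooth) {
    # the normal-reference rule needs >= 2 distinct points; fall back to the
    # bin width for degenerate samples
    bw <- if (length(unique(diameters)) >= 2L) "nrd0" else bin_width
    den <- stats::density(diameters, bw = bw, n = 512)
    out$density <- data.frame(x = den$x, y = den$y)
    out$bandwidth <- den$bw
  }
  out
}

#' Local maxima of a smoothed diameter distribution
#'
#' Convenience for locating population modes (e.g. the motor and autonomic
#' peaks of a ventral-root size distribution) on the kernel density of
#' [frequency_distribution()].
#'
#' @param diameters Numeric vector (um).
#' @param n_modes Return at most this many modes, highest density first.
#' @return Numeric vector of mode locations (um), sorted increasing.
#' @export
density_modes <- function(diameters, n_modes = 2L) {
  den <- frequency_distribution(diameters, smooth = TRUE)$density
  y <- den$y
  nY <- length(y)
  mid <- y[2:(nY - 1L)]
  k <- which(mid > y[1:(nY - 2L)] & mid > y[3:nY]) + 1L
  if (!length(k)) return(den$x[which.max(y)])
  k <- k[order(-y[k])][seq_len(min(n_modes, length(k)))]
  sort(den$x[k])
}

#' Agreement between two diameter series
#'
#' Ordinary least-squares regression of `y` on `x` with the coefficient of
#' determination, used to quantify agreement between SAE diameters and a
#' traditional method's diameters over the same fibers.
#'
#' @param x Independent variable (traditional method diameters, um).
#' @param y Dependent variable (SAE diameters, um).
#' @return A list: `slope`, `intercept`, `r_squared`.
#' @export
regression_agreement <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  if (stats::var(x) <= 0)
    stop("`x` is degenerate (zero variance)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Compare diameter-estimation methods on one set of measurements
#'
#' Computes, from the same per-fiber measurements, the four diameters —
#' shape-adjusted ellipse (`sae`), minimum Feret (`feret_min`),
#' area-circle (`area_circle`) and perimeter-circle (`perimeter_circle`) —
#' and summarizes each method as mean +/- standard error and median, with
#' the percent overestimation relative to the SAE mean,
#' `100 * (mean_method - mean_sae) / mean_sae` (and the same on medians,
#' since either basis is defensible).
#'
#' @param measurements Data frame with `area`, `perimeter` and (for the
#'   Feret method) `feret_min` columns, e.g. from [measure_contour()].
#' @param ... Passed to [solve_sae()].
#' @return A list: `per_fiber` (data frame of the four diameters plus the
#'   SAE `feasible` flag), `summary` (data frame: `method`, `n`, `mean`,
#'   `se`, `median`, `overestimation_pct`, `overestimation_median_pct`)
#'   and `n_infeasible` (records clamped at the isoperimetric bound).
#' @export
compare_methods <- function(measurements, ...) {
  m <- measurements
  if (!all(c("area", "perimeter") %in% names(m)) || nrow(m) < 1L)
    stop("`measurements` needs `area` and `perimeter` columns and >= 1 row",
         call. = FALSE)
  sae <- solve_sae(m$area, m$perimeter, ...)
  per <- data.frame(
    sae = sae$minor_diameter,
    feret_min = if ("feret_min" %in% names(m)) m$feret_min else NA_real_,
    area_circle = circle_diameter_from_area(m$area),
    perimeter_circle = circle_diameter_from_perimeter(m$perimeter),
    feasible = sae$feasible)
  if ("id" %in% names(m)) per <- cbind(id = m$id, per)
  methods <- c("sae", "feret_min", "area_circle", "perimeter_circle")
  summ <- do.call(rbind, lapply(methods, function(mm) {
    v <- per[[mm]]
    v <- v[is.finite(v)]
    data.frame(method = mm, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), median = stats::median(v),
               stringsAsFactors = FALSE)
  }))
  base_mean <- summ$mean[summ$method == "sae"]
  base_med <- summ$median[summ$method == "sae"]
  summ$overestimation_pct <- 100 * (summ$mean - base_mean) / base_mean
  summ$overestimation_median_pct <- 100 * (summ$median - base_med) / base_med
  list(per_fiber = per, summary = summ,
       n_infeasible = sum(!sae$feasible))
}
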