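# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Polygon contour of a tilted-cylinder cross-section
#'
#' Renders the ellipse produced by sectioning a cylinder of base radius `r`
#' at tilt angle `tilt`: semi-axes `(r / cos(tilt), r)`, rotated by
#' `orientation` and translated to `center`. Each vertex radius is
#' multiplicatively perturbed by `1 + noise * u`, `u ~ U(-1, 1)`, a
#' star-convexity-preserving model of segmentation boundary error;
#' `noise = 0` gives the exact inscribed ellipse polygon.
#'
#' @param r Cylinder base radius (um).
#' @param tilt Tilt angle (degrees, `[0, 90)`).
#' @param orientation In-plane rotation of the major axis (degrees).
#' @param center Length-2 numeric, contour centre (um).
#' @param n_vertices Vertex count (>= 32).
#' @param noise Fractional radial perturbation amplitude (>= 0, < 1).
#' @param seed Optional integer; when given, the perturbation is drawn from
#'   a private seeded stream and the caller's RNG state is untouched.
#' @param id,structure_type Passed to [contour()].
#' @return A [contour()].
#' @export
render_ellipse_contour <- function(r, tilt, orientation = 0,
                                   center = c(0, 0), n_vertices = 100L,
                                   noise = 0, seed = NULL, id = "1",
                                   structure_type = "fiber_outer") {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (!is.numeric(tilt) || length(tilt) != 1L || tilt < 0 || tilt >= 90)
    stop("`tilt` must be in [0, 90) degrees", call. = FALSE)
  if (n_vertices < 32L)
    stop("`n_vertices` must be at least 32", call. = FALSE)
  if (noise < 0 || noise >= 1)
    stop("`noise` must be in [0, 1)", call. = FALSE)
  R <- r / cos(tilt * pi / 180)
  t <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  x <- R * cos(t)
  y <- r * sin(t)
  if (noise > 0) {
    u <- with_seed(seed, stats::runif(n_vertices, -1, 1))
    x <- x * (1 + noise * u)
    y <- y * (1 + noise * u)
  }
  a <- orientation * pi / 180
  contour(center[1L] + cos(a) * x - sin(a) * y,
          center[2L] + sin(a) * x + cos(a) * y,
          id = id, structure_type = structure_type)
}

#' Specification of a synthetic myelinated-fiber population
#'
#' Defines the mixture, tilt, G-ratio and boundary-noise model from which
#' [sample_population()] draws ground-truth fibers. The defaults emulate a
#' lumbosacral ventral-root-like population with three normal size
#' components — small preganglionic autonomic (~2.5 um), gamma-motor
#' (~4.5 um) and alpha-motor (~11 um) fibers — dispersion (tilt) angles
#' uniform on \[0, 45\] degrees, a G-ratio that rises weakly with fiber
#' diameter, and 2% boundary noise on 100-vertex contours.
#'
#' @param components Data frame with columns `weight` (fractions summing to
#'   1), `mean_diameter` (um) and `sd` (um, with `mean - 3*sd > 0`).
#' @param tilt_model `list(kind = "uniform", max = degrees)`,
#'   `list(kind = "folded_normal", sd = degrees)` (absolute value of a
#'   centred normal, truncated below 90), or
#'   `list(kind = "fixed", value = degrees)`.
#' @param g_ratio_model `list(intercept, slope, sd)`: mean G-ratio is
#'   `intercept + slope * fiber_diameter` (slope per um); draws are clipped
#'   to (0.05, 0.95).
#' @param boundary_noise Fractional radial vertex perturbation.
#' @param vertices_per_contour Vertices per rendered contour.
#' @param seed Default seed used by [sample_population()].
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(
    components = data.frame(
      weight = c(0.30, 0.35, 0.35),
      mean_diameter = c(2.5, 4.5, 11),
      sd = c(0.4, 0.8, 1.8)),
    tilt_model = list(kind = "uniform", max = 45),
    g_ratio_model = list(intercept = 0.55, slope = 0.01, sd = 0.04),
    boundary_noise = 0.02,
    vertices_per_contour = 100L,
    seed = 1L) {
  if (!is.data.frame(components) ||
      !all(c("weight", "mean_diameter", "sd") %in% names(components)))
    stop("`components` needs columns weight, mean_diameter, sd",
         call. = FALSE)
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must sum to 1", call. = FALSE)
  if (any(components$mean_diameter - 3 * components$sd <= 0))
    stop("each component needs mean_diameter - 3*sd > 0", call. = FALSE)
  kind <- match.arg(tilt_model$kind,
                    c("uniform", "folded_normal", "fixed"))
  if (kind == "uniform" &&
      (is.null(tilt_model$max) || tilt_model$max < 0 || tilt_model$max >= 90))
    stop("uniform tilt model needs `max` in [0, 90)", call. = FALSE)
  if (kind == "folded_normal" &&
      (is.null(tilt_model$sd) || tilt_model$sd < 0))
    stop("folded_normal tilt model needs `sd` >= 0", call. = FALSE)
  if (kind == "fixed" &&
      (is.null(tilt_model$value) || tilt_model$value < 0 ||
       tilt_model$value >= 90))
    stop("fixed tilt model needs `value` in [0, 90)", call. = FALSE)
  if (boundary_noise < 0 || boundary_noise >= 1)
    stop("`boundary_noise` must be in [0, 1)", call. = FALSE)
  if (vertices_per_contour < 32L)
    stop("`vertices_per_contour` must be at least 32", call. = FALSE)
  structure(list(components = components, tilt_model = tilt_model,
                 g_ratio_model = g_ratio_model,
                 boundary_noise = boundary_noise,
                 vertices_per_contour = as.integer(vertices_per_contour),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat(sprintf("  %d size component(s); tilt: %s; noise: %g; vertices: %d\n",
              nrow(x$components), x$tilt_model$kind, x$boundary_noise,
              x$vertices_per_contour))
  invisible(x)
}

#' Sample a synthetic myelinated-fiber population
#'
#' Draws `n` ground-truth fibers from a [population_spec()]: per fiber a
#' size component, a true base diameter, a tilt angle, an in-plane
#' orientation (uniform on \[0, 180) degrees) and a G-ratio; renders the
#' outer contour with [render_ellipse_contour()] and the inner (axon)
#' contour as the outer polygon scaled by the G-ratio about the shared
#' centroid. Fibers are laid out on a non-overlapping grid. Fully
#' reproducible given `seed`.
#'
#' @param spec A [population_spec()].
#' @param n Number of fibers (>= 1).
#' @param seed Integer; defaults to `spec$seed`.
#' @return A list of class `"synthetic_population"` with elements `truth`
#'   (data frame: `fiber_id`, `axon_id`, `component`, `true_diameter`,
#'   `tilt_angle`, `orientation`, `true_g_ratio`, `center_x`, `center_y`)
#'   and `contours` (list of `list(outer = , inner = )` [contour()] pairs).
#' @export
sample_population <- function(spec, n, seed = spec$seed) {
  if (!inherits(spec, "population_spec"))
    stop("`spec` must be a population_spec", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    comp <- sample.int(nrow(spec$components), n, replace = TRUE,
                       prob = spec$components$weight)
    d <- stats::rnorm(n, spec$components$mean_diameter[comp],
                      spec$components$sd[comp])
    # components satisfy mean - 3 sd > 0, so redraws are rare
    while (any(bad <- d <= 0))
      d[bad] <- stats::rnorm(sum(bad),
                             spec$components$mean_diameter[comp[bad]],
                             spec$components$sd[comp[bad]])
    tilt <- switch(spec$tilt_model$kind,
      uniform = stats::runif(n, 0, spec$tilt_model$max),
      folded_normal = pmin(abs(stats::rnorm(n, 0, spec$tilt_model$sd)),
                           89.9),
      fixed = rep(spec$tilt_model$value, n))
    orient <- stats::runif(n, 0, 180)
    gm <- spec$g_ratio_model
    g <- stats::rnorm(n, gm$intercept + gm$slope * d, gm$sd)
    g <- pmin(pmax(g, 0.05), 0.95)
    # grid layout with clearance beyond the largest major axis
    spacing <- 2.2 * max(d / cos(tilt * pi / 180))
    side <- ceiling(sqrt(n))
    cx <- ((seq_len(n) - 1L) %% side) * spacing
    cy <- ((seq_len(n) - 1L) %/% side) * spacing
    contours <- vector("list", n)
    for (i in seq_len(n)) {
      outer_ct <- render_ellipse_contour(
        r = d[i] / 2, tilt = tilt[i], orientation = orient[i],
        center = c(cx[i], cy[i]),
        n_vertices = spec$vertices_per_contour,
        noise = spec$boundary_noise, seed = NULL,
        id = sprintf("f%04d", i), structure_type = "fiber_outer")
      inner_ct <- contour(
        cx[i] + g[i] * (outer_ct$x - cx[i]),
        cy[i] + g[i] * (outer_ct$y - cy[i]),
        id = sprintf("a%04d", i), structure_type = "axon_inner")
      contours[[i]] <- list(outer = outer_ct, inner = inner_ct)
    }
    truth <- data.frame(
      fiber_id = sprintf("f%04d", seq_len(n)),
      axon_id = sprintf("a%04d", seq_len(n)),
      component = comp, true_diameter = d, tilt_angle = tilt,
      orientation = orient, true_g_ratio = g,
      center_x = cx, center_y = cy, stringsAsFactors = FALSE)
    structure(list(truth = truth, contours = contours),
              class = "synthetic_population")
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d fibers\n", nrow(x$truth)))
  invisible(x)
}

#' Persist / reload a synthetic population as plain-text fixtures
#'
#' `write_fixture()` writes `contours.jsonl` (outer and inner polygons, see
#' [write_contours()]) and `truth.csv` (the ground-truth table) under
#' `path`; `read_fixture()` reads them back. Coordinates round-trip at full
#' double precision.
#'
#' @param population A `"synthetic_population"` (or `list(truth, contours)`).
#' @param path Directory to write into (created if missing).
#' @return `write_fixture()` returns `path` invisibly; `read_fixture()` a
#'   list with `truth` (data frame) and `contours` (flat named list of
#'   [contour()]s).
#' @export
write_fixture <- function(population, path) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create fixture directory '%s'", path),
         call. = FALSE)
  flat <- unlist(lapply(population$contours,
                        function(p) list(p$outer, p$inner)),
                 recursive = FALSE)
  write_contours(flat, file.path(path, "contours.jsonl"))
  utils::write.csv(population$truth, file.path(path, "truth.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  tf <- file.path(path, "truth.csv")
  cf <- file.path(path, "contours.jsonl")
  for (f in c(tf, cf))
    if (!file.exists(f))
      stop(sprintf("fixture file '%s' not found", f), call. = FALSE)
  truth <- utils::read.csv(tf, stringsAsFactors = FALSE)
  contours <- read_contours(cf)
  list(truth = truth, contours = contours)
}
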