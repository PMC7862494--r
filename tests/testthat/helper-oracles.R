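# Independent oracles and small generators used across the suite.

# Ellipse perimeter via the complete elliptic integral of the second kind
# (pracma); the reference for the Gauss-Kummer series and the SAE solve.
oracle_perimeter <- function(r, R) {
  stopifnot(r <= R)
  4 * R * pracma::ellipke(1 - (r / R)^2)$e
}

# Minimum-cost assignment by exhaustive enumeration over all injections of
# the smaller dimension into the larger; the oracle for the Hungarian
# solver. Returns the minimal total cost.
brute_force_assignment_cost <- function(cost) {
  transposed <- nrow(cost) > ncol(cost)
  cm <- if (transposed) t(cost) else cost
  nr <- nrow(cm); nc <- ncol(cm)
  combos <- utils::combn(nc, nr, simplify = FALSE)
  best <- Inf
  for (cols in combos) {
    perms <- perms_of(cols)
    for (p in perms) {
      tot <- sum(cm[cbind(seq_len(nr), p)])
      if (tot < best) best <- tot
    }
  }
  best
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms_of(v[-i]), function(p) c(v[i], p)))
  out
}

# Feret diameters by dense direction sampling (independent of the
# rotating-calipers path).
brute_force_ferets <- function(x, y, n_dir = 3600L) {
  th <- pi * (seq_len(n_dir) - 1L) / n_dir
  proj <- outer(x, cos(th)) + outer(y, sin(th))
  w <- apply(proj, 2L, max) - apply(proj, 2L, min)
  c(feret_min = min(w), feret_max = max(w))
}

# Exact ellipse polygon (no noise) used where a deterministic contour is
# wanted without touching the generator under test.
ellipse_polygon <- function(r, R, n = 3600L, rot = 0, center = c(0, 0)) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  x <- R * cos(t); y <- r * sin(t)
  a <- rot * pi / 180
  contour(center[1] + cos(a) * x - sin(a) * y,
          center[2] + sin(a) * x + cos(a) * y)
}

# The bimodal validation population: motor-fiber-like peaks at 3 and 10 um,
# dispersion angles uniform on [0, 60] degrees.
bimodal_spec <- function(noise, seed = 1L) {
  population_spec(
    components = data.frame(weight = c(0.5, 0.5),
                            mean_diameter = c(3, 10),
                            sd = c(0.5, 1.0)),
    tilt_model = list(kind = "uniform", max = 60),
    boundary_noise = noise,
    seed = seed)
}

# Measurement table of the outer contours of a synthetic population.
measure_population <- function(pop) {
  measure_contour(lapply(pop$contours, `[[`, "outer"))
}

local_tempdir <- function() {
  d <- tempfile("saemorph")
  dir.create(d)
  d
}
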