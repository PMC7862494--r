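test_that("ellipse area and circle-based diameters follow the closed forms", {
  expect_equal(ellipse_area(1, 1), pi)
  expect_equal(ellipse_area(2, 3), 6 * pi)
  expect_equal(ellipse_area(1, 2), 2 * pi)
  expect_error(ellipse_area(-1, 2), "positive")
  expect_error(ellipse_area(3, 2), "exceed")

  expect_equal(circle_diameter_from_area(pi), 2)
  expect_equal(circle_diameter_from_area(c(2 * pi, 4 * pi)),
               c(2 * sqrt(2), 4))
  expect_equal(circle_diameter_from_perimeter(c(2 * pi, pi)), c(2, 1))
  expect_equal(circle_diameter_from_perimeter(9.68846), 9.68846 / pi)
  expect_equal(circle_diameter_from_perimeter(9.68846), 3.083933,
               tolerance = 1e-6)
})

test_that("perimeter series matches the elliptic integral and is monotone in terms", {
  expect_equal(ellipse_perimeter_series(1, 1, 1), 2 * pi)
  expect_equal(ellipse_perimeter_series(1, 1, 30), 2 * pi)
  p_exact <- oracle_perimeter(1, 2)
  expect_equal(p_exact, 9.688448, tolerance = 1e-6)
  expect_equal(ellipse_perimeter_series(1, 2, 4), 9.68846,
               tolerance = 1e-5)
  expect_equal(ellipse_perimeter_series(1, 2, 20), p_exact,
               tolerance = 1e-9)
  # non-decreasing in n_terms, converging from below, across eccentricities
  for (R in c(1.2, 2, 4, 8)) {
    ps <- vapply(1:25, function(k) ellipse_perimeter_series(1, R, k),
                 numeric(1))
    expect_true(all(diff(ps) >= 0))
    expect_lte(ps[25], oracle_perimeter(1, R) + 1e-12)
    expect_equal(ps[25], oracle_perimeter(1, R), tolerance = 1e-6)
  }
  expect_equal(ellipse_perimeter_exact(1, 2), p_exact, tolerance = 1e-12)
})

test_that("fixed-area truncated perimeter is consistent with the series", {
  expect_equal(sae_perimeter(1, pi), 2 * pi)
  expect_equal(sae_perimeter(1, 2 * pi),
               ellipse_perimeter_series(1, 2, 4), tolerance = 1e-12)
  expect_equal(sae_perimeter(0.5, pi),
               ellipse_perimeter_series(0.5, 2, 4), tolerance = 1e-12)
  # r exceeding the semi-major radius is a domain error
  expect_error(sae_perimeter(2, pi), "exceeds")
})

test_that("SAE solve inverts the forward map and clamps sub-circular input", {
  s <- solve_sae(pi, 2 * pi)
  expect_equal(s$minor_diameter, 2)
  expect_equal(s$tilt_angle, 0)
  expect_equal(s$rho, 1)
  expect_true(s$feasible && s$converged)

  s <- solve_sae(2 * pi, 9.688446)
  expect_equal(s$minor_radius, 1, tolerance = 1e-6)
  expect_equal(s$major_radius, 2, tolerance = 1e-6)
  expect_equal(s$tilt_angle, 60, tolerance = 1e-4)
  expect_equal(s$rho, 2, tolerance = 1e-5)

  # perimeter below the isoperimetric bound cannot come from any ellipse
  s <- solve_sae(pi, 6.0)
  expect_false(s$feasible)
  expect_equal(s$minor_diameter, 2)
  expect_equal(s$tilt_angle, 0)

  expect_error(solve_sae(-1, 5), "positive")
  expect_error(solve_sae(pi, c(1, 2)), "equal length")
})

test_that("Newton solve agrees with an independent root-finder oracle", {
  set.seed(42)
  for (k in 1:500) {
    r <- runif(1, 0.2, 6)
    R <- r * runif(1, 1, 6)
    area <- pi * r * R
    p <- sae_perimeter(r, area) # exact root r by construction
    s <- solve_sae(area, p)
    expect_true(s$converged)
    expect_equal(s$minor_radius, r, tolerance = 1e-8)
    # independent oracle: stats::uniroot on the same residual
    o <- stats::uniroot(function(rr) sae_perimeter(rr, area) - p,
                        c(1e-9, sqrt(area / pi)), tol = 1e-12)$root
    expect_equal(s$minor_radius, o, tolerance = 1e-8)
  }
})

test_that("tilt angle and overestimation factor behave as the cylinder model predicts", {
  expect_equal(tilt_angle(1, 1), 0)
  expect_equal(tilt_angle(1, 2), 60)
  expect_equal(tilt_angle(1, sqrt(2)), 45)
  expect_error(tilt_angle(2, 1), "exceed")

  expect_equal(overestimation_factor(0), 1)
  expect_equal(overestimation_factor(60), 2)
  expect_equal(overestimation_factor(45), sqrt(2))
  expect_error(overestimation_factor(90), "90")

  # rho equals the ellipse-to-base-circle area ratio
  th <- seq(0, 75, by = 5)
  r <- 1.3
  expect_equal(overestimation_factor(th),
               ellipse_area(r, r / cos(th * pi / 180)) / (pi * r^2))
  # strictly increasing and strictly convex on a fine grid
  rho <- overestimation_factor(seq(0, 89, by = 0.5))
  expect_true(all(diff(rho) > 0))
  expect_true(all(diff(diff(rho)) > 0))
})

test_that("per-fiber diameters obey the SAE <= area-circle <= perimeter-circle chain", {
  for (r in c(0.25, 0.5, 1, 2, 4, 8)) {
    for (th in seq(0, 75, by = 15)) {
      R <- r / cos(th * pi / 180)
      area <- pi * r * R
      p <- oracle_perimeter(r, R)
      d_sae <- solve_sae(area, p)$minor_diameter
      d_a <- circle_diameter_from_area(area)
      d_p <- circle_diameter_from_perimeter(p)
      expect_lte(d_sae, d_a * (1 + 1e-9))
      expect_lte(d_a, d_p * (1 + 1e-9))
      if (th == 0) {
        expect_equal(d_sae, d_a, tolerance = 1e-9)
        expect_equal(d_a, d_p, tolerance = 1e-9)
      } else {
        expect_lt(d_sae, d_a)
        expect_lt(d_a, d_p)
      }
    }
  }
})
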