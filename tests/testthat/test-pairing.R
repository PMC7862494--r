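test_that("centroid distance matrix is the Euclidean distance table", {
  ax <- data.frame(id = "a1", centroid_x = 0, centroid_y = 0)
  fb <- data.frame(id = "f1", centroid_x = 3, centroid_y = 4)
  expect_equal(unname(distance_matrix(ax, fb)[1, 1]), 5)
  expect_equal(unname(distance_matrix(ax, ax)[1, 1]), 0)

  set.seed(5)
  ax <- data.frame(id = c("a1", "a2"), centroid_x = runif(2),
                   centroid_y = runif(2))
  fb <- data.frame(id = c("f1", "f2", "f3"), centroid_x = runif(3),
                   centroid_y = runif(3))
  d <- distance_matrix(ax, fb)
  expect_equal(dim(d), c(2L, 3L))
  for (i in 1:2) for (j in 1:3)
    expect_equal(d[i, j],
                 sqrt((ax$centroid_x[i] - fb$centroid_x[j])^2 +
                      (ax$centroid_y[i] - fb$centroid_y[j])^2))
  expect_equal(distance_matrix(fb, ax), t(d), ignore_attr = TRUE)
  expect_error(distance_matrix(ax[0, ], fb), "non-empty")
})

test_that("Hungarian solver reproduces brute-force optima with deterministic ties", {
  a <- optimal_assignment(rbind(c(0, 5), c(5, 0)))
  expect_equal(a$col, c(1L, 2L))
  expect_equal(attr(a, "total_cost"), 0)

  a <- optimal_assignment(rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2)))
  expect_equal(attr(a, "total_cost"), 5)

  # all-tied costs: lexicographic tie-break gives the identity matching
  a <- optimal_assignment(matrix(1, 3, 3))
  expect_equal(a$col, 1:3)

  # rectangular: covers the smaller dimension
  cost <- rbind(c(10, 1, 10), c(1, 10, 10))
  a <- optimal_assignment(cost)
  expect_equal(nrow(a), 2L)
  expect_equal(attr(a, "total_cost"), 2)
  expect_equal(attr(a, "total_cost"), brute_force_assignment_cost(cost))

  set.seed(99)
  for (k in 1:200) {
    nr <- sample(1:7, 1); nc <- sample(1:7, 1)
    cost <- matrix(round(runif(nr * nc, 0, 20), 2), nr, nc)
    a <- optimal_assignment(cost)
    expect_equal(nrow(a), min(nr, nc))
    expect_equal(attr(a, "total_cost"), brute_force_assignment_cost(cost),
                 tolerance = 1e-12)
  }
  expect_error(optimal_assignment(matrix(c(1, NA, 2, 3), 2)), "finite")
  expect_error(optimal_assignment(matrix(c(1, -2, 2, 3), 2)),
               "non-negative")
})

test_that("assignment is invariant to input ordering", {
  set.seed(12)
  cost <- matrix(runif(30), 5, 6)
  a <- optimal_assignment(cost)
  pr <- sample(5); pc <- sample(6)
  b <- optimal_assignment(cost[pr, pc])
  # map back to original indices and compare as sets of pairs
  orig <- sort(paste(a$row, a$col))
  back <- sort(paste(pr[b$row], pc[b$col]))
  expect_equal(orig, back)
  expect_equal(attr(b, "total_cost"), attr(a, "total_cost"))
})

test_that("pair scoring applies the G-ratio and myelin-thickness formulas", {
  fb <- data.frame(id = "f1", centroid_x = 0, centroid_y = 0,
                   sae_diameter = 2.0)
  ax <- data.frame(id = "a1", centroid_x = 0.1, centroid_y = 0,
                   sae_diameter = 1.2)
  p <- pair_and_score(ax, fb)
  expect_equal(p$g_ratio, 0.6)
  expect_equal(p$myelin_thickness, 0.4)
  expect_true(p$valid)

  # axon too far from every fiber: dropped with a reason, no pairs
  far <- data.frame(id = "a9", centroid_x = 50, centroid_y = 0,
                    sae_diameter = 1)
  expect_message(p <- pair_and_score(far, fb, max_distance = 5), "dropped")
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "dropped")$reason, "centroid_distance_exceeds_max")

  # an axon at least as large as its fiber is flagged, not discarded
  big <- data.frame(id = "a2", centroid_x = 0, centroid_y = 0,
                    sae_diameter = 2.5)
  p <- pair_and_score(big, fb)
  expect_false(p$valid)
  expect_gte(p$g_ratio, 1)
})

test_that("containment filter drops axon centroids outside the fiber polygon", {
  fb <- data.frame(id = c("f1", "f2"),
                   centroid_x = c(0, 10), centroid_y = c(0, 0),
                   sae_diameter = c(2, 2))
  cts <- list(
    f1 = render_ellipse_contour(1, 0, center = c(0, 0), id = "f1"),
    f2 = render_ellipse_contour(1, 0, center = c(10, 0), id = "f2"))
  ax <- data.frame(id = c("a1", "a2"),
                   centroid_x = c(0.2, 8.5), centroid_y = c(0, 0),
                   sae_diameter = c(1.2, 1.2))
  expect_message(
    p <- pair_and_score(ax, fb, max_distance = 3,
                        require_containment = TRUE, fiber_contours = cts),
    "outside")
  expect_equal(p$axon_id, "a1")
  expect_equal(attr(p, "dropped")$axon_id, "a2")
})

test_that("a shuffled concentric bundle is re-paired exactly with recovered G-ratios", {
  spec <- population_spec(boundary_noise = 0, seed = 77)
  pop <- sample_population(spec, 20)
  outer_m <- add_sae_columns(measure_contour(lapply(pop$contours,
                                                   `[[`, "outer")))
  inner_m <- add_sae_columns(measure_contour(lapply(pop$contours,
                                                   `[[`, "inner")))
  set.seed(8)
  inner_m <- inner_m[sample(nrow(inner_m)), ]
  p <- pair_and_score(inner_m, outer_m)
  expect_equal(nrow(p), 20L)
  truth <- pop$truth
  key <- truth$axon_id[match(p$fiber_id, truth$fiber_id)]
  expect_identical(p$axon_id, key) # zero mismatches
  g_true <- truth$true_g_ratio[match(p$fiber_id, truth$fiber_id)]
  expect_equal(p$g_ratio, g_true, tolerance = 5e-3)
  expect_equal(length(attr(p, "unmatched")), 0L)
})
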