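shoelace <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

test_that("shoelace area on reference polygons, orientation-independent", {
  sq <- cell_contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  tri <- cell_contour(c(0, 2, 0), c(0, 0, 2))
  expect_equal(polygon_area(tri), 2)
  tri_cw <- cell_contour(rev(c(0, 2, 0)), rev(c(0, 0, 2)))
  expect_equal(polygon_area(tri_cw), 2)
  expect_error(polygon_area(cell_contour(c(0, 1, 2), c(0, 1, 2),
                                         validate = FALSE)),
               "zero area")
})

test_that("contour validation rejects self-intersections and degeneracy", {
  # bowtie
  expect_error(cell_contour(c(0, 1, 1, 0), c(0, 1, 0, 1)),
               "self-intersecting")
  # collinear vertices survive construction but have no area or hull
  collin <- cell_contour(c(0, 0.5, 1), c(0, 0, 0))
  expect_error(polygon_area(collin), "zero area")
  expect_error(area_ratio(collin), "zero area")
  expect_error(cell_contour(c(0, 1), c(0, 1)), "3 distinct")
  # an explicitly closed polygon is accepted (closing vertex dropped)
  cl <- cell_contour(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_length(cl$x, 4)
})

test_that("monotone-chain hull matches the reference implementation", {
  # convex input: identity up to vertex rotation
  sq <- cell_contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- convex_hull(sq)
  expect_setequal(paste(h$x, h$y), paste(sq$x, sq$y))
  # interior point dropped
  sq_in <- cell_contour(c(0, 1, 0.5, 1, 0), c(0, 0, 0.5, 1, 1),
                        validate = FALSE)
  h2 <- convex_hull(sq_in)
  expect_length(h2$x, 4)
  expect_equal(polygon_area(h2), 1)
  # random clouds against grDevices::chull
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(20:1000, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    h <- convex_hull(list(x = x, y = y))
    ref <- grDevices::chull(x, y)
    expect_setequal(paste(h$x, h$y), paste(x[ref], y[ref]))
    expect_equal(polygon_area(h), shoelace(x[ref], y[ref]))
  }
  expect_error(convex_hull(list(x = c(0, 1, 2), y = c(0, 1, 2))),
               "collinear")
})

test_that("hull is idempotent and counter-clockwise", {
  set.seed(3)
  x <- stats::runif(50); y <- stats::runif(50)
  h <- convex_hull(list(x = x, y = y))
  hh <- convex_hull(h)
  expect_setequal(paste(h$x, h$y), paste(hh$x, hh$y))
  # signed area positive => counter-clockwise
  x2 <- c(h$x[-1], h$x[1]); y2 <- c(h$y[-1], h$y[1])
  expect_gt(sum(h$x * y2 - x2 * h$y) / 2, 0)
})

test_that("area ratio: convex = 1, notched square = 4/3", {
  set.seed(8)
  for (rep in 1:10) {
    # random convex polygon via hull of a cloud
    h <- convex_hull(list(x = stats::rnorm(30), y = stats::rnorm(30)))
    expect_equal(area_ratio(h)$area_ratio, 1, tolerance = 1e-9)
  }
  notched <- cell_contour(c(0, 1, 1, 0.5, 0), c(0, 0, 1, 0.5, 1))
  res <- area_ratio(notched)
  expect_equal(res$contour_area, 0.75)
  expect_equal(res$hull_area, 1)
  expect_equal(res$area_ratio, 4 / 3)
  # cross-check against the independent shoelace + chull oracle
  oracle_hull <- grDevices::chull(notched$x, notched$y)
  expect_equal(res$hull_area,
               shoelace(notched$x[oracle_hull], notched$y[oracle_hull]))
  expect_equal(res$contour_area, shoelace(notched$x, notched$y))
})

test_that("area ratio is invariant to rigid motion and uniform scaling", {
  notched <- cell_contour(c(0, 1, 1, 0.5, 0), c(0, 0, 1, 0.5, 1))
  th <- 0.83
  rot_x <- cos(th) * notched$x - sin(th) * notched$y + 12
  rot_y <- sin(th) * notched$x + cos(th) * notched$y - 5
  moved <- cell_contour(3.7 * rot_x, 3.7 * rot_y)
  expect_equal(area_ratio(moved)$area_ratio, 4 / 3, tolerance = 1e-12)
})

test_that("area ratio grows monotonically with protrusion amplitude", {
  # deterministic star contours r = R(1 + a sin(8 theta))
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  ratios <- sapply(c(0, 0.1, 0.2), function(a) {
    r <- 30 * (1 + a * sin(8 * theta))
    area_ratio(cell_contour(r * cos(theta), r * sin(theta)))$area_ratio
  })
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], 1, tolerance = 1e-3)  # polygonized circle
})

test_that("population summaries and the event-count flag", {
  smooth <- simulate_contours(300, amplitude = 0, noise_amp = 0.005,
                              seed = 21)
  lobed <- simulate_contours(300, amplitude = 0.15, noise_amp = 0.005,
                             seed = 22)
  s1 <- summarize_population(smooth, min_events = 100)
  s2 <- summarize_population(lobed, min_events = 100)
  expect_false(s1$below_threshold)
  expect_lt(s1$median_ratio, 1.02)
  expect_gt(s2$median_ratio, s1$median_ratio + 0.05)
  # mixture median lies between the pure-population medians
  mix <- summarize_population(c(smooth, lobed), min_events = 100)
  expect_gt(mix$median_ratio, s1$median_ratio)
  expect_lt(mix$median_ratio, s2$median_ratio)
  expect_true(summarize_population(smooth[1:50])$below_threshold)
  expect_error(summarize_population(list()), "empty")
})

test_that("contour tables round-trip", {
  cts <- simulate_contours(5, amplitude = 0.1, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour_table(cts, f)
  back <- read_contour_table(f)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$x, cts[[i]]$x, tolerance = 1e-10)
    expect_equal(back[[i]]$y, cts[[i]]$y, tolerance = 1e-10)
  }
})
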