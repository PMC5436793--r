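test_that("linear interpolation places snapshots evenly", {
  p <- interpolate_linear(c(0, 0), c(1, 1), 3)
  expect_equal(p$snapshots,
               rbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  p2 <- interpolate_linear(c(0, 0), c(1, 1), 2)
  expect_equal(nrow(p2$snapshots), 2L)
  expect_error(interpolate_linear(c(0, 0), c(1, 1), 1), "2")
})

test_that("a 40-snapshot interpolated path has constant spacing", {
  fx <- ala_fixture()
  p <- interpolate_linear(fx$reactant, fx$product, 40)
  expect_equal(nrow(p$snapshots), 40L)
  d <- diff(p$snapshots)
  steps <- sqrt(rowSums(d * d))
  want <- cv_distance_between(fx$reactant, fx$product) / 39
  expect_equal(steps, rep(want, 39), tolerance = 1e-12)
})

test_that("interpolation takes the shortest arc across the periodic seam", {
  p <- interpolate_linear(c(3.0, 0), c(-3.0, 0), 3, periodic = c(TRUE, FALSE))
  # midpoint is past +pi, wrapped near -pi
  expect_equal(p$snapshots[2, 1], wrap_periodic(3.0 + (2 * pi - 6) / 2, TRUE),
               tolerance = 1e-12)
})

test_that("arc length is exact on straight paths and accurate on arcs", {
  p <- new_path(rbind(c(0, 0), c(3, 4)))
  expect_equal(arc_length(p), 5.0)
  # straight interpolation adds no curvature
  p40 <- interpolate_linear(c(-1, 2), c(2, -2), 40)
  expect_equal(arc_length(p40), 5.0, tolerance = 1e-9)
  # quarter circle of radius 1 sampled at 20 snapshots
  th <- seq(0, pi / 2, length.out = 20)
  qc <- new_path(cbind(cos(th), sin(th)))
  expect_equal(arc_length(qc), pi / 2, tolerance = 1e-4)
})

test_that("inserting on-curve midpoints barely changes the arc length", {
  th <- seq(0, pi / 2, length.out = 20)
  qc <- new_path(cbind(cos(th), sin(th)))
  th2 <- sort(c(th, th[-1] - diff(th) / 2))
  qc2 <- new_path(cbind(cos(th2), sin(th2)))
  expect_lt(abs(arc_length(qc2) - arc_length(qc)) / arc_length(qc), 1e-6)
})

test_that("reparametrization evens the spacing and fixes the endpoints", {
  # uneven straight path: fractions (0, 0.9, 1) move to (0, 0.5, 1)
  p <- new_path(rbind(c(0, 0), c(0.9, 0), c(1, 0)))
  r <- reparametrize(p)
  expect_equal(r$snapshots[2, ], c(0.5, 0), tolerance = 1e-9)
  expect_equal(r$snapshots[1, ], c(0, 0))
  expect_equal(r$snapshots[3, ], c(1, 0))
  # an already-even straight path is a fixed point
  pe <- interpolate_linear(c(0, 0), c(2, 1), 7)
  re <- reparametrize(pe)
  expect_lt(max(abs(re$snapshots - pe$snapshots)), 1e-10)
})

test_that("reparametrization is idempotent and preserves arc length", {
  set.seed(11)
  th <- seq(0, 1, length.out = 15)^1.7 * pi * 0.6
  p <- new_path(cbind(1.3 * cos(th), sin(th)))
  r1 <- reparametrize(p)
  r2 <- reparametrize(r1)
  expect_lt(max(abs(r2$snapshots - r1$snapshots)), 5e-4)
  expect_lt(abs(arc_length(r1) - arc_length(p)) / arc_length(p), 1e-3)
  seg <- diff(path_arc_fractions(r1))
  expect_lt(max(abs(seg - mean(seg))) / mean(seg), 1e-3)
})

test_that("tangents are central-difference unit vectors, one-sided at ends", {
  p <- interpolate_linear(c(0, 0), c(3, 0), 5)
  for (i in 1:5) expect_equal(tangent(p, i), c(1, 0))
  elbow <- new_path(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(tangent(elbow, 2), c(1, 1) / sqrt(2))
  expect_error(tangent(p, 9), "range")
})

test_that("reversing a path negates every tangent", {
  set.seed(2)
  s <- matrix(cumsum(runif(12, 0.2, 1)), ncol = 2)
  p <- new_path(s)
  pr <- new_path(s[rev(seq_len(nrow(s))), ])
  m <- nrow(s)
  for (i in seq_len(m))
    expect_equal(tangent(p, i), -tangent(pr, m + 1 - i), tolerance = 1e-12)
})

test_that("path files round-trip bit-exactly with periodicity preserved", {
  p <- new_path(rbind(c(0.1, 3.1), c(0.5, -3.0), c(0.9, -2.5)),
                periodic = c(FALSE, TRUE))
  f1 <- tempfile(); f2 <- tempfile()
  write_path(p, f1, units = c("A", "rad"), extra_header = c(seed = "7"))
  p2 <- read_path(f1)
  write_path(p2, f2, units = c("A", "rad"), extra_header = c(seed = "7"))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(p2$snapshots, p$snapshots)
  expect_identical(p2$periodic, p$periodic)
})
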