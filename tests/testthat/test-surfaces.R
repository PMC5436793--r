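test_that("harmonic surface evaluates in closed form", {
  s <- surface_harmonic(k = 2, center = c(0, 0))
  at_min <- analytic_eval(s, c(0, 0))
  expect_equal(at_min$gradient, c(0, 0))
  ev <- analytic_eval(s, c(1, 0))
  expect_equal(ev$value, 1)
  expect_equal(ev$gradient, c(2, 0))
  expect_error(analytic_eval(s, c(1, 2, 3)), "dimension")
})

test_that("double-well stored minima are stationary to machine precision", {
  s <- surface_double_well()
  for (m in s$minima)
    expect_lt(sqrt(sum(s$gradient(m)^2)), 1e-10)
  # unequal depths: the product basin sits above the reactant basin
  expect_gt(s$value(s$minima[[2]]), s$value(s$minima[[1]]))
})

test_that("analytic surfaces pass the finite-difference consistency check", {
  set.seed(5)
  surfaces <- list(surface_harmonic(2, c(0.3, -0.2)),
                   surface_double_well(),
                   surface_mueller_brown(),
                   surface_saddle())
  for (s in surfaces) {
    for (rep in 1:25) {
      p <- runif(2, -2, 2)
      expect_lt(field_fd_error(s, p), 1e-4)
    }
  }
})

test_that("grid interpolation is exact on a linear surface", {
  lin <- gradient_field(gradient = function(chi) c(1, 2),
                        value = function(chi) chi[1] + 2 * chi[2],
                        dim = 2)
  axes <- list(list(min = -1, max = 1, step = 0.1, periodic = FALSE),
               list(min = -1, max = 1, step = 0.1, periodic = FALSE))
  g <- sample_to_grid(lin, axes, order = "bilinear")
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(2, -0.85, 0.85)
    expect_lt(max(abs(grid_gradient(g, p) - c(1, 2))), 1e-8)
  }
  # exactly on a node
  expect_lt(max(abs(grid_gradient(g, c(0.2, -0.4)) - c(1, 2))), 1e-8)
  expect_error(g$gradient(c(2, 0)), "outside")
})

test_that("bicubic grid gradients track a smooth analytic surface", {
  h <- surface_harmonic(k = 2, center = c(0, 0))
  axes <- list(list(min = -1.5, max = 1.5, step = 0.05, periodic = FALSE),
               list(min = -1.5, max = 1.5, step = 0.05, periodic = FALSE))
  g <- sample_to_grid(h, axes, order = "bicubic")
  set.seed(4)
  for (rep in 1:15) {
    p <- runif(2, -1, 1)
    expect_lt(max(abs(grid_gradient(g, p) - h$gradient(p))), 1e-3)
  }
})

test_that("grid interpolation error shrinks with refinement at the right order", {
  f <- gradient_field(
    gradient = function(chi) c(cos(chi[1]), -sin(chi[2])),
    value = function(chi) sin(chi[1]) + cos(chi[2]), dim = 2)
  err <- function(step, order) {
    axes <- list(list(min = -2, max = 2, step = step, periodic = FALSE),
                 list(min = -2, max = 2, step = step, periodic = FALSE))
    g <- sample_to_grid(f, axes, order = order)
    pts <- expand.grid(x = seq(-1, 1, 0.23), y = seq(-1, 1, 0.23))
    max(vapply(seq_len(nrow(pts)), function(i) {
      p <- as.numeric(pts[i, ])
      abs(g$value(p) - f$value(p))
    }, numeric(1)))
  }
  e_lin <- c(err(0.4, "bilinear"), err(0.2, "bilinear"))
  e_cub <- c(err(0.4, "bicubic"), err(0.2, "bicubic"))
  order_lin <- log2(e_lin[1] / e_lin[2])
  order_cub <- log2(e_cub[1] / e_cub[2])
  expect_gt(order_lin, 1)
  expect_gt(order_cub, 2)
})

test_that("periodic grid axes interpolate across the seam", {
  f <- gradient_field(gradient = function(chi) c(cos(chi[1]), 0),
                      value = function(chi) sin(chi[1]), dim = 2)
  step <- 2 * pi / 64
  axes <- list(list(min = -pi, max = pi - step, step = step, periodic = TRUE),
               list(min = -1, max = 1, step = 0.25, periodic = FALSE))
  g <- sample_to_grid(f, axes, order = "bicubic")
  near_seam <- c(pi - 0.01, 0)
  expect_lt(abs(g$value(near_seam) - sin(pi - 0.01)), 1e-4)
  # a point past the nominal maximum wraps around
  expect_lt(abs(g$value(c(pi + 0.3, 0)) - sin(pi + 0.3)), 1e-4)
})

test_that("grid files round-trip bit-exactly and fail loudly when malformed", {
  h <- surface_harmonic(k = 1.7, center = c(0.1, -0.2))
  axes <- list(list(min = -1, max = 1, step = 0.25, periodic = FALSE),
               list(min = -1, max = 1, step = 0.25, periodic = TRUE))
  g <- sample_to_grid(h, axes)
  f1 <- tempfile(fileext = ".dat")
  f2 <- tempfile(fileext = ".dat")
  save_grid(g, f1)
  g2 <- load_grid(f1)
  save_grid(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g2$values, g$values)
  expect_true(g2$axes[[2]]$periodic)
  expect_false(g2$axes[[1]]$periodic)

  lines <- readLines(f1)
  drop_one <- tempfile()
  writeLines(lines[-20], drop_one)
  expect_error(load_grid(drop_one), "line")
  ragged <- tempfile()
  bad <- lines
  bad[10] <- paste(bad[10], "99")
  writeLines(bad, ragged)
  expect_error(load_grid(ragged), "line 10")
  nan_file <- tempfile()
  bad <- lines
  bad[12] <- sub("[0-9.eE+-]+$", "NaN", bad[12])
  writeLines(bad, nan_file)
  expect_error(load_grid(nan_file), "line 12")
})

test_that("counted fields track gradient evaluations", {
  s <- counted_field(surface_harmonic(1, c(0, 0)))
  expect_equal(s$count(), 0L)
  s$gradient(c(1, 1))
  s$gradient(c(0, 1))
  expect_equal(s$count(), 2L)
  s$reset()
  expect_equal(s$count(), 0L)
})
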