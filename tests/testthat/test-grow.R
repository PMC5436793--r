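test_that("growing direction blends gradient and pull, normalized", {
  # zero gradient: exactly the unit vector toward the product
  d <- growth_direction(c(0, 0), c(0, 0), c(2, 0), w = 3)
  expect_equal(d, c(1, 0))
  # worked case: raw (1, -1), normalized
  d2 <- growth_direction(c(0, 1), c(0, 0), c(1, 0), w = 1)
  expect_equal(d2, c(1, -1) / sqrt(2), tolerance = 1e-12)
  d2r <- growth_direction(c(0, 1), c(0, 0), c(1, 0), w = 1, raw = TRUE)
  expect_equal(d2r, c(1, -1))
  expect_error(growth_direction(c(0, 1), c(0, 0), c(1, 0), w = 0,
                                raw = FALSE),
               NA) # gradient alone is a fine direction
  # exact cancellation is degenerate
  expect_error(growth_direction(c(1, 0), c(0, 0), c(1, 0), w = 1),
               "degenerate")
})

test_that("the angle to the product shrinks monotonically in w", {
  g <- c(0.8, 0.9)
  to_prod <- c(1, 0)
  angs <- vapply(c(0.5, 1, 2, 5, 10, 50), function(w) {
    d <- growth_direction(g, c(0, 0), c(3, 0), w = w)
    acos(sum(d * to_prod))
  }, numeric(1))
  expect_true(all(diff(angs) < 0))
})

test_that("growth on a flat surface is straight and terminates on schedule", {
  flat <- gradient_field(gradient = function(chi) c(0, 0), dim = 2)
  run <- grow_path(c(0, 0), c(1, 0), flat,
                   grow_config(s_g = 0.11, w = 5, sweeps = 0))
  m <- run$n_snapshots
  expect_equal(m, ceiling(1 / 0.11) + 1)  # interior steps plus the product
  expect_equal(run$path$snapshots[m, ], c(1, 0))
  # straight: every snapshot on the x-axis
  expect_lt(max(abs(run$path$snapshots[, 2])), 1e-10)
})

test_that("a path end within s_g of the product is finished immediately", {
  flat <- gradient_field(gradient = function(chi) c(0, 0), dim = 2)
  p <- new_path(rbind(c(0, 0), c(0.95, 0)), complete = FALSE)
  st <- grow_step(p, c(1, 0), flat, grow_config(s_g = 0.2, sweeps = 0))
  expect_true(st$finished)
  expect_equal(st$path$snapshots[nrow(st$path$snapshots), ], c(1, 0))
  expect_true(st$path$complete)
})

test_that("growth stalls hit the max-snapshot guard with a diagnostic", {
  # free energy force (-grad F) always points away from the product
  away <- gradient_field(gradient = function(chi) c(10, 0), dim = 2)
  expect_error(
    grow_path(c(0, 0), c(1, 0), away,
              grow_config(s_g = 0.1, w = 1, sweeps = 0,
                          max_snapshots = 30)),
    "stall")
})

test_that("the grown path avoids the barrier the straight path climbs", {
  fx <- ala_fixture()
  s <- fx$surface
  run <- grow_path(fx$reactant, fx$product, s,
                   grow_config(s_g = fx$s_g, w = fx$w, s_op = fx$s_op))
  straight <- interpolate_linear(fx$reactant, fx$product, run$n_snapshots)
  f_grown <- apply(run$path$snapshots, 1, s$value)
  f_straight <- apply(straight$snapshots, 1, s$value)
  expect_lt(max(f_grown), max(f_straight))
})

test_that("budget arithmetic reproduces the protocol accounting exactly", {
  full <- budget(m = 40, method = "full_path", iterations = 200,
                 sampling_ps = 3, timestep_fs = 1)
  expect_equal(full$n_simulations, 8000L)
  expect_equal(full$total_ns, 24)
  expect_equal(full$steps_per_snapshot, 6e5)
  grow <- budget(m = 40, method = "growing", sweeps = 2,
                 sampling_ps = 3, timestep_fs = 1)
  expect_equal(grow$n_simulations, 2L * (40L + 40L * 39L / 2L))
  expect_equal(grow$n_simulations, 1640L)
  expect_equal(grow$total_ns, 4.92)
  expect_equal(grow$steps_per_snapshot, 1.23e5)
  # degenerate single-snapshot path admits no sweeps
  expect_equal(budget(m = 1, method = "growing", sweeps = 2)$n_simulations, 0L)
  # counts are exact integers, no float drift
  expect_type(full$n_simulations, "integer")
  expect_type(grow$n_simulations, "integer")
})
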