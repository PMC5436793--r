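test_that("perpendicular component is orthogonal by construction", {
  expect_equal(perp_component(c(2, 0), c(1, 0)), c(0, 0))
  expect_equal(perp_component(c(1, 0), c(0, 1)), c(-1, 0))
  set.seed(9)
  for (rep in 1:30) {
    g <- rnorm(4)
    t0 <- rnorm(4)
    t0 <- t0 / sqrt(sum(t0^2))
    p <- perp_component(g, t0)
    expect_lt(abs(sum(p * t0)), 1e-12)
  }
  expect_error(perp_component(c(1, 0), c(2, 0)), "unit")
})

test_that("snapshots on a symmetry axis of a saddle do not drift off it", {
  s <- surface_saddle()
  p <- interpolate_linear(c(-1, 0), c(1, 0), 9)
  p1 <- sd_sweep(p, s, 0.01)
  expect_lt(max(abs(p1$snapshots[, 2])), 1e-12)
})

test_that("one steepest-descent sweep lowers the free energy sum on the fixture", {
  fx <- ala_fixture()
  p <- interpolate_linear(fx$reactant, fx$product, 25)
  before <- sum(apply(p$snapshots, 1, fx$surface$value))
  p1 <- sd_sweep(p, fx$surface, 0.002)
  after <- sum(apply(p1$snapshots, 1, fx$surface$value))
  expect_lt(after, before)
  # anchors never move
  expect_equal(p1$snapshots[1, ], p$snapshots[1, ])
  expect_equal(p1$snapshots[25, ], p$snapshots[25, ])
})

test_that("a path already on the minimum path barely moves under a sweep", {
  fx <- ala_fixture()
  s <- fx$surface
  sad <- find_saddle(s, c(-2.5, -2.5), c(2.5, 2.5), n_scan = 9)
  mep <- trace_descent_path(s, sad, h = 0.005)
  idx <- round(seq(1, nrow(mep$snapshots), length.out = 31))
  p <- reparametrize(new_path(mep$snapshots[idx, ]))
  p1 <- sd_sweep(p, s, 0.002)
  # reparametrization slides snapshots along the curve; what must be
  # small is the move off the path
  expect_lt(path_deviation(p1, p), 1e-3)
})

test_that("the variable step rule follows the printed halve/reset schedule", {
  expect_equal(variable_step_controller(c(10), 0.004, 0.004), 0.004)
  expect_equal(variable_step_controller(c(10, 9), 0.004, 0.004), 0.002)
  expect_equal(variable_step_controller(c(10, 9, 8.5), 0.002, 0.004), 0.001)
  expect_equal(variable_step_controller(c(9, 10), 0.001, 0.004), 0.004)
  # inverted (conventional) rule
  expect_equal(variable_step_controller(c(9, 10), 0.004, 0.004,
                                        inverted = TRUE), 0.002)
  expect_equal(variable_step_controller(c(10, 9), 0.001, 0.004,
                                        inverted = TRUE), 0.004)
})

test_that("angle smoothing decreases the bending objective and fixes anchors", {
  elbow <- new_path(rbind(c(0, 0), c(1, 0), c(1, 1)))
  f0 <- smooth_objective(elbow)
  expect_equal(f0, (pi / 2 - pi)^2, tolerance = 1e-12)
  sm <- smooth_path(elbow, steps = 200, step_size = 1e-3)
  expect_lt(sm$f_final, sm$f_initial)
  expect_equal(sm$path$snapshots[1, ], c(0, 0))
  expect_equal(sm$path$snapshots[3, ], c(1, 1))
  # straight path: f = 0 and unchanged
  straight <- interpolate_linear(c(0, 0), c(1, 1), 5)
  sms <- smooth_path(straight)
  expect_equal(sms$f_initial, 0)
  expect_equal(sms$path$snapshots, straight$snapshots, tolerance = 1e-12)
})

test_that("smoothing never increases the objective on random paths", {
  set.seed(21)
  for (rep in 1:5) {
    p <- new_path(matrix(rnorm(16), ncol = 2))
    sm <- smooth_path(p, steps = 150, step_size = 1e-3)
    expect_lte(sm$f_final, sm$f_initial)
  }
})

test_that("sigma-perp implements the RMS-per-dimension reading", {
  p1 <- new_path(rbind(c(0, 0), c(1, 0)))
  g <- rbind(c(0, 0), c(0, 0))
  expect_equal(sigma_perp(p1, g), 0)
  # single effective snapshot with P_op = (3, 4): sqrt(25 / (n m))
  p <- new_path(rbind(c(0, 0), c(1, 0), c(2, 0)))
  grads <- rbind(c(0, 0), c(0, -5), c(0, 0))  # perp component (0,5) at i=2
  expect_equal(sigma_perp(p, grads), sqrt(25 / 6), tolerance = 1e-12)
  expect_equal(sigma_perp(p, grads, mean_square = TRUE), 25 / 3,
               tolerance = 1e-12)
})

test_that("quasi-Newton respects the step-control limits", {
  fx <- ala_fixture()
  p <- interpolate_linear(fx$reactant, fx$product, 15)
  # s_step -> 0 leaves the path unchanged (no smoothing, no reparam drift)
  cfg0 <- optimize_config("quasi_newton", s_step = 1e-12, smooth_steps = 0)
  r0 <- quasi_newton_sweep(p, fx$surface, cfg0)
  expect_lt(max(abs(r0$path$snapshots - p$snapshots)), 1e-9)
  # first iteration with identity scaling and s_step = 1 is one P_op step
  cfg1 <- optimize_config("quasi_newton", s_step = 1, smooth_steps = 0)
  r1 <- quasi_newton_sweep(p, fx$surface, cfg1)
  grads <- t(apply(p$snapshots, 1, fx$surface$gradient))
  P <- t(vapply(1:15, function(i)
    perp_component(grads[i, ], tangent(p, i)), numeric(2)))
  manual <- p$snapshots + P
  manual[c(1, 15), ] <- p$snapshots[c(1, 15), ]
  manual <- reparametrize(new_path(manual))$snapshots
  expect_lt(max(abs(r1$path$snapshots - manual)), 1e-9)
})

test_that("optimization converges on the fixture and anchors stay put", {
  fx <- ala_fixture()
  p0 <- interpolate_linear(fx$reactant, fx$product, 30)
  res <- optimize_path(p0, fx$surface,
                       optimize_config("sd_fixed", s_op = 0.002,
                                       max_iter = 400, tol_factor = 0.05))
  expect_true(res$converged)
  expect_lt(res$sigma_final, 0.05 * res$sigma_initial)
  expect_equal(res$path$snapshots[1, ], p0$snapshots[1, ])
  expect_equal(res$path$snapshots[30, ], p0$snapshots[30, ])
  expect_equal(res$n_gradient_evals,
               30L * (max(res$trace$iteration) + 1L))
  # trace is tidy-accessible
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1L)
})

test_that("variable-step optimization runs and records its step sizes", {
  fx <- ala_fixture()
  p0 <- interpolate_linear(fx$reactant, fx$product, 20)
  res <- optimize_path(p0, fx$surface,
                       optimize_config("sd_variable", s_op_initial = 0.004,
                                       max_iter = 30, tol_factor = 0))
  expect_true(all(res$trace$s_op <= 0.004))
  expect_gt(length(unique(res$trace$s_op)), 1L)
})
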