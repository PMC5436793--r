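test_that("Z matrix assembles from CV gradients and masses", {
  # single particle, coordinate CVs x and y: Z = I/m
  sys <- toy_harmonic_system(mass = 12)
  zm <- z_matrix(sys, sys$coords0)
  expect_equal(zm$Z, diag(2) / 12)
  expect_equal(zm$det, 1 / 144)
  expect_false(zm$singular)
  # one distance CV between masses m1, m2: scalar 1/m1 + 1/m2
  sysd <- toy_distance_system(masses = c(12, 16))
  zd <- z_matrix(sysd, rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(as.numeric(zd$Z), 1 / 12 + 1 / 16)
  # duplicated CV specs make Z singular
  sys2 <- toy_system(masses = 12,
                     potential = potential_harmonic(1, matrix(0, 1, 3)),
                     cvs = list(cv_coordinate(1, 1), cv_coordinate(1, 1)),
                     coords0 = matrix(0, 1, 3))
  z2 <- z_matrix(sys2, sys2$coords0)
  expect_equal(z2$det, 0)
  expect_true(z2$singular)
})

test_that("SHAKE restores constraints and reports zero lambda when satisfied", {
  sys <- toy_harmonic_system()
  cfg <- md_config()
  ref <- sys$coords0
  tgt <- ref[1, 1:2]
  out <- shake_correct(sys, ref, ref, tgt, cfg)
  expect_equal(out$lambda, c(0, 0))
  expect_equal(out$coords, ref)
  # a displaced unconstrained step is pulled back onto the target
  unc <- ref
  unc[1, 1] <- unc[1, 1] + 0.1
  out2 <- shake_correct(sys, unc, ref, tgt, cfg)
  expect_lt(abs(out2$coords[1, 1] - tgt[1]), cfg$shake_tol)
  expect_true(out2$lambda[1] != 0)
})

test_that("SHAKE residuals meet tolerance for randomized perturbations", {
  set.seed(31)
  sysd <- toy_distance_system()
  cfg <- md_config()
  ref <- rbind(c(0, 0, 0), c(2.7, 0, 0))
  for (rep in 1:20) {
    unc <- ref + matrix(rnorm(6, sd = 0.05), 2, 3)
    out <- shake_correct(sysd, unc, ref, 2.7, cfg)
    expect_lte(out$residual, cfg$shake_tol)
    d <- out$coords[2, ] - out$coords[1, ]
    expect_equal(sqrt(sum(d * d)), 2.7, tolerance = 1e-7)
  }
})

test_that("constrained harmonic dynamics recovers the exact mean force", {
  sys <- toy_harmonic_system(k = 2, center = c(0.5, -0.25, 0))
  cfg <- md_config(n_prod = 2000, seed = 3)
  est <- run_constrained(sys, targets = c(1.2, 0.4), cfg)
  want <- c(2 * (1.2 - 0.5), 2 * (0.4 + 0.25))
  expect_lt(max(abs(est$lambda_mean - want) -
                  3 * est$lambda_se - 1e-8), 0)
  expect_equal(est$n_samples, 2000L)
  expect_true(all(est$lambda_se >= 0))
  # |Z|^{-1/2} for coordinate CVs is the mass, exactly
  expect_equal(est$z_invsqrt_mean, 12)
})

test_that("an ignorable constrained coordinate carries no mean force", {
  sys <- toy_system(
    masses = 12,
    potential = potential_harmonic(rbind(c(2, 0, 2)), matrix(0, 1, 3)),
    cvs = list(cv_coordinate(1, 2)),
    coords0 = matrix(0, 1, 3))
  est <- run_constrained(sys, targets = 0.7,
                         md_config(n_prod = 1500, seed = 5))
  expect_lt(abs(est$lambda_mean) - 3 * est$lambda_se - 1e-8, 0)
})

test_that("constrained runs are bit-reproducible under a fixed seed", {
  sys <- toy_coupled_system()
  cfg <- md_config(n_prod = 400, seed = 12)
  e1 <- run_constrained(sys, c(0.9, 0.1), cfg)
  e2 <- run_constrained(sys, c(0.9, 0.1), cfg)
  expect_identical(e1$lambda_samples, e2$lambda_samples)
  expect_identical(e1$lambda_mean, e2$lambda_mean)
  # and the outer RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(run_constrained(sys, c(0.9, 0.1), cfg))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the coupled toy recovers its closed-form mean force within error", {
  sys <- toy_coupled_system()
  cfg <- md_config(n_prod = 6000, seed = 8)
  tgt <- c(1.1, 0.2)
  est <- run_constrained(sys, tgt, cfg)
  want <- sys$mean_force(tgt)
  z <- abs(est$lambda_mean - want) / est$lambda_se
  expect_lt(max(z), 3)
})

test_that("a mean-force field behaves as a gradient provider", {
  sys <- toy_harmonic_system(k = 2, center = c(0.5, -0.25, 0))
  f <- mean_force_field(sys, md_config(n_prod = 800, seed = 2))
  g1 <- f$gradient(c(1.0, 0.0))
  expect_equal(g1, c(2 * 0.5, 2 * 0.25), tolerance = 1e-6)
  expect_false(f$has_value)
  # at the minimum the mean force vanishes
  g0 <- f$gradient(c(0.5, -0.25))
  expect_lt(max(abs(g0)), 1e-8)
  est <- f$last_estimate()
  expect_s3_class(est, "lambda_estimate")
})

test_that("independent seeds agree with the closed form on average", {
  sys <- toy_coupled_system()
  tgt <- c(0.8, -0.3)
  want <- sys$mean_force(tgt)
  ests <- lapply(1:6, function(s)
    run_constrained(sys, tgt, md_config(n_prod = 1200, seed = 100 + s)))
  mats <- t(vapply(ests, function(e) e$lambda_mean, numeric(2)))
  expect_gt(max(dist(mats)), 0)  # distinct seeds give distinct estimates
  pooled <- colMeans(mats)
  pooled_se <- apply(mats, 2, sd) / sqrt(nrow(mats))
  expect_lt(max(abs(pooled - want) / (3 * pooled_se)), 1)
})

test_that("endpoint correction is -kBT log of the mean inverse root determinant", {
  est <- structure(list(z_invsqrt_mean = 1), class = "lambda_estimate")
  expect_equal(endpoint_correction(est, 298), 0)
  este <- structure(list(z_invsqrt_mean = exp(1)), class = "lambda_estimate")
  expect_equal(endpoint_correction(este, 298),
               -gp_constants$kB * 298, tolerance = 1e-12)
  expect_equal(endpoint_correction(este, 298), -0.5922, tolerance = 1e-3)
  bad <- structure(list(z_invsqrt_mean = -1), class = "lambda_estimate")
  expect_error(endpoint_correction(bad), "positive")
  # identical Z at both endpoints cancels in the 0 -> 1 difference
  sys <- toy_harmonic_system()
  c1 <- endpoint_correction(
    run_constrained(sys, c(0, 0), md_config(n_prod = 200, seed = 1)))
  c2 <- endpoint_correction(
    run_constrained(sys, c(0.8, 0.3), md_config(n_prod = 200, seed = 2)))
  expect_equal(c1 - c2, 0)
})

test_that("thermodynamic integration along a segment recovers the harmonic dF", {
  k <- 2; x0 <- c(0.5, -0.25)
  sys <- toy_harmonic_system(k = k, center = c(x0, 0))
  a <- c(-0.2, 0.3); b <- c(1.5, -0.85)
  p <- interpolate_linear(a, b, 9)
  field <- mean_force_field(sys, md_config(n_prod = 600, seed = 17))
  prof <- profile_on_field(p, field)
  want <- 0.5 * k * (sum((b - x0)^2) - sum((a - x0)^2))
  expect_equal(prof$F[nrow(prof)], want, tolerance = 1e-6)
  # the entropic correction is much smaller than the integral term here
  est_a <- run_constrained(sys, a, md_config(n_prod = 300, seed = 4))
  est_b <- run_constrained(sys, b, md_config(n_prod = 300, seed = 5))
  term2 <- endpoint_correction(est_b) - endpoint_correction(est_a)
  expect_lt(abs(term2), abs(prof$F[nrow(prof)]))
})

test_that("the velocity-Verlet fallback agrees with Beeman at equilibrium", {
  sys <- toy_harmonic_system(k = 2, center = c(0.5, -0.25, 0))
  tgt <- c(1.0, 0.1)
  eb <- run_constrained(sys, tgt, md_config(n_prod = 800, seed = 6))
  ev <- run_constrained(sys, tgt, md_config(n_prod = 800, seed = 6,
                                            integrator = "velocity_verlet"))
  want <- c(2 * 0.5, 2 * 0.35)
  expect_lt(max(abs(eb$lambda_mean - want)), 1e-6)
  expect_lt(max(abs(ev$lambda_mean - want)), 1e-6)
})
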