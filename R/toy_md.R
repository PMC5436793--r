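#' Toy particle systems for constrained dynamics
#'
#' A toy system is a set of point particles in an analytic potential with
#' a list of collective variables. It exists to validate the blue-moon
#' mean-force estimator: the ensemble average of the SHAKE Lagrange
#' multipliers under constrained dynamics estimates \eqn{\partial F /
#' \partial \chi}, and for harmonic potentials the closed form is known
#' exactly.
#'
#' @param masses Numeric vector of atom masses (amu).
#' @param potential List with functions `value(coords)` (kcal/mol) and
#'   `gradient(coords)` (N x 3 matrix, kcal/mol/A).
#' @param cvs List of [cv_spec] objects.
#' @param coords0 Initial N x 3 coordinates.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(masses, potential, cvs, coords0) {
  coords0 <- as.matrix(coords0)
  stopifnot(all(masses > 0), nrow(coords0) == length(masses),
            ncol(coords0) == 3L)
  structure(list(masses = as.numeric(masses), potential = potential,
                 cvs = cvs, coords0 = coords0, n_cv = length(cvs)),
            class = "toy_system")
}

#' Harmonic potential on Cartesian coordinates
#'
#' \eqn{V = \tfrac{1}{2} \sum k (x - x_0)^2} over all coordinates.
#'
#' @param k Force constant (kcal/mol/A^2); scalar or N x 3.
#' @param center N x 3 matrix of equilibrium positions.
#' @return A potential list usable in [toy_system()].
#' @export
potential_harmonic <- function(k, center) {
  center <- as.matrix(center)
  kk <- if (length(k) == 1) matrix(k, nrow(center), 3L) else as.matrix(k)
  list(
    value = function(coords) 0.5 * sum(kk * (as.matrix(coords) - center)^2),
    gradient = function(coords) kk * (as.matrix(coords) - center)
  )
}

#' Sum of potentials
#'
#' @param ... Potential lists.
#' @return A composed potential list.
#' @export
potential_sum <- function(...) {
  parts <- list(...)
  list(
    value = function(coords) sum(vapply(parts, function(p)
      p$value(coords), numeric(1))),
    gradient = function(coords) Reduce(`+`, lapply(parts, function(p)
      p$gradient(coords)))
  )
}

#' Double-well potential along one coordinate
#'
#' \eqn{V = a (x^2 - b^2)^2} on one Cartesian component of one atom.
#'
#' @param a Quartic coefficient (kcal/mol/A^4).
#' @param b Well position (A).
#' @param atom,axis Which coordinate.
#' @param n_atoms Total atom count (for the gradient shape).
#' @return A potential list.
#' @export
potential_double_well_1d <- function(a = 1, b = 1, atom = 1L, axis = 1L,
                                     n_atoms = 1L) {
  list(
    value = function(coords) {
      x <- as.matrix(coords)[atom, axis]
      a * (x^2 - b^2)^2
    },
    gradient = function(coords) {
      g <- matrix(0, n_atoms, 3L)
      x <- as.matrix(coords)[atom, axis]
      g[atom, axis] <- 4 * a * x * (x^2 - b^2)
      g
    }
  )
}

#' MD configuration for the toy engine
#'
#' @param timestep Integration timestep (fs, default 1.0).
#' @param temperature Target temperature (K, default 298).
#' @param tau_thermostat Berendsen coupling time (fs, default 100).
#' @param shake_tol Constraint tolerance in CV units (default 1e-8).
#' @param shake_maxit Maximum SHAKE Newton iterations per step.
#' @param n_prod Production steps (each contributes one lambda sample).
#' @param n_equil Equilibration steps discarded before averaging; default
#'   20% of production.
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @param integrator `"beeman"` (default) or `"velocity_verlet"`
#'   (cross-checking fallback; equilibrium averages should not depend on
#'   the choice).
#' @param collision_interval Every this many steps the velocities are
#'   redrawn from the Maxwell distribution (Andersen-style massive
#'   collision) and re-projected onto the constraint manifold. Weak
#'   coupling alone is pathological on systems with a handful of degrees
#'   of freedom (energy migrates into a quasi-static drift mode and the
#'   kinetic temperature collapses); the periodic redraw restores
#'   canonical sampling. Set to `Inf` to disable.
#' @return A list of class `md_config`.
#' @export
md_config <- function(timestep = 1.0, temperature = 298,
                      tau_thermostat = 100, shake_tol = 1e-8,
                      shake_maxit = 100L, n_prod = 3000L,
                      n_equil = NULL, seed = 1L,
                      integrator = c("beeman", "velocity_verlet"),
                      collision_interval = 50L) {
  integrator <- match.arg(integrator)
  if (is.null(n_equil)) n_equil <- as.integer(ceiling(0.2 * n_prod))
  stopifnot(timestep > 0, temperature > 0, tau_thermostat > 0,
            shake_tol > 0, n_prod >= 1, collision_interval >= 1)
  structure(list(timestep = timestep, temperature = temperature,
                 tau_thermostat = tau_thermostat, shake_tol = shake_tol,
                 shake_maxit = as.integer(shake_maxit),
                 n_prod = as.integer(n_prod),
                 n_equil = as.integer(n_equil), seed = as.integer(seed),
                 integrator = integrator,
                 collision_interval = collision_interval),
            class = "md_config")
}

cv_values_all <- function(system, coords) {
  vapply(system$cvs, cv_value, numeric(1), coords = coords)
}

# n_cv x (3N) matrix of flattened CV gradients.
cv_grad_matrix <- function(system, coords) {
  t(vapply(system$cvs, function(sp) as.vector(cv_gradient(sp, coords)),
           numeric(3L * nrow(coords))))
}

#' Constraint matrix Z
#'
#' The mass-weighted Gram matrix of the CV gradients,
#' \eqn{Z_{\alpha\beta} = \sum_i (1/m_i) \partial\sigma_\alpha/\partial
#' x_i \, \partial\sigma_\beta/\partial x_i}. Its determinant enters the
#' entropic correction term of the constrained free energy; linearly
#' dependent CV gradients make it singular (flagged, not an error).
#'
#' @param system A `toy_system`.
#' @param coords N x 3 coordinates.
#' @return List of class `z_matrix` with elements `Z` (n x n symmetric
#'   matrix), `det`, and `singular` flag.
#' @export
z_matrix <- function(system, coords) {
  G <- cv_grad_matrix(system, coords)
  W <- G * rep(rep(1 / system$masses, times = 3L), each = nrow(G))
  Z <- W %*% t(G)
  Z <- (Z + t(Z)) / 2
  d <- det(Z)
  structure(list(Z = Z, det = d,
                 singular = abs(d) < 1e-12 * max(abs(diag(Z)))^nrow(Z)),
            class = "z_matrix")
}

# Solve the coupled (matrix) SHAKE problem: find lambda so that
#   coords_corrected = coords_unc + coeff * t(G_ref) lambda / m
# satisfies cv = targets. Newton iteration on lambda; G_ref is evaluated
# at the reference (pre-step, constrained) coordinates.
shake_solve <- function(system, coords_unc, G_ref, targets, coeff,
                        tol, maxit, periodic) {
  nat <- nrow(coords_unc)
  invm3 <- rep(1 / system$masses, times = 3L)
  lambda <- numeric(system$n_cv)
  # displacement direction per constraint, flattened: coeff * g_ref / m
  D <- t(G_ref) * invm3 * coeff            # (3N) x n
  x0 <- as.vector(coords_unc)
  for (it in seq_len(maxit)) {
    x <- x0 + as.vector(D %*% lambda)
    cc <- matrix(x, nat, 3L)
    vals <- cv_values_all(system, cc)
    r <- cv_displacement(targets, vals, periodic)
    if (max(abs(r)) <= tol)
      return(list(coords = cc, lambda = lambda, iters = it,
                  residual = max(abs(r))))
    Gc <- cv_grad_matrix(system, cc)
    J <- Gc %*% D                          # d residual / d lambda
    lambda <- lambda - solve(J, r)
  }
  abort(sprintf("SHAKE failed to converge in %d iterations (worst residual %.3g)",
                maxit, max(abs(r))))
}

#' SHAKE correction of an unconstrained step
#'
#' Given coordinates after an unconstrained update and the constrained
#' reference coordinates before it, finds coupled Lagrange multipliers
#' such that adding the mass-weighted constraint-gradient displacement
#' restores every CV to its target within tolerance. The multipliers are
#' returned in force units (kcal/mol per CV unit): the displacement
#' applied is `coeff * lambda * grad(sigma) / m` with
#' `coeff = timestep^2` for a plain position-Verlet step, so `lambda` is
#' the constraint force whose action over one step produces the
#' correction.
#'
#' @param system A `toy_system`.
#' @param coords_unc Coordinates after the unconstrained step.
#' @param coords_ref Constrained reference coordinates (constraint
#'   gradients are evaluated here).
#' @param targets Numeric vector of CV targets.
#' @param cfg An [md_config()].
#' @param coeff Position-response coefficient of the integrator (fs^2);
#'   default `cfg$timestep^2`.
#' @return List with `coords`, `lambda` (force units), `iters`,
#'   `residual`.
#' @export
shake_correct <- function(system, coords_unc, coords_ref, targets, cfg,
                          coeff = cfg$timestep^2) {
  periodic <- vapply(system$cvs, function(s) isTRUE(s$periodic), logical(1))
  G_ref <- cv_grad_matrix(system, as.matrix(coords_ref))
  shake_solve(system, as.matrix(coords_unc), G_ref, targets,
              coeff * gp_constants$accel, cfg$shake_tol, cfg$shake_maxit,
              periodic)
}

# Remove velocity components along the constraint gradients (RATTLE-style
# projection): solve Z mu = G M^-1 ... here directly G v = 0.
project_velocities <- function(system, coords, vel) {
  G <- cv_grad_matrix(system, coords)
  invm3 <- rep(1 / system$masses, times = 3L)
  v <- as.vector(vel)
  Zm <- G %*% (t(G) * invm3)
  rhs <- G %*% v
  mu <- solve(Zm, rhs)
  v <- v - (t(G) * invm3) %*% mu
  matrix(v, nrow(coords), 3L)
}

kinetic_temperature <- function(system, vel, ndof) {
  ke <- 0.5 * sum(system$masses * rowSums(vel * vel)) * gp_constants$kin
  2 * ke / (ndof * gp_constants$kB)
}

# Damped gradient descent on sum (sigma - target)^2 to land on the
# constraint manifold before dynamics begin.
relax_to_constraints <- function(system, targets, tol = 1e-10,
                                 maxit = 5000L) {
  coords <- system$coords0
  periodic <- vapply(system$cvs, function(s) isTRUE(s$periodic), logical(1))
  step <- 0.2
  for (it in seq_len(maxit)) {
    vals <- cv_values_all(system, coords)
    r <- cv_displacement(targets, vals, periodic)
    if (max(abs(r)) < tol) return(coords)
    G <- cv_grad_matrix(system, coords)
    g <- 2 * as.vector(t(G) %*% r)       # gradient of sum r^2 wrt coords
    coords <- coords - step * matrix(g, nrow(coords), 3L) /
      max(1, sqrt(sum(g * g)))
  }
  abort("failed to relax onto the constraint manifold")
}

#' Run a constrained toy-MD simulation
#'
#' Beeman-integrated, Berendsen-thermostatted dynamics with all CVs held
#' at `targets` by coupled SHAKE. Each production step contributes one
#' sample of the Lagrange multipliers (force units; `<lambda>` estimates
#' \eqn{+\partial F/\partial\chi}) and one sample of
#' \eqn{|Z|^{-1/2}}. Standard errors of `<lambda>` are block averages
#' (about 50 blocks) because successive MD samples are correlated.
#' Deterministic given `cfg$seed`.
#'
#' @param system A `toy_system`.
#' @param targets Numeric CV target vector.
#' @param cfg An [md_config()].
#' @return Object of class `lambda_estimate`: list with `lambda_mean`,
#'   `lambda_se`, `n_samples`, `z_invsqrt_mean`, `chi` (the targets),
#'   `temperature_mean`, and the raw `lambda_samples` matrix.
#' @export
run_constrained <- function(system, targets, cfg = md_config()) {
  with_seed(cfg$seed, function() run_constrained_impl(system, targets, cfg))
}

run_constrained_impl <- function(system, targets, cfg) {
  nat <- length(system$masses)
  ncv <- system$n_cv
  dt <- cfg$timestep
  periodic <- vapply(system$cvs, function(s) isTRUE(s$periodic), logical(1))
  ndof <- max(1L, 3L * nat - ncv)

  coords <- relax_to_constraints(system, targets)
  # Maxwell-Boltzmann velocities, then remove constraint-direction parts
  sdv <- sqrt(gp_constants$kB * cfg$temperature * gp_constants$accel /
                system$masses)
  vel <- matrix(rnorm(3L * nat), nat, 3L) * sdv
  vel <- project_velocities(system, coords, vel)

  accel_of <- function(coords, lambda, G) {
    # total acceleration (A/fs^2) from potential plus constraint force
    Fp <- -system$potential$gradient(coords)
    Fc <- matrix(as.vector(t(G) %*% lambda), nat, 3L)
    (Fp + Fc) / system$masses * gp_constants$accel
  }

  # static initial multipliers: cancel constraint-direction acceleration
  G <- cv_grad_matrix(system, coords)
  invm3 <- rep(1 / system$masses, times = 3L)
  Fp <- -as.vector(system$potential$gradient(coords))
  Zm <- G %*% (t(G) * invm3)
  lam0 <- as.vector(solve(Zm, -G %*% (Fp * invm3)))
  a_prev <- accel_of(coords, lam0, G)
  a_cur <- a_prev

  n_total <- cfg$n_equil + cfg$n_prod
  lam_samples <- matrix(NA_real_, cfg$n_prod, ncv)
  z_samples <- numeric(cfg$n_prod)
  temp_acc <- 0
  beeman <- cfg$integrator == "beeman"
  # position-response coefficient of the current-step force
  coeff <- if (beeman) (2 / 3) * dt * dt else 0.5 * dt * dt

  for (step in seq_len(n_total)) {
    G <- cv_grad_matrix(system, coords)
    Fp <- -system$potential$gradient(coords)
    a_pot <- Fp / system$masses * gp_constants$accel
    # unconstrained position update
    x_unc <- if (beeman) {
      coords + vel * dt + (dt * dt / 6) * (4 * a_pot - a_prev)
    } else {
      coords + vel * dt + 0.5 * dt * dt * a_pot
    }
    sol <- shake_solve(system, x_unc, G, targets,
                       coeff * gp_constants$accel,
                       cfg$shake_tol, cfg$shake_maxit, periodic)
    lambda <- sol$lambda
    a_tot <- a_pot + matrix(as.vector(t(G) %*% lambda), nat, 3L) /
      system$masses * gp_constants$accel
    new_coords <- sol$coords
    # velocity update with potential-only new force; RATTLE projection
    # absorbs the new constraint component
    Fp_new <- -system$potential$gradient(new_coords)
    a_pot_new <- Fp_new / system$masses * gp_constants$accel
    vel <- if (beeman) {
      vel + (dt / 6) * (2 * a_pot_new + 5 * a_tot - a_prev)
    } else {
      vel + 0.5 * dt * (a_tot + a_pot_new)
    }
    vel <- project_velocities(system, new_coords, vel)
    # Berendsen weak coupling
    Tk <- kinetic_temperature(system, vel, ndof)
    if (Tk > 0) {
      scale <- sqrt(1 + dt / cfg$tau_thermostat *
                      (cfg$temperature / Tk - 1))
      vel <- vel * scale
    }
    if (!all(is.finite(new_coords)))
      abort("constrained dynamics diverged (non-finite coordinates)")
    if (is.finite(cfg$collision_interval) &&
        step %% cfg$collision_interval == 0L) {
      vel <- matrix(rnorm(3L * nat), nat, 3L) * sdv
      vel <- project_velocities(system, new_coords, vel)
    }
    if (step > cfg$n_equil) {
      k <- step - cfg$n_equil
      lam_samples[k, ] <- lambda
      z_samples[k] <- 1 / sqrt(z_matrix(system, coords)$det)
      temp_acc <- temp_acc + Tk
    }
    a_prev <- a_tot
    coords <- new_coords
  }

  nb <- max(2L, min(50L, cfg$n_prod %/% 10L))
  block <- cfg$n_prod %/% nb
  se <- vapply(seq_len(ncv), function(j) {
    bm <- vapply(seq_len(nb), function(b)
      mean(lam_samples[((b - 1L) * block + 1L):(b * block), j]),
      numeric(1))
    sd(bm) / sqrt(nb)
  }, numeric(1))

  structure(
    list(lambda_mean = colMeans(lam_samples),
         lambda_se = se,
         n_samples = cfg$n_prod,
         z_invsqrt_mean = mean(z_samples),
         chi = targets,
         temperature_mean = temp_acc / cfg$n_prod,
         lambda_samples = lam_samples),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat("<lambda_estimate>", x$n_samples, "samples at chi = (",
      paste(signif(x$chi, 4), collapse = ", "), ")\n")
  cat("  <lambda> =", paste(signif(x$lambda_mean, 5), collapse = ", "),
      " (SE", paste(signif(x$lambda_se, 3), collapse = ", "), ")\n")
  invisible(x)
}

#' Mean-force gradient field from constrained dynamics
#'
#' Wraps the toy engine as a [gradient_field()]: each gradient call runs
#' one constrained simulation at the requested point and returns
#' `<lambda>` as \eqn{\nabla F} (so `-<lambda>` is the downhill
#' direction). Only the multiplier term of the free energy gradient is
#' used; `has_value` is `FALSE`. Successive calls use successive derived
#' seeds so repeated evaluations are independent yet reproducible.
#'
#' @param system A `toy_system`.
#' @param cfg An [md_config()]; `cfg$seed` seeds the stream.
#' @return A `gradient_field` with an extra `last_estimate()` accessor.
#' @export
mean_force_field <- function(system, cfg = md_config()) {
  env <- new.env(parent = emptyenv())
  env$call <- 0L
  env$last <- NULL
  periodic <- vapply(system$cvs, function(s) isTRUE(s$periodic), logical(1))
  f <- gradient_field(
    gradient = function(chi) {
      env$call <- env$call + 1L
      cfg_i <- cfg
      cfg_i$seed <- (cfg$seed + 7919L * env$call) %% 2147483647L
      est <- run_constrained(system, chi, cfg_i)
      env$last <- est
      est$lambda_mean
    },
    dim = system$n_cv,
    periodic = periodic
  )
  f$last_estimate <- function() env$last
  f
}

#' Entropic correction term of the constrained free energy
#'
#' \eqn{-k_B T \ln \langle |Z|^{-1/2} \rangle} in kcal/mol; the
#' end-to-end difference of this quantity corrects the thermodynamic
#' integral of `<lambda>`.
#'
#' @param estimate A `lambda_estimate`.
#' @param temperature Temperature in K.
#' @return The correction in kcal/mol.
#' @export
endpoint_correction <- function(estimate, temperature = 298) {
  z <- estimate$z_invsqrt_mean
  if (!is.finite(z) || z <= 0)
    abort("mean |Z|^(-1/2) must be positive")
  -gp_constants$kB * temperature * log(z)
}
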