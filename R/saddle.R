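#' Locate an index-1 saddle point of a 2-D surface
#'
#' Coarse grid scan over a bounding box for points where the gradient is
#' small and the (finite-difference) Hessian is indefinite, followed by
#' Newton refinement of the stationary point. Independent of the path
#' optimizers: uses only the field's gradient.
#'
#' @param field A `gradient_field` (dim 2).
#' @param lower,upper Bounding box corners.
#' @param n_scan Scan resolution per axis.
#' @param tol Gradient-norm convergence tolerance.
#' @return The saddle point (numeric length 2).
#' @export
find_saddle <- function(field, lower, upper, n_scan = 25L, tol = 1e-10) {
  sp <- find_stationary_points(field, lower, upper, n_scan, tol)
  sad <- sp[vapply(sp, function(q) q$index == 1L, logical(1))]
  if (length(sad) == 0)
    abort("no index-1 saddle found in the box")
  # the saddle of the optimal channel is the lowest-energy one
  if (isTRUE(field$has_value)) {
    fv <- vapply(sad, function(q) field$value(q$point), numeric(1))
    sad[[which.min(fv)]]$point
  } else {
    sad[[1L]]$point
  }
}

#' Enumerate stationary points of a 2-D field
#'
#' Damped Newton iteration on \eqn{\nabla F = 0} started from every node
#' of a coarse grid; converged points are deduplicated and classified by
#' the eigenvalues of the finite-difference Hessian (index = number of
#' negative eigenvalues).
#'
#' @inheritParams find_saddle
#' @return List of `list(point, index, eigenvalues)`.
#' @export
find_stationary_points <- function(field, lower, upper, n_scan = 25L,
                                   tol = 1e-10) {
  xs <- seq(lower[1L], upper[1L], length.out = n_scan)
  ys <- seq(lower[2L], upper[2L], length.out = n_scan)
  span <- max(upper - lower)
  out <- list()
  for (x in xs) for (y in ys) {
    p <- c(x, y)
    ok <- TRUE
    for (it in 1:80) {
      g <- field$gradient(p)
      if (!all(is.finite(p)) ||
          any(p < lower - span) || any(p > upper + span)) {
        ok <- FALSE; break
      }
      if (sqrt(sum(g * g)) < tol) break
      H <- num_jacobian(field$gradient, p, h = 1e-6)
      st <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) NULL)
      if (is.null(st)) { ok <- FALSE; break }
      ns <- sqrt(sum(st * st))
      if (ns > 0.25 * span) st <- st * (0.25 * span / ns)
      p <- p - st
    }
    if (!ok || sqrt(sum(field$gradient(p)^2)) > tol * 100) next
    if (any(vapply(out, function(q) sum((q$point - p)^2) < 1e-10,
                   logical(1)))) next
    H <- num_jacobian(field$gradient, p, h = 1e-6)
    ev <- eigen((H + t(H)) / 2, only.values = TRUE)$values
    out[[length(out) + 1L]] <- list(point = p,
                                    index = sum(ev < 0),
                                    eigenvalues = ev)
  }
  out
}

#' Trace the steepest-descent path from a saddle
#'
#' Fourth-order Runge-Kutta integration of \eqn{d\chi/dt = -\nabla F}
#' (normalized to unit speed) from the saddle in both directions along
#' the unstable eigenvector, until the gradient vanishes at a minimum.
#' The result is the dense minimum free energy path against which the
#' string optimizers are validated.
#'
#' @param field A `gradient_field` (dim 2).
#' @param saddle The saddle point (from [find_saddle()]).
#' @param h Arc-length integration step.
#' @param max_steps Per-branch step cap.
#' @param grad_tol Stop when the gradient norm falls below this.
#' @return A dense `cv_path` running minimum-to-minimum through the
#'   saddle.
#' @export
trace_descent_path <- function(field, saddle, h = 0.002,
                               max_steps = 20000L, grad_tol = 1e-5) {
  H <- num_jacobian(field$gradient, saddle, h = 1e-6)
  ev <- eigen((H + t(H)) / 2)
  vneg <- ev$vectors[, which.min(ev$values)]
  branch <- function(dir) {
    p <- saddle + 1e-4 * dir
    pts <- list(p)
    # unit speed away from minima; proportional speed below the floor so
    # the flow converges exponentially onto the minimum. The floor
    # scales with h to keep the stiffness h * kappa / floor inside the
    # integrator's stability region.
    floor_g <- 25 * h
    f <- function(x) {
      g <- field$gradient(x)
      -g / max(sqrt(sum(g * g)), floor_g)
    }
    for (i in seq_len(max_steps)) {
      g <- field$gradient(p)
      if (sqrt(sum(g * g)) < grad_tol) break
      k1 <- f(p)
      k2 <- f(p + h / 2 * k1)
      k3 <- f(p + h / 2 * k2)
      k4 <- f(p + h * k3)
      p_new <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (sqrt(sum((p_new - p)^2)) < 1e-12) break
      p <- p_new
      pts[[length(pts) + 1L]] <- p
    }
    do.call(rbind, pts)
  }
  up <- branch(vneg)
  down <- branch(-vneg)
  snaps <- rbind(up[rev(seq_len(nrow(up))), , drop = FALSE],
                 saddle,
                 down)
  new_path(snaps, periodic = field$periodic, complete = TRUE)
}

#' Maximum pointwise deviation of a path from a reference polyline
#'
#' For every snapshot of `path`, the distance to the nearest point on the
#' segments of `reference`; returns the maximum. Used to compare a
#' converged string against the dense steepest-descent oracle.
#'
#' @param path A `cv_path`.
#' @param reference A dense `cv_path` treated as a polyline.
#' @return Maximum over snapshots of the distance to the polyline.
#' @export
path_deviation <- function(path, reference) {
  P <- path$snapshots
  Q <- reference$snapshots
  A <- Q[-nrow(Q), , drop = FALSE]
  B <- Q[-1L, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB * AB)
  max(vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    tt <- rowSums(sweep(A, 2L, p, function(a, b) b - a) * AB) /
      pmax(len2, 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    proj <- A + AB * tt
    d2 <- rowSums(sweep(proj, 2L, p)^2)
    sqrt(min(d2))
  }, numeric(1)))
}
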