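#' Optimizer configuration
#'
#' @param method `"sd_fixed"` (steepest descent, fixed step),
#'   `"sd_variable"` (step halved/reset by the printed free-energy-sum
#'   rule), or `"quasi_newton"` (limited-memory BFGS proposal moved by the
#'   fraction `s_step`, followed by angle smoothing).
#' @param s_op Steepest-descent step size (CV units per unit gradient).
#' @param s_op_initial Initial/reset step for the variable-step rule
#'   (default 0.004).
#' @param s_step Quasi-Newton step-control fraction in (0, 1].
#' @param memory Limited-memory depth of the BFGS recursion.
#' @param smooth_steps,smooth_step_size Angle-smoothing descent schedule
#'   (defaults 1000 steps of 1e-4).
#' @param max_iter Maximum optimization iterations.
#' @param tol_factor Convergence when sigma-perp falls below `tol_factor`
#'   times its initial value (default 0.05), or `max_iter`, whichever
#'   comes first.
#' @param inverted_variable_rule If `TRUE`, the variable-step rule halves
#'   the step on an *increase* of the free-energy sum (the conventional
#'   reading) instead of the as-printed rule (halve on decrease, reset on
#'   increase).
#' @return A list of class `optimize_config`.
#' @export
optimize_config <- function(method = c("sd_fixed", "sd_variable",
                                       "quasi_newton"),
                            s_op = 0.002, s_op_initial = 0.004,
                            s_step = 0.2, memory = 5L,
                            smooth_steps = 1000L,
                            smooth_step_size = 1e-4,
                            max_iter = 200L, tol_factor = 0.05,
                            inverted_variable_rule = FALSE) {
  method <- match.arg(method)
  stopifnot(s_op > 0, s_op_initial > 0, s_step > 0, s_step <= 1,
            smooth_step_size > 0, max_iter >= 1)
  structure(list(method = method, s_op = s_op,
                 s_op_initial = s_op_initial, s_step = s_step,
                 memory = as.integer(memory),
                 smooth_steps = as.integer(smooth_steps),
                 smooth_step_size = smooth_step_size,
                 max_iter = as.integer(max_iter),
                 tol_factor = tol_factor,
                 inverted_variable_rule = isTRUE(inverted_variable_rule)),
            class = "optimize_config")
}

#' Perpendicular component of the free energy gradient
#'
#' The string-method update direction with identity metric:
#' \eqn{P_{op} = -\nabla F + (\nabla F \cdot s) s}, exactly orthogonal to
#' the unit tangent s. At a converged minimum free energy path the
#' gradient is parallel to the tangent and \eqn{P_{op} = 0}.
#'
#' @param gradF Free energy gradient at a snapshot.
#' @param tang Unit tangent at the snapshot.
#' @return The perpendicular update direction.
#' @export
perp_component <- function(gradF, tang) {
  nt <- sqrt(sum(tang * tang))
  if (abs(nt - 1) > 1e-9) abort("tangent must be a unit vector")
  -gradF + sum(gradF * tang) * tang
}

# Gradients and perpendicular components for every snapshot.
path_gradients <- function(path, field) {
  t(vapply(seq_len(path_m(path)),
           function(i) field$gradient(path$snapshots[i, ]),
           numeric(path_n(path))))
}

path_perp <- function(path, grads) {
  tg <- path_tangents(path)
  t(vapply(seq_len(nrow(grads)), function(i)
    perp_component(grads[i, ], tg[i, ]), numeric(ncol(grads))))
}

# Which snapshots are anchored (never moved by any optimizer)?
anchor_idx <- function(path) {
  m <- path_m(path)
  if (path$complete) c(1L, m) else 1L
}

#' One steepest-descent sweep
#'
#' Moves every non-anchor snapshot by `s_op * P_op` and reparametrizes.
#' The reactant is always anchored; the product is anchored once the path
#' is complete (during growth the newest snapshot moves too).
#'
#' @param path A `cv_path`.
#' @param field A `gradient_field`.
#' @param s_op Step size.
#' @param grads Optional precomputed m x n gradient matrix (one gradient
#'   evaluation per snapshot per sweep otherwise).
#' @return The updated, reparametrized `cv_path`.
#' @export
sd_sweep <- function(path, field, s_op, grads = NULL) {
  if (is.null(grads)) grads <- path_gradients(path, field)
  P <- path_perp(path, grads)
  keep <- anchor_idx(path)
  snaps <- path$snapshots
  mv <- setdiff(seq_len(path_m(path)), keep)
  snaps[mv, ] <- snaps[mv, ] + s_op * P[mv, , drop = FALSE]
  out <- new_path(snaps, periodic = path$periodic,
                  complete = path$complete)
  if (path_m(out) >= 3) out <- reparametrize(out) else out
}

#' Variable step-size controller
#'
#' The as-printed rule: if the sum of snapshot free energies decreased
#' relative to the previous iteration, the step is halved; otherwise it is
#' reset to the initial value. `inverted = TRUE` gives the conventional
#' rule (halve on increase, reset on decrease).
#'
#' @param sum_history Numeric vector of free-energy sums, most recent
#'   last; must include at least the previous and the current sum for the
#'   rule to fire.
#' @param s_current Current step size.
#' @param s_initial Initial (reset) step size.
#' @param inverted Use the conventional orientation of the rule.
#' @return The next step size.
#' @export
variable_step_controller <- function(sum_history, s_current, s_initial,
                                     inverted = FALSE) {
  k <- length(sum_history)
  if (k < 2) return(s_current)
  decreased <- sum_history[k] < sum_history[k - 1L]
  halve <- if (inverted) !decreased else decreased
  if (halve) s_current / 2 else s_initial
}

#' Smooth a path by angle-based descent
#'
#' Steepest descent on the bending objective
#' \eqn{f = \sum_i (\theta_i - \pi)^2}, where \eqn{\theta_i} is the angle
#' at snapshot i between the vectors to its neighbors. Only interior
#' snapshots move; the descent never lets f increase (a step that would is
#' retried at half size). Triples with a zero-length arm are skipped.
#'
#' @param path A `cv_path` with m >= 3.
#' @param steps Number of descent steps (default 1000).
#' @param step_size Descent step size (default 1e-4).
#' @return List with the smoothed `path`, `f_initial`, and `f_final`.
#' @export
smooth_path <- function(path, steps = 1000L, step_size = 1e-4) {
  m <- path_m(path)
  if (m < 3) abort("need at least 3 snapshots to smooth")
  s <- unwrap_snapshots(path)
  f0 <- smooth_objective(s)
  f <- f0
  for (it in seq_len(steps)) {
    g <- smooth_gradient(s)
    h <- step_size
    for (try in 1:4) {
      s_new <- s
      s_new[2:(m - 1L), ] <- s[2:(m - 1L), ] - h * g[2:(m - 1L), , drop = FALSE]
      f_new <- smooth_objective(s_new)
      if (f_new <= f) break
      h <- h / 2
    }
    if (f_new > f) break
    s <- s_new
    f <- f_new
    if (f < 1e-18) break
  }
  list(path = new_path(s, periodic = path$periodic,
                       complete = path$complete),
       f_initial = f0, f_final = f)
}

smooth_angles <- function(s) {
  m <- nrow(s)
  u <- s[1:(m - 2L), , drop = FALSE] - s[2:(m - 1L), , drop = FALSE]
  v <- s[3:m, , drop = FALSE] - s[2:(m - 1L), , drop = FALSE]
  nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
  ok <- nu > 1e-12 & nv > 1e-12
  ct <- rowSums(u * v) / pmax(nu * nv, 1e-300)
  ct <- pmin(pmax(ct, -1), 1)
  list(theta = acos(ct), u = u, v = v, nu = nu, nv = nv, ct = ct, ok = ok)
}

#' Bending objective of a path
#'
#' @param s An m x n snapshot matrix (or a `cv_path`).
#' @return \eqn{\sum_i (\theta_i - \pi)^2} over interior snapshots.
#' @export
smooth_objective <- function(s) {
  if (inherits(s, "cv_path")) s <- unwrap_snapshots(s)
  a <- smooth_angles(s)
  sum(((a$theta - pi)^2)[a$ok])
}

# Analytic gradient of the bending objective with respect to every
# snapshot. The factor (theta - pi)/sin(theta) is finite at theta = pi
# (limit -1), which keeps straight paths well behaved. Fully vectorized
# over the interior triples.
smooth_gradient <- function(s) {
  m <- nrow(s); n <- ncol(s)
  g <- matrix(0, m, n)
  a <- smooth_angles(s)
  st <- sin(a$theta)
  fac <- ifelse(st < 1e-8, -1, (a$theta - pi) / st)
  w <- ifelse(a$ok, -2 * fac, 0)
  # dcos/du and dcos/dv, rowwise over triples
  inv_uv <- 1 / pmax(a$nu * a$nv, 1e-300)
  dcos_du <- a$v * inv_uv - a$ct / pmax(a$nu^2, 1e-300) * a$u
  dcos_dv <- a$u * inv_uv - a$ct / pmax(a$nv^2, 1e-300) * a$v
  cu <- w * dcos_du
  cv <- w * dcos_dv
  g[1:(m - 2L), ] <- g[1:(m - 2L), ] + cu
  g[3:m, ] <- g[3:m, ] + cv
  g[2:(m - 1L), ] <- g[2:(m - 1L), ] - cu - cv
  g
}

#' Convergence metric: RMS perpendicular gradient
#'
#' \eqn{\sigma_\perp = \sqrt{\sum_i P_{op}^{(i)} \cdot P_{op}^{(i)} /
#' (n m)}}: the root-mean-square per-CV-dimension magnitude of the
#' perpendicular free energy gradients over the path. Smaller values mean
#' the gradients are more parallel to the path tangent. The
#' `mean_square` reading (no root, mean of squared norms over m) is
#' available behind a flag.
#'
#' @param path A `cv_path`.
#' @param grads m x n matrix of per-snapshot gradients.
#' @param mean_square Use the alternative no-root reading.
#' @return The convergence metric (gradient units).
#' @export
sigma_perp <- function(path, grads, mean_square = FALSE) {
  grads <- matrix(grads, nrow = path_m(path))
  P <- path_perp(path, grads)
  ss <- sum(P * P)
  n <- path_n(path); m <- path_m(path)
  if (mean_square) ss / m else sqrt(ss / (n * m))
}

## ---- quasi-Newton ---------------------------------------------------

# Two-loop L-BFGS recursion: direction = -H g from stored (s, y) pairs.
lbfgs_direction <- function(g, mem) {
  q <- g
  k <- length(mem$s)
  alpha <- numeric(k)
  if (k > 0) {
    for (i in k:1) {
      rho <- 1 / sum(mem$y[[i]] * mem$s[[i]])
      alpha[i] <- rho * sum(mem$s[[i]] * q)
      q <- q - alpha[i] * mem$y[[i]]
    }
    gamma <- sum(mem$s[[k]] * mem$y[[k]]) / sum(mem$y[[k]] * mem$y[[k]])
    q <- gamma * q
    for (i in 1:k) {
      rho <- 1 / sum(mem$y[[i]] * mem$s[[i]])
      beta <- rho * sum(mem$y[[i]] * q)
      q <- q + (alpha[i] - beta) * mem$s[[i]]
    }
  }
  -q
}

#' One quasi-Newton sweep
#'
#' Stacks all snapshots into one n*m vector, forms a limited-memory BFGS
#' proposal on the objective whose gradient is `-P_op`, moves each
#' snapshot the fraction `s_step` of the way toward the proposal, then
#' smooths the path ([smooth_path()]) and reparametrizes. If the proposal
#' is not a descent direction (or not finite) the sweep falls back to one
#' fixed-step steepest-descent sweep.
#'
#' @param path A `cv_path`.
#' @param field A `gradient_field`.
#' @param cfg An [optimize_config()] with `method = "quasi_newton"`.
#' @param state Internal memory carried across iterations (list with
#'   `mem`, `x_prev`, `g_prev`); pass the value returned by the previous
#'   call, or `NULL` on the first.
#' @param grads Optional precomputed gradients.
#' @return List with `path` and the updated `state`.
#' @export
quasi_newton_sweep <- function(path, field, cfg = optimize_config("quasi_newton"),
                               state = NULL, grads = NULL) {
  if (is.null(grads)) grads <- path_gradients(path, field)
  P <- path_perp(path, grads)
  keep <- anchor_idx(path)
  P[keep, ] <- 0
  g <- -as.vector(t(P))          # objective gradient = -P_op, stacked
  x <- as.vector(t(path$snapshots))
  if (is.null(state)) state <- list(mem = list(s = list(), y = list()),
                                    x_prev = NULL, g_prev = NULL)
  if (!is.null(state$x_prev)) {
    sv <- x - state$x_prev
    yv <- g - state$g_prev
    if (sum(sv * yv) > 1e-12) {
      state$mem$s <- c(state$mem$s, list(sv))
      state$mem$y <- c(state$mem$y, list(yv))
      if (length(state$mem$s) > cfg$memory) {
        state$mem$s <- state$mem$s[-1L]
        state$mem$y <- state$mem$y[-1L]
      }
    }
  }
  d <- lbfgs_direction(g, state$mem)
  fallback <- !all(is.finite(d)) || sum(d * g) >= 0
  if (fallback) {
    out <- sd_sweep(path, field, cfg$s_op, grads = grads)
    state$x_prev <- x
    state$g_prev <- g
    state$fallbacks <- (state$fallbacks %||% 0L) + 1L
    return(list(path = out, state = state))
  }
  x_bfgs <- x + d
  x_new <- x + cfg$s_step * (x_bfgs - x)
  snaps <- matrix(x_new, ncol = path_n(path), byrow = TRUE)
  snaps[keep, ] <- path$snapshots[keep, ]
  out <- new_path(snaps, periodic = path$periodic,
                  complete = path$complete)
  if (path_m(out) >= 3 && cfg$smooth_steps > 0)
    out <- smooth_path(out, cfg$smooth_steps, cfg$smooth_step_size)$path
  if (path_m(out) >= 3) out <- reparametrize(out)
  state$x_prev <- x
  state$g_prev <- g
  list(path = out, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimize a path on a free energy surface
#'
#' Iterates the selected optimizer until the convergence metric
#' \eqn{\sigma_\perp} falls below `tol_factor` times its initial value or
#' `max_iter` iterations are reached. One gradient evaluation per snapshot
#' per iteration is spent (and counted).
#'
#' @param path A complete `cv_path`.
#' @param field A `gradient_field`.
#' @param cfg An [optimize_config()].
#' @return Object of class `path_opt`: list with the final `path`, a
#'   `trace` tibble (iteration, sigma_perp, s_op, sum_F when available,
#'   cumulative gradient evaluations), `converged`, `config`.
#' @export
optimize_path <- function(path, field, cfg = optimize_config()) {
  field <- counted_field(field)
  has_val <- isTRUE(field$has_value)
  s_cur <- if (cfg$method == "sd_variable") cfg$s_op_initial else cfg$s_op
  sums <- numeric(0)
  qn_state <- NULL
  rows <- vector("list", cfg$max_iter + 1L)
  sigma0 <- NULL
  for (it in 0:cfg$max_iter) {
    grads <- path_gradients(path, field)
    sg <- sigma_perp(path, grads)
    if (is.null(sigma0)) sigma0 <- sg
    sumF <- if (has_val)
      sum(vapply(seq_len(path_m(path)),
                 function(i) field$value(path$snapshots[i, ]), numeric(1)))
    else NA_real_
    rows[[it + 1L]] <- tibble(iteration = it, sigma_perp = sg,
                              s_op = s_cur, sum_F = sumF,
                              n_evals = field$count())
    if (it == cfg$max_iter) break
    if (sg <= cfg$tol_factor * sigma0) break
    if (cfg$method == "sd_variable" && has_val) {
      sums <- c(sums, sumF)
      s_cur <- variable_step_controller(sums, s_cur, cfg$s_op_initial,
                                        cfg$inverted_variable_rule)
    }
    path <- switch(cfg$method,
      sd_fixed = sd_sweep(path, field, cfg$s_op, grads = grads),
      sd_variable = sd_sweep(path, field, s_cur, grads = grads),
      quasi_newton = {
        r <- quasi_newton_sweep(path, field, cfg, qn_state, grads = grads)
        qn_state <- r$state
        r$path
      })
  }
  trace <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  structure(
    list(path = path, trace = trace,
         converged = tail(trace$sigma_perp, 1L) <= cfg$tol_factor * sigma0,
         sigma_initial = sigma0,
         sigma_final = tail(trace$sigma_perp, 1L),
         n_gradient_evals = field$count(),
         config = cfg),
    class = "path_opt"
  )
}

#' @export
print.path_opt <- function(x, ...) {
  cat("<path_opt>", x$config$method, ":",
      max(x$trace$iteration), "iterations, sigma_perp",
      signif(x$sigma_initial, 4), "->", signif(x$sigma_final, 4),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  invisible(x)
}
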