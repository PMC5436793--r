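#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-snapshot or
#' per-iteration table of a result, `glance()` a one-row summary.
#'
#' @param x A `path_opt`, `grow_run`, `fe_profile`, `lambda_estimate`, or
#'   `cv_path`.
#' @param ... Unused.
#' @return A tibble.
#' @name growpath-tidiers
NULL

#' @rdname growpath-tidiers
#' @export
tidy.path_opt <- function(x, ...) x$trace

#' @rdname growpath-tidiers
#' @export
glance.path_opt <- function(x, ...) {
  tibble(method = x$config$method,
         iterations = max(x$trace$iteration),
         sigma_initial = x$sigma_initial,
         sigma_final = x$sigma_final,
         converged = x$converged,
         n_gradient_evals = x$n_gradient_evals)
}

#' @rdname growpath-tidiers
#' @export
tidy.grow_run <- function(x, ...) as_tibble(x$path)

#' @rdname growpath-tidiers
#' @export
glance.grow_run <- function(x, ...) {
  tibble(n_snapshots = x$n_snapshots,
         n_gradient_evals = x$n_gradient_evals,
         s_g = x$config$s_g, w = x$config$w,
         arc_length = arc_length(x$path))
}

#' @rdname growpath-tidiers
#' @export
tidy.fe_profile <- function(x, ...) as_tibble(x)

#' @rdname growpath-tidiers
#' @export
glance.fe_profile <- function(x, ...) {
  b <- barrier(x)
  tibble(delta_F = x$F[nrow(x)] - x$F[1L],
         barrier_height = b$height,
         barrier_xi = b$xi,
         correction = x$correction_term[nrow(x)])
}

#' @rdname growpath-tidiers
#' @export
tidy.lambda_estimate <- function(x, ...) {
  tibble(cv = seq_along(x$lambda_mean),
         chi = x$chi,
         lambda_mean = x$lambda_mean,
         lambda_se = x$lambda_se)
}

#' @rdname growpath-tidiers
#' @export
glance.lambda_estimate <- function(x, ...) {
  tibble(n_samples = x$n_samples,
         z_invsqrt_mean = x$z_invsqrt_mean,
         temperature_mean = x$temperature_mean)
}

#' @rdname growpath-tidiers
#' @export
tidy.cv_path <- function(x, ...) as_tibble(x)
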