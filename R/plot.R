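#' Plot a path (optionally on a surface contour)
#'
#' @param surface A `gradient_field` with values (analytic or grid), or
#'   `NULL` for a bare path plot.
#' @param paths A named list of `cv_path` objects (or a single path).
#' @param lower,upper Plot window corners; defaults to the bounding box
#'   of the paths padded by 20%.
#' @param bins Contour bins.
#' @return A ggplot object: filled contours of F with path polylines
#'   overlaid (first two CV dimensions).
#' @export
plot_path_on_surface <- function(surface, paths, lower = NULL,
                                 upper = NULL, bins = 25) {
  if (inherits(paths, "cv_path")) paths <- list(path = paths)
  all_pts <- do.call(rbind, lapply(paths, function(p) p$snapshots[, 1:2]))
  if (is.null(lower)) lower <- apply(all_pts, 2L, min) - 0.2 * diff(range(all_pts))
  if (is.null(upper)) upper <- apply(all_pts, 2L, max) + 0.2 * diff(range(all_pts))
  pd <- dplyr::bind_rows(lapply(names(paths), function(nm) {
    s <- paths[[nm]]$snapshots
    tibble(path = nm, x = s[, 1L], y = s[, 2L])
  }))
  g <- ggplot2::ggplot()
  if (!is.null(surface) && isTRUE(surface$has_value)) {
    xs <- seq(lower[1L], upper[1L], length.out = 80)
    ys <- seq(lower[2L], upper[2L], length.out = 80)
    sd_ <- expand.grid(x = xs, y = ys)
    sd_$F <- apply(sd_, 1L, function(r) surface$value(c(r[["x"]], r[["y"]])))
    g <- g + ggplot2::geom_contour_filled(
      data = sd_, ggplot2::aes(x = .data$x, y = .data$y, z = .data$F),
      bins = bins, alpha = 0.8)
  }
  g + ggplot2::geom_path(data = pd,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      color = .data$path),
                         linewidth = 0.8) +
    ggplot2::geom_point(data = pd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$path), size = 0.9) +
    ggplot2::labs(x = "CV 1", y = "CV 2", fill = "F (kcal/mol)")
}

#' @export
autoplot.cv_path <- function(object, ...) {
  plot_path_on_surface(NULL, list(path = object))
}

#' @export
autoplot.fe_profile <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$xi, y = .data$F)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(xi), y = "F (kcal/mol)")
  if (any(is.finite(object$stderr)))
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$F - .data$stderr,
                   ymax = .data$F + .data$stderr), alpha = 0.25)
  g
}

#' @export
autoplot.path_opt <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$sigma_perp)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = expression(sigma[perp]))
}

#' Compare convergence traces of several optimizations
#'
#' @param runs Named list of `path_opt` objects.
#' @return A ggplot of the sigma-perp traces on a log scale.
#' @export
plot_sigma_traces <- function(runs) {
  d <- dplyr::bind_rows(lapply(names(runs), function(nm)
    dplyr::mutate(runs[[nm]]$trace, run = nm)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration,
                                  y = .data$sigma_perp,
                                  color = .data$run)) +
    ggplot2::geom_line() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = expression(sigma[perp]))
}

#' Stacked free energy profiles across iterations
#'
#' @param profiles Named list of `fe_profile` objects (e.g. one per
#'   saved iteration).
#' @return A ggplot with one line per profile.
#' @export
plot_profile_series <- function(profiles) {
  d <- dplyr::bind_rows(lapply(names(profiles), function(nm)
    dplyr::mutate(as_tibble(profiles[[nm]]), series = nm)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi, y = .data$F,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi), y = "F (kcal/mol)")
}
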