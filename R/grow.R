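#' Growth configuration
#'
#' Parameters of the growing method: the path is extended from its current
#' end by a step of size `s_g` along a blend of the downhill free-energy
#' direction and the unit vector toward the product, the blend weighted by
#' `w`. After each new snapshot, the whole current path is reparametrized
#' and swept `sweeps` times by the selected optimizer.
#'
#' @param s_g Growth step size (CV units).
#' @param w Weighting factor of the pull toward the product
#'   (dimensionless); larger w gives a straighter path.
#' @param sweeps Optimization sweeps after each growth step (default 2).
#' @param s_op Step size of the per-growth optimization sweeps.
#' @param max_snapshots Guard against growth stalling.
#' @param raw_direction If `TRUE`, use the literal unnormalized growing
#'   direction (gradient plus weighted pull); by default the direction is
#'   normalized to unit length so `s_g` is the geometric arc step and the
#'   termination test `|end - product| < s_g` is consistent.
#' @return A list of class `grow_config`.
#' @export
grow_config <- function(s_g = 0.102, w = 10, sweeps = 2L, s_op = 0.002,
                        max_snapshots = 500L, raw_direction = FALSE) {
  stopifnot(s_g > 0, w >= 0, sweeps >= 0, s_op > 0)
  structure(list(s_g = s_g, w = w, sweeps = as.integer(sweeps),
                 s_op = s_op, max_snapshots = as.integer(max_snapshots),
                 raw_direction = isTRUE(raw_direction)),
            class = "grow_config")
}

#' Growing direction at the end of a path
#'
#' The blend of the downhill free-energy direction and the pull toward the
#' product: \eqn{P_g = -\nabla F(\chi^{(end)}) + w \, (\chi^{(p)} -
#' \chi^{(end)}) / |\chi^{(p)} - \chi^{(end)}|}. By default the result is
#' normalized to unit length (see [grow_config()]).
#'
#' @param gradF Free energy gradient at the path end.
#' @param end Current end snapshot.
#' @param product Product point.
#' @param w Weighting factor.
#' @param periodic Per-CV periodic flags.
#' @param raw If `TRUE`, return the unnormalized blend.
#' @return Growing direction vector (unit length unless `raw`).
#' @export
growth_direction <- function(gradF, end, product, w, periodic = FALSE,
                             raw = FALSE) {
  d <- cv_displacement(end, product, periodic)
  nd <- sqrt(sum(d * d))
  if (nd < 1e-14) abort("path end coincides with the product")
  p <- -gradF + w * d / nd
  np <- sqrt(sum(p * p))
  if (np < 1e-12)
    abort("degenerate growing direction: gradient cancels the pull toward the product")
  if (raw) p else p / np
}

#' One growth step
#'
#' If the path end is within `s_g` of the product, the product itself is
#' appended and the path is complete. Otherwise a new snapshot is appended
#' at `end + s_g * P_g`. In both cases the path is then reparametrized and
#' swept `cfg$sweeps` times by fixed-step steepest descent at `cfg$s_op`
#' (anchors unmoved; the newest snapshot is included in the sweeps while
#' the path is still growing).
#'
#' @param path A growing `cv_path` (complete = FALSE) with >= 1 snapshot.
#' @param product Product CV vector.
#' @param field A `gradient_field`.
#' @param cfg A [grow_config()].
#' @return List with elements `path` and `finished`.
#' @export
grow_step <- function(path, product, field, cfg = grow_config()) {
  m <- path_m(path)
  end <- path$snapshots[m, ]
  d <- cv_displacement(end, product, path$periodic)
  if (sqrt(sum(d * d)) < cfg$s_g) {
    snaps <- rbind(path$snapshots, product)
    out <- new_path(snaps, periodic = path$periodic, complete = TRUE)
    finished <- TRUE
  } else {
    if (m >= cfg$max_snapshots)
      abort("growth stalled: max snapshots reached (the gradient term may be overwhelming w)")
    g <- field$gradient(end)
    dir <- growth_direction(g, end, product, cfg$w, path$periodic,
                            raw = cfg$raw_direction)
    snaps <- rbind(path$snapshots, end + cfg$s_g * dir)
    out <- new_path(snaps, periodic = path$periodic, complete = FALSE)
    finished <- FALSE
  }
  if (path_m(out) >= 3) out <- reparametrize(out)
  if (cfg$sweeps > 0 && path_m(out) >= 3)
    for (s in seq_len(cfg$sweeps))
      out <- sd_sweep(out, field, cfg$s_op)
  list(path = out, finished = finished)
}

#' Grow a complete path from reactant to product
#'
#' Repeats [grow_step()] until the product is reached, starting from the
#' single reactant state. Returns the complete path together with the
#' number of gradient evaluations spent.
#'
#' @param reactant,product Numeric CV vectors.
#' @param field A `gradient_field`.
#' @param cfg A [grow_config()].
#' @param periodic Per-CV periodic flags.
#' @return Object of class `grow_run`: list with `path`, `n_snapshots`,
#'   `n_gradient_evals`, `config`.
#' @export
grow_path <- function(reactant, product, field, cfg = grow_config(),
                      periodic = FALSE) {
  field <- counted_field(field)
  path <- new_path(matrix(reactant, nrow = 1L), periodic = periodic,
                   complete = FALSE)
  repeat {
    st <- grow_step(path, product, field, cfg)
    path <- st$path
    if (st$finished) break
  }
  structure(
    list(path = path, n_snapshots = path_m(path),
         n_gradient_evals = field$count(), config = cfg),
    class = "grow_run"
  )
}

#' @export
print.grow_run <- function(x, ...) {
  cat("<grow_run>", x$n_snapshots, "snapshots grown;",
      x$n_gradient_evals, "gradient evaluations\n")
  invisible(x)
}
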