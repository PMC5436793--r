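#' Gradient-field contract
#'
#' Anything that can return the free energy gradient \eqn{\nabla F(\chi)}
#' at a point of CV space is a gradient field: analytic test surfaces,
#' interpolated grid surfaces, or the constrained-dynamics mean-force
#' estimator ([mean_force_field()]). A field may additionally expose the
#' free energy value itself (`has_value = TRUE`), in which case gradient
#' and value must be mutually consistent.
#'
#' @param gradient Function of a numeric CV vector returning the gradient
#'   (kcal/mol per CV unit).
#' @param value Optional function returning F (kcal/mol).
#' @param dim Dimension n of the CV space.
#' @param periodic Logical vector of per-CV periodic flags.
#' @param ... Extra named fields stored on the object (e.g. `minima`).
#' @return An object of class `gradient_field`.
#' @export
gradient_field <- function(gradient, value = NULL, dim, periodic = FALSE,
                           ...) {
  structure(
    list(gradient = gradient, value = value,
         has_value = !is.null(value), dim = as.integer(dim),
         periodic = rep_len(periodic, dim), ...),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("<gradient_field> dim", x$dim,
      if (x$has_value) "(value available)" else "(gradient only)", "\n")
  invisible(x)
}

#' Evaluate an analytic surface
#'
#' @param surface A `gradient_field` with `has_value = TRUE`.
#' @param chi Numeric CV vector.
#' @return List with elements `value` (kcal/mol) and `gradient`.
#' @export
analytic_eval <- function(surface, chi) {
  if (length(chi) != surface$dim)
    abort(sprintf("point has dimension %d, surface %d",
                  length(chi), surface$dim))
  if (!surface$has_value) abort("surface has no value function")
  list(value = surface$value(chi), gradient = surface$gradient(chi))
}

#' Wrap a field to count gradient evaluations
#'
#' The simulation-budget ledger counts gradient-provider calls (each call
#' stands for one constrained simulation); this wrapper makes any field
#' countable.
#'
#' @param field A `gradient_field`.
#' @return The same field with an added `count()` accessor and a
#'   `reset()`.
#' @export
counted_field <- function(field) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  inner <- field$gradient
  field$gradient <- function(chi) {
    env$n <- env$n + 1L
    inner(chi)
  }
  field$count <- function() env$n
  field$reset <- function() env$n <- 0L
  field
}

#' Harmonic test surface
#'
#' \eqn{F(\chi) = \tfrac{1}{2} k |\chi - \chi_0|^2}.
#'
#' @param k Force constant (kcal/mol per CV-unit^2); scalar or per-CV.
#' @param center The minimum \eqn{\chi_0}.
#' @return A `gradient_field` with `has_value = TRUE`.
#' @export
surface_harmonic <- function(k = 1, center = c(0, 0)) {
  n <- length(center)
  kv <- rep_len(k, n)
  gradient_field(
    gradient = function(chi) kv * (chi - center),
    value = function(chi) 0.5 * sum(kv * (chi - center)^2),
    dim = n,
    minima = list(center)
  )
}

#' Quadratic saddle surface
#'
#' \eqn{F(x, y) = a x^2 - b y^2}, the canonical index-1 saddle at the
#' origin. Useful for symmetry tests of the perpendicular-gradient update.
#'
#' @param a,b Positive curvatures.
#' @return A `gradient_field`.
#' @export
surface_saddle <- function(a = 1, b = 1) {
  gradient_field(
    gradient = function(chi) c(2 * a * chi[1L], -2 * b * chi[2L]),
    value = function(chi) a * chi[1L]^2 - b * chi[2L]^2,
    dim = 2L,
    saddle = c(0, 0)
  )
}

gauss2 <- function(chi, c0, s) {
  d <- chi - c0
  e <- exp(-sum(d * d) / (2 * s * s))
  list(v = e, g = -d / (s * s) * e)
}

#' Two-dimensional double-well test surface
#'
#' Two Gaussian wells of unequal depth, a Gaussian barrier displaced from
#' the straight line joining them, and a weak quadratic confinement. The
#' straight interpolated path between the minima climbs over the barrier
#' while the optimal path curves around it through the valley on the far
#' side -- the qualitative geometry of a dipeptide backbone-dihedral
#' surface with two conformational basins. The stored `minima` (reactant
#' then product) are Newton-refined stationary points of the composed
#' surface, so the gradient vanishes there to machine precision. Nothing
#' about the default parameters is claimed to match any real molecular
#' surface.
#'
#' @param wells 2 x 2 matrix of nominal well centers (rows).
#' @param depths Well depths (kcal/mol), length 2.
#' @param widths Well Gaussian widths, length 2.
#' @param barrier_height Barrier Gaussian height (kcal/mol).
#' @param barrier_center Barrier Gaussian center.
#' @param barrier_width Barrier Gaussian width.
#' @param confine Quadratic confinement coefficient.
#' @param confine_center Center of the confinement term.
#' @return A `gradient_field` with fields `minima` (refined) and the
#'   parameter list in `params`.
#' @export
surface_double_well <- function(
    wells = rbind(c(-1.45, 1.31), c(1.29, -1.05)),
    depths = c(6, 4),
    widths = c(0.85, 0.85),
    barrier_height = 5,
    barrier_center = c(0.30, 0.55),
    barrier_width = 0.65,
    confine = 0.35,
    confine_center = c(0, 0)) {
  value <- function(chi) {
    v <- confine * sum((chi - confine_center)^2)
    for (i in 1:2) v <- v - depths[i] * gauss2(chi, wells[i, ], widths[i])$v
    v + barrier_height * gauss2(chi, barrier_center, barrier_width)$v
  }
  gradient <- function(chi) {
    g <- 2 * confine * (chi - confine_center)
    for (i in 1:2) g <- g - depths[i] * gauss2(chi, wells[i, ], widths[i])$g
    g + barrier_height * gauss2(chi, barrier_center, barrier_width)$g
  }
  refine <- function(x0) {
    for (it in 1:200) {
      g <- gradient(x0)
      if (sqrt(sum(g * g)) < 1e-13) break
      H <- num_jacobian(gradient, x0)
      x0 <- x0 - solve(H, g)
    }
    x0
  }
  f <- gradient_field(
    gradient = gradient, value = value, dim = 2L,
    minima = NULL,
    params = list(wells = wells, depths = depths, widths = widths,
                  barrier_height = barrier_height,
                  barrier_center = barrier_center,
                  barrier_width = barrier_width, confine = confine)
  )
  f$minima <- list(refine(wells[1L, ]), refine(wells[2L, ]))
  f
}

#' Mueller-Brown-like test surface
#'
#' The classic sum of four anisotropic Gaussians used throughout the
#' path-optimization literature, rescaled to kcal/mol magnitudes.
#'
#' @param scale Multiplier applied to the canonical parameters.
#' @return A `gradient_field`.
#' @export
surface_mueller_brown <- function(scale = 0.05) {
  A <- scale * c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  value <- function(chi) {
    dx <- chi[1L] - x0; dy <- chi[2L] - y0
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  }
  gradient <- function(chi) {
    dx <- chi[1L] - x0; dy <- chi[2L] - y0
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(e * (2 * a * dx + b * dy)), sum(e * (b * dx + 2 * cc * dy)))
  }
  gradient_field(gradient = gradient, value = value, dim = 2L)
}

# Finite-difference Jacobian of a vector function (used for Newton saddle
# refinement and the consistency checks).
num_jacobian <- function(fn, x, h = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hp <- x; hm <- x
    hp[i] <- hp[i] + h; hm[i] <- hm[i] - h
    J[, i] <- (fn(hp) - fn(hm)) / (2 * h)
  }
  J
}

#' Finite-difference gradient check for a field with values
#'
#' @param field A `gradient_field` with `has_value = TRUE`.
#' @param chi Point to check.
#' @param h Central-difference step.
#' @return Max absolute difference between analytic and numeric gradient.
#' @export
field_fd_error <- function(field, chi, h = 1e-5) {
  g <- field$gradient(chi)
  gn <- vapply(seq_along(chi), function(i) {
    hp <- chi; hm <- chi
    hp[i] <- hp[i] + h; hm[i] <- hm[i] - h
    (field$value(hp) - field$value(hm)) / (2 * h)
  }, numeric(1))
  max(abs(g - gn))
}

## ---- gridded surfaces -----------------------------------------------

#' Gridded free energy surface
#'
#' A regular grid of free energy values over CV space, typically exported
#' from a full-space sampling run (metadynamics-style flooding), with
#' multilinear or cubic-convolution interpolation. Gradients are the
#' analytic derivative of the interpolant, continuous inside each cell.
#' No extrapolation: evaluating outside a non-periodic axis is an error.
#'
#' @param axes List of per-axis lists with fields `min`, `max`, `step`,
#'   `periodic`. Nodes run `min, min+step, ..., max`; on a periodic axis
#'   the period is `max - min + step`.
#' @param values Array of F values (kcal/mol), dim = node counts.
#' @param order `"bilinear"` (multilinear) or `"bicubic"`
#'   (cubic convolution, Catmull-Rom kernel; third-order accurate).
#' @return A `gradient_field` of class `c("grid_surface",
#'   "gradient_field")`.
#' @export
surface_grid <- function(axes, values, order = c("bicubic", "bilinear")) {
  order <- match.arg(order)
  counts <- vapply(axes, function(a)
    as.integer(round((a$max - a$min) / a$step)) + 1L, integer(1))
  values <- array(as.numeric(values), dim = counts)
  for (a in axes) {
    if (a$step <= 0 || a$max <= a$min)
      abort("grid axis must have positive step and max > min")
  }
  if (any(is.na(values))) abort("grid contains NA/NaN cells")
  g <- structure(
    list(axes = axes, values = values, order = order,
         dim = length(axes),
         periodic = vapply(axes, function(a) isTRUE(a$periodic), logical(1)),
         has_value = TRUE),
    class = c("grid_surface", "gradient_field")
  )
  g$value <- function(chi) grid_eval(g, chi)$value
  g$gradient <- function(chi) grid_eval(g, chi)$gradient
  g
}

# 1-D basis weights on the stencil, and their derivatives wrt the cell
# fraction t in [0,1).
basis_linear <- function(t) list(w = c(1 - t, t), dw = c(-1, 1))
basis_cubic <- function(t) {
  # Catmull-Rom: nodes p_{-1}, p_0, p_1, p_2, evaluated at fraction t
  t2 <- t * t; t3 <- t2 * t
  w <- c(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
         -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
  dw <- c(-1.5 * t2 + 2 * t - 0.5,
          4.5 * t2 - 5 * t,
          -4.5 * t2 + 4 * t + 0.5,
          1.5 * t2 - t)
  list(w = w, dw = dw)
}

grid_locate <- function(axis, n, x) {
  if (isTRUE(axis$periodic)) {
    period <- axis$max - axis$min + axis$step
    u <- (x - axis$min) / axis$step
    u <- u - floor(u / n) * n
  } else {
    lo <- axis$min - 1e-9 * axis$step
    hi <- axis$max + 1e-9 * axis$step
    if (x < lo || x > hi)
      abort(sprintf("point %.6g outside grid axis [%g, %g]",
                    x, axis$min, axis$max))
    u <- (x - axis$min) / axis$step
    u <- min(max(u, 0), n - 1)
  }
  i0 <- floor(u)
  if (!isTRUE(axis$periodic) && i0 >= n - 1) i0 <- n - 2
  list(i0 = as.integer(i0), t = u - i0)
}

stencil_index <- function(i, n, periodic) {
  if (periodic) (i %% n) + 1L
  else pmin(pmax(i, 0L), n - 1L) + 1L
}

grid_eval <- function(g, chi) {
  nd <- g$dim
  if (length(chi) != nd)
    abort(sprintf("point has dimension %d, grid %d", length(chi), nd))
  counts <- dim(g$values)
  cubic <- g$order == "bicubic"
  offs <- if (cubic) -1:2 else 0:1
  W <- vector("list", nd); DW <- vector("list", nd); IDX <- vector("list", nd)
  for (d in seq_len(nd)) {
    loc <- grid_locate(g$axes[[d]], counts[d], chi[d])
    b <- if (cubic) basis_cubic(loc$t) else basis_linear(loc$t)
    W[[d]] <- b$w
    DW[[d]] <- b$dw
    IDX[[d]] <- stencil_index(loc$i0 + offs, counts[d],
                              isTRUE(g$axes[[d]]$periodic))
  }
  sub <- do.call(expand.grid, lapply(seq_len(nd), function(d)
    seq_along(IDX[[d]])))
  val <- 0
  grad <- numeric(nd)
  for (r in seq_len(nrow(sub))) {
    pos <- integer(nd); wts <- numeric(nd); dwts <- numeric(nd)
    for (d in seq_len(nd)) {
      k <- sub[r, d]
      pos[d] <- IDX[[d]][k]
      wts[d] <- W[[d]][k]
      dwts[d] <- DW[[d]][k]
    }
    fv <- g$values[matrix(pos, 1L)]
    pw <- prod(wts)
    val <- val + fv * pw
    for (d in seq_len(nd)) {
      others <- prod(wts[-d])
      grad[d] <- grad[d] + fv * dwts[d] * others / g$axes[[d]]$step
    }
  }
  list(value = val, gradient = grad)
}

#' @rdname surface_grid
#' @param grid A `grid_surface`.
#' @param chi Numeric CV vector.
#' @export
grid_gradient <- function(grid, chi) grid_eval(grid, chi)$gradient

#' Sample an analytic surface onto a grid
#'
#' @param field A `gradient_field` with values.
#' @param axes Axis list as in [surface_grid()].
#' @param order Interpolation order for the resulting grid surface.
#' @return A `grid_surface`.
#' @export
sample_to_grid <- function(field, axes, order = "bicubic") {
  counts <- vapply(axes, function(a)
    as.integer(round((a$max - a$min) / a$step)) + 1L, integer(1))
  nodes <- lapply(axes, function(a) a$min + (seq_len(
    as.integer(round((a$max - a$min) / a$step)) + 1L) - 1L) * a$step)
  pts <- do.call(expand.grid, nodes)
  vals <- apply(as.matrix(pts), 1L, function(p) field$value(p))
  surface_grid(axes, array(vals, dim = counts), order = order)
}

#' Read and write grid-surface files
#'
#' Delimited text: header lines `# axis <i> <min> <max> <step> <periodic>`
#' (periodic as 0/1), an optional `# interpolation <order>` line, then one
#' `chi_1 ... chi_n F` row per node in node order (first axis fastest).
#' Values are written with 17 significant digits so a save/load cycle
#' round-trips bit-exactly on the text form.
#'
#' @param path File path.
#' @param grid A `grid_surface`.
#' @return `load_grid` returns a `grid_surface`; `save_grid` returns
#'   `path` invisibly.
#' @export
load_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  axes <- list()
  order <- "bicubic"
  for (ln in lines[hdr]) {
    tok <- strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]
    if (length(tok) >= 6 && tok[1] == "axis") {
      i <- as.integer(tok[2])
      axes[[i]] <- list(min = as.numeric(tok[3]), max = as.numeric(tok[4]),
                        step = as.numeric(tok[5]),
                        periodic = as.integer(tok[6]) == 1L)
    } else if (length(tok) >= 2 && tok[1] == "interpolation") {
      order <- tok[2]
    }
  }
  if (length(axes) == 0) abort("grid file has no axis headers")
  body_idx <- which(!hdr & nzchar(trimws(lines)))
  nd <- length(axes)
  counts <- vapply(axes, function(a)
    as.integer(round((a$max - a$min) / a$step)) + 1L, integer(1))
  need <- prod(counts)
  if (length(body_idx) != need)
    abort(sprintf("grid file has %d data rows, expected %d (missing cell near line %d)",
                  length(body_idx), need,
                  if (length(body_idx) > 0) body_idx[length(body_idx)] else 1L))
  vals <- numeric(need)
  for (r in seq_along(body_idx)) {
    ln <- body_idx[r]
    tok <- as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]])
    if (length(tok) != nd + 1L)
      abort(sprintf("ragged row at line %d: %d fields, expected %d",
                    ln, length(tok), nd + 1L))
    if (any(is.na(tok)))
      abort(sprintf("NaN/non-numeric cell at line %d", ln))
    # check node coordinates are on the declared lattice, in order
    idx <- (r - 1L)
    for (d in seq_len(nd)) {
      k <- idx %% counts[d]
      idx <- idx %/% counts[d]
      expect <- axes[[d]]$min + k * axes[[d]]$step
      if (abs(tok[d] - expect) > 1e-6 * max(1, abs(expect)))
        abort(sprintf("non-monotone or off-lattice axis value at line %d (axis %d: %g, expected %g)",
                      ln, d, tok[d], expect))
    }
    vals[r] <- tok[nd + 1L]
  }
  surface_grid(axes, array(vals, dim = counts), order = order)
}

#' @rdname load_grid
#' @export
save_grid <- function(grid, path) {
  axes <- grid$axes
  counts <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(axes)) {
    a <- axes[[i]]
    writeLines(sprintf("# axis %d %.17g %.17g %.17g %d", i, a$min, a$max,
                       a$step, as.integer(isTRUE(a$periodic))), con)
  }
  writeLines(paste("# interpolation", grid$order), con)
  nodes <- lapply(seq_along(axes), function(d)
    axes[[d]]$min + (seq_len(counts[d]) - 1L) * axes[[d]]$step)
  pts <- do.call(expand.grid, nodes)
  vals <- as.vector(grid$values)
  rows <- vapply(seq_len(nrow(pts)), function(r) {
    paste(c(sprintf("%.17g", as.numeric(pts[r, ])),
            sprintf("%.17g", vals[r])), collapse = " ")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}
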