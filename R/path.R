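#' Paths in collective-variable space
#'
#' A path is an ordered sequence of m snapshots (points of the
#' n-dimensional CV space), stored as an m x n matrix with per-CV
#' periodicity. The reactant (first snapshot) is always anchored; the
#' product (last snapshot) is anchored once the path is complete.
#'
#' @param snapshots An m x n numeric matrix, one snapshot per row.
#' @param periodic Logical vector of per-CV periodic flags.
#' @param complete Logical; is the product end anchored?
#' @return An object of class `cv_path`.
#' @export
new_path <- function(snapshots, periodic = FALSE, complete = TRUE) {
  snapshots <- as.matrix(snapshots)
  per <- rep_len(periodic, ncol(snapshots))
  for (j in which(per))
    snapshots[, j] <- wrap_periodic(snapshots[, j], TRUE)
  structure(
    list(snapshots = snapshots,
         periodic = rep_len(periodic, ncol(snapshots)),
         complete = isTRUE(complete)),
    class = "cv_path"
  )
}

#' @export
print.cv_path <- function(x, ...) {
  cat("<cv_path>", nrow(x$snapshots), "snapshots in", ncol(x$snapshots),
      "CV dimensions;", if (x$complete) "complete" else "growing", "\n")
  invisible(x)
}

#' @export
as_tibble.cv_path <- function(x, ...) {
  m <- x$snapshots
  colnames(m) <- paste0("cv", seq_len(ncol(m)))
  out <- as_tibble(m)
  al <- path_arc_fractions(x)
  tibble(snapshot = seq_len(nrow(m)), xi = al, out)
}

path_m <- function(path) nrow(path$snapshots)
path_n <- function(path) ncol(path$snapshots)

#' Linear interpolation between reactant and product
#'
#' Builds the standard straight initial path: m snapshots evenly spaced on
#' the segment from reactant to product, periodic components along the
#' shortest arc.
#'
#' @param reactant,product Numeric CV vectors.
#' @param m Number of snapshots (>= 2).
#' @param periodic Per-CV periodic flags.
#' @return A complete [new_path()] object.
#' @export
interpolate_linear <- function(reactant, product, m, periodic = FALSE) {
  if (m < 2) abort("need at least 2 snapshots")
  d <- cv_displacement(reactant, product, periodic)
  fr <- seq(0, 1, length.out = m)
  snaps <- t(vapply(fr, function(f) reactant + f * d, numeric(length(d))))
  new_path(snaps, periodic = periodic, complete = TRUE)
}

# Unwrap periodic columns so consecutive snapshots differ by the shortest
# arc; spline fitting then happens on a continuous representation.
unwrap_snapshots <- function(path) {
  s <- path$snapshots
  if (any(path$periodic) && nrow(s) > 1) {
    for (j in which(path$periodic)) {
      d <- diff(s[, j])
      d <- d - 2 * pi * round(d / (2 * pi))
      s[, j] <- s[1L, j] + c(0, cumsum(d))
    }
  }
  s
}

# Interpolating curve through the snapshots: cubic spline per CV against
# the snapshot-index parameter (fmm end conditions: exact cubics fitted
# through the four points at each end, which keeps refinement stable at
# the path ends); piecewise linear for m < 4.
# points(ts)/derivs(ts) are vectorized over the parameter, t in [1, m].
path_curve <- function(path) {
  s <- unwrap_snapshots(path)
  m <- nrow(s); n <- ncol(s)
  tt <- seq_len(m)
  if (m < 4) {
    points <- function(ts) {
      ts <- pmin(pmax(ts, 1), m)
      i <- pmin(floor(ts), m - 1)
      f <- ts - i
      s[i, , drop = FALSE] + f * (s[i + 1L, , drop = FALSE] -
                                    s[i, , drop = FALSE])
    }
    derivs <- function(ts) {
      ts <- pmin(pmax(ts, 1), m)
      i <- pmin(floor(ts), m - 1)
      s[i + 1L, , drop = FALSE] - s[i, , drop = FALSE]
    }
    return(list(points = points, derivs = derivs, m = m))
  }
  fns <- lapply(seq_len(n), function(j)
    splinefun(tt, s[, j], method = "fmm"))
  points <- function(ts)
    vapply(fns, function(f) f(ts), numeric(length(ts)))
  derivs <- function(ts)
    vapply(fns, function(f) f(ts, deriv = 1L), numeric(length(ts)))
  list(points = points,
       derivs = derivs, m = m)
}

curve_speed <- function(curve, ts) {
  d <- curve$derivs(ts)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  sqrt(rowSums(d * d))
}

# Composite Simpson of |dchi/dt| per inter-snapshot segment, all
# segments at once with a fixed nsub subdivision. Segment-end nodes are
# nudged inside the segment so the piecewise-linear branch (whose speed
# jumps at the joints) integrates each segment with its own speed.
simpson_segment_lengths <- function(curve, m, nsub = 16L) {
  ts <- as.vector(vapply(seq_len(m - 1L), function(i) {
    tt <- seq(i, i + 1L, length.out = nsub + 1L)
    tt[nsub + 1L] <- i + 1L - 1e-9
    tt
  }, numeric(nsub + 1L)))
  sp <- matrix(curve_speed(curve, ts), nrow = nsub + 1L)
  h <- 1 / nsub
  w <- c(1, rep(c(4, 2), length.out = nsub - 1L), 1)
  as.vector(h / 3 * colSums(sp * w))
}

#' Arc length of a path
#'
#' Length of the interpolating curve (cubic spline through the
#' snapshots, Forsythe-Malcolm-Moler end conditions; piecewise linear
#' for m < 4), each inter-snapshot segment
#' integrated by composite Simpson's rule with a fixed 16-subinterval
#' subdivision.
#'
#' @param path A `cv_path`.
#' @return Total arc length (CV units).
#' @export
arc_length <- function(path) {
  m <- path_m(path)
  if (m < 2) abort("need at least 2 snapshots")
  sum(simpson_segment_lengths(path_curve(path), m))
}

# Per-snapshot arc length (Simpson per segment).
segment_lengths <- function(path) {
  simpson_segment_lengths(path_curve(path), path_m(path))
}

#' Arc-length fractions of the snapshots
#'
#' The reaction coordinate \eqn{\xi} of snapshot i is the fraction of the
#' total arc length accumulated up to i: 0 at the reactant, 1 at the
#' product.
#'
#' @param path A `cv_path`.
#' @return Numeric vector of length m, increasing from 0 to 1.
#' @export
path_arc_fractions <- function(path) {
  if (path_m(path) < 2) return(0)
  seg <- segment_lengths(path)
  cum <- c(0, cumsum(seg))
  cum / cum[length(cum)]
}

#' Reparametrize a path to even arc-length spacing
#'
#' Moves the snapshots to equal arc-length fractions
#' \eqn{\xi_i = (i-1)/(m-1)} on the same interpolating curve, leaving the
#' endpoints unmoved. Because resampling changes the interpolant slightly,
#' the redivision is iterated until per-segment arc lengths agree with
#' their mean to better than 0.1% (or a small fixed iteration cap).
#'
#' @param path A `cv_path` with m >= 3.
#' @param tol Relative spacing tolerance (default 1e-3).
#' @param max_pass Maximum redivision passes.
#' @return A `cv_path` on the same curve with even spacing.
#' @export
reparametrize <- function(path, tol = 1e-3, max_pass = 8L) {
  m <- path_m(path)
  if (m < 3) return(path)
  for (pass in seq_len(max_pass)) {
    curve <- path_curve(path)
    nsub <- 16L
    tgrid <- as.vector(vapply(seq_len(m - 1L), function(i) {
      tt <- seq(i, i + 1L, length.out = nsub + 1L)
      tt[nsub + 1L] <- i + 1L - 1e-9
      tt
    }, numeric(nsub + 1L)))
    tgrid <- c(tgrid, m)
    sp <- curve_speed(curve, tgrid)
    # cumulative arc by trapezoid on the fine grid (dense, monotone)
    dt <- diff(tgrid)
    cum <- c(0, cumsum(dt * (head(sp, -1L) + tail(sp, -1L)) / 2))
    total <- cum[length(cum)]
    if (total <= 0) abort("degenerate zero-length path")
    targets <- seq(0, total, length.out = m)
    tx <- stats::approx(cum, tgrid, xout = targets, ties = "ordered")$y
    snaps <- curve$points(tx)
    snaps[1L, ] <- path$snapshots[1L, ]
    snaps[m, ] <- path$snapshots[m, ]
    out <- new_path(snaps, periodic = path$periodic,
                    complete = path$complete)
    seg <- segment_lengths(out)
    if (max(abs(seg - mean(seg))) / mean(seg) < tol) return(out)
    path <- out
  }
  out
}

#' Unit tangent of a path at a snapshot
#'
#' Central difference \eqn{\chi^{(i+1)} - \chi^{(i-1)}} normalized for
#' interior snapshots; one-sided at the ends. Periodic wrapping is applied
#' to the differences.
#'
#' @param path A `cv_path`.
#' @param i Snapshot index (1-based).
#' @return Unit tangent vector.
#' @export
tangent <- function(path, i) {
  m <- path_m(path)
  if (i < 1 || i > m) abort("snapshot index out of range")
  s <- path$snapshots
  d <- if (i == 1L) {
    cv_displacement(s[1L, ], s[2L, ], path$periodic)
  } else if (i == m) {
    cv_displacement(s[m - 1L, ], s[m, ], path$periodic)
  } else {
    cv_displacement(s[i - 1L, ], s[i + 1L, ], path$periodic)
  }
  nd <- sqrt(sum(d * d))
  if (nd < 1e-14) abort("zero-norm tangent: coincident snapshots")
  d / nd
}

#' All unit tangents of a path
#'
#' @param path A `cv_path`.
#' @return An m x n matrix of unit tangents.
#' @export
path_tangents <- function(path) {
  t(vapply(seq_len(path_m(path)), function(i) tangent(path, i),
           numeric(path_n(path))))
}

#' Read and write path files
#'
#' Delimited text with a header
#' `# n=<dim> periodic=<0/1 flags> units=<list>` and one snapshot per row,
#' 17 significant digits, so the text form round-trips bit-exactly.
#'
#' @param path A `cv_path` (for writing).
#' @param file File path.
#' @param units Character vector of per-CV unit labels.
#' @param extra_header Named character vector of extra `# key=value`
#'   header lines (e.g. seed, config hash).
#' @return `read_path` returns a `cv_path`; `write_path` returns `file`
#'   invisibly.
#' @export
write_path <- function(path, file, units = NULL,
                       extra_header = NULL) {
  n <- path_n(path)
  if (is.null(units)) units <- rep("cv", n)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d periodic=%s units=%s", n,
                     paste(as.integer(path$periodic), collapse = ","),
                     paste(units, collapse = ",")), con)
  if (!is.null(extra_header))
    for (k in names(extra_header))
      writeLines(sprintf("# %s=%s", k, extra_header[[k]]), con)
  rows <- apply(path$snapshots, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, con)
  invisible(file)
}

#' @rdname write_path
#' @export
read_path <- function(file) {
  lines <- readLines(file)
  hdr <- lines[grepl("^#", lines)]
  main <- hdr[grepl("n=", hdr)][1]
  if (is.na(main)) abort("path file missing '# n=... periodic=...' header")
  get_field <- function(name) {
    m <- regmatches(main, regexec(paste0(name, "=([^ ]+)"), main))[[1]]
    if (length(m) < 2) abort(paste("path header missing", name))
    m[2]
  }
  n <- as.integer(get_field("n"))
  periodic <- as.integer(strsplit(get_field("periodic"), ",")[[1]]) == 1L
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  snaps <- do.call(rbind, lapply(seq_along(body), function(r) {
    tok <- as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    if (length(tok) != n)
      abort(sprintf("path row %d has %d fields, expected %d",
                    r, length(tok), n))
    tok
  }))
  new_path(snaps, periodic = periodic, complete = TRUE)
}
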