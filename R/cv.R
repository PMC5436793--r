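#' Collective variable definitions
#'
#' A collective variable (CV) is a scalar function of the Cartesian
#' coordinates of a few atoms. Four kinds are supported:
#' \describe{
#'   \item{distance}{interatomic distance between one pair of atoms (A).}
#'   \item{dihedral}{signed torsion angle over an atom quadruple, wrapped
#'     into \eqn{(-\pi, \pi]} (radians, periodic).}
#'   \item{hbond_count}{smooth hydrogen-bond count over k donor-H/acceptor
#'     pairs, \eqn{n_{HB} = \sum_{i=1}^{k} 1/(1 + (d_i/d_0)^6)}, where
#'     \eqn{d_i} is the O...H distance and \eqn{d_0} a reference length
#'     (dimensionless, bounded in (0, k)).}
#'   \item{coordinate}{a bare Cartesian component of one atom; used by the
#'     toy constrained-dynamics systems whose mean force has a closed form.}
#' }
#'
#' @param atoms For `cv_distance` a length-2 vector of atom indices; for
#'   `cv_dihedral` length 4; for `cv_coordinate` a single index. 1-based.
#' @param pairs For `cv_hbond_count`, a k x 2 matrix (or length-2 vector)
#'   of donor-H / acceptor atom index pairs.
#' @param d0 Reference bond length in Angstrom (default 3.5 A, the
#'   conventional N-O hydrogen-bond reference).
#' @param axis For `cv_coordinate`, which Cartesian component (1 = x,
#'   2 = y, 3 = z).
#' @return An object of class `cv_spec`.
#' @examples
#' sp <- cv_distance(c(1, 2))
#' coords <- rbind(c(0, 0, 0), c(1, 0, 0))
#' cv_value(sp, coords)
#' @name cv_spec
NULL

new_cv_spec <- function(kind, atoms, d0 = NULL, axis = NULL,
                        periodic = FALSE) {
  structure(
    list(kind = kind, atoms = atoms, d0 = d0, axis = axis,
         periodic = periodic),
    class = "cv_spec"
  )
}

#' @rdname cv_spec
#' @export
cv_distance <- function(atoms) {
  atoms <- as.integer(atoms)
  stopifnot(length(atoms) == 2L)
  if (anyDuplicated(atoms)) abort("distance CV atoms must be distinct")
  new_cv_spec("distance", atoms)
}

#' @rdname cv_spec
#' @export
cv_dihedral <- function(atoms) {
  atoms <- as.integer(atoms)
  stopifnot(length(atoms) == 4L)
  if (anyDuplicated(atoms)) abort("dihedral CV atoms must be distinct")
  new_cv_spec("dihedral", atoms, periodic = TRUE)
}

#' @rdname cv_spec
#' @export
cv_hbond_count <- function(pairs, d0 = 3.5) {
  if (is.null(dim(pairs))) pairs <- matrix(as.integer(pairs), ncol = 2L,
                                           byrow = TRUE)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (d0 <= 0) abort("d0 must be positive")
  if (any(pairs[, 1L] == pairs[, 2L]))
    abort("hbond pair atoms must be distinct")
  new_cv_spec("hbond_count", pairs, d0 = d0)
}

#' @rdname cv_spec
#' @export
cv_coordinate <- function(atoms, axis = 1L) {
  atoms <- as.integer(atoms)
  stopifnot(length(atoms) == 1L, axis %in% 1:3)
  new_cv_spec("coordinate", atoms, axis = as.integer(axis))
}

#' @export
print.cv_spec <- function(x, ...) {
  cat("<cv_spec>", x$kind, "\n")
  if (x$kind == "hbond_count")
    cat("  pairs:", nrow(x$atoms), " d0:", x$d0, "A\n")
  else cat("  atoms:", paste(x$atoms, collapse = " "),
           if (!is.null(x$axis)) paste("axis", x$axis) else "", "\n")
  invisible(x)
}

check_atoms <- function(idx, coords) {
  if (max(idx) > nrow(coords) || min(idx) < 1L)
    abort(sprintf("atom index %d outside coordinate set (%d atoms)",
                  max(idx), nrow(coords)))
}

#' Evaluate a collective variable
#'
#' @param spec A [cv_spec] object.
#' @param coords An N x 3 matrix of Cartesian positions (Angstrom), rows
#'   indexed by atom.
#' @return A single numeric value; dihedrals in \eqn{(-\pi, \pi]}.
#' @seealso [cv_gradient()]
#' @export
cv_value <- function(spec, coords) {
  coords <- as.matrix(coords)
  check_atoms(spec$atoms, coords)
  switch(spec$kind,
    coordinate = coords[spec$atoms, spec$axis],
    distance = {
      d <- coords[spec$atoms[2L], ] - coords[spec$atoms[1L], ]
      sqrt(sum(d * d))
    },
    dihedral = dihedral_value(coords[spec$atoms, , drop = FALSE]),
    hbond_count = {
      d <- sqrt(rowSums((coords[spec$atoms[, 2L], , drop = FALSE] -
                         coords[spec$atoms[, 1L], , drop = FALSE])^2))
      sum(1 / (1 + (d / spec$d0)^6))
    },
    abort(paste("unknown CV kind", spec$kind))
  )
}

dihedral_value <- function(p) {
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20)
    abort("degenerate dihedral: three collinear atoms")
  # IUPAC signed dihedral via atan2; numerically stable near 0 and pi
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  atan2(y, x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Analytic gradient of a collective variable
#'
#' Returns the derivative of the CV with respect to every Cartesian
#' coordinate; rows for atoms not named in the spec are zero. These
#' gradients assemble the constraint matrix Z (mass-weighted Gram matrix of
#' CV gradients) and the SHAKE correction directions.
#'
#' @inheritParams cv_value
#' @return An N x 3 matrix, same shape as `coords`.
#' @export
cv_gradient <- function(spec, coords) {
  coords <- as.matrix(coords)
  check_atoms(spec$atoms, coords)
  g <- matrix(0, nrow(coords), 3L)
  switch(spec$kind,
    coordinate = {
      g[spec$atoms, spec$axis] <- 1
    },
    distance = {
      i <- spec$atoms[1L]; j <- spec$atoms[2L]
      d <- coords[j, ] - coords[i, ]
      r <- sqrt(sum(d * d))
      if (r < 1e-12) abort("degenerate distance: coincident atoms")
      g[i, ] <- -d / r
      g[j, ] <- d / r
    },
    dihedral = {
      g[spec$atoms, ] <- dihedral_gradient(coords[spec$atoms, , drop = FALSE])
    },
    hbond_count = {
      for (kk in seq_len(nrow(spec$atoms))) {
        i <- spec$atoms[kk, 1L]; j <- spec$atoms[kk, 2L]
        d <- coords[j, ] - coords[i, ]
        r <- sqrt(sum(d * d))
        if (r < 1e-12) abort("degenerate hbond pair: coincident atoms")
        u <- (r / spec$d0)^6
        # d/dr [1/(1+u)] = -6 u / (r (1+u)^2)
        dfdr <- -6 * u / (r * (1 + u)^2)
        g[i, ] <- g[i, ] - dfdr * d / r
        g[j, ] <- g[j, ] + dfdr * d / r
      }
    },
    abort(paste("unknown CV kind", spec$kind))
  )
  g
}

# Standard analytic torsion derivatives (Blondel & Karplus form).
dihedral_gradient <- function(p) {
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1sq <- sum(n1 * n1)
  n2sq <- sum(n2 * n2)
  if (n1sq < 1e-20 || n2sq < 1e-20)
    abort("degenerate dihedral: three collinear atoms")
  nb2 <- sqrt(sum(b2 * b2))
  g <- matrix(0, 4L, 3L)
  g1 <- -nb2 / n1sq * n1
  g4 <- nb2 / n2sq * n2
  s12 <- sum(b1 * b2) / (nb2 * nb2)
  s32 <- sum(b3 * b2) / (nb2 * nb2)
  g[1L, ] <- g1
  g[4L, ] <- g4
  g[2L, ] <- -(1 + s12) * g1 + s32 * g4
  g[3L, ] <- s12 * g1 - (1 + s32) * g4
  g
}

#' Wrap periodic components into the principal interval
#'
#' Periodic components (dihedrals) are stored wrapped into
#' \eqn{(-\pi, \pi]}; all differences are taken along the shortest arc.
#'
#' @param x Numeric vector of CV values.
#' @param periodic Logical vector marking which components are periodic
#'   (period \eqn{2\pi}); recycled to the length of `x`.
#' @return `x` with periodic components wrapped.
#' @export
wrap_periodic <- function(x, periodic) {
  periodic <- rep_len(periodic, length(x))
  if (any(periodic)) {
    v <- x[periodic]
    v <- v - 2 * pi * round(v / (2 * pi))
    # round() maps the boundary to -pi; the convention is (-pi, pi]
    v[v <= -pi] <- v[v <= -pi] + 2 * pi
    x[periodic] <- v
  }
  x
}

#' Displacement between two points in CV space
#'
#' Componentwise `b - a` with periodic components wrapped into
#' \eqn{(-\pi, \pi]} (shortest arc). The Euclidean norm of this
#' displacement defines the CV-space distance used throughout the package;
#' radians and Angstrom mix unscaled unless a weight vector is supplied.
#'
#' @param a,b Numeric CV vectors of equal length.
#' @param periodic Logical vector marking periodic components.
#' @param weights Optional per-CV weights applied multiplicatively to the
#'   displacement (default 1).
#' @return Numeric displacement vector.
#' @export
cv_displacement <- function(a, b, periodic = FALSE, weights = NULL) {
  if (length(a) != length(b))
    abort(sprintf("dimension mismatch: %d vs %d", length(a), length(b)))
  d <- wrap_periodic(b - a, periodic)
  if (!is.null(weights)) d <- d * rep_len(weights, length(d))
  d
}

#' @rdname cv_displacement
#' @export
cv_distance_between <- function(a, b, periodic = FALSE, weights = NULL) {
  sqrt(sum(cv_displacement(a, b, periodic, weights)^2))
}
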