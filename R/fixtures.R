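#' Synthetic fixture bundle
#'
#' Named synthetic systems used throughout the examples and tests:
#' \describe{
#'   \item{ala_like_2d}{the bundled 2-D double-well surface
#'     ([surface_double_well()] with its default parameters) together
#'     with its Newton-refined reactant and product minima -- the
#'     dipeptide-like scenario: a straight interpolated path climbs the
#'     central barrier, the optimal path curves around it.}
#'   \item{saddle_quadratic}{the quadratic index-1 saddle surface.}
#'   \item{harmonic_nd}{an n-dimensional harmonic surface.}
#'   \item{toy_harmonic_2d}{a single-particle toy system, harmonic
#'     potential, coordinate CVs x and y -- the constrained mean force is
#'     exactly \eqn{k(\chi - \chi_0)}.}
#'   \item{toy_distance}{two particles with a distance CV (nontrivial Z
#'     matrix).}
#' }
#' Regeneration is deterministic: the bundle carries no random state
#' beyond the seed recorded for downstream runs.
#'
#' @param seed Seed recorded in the bundle and used to derive MD seeds.
#' @param n Dimension of the harmonic surface fixture.
#' @return A named list of class `fixture_set`.
#' @export
fixture_set <- function(seed = 1L, n = 2L) {
  ala <- surface_double_well()
  fx <- list(
    seed = as.integer(seed),
    ala_like_2d = list(
      surface = ala,
      reactant = ala$minima[[1L]],
      product = ala$minima[[2L]],
      s_g = 0.102, w = 10, s_op = 0.002
    ),
    saddle_quadratic = surface_saddle(),
    harmonic_nd = surface_harmonic(k = 2, center = rep(0, n)),
    toy_harmonic_2d = toy_harmonic_system(),
    toy_distance = toy_distance_system()
  )
  structure(fx, class = "fixture_set")
}

#' Single-particle harmonic toy system
#'
#' One particle of mass 12 amu in \eqn{V = \tfrac{1}{2} k |r - r_0|^2}
#' with coordinate CVs x and y. Constraining (x, y) at \eqn{c} gives the
#' exact, temperature-independent mean force \eqn{k (c - r_{0,xy})}.
#'
#' @param k Force constant (kcal/mol/A^2).
#' @param center Equilibrium position (length 3).
#' @param mass Particle mass (amu).
#' @return A `toy_system`.
#' @export
toy_harmonic_system <- function(k = 2, center = c(0.5, -0.25, 0),
                                mass = 12) {
  toy_system(
    masses = mass,
    potential = potential_harmonic(k, matrix(center, 1L)),
    cvs = list(cv_coordinate(1L, 1L), cv_coordinate(1L, 2L)),
    coords0 = matrix(center, 1L)
  )
}

#' Coupled harmonic toy system with a fluctuating multiplier
#'
#' One particle with constrained CVs x and y harmonically confined and
#' linearly coupled to the free (thermal) z coordinate:
#' \deqn{V = \tfrac{1}{2} k_x u^2 + \tfrac{1}{2} k_y v^2 +
#'   \tfrac{1}{2} k_z z^2 + c\, z (u + v), \quad u = x - x_0,\;
#'   v = y - y_0.}
#' Integrating out z gives the exact, temperature-independent mean force
#' \eqn{\partial F/\partial x = k_x u - c^2 (u + v)/k_z} (and
#' symmetrically in y), while the instantaneous multiplier
#' \eqn{k_x u + c z} fluctuates with the thermal z -- a statistically
#' nontrivial closed-form validation target.
#'
#' @param kx,ky,kz Force constants (kcal/mol/A^2); require
#'   \eqn{c^2 < k_z \min(k_x, k_y)} for a bound surface.
#' @param cc Coupling constant c (kcal/mol/A^2).
#' @param center (x0, y0).
#' @param mass Particle mass (amu).
#' @return A `toy_system` with a `mean_force(chi)` closure attached.
#' @export
toy_coupled_system <- function(kx = 2, ky = 2, kz = 4, cc = 1.5,
                               center = c(0.5, -0.25), mass = 12) {
  stopifnot(cc^2 < kz * min(kx, ky))
  pot <- list(
    value = function(coords) {
      p <- as.matrix(coords)[1L, ]
      u <- p[1L] - center[1L]; v <- p[2L] - center[2L]; z <- p[3L]
      0.5 * kx * u^2 + 0.5 * ky * v^2 + 0.5 * kz * z^2 + cc * z * (u + v)
    },
    gradient = function(coords) {
      p <- as.matrix(coords)[1L, ]
      u <- p[1L] - center[1L]; v <- p[2L] - center[2L]; z <- p[3L]
      matrix(c(kx * u + cc * z, ky * v + cc * z,
               kz * z + cc * (u + v)), 1L)
    }
  )
  sys <- toy_system(masses = mass, potential = pot,
                    cvs = list(cv_coordinate(1L, 1L), cv_coordinate(1L, 2L)),
                    coords0 = matrix(c(center, 0), 1L))
  sys$mean_force <- function(chi) {
    u <- chi[1L] - center[1L]; v <- chi[2L] - center[2L]
    c(kx * u - cc^2 * (u + v) / kz, ky * v - cc^2 * (u + v) / kz)
  }
  sys
}

#' Two-particle distance-constrained toy system
#'
#' Two particles joined by a harmonic well on each coordinate, with the
#' interparticle distance as the single CV. The Z matrix is the scalar
#' \eqn{1/m_1 + 1/m_2}.
#'
#' @param masses Length-2 masses (amu).
#' @param k Force constant of the confining wells.
#' @return A `toy_system`.
#' @export
toy_distance_system <- function(masses = c(12, 16), k = 1.5) {
  centers <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  toy_system(
    masses = masses,
    potential = potential_harmonic(k, centers),
    cvs = list(cv_distance(c(1L, 2L))),
    coords0 = centers + 1e-3
  )
}

#' Write the bundled fixtures to disk
#'
#' Emits the ala_like_2d surface as a grid file loadable by
#' [load_grid()], plus the straight interpolated path between its minima.
#'
#' @param dir Output directory (created if missing).
#' @param step Grid step for the sampled surface.
#' @param m Snapshots on the straight path.
#' @param seed Seed recorded in the file headers.
#' @return Invisibly, the named vector of files written.
#' @export
write_fixtures <- function(dir, step = 0.05, m = 40L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- fixture_set(seed)
  ala <- fx$ala_like_2d
  axes <- list(
    list(min = -3, max = 3, step = step, periodic = FALSE),
    list(min = -3, max = 3, step = step, periodic = FALSE)
  )
  grid <- sample_to_grid(ala$surface, axes, order = "bicubic")
  gfile <- file.path(dir, "ala_like_2d_grid.dat")
  save_grid(grid, gfile)
  p <- interpolate_linear(ala$reactant, ala$product, m)
  pfile <- file.path(dir, "ala_like_2d_straight_path.dat")
  write_path(p, pfile, units = c("rad", "rad"),
             extra_header = c(seed = as.character(seed)))
  invisible(c(grid = gfile, path = pfile))
}
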