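# Shared helpers: small geometries and finite-difference oracles.

random_coords <- function(n_atoms, spread = 3) {
  matrix(runif(3 * n_atoms, -spread, spread), n_atoms, 3)
}

# central finite difference of a CV over every Cartesian coordinate
fd_cv_gradient <- function(spec, coords, h = 1e-5) {
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (j in 1:3) {
    cp <- coords; cm <- coords
    cp[i, j] <- cp[i, j] + h
    cm[i, j] <- cm[i, j] - h
    vp <- cv_value(spec, cp)
    vm <- cv_value(spec, cm)
    d <- vp - vm
    if (isTRUE(spec$periodic)) d <- d - 2 * pi * round(d / (2 * pi))
    g[i, j] <- d / (2 * h)
  }
  g
}

# well-separated non-collinear 4-atom geometry for dihedral tests
dihedral_coords <- function(phi) {
  rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1.5),
        c(cos(phi), sin(phi), 1.5) + c(0, 0, 0.8) * 0)
}

ala_fixture <- function() fixture_set(1)$ala_like_2d
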