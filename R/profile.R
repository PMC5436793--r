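#' Free energy profile along a path
#'
#' Thermodynamic integration of the tangential mean force: with
#' per-snapshot gradients \eqn{\nabla F_i} (ensemble-averaged Lagrange
#' multipliers, or analytic gradients) the profile is
#' \eqn{F(\xi_i) = \int_0^{\xi_i} (\nabla F \cdot \hat{t}) \, ds}
#' evaluated by the trapezoid rule on the snapshot grid, with arc length
#' as the integration measure and \eqn{F(0) = 0}. An optional endpoint
#' correction pair (the \eqn{-k_B T \ln\langle|Z|^{-1/2}\rangle} term at
#' reactant and product) adds its difference to the product end; if
#' per-snapshot corrections are supplied the correction is attributed
#' pointwise instead.
#'
#' @param path A reparametrized complete `cv_path`.
#' @param gradients m x n matrix of per-snapshot free energy gradients.
#' @param corrections Either `NULL`, a length-2 numeric (reactant and
#'   product correction terms, kcal/mol), or a length-m numeric of
#'   per-snapshot correction terms.
#' @param stderrs Optional m x n matrix of per-component gradient
#'   standard errors; propagated through the quadrature.
#' @return A tibble of class `fe_profile` with columns `xi`, `F`,
#'   `stderr`, plus attributes `correction_applied` and `ti_term` /
#'   `correction_term` columns when corrections are supplied.
#' @export
integrate_profile <- function(path, gradients, corrections = NULL,
                              stderrs = NULL) {
  m <- path_m(path)
  gradients <- matrix(gradients, nrow = m)
  if (nrow(gradients) != m)
    abort("gradients misaligned with path snapshots")
  tg <- path_tangents(path)
  proj <- rowSums(gradients * tg)
  seg <- segment_lengths(path)
  xi <- path_arc_fractions(path)
  # trapezoid in arc length
  incr <- seg * (head(proj, -1L) + tail(proj, -1L)) / 2
  Fv <- c(0, cumsum(incr))
  serr <- rep(NA_real_, m)
  if (!is.null(stderrs)) {
    stderrs <- matrix(stderrs, nrow = m)
    pvar <- rowSums((stderrs * tg)^2)
    ivar <- (seg / 2)^2 * (head(pvar, -1L) + tail(pvar, -1L))
    serr <- sqrt(c(0, cumsum(ivar)))
  }
  ti <- Fv
  corr <- rep(0, m)
  if (!is.null(corrections)) {
    if (length(corrections) == 2L) {
      corr[m] <- corrections[2L] - corrections[1L]
    } else if (length(corrections) == m) {
      corr <- corrections - corrections[1L]
    } else {
      abort("corrections must have length 2 (endpoints) or m (per snapshot)")
    }
    Fv <- Fv + corr
  }
  structure(
    tibble(xi = xi, F = Fv, stderr = serr, ti_term = ti,
           correction_term = corr),
    class = c("fe_profile", "tbl_df", "tbl", "data.frame"),
    correction_applied = !is.null(corrections)
  )
}

#' Barrier of a free energy profile
#'
#' @param profile An `fe_profile` (or any data frame with `xi` and `F`).
#' @return List with `height` (max F minus F at the reactant) and `xi`
#'   (location of the maximum).
#' @export
barrier <- function(profile) {
  if (nrow(profile) == 0) abort("empty profile")
  i <- which.max(profile$F)
  list(height = profile$F[i] - profile$F[1L], xi = profile$xi[i])
}

#' Read and write profile files
#'
#' Delimited text with a `# columns: xi F stderr` header.
#'
#' @param profile An `fe_profile`.
#' @param file File path.
#' @param extra_header Named character vector of extra header lines.
#' @return `read_profile` returns an `fe_profile`; `write_profile`
#'   returns `file` invisibly.
#' @export
write_profile <- function(profile, file, extra_header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# columns: xi F stderr ti_term correction_term", con)
  if (!is.null(extra_header))
    for (k in names(extra_header))
      writeLines(sprintf("# %s=%s", k, extra_header[[k]]), con)
  rows <- vapply(seq_len(nrow(profile)), function(r)
    paste(sprintf("%.17g", c(profile$xi[r], profile$F[r],
                             profile$stderr[r], profile$ti_term[r],
                             profile$correction_term[r])),
          collapse = " "), character(1))
  writeLines(rows, con)
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  lines <- readLines(file)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- do.call(rbind, lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    tok[tok == "NA"] <- NA_character_
    as.numeric(tok)
  }))
  structure(
    tibble(xi = vals[, 1L], F = vals[, 2L], stderr = vals[, 3L],
           ti_term = vals[, 4L], correction_term = vals[, 5L]),
    class = c("fe_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Profile of a path on a surface with known values or gradients
#'
#' Convenience wrapper: evaluates the field gradient at every snapshot
#' and integrates.
#'
#' @param path A `cv_path`.
#' @param field A `gradient_field`.
#' @param corrections Passed to [integrate_profile()].
#' @return An `fe_profile`.
#' @export
profile_on_field <- function(path, field, corrections = NULL) {
  integrate_profile(path, path_gradients(path, field),
                    corrections = corrections)
}
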