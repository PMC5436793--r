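#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Tiny polynomial hash of the serialized configuration, recorded in
# output headers so artifacts can be matched to the run that produced
# them.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

default_run_config <- function() {
  list(
    mode = "budget",
    out_dir = ".",
    seed = 1L,
    surface = "ala_like_2d",   # fixture name or grid file path
    grid_file = NULL,
    path_file = NULL,
    m = 40L,
    grow = list(s_g = 0.102, w = 10, sweeps = 2L, s_op = 0.002),
    optimize = list(method = "sd_fixed", s_op = 0.002,
                    s_op_initial = 0.004, s_step = 0.2,
                    max_iter = 200L),
    budget = list(method = "full_path", iterations = 200L, sweeps = 2L,
                  sampling_ps = 3, timestep_fs = 1)
  )
}

resolve_surface <- function(config) {
  if (!is.null(config$grid_file)) return(load_grid(config$grid_file))
  fx <- fixture_set(config$seed)
  switch(config$surface,
    ala_like_2d = fx$ala_like_2d$surface,
    saddle_quadratic = fx$saddle_quadratic,
    harmonic_nd = fx$harmonic_nd,
    mueller_brown = surface_mueller_brown(),
    abort(sprintf("unknown surface '%s'", config$surface))
  )
}

resolve_endpoints <- function(config, surface) {
  if (!is.null(config$reactant))
    return(list(reactant = as.numeric(config$reactant),
                product = as.numeric(config$product)))
  if (!is.null(surface$minima) && length(surface$minima) >= 2)
    return(list(reactant = surface$minima[[1L]],
                product = surface$minima[[2L]]))
  abort("config must give reactant/product (surface has no stored minima)")
}

#' Run a configured job
#'
#' The programmatic equivalent of the `growpath` command line: executes
#' one mode (`fixtures`, `grow`, `optimize`, `profile`, `budget`) and
#' writes its artifacts (path files, profiles, sigma-perp trace, ledger)
#' into `config$out_dir`. Every output header records the seed and a hash
#' of the configuration; runs are deterministic given the seed.
#'
#' @param config A named list; see `growpath:::default_run_config()` for
#'   the recognized fields. Missing fields take their defaults.
#' @return Invisibly, a named list of artifact file paths and the main
#'   result object.
#' @export
run_growpath <- function(config = list()) {
  config <- modifyList(default_run_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # the hash identifies the scientific configuration, not where the
  # artifacts land
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  hdr <- c(seed = as.character(config$seed), config_hash = hash)
  out <- list()

  if (config$mode == "fixtures") {
    files <- write_fixtures(config$out_dir, seed = config$seed)
    return(invisible(list(files = files)))
  }
  if (config$mode == "budget") {
    b <- config$budget
    led <- budget(m = config$m, method = b$method,
                  iterations = b$iterations, sweeps = b$sweeps,
                  sampling_ps = b$sampling_ps,
                  timestep_fs = b$timestep_fs)
    f <- file.path(config$out_dir, "budget.tsv")
    con <- file(f, "w")
    writeLines(sprintf("# seed=%s config_hash=%s", hdr[1], hash), con)
    close(con)
    suppressWarnings(utils::write.table(led, f, append = TRUE, sep = "\t",
                                        row.names = FALSE, quote = FALSE))
    return(invisible(list(ledger = led, files = c(budget = f))))
  }

  surface <- resolve_surface(config)
  ep <- resolve_endpoints(config, surface)

  if (config$mode == "grow") {
    g <- config$grow
    run <- grow_path(ep$reactant, ep$product, surface,
                     grow_config(s_g = g$s_g, w = g$w, sweeps = g$sweeps,
                                 s_op = g$s_op))
    f <- file.path(config$out_dir, "grown_path.dat")
    write_path(run$path, f, extra_header = hdr)
    return(invisible(list(result = run, files = c(path = f))))
  }
  if (config$mode == "optimize") {
    o <- config$optimize
    p0 <- if (!is.null(config$path_file)) read_path(config$path_file)
          else interpolate_linear(ep$reactant, ep$product, config$m)
    cfg <- optimize_config(method = o$method, s_op = o$s_op,
                           s_op_initial = o$s_op_initial,
                           s_step = o$s_step, max_iter = o$max_iter)
    res <- optimize_path(p0, surface, cfg)
    fp <- file.path(config$out_dir, "optimized_path.dat")
    ft <- file.path(config$out_dir, "sigma_trace.tsv")
    write_path(res$path, fp, extra_header = hdr)
    con <- file(ft, "w")
    writeLines(sprintf("# seed=%s config_hash=%s", hdr[1], hash), con)
    close(con)
    suppressWarnings(utils::write.table(res$trace, ft, append = TRUE,
                                        sep = "\t", row.names = FALSE,
                                        quote = FALSE))
    return(invisible(list(result = res,
                          files = c(path = fp, trace = ft))))
  }
  if (config$mode == "profile") {
    p <- if (!is.null(config$path_file)) read_path(config$path_file)
         else interpolate_linear(ep$reactant, ep$product, config$m)
    p <- reparametrize(p)
    prof <- profile_on_field(p, surface)
    f <- file.path(config$out_dir, "profile.dat")
    write_profile(prof, f, extra_header = hdr)
    return(invisible(list(result = prof, files = c(profile = f))))
  }
  abort(sprintf("unknown mode '%s'", config$mode))
}
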