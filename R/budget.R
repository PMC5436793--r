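#' Simulation-budget ledger
#'
#' Pure arithmetic accounting of the constrained-simulation cost of a path
#' protocol. Each snapshot optimization or growth evaluation costs one
#' constrained simulation of `sampling_ps` picoseconds.
#'
#' Full-path protocol: every iteration simulates all m snapshots, so
#' `iterations * m` simulations. Growing protocol with k optimization
#' sweeps per growth step: after growing snapshot i the sweep touches all
#' i current snapshots, so `k * sum(i = 1..m) = k * (m + m(m-1)/2)`
#' simulations in total.
#'
#' @param m Number of snapshots on the complete path.
#' @param method `"full_path"` or `"growing"`.
#' @param iterations Optimization iterations (full-path protocol).
#' @param sweeps Optimization sweeps per growth step (growing protocol).
#' @param sampling_ps Constrained-simulation length per snapshot per
#'   evaluation, in ps.
#' @param timestep_fs MD timestep in fs.
#' @return A tibble of class `budget_ledger` with columns `method`, `m`,
#'   `n_simulations`, `sampling_ps`, `timestep_fs`, `total_ns`,
#'   `steps_per_snapshot`.
#' @examples
#' budget(m = 40, method = "full_path", iterations = 200)   # 24 ns
#' budget(m = 40, method = "growing", sweeps = 2)           # 4.92 ns
#' @export
budget <- function(m, method = c("full_path", "growing"),
                   iterations = 200L, sweeps = 2L,
                   sampling_ps = 3, timestep_fs = 1) {
  method <- match.arg(method)
  m <- as.integer(m)
  n_sim <- if (method == "full_path") {
    as.integer(iterations) * m
  } else {
    # a 1-snapshot "path" admits no optimization sweeps at all
    if (m < 2L) 0L else as.integer(sweeps) * (m + (m * (m - 1L)) %/% 2L)
  }
  total_ns <- n_sim * sampling_ps / 1000
  steps_per_snapshot <- if (m > 0) total_ns * 1e6 / (m * timestep_fs)
                        else 0
  structure(
    tibble(method = method, m = m, n_simulations = n_sim,
           sampling_ps = sampling_ps, timestep_fs = timestep_fs,
           total_ns = total_ns, steps_per_snapshot = steps_per_snapshot),
    class = c("budget_ledger", "tbl_df", "tbl", "data.frame")
  )
}
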