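#' Configure a culture scenario
#'
#' The three culture strategies share one geometry: MSCs seeded at density 1
#' in the lower scaffold layer `0 < x < 1 - d`, chondrocytes at density `n0`
#' in the upper layer `1 - d < x < 1`, and active TGF-beta at concentration
#' `a0` in the culture medium `1 < x < 2`.
#'
#' * **Case 1** — layered co-culture, no exogenous TGF-beta (`a0 = 0`).
#' * **Case 2** — MSCs only (`n0 = 0`, `d = 0`), exogenous dose `a0`.
#' * **Case 3** — both: layered co-culture plus exogenous dose.
#'
#' Internally case 2 is the `d -> 0` limit of case 3, so a single code path
#' builds every initial state. Exogenous TGF-beta enters only as the active
#' pool; the single initial dose is not replenished.
#'
#' @param case Case id, 1, 2 or 3.
#' @param n0 Initial upper-layer chondrocyte density (dimensionless, `>= 0`).
#' @param a0 Initial active TGF-beta concentration in the medium
#'   (dimensionless, `>= 0`).
#' @param d Upper-layer depth fraction in \[0, 1\].
#' @param N Grid size (nodes over \[0, 2\]). Default 200.
#' @param t_end Final dimensionless time if 90% differentiation is not
#'   reached earlier. Default 20.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param snapshot_dt Snapshot cadence in dimensionless time.
#' @param eps_H Heaviside smoothing half-width (0 = exact switch).
#' @param guard Emptiness guard for fraction recovery.
#' @param max_neg Floor of the tolerated negative undershoot in any stored
#'   field. The working bound scales with the integrator's permitted local
#'   error (`100 atol + rtol * max(field)`); undershoots within the bound
#'   are clipped to zero, larger negatives abort the run.
#' @param hmax Maximum integrator step (guards against stepping over
#'   switch ignition).
#' @param stop_at_t90 Terminate when 90% of the initial MSC population has
#'   differentiated (the standard stopping rule). Set `FALSE` to always
#'   integrate to `t_end`.
#' @param seed Reserved; the deterministic core ignores it.
#'
#' @return An object of class `chondro_config`.
#' @export
#' @examples
#' scenario_config(1, n0 = 0.3, d = 0.5)
scenario_config <- function(case, n0 = 0, a0 = 0, d = 0,
                            N = 200, t_end = 20,
                            rtol = 1e-6, atol = 1e-9,
                            snapshot_dt = 0.1, eps_H = 0,
                            guard = 1e-9, max_neg = 1e-10, hmax = 0.05,
                            stop_at_t90 = TRUE, seed = NULL) {
  if (!case %in% 1:3)
    stop("case must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(n0) || length(n0) != 1L || is.na(n0) || n0 < 0)
    stop("n0 must be a single non-negative number", call. = FALSE)
  if (!is.numeric(a0) || length(a0) != 1L || is.na(a0) || a0 < 0)
    stop("a0 must be a single non-negative number", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
    stop("d must lie in [0, 1]", call. = FALSE)
  if (case == 1 && a0 != 0)
    stop("case 1 has no exogenous TGF-beta: a0 must be 0", call. = FALSE)
  if (case == 2 && (n0 != 0 || d != 0))
    stop("case 2 seeds MSCs only: n0 and d must be 0", call. = FALSE)
  if (case == 3 && n0 <= 0 && a0 <= 0)
    stop("case 3 needs a TGF-beta source: n0 > 0 or a0 > 0", call. = FALSE)
  if (t_end <= 0 || snapshot_dt <= 0 || rtol <= 0 || atol <= 0 ||
      guard <= 0 || max_neg <= 0 || hmax <= 0 || eps_H < 0)
    stop("numerical settings must be positive (eps_H may be 0)",
         call. = FALSE)
  structure(list(case = as.integer(case), n0 = n0, a0 = a0, d = d,
                 N = as.integer(N), t_end = t_end, rtol = rtol, atol = atol,
                 snapshot_dt = snapshot_dt, eps_H = eps_H, guard = guard,
                 max_neg = max_neg, hmax = hmax,
                 stop_at_t90 = isTRUE(stop_at_t90), seed = seed),
            class = "chondro_config")
}

#' Initial state for a culture scenario
#'
#' Seeding layers and the exogenous dose are indicator functions evaluated
#' at the grid nodes with the `H(0) = 0` convention, which snaps each layer
#' interface to the nearest enclosed node. All other pools start at zero.
#'
#' @param config A `chondro_config`.
#' @param grid A `chondro_grid`; defaults to the grid implied by the config.
#'
#' @return A `chondro_state` matrix.
#' @export
initial_state <- function(config, grid = chondro_grid(config$N)) {
  stopifnot(inherits(config, "chondro_config"))
  x <- grid$x
  s <- new_state(grid)
  s["m", ] <- heaviside(1 - config$d - x) * heaviside(x)
  s["n", ] <- config$n0 * heaviside(x - 1 + config$d) * heaviside(1 - x)
  s["a", ] <- config$a0 * heaviside(x - 1) * heaviside(2 - x)
  s
}

#' Initial MSC support interval
#'
#' The region over which the chondrocyte yield `N(t)` is integrated: the
#' initially MSC-seeded interval `[0, 1 - d]` (the whole scaffold `[0, 1]`
#' for case 2, where `d = 0`).
#'
#' @param config A `chondro_config`.
#' @return Numeric length-2 interval.
#' @export
msc_support <- function(config) {
  stopifnot(inherits(config, "chondro_config"))
  c(0, 1 - config$d)
}

#' @export
print.chondro_config <- function(x, ...) {
  cat(sprintf(paste0("Culture scenario: case %d (n0 = %g, a0 = %g, ",
                     "d = %g)\n"), x$case, x$n0, x$a0, x$d))
  cat(sprintf("  grid N = %d, t_end = %g, rtol = %g, atol = %g\n",
              x$N, x$t_end, x$rtol, x$atol))
  invisible(x)
}
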