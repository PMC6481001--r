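# Trapezoidal quadrature of a nodal field over the nodes inside an interval.
trapezoid_interval <- function(values, support, grid) {
  idx <- which(grid$x >= support[1] - 1e-12 & grid$x <= support[2] + 1e-12)
  if (length(idx) < 2L) return(0)
  v <- values[idx]
  grid$h * (sum(v) - 0.5 * v[1L] - 0.5 * v[length(v)])
}

#' Simulate a culture scenario
#'
#' Advances the semi-discrete reaction-diffusion system in time with the
#' adaptive stiff integrator [deSolve::lsoda()] (banded Jacobian, maximum
#' step `hmax` so that switch ignition is not stepped over). Following the
#' standard stopping rule, integration terminates at `t90`, the first time
#' at which the chondrocyte yield `N(t)` over the initial MSC region reaches
#' 90% of the initial MSC population (located by the integrator's root
#' finder), or at `t_end`, whichever is earlier.
#'
#' @param config A `chondro_config`, see [scenario_config()].
#' @param params Dimensionless parameters (`chondro_dimless`), a dimensional
#'   set (`chondro_params`, non-dimensionalised internally), or `NULL` for
#'   the defaults.
#' @param scales A `chondro_scales` used when non-dimensionalising and when
#'   converting reported times to hours.
#' @param init Optional `chondro_state` overriding the scenario's initial
#'   state (useful for analytic test problems).
#'
#' @return An object of class `chondro_sim` with components:
#' \describe{
#'   \item{times}{sampled dimensionless times (strictly increasing).}
#'   \item{states}{7 x N x length(times) array of field snapshots.}
#'   \item{yield}{the series `N(t)` at the sampled times.}
#'   \item{t90}{dimensionless 90% differentiation time, or `NA` if the
#'     threshold was not crossed.}
#'   \item{initial_msc}{initial MSC number per cross-sectional area.}
#'   \item{terminal_state}{`chondro_state` at the final time.}
#'   \item{termination}{one of `"t90_reached"`, `"t_end_reached"`,
#'     `"aborted"`.}
#'   \item{diagnostics}{solver metadata: terminal steady-state residual
#'     `max |rhs|`, wall time, and (for aborted runs) the failure message.}
#' }
#' @export
#' @examples
#' \donttest{
#' cfg <- scenario_config(1, n0 = 0.3, d = 0.5)
#' sim <- simulate_culture(cfg)
#' summary(sim)
#' }
simulate_culture <- function(config, params = NULL,
                             scales = default_scales(), init = NULL) {
  stopifnot(inherits(config, "chondro_config"))
  dim_params <- NULL
  if (is.null(params)) {
    dim_params <- default_parameters()
    params <- nondimensionalise(dim_params, scales)
  } else if (inherits(params, "chondro_params")) {
    dim_params <- params
    params <- nondimensionalise(dim_params, scales)
  } else if (!inherits(params, "chondro_dimless")) {
    stop("params must be chondro_dimless, chondro_params or NULL",
         call. = FALSE)
  }

  grid <- chondro_grid(config$N)
  state0 <- if (is.null(init)) initial_state(config, grid) else {
    stopifnot(inherits(init, "chondro_state"), ncol(init) == grid$N)
    init
  }
  support <- msc_support(config)
  initial_msc <- trapezoid_interval(state0["m", ], support, grid)
  threshold <- 0.9 * initial_msc

  times <- seq(0, config$t_end, by = config$snapshot_dt)
  if (times[length(times)] < config$t_end) times <- c(times, config$t_end)

  parms <- list(dimless = params, grid = grid, eps_H = config$eps_H,
                guard = config$guard)
  last_good <- new.env(parent = emptyenv())
  last_good$y <- pack_state(state0); last_good$t <- 0
  rhs_tracked <- function(t, y, p) {
    out <- rhs_vec(t, y, p)
    last_good$y <- y; last_good$t <- t
    out
  }
  rootfun <- NULL
  if (config$stop_at_t90 && initial_msc > 0)
    rootfun <- function(t, y, p)
      trapezoid_interval(pmax(matrix(y, nrow = 7L)[2L, ], 0), support,
                         grid) - threshold

  wall <- system.time(
    out <- tryCatch(
      deSolve::lsoda(pack_state(state0), times, rhs_tracked, parms,
                     rtol = config$rtol, atol = config$atol,
                     jactype = "bandint", bandup = 7L, banddown = 7L,
                     hmax = config$hmax, rootfunc = rootfun,
                     maxsteps = 200000L),
      error = function(e) e)
  )[["elapsed"]]

  fail_msg <- NULL
  if (inherits(out, "error")) {
    fail_msg <- conditionMessage(out)
    out <- NULL
  }

  if (!is.null(out)) {
    ymat <- unname(out[, -1L, drop = FALSE])
    # tolerated undershoot scales with the local error the integrator is
    # allowed per field; max_neg is an absolute floor below that
    for (k in seq_len(7L)) {
      cols <- seq(k, ncol(ymat), by = 7L)
      fv <- ymat[, cols, drop = FALSE]
      neg_tol <- max(config$max_neg,
                     100 * config$atol + config$rtol * max(fv))
      if (min(fv) < -neg_tol) {
        fail_msg <- sprintf(
          "negative undershoot %.3g in field '%s' exceeds tolerance %.3g",
          min(fv), state_fields[k], neg_tol)
        bad_row <- which(fv == min(fv), arr.ind = TRUE)[1L, 1L]
        out <- out[seq_len(max(bad_row - 1L, 1L)), , drop = FALSE]
        break
      }
    }
  }

  if (is.null(out) || nrow(out) < 1L) {
    term_state <- unpack_state(pmax(last_good$y, 0), grid$N)
    res <- list(times = last_good$t, states = NULL,
                yield = trapezoid_interval(term_state["n", ], support, grid),
                t90 = NA_real_, initial_msc = initial_msc,
                terminal_state = term_state, termination = "aborted",
                config = config, params = params, dim_params = dim_params,
                scales = scales, grid = grid,
                diagnostics = list(message = fail_msg, wall_time = wall))
    return(structure(res, class = "chondro_sim"))
  }

  t_out <- out[, 1L]
  n_t <- length(t_out)
  states <- array(pmax(out[, -1L, drop = FALSE], 0),
                  dim = c(n_t, 7L, grid$N))
  states <- aperm(states, c(2L, 3L, 1L))
  dimnames(states) <- list(state_fields, NULL, NULL)
  yield <- vapply(seq_len(n_t), function(i)
    trapezoid_interval(states["n", , i], support, grid), numeric(1))

  troot <- attr(out, "troot")
  t90 <- if (!is.null(troot) && length(troot)) troot[1L] else NA_real_
  termination <- if (!is.null(fail_msg)) "aborted"
                 else if (!is.na(t90)) "t90_reached" else "t_end_reached"
  if (is.na(t90) && initial_msc > 0) {
    # no terminating root (e.g. stop_at_t90 = FALSE): interpolate the series
    t90 <- detect_t90(t_out, yield, initial_msc)
  }

  terminal_state <- structure(states[, , n_t],
                              dimnames = list(state_fields, NULL),
                              class = "chondro_state")
  resid <- max(abs(rhs_derivatives(terminal_state, params, grid,
                                   t = t_out[n_t], eps_H = config$eps_H,
                                   guard = config$guard)))
  res <- list(times = t_out, states = states, yield = yield, t90 = t90,
              initial_msc = initial_msc, terminal_state = terminal_state,
              termination = termination, config = config, params = params,
              dim_params = dim_params, scales = scales, grid = grid,
              diagnostics = list(steady_residual = resid, wall_time = wall,
                                 solver = "lsoda (deSolve), banded Jacobian",
                                 message = fail_msg))
  structure(res, class = "chondro_sim")
}

#' Locate the 90% differentiation time on a yield series
#'
#' Finds the first time at which the chondrocyte yield `N(t)` reaches 90% of
#' the initial MSC number, by linear interpolation between samples. `N(t)` is
#' monotone non-decreasing for this model, so the first bracketing interval
#' contains the only crossing.
#'
#' @param times Sample times (strictly increasing).
#' @param yield Yield series `N(t)` at `times`.
#' @param initial_msc Initial MSC number per cross-sectional area.
#'
#' @return The crossing time, or `NA` if the threshold is not reached.
#' @export
#' @examples
#' t <- seq(0, 5, 0.01)
#' detect_t90(t, 1 - exp(-t), 1)   # log(10) ~ 2.3026
detect_t90 <- function(times, yield, initial_msc) {
  stopifnot(length(times) == length(yield), initial_msc >= 0)
  thr <- 0.9 * initial_msc
  hit <- which(yield >= thr)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(times[1L])
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- yield[i - 1L]; y1 <- yield[i]
  if (y1 == y0) return(t1)
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' @export
print.chondro_sim <- function(x, ...) {
  cat(sprintf("chondrogenesis simulation: case %d (n0 = %g, a0 = %g, d = %g)\n",
              x$config$case, x$config$n0, x$config$a0, x$config$d))
  cat(sprintf("  termination: %s at t = %.4g\n", x$termination,
              x$times[length(x$times)]))
  if (!is.na(x$t90))
    cat(sprintf("  t90 = %.4g (%.1f h)\n", x$t90,
                if (!is.null(x$dim_params))
                  dimensional_time(x$t90, x$dim_params) else NA))
  cat(sprintf("  final yield N = %.4g of initial MSC number %.4g\n",
              x$yield[length(x$yield)], x$initial_msc))
  invisible(x)
}

#' @export
summary.chondro_sim <- function(object, ...) {
  out <- classify_outcome(object)
  hrs <- if (!is.null(object$dim_params) && !is.na(object$t90))
    dimensional_time(object$t90, object$dim_params) else NA_real_
  s <- list(case = object$config$case, n0 = object$config$n0,
            a0 = object$config$a0, d = object$config$d,
            outcome = out$label,
            N_final = out$N_final,
            yield_fraction = if (object$initial_msc > 0)
              out$N_final / object$initial_msc else NA_real_,
            t90 = object$t90, t90_hours = hrs,
            termination = object$termination,
            steady_residual = object$diagnostics$steady_residual)
  structure(s, class = "summary.chondro_sim")
}

#' @export
print.summary.chondro_sim <- function(x, ...) {
  cat(sprintf("case %d: n0 = %g, a0 = %g, d = %g\n", x$case, x$n0, x$a0, x$d))
  cat(sprintf("  outcome: %s differentiation\n", x$outcome))
  cat(sprintf("  chondrocyte yield N = %.4g (%.1f%% of initial MSCs)\n",
              x$N_final, 100 * x$yield_fraction))
  if (!is.na(x$t90))
    cat(sprintf("  t90 = %.4g dimensionless = %.1f hours\n",
                x$t90, x$t90_hours))
  cat(sprintf("  termination: %s, terminal max|rhs| = %.3g\n",
              x$termination, x$steady_residual))
  invisible(x)
}

#' Plot field profiles from a simulation
#'
#' Draws the chondrocyte density `n(x, t)` and the MSC receptor occupancy
#' `f(x, t)` against depth at a selection of snapshot times, with the
#' differentiation threshold `fd` marked.
#'
#' @param x A `chondro_sim`.
#' @param times Snapshot times to draw (nearest stored snapshots are used).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.chondro_sim <- function(x, times = pretty(range(x$times), 4), ...) {
  if (is.null(x$states)) stop("aborted run holds no snapshots", call. = FALSE)
  idx <- unique(vapply(times, function(t)
    which.min(abs(x$times - t)), integer(1)))
  xx <- x$grid$x
  old <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(xx, t(x$states["n", , idx, drop = TRUE]), type = "l",
                    lty = 1, xlab = "depth x", ylab = "n(x, t)",
                    main = "chondrocyte density", ...)
  fmat <- vapply(idx, function(i)
    recover_fraction(x$states["p", , i], x$states["m", , i],
                     x$config$guard), numeric(x$grid$N))
  graphics::matplot(xx, fmat, type = "l", lty = 1, xlab = "depth x",
                    ylab = "f(x, t)", main = "MSC receptor occupancy", ...)
  graphics::abline(h = x$params$fd, lty = 2, col = "red")
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_along(idx),
                   legend = sprintf("t = %.3g", x$times[idx]))
  invisible(x)
}
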