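#' Chondrocyte yield per cross-sectional area
#'
#' Trapezoidal quadrature of the chondrocyte density over a depth interval,
#' normally the initially MSC-seeded region `[0, 1 - d]` (see
#' [msc_support()]).
#'
#' @param state A `chondro_state`.
#' @param support Length-2 interval inside the scaffold `[0, 1]`.
#' @param grid A `chondro_grid`.
#'
#' @return The yield (dimensionless cell number per cross-sectional area).
#' @export
yield_N <- function(state, support, grid) {
  stopifnot(inherits(state, "chondro_state"),
            length(support) == 2L, support[1] >= 0,
            support[2] <= 1 + 1e-12)
  trapezoid_interval(state["n", ], support, grid)
}

#' Classify the long-term outcome of a simulation
#'
#' Three outcomes are possible. **Full** differentiation: the 90% time `t90`
#' was reached, or the terminal MSC receptor occupancy satisfies `f >= fd`
#' wherever MSCs remain (such cells are already committed and will
#' differentiate beyond the simulated horizon). **None**: the final yield is
#' below a small floor relative to the initial MSC number. **Partial**:
#' anything in between, typically a thin chondrocyte layer at the top of the
#' scaffold.
#'
#' @param result A `chondro_sim`.
#' @param config Scenario configuration; defaults to the one stored in
#'   `result`.
#' @param yield_floor Fraction of the initial MSC number below which the
#'   outcome is labelled `none`. Default `1e-4`.
#'
#' @return An object of class `chondro_outcome`: list with `label`
#'   (`"none"`, `"partial"` or `"full"`), `N_final`, `t90` and
#'   `initial_msc`.
#' @export
classify_outcome <- function(result, config = result$config,
                             yield_floor = 1e-4) {
  stopifnot(inherits(result, "chondro_sim"))
  if (result$termination == "aborted")
    stop("cannot classify an aborted simulation: ",
         result$diagnostics$message, call. = FALSE)
  support <- msc_support(config)
  N_final <- yield_N(result$terminal_state, support, result$grid)
  m_term <- result$terminal_state["m", ]
  f_term <- recover_fraction(result$terminal_state["p", ], m_term,
                             config$guard)
  committed <- all(f_term[m_term > config$guard] >= result$params$fd)
  label <- if (!is.na(result$t90) || committed) "full"
           else if (N_final < yield_floor * result$initial_msc) "none"
           else "partial"
  structure(list(label = label, N_final = N_final, t90 = result$t90,
                 initial_msc = result$initial_msc),
            class = "chondro_outcome")
}

#' @export
print.chondro_outcome <- function(x, ...) {
  cat(sprintf("%s differentiation: N_final = %.4g (initial MSCs %.4g)",
              x$label, x$N_final, x$initial_msc))
  if (!is.na(x$t90)) cat(sprintf(", t90 = %.4g", x$t90))
  cat("\n")
  invisible(x)
}

#' Bisection on a monotone full/not-full classifier
#'
#' Generic threshold search used by [find_critical()]: the classifier must
#' return `"full"` above the threshold and another label below.
#'
#' @param classify_fn Function of one numeric value returning an outcome
#'   label.
#' @param bracket Length-2 bracket; the lower endpoint must classify
#'   not-full and the upper full.
#' @param tol Bracket-width stopping tolerance: absolute width on a linear
#'   scale, relative width (`hi/lo - 1`) on the log scale.
#' @param log_scale Bisect in `log10` of the value (for quantities spanning
#'   orders of magnitude).
#'
#' @return List with `value` (bracket midpoint), `bracket` (final
#'   endpoints), `tol_achieved` and `log` (data frame of evaluations).
#' @export
#' @examples
#' step <- function(v) if (v > 0.4) "full" else "none"
#' bisect_threshold(step, c(0, 1), tol = 0.001)$value   # ~0.4
bisect_threshold <- function(classify_fn, bracket, tol, log_scale = FALSE) {
  lo <- bracket[1]; hi <- bracket[2]
  stopifnot(lo < hi, tol > 0, !log_scale || lo > 0)
  log_rows <- list()
  eval1 <- function(v) {
    lab <- classify_fn(v)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(value = v, label = lab)
    lab
  }
  lab_lo <- eval1(lo); lab_hi <- eval1(hi)
  if (lab_lo == "full" || lab_hi != "full")
    stop("bracket endpoints must classify not-full (lower) and full ",
         "(upper); got '", lab_lo, "' and '", lab_hi, "'", call. = FALSE)
  width <- function() if (log_scale) hi / lo - 1 else hi - lo
  while (width() > tol) {
    mid <- if (log_scale) sqrt(lo * hi) else (lo + hi) / 2
    if (eval1(mid) == "full") hi <- mid else lo <- mid
  }
  value <- if (log_scale) sqrt(lo * hi) else (lo + hi) / 2
  list(value = value, bracket = c(lo, hi), tol_achieved = width(),
       log = do.call(rbind, log_rows))
}

# Outcomes must be ordered none <= partial <= full as the swept value
# increases; aborted cells are ignored.
labels_monotone <- function(values, labels) {
  rank <- c(none = 1L, partial = 2L, full = 3L)[labels[order(values)]]
  !is.unsorted(rank, na.rm = TRUE)
}

#' Critical seeding density or exogenous dose
#'
#' Locates the critical value of `n0` (initial chondrocyte density) or `a0`
#' (initial exogenous active TGF-beta concentration) above which the whole
#' MSC population differentiates, by bisection on the outcome
#' classification. The dose search runs on a log scale because the
#' full-differentiation boundary spans orders of magnitude.
#'
#' @param param `"n0"` or `"a0"`.
#' @param base_config Scenario configuration whose `n0`/`a0` field is swept.
#' @param bracket Length-2 search bracket (not-full at the lower endpoint,
#'   full at the upper).
#' @param tol Stopping tolerance: absolute for `n0` (default 0.005),
#'   relative for `a0` (default 0.02).
#' @param params Dimensionless parameters, `NULL` for defaults.
#' @param classify_fn Optional replacement classifier (value -> label),
#'   used instead of running simulations; intended for testing the search
#'   machinery.
#'
#' @return An object of class `chondro_critical`: list with `param`,
#'   `value`, `bracket`, `tol_achieved` and the per-evaluation `log`
#'   (value, label, N_final, t90). A warning attribute `nonmonotone` is set
#'   if the evaluation log violates the none <= partial <= full ordering.
#' @export
find_critical <- function(param = c("n0", "a0"), base_config = NULL, bracket,
                          tol = if (param == "n0") 0.005 else 0.02,
                          params = NULL, classify_fn = NULL) {
  param <- match.arg(param)
  log_scale <- param == "a0"
  extra <- new.env(parent = emptyenv()); extra$rows <- list()
  if (is.null(classify_fn)) {
    stopifnot(inherits(base_config, "chondro_config"))
    classify_fn <- function(v) {
      cfg <- base_config
      cfg[[param]] <- v
      sim <- simulate_culture(cfg, params = params)
      out <- classify_outcome(sim, cfg)
      extra$rows[[length(extra$rows) + 1L]] <-
        data.frame(value = v, N_final = out$N_final,
                   t90 = if (is.na(out$t90)) NA_real_ else out$t90)
      out$label
    }
  }
  res <- bisect_threshold(classify_fn, bracket, tol, log_scale = log_scale)
  log <- res$log
  if (length(extra$rows)) {
    det <- do.call(rbind, extra$rows)
    log <- merge(log, det, by = "value", all.x = TRUE, sort = FALSE)
  }
  log <- log[order(log$value), , drop = FALSE]
  mono <- labels_monotone(log$value, log$label)
  out <- structure(list(param = param, value = res$value,
                        bracket = res$bracket,
                        tol_achieved = res$tol_achieved, log = log),
                   class = "chondro_critical")
  if (!mono) {
    attr(out, "nonmonotone") <- TRUE
    warning("outcome labels are not monotone in ", param,
            " over the evaluation log", call. = FALSE)
  }
  out
}

#' @export
print.chondro_critical <- function(x, ...) {
  cat(sprintf("critical %s = %.4g (bracket [%.4g, %.4g], %d evaluations)\n",
              x$param, x$value, x$bracket[1], x$bracket[2], nrow(x$log)))
  invisible(x)
}

#' Two-parameter phase sweep over dose and seeding density
#'
#' Runs one classified simulation per `(a0, n0)` pair and tabulates the
#' long-term outcome, final yield and `t90`. Aborted runs are recorded as
#' `aborted` cells and the sweep continues.
#'
#' @param a0_values,n0_values Non-negative value ladders (non-empty).
#' @param base_config Scenario configuration supplying the layer depth `d`
#'   and numerical settings; its `a0` and `n0` are overridden per cell.
#' @param params Dimensionless parameters, `NULL` for defaults.
#'
#' @return A data frame of class `chondro_sweep` with columns `a0`, `n0`,
#'   `d`, `label`, `N_final`, `t90`.
#' @seealso [synergy_region()]
#' @export
phase_sweep <- function(a0_values, n0_values, base_config, params = NULL) {
  stopifnot(length(a0_values) >= 1L, length(n0_values) >= 1L,
            all(a0_values >= 0), all(n0_values >= 0),
            inherits(base_config, "chondro_config"))
  cells <- expand.grid(a0 = a0_values, n0 = n0_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base_config
    cfg$a0 <- cells$a0[i]; cfg$n0 <- cells$n0[i]
    row <- data.frame(a0 = cfg$a0, n0 = cfg$n0, d = cfg$d,
                      label = "aborted", N_final = NA_real_,
                      t90 = NA_real_)
    sim <- simulate_culture(cfg, params = params)
    if (sim$termination != "aborted") {
      out <- classify_outcome(sim, cfg)
      row$label <- out$label
      row$N_final <- out$N_final
      row$t90 <- out$t90
    }
    row
  })
  structure(do.call(rbind, rows), class = c("chondro_sweep", "data.frame"))
}

#' Synergy region of a phase sweep
#'
#' Cells achieving full differentiation with a seeding density below the
#' critical density `ncrit` *and* a dose below the critical dose `acrit`,
#' i.e. combinations that succeed where either source of TGF-beta alone
#' would fail.
#'
#' @param sweep A `chondro_sweep`.
#' @param ncrit Critical chondrocyte seeding density (for the sweep's `d`).
#' @param acrit Critical exogenous dose (chondrocyte-free scaffold).
#'
#' @return The qualifying rows of `sweep`.
#' @export
synergy_region <- function(sweep, ncrit, acrit) {
  stopifnot(inherits(sweep, "chondro_sweep"))
  sweep[sweep$label == "full" & sweep$n0 < ncrit & sweep$a0 < acrit, ,
        drop = FALSE]
}
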