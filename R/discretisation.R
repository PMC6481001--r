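#' Uniform 1D grid over the culture domain
#'
#' Vertex-centred nodes spanning the dimensionless domain \[0, 2\]: the
#' cell-seeded scaffold occupies \[0, 1\] and the cell-free culture medium
#' (1, 2\].
#'
#' @param N Number of nodes (integer, at least 3). Default 200.
#'
#' @return An object of class `chondro_grid` with components `N`, `h`
#'   (spacing `2/(N-1)`), `x` (node positions), and logical masks `scaffold`
#'   (`x <= 1`) and `medium` (`x > 1`).
#' @export
#' @examples
#' g <- chondro_grid(5)
#' g$x    # 0.0 0.5 1.0 1.5 2.0
chondro_grid <- function(N = 200) {
  if (!is.numeric(N) || length(N) != 1L || N < 3 || N != round(N))
    stop("N must be a single integer >= 3", call. = FALSE)
  N <- as.integer(N)
  h <- 2 / (N - 1)
  x <- (seq_len(N) - 1L) * h
  structure(list(N = N, h = h, x = x,
                 scaffold = x <= 1 + 1e-12,
                 medium = x > 1 + 1e-12),
            class = "chondro_grid")
}

#' Heaviside step switch
#'
#' The differentiation switch: `H(z) = 1` for `z > 0` and `0` otherwise,
#' so in particular `H(0) = 0`. An optional half-width `eps` replaces the
#' jump by a linear ramp over `[-eps, eps]` for solver-robustness studies;
#' the default is the exact discontinuous form.
#'
#' @param z Numeric vector.
#' @param eps Smoothing half-width (dimensionless, `>= 0`). Default 0 (off).
#'
#' @return Numeric vector of switch values in \[0, 1\].
#' @export
#' @examples
#' heaviside(c(-1, 0, 2))   # 0 0 1
heaviside <- function(z, eps = 0) {
  if (eps > 0) return(pmin(pmax((z + eps) / (2 * eps), 0), 1))
  as.numeric(z > 0)
}

#' Recover receptor-occupancy fractions from bound-mass densities
#'
#' The state evolves the products `p = f m` and `q = g n`; the switch and
#' binding terms need the per-cell fractions `f` and `g`. Division is guarded
#' at (near-)empty nodes: where the cell density does not exceed `guard` the
#' fraction is defined to be 0. Results are clipped to \[0, 1\].
#'
#' @param bound_mass Per-node bound receptor mass density (`p` or `q`).
#' @param cell_density Per-node cell density (`m` or `n`).
#' @param guard Emptiness guard (dimensionless density, `> 0`).
#'
#' @return Per-node fractions in \[0, 1\].
#' @export
recover_fraction <- function(bound_mass, cell_density, guard = 1e-9) {
  stopifnot(length(bound_mass) == length(cell_density), guard > 0)
  f <- numeric(length(bound_mass))
  ok <- cell_density > guard
  f[ok] <- bound_mass[ok] / cell_density[ok]
  pmin(pmax(f, 0), 1)
}

#' Discrete diffusion operator with no-flux boundaries
#'
#' Second-order central-difference Laplacian scaled by the diffusivity `D`,
#' with zero-flux (reflecting ghost node) closure at both ends of the domain.
#'
#' @param field Per-node values (length `grid$N`).
#' @param D Diffusivity (dimensionless).
#' @param grid A `chondro_grid`.
#'
#' @return Per-node values of `D * d2 field / dx2`.
#' @export
diffusion_operator <- function(field, D, grid) {
  N <- grid$N
  stopifnot(length(field) == N)
  out <- numeric(N)
  out[2:(N - 1)] <- field[1:(N - 2)] - 2 * field[2:(N - 1)] + field[3:N]
  out[1] <- 2 * (field[2] - field[1])       # ghost node u[-1] = u[1]
  out[N] <- 2 * (field[N - 1] - field[N])   # ghost node u[N+1] = u[N-1]
  D * out / grid$h^2
}

# Field names and ordering of the semi-discrete state. Per-node interleaving
# (column-major over a 7 x N matrix) keeps the Jacobian banded with half
# bandwidth 7: neighbour coupling only enters through the two diffusing
# fields c and a.
state_fields <- c("m", "n", "c", "b", "a", "p", "q")

#' Create an empty system state
#'
#' @param grid A `chondro_grid`.
#' @return A `chondro_state`: a 7 x N numeric matrix with rows `m` (MSC
#'   density), `n` (chondrocyte density), `c` (unbound latent TGF-beta),
#'   `b` (matrix-bound latent TGF-beta), `a` (active TGF-beta), `p` (`f m`,
#'   receptor-bound mass on MSCs) and `q` (`g n`, on chondrocytes).
#' @export
new_state <- function(grid) {
  structure(matrix(0, nrow = 7L, ncol = grid$N,
                   dimnames = list(state_fields, NULL)),
            class = "chondro_state")
}

pack_state <- function(state) as.vector(state)

unpack_state <- function(y, N) {
  structure(matrix(y, nrow = 7L, ncol = N,
                   dimnames = list(state_fields, NULL)),
            class = "chondro_state")
}

#' Method-of-lines right-hand side of the dimensionless system
#'
#' Computes the time derivative of every field at every node. Per node (with
#' `H` the [heaviside()] switch, `f`, `g` recovered by [recover_fraction()]
#' and `lap` the no-flux [diffusion_operator()]):
#' \preformatted{
#'   dm/dt = -H(f - fd) m
#'   dn/dt = +H(f - fd) m
#'   dc/dt = Dtc lap(c) + lt3 n - lt4 c - lt5 c
#'   db/dt = lt4 c - lt6 b - lt7 b
#'   da/dt = Dta lap(a) + lt6 b - lt8 a - ltm9 a m (1 - f) - ltn9 a n (1 - g)
#'   dp/dt = lhm9 a m (1 - f) - ltm10 p - H(f - fd) f m
#'   dq/dt = lhn9 a n (1 - g) - ltn10 q + H(f - fd) f m
#' }
#' Differentiation transfers cells (and their bound TGF-beta) from the MSC
#' pool to the chondrocyte pool, so `dm/dt + dn/dt = 0` pointwise and the
#' `p` sink equals the `q` source. Small negative solver undershoots are
#' clipped to zero before fractions are recovered.
#'
#' @param state A `chondro_state` (7 x N matrix).
#' @param params A `chondro_dimless` parameter set.
#' @param grid A `chondro_grid`.
#' @param t Dimensionless time (unused by the autonomous system; kept for
#'   the integrator signature).
#' @param eps_H Heaviside smoothing half-width, see [heaviside()].
#' @param guard Emptiness guard for fraction recovery.
#'
#' @return A 7 x N matrix of time derivatives (rows as in [new_state()]).
#' @export
rhs_derivatives <- function(state, params, grid, t = 0, eps_H = 0,
                            guard = 1e-9) {
  if (!all(is.finite(state))) {
    bad <- which(!is.finite(state), arr.ind = TRUE)[1L, ]
    stop("non-finite value in field '", state_fields[bad[1L]],
         "' at node ", bad[2L], " (t = ", signif(t, 6), ")", call. = FALSE)
  }
  m <- pmax(state[1L, ], 0); n <- pmax(state[2L, ], 0)
  cc <- pmax(state[3L, ], 0); b <- pmax(state[4L, ], 0)
  a <- pmax(state[5L, ], 0); p <- pmax(state[6L, ], 0)
  q <- pmax(state[7L, ], 0)
  f <- recover_fraction(p, m, guard)
  g <- recover_fraction(q, n, guard)
  Hf <- heaviside(f - params$fd, eps_H)
  diff_m <- Hf * m
  switch_pq <- Hf * f * m
  out <- matrix(0, nrow = 7L, ncol = grid$N,
                dimnames = list(state_fields, NULL))
  out[1L, ] <- -diff_m
  out[2L, ] <- diff_m
  out[3L, ] <- diffusion_operator(cc, params$Dtc, grid) +
    params$lt3 * n - (params$lt4 + params$lt5) * cc
  out[4L, ] <- params$lt4 * cc - (params$lt6 + params$lt7) * b
  out[5L, ] <- diffusion_operator(a, params$Dta, grid) +
    params$lt6 * b - params$lt8 * a -
    params$ltm9 * a * m * (1 - f) - params$ltn9 * a * n * (1 - g)
  out[6L, ] <- params$lhm9 * a * m * (1 - f) - params$ltm10 * p - switch_pq
  out[7L, ] <- params$lhn9 * a * n * (1 - g) - params$ltn10 * q + switch_pq
  out
}

# deSolve-facing wrapper over the interleaved state vector.
rhs_vec <- function(t, y, parms) {
  d <- rhs_derivatives(unpack_state(y, parms$grid$N), parms$dimless,
                       parms$grid, t = t, eps_H = parms$eps_H,
                       guard = parms$guard)
  list(as.vector(d))
}
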