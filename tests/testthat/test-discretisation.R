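test_that("grid nodes span [0, 2] uniformly and the masks partition them", {
  g <- chondro_grid(5)
  expect_equal(g$x, c(0, 0.5, 1, 1.5, 2))
  expect_equal(g$h, 0.5)
  expect_true(all(xor(g$scaffold, g$medium)))
  g2 <- chondro_grid(200)
  expect_equal(g2$x[1], 0)
  expect_equal(g2$x[200], 2)
  expect_equal(diff(range(diff(g2$x))), 0, tolerance = 1e-15)
  expect_error(chondro_grid(2), ">= 3")
})

test_that("heaviside switch is right-open with H(0) = 0, with optional ramp", {
  expect_identical(heaviside(c(-1, 0, 2)), c(0, 0, 1))
  # ramp of half-width eps: linear between -eps and eps
  expect_equal(heaviside(0, eps = 0.1), 0.5)
  expect_equal(heaviside(-0.1, eps = 0.1), 0)
  expect_equal(heaviside(0.1, eps = 0.1), 1)
  expect_equal(heaviside(0.05, eps = 0.1), 0.75)
  z <- seq(-1, 1, 0.01)
  expect_true(all(diff(heaviside(z, eps = 0.2)) >= 0))
})

test_that("fraction recovery guards empty nodes and clips to [0, 1]", {
  expect_equal(recover_fraction(0.5, 1), 0.5)
  expect_equal(recover_fraction(0, 0), 0)
  expect_equal(recover_fraction(1e-18, 1e-18, guard = 1e-12), 0)
  expect_equal(recover_fraction(2, 1), 1)       # clipped
  expect_equal(recover_fraction(-0.1, 1), 0)    # clipped
  expect_equal(recover_fraction(c(0.2, 0, 3), c(0.4, 0, 1)),
               c(0.5, 0, 1))
})

test_that("diffusion operator is exact on constants and quadratics and has the no-flux cosine eigenfunctions", {
  g <- chondro_grid(41)
  expect_equal(diffusion_operator(rep(3.7, g$N), 0.5, g), rep(0, g$N))
  u <- g$x^2
  interior <- 2:(g$N - 1)
  expect_equal(diffusion_operator(u, 0.25, g)[interior],
               rep(2 * 0.25, length(interior)), tolerance = 1e-10)
  # cos(k pi x / 2) satisfies the ghost-node reflection exactly, with
  # discrete eigenvalue -(2 D / h^2) (1 - cos(k pi h / 2)) -> -D (k pi/2)^2
  for (k in 1:3) {
    u <- cos(k * pi * g$x / 2)
    lam_disc <- -(2 * 0.3 / g$h^2) * (1 - cos(k * pi * g$h / 2))
    expect_equal(diffusion_operator(u, 0.3, g), lam_disc * u,
                 tolerance = 1e-10)
    expect_equal(lam_disc, -0.3 * (k * pi / 2)^2,
                 tolerance = (k * pi * g$h / 2)^2 / 4)
  }
})

test_that("a cosine mode decays at the analytic no-flux diffusion rate", {
  g <- chondro_grid(101)
  D <- 0.04
  u0 <- cos(pi * g$x / 2)
  out <- deSolve::lsoda(u0, c(0, 1),
                        function(t, y, p) list(diffusion_operator(y, D, g)),
                        NULL, rtol = 1e-10, atol = 1e-12)
  rate <- unname(-log(out[2, 2] / u0[1]))
  expect_equal(rate, D * (pi / 2)^2, tolerance = 1e-3)
})

test_that("differentiation moves cells (and bound TGF-beta) conservatively in the rhs", {
  g <- chondro_grid(60)
  for (seed in 1:5) {
    s <- random_state(g, seed)
    d <- rhs_derivatives(s, default_dimless, g)
    expect_equal(d["m", ] + d["n", ], rep(0, g$N))
    # switching off the threshold isolates the differentiation transfer:
    # its sink in dp/dt must equal its source in dq/dt at every node
    off <- default_dimless; off$fd <- 2
    d0 <- rhs_derivatives(s, off, g)
    expect_equal(d["p", ] - d0["p", ], -(d["q", ] - d0["q", ]),
                 tolerance = 1e-12)
  }
})

test_that("with no cells or stores, active TGF-beta only decays", {
  g <- chondro_grid(50)
  s <- new_state(g)
  s["a", ] <- 2.5
  d <- rhs_derivatives(s, default_dimless, g)
  expect_equal(d["a", ], rep(-default_dimless$lt8 * 2.5, g$N))
  for (fld in c("m", "n", "c", "b", "p", "q"))
    expect_equal(d[fld, ], rep(0, g$N))
})

test_that("non-finite state values abort with a diagnostic naming field and node", {
  g <- chondro_grid(20)
  s <- new_state(g)
  s["a", 7] <- NaN
  expect_error(rhs_derivatives(s, default_dimless, g),
               "field 'a' at node 7")
})

test_that("receptor-bound mass bookkeeping balances binding against internalisation", {
  g <- chondro_grid(80)
  p <- default_dimless
  for (seed in 6:8) {
    s <- random_state(g, seed)
    d <- rhs_derivatives(s, p, g)
    f <- recover_fraction(s["p", ], s["m", ])
    gfrac <- recover_fraction(s["q", ], s["n", ])
    expected <- p$lhm9 * s["a", ] * s["m", ] * (1 - f) -
      p$ltm10 * s["p", ] +
      p$lhn9 * s["a", ] * s["n", ] * (1 - gfrac) - p$ltn10 * s["q", ]
    expect_equal(d["p", ] + d["q", ], expected, tolerance = 1e-12)
  }
})

test_that("no-flux boundaries contribute nothing to the TGF-beta budget", {
  g <- chondro_grid(90)
  p <- default_dimless
  trap <- function(v) g$h * (sum(v) - 0.5 * v[1] - 0.5 * v[g$N])
  for (seed in 11:13) {
    s <- random_state(g, seed)
    d <- rhs_derivatives(s, p, g)
    rp <- p$ltm9 / p$lhm9    # ng of ligand per unit of bound-mass density
    rq <- p$ltn9 / p$lhn9
    lhs <- trap(d["c", ] + d["b", ] + d["a", ] + rp * d["p", ] +
                  rq * d["q", ])
    rhs <- trap(p$lt3 * s["n", ] - p$lt5 * s["c", ] - p$lt7 * s["b", ] -
                  p$lt8 * s["a", ] - rp * p$ltm10 * s["p", ] -
                  rq * p$ltn10 * s["q", ])
    # differentiation transfer cancels between p and q; diffusion
    # telescopes to zero under the reflecting boundary
    expect_equal(lhs, rhs, tolerance = 1e-6 * max(1, abs(rhs)))
  }
})
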