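test_that("a uniform cell-free dose decays at the closed-form rate", {
  cfg <- scenario_config(2, a0 = 5, N = 100, t_end = 0.3)
  g <- chondro_grid(cfg$N)
  init <- new_state(g)
  init["a", ] <- 5
  sim <- simulate_culture(cfg, init = init)
  i <- which.min(abs(sim$times - 0.1))
  expect_equal(sim$times[i], 0.1, tolerance = 1e-10)
  a_exact <- 5 * exp(-default_dimless$lt8 * 0.1)
  expect_lt(max(abs(sim$states["a", , i] - a_exact)), 1e-6 * 5)
  # spatially uniform: diffusion must not distort the profile
  expect_lt(diff(range(sim$states["a", , i])), 1e-9)
  # dimensionless half-life of active TGF-beta
  expect_equal(log(2) / default_dimless$lt8, 0.0161, tolerance = 1e-2)
})

test_that("without any TGF-beta source the MSC layer is inert", {
  sim <- cached_sim(1, n0 = 0, d = 0.5, t_end = 2)
  expect_identical(sim$termination, "t_end_reached")
  expect_true(is.na(sim$t90))
  last <- length(sim$times)
  expect_equal(sim$states["m", , last], sim$states["m", , 1],
               tolerance = 1e-9)
  expect_equal(max(sim$yield), 0)
})

test_that("t90 interpolation inverts a synthetic exponential yield curve", {
  t <- seq(0, 5, 0.001)
  expect_equal(detect_t90(t, 3 * (1 - exp(-t)), 3), log(10),
               tolerance = 1e-3)
  expect_true(is.na(detect_t90(t, 0.5 * (1 - exp(-t)), 3)))
  expect_equal(detect_t90(c(0, 1), c(5, 6), 1), 0)  # already past
})

test_that("a triggered co-culture differentiates monotonically and conserves cells", {
  sim <- cached_sim(1, n0 = 0.3, d = 0.5)
  expect_identical(sim$termination, "t90_reached")
  expect_equal(sim$t90, 6.57, tolerance = 0.05)
  g <- sim$grid
  trap_scaffold <- function(v) {
    idx <- which(g$scaffold)
    g$h * (sum(v[idx]) - 0.5 * v[idx[1]] - 0.5 * v[idx[length(idx)]])
  }
  total0 <- trap_scaffold(sim$states["m", , 1] + sim$states["n", , 1])
  nt <- length(sim$times)
  for (i in seq(1, nt, length.out = 12)) {
    i <- round(i)
    expect_equal(trap_scaffold(sim$states["m", , i] +
                                 sim$states["n", , i]),
                 total0, tolerance = 1e-6 * total0)
  }
  # m pointwise non-increasing, n non-decreasing over snapshots
  dm <- apply(sim$states["m", , ], 1, diff)
  dn <- apply(sim$states["n", , ], 1, diff)
  expect_lt(max(dm), 1e-7)
  expect_gt(min(dn), -1e-7)
  # receptor fractions stay physical
  for (i in c(1, round(nt / 2), nt)) {
    f <- recover_fraction(sim$states["p", , i], sim$states["m", , i])
    gg <- recover_fraction(sim$states["q", , i], sim$states["n", , i])
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(gg >= 0 & gg <= 1))
    expect_true(all(sim$states["p", , i] <=
                      sim$states["m", , i] * (1 + 1e-6) + 1e-9))
  }
})

test_that("termination by t90 leaves only committed MSCs behind", {
  sim <- cached_sim(1, n0 = 0.3, d = 0.5)
  m <- sim$terminal_state["m", ]
  f <- recover_fraction(sim$terminal_state["p", ], m, sim$config$guard)
  expect_true(all(f[m > sim$config$guard] >= sim$params$fd))
})

test_that("a non-finite initial state yields an aborted result with a diagnostic", {
  cfg <- scenario_config(2, a0 = 1, N = 50, t_end = 1)
  init <- new_state(chondro_grid(50))
  init["c", 5] <- Inf
  sim <- simulate_culture(cfg, init = init)
  expect_identical(sim$termination, "aborted")
  expect_match(sim$diagnostics$message, "field 'c'")
  expect_error(classify_outcome(sim), "aborted")
})
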