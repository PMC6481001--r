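test_that("default dimensional set non-dimensionalises to the printed table", {
  dl <- nondimensionalise(default_parameters())
  # printed values, at their printed precision
  expect_equal(signif(dl$lt3, 3), 18.2)
  expect_equal(signif(dl$lt4, 3), 16.7)
  expect_equal(dl$lt5, 1)
  expect_equal(dl$lt6, 10)
  expect_equal(dl$lt7, 1)
  expect_equal(dl$lt8, 43)
  expect_equal(signif(dl$ltm9, 3), 6.23)
  expect_equal(signif(dl$ltn9, 3), 6.23)
  expect_equal(dl$lhm9, 10)
  expect_equal(dl$lhn9, 10)
  expect_equal(signif(dl$ltm10, 3), 41.7)
  expect_equal(signif(dl$ltn10, 3), 41.7)
  expect_equal(signif(dl$Dtc, 2), 3.7e-2)
  expect_equal(signif(dl$Dta, 2), 3.7e-2)
  expect_equal(dl$fd, 0.01)
})

test_that("non-dimensionalisation matches hand-computed ratios on arbitrary inputs", {
  p <- default_parameters(Lambda1 = 2e-3, lambda3 = 0.05, lambda8 = 0.4,
                          Ftot = 0.9, Gtot = 0.31, lambda_m9 = 0.02,
                          Dc = 5e-10)
  s <- default_scales(A0 = 2, M0 = 3, L = 1.5e-3)
  dl <- nondimensionalise(p, s)
  # each ratio computed independently, term by term
  expect_equal(dl$lt3, 3 * 0.05 / (2 * 2e-3))
  expect_equal(dl$lt8, 0.4 / 2e-3)
  expect_equal(dl$ltm9, 3 * 0.9 * 0.02 / 2e-3)
  expect_equal(dl$lhm9, 2 * 0.02 / 2e-3)
  expect_equal(dl$ltn9, 3 * 0.31 * 6e-2 / 2e-3)
  expect_equal(dl$Dtc, 5e-10 / (2e-3 * 1.5e-3^2))
  expect_equal(dl$fd, p$fd)
})

test_that("binding-consistency identity and round-trip hold for random positive sets", {
  set.seed(42)
  for (i in 1:20) {
    draw <- function() 10^stats::runif(1, -3, 2)
    p <- default_parameters(Lambda1 = draw(), lambda3 = draw(),
                            lambda4 = draw(), lambda5 = draw(),
                            lambda6 = draw(), lambda7 = draw(),
                            lambda8 = draw(), lambda_m9 = draw(),
                            lambda_n9 = draw(), lambda_m10 = draw(),
                            lambda_n10 = draw(), Ftot = draw(),
                            Gtot = draw(), Dc = draw(), Da = draw(),
                            fd = stats::runif(1, 0.001, 0.999))
    s <- default_scales(A0 = draw(), M0 = draw(), L = draw())
    dl <- nondimensionalise(p, s)
    expect_equal(dl$ltm9, dl$lhm9 * p$Ftot * s$M0 / s$A0,
                 tolerance = 1e-12)
    expect_equal(dl$ltn9, dl$lhn9 * p$Gtot * s$M0 / s$A0,
                 tolerance = 1e-12)
    # invert the scaling map field by field
    expect_equal(dl$lt3 * s$A0 * p$Lambda1 / s$M0, p$lambda3,
                 tolerance = 1e-12)
    expect_equal(dl$lt4 * p$Lambda1, p$lambda4, tolerance = 1e-12)
    expect_equal(dl$lt8 * p$Lambda1, p$lambda8, tolerance = 1e-12)
    expect_equal(dl$lhm9 * p$Lambda1 / s$A0, p$lambda_m9,
                 tolerance = 1e-12)
    expect_equal(dl$ltm10 * p$Lambda1, p$lambda_m10, tolerance = 1e-12)
    expect_equal(dl$Dtc * p$Lambda1 * s$L^2, p$Dc, tolerance = 1e-12)
  }
})

test_that("dimensionless time converts to hours on the differentiation timescale", {
  expect_equal(dimensional_time(0), 0)
  expect_equal(dimensional_time(1), 1 / 6e-3 / 60, tolerance = 1e-12)
  # ~28 h and ~25 h marks quoted for the combined-strategy runs
  expect_equal(dimensional_time(10), 27.8, tolerance = 0.005)
  expect_equal(dimensional_time(9.1), 25.3, tolerance = 0.005)
})

test_that("parameter and scale validation rejects non-positive or out-of-range values", {
  expect_error(default_parameters(lambda8 = 0), "positive")
  expect_error(default_parameters(Dc = -1), "positive")
  expect_error(default_parameters(fd = 1), "between 0 and 1")
  expect_error(default_scales(L = 0), "positive")
  expect_error(nondimensionalise(structure(list(), class = "chondro_params")))
})
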