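test_that("averageWindow takes the mean of the 10 surrounding delay columns", {
  wl <- seq(350, 520, 10)
  d <- seq(1e-6, 30e-6, by = 1e-6)
  const <- new("SpectralTimeSeries", wavelengths = wl, delays = d,
               deltaA = matrix(0.7, length(wl), length(d)),
               condition = "toy")
  expect_equal(unname(averageWindow(const, 1.5e-5)), rep(0.7, length(wl)))

  # ramp: deltaA(t_k) = k at a single wavelength; oracle = arithmetic mean
  # of the ten surrounding indices
  ramp <- new("SpectralTimeSeries", wavelengths = 400, delays = d,
              deltaA = matrix(seq_along(d), 1), condition = "toy")
  i <- which.min(abs(d - 1.2e-5))
  oracle <- mean(setdiff((i - 5):(i + 5), i))
  expect_equal(unname(averageWindow(ramp, 1.2e-5)), oracle)

  # edge: too few points on one side, error names the deficit
  expect_error(averageWindow(const, 2e-6), "1 point")

  # averaged value bounded by the extremes of the contributing points
  ts <- simulateTransientSpectra(flatScheme(tau = 1e-5),
                                 list(wavelengths = 400, delays = d),
                                 sigma = 0)
  i <- which.min(abs(d - 1.5e-5))
  win <- deltaA(ts)[1, setdiff((i - 5):(i + 5), i)]
  av <- unname(averageWindow(ts, 1.5e-5))
  expect_gte(av, min(win))
  expect_lte(av, max(win))
})

test_that("noiseless single-exponential data are recovered exactly", {
  ts <- simulateTransientSpectra(flatScheme(tau = 1e-6), smallGrid(50),
                                 sigma = 0)
  fit <- fitGlobal(ts, 1)
  expect_true(converged(fit))
  expect_lt(abs(taus(fit) - 1e-6) / 1e-6, 1e-6)
  expect_equal(unname(dasMatrix(fit)[, 1]),
               rep(1, length(wavelengths(ts))), tolerance = 1e-6)
})

test_that("two-component fit matches a brute-force grid-search oracle", {
  sch <- new("KineticScheme", taus = c(2e-6, 50e-6),
             bands = list(
               data.frame(center = 400, width = 30, amplitude = 1),
               data.frame(center = 470, width = 25, amplitude = -0.8)),
             condition = "toy")
  grid <- smallGrid(80, 2e-7, 5e-4)
  ts <- simulateTransientSpectra(sch, grid, sigma = 0)
  fit <- fitGlobal(ts, 2)

  # oracle: exhaustive 2-D grid at 1% spacing around the truth, linear
  # subproblem solved by QR through lm.fit (independent of varproParts)
  Y <- t(deltaA(ts))
  gridTau <- function(centre) centre * 1.01^(-30:30)
  best <- c(Inf, NA, NA)
  for (t1 in gridTau(2e-6)) for (t2 in gridTau(50e-6)) {
    E <- cbind(exp(-grid$delays / t1), exp(-grid$delays / t2))
    rss <- sum(stats::lm.fit(E, Y)$residuals^2)
    if (rss < best[1]) best <- c(rss, t1, t2)
  }
  expect_lt(abs(taus(fit)[1] - best[2]) / best[2], 0.01)
  expect_lt(abs(taus(fit)[2] - best[3]) / best[3], 0.01)
  expect_lte(chi2(fit), best[1] + 1e-20)
})

test_that("DAS at the optimum satisfy the linear normal equations", {
  ts <- h2oDataset(seed = 3)
  fit <- fitGlobal(ts, 3)
  E <- exp(outer(delays(ts), -1 / taus(fit)))
  lhs <- dasMatrix(fit) %*% crossprod(E)
  rhs <- deltaA(ts) %*% E
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("fitted taus are invariant under uniform rescaling of the data", {
  ts <- h2oDataset(seed = 4)
  f1 <- fitGlobal(ts, 3)
  ts2 <- new("SpectralTimeSeries", wavelengths = wavelengths(ts),
             delays = delays(ts), deltaA = deltaA(ts) * 137,
             condition = "toy")
  f2 <- fitGlobal(ts2, 3)
  expect_equal(taus(f2), taus(f1), tolerance = 1e-6)
})

test_that("adding a component never increases the optimal chi-square", {
  ts <- h2oDataset(seed = 5)
  f3 <- fitGlobal(ts, 3)
  f4 <- suppressWarnings(
    fitGlobal(ts, 4, initTaus = sort(c(taus(f3), 1e-4))))
  expect_lte(chi2(f4), chi2(f3) * (1 + 1e-9))
})

test_that("residual diagnostics separate white noise from model misfit", {
  ts <- h2oDataset(seed = 6)
  fit <- fitGlobal(ts, 3)
  dg <- residualDiagnostics(fit)
  n <- length(delays(ts))
  expect_lt(abs(mean(dg$lag1)), 3 / sqrt(n))

  # construct residuals equal to a pure exponential: strong structure
  bad <- fit
  bad@residuals <- matrix(rep(exp(-delays(ts) / 5e-5), each = 2),
                          nrow = 2, byrow = FALSE)
  bad@wavelengths <- c(400, 410)
  dgBad <- residualDiagnostics(bad)
  expect_true(all(abs(dgBad$lag1) > 0.5))

  zero <- fit
  zero@residuals <- matrix(0, 2, n)
  zero@wavelengths <- c(400, 410)
  dgZero <- residualDiagnostics(zero)
  expect_true(all(is.na(dgZero$lag1)))
  expect_true(all(dgZero$degenerate))
})

test_that("bootstrap degenerate cases and determinism behave as closed forms dictate", {
  ts <- h2oDataset(seed = 7, thin = 200)
  fit <- fitGlobal(ts, 3)
  b0 <- bootstrapFit(ts, fit, nReplicates = 5, shuffleFraction = 0,
                     seed = 1)
  expect_equal(unname(b0@sds), rep(0, 3))
  b1 <- bootstrapFit(ts, fit, nReplicates = 1, shuffleFraction = 0.25,
                     seed = 2)
  expect_equal(b1@means, b1@replicateTaus[1, ])
  bA <- bootstrapFit(ts, fit, nReplicates = 8, shuffleFraction = 0.25,
                     seed = 3)
  bB <- bootstrapFit(ts, fit, nReplicates = 8, shuffleFraction = 0.25,
                     seed = 3)
  expect_identical(bA@replicateTaus, bB@replicateTaus)
})

test_that("bootstrap spread weakly increases with the shuffle fraction", {
  ts <- h2oDataset(seed = 8, thin = 200)
  fit <- fitGlobal(ts, 3)
  sLow <- bootstrapFit(ts, fit, nReplicates = 40, shuffleFraction = 0.1,
                       seed = 4)@sds
  sHigh <- bootstrapFit(ts, fit, nReplicates = 40, shuffleFraction = 0.9,
                        seed = 4)@sds
  expect_gt(mean(sHigh / sLow), 1)
})

test_that("isotope ratios match the published kinetic isotope effect", {
  iso <- isotopeRatios(c(5.57, 36.1, 824.8) * 1e-6,
                       c(5.16, 88.4, 2041.1) * 1e-6)
  expect_equal(signif(ratios(iso), 3), c(0.926, 2.45, 2.47))
  expect_equal(ratios(isotopeRatios(c(1e-6, 1e-5), c(1e-6, 1e-5))),
               c(1, 1))
  expect_equal(ratios(isotopeRatios(1e-6, 2e-6)), 2)
  expect_error(isotopeRatios(c(1e-6, 1e-5), 1e-6), "component counts")
})
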