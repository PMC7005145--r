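# small matched reflection pair built directly from records
mkSet <- function(records, cell = c(20, 20, 20, 90, 90, 90), dmin = 2) {
  new("ReflectionSet", cell = cell, dmin = dmin, records = records)
}

test_that("q-weights hit their noiseless and no-signal limits", {
  xtl <- buildToyPair(seed = 1)$off
  rs <- structureFactors(xtl, dmin = 2.5)
  r <- reflections(rs)

  # all sigmas zero -> every weight 1
  on <- mkSet(transform(r, amp = amp * 1.1, phase = NA), dmin = 2.5)
  off <- mkSet(transform(r, phase = NA), dmin = 2.5)
  q0 <- qWeights(on, off)
  expect_true(all(qValues(q0) == 1))
  expect_equal(qMean(q0), 1)

  # pure noise: differences far below sigma in every bin -> floored weights
  set.seed(42)
  noise <- 1e-3 * stats::rnorm(nrow(r))
  onN <- mkSet(transform(r, amp = amp + noise, sigma = 1, phase = NA),
               dmin = 2.5)
  offN <- mkSet(transform(r, sigma = 1, phase = NA), dmin = 2.5)
  qN <- qWeights(onN, offN)
  expect_true(all(qValues(qN) == 0.01))

  expect_error(qWeights(mkSet(transform(r, sigma = NA)), off),
               "sigma")
})

test_that("q-weights match a hand-computed shrinkage ratio on two bins", {
  # two resolution shells with known moments, constructed by hand
  rec <- data.frame(h = c(1, 0, 0, 8, 0, 7),
                    k = c(0, 1, 0, 0, 8, 0),
                    l = c(0, 0, 1, 0, 0, 4),
                    amp = c(10, 12, 11, 5, 6, 4),
                    sigma = c(1, 1, 1, 2, 2, 2),
                    phase = NA)
  on <- mkSet(transform(rec, amp = amp + c(4, -5, 3, 1, -1, 0.5)))
  off <- mkSet(rec)
  qs <- qWeights(on, off, nBins = 2)
  dF <- c(4, -5, 3); s2 <- 2          # low-resolution bin
  vs <- mean(dF^2) - s2
  expect_equal(qValues(qs)[1:3], rep(vs / (vs + s2), 3), tolerance = 1e-12)
  dF2 <- c(1, -1, 0.5); s22 <- 8      # high-resolution bin
  vs2 <- max(0, mean(dF2^2) - s22)    # no signal -> floored
  expect_equal(qValues(qs)[4:6], rep(0.01, 3))
  expect_equal(qMean(qs), mean(qValues(qs)))
})

test_that("q-weights decrease monotonically with per-reflection sigma", {
  # one bin, fixed moments; vary a single reflection's sigma
  base <- data.frame(h = 1:6, k = 0, l = 0,
                     amp = c(10, 12, 11, 9, 10, 11),
                     sigma = c(1, 1, 1, 1, 1, 3), phase = NA)
  on <- mkSet(transform(base, amp = amp + c(4, -5, 3, 4, -4, 3)))
  qs <- qWeights(on, mkSet(base), nBins = 1)
  expect_lt(qValues(qs)[6], min(qValues(qs)[1:5]))
})

test_that("identical on/off amplitudes give an identically zero map", {
  xtl <- buildToyPair(seed = 3)$off
  rs <- structureFactors(xtl, dmin = 2.5)
  m <- differenceMap(rs, rs, phases = rs, weights = NULL)
  expect_true(all(mapValues(m) == 0))
  expect_equal(mapRms(m), 0)
})

test_that("difference density localizes at the displaced atom", {
  pair <- buildToyPair(seed = 7, nAtoms = 6, nDisplaced = 2)
  # single-atom displacement: move exactly one atom for a clean signature
  atInt <- atoms(pair$off)
  moved <- pair$displaced[1]
  atInt[moved, c("x", "y", "z")] <-
    atoms(pair$intermediate)[moved, c("x", "y", "z")]
  inter <- new("ToyCrystal", cell = cellParams(pair$off), atoms = atInt)
  fOff <- structureFactors(pair$off, dmin = 1.5)
  fInt <- structureFactors(inter, dmin = 1.5)
  m <- differenceMap(fInt, fOff, phases = fOff, weights = NULL)
  v <- mapValues(m)
  g <- dim(v)
  toFrac <- function(idx) (idx - 1) / g
  iMax <- toFrac(which(v == max(v), arr.ind = TRUE)[1, ])
  iMin <- toFrac(which(v == min(v), arr.ind = TRUE)[1, ])
  cell <- cellParams(pair$off)
  posOff <- unlist(atoms(pair$off)[moved, c("x", "y", "z")])
  posInt <- unlist(atInt[moved, c("x", "y", "z")])
  expect_lt(fracDist(cell, iMin, posOff), 1.5)
  expect_lt(fracDist(cell, iMax, posInt), 1.5)
})

test_that("FFT synthesis equals direct summation", {
  pair <- buildToyPair(seed = 4)
  on <- structureFactors(pair$intermediate, dmin = 2.5)
  off <- structureFactors(pair$off, dmin = 2.5)
  m <- differenceMap(on, off, phases = off, weights = NULL)
  r <- reflections(off)
  coeff <- (reflections(on)$amp - r$amp) *
    exp(1i * r$phase * pi / 180)
  ref <- directSumMap(cellParams(pair$off),
                      as.matrix(r[, c("h", "k", "l")]), coeff,
                      dim(mapValues(m)))
  ref <- ref / sqrt(mean(ref^2))
  expect_lt(max(abs(mapValues(m) - ref)) / max(abs(ref)), 1e-8)
})

test_that("peak integration matches a brute-force voxel loop", {
  cell <- c(20, 20, 20, 90, 90, 90)
  g <- c(24, 24, 24)
  # synthetic 5-sigma Gaussian blob at a site
  fr <- as.matrix(expand.grid(x = (0:23) / 24, y = (0:23) / 24,
                              z = (0:23) / 24))
  site <- c(0.4, 0.5, 0.6)
  d2 <- rowSums((20 * (fr - matrix(site, nrow(fr), 3, byrow = TRUE)))^2)
  v <- 5 * exp(-d2 / (2 * 1.2^2))
  v <- v / sqrt(mean(v^2)) * 5 / max(v / sqrt(mean(v^2)))  # peak at 5 sigma
  m <- new("DensityMap", cell = cell, values = array(v, g),
           rms = sqrt(mean(v^2)))

  got <- integratePeaks(m, site, radius = 3, threshold = 3)
  # voxel loop oracle
  acc <- 0
  for (i in seq_len(nrow(fr))) {
    d <- fr[i, ] - site
    d <- d - round(d)
    if (sum((20 * d)^2) <= 9 && abs(v[i]) >= 3) acc <- acc + abs(v[i])
  }
  expect_equal(got, acc, tolerance = 1e-12)
  expect_gt(got, 0)

  expect_equal(integratePeaks(m, site, radius = 3, threshold = 99), 0)
  zero <- new("DensityMap", cell = cell, values = array(0, g), rms = 0)
  expect_equal(integratePeaks(zero, site, radius = 3), 0)
})
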