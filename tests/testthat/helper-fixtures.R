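# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately avoid the package's own
# computational path.

# one-component scheme with a flat unit DAS (width huge => amplitude ~ 1
# across the band)
flatScheme <- function(tau = 1e-6, amplitude = 1) {
  # infinite width: the band is exactly `amplitude` at every wavelength
  new("KineticScheme", taus = tau,
      bands = list(data.frame(center = 435, width = Inf,
                              amplitude = amplitude)),
      condition = "toy")
}

smallGrid <- function(nDelays = 60, tmin = 1e-7, tmax = 1e-5,
                      wavelengths = seq(350, 520, by = 10)) {
  list(wavelengths = wavelengths,
       delays = exp(seq(log(tmin), log(tmax), length.out = nDelays)))
}

# direct evaluation of the multi-exponential model, independent of
# simulateTransientSpectra's internals
directModel <- function(das, taus, wavelengths, delays) {
  m <- matrix(0, length(wavelengths), length(delays))
  for (i in seq_along(taus))
    m <- m + outer(das[, i], exp(-delays / taus[i]))
  m
}

# brute-force direct Fourier summation over the whole grid:
# rho(x) = (1/V) sum_h [c_h exp(-2 pi i h.x) + conj(c_h) exp(2 pi i h.x)]
directSumMap <- function(cell, hkl, coeff, grid) {
  vol <- prod(cell[1:3])  # orthogonal test cells only
  fr <- as.matrix(expand.grid(x = (seq_len(grid[1]) - 1) / grid[1],
                              y = (seq_len(grid[2]) - 1) / grid[2],
                              z = (seq_len(grid[3]) - 1) / grid[3]))
  ph <- fr %*% t(hkl)                      # npoints x nrefl
  rho <- as.vector(2 * (cos(2 * pi * ph) %*% Re(coeff) +
                        sin(2 * pi * ph) %*% Im(coeff))) / vol
  array(rho, dim = grid)
}

# hand-rolled complex structure-factor sum for an orthogonal cell,
# written against the formula rather than the package routine
oracleComplexF <- function(xtl, hkl) {
  cell <- cellParams(xtl)
  at <- atoms(xtl)
  vapply(seq_len(nrow(hkl)), function(r) {
    s2 <- sum((hkl[r, ] / cell[1:3])^2)
    f <- 0 + 0i
    for (j in seq_len(nrow(at))) {
      fj <- formFactor(at$element[j], sqrt(s2))
      arg <- 2 * pi * sum(hkl[r, ] * unlist(at[j, c("x", "y", "z")]))
      f <- f + at$occ[j] * fj * exp(-at$b[j] * s2 / 4) *
        complex(modulus = 1, argument = arg)
    }
    f
  }, complex(1))
}

# cartesian minimum-image distance between fractional positions in an
# orthogonal cell
fracDist <- function(cell, a, b) {
  d <- a - b
  d <- d - round(d)
  sqrt(sum((d * cell[1:3])^2))
}

# standard noisy H2O-condition dataset used across kinetics tests
h2oDataset <- function(seed, sigma = 0.01, thin = 100) {
  grid <- defaultAcquisitionGrid(thin = thin)
  simulateTransientSpectra(buildReferenceScheme("H2O"), grid,
                           sigma = sigma, seed = seed)
}
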