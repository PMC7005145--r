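#' @include AllClasses.R
NULL

# Fixed Gaussian-band compositions for the three decay-associated spectra of
# the reference photoswitching scheme. The published DAS are not tabulated,
# so these shapes are a versioned package choice reproducing the qualitative
# band structure: component 1 grows the 460-nm band while the 390-nm band
# decays; component 2 carries the 460 -> 480 nm band shift and the negative
# band near 410-420 nm; component 3 carries the final 390-nm decay and
# 480-nm growth. Growth of a band appears as a negative DAS amplitude since
# each component relaxes as exp(-t/tau) toward zero.
referenceBands <- function() {
  list(
    data.frame(center = c(390, 460), width = c(18, 22),
               amplitude = c(0.50, -0.45)),
    data.frame(center = c(390, 460, 480, 415),
               width = c(18, 20, 20, 18),
               amplitude = c(0.30, 0.25, -0.30, -0.15)),
    data.frame(center = c(390, 480, 412), width = c(18, 20, 14),
               amplitude = c(0.40, -0.45, -0.35))
  )
}

referenceTaus <- list(
  H2O              = c(5.57, 36.1, 824.8) * 1e-6,
  D2O              = c(5.16, 88.4, 2041.1) * 1e-6,
  microcrystal     = c(4.75, 42.9, 295) * 1e-6,
  ammonium_sulfate = c(4.23, 40.4, 245.2) * 1e-6
)

#' Reference three-exponential photoswitching scheme
#'
#' Returns the ground-truth [KineticScheme-class] for one of the measured
#' conditions of the off-to-on photoswitching photocycle: protein in H2O or
#' D2O buffer, microcrystal suspension, or H2O buffer with 1.25 M ammonium
#' sulfate. Time constants are the published condition-specific values; the
#' DAS shapes are fixed Gaussian-band compositions reproducing the
#' qualitative band structure (growth at 460 then 480 nm, decay at 390 nm,
#' a negative band near 400-420 nm).
#'
#' @param condition one of "H2O", "D2O", "microcrystal", "ammonium_sulfate"
#' @return a [KineticScheme-class] with three components (taus in seconds)
#' @examples
#' taus(buildReferenceScheme("H2O")) * 1e6   # 5.57 36.1 824.8
#' @export
buildReferenceScheme <- function(condition = c("H2O", "D2O", "microcrystal",
                                               "ammonium_sulfate")) {
  condition <- match.arg(condition)
  new("KineticScheme", taus = referenceTaus[[condition]],
      bands = referenceBands(), condition = condition)
}

#' Evaluate the decay-associated spectra of a scheme
#'
#' @param object a [KineticScheme-class]
#' @param wavelengths numeric vector, nm
#' @return matrix \code{length(wavelengths) x n_components}
#' @rdname accessors
#' @export
setMethod("dasMatrix", "KineticScheme", function(object, wavelengths, ...) {
  cols <- vapply(object@bands, function(b) {
    out <- numeric(length(wavelengths))
    for (i in seq_len(nrow(b)))
      out <- out + b$amplitude[i] *
        exp(-(wavelengths - b$center[i])^2 / (2 * b$width[i]^2))
    out
  }, numeric(length(wavelengths)))
  matrix(cols, nrow = length(wavelengths))
})

#' Acquisition grid of a nanosecond flash-photolysis experiment
#'
#' Builds the wavelength/delay grids of the transient-absorption
#' measurement: wavelengths in 10-nm steps over 350-520 nm and three
#' concatenated delay windows, 10 ns to 5 us at 500 ps/point, 5 us to
#' 100 us at 10 ns/point, and 100 us to 10 ms at 1 us/point. \code{thin}
#' keeps every thin-th delay point per window (window endpoints retained),
#' which preserves the three-window structure at a reduced problem size.
#'
#' @param wavelengths numeric, nm
#' @param windows list of \code{c(t_start, t_end, step)} triples (seconds);
#'   windows must be non-overlapping and in increasing order
#' @param thin positive integer subsampling factor
#' @return list with elements \code{wavelengths}, \code{delays} (strictly
#'   increasing, duplicates at window joins removed), \code{windows}
#' @export
defaultAcquisitionGrid <- function(wavelengths = seq(350, 520, by = 10),
                                   windows = list(c(10e-9, 5e-6, 500e-12),
                                                  c(5e-6, 100e-6, 10e-9),
                                                  c(100e-6, 10e-3, 1e-6)),
                                   thin = 1L) {
  stopifnot(thin >= 1)
  delays <- unlist(lapply(windows, function(w) {
    if (w[3] <= 0) stop("window step must be positive")
    d <- seq(w[1], w[2], by = w[3])
    if (thin > 1L) d <- unique(c(d[seq(1L, length(d), by = as.integer(thin))],
                                 d[length(d)]))
    d
  }))
  delays <- sort(unique(delays))
  if (length(delays) > 1 && any(diff(delays) <= 0))
    stop("delays must be strictly increasing")
  list(wavelengths = wavelengths, delays = delays, windows = windows)
}

#' Simulate a transient-absorption matrix from a kinetic scheme
#'
#' Evaluates \eqn{\Delta A(\lambda,t) = \sum_i DAS_i(\lambda) e^{-t/\tau_i}
#' + \epsilon} with additive Gaussian noise of standard deviation
#' \code{sigma}, reproducibly under \code{seed}. Optionally adds the static
#' spectrum of a residual fraction of molecules left in the on-state before
#' pumping (a bleach-like offset that does not decay), disabled by default.
#'
#' @param scheme a [KineticScheme-class]
#' @param grid list from [defaultAcquisitionGrid()] (or with elements
#'   \code{wavelengths}, \code{delays})
#' @param sigma additive noise sd in delta-A units (>= 0)
#' @param seed integer seed for the noise draw
#' @param residualOnFraction fraction of molecules contributing a static
#'   on-state offset (default 0, i.e. disabled); the offset spectrum is a
#'   negative 480-nm band scaled by this fraction
#' @return a [SpectralTimeSeries-class]
#' @export
simulateTransientSpectra <- function(scheme, grid, sigma = 0.01,
                                     seed = 1L, residualOnFraction = 0) {
  stopifnot(is(scheme, "KineticScheme"), sigma >= 0)
  if (length(grid$delays) == 0 || length(grid$wavelengths) == 0)
    stop("empty acquisition grid")
  if (any(grid$delays <= 0)) stop("grid delays must be positive")
  das <- dasMatrix(scheme, grid$wavelengths)          # n_wl x k
  decay <- exp(outer(grid$delays, -1 / scheme@taus))  # n_t x k
  m <- das %*% t(decay)
  if (residualOnFraction > 0) {
    offset <- -residualOnFraction *
      exp(-(grid$wavelengths - 480)^2 / (2 * 20^2))
    m <- m + offset   # recycled down columns: one offset per wavelength
  }
  if (sigma > 0) {
    set.seed(as.integer(seed))
    m <- m + matrix(stats::rnorm(length(m), sd = sigma), nrow = nrow(m))
  }
  new("SpectralTimeSeries", wavelengths = grid$wavelengths,
      delays = grid$delays, deltaA = m, condition = scheme@condition)
}
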