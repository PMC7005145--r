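#' KineticScheme: a multi-exponential difference-spectrum kinetic model
#'
#' Ground-truth description of photocycle kinetics as observed by transient
#' absorption: a set of time constants (seconds) and, for each, a
#' decay-associated spectrum (DAS) expressed as a signed sum of Gaussian
#' bands over wavelength. The model for the difference absorbance is
#' \deqn{\Delta A(\lambda, t) = \sum_i DAS_i(\lambda) e^{-t/\tau_i}.}
#'
#' @slot taus numeric, time constants in seconds, strictly positive and
#'   strictly increasing
#' @slot bands list with one data.frame per component, columns
#'   \code{center} (nm), \code{width} (nm, Gaussian sd), \code{amplitude}
#'   (delta-A units); each DAS is the sum of its rows
#' @slot condition character label (e.g. "H2O", "D2O")
#'
#' @seealso [buildReferenceScheme()], [simulateTransientSpectra()]
#' @export
setClass("KineticScheme",
  representation(taus = "numeric", bands = "list", condition = "character"))

setValidity("KineticScheme", function(object) {
  msg <- character()
  n <- length(object@taus)
  if (n < 1) msg <- c(msg, "at least one component required")
  if (any(object@taus <= 0)) msg <- c(msg, "taus must be strictly positive")
  if (n > 1 && any(diff(object@taus) <= 0))
    msg <- c(msg, "taus must be strictly increasing")
  if (length(object@bands) != n)
    msg <- c(msg, "bands must have exactly one entry per component")
  for (b in object@bands) {
    if (!is.data.frame(b) ||
        !all(c("center", "width", "amplitude") %in% names(b)))
      msg <- c(msg, "each bands entry needs center/width/amplitude columns")
  }
  if (length(msg)) msg else TRUE
})

#' SpectralTimeSeries: a transient-absorption data matrix
#'
#' Difference absorbance \eqn{\Delta A} on a wavelength-by-delay grid, the
#' central data object of the global lifetime analysis.
#'
#' @slot wavelengths numeric, nm
#' @slot delays numeric, seconds, strictly increasing
#' @slot deltaA matrix, \code{n_wavelengths x n_delays}, delta-A units
#' @slot condition character label
#'
#' @seealso [fitGlobal()], [averageWindow()], [readSpectraTSV()]
#' @export
setClass("SpectralTimeSeries",
  representation(wavelengths = "numeric", delays = "numeric",
                 deltaA = "matrix", condition = "character"))

setValidity("SpectralTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@deltaA) != length(object@wavelengths))
    msg <- c(msg, "deltaA rows must match wavelengths")
  if (ncol(object@deltaA) != length(object@delays))
    msg <- c(msg, "deltaA columns must match delays")
  if (length(object@delays) > 1 && any(diff(object@delays) <= 0))
    msg <- c(msg, "delays must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' GlobalFitResult: outcome of a global multi-exponential fit
#'
#' Shared time constants, per-wavelength DAS amplitudes, the residual
#' matrix and convergence diagnostics returned by [fitGlobal()].
#'
#' @slot taus numeric, fitted time constants (s), ascending
#' @slot tauStderr numeric, curvature-matrix standard errors (s)
#' @slot das matrix, \code{n_wavelengths x n_components} DAS amplitudes
#' @slot residuals matrix, data minus reconstruction
#' @slot chi2 numeric, sum of squared residuals
#' @slot converged logical
#' @slot nIterations integer
#' @slot wavelengths,delays numeric grids of the fitted data
#' @slot degenerate logical, TRUE when two optimal taus differ by < 5\%
#' @slot message character, minimizer status message
#' @export
setClass("GlobalFitResult",
  representation(taus = "numeric", tauStderr = "numeric", das = "matrix",
                 residuals = "matrix", chi2 = "numeric",
                 converged = "logical", nIterations = "integer",
                 wavelengths = "numeric", delays = "numeric",
                 degenerate = "logical", message = "character"))

setValidity("GlobalFitResult", function(object) {
  msg <- character()
  if (any(object@taus <= 0)) msg <- c(msg, "taus must be positive")
  if (is.unsorted(object@taus)) msg <- c(msg, "taus must be sorted ascending")
  if (ncol(object@das) != length(object@taus))
    msg <- c(msg, "das column count must equal component count")
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BootstrapResult: residual-shuffling bootstrap of a global fit
#'
#' Distribution of refitted time constants over replicate datasets built by
#' adding partially shuffled residuals back onto the best-fit
#' reconstruction; see [bootstrapFit()].
#'
#' @slot replicateTaus matrix, \code{n_replicates x n_components} (s);
#'   failed replicates are excluded
#' @slot means,sds numeric per-component summaries (s)
#' @slot shuffleFraction numeric in [0, 1]
#' @slot nReplicates integer, replicates requested
#' @slot nFailed integer, replicates that did not converge (excluded)
#' @slot seed integer
#' @export
setClass("BootstrapResult",
  representation(replicateTaus = "matrix", means = "numeric", sds = "numeric",
                 shuffleFraction = "numeric", nReplicates = "integer",
                 nFailed = "integer", seed = "integer"))

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (isTRUE(any(object@sds < 0)))
    msg <- c(msg, "sds must be non-negative")
  ok <- object@means >= apply(object@replicateTaus, 2, min) - 1e-12 &
        object@means <= apply(object@replicateTaus, 2, max) + 1e-12
  if (!all(ok)) msg <- c(msg, "means must lie within replicate span")
  if (length(msg)) msg else TRUE
})

#' IsotopeComparison: kinetic isotope effect from matched global fits
#'
#' Per-component ratios \eqn{\tau_D/\tau_H = k_H/k_D}, components matched
#' by ascending-tau rank; see [isotopeRatios()].
#'
#' @slot ratios numeric, dimensionless, one per matched component
#' @slot tausH,tausD numeric, the matched time constants (s)
#' @export
setClass("IsotopeComparison",
  representation(ratios = "numeric", tausH = "numeric", tausD = "numeric"))

setValidity("IsotopeComparison", function(object) {
  msg <- character()
  if (any(object@ratios <= 0)) msg <- c(msg, "ratios must be positive")
  if (length(object@ratios) != length(object@tausH) ||
      length(object@ratios) != length(object@tausD))
    msg <- c(msg, "one ratio per matched component required")
  if (length(msg)) msg else TRUE
})

#' ToyCrystal: a minimal P1 atomic model
#'
#' A handful of atoms in a triclinic P1 cell, enough to exercise structure
#' factors, difference maps and occupancy estimation with a direct-sum
#' oracle in reach.
#'
#' @slot cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @slot atoms data.frame with columns \code{element} (C/N/O/S),
#'   \code{x,y,z} (fractional, wrapped to [0,1)), \code{b} (isotropic B,
#'   Angstrom^2), \code{occ} (occupancy in [0,1])
#' @seealso [buildToyPair()], [structureFactors()], [writeToyPDB()]
#' @export
setClass("ToyCrystal",
  representation(cell = "numeric", atoms = "data.frame"))

setValidity("ToyCrystal", function(object) {
  msg <- character()
  if (length(object@cell) != 6 || any(object@cell[1:3] <= 0))
    msg <- c(msg, "cell must be 6 parameters with positive lengths")
  a <- object@atoms
  need <- c("element", "x", "y", "z", "b", "occ")
  if (!all(need %in% names(a))) {
    msg <- c(msg, "atoms needs element/x/y/z/b/occ columns")
  } else {
    fr <- as.matrix(a[, c("x", "y", "z")])
    if (nrow(a) && (any(fr < 0) || any(fr >= 1)))
      msg <- c(msg, "fractional coordinates must be wrapped to [0,1)")
    if (nrow(a) && (any(a$occ < 0) || any(a$occ > 1)))
      msg <- c(msg, "occupancies must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' ReflectionSet: indexed structure-factor records
#'
#' One hemisphere of unique reflections (Friedel mate implied) with
#' amplitudes, sigmas and optional phases, over a P1 cell and resolution
#' cutoff.
#'
#' @slot cell numeric(6) unit-cell parameters
#' @slot dmin numeric, high-resolution cutoff (Angstrom)
#' @slot records data.frame with columns \code{h,k,l} (integer),
#'   \code{amp} (>= 0), \code{sigma} (>= 0 or NA), \code{phase}
#'   (degrees or NA)
#' @seealso [structureFactors()], [readReflectionTSV()]
#' @export
setClass("ReflectionSet",
  representation(cell = "numeric", dmin = "numeric", records = "data.frame"))

setValidity("ReflectionSet", function(object) {
  msg <- character()
  r <- object@records
  need <- c("h", "k", "l", "amp", "sigma", "phase")
  if (!all(need %in% names(r))) {
    msg <- c(msg, "records needs h/k/l/amp/sigma/phase columns")
  } else {
    if (anyDuplicated(r[, c("h", "k", "l")]))
      msg <- c(msg, "hkl indices must be unique")
    if (nrow(r) && any(r$amp < 0)) msg <- c(msg, "amplitudes must be >= 0")
  }
  if (length(object@cell) != 6) msg <- c(msg, "cell must have 6 parameters")
  if (object@dmin <= 0) msg <- c(msg, "dmin must be positive")
  if (length(msg)) msg else TRUE
})

#' QWeightSet: Bayesian difference-amplitude weights
#'
#' Per-reflection shrinkage weights in (0, 1] applied to difference
#' structure-factor amplitudes before Fourier synthesis, plus their mean;
#' see [qWeights()].
#'
#' @slot q numeric, one weight per reflection, in (0, 1]
#' @slot qMean numeric, arithmetic mean of \code{q}
#' @export
setClass("QWeightSet", representation(q = "numeric", qMean = "numeric"))

setValidity("QWeightSet", function(object) {
  msg <- character()
  if (any(object@q <= 0) || any(object@q > 1))
    msg <- c(msg, "weights must lie in (0,1]")
  if (length(object@q) &&
      abs(object@qMean - mean(object@q)) > 1e-9 * max(1, object@qMean))
    msg <- c(msg, "qMean must be the arithmetic mean of q")
  if (length(msg)) msg else TRUE
})

#' DensityMap: a real-space difference electron-density grid
#'
#' Map values on a fractional-coordinate grid over the whole P1 cell,
#' stored in sigma units (grid rms = 1 unless the map is identically
#' zero). The pre-normalisation rms is kept in \code{rms}.
#'
#' @slot cell numeric(6) unit-cell parameters
#' @slot values 3-D array, dimensions = grid divisions along a, b, c
#' @slot rms numeric, rms of the raw synthesis (defines the sigma unit)
#' @seealso [differenceMap()], [integratePeaks()]
#' @export
setClass("DensityMap",
  representation(cell = "numeric", values = "array", rms = "numeric"))

setValidity("DensityMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3-D array")
  if (object@rms < 0) msg <- c(msg, "rms must be non-negative")
  if (object@rms == 0 && any(object@values != 0))
    msg <- c(msg, "rms may be zero only for an identically zero map")
  if (length(msg)) msg else TRUE
})

#' AlphaScanResult: occupancy estimate from the extrapolation-factor scan
#'
#' Ratio of integrated peaks in the extrapolated-minus-calculated map to
#' those in the observed q-weighted difference map, as a function of the
#' extrapolation factor alpha; the argmax alpha* gives occupancy 1/alpha*.
#'
#' @slot alphas numeric, ascending grid of extrapolation factors (>= 1)
#' @slot ratios numeric, peak-integral ratio per alpha
#' @slot alphaStar numeric, argmax alpha (ties broken toward smaller alpha)
#' @slot occupancy numeric, 1/alphaStar
#' @slot clampCounts integer, negative-amplitude clamps per alpha
#' @slot flagged logical, TRUE when the ratio curve is essentially flat
#'   (max/min < 1.01) and the estimate is indeterminate
#' @seealso [alphaScan()]
#' @export
setClass("AlphaScanResult",
  representation(alphas = "numeric", ratios = "numeric",
                 alphaStar = "numeric", occupancy = "numeric",
                 clampCounts = "integer", flagged = "logical"))

setValidity("AlphaScanResult", function(object) {
  msg <- character()
  if (!object@alphaStar %in% object@alphas)
    msg <- c(msg, "alphaStar must belong to the alpha grid")
  if (object@occupancy <= 0 || object@occupancy > 1)
    msg <- c(msg, "occupancy must lie in (0,1]")
  if (any(!is.finite(object@ratios)))
    msg <- c(msg, "ratios must be finite")
  if (length(msg)) msg else TRUE
})
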