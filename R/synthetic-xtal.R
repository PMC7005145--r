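#' @include AllClasses.R structure-factors.R
NULL

wrapFrac <- function(x) x - floor(x)

#' Toy off/intermediate model pair
#'
#' Builds two P1 atomic models in the same 20 x 20 x 20 Angstrom cell that
#' mimic a chromophore isomerisation: a subset of atoms is displaced by
#' 1-2 Angstrom between the resting (off) and photo-intermediate states,
#' the remainder identical. The models are small enough that a direct-sum
#' density oracle is affordable, yet give non-trivial difference maps.
#'
#' In addition to the ground-truth pair, a \code{refined} replica of the
#' off model is returned: every atom jittered by a coordinate error of
#' \code{modelError} Angstrom (rms), emulating the finite accuracy of a
#' refined crystallographic model. Difference-map phases and calculated
#' amplitudes in a real experiment come from such a model, never from the
#' true structure, and the alpha-scan's ratio curve takes its rising
#' branch from exactly this model-error background.
#'
#' @param seed integer; the construction is bit-reproducible under it
#' @param nAtoms total atom count (default 10, drawn from C/N/O)
#' @param nDisplaced number of displaced atoms (default 2, >= 2); kept
#'   small so the conformational change stays a modest perturbation of
#'   the total scattering, the regime in which amplitude-space
#'   extrapolation is valid
#' @param modelError rms coordinate error of the refined replica,
#'   Angstrom (default 0.15, typical of refinement at ~1.5-1.6 Angstrom
#'   resolution; 0 gives an exact model)
#' @return list with elements \code{off}, \code{intermediate} and
#'   \code{refined} ([ToyCrystal-class]) and \code{displaced}, the
#'   indices of the moved atoms
#' @export
buildToyPair <- function(seed = 0L, nAtoms = 10L, nDisplaced = 2L,
                         modelError = 0.15) {
  stopifnot(nAtoms >= nDisplaced, nDisplaced >= 2L)
  set.seed(as.integer(seed))
  cell <- c(20, 20, 20, 90, 90, 90)
  elements <- sample(c("C", "N", "O"), nAtoms, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
  # keep atoms in a central pocket so displaced copies stay well separated
  # from periodic images
  xyz <- matrix(stats::runif(3 * nAtoms, 0.25, 0.75), ncol = 3)
  bfac <- stats::runif(nAtoms, 8, 15)
  off <- new("ToyCrystal", cell = cell,
             atoms = data.frame(element = elements,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                b = bfac, occ = 1))
  idx <- sample.int(nAtoms, nDisplaced)
  shift <- matrix(stats::rnorm(3 * nDisplaced), ncol = 3)
  shift <- shift / sqrt(rowSums(shift^2)) *
    stats::runif(nDisplaced, 1, 2)          # Angstrom, magnitude in [1,2]
  atInt <- off@atoms
  atInt[idx, c("x", "y", "z")] <-
    wrapFrac(as.matrix(atInt[idx, c("x", "y", "z")]) +
             shift / matrix(cell[1:3], nDisplaced, 3, byrow = TRUE))
  atRef <- off@atoms
  if (modelError > 0) {
    jit <- matrix(stats::rnorm(3 * nAtoms, sd = modelError / sqrt(3)),
                  ncol = 3)
    atRef[, c("x", "y", "z")] <-
      wrapFrac(as.matrix(atRef[, c("x", "y", "z")]) +
               jit / matrix(cell[1:3], nAtoms, 3, byrow = TRUE))
  }
  list(off = off,
       intermediate = new("ToyCrystal", cell = cell, atoms = atInt),
       refined = new("ToyCrystal", cell = cell, atoms = atRef),
       displaced = sort(idx))
}

#' Simulate a laser_off / laser_on observed amplitude pair
#'
#' Emulates the interleaved pump-probe diffraction measurement: the
#' laser_off crystal is pure resting state, while in the laser_on crystal a
#' fraction of the molecules has switched to the intermediate conformation.
#' Mixing happens in complex structure-factor space before taking moduli,
#' \deqn{F_{on}(h) = |(1-f)\,F_{off}(h) + f\,F_{int}(h)|,} then both
#' amplitude sets receive multiplicative Gaussian noise
#' \code{(1 + eta), eta ~ N(0, noiseFrac)} and per-reflection sigmas
#' \code{noiseFrac * amplitude}, mirroring counting-statistics scaling.
#'
#' @param off,intermediate [ToyCrystal-class] models in the same cell
#' @param fraction real in [0, 1], occupancy of the intermediate state in
#'   the laser_on data
#' @param dmin resolution cutoff, Angstrom
#' @param noiseFrac fractional amplitude noise (>= 0)
#' @param seed integer seed
#' @return list with [ReflectionSet-class] elements \code{laser_off} and
#'   \code{laser_on} (amplitudes and sigmas, no phases)
#' @export
simulateObservedPair <- function(off, intermediate, fraction, dmin = 1.5,
                                 noiseFrac = 0.02, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0,1]")
  stopifnot(dmin > 0, noiseFrac >= 0)
  if (!isTRUE(all.equal(off@cell, intermediate@cell)))
    stop("off and intermediate models must share a unit cell")
  hkl <- hemisphereHKL(off@cell, dmin)
  fOff <- complexStructureFactors(off, hkl)
  fInt <- complexStructureFactors(intermediate, hkl)
  fOn <- (1 - fraction) * fOff + fraction * fInt
  ampOff <- Mod(fOff)
  ampOn <- Mod(fOn)
  if (noiseFrac > 0) {
    set.seed(as.integer(seed))
    ampOff <- ampOff * (1 + stats::rnorm(length(ampOff), sd = noiseFrac))
    ampOn <- ampOn * (1 + stats::rnorm(length(ampOn), sd = noiseFrac))
    ampOff <- pmax(ampOff, 0)
    ampOn <- pmax(ampOn, 0)
  }
  mkSet <- function(amp) {
    new("ReflectionSet", cell = off@cell, dmin = dmin,
        records = data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                             amp = amp, sigma = noiseFrac * amp,
                             phase = NA_real_))
  }
  list(laser_off = mkSet(ampOff), laser_on = mkSet(ampOn))
}
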