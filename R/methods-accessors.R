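#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("taus", "KineticScheme", function(object, ...) object@taus)

#' @rdname accessors
#' @export
setMethod("taus", "GlobalFitResult", function(object, ...) object@taus)

#' @rdname accessors
#' @export
setMethod("taus", "BootstrapResult", function(object, ...) object@replicateTaus)

#' @rdname accessors
#' @export
setMethod("tauStderr", "GlobalFitResult", function(object, ...) object@tauStderr)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralTimeSeries",
          function(object, ...) object@wavelengths)

#' @rdname accessors
#' @export
setMethod("delays", "SpectralTimeSeries", function(object, ...) object@delays)

#' @rdname accessors
#' @export
setMethod("deltaA", "SpectralTimeSeries", function(object, ...) object@deltaA)

#' @rdname accessors
#' @export
setMethod("chi2", "GlobalFitResult", function(object, ...) object@chi2)

#' @rdname accessors
#' @export
setMethod("converged", "GlobalFitResult", function(object, ...) object@converged)

#' Residual matrix of a global fit
#'
#' @param object a [GlobalFitResult-class]
#' @return matrix of data minus reconstruction, wavelengths by delays
#' @export
setMethod("residuals", "GlobalFitResult", function(object, ...) object@residuals)

#' DAS of a fit: the per-wavelength amplitude attached to each component
#'
#' @rdname accessors
#' @export
setMethod("dasMatrix", "GlobalFitResult", function(object, ...) object@das)

#' @rdname accessors
#' @export
setMethod("reflections", "ReflectionSet", function(object, ...) object@records)

#' @rdname accessors
#' @export
setMethod("cellParams", "ReflectionSet", function(object, ...) object@cell)

#' @rdname accessors
#' @export
setMethod("cellParams", "ToyCrystal", function(object, ...) object@cell)

#' @rdname accessors
#' @export
setMethod("cellParams", "DensityMap", function(object, ...) object@cell)

#' @rdname accessors
#' @export
setMethod("atoms", "ToyCrystal", function(object, ...) object@atoms)

#' @rdname accessors
#' @export
setMethod("qValues", "QWeightSet", function(object, ...) object@q)

#' @rdname accessors
#' @export
setMethod("qMean", "QWeightSet", function(object, ...) object@qMean)

#' @rdname accessors
#' @export
setMethod("mapValues", "DensityMap", function(object, ...) object@values)

#' @rdname accessors
#' @export
setMethod("mapRms", "DensityMap", function(object, ...) object@rms)

#' @rdname accessors
#' @export
setMethod("alphaStar", "AlphaScanResult", function(object, ...) object@alphaStar)

#' @rdname accessors
#' @export
setMethod("occupancy", "AlphaScanResult", function(object, ...) object@occupancy)

#' @rdname accessors
#' @export
setMethod("ratios", "AlphaScanResult", function(object, ...) object@ratios)

#' @rdname accessors
#' @export
setMethod("ratios", "IsotopeComparison", function(object, ...) object@ratios)

fmtTaus <- function(t) paste(sprintf("%.3g", t * 1e6), collapse = ", ")

setMethod("show", "KineticScheme", function(object) {
  cat("KineticScheme (", object@condition, "): ",
      length(object@taus), " components\n", sep = "")
  cat("  taus (us): ", fmtTaus(object@taus), "\n", sep = "")
})

setMethod("show", "SpectralTimeSeries", function(object) {
  cat("SpectralTimeSeries (", object@condition, "): ",
      length(object@wavelengths), " wavelengths x ",
      length(object@delays), " delays\n", sep = "")
  cat(sprintf("  wavelengths: %g-%g nm; delays: %.3g-%.3g s\n",
              min(object@wavelengths), max(object@wavelengths),
              min(object@delays), max(object@delays)))
})

setMethod("show", "GlobalFitResult", function(object) {
  cat("GlobalFitResult: ", length(object@taus), " components, ",
      if (object@converged) "converged" else "NOT converged",
      " in ", object@nIterations, " iterations\n", sep = "")
  cat("  taus (us):   ", fmtTaus(object@taus), "\n", sep = "")
  cat("  stderr (us): ", fmtTaus(object@tauStderr), "\n", sep = "")
  cat(sprintf("  chi2: %.6g%s\n", object@chi2,
              if (object@degenerate) "  [degenerate taus]" else ""))
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult: ", nrow(object@replicateTaus), "/",
      object@nReplicates, " replicates (", object@nFailed,
      " failed), shuffle fraction ", object@shuffleFraction, "\n", sep = "")
  cat("  tau means (us): ", fmtTaus(object@means), "\n", sep = "")
  cat("  tau sds (us):   ", fmtTaus(object@sds), "\n", sep = "")
})

setMethod("show", "IsotopeComparison", function(object) {
  cat("IsotopeComparison: tau_D/tau_H (= k_H/k_D) by ascending-tau rank\n")
  cat("  ratios: ", paste(signif(object@ratios, 3), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ToyCrystal", function(object) {
  cat("ToyCrystal: ", nrow(object@atoms), " atoms, P1 cell ",
      paste(sprintf("%.4g", object@cell), collapse = " "), "\n", sep = "")
})

setMethod("show", "ReflectionSet", function(object) {
  cat("ReflectionSet: ", nrow(object@records),
      " unique reflections to ", object@dmin, " A",
      if (all(is.na(object@records$phase))) "" else " (with phases)",
      "\n", sep = "")
})

setMethod("show", "QWeightSet", function(object) {
  cat(sprintf("QWeightSet: %d weights, <q> = %.4g, range [%.4g, %.4g]\n",
              length(object@q), object@qMean,
              min(object@q), max(object@q)))
})

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "DensityMap: %d x %d x %d grid, rms %.4g (values in sigma units)\n",
    d[1], d[2], d[3], object@rms))
})

setMethod("show", "AlphaScanResult", function(object) {
  cat(sprintf(
    "AlphaScanResult: alpha* = %.3g, occupancy = %.1f%%%s\n",
    object@alphaStar, 100 * object@occupancy,
    if (object@flagged) "  [flat curve - indeterminate]" else ""))
})
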