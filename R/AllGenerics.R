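#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the container classes: time constants,
#' decay-associated spectra, grids, fit diagnostics, reflection records, map
#' values and alpha-scan results. Each class documents which of these it
#' supports.
#'
#' @param object an object of one of the package's S4 classes
#' @param ... passed to methods
#' @return the slot content (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taus", function(object, ...) standardGeneric("taus"))

#' @rdname accessors
#' @export
setGeneric("tauStderr", function(object, ...) standardGeneric("tauStderr"))

#' @rdname accessors
#' @export
setGeneric("dasMatrix", function(object, ...) standardGeneric("dasMatrix"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object, ...) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("delays", function(object, ...) standardGeneric("delays"))

#' @rdname accessors
#' @export
setGeneric("deltaA", function(object, ...) standardGeneric("deltaA"))

#' @rdname accessors
#' @export
setGeneric("chi2", function(object, ...) standardGeneric("chi2"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object, ...) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("reflections", function(object, ...) standardGeneric("reflections"))

#' @rdname accessors
#' @export
setGeneric("cellParams", function(object, ...) standardGeneric("cellParams"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(object, ...) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("qValues", function(object, ...) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setGeneric("qMean", function(object, ...) standardGeneric("qMean"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object, ...) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("mapRms", function(object, ...) standardGeneric("mapRms"))

#' @rdname accessors
#' @export
setGeneric("alphaStar", function(object, ...) standardGeneric("alphaStar"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object, ...) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("ratios", function(object, ...) standardGeneric("ratios"))
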