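#' @name nirquant-generics
#' @title Accessor generics
#' @description Accessors for the spectral container and fitted objects.
#' @param x an object.
#' @param value replacement value.
#' @keywords internal
NULL

#' @rdname nirquant-generics
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname nirquant-generics
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname nirquant-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname nirquant-generics
#' @export
setGeneric("contents", function(x) standardGeneric("contents"))

#' @rdname nirquant-generics
#' @export
setGeneric("contents<-", function(x, value) standardGeneric("contents<-"))

#' @rdname nirquant-generics
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname nirquant-generics
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname nirquant-generics
#' @export
setGeneric("roles<-", function(x, value) standardGeneric("roles<-"))

#' @rdname nirquant-generics
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' Subset a spectrum set to wavenumber windows
#'
#' @param x a [SpectrumSet-class].
#' @param windows a list of length-2 numeric vectors `c(low, high)` in
#'   cm^-1, bounds inclusive, or a 2-column matrix with one window per row.
#' @return an object of the same class restricted to axis points falling in
#'   at least one window (overlapping windows are deduplicated; ascending
#'   order preserved).
#' @export
setGeneric("subsetWindows", function(x, windows) standardGeneric("subsetWindows"))

#' @rdname nirquant-generics
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname nirquant-generics
#' @export
setGeneric("chosenFactors", function(x) standardGeneric("chosenFactors"))

#' @rdname nirquant-generics
#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))

#' @rdname nirquant-generics
#' @export
setGeneric("gridTable", function(x) standardGeneric("gridTable"))

#' @rdname nirquant-generics
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
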