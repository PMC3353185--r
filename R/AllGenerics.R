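#' @include RcppExports.R
NULL

#' Accessor generics
#'
#' Small accessor generics used across the simulation classes.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The slot value (see individual methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("census", function(x, ...) standardGeneric("census"))

#' @rdname accessors
#' @export
setGeneric("femaleCount", function(x, ...) standardGeneric("femaleCount"))

#' @rdname accessors
#' @export
setGeneric("maleCount", function(x, ...) standardGeneric("maleCount"))

#' @rdname accessors
#' @export
setGeneric("alphaAsex", function(x, ...) standardGeneric("alphaAsex"))

#' @rdname accessors
#' @export
setGeneric("sigmaP", function(x, ...) standardGeneric("sigmaP"))

#' @rdname accessors
#' @export
setGeneric("resources", function(x, ...) standardGeneric("resources"))

#' @rdname accessors
#' @export
setGeneric("stabilityPeriod", function(x, ...) standardGeneric("stabilityPeriod"))

#' @rdname accessors
#' @export
setGeneric("currentGeneration", function(x, ...) standardGeneric("currentGeneration"))

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x, ...) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setGeneric("outcome", function(x, ...) standardGeneric("outcome"))

#' @rdname complementEnvironment
#' @export
setGeneric("complementEnvironment", function(x) standardGeneric("complementEnvironment"))
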