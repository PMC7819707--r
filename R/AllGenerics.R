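#' @title Generics for somadendrite classes
#' @description Accessor generics for the core data containers.
#' @param x an object
#' @param value replacement value
#' @name somadendrite-generics
NULL

#' @rdname somadendrite-generics
#' @export
setGeneric("isErcc", function(x) standardGeneric("isErcc"))

#' @rdname somadendrite-generics
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname somadendrite-generics
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname somadendrite-generics
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' @rdname somadendrite-generics
#' @export
setGeneric("qcPass<-", function(x, value) standardGeneric("qcPass<-"))

#' @rdname somadendrite-generics
#' @export
setGeneric("genesDetected", function(x) standardGeneric("genesDetected"))

#' @rdname somadendrite-generics
#' @export
setGeneric("totalUmi", function(x) standardGeneric("totalUmi"))

#' @rdname somadendrite-generics
#' @export
setGeneric("selectedCutoff", function(x) standardGeneric("selectedCutoff"))

#' @rdname somadendrite-generics
#' @export
setGeneric("fdrCurve", function(x) standardGeneric("fdrCurve"))
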