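#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the classes in this package:
#' \code{binLabels} and \code{cardinalities} expose the integer label matrix
#' and per-column cardinalities of a [BinnedMatrix-class]; \code{nSamples}
#' and \code{nVariables} its dimensions; \code{omegaNaive},
#' \code{omegaCorrected} and \code{biasTerm} the components of an
#' [OInfoResult-class] (for an [EntropyEstimate-class], \code{biasTerm}
#' returns its additive Miller-Maddow term and \code{entropyValue} its
#' value in bits); \code{observedSupport} the number of distinct joint
#' label combinations stored in a [CountTable-class].
#'
#' @param x an object of the documented class.
#' @return A numeric or integer scalar (vector for \code{cardinalities}),
#'   or the label matrix for \code{binLabels}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname accessors
#' @export
setGeneric("cardinalities", function(x) standardGeneric("cardinalities"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' @rdname accessors
#' @export
setGeneric("omegaNaive", function(x) standardGeneric("omegaNaive"))

#' @rdname accessors
#' @export
setGeneric("omegaCorrected", function(x) standardGeneric("omegaCorrected"))

#' @rdname accessors
#' @export
setGeneric("biasTerm", function(x) standardGeneric("biasTerm"))

#' @rdname accessors
#' @export
setGeneric("entropyValue", function(x) standardGeneric("entropyValue"))

#' @rdname accessors
#' @export
setGeneric("observedSupport", function(x) standardGeneric("observedSupport"))
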