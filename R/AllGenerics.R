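#' @rdname PdzInteractionSet-class
#' @param x a \code{PdzInteractionSet}.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname PdzInteractionSet-class
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname PdzInteractionSet-class
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname PdzInteractionSet-class
#' @export
setGeneric("nNegative", function(x) standardGeneric("nNegative"))

#' @rdname ContactMap-class
#' @param x a \code{ContactMap}.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname PWM-class
#' @param x a \code{PWM}.
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' Classify feature vectors with a trained SVM
#'
#' Evaluates the kernel-expansion decision function for each query vector and
#' assigns the binary label: +1 when the score is >= 0 (sgn(0) = +1), -1
#' otherwise.
#'
#' @param model a trained \code{\linkS4class{PdzSVM}}.
#' @param x numeric vector (a single feature vector) or a matrix / sparse
#'   \code{Matrix} with one feature vector per row.
#' @return data.frame with columns \code{score} and \code{label}.
#' @export
setGeneric("decide", function(model, x) standardGeneric("decide"))
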