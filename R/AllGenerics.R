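#' Accessors for fitted model objects
#'
#' @param x a `GanModel` or `EncoderModel`.
#' @return `modelConfig` returns the configuration object; `trainingStep`
#'   the number of completed optimiser steps.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setGeneric("trainingStep", function(x) standardGeneric("trainingStep"))
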