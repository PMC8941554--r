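#' @rdname epochMatrix
#' @export
setGeneric("epochMatrix", function(x) standardGeneric("epochMatrix"))

#' @rdname epochLabels
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname samplingRate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname classNames
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname nEpochs
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname epochLength
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @rdname nClasses
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname pairLabel
#' @export
setGeneric("pairLabel", function(x) standardGeneric("pairLabel"))

#' @rdname pairProbability
#' @export
setGeneric("pairProbability",
    function(pair, model, mode = c("infer", "train"))
        standardGeneric("pairProbability"))

#' @rdname classifyEpochs
#' @export
setGeneric("classifyEpochs",
    function(model, epochs) standardGeneric("classifyEpochs"))
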