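#' Construct an EpochSet from an epoch matrix and labels
#'
#' @param epochs numeric matrix with one epoch per row
#'   (n_epochs x epoch_length).
#' @param labels integer vector of 0-based class ids, one per epoch.
#' @param samplingRate sampling rate in Hz (default 100, the convention for
#'   single-channel sleep EEG).
#' @param classNames optional character vector of class display names; when
#'   omitted, classes are named `"class0"`, `"class1"`, ...
#'
#' @return An [EpochSet-class] object.
#' @examples
#' x <- EpochSet(matrix(rnorm(40), nrow = 4), labels = c(0, 0, 1, 1))
#' nEpochs(x)
#' epochLength(x)
#' @export
EpochSet <- function(epochs, labels, samplingRate = 100, classNames = NULL) {
    epochs <- as.matrix(epochs)
    labels <- as.integer(labels)
    if (nrow(epochs) != length(labels))
        stop("number of epochs (", nrow(epochs), ") does not match number ",
             "of labels (", length(labels), ")")
    if (is.null(classNames)) {
        k <- if (length(labels)) max(labels) + 1L else 0L
        classNames <- paste0("class", seq_len(k) - 1L)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(signal = t(epochs)),
        colData = S4Vectors::DataFrame(label = labels),
        metadata = list(samplingRate = samplingRate,
                        classNames = as.character(classNames)))
    methods::new("EpochSet", se)
}

#' Epoch matrix of an EpochSet
#'
#' Returns the epochs as a numeric matrix with one epoch per row
#' (n_epochs x epoch_length).
#' @param x an [EpochSet-class].
#' @return numeric matrix.
#' @export
setMethod("epochMatrix", "EpochSet", function(x)
    t(SummarizedExperiment::assay(x, "signal")))

#' Per-epoch class labels
#'
#' @param x an [EpochSet-class].
#' @return integer vector of 0-based class ids.
#' @export
setMethod("epochLabels", "EpochSet", function(x)
    as.integer(SummarizedExperiment::colData(x)$label))

#' Sampling rate in Hz
#' @param x an [EpochSet-class].
#' @return numeric scalar.
#' @export
setMethod("samplingRate", "EpochSet", function(x)
    S4Vectors::metadata(x)$samplingRate)

#' Class display names
#' @param x an [EpochSet-class] or [EvalReport-class].
#' @return character vector.
#' @export
setMethod("classNames", "EpochSet", function(x)
    S4Vectors::metadata(x)$classNames)

#' Number of epochs
#' @param x an [EpochSet-class].
#' @return integer scalar.
#' @export
setMethod("nEpochs", "EpochSet", function(x) ncol(x))

#' Samples per epoch
#' @param x an [EpochSet-class].
#' @return integer scalar.
#' @export
setMethod("epochLength", "EpochSet", function(x) nrow(x))

#' Number of classes
#'
#' The number of classes declared by `classNames`, which may exceed the
#' number of classes observed among the labels.
#' @param x an [EpochSet-class].
#' @return integer scalar.
#' @export
setMethod("nClasses", "EpochSet", function(x) length(classNames(x)))

setMethod("show", "EpochSet", function(object) {
    lab <- epochLabels(object)
    cat("EpochSet with", nEpochs(object), "epochs of length",
        epochLength(object), "at", samplingRate(object), "Hz\n")
    tab <- table(factor(lab, levels = seq_along(classNames(object)) - 1L,
                        labels = classNames(object)))
    cat("class counts:\n")
    print(tab)
    invisible(NULL)
})

#' Accessors for SamplePair
#' @param x a [SamplePair-class].
#' @return `pairLabel` returns the binary pair label (1 positive,
#'   0 negative).
#' @export
setMethod("pairLabel", "SamplePair", function(x) x@pairLabel)

setMethod("show", "SamplePair", function(object) {
    kind <- if (object@pairLabel == 1L) "positive" else "negative"
    cat(sprintf("SamplePair (%s): left class %d, right class %d, %d x %d\n",
                kind, object@leftClass, object@rightClass,
                4L, ncol(object@left)))
    invisible(NULL)
})

setMethod("show", "PretextModel", function(object) {
    d <- object@dims
    cat("PretextModel\n")
    cat(sprintf("  encoder: input %d -> blocks [%s] -> latent dZ = %d\n",
                d$inputLength, paste(d$widths, collapse = ", "), d$dZ))
    cat(sprintf("  GRU context: dC = %d; prediction steps: %d\n",
                d$dC, d$steps))
    if (!is.null(object@config$trainedEpochs))
        cat(sprintf("  trained: %d epochs x %d iterations\n",
                    object@config$trainedEpochs,
                    object@config$iterationsPerEpoch))
    invisible(NULL)
})

setMethod("show", "ClassifierModel", function(object) {
    c1 <- object@conv1$spec; c2 <- object@conv2$spec
    cat("ClassifierModel\n")
    cat(sprintf("  encoder: input %d -> latent %d (%s)\n",
                object@dims$inputLength, object@dims$dZ,
                if (isTRUE(object@config$encoderTrainable)) "fine-tuned"
                else "frozen"))
    cat(sprintf("  conv1: %d filters, kernel %d; conv2: %d filters, kernel %d\n",
                c1$filters, c1$kernel, c2$filters, c2$kernel))
    cat(sprintf("  softmax head over %d classes\n", object@nClasses))
    invisible(NULL)
})
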