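#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats fft rnorm runif sd setNames predict
#' @importFrom utils head tail
NULL

# encoder parameter bundles are S3 lists (nested numeric arrays); register
# them so S4 slots typed "list" accept them
setOldClass(c("EncoderParams", "list"))

#' EpochSet: a set of fixed-length signal epochs with class labels
#'
#' `EpochSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' matrix of fixed-length physiological signal epochs (e.g. 30-s EEG windows
#' or ECG beats) together with a per-epoch integer class label. Epochs are
#' stored as columns of the `"signal"` assay (samples x epochs); labels live
#' in `colData(x)$label` as 0-based class ids; the sampling rate (Hz) and
#' optional class names live in `metadata(x)`.
#'
#' Validity requires every label to be a valid class id in
#' `0..nClasses(x)-1` and the label vector to match the number of epochs.
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @seealso [EpochSet()] the constructor, [epochMatrix()], [epochLabels()],
#'   [generateEpochs()]
#' @export
setClass("EpochSet", contains = "SummarizedExperiment")

setValidity("EpochSet", function(object) {
    msg <- character()
    if (!"signal" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'signal' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% colnames(cd)) {
        msg <- c(msg, "colData column 'label' is required")
    } else {
        lab <- cd$label
        if (anyNA(lab) || !is.numeric(lab) || any(lab != floor(lab)))
            msg <- c(msg, "labels must be non-missing integers")
        else if (length(lab) && min(lab) < 0L)
            msg <- c(msg, "labels must be 0-based class ids (>= 0)")
        cn <- S4Vectors::metadata(object)$classNames
        if (!is.null(cn) && length(lab) && max(lab) >= length(cn))
            msg <- c(msg, "a label exceeds the number of class names")
    }
    if (length(msg)) msg else TRUE
})

#' SamplePair: a positive or negative contrastive pair of epochs
#'
#' An ordered pair of two blocks of 4 epochs each. The left block is the
#' "training set" half fed to the context model; the right block is the
#' "waiting training set" half whose latents the context must predict. A
#' positive pair (`pairLabel = 1`) draws all 8 epochs, without replacement,
#' from one class; a negative pair (`pairLabel = 0`) draws 4 epochs from one
#' class on the left and 4 from a different class on the right.
#'
#' @slot left numeric matrix, 4 x epochLength; the left (context) block.
#' @slot right numeric matrix, 4 x epochLength; the right (prediction) block.
#' @slot pairLabel integer, 1 for positive, 0 for negative.
#' @slot leftClass,rightClass integer class ids of the two blocks
#'   (equal iff positive).
#' @slot leftIndex,rightIndex integer vectors of the source epoch indices
#'   in the originating `EpochSet` (1-based); all 8 are distinct.
#' @seealso [buildPositivePair()], [buildNegativePair()], [pairBatch()]
#' @export
setClass("SamplePair", representation(
    left = "matrix", right = "matrix",
    pairLabel = "integer",
    leftClass = "integer", rightClass = "integer",
    leftIndex = "integer", rightIndex = "integer"))

setValidity("SamplePair", function(object) {
    msg <- character()
    if (nrow(object@left) != 4L || nrow(object@right) != 4L)
        msg <- c(msg, "each block must contain exactly 4 epochs")
    if (ncol(object@left) != ncol(object@right))
        msg <- c(msg, "left and right epochs must have equal length")
    if (!object@pairLabel %in% c(0L, 1L))
        msg <- c(msg, "pairLabel must be 0 or 1")
    if (object@pairLabel == 1L && object@leftClass != object@rightClass)
        msg <- c(msg, "positive pair must have leftClass == rightClass")
    if (object@pairLabel == 0L && object@leftClass == object@rightClass)
        msg <- c(msg, "negative pair must have leftClass != rightClass")
    idx <- c(object@leftIndex, object@rightIndex)
    if (length(idx) != 8L || anyDuplicated(idx))
        msg <- c(msg, "the 8 source epochs must be distinct")
    if (length(msg)) msg else TRUE
})

#' PretextModel: CPC pretext model (encoder + GRU context + step predictors)
#'
#' Holds the parameters of the self-supervised pretext model: the 4-block
#' dense encoder `g_enc` (shared later with the downstream classifier), the
#' GRU summariser `g_ar` producing the context vector `c`, and one linear
#' prediction map `W_k` (d_c x d_z) per prediction step `k = 1..t`.
#'
#' @slot encoder list of encoder parameters (dense blocks with batch
#'   normalisation, plus the final latent projection); see [encodeEpochs()].
#' @slot gru list of GRU gate parameters (hidden size d_c).
#' @slot predictors list of t numeric matrices `W_k` of shape d_c x d_z.
#' @slot dims named list: inputLength, hidden widths, dZ, dC, steps.
#' @slot config named list of training configuration used to build/train.
#' @seealso [newPretextModel()], [trainPretext()], [pairProbability()]
#' @export
setClass("PretextModel", representation(
    encoder = "list", gru = "list", predictors = "list",
    dims = "list", config = "list"))

setValidity("PretextModel", function(object) {
    d <- object@dims
    msg <- character()
    if (length(object@predictors) != d$steps)
        msg <- c(msg, "need one predictor map per prediction step")
    for (W in object@predictors)
        if (!all(dim(W) == c(d$dC, d$dZ)))
            msg <- c(msg, "predictor maps must be dC x dZ")
    if (length(msg)) unique(msg) else TRUE
})

#' ClassifierModel: downstream epoch classifier built on the CPC encoder
#'
#' The supervised classifier reuses the pretext encoder: each input epoch is
#' replicated four times, each copy is encoded by the shared-weight encoder
#' into a 4 x d_z latent sequence, which passes through two distinct 1-D
#' convolution layers, global average pooling, and a dense softmax head.
#'
#' @slot encoder encoder parameter list (pretrained or freshly initialised).
#' @slot conv1,conv2 1-D convolution parameter lists; the two layers must
#'   differ in filters and/or kernel size.
#' @slot head dense softmax layer parameters over `nClasses` outputs.
#' @slot nClasses integer number of target classes.
#' @slot dims named list of layer dimensions.
#' @slot config named list: encoderTrainable flag, architecture, training
#'   provenance (seed etc.).
#' @seealso [buildClassifier()], [trainClassifier()], [classifyEpochs()]
#' @export
setClass("ClassifierModel", representation(
    encoder = "list", conv1 = "list", conv2 = "list", head = "list",
    nClasses = "integer", dims = "list", config = "list"))

setValidity("ClassifierModel", function(object) {
    msg <- character()
    if (object@nClasses < 2L)
        msg <- c(msg, "nClasses must be >= 2")
    c1 <- object@conv1$spec; c2 <- object@conv2$spec
    if (identical(c1$filters, c2$filters) && identical(c1$kernel, c2$kernel))
        msg <- c(msg, "conv1 and conv2 must differ in filters or kernel size")
    if (length(msg)) msg else TRUE
})

#' EvalReport: confusion matrix with per-class and aggregate metrics
#'
#' Per-class precision, recall and F1 (percent), macro-averaged F1 and
#' overall accuracy computed from a confusion matrix whose rows are true
#' classes and columns predicted classes. Values are stored at full
#' precision; `show()` displays them rounded half-up to 2 decimals in the
#' conventional layout (matrix columns, then PR/RE/F1 columns, macro-average
#' and accuracy footer rows).
#'
#' @slot confusion integer matrix, rows true class, columns predicted class.
#' @slot perClass data.frame with columns precision, recall, f1 (percent,
#'   full precision), one row per class.
#' @slot accuracy overall accuracy, percent.
#' @slot macroF1 unweighted mean of per-class F1, percent.
#' @slot classNames character vector of class display names.
#' @slot degenerate character vector naming classes that were never
#'   predicted or never present (their undefined ratios are reported as 0).
#' @seealso [reportMetrics()], [confusionMatrix()]
#' @export
setClass("EvalReport", representation(
    confusion = "matrix", perClass = "data.frame",
    accuracy = "numeric", macroF1 = "numeric",
    classNames = "character", degenerate = "character"))

setValidity("EvalReport", function(object) {
    cm <- object@confusion
    msg <- character()
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion matrix must be square")
    if (any(cm < 0)) msg <- c(msg, "confusion entries must be nonnegative")
    if (nrow(object@perClass) != nrow(cm))
        msg <- c(msg, "perClass must have one row per class")
    if (length(msg)) msg else TRUE
})
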