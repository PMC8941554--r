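ENCODER_FORMAT <- "epochcpc-encoder"
CLASSIFIER_FORMAT <- "epochcpc-classifier"
CHECKPOINT_VERSION <- 1L

#' Save / load the pretext encoder
#'
#' After the pretext task is trained, only the encoder is carried over to
#' the downstream classifier; the GRU and the step predictors are
#' discarded. The checkpoint is a self-describing container (format tag,
#' version, layer shapes, parameters, batch-normalisation statistics, and
#' the configuration and seed that produced it); the round trip is
#' bit-exact, so a loaded encoder reproduces identical latents on any
#' probe epoch.
#'
#' @param model a [PretextModel-class] or an `EncoderParams`.
#' @param path file path for the checkpoint.
#' @return `saveEncoder` returns `path` invisibly; `loadEncoder` returns
#'   an `EncoderParams`.
#' @examples
#' m <- newPretextModel(64, widths = c(16, 8, 8, 8), dZ = 4, dC = 4,
#'                      seed = 1)
#' f <- tempfile(fileext = ".rds")
#' saveEncoder(m, f)
#' enc <- loadEncoder(f)
#' identical(encodeEpochs(rnorm(64), enc), encodeEpochs(rnorm(64), m))
#' @export
saveEncoder <- function(model, path) {
    enc <- asEncoder(model)
    cfg <- if (methods::is(model, "PretextModel")) model@config else list()
    obj <- list(format = ENCODER_FORMAT, version = CHECKPOINT_VERSION,
                dims = enc$dims, par = enc$par, buf = enc$buf,
                config = cfg)
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveEncoder
#' @export
loadEncoder <- function(path) {
    if (!file.exists(path))
        stop("encoder checkpoint not found: ", path)
    obj <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupt encoder checkpoint: ",
                                             path, " (", conditionMessage(e),
                                             ")"))
    if (!is.list(obj) || !identical(obj$format, ENCODER_FORMAT))
        stop("file is not an encoder checkpoint: ", path)
    if (!identical(obj$version, CHECKPOINT_VERSION))
        stop("unsupported encoder checkpoint version: ", obj$version)
    structure(list(par = obj$par, buf = obj$buf, dims = obj$dims),
              class = c("EncoderParams", "list"))
}

#' Save / load a downstream classifier
#'
#' Same container format as the encoder checkpoint, extended with the
#' convolution layers, the softmax head and the classifier configuration.
#'
#' @param model a [ClassifierModel-class].
#' @param path file path for the checkpoint.
#' @return `saveClassifier` returns `path` invisibly; `loadClassifier`
#'   returns the [ClassifierModel-class].
#' @export
saveClassifier <- function(model, path) {
    stopIfNot(methods::is(model, "ClassifierModel"),
              "model must be a ClassifierModel")
    obj <- list(format = CLASSIFIER_FORMAT, version = CHECKPOINT_VERSION,
                encoder = unclass(model@encoder), conv1 = model@conv1,
                conv2 = model@conv2, head = model@head,
                nClasses = model@nClasses, dims = model@dims,
                config = model@config)
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
    if (!file.exists(path))
        stop("classifier checkpoint not found: ", path)
    obj <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupt classifier ",
                                             "checkpoint: ", path))
    if (!is.list(obj) || !identical(obj$format, CLASSIFIER_FORMAT))
        stop("file is not a classifier checkpoint: ", path)
    if (!identical(obj$version, CHECKPOINT_VERSION))
        stop("unsupported classifier checkpoint version: ", obj$version)
    methods::new("ClassifierModel",
                 encoder = structure(obj$encoder, class = c("EncoderParams", "list")),
                 conv1 = obj$conv1, conv2 = obj$conv2, head = obj$head,
                 nClasses = obj$nClasses, dims = obj$dims,
                 config = obj$config)
}
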