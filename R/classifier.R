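#' Replicate an epoch four times
#'
#' The downstream classifier keeps the dimensionality the encoder was
#' pretrained with by copying each sample four times before classification:
#' a sample `x` enters the model as `[x, x, x, x]`, and each copy is
#' encoded independently by the shared-weight encoder into a 4 x dZ latent
#' sequence for the convolution stack.
#'
#' @param epoch numeric vector, one signal epoch.
#' @return Numeric matrix with 4 identical rows.
#' @examples
#' replicateInput(c(1, 2, 3))
#' @export
replicateInput <- function(epoch) {
    matrix(rep(as.numeric(epoch), each = 4L), nrow = 4L)
}

#' Assemble the downstream classifier
#'
#' Stacks the (pretrained or fresh) encoder, two 1-D convolution layers
#' that must not be identical in (filters, kernel), global average pooling
#' over the replicated-sequence axis, and a dense softmax head.
#'
#' @param encoder an `EncoderParams` (e.g. from [loadEncoder()] or a
#'   trained [PretextModel-class]), or `NULL` to initialise the encoder
#'   from scratch (fully supervised baseline).
#' @param nClasses number of target classes (>= 2), e.g. 5 sleep stages or
#'   3 AAMI beat classes.
#' @param inputLength samples per epoch; required when `encoder` is `NULL`.
#' @param conv1,conv2 lists with elements `filters` and `kernel`; defaults
#'   (64, 3) and (32, 2).
#' @param widths,dZ encoder architecture used when initialising from
#'   scratch.
#' @param encoderTrainable fine-tune the encoder (default) or freeze it for
#'   a linear-probe-style comparison.
#' @param seed optional integer seed for the fresh layers.
#' @return A [ClassifierModel-class].
#' @examples
#' m <- buildClassifier(NULL, nClasses = 5, inputLength = 64,
#'                      widths = c(16, 8, 8, 8), dZ = 4, seed = 1)
#' m
#' @export
buildClassifier <- function(encoder, nClasses, inputLength = NULL,
                            conv1 = list(filters = 64L, kernel = 3L),
                            conv2 = list(filters = 32L, kernel = 2L),
                            widths = c(256, 128, 128, 128), dZ = 64,
                            encoderTrainable = TRUE, seed = NULL) {
    nClasses <- as.integer(nClasses)
    stopIfNot(nClasses >= 2L, "nClasses must be >= 2")
    if (identical(as.integer(conv1$filters), as.integer(conv2$filters)) &&
        identical(as.integer(conv1$kernel), as.integer(conv2$kernel)))
        stop("conv1 and conv2 must differ in filters or kernel size")
    seqLen <- 4L
    if (conv1$kernel > seqLen ||
        conv2$kernel > (seqLen - conv1$kernel + 1L))
        stop("convolution kernels exceed the replicated-sequence length")
    withSeed(seed, {
        if (is.null(encoder)) {
            stopIfNot(!is.null(inputLength),
                      "inputLength is required for a scratch encoder")
            enc <- encoderInit(as.integer(inputLength), as.integer(widths),
                               as.integer(dZ))
            pretrained <- FALSE
        } else {
            if (methods::is(encoder, "PretextModel"))
                encoder <- encoder@encoder
            stopIfNot(inherits(encoder, "EncoderParams"),
                      "encoder must be an EncoderParams or PretextModel")
            enc <- encoder
            pretrained <- TRUE
        }
        dZa <- enc$dims$dZ
        c1 <- convInit(dZa, as.integer(conv1$filters),
                       as.integer(conv1$kernel))
        c1$spec <- list(filters = as.integer(conv1$filters),
                        kernel = as.integer(conv1$kernel))
        c2 <- convInit(as.integer(conv1$filters), as.integer(conv2$filters),
                       as.integer(conv2$kernel))
        c2$spec <- list(filters = as.integer(conv2$filters),
                        kernel = as.integer(conv2$kernel))
        head <- list(W = heInit(as.integer(conv2$filters), nClasses),
                     b = numeric(nClasses))
        methods::new("ClassifierModel", encoder = enc, conv1 = c1,
                     conv2 = c2, head = head, nClasses = nClasses,
                     dims = list(inputLength = enc$dims$inputLength,
                                 dZ = dZa, seqLen = seqLen),
                     config = list(encoderTrainable =
                                       isTRUE(encoderTrainable),
                                   pretrainedEncoder = pretrained,
                                   seed = seed))
    })
}

# forward pass over a batch of epochs (rows); returns caches for backward
classifierForward <- function(model, X, mode = "infer") {
    # a frozen encoder always runs on its stored statistics
    encMode <- if (isTRUE(model@config$encoderTrainable)) mode else "infer"
    ef <- encoderForward(model@encoder, X, encMode)
    Z <- ef$Z
    # the four replicated copies share weights, so their latents coincide;
    # the sequence axis carries four identical positions
    Xs <- rep(list(Z), model@dims$seqLen)
    cf1 <- convForward(model@conv1[c("W", "b")], Xs)
    A1s <- lapply(cf1$Ys, reluAct)
    cf2 <- convForward(model@conv2[c("W", "b")], A1s)
    A2s <- lapply(cf2$Ys, reluAct)
    pooled <- Reduce(`+`, A2s) / length(A2s)
    hf <- denseForward(pooled, model@head$W, model@head$b)
    P <- softmaxRows(hf$Y)
    list(P = P, enc = ef$enc, encCache = ef$cache, cf1 = cf1, cf2 = cf2,
         A2s = A2s, hf = hf)
}

classifierBackward <- function(model, fw, labels) {
    n <- nrow(fw$P)
    dLogits <- fw$P
    idx <- cbind(seq_len(n), labels + 1L)
    dLogits[idx] <- dLogits[idx] - 1
    dLogits <- dLogits / n
    hb <- denseBackward(fw$hf, model@head$W, dLogits)
    lOut <- length(fw$A2s)
    dA2s <- rep(list(hb$dX / lOut), lOut)
    dY2s <- lapply(seq_len(lOut),
                   function(p) dA2s[[p]] * (fw$cf2$Ys[[p]] > 0))
    cb2 <- convBackward(model@conv2[c("W", "b")], fw$cf2, dY2s)
    dY1s <- lapply(seq_along(cb2$dXs),
                   function(p) cb2$dXs[[p]] * (fw$cf1$Ys[[p]] > 0))
    cb1 <- convBackward(model@conv1[c("W", "b")], fw$cf1, dY1s)
    dZ <- Reduce(`+`, cb1$dXs)
    out <- list(conv1 = cb1$grads, conv2 = cb2$grads,
                head = list(W = hb$dW, b = hb$db))
    if (isTRUE(model@config$encoderTrainable))
        out$enc <- encoderBackward(model@encoder, fw$encCache, dZ)$grads
    out
}

classifierParams <- function(model) {
    p <- list(conv1 = model@conv1[c("W", "b")],
              conv2 = model@conv2[c("W", "b")],
              head = model@head)
    if (isTRUE(model@config$encoderTrainable))
        p$enc <- model@encoder$par
    p
}

setClassifierParams <- function(model, params) {
    model@conv1$W <- params$conv1$W; model@conv1$b <- params$conv1$b
    model@conv2$W <- params$conv2$W; model@conv2$b <- params$conv2$b
    model@head <- params$head
    if (isTRUE(model@config$encoderTrainable))
        model@encoder$par <- params$enc
    model
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Replays a validation-loss sequence through the plateau scheduler used by
#' [trainClassifier()]: the learning rate starts at `initialLr`; whenever
#' `patience` consecutive epochs fail to improve on the best loss seen so
#' far by at least `minDelta`, the rate is multiplied by `factor` (1/3 by
#' default) from the next epoch on, never falling below `minLr`.
#'
#' @param valLoss numeric vector of per-epoch validation losses.
#' @param initialLr initial learning rate (default 0.001).
#' @param factor multiplicative reduction (default 1/3).
#' @param patience epochs without improvement before reducing (default 2).
#' @param minDelta minimum decrease that counts as improvement.
#' @param minLr learning-rate floor.
#' @return Numeric vector: the learning rate in force at each epoch.
#' @examples
#' lrPlateauSchedule(c(1, 0.9, 0.9, 0.9, 0.8))
#' @export
lrPlateauSchedule <- function(valLoss, initialLr = 0.001, factor = 1 / 3,
                              patience = 2L, minDelta = 1e-4,
                              minLr = 1e-6) {
    stopIfNot(factor > 0 && factor < 1, "factor must lie in (0, 1)")
    stopIfNot(patience >= 1L, "patience must be >= 1")
    sched <- makePlateau(initialLr, factor, patience, minDelta, minLr)
    out <- numeric(length(valLoss))
    for (e in seq_along(valLoss)) {
        out[e] <- sched$lr()
        sched$observe(valLoss[e])
    }
    out
}

# stateful plateau monitor shared by the schedule replay and the training
# loop, so both follow the identical rule
makePlateau <- function(initialLr, factor, patience, minDelta, minLr) {
    lr <- initialLr
    best <- Inf
    wait <- 0L
    list(
        lr = function() lr,
        observe = function(loss) {
            if (loss < best - minDelta) {
                best <<- loss
                wait <<- 0L
            } else {
                wait <<- wait + 1L
                if (wait >= patience) {
                    lr <<- max(minLr, lr * factor)
                    wait <<- 0L
                }
            }
            invisible(lr)
        })
}

#' Training configuration for the downstream classifier
#'
#' @param initialLr initial learning rate (default 0.001).
#' @param plateauPatience epochs without validation improvement before the
#'   learning rate is reduced (default 2).
#' @param lrFactor plateau reduction factor (default 1/3).
#' @param minDelta minimum validation-loss decrease counting as
#'   improvement.
#' @param minLr learning-rate floor.
#' @param maxEpochs training epochs (no early stopping is applied).
#' @param batchSize mini-batch size.
#' @param seed integer seed for shuffling.
#' @return A validated `TrainConfig` list.
#' @export
trainConfig <- function(initialLr = 0.001, plateauPatience = 2L,
                        lrFactor = 1 / 3, minDelta = 1e-4, minLr = 1e-6,
                        maxEpochs = 15L, batchSize = 32L, seed = 1L) {
    stopIfNot(lrFactor > 0 && lrFactor < 1, "lrFactor must lie in (0, 1)")
    stopIfNot(plateauPatience >= 1L, "plateauPatience must be >= 1")
    structure(list(initialLr = initialLr,
                   plateauPatience = as.integer(plateauPatience),
                   lrFactor = lrFactor, minDelta = minDelta, minLr = minLr,
                   maxEpochs = as.integer(maxEpochs),
                   batchSize = as.integer(batchSize),
                   seed = as.integer(seed)),
              class = "TrainConfig")
}

#' Train the downstream classifier
#'
#' Minimises categorical cross-entropy over one-hot class targets with the
#' adaptive-moment optimiser. The validation loss is monitored after every
#' epoch; when it fails to improve for `plateauPatience` consecutive
#' epochs, the learning rate is reduced to `lrFactor` (1/3) of its value.
#'
#' @param model a [ClassifierModel-class] from [buildClassifier()].
#' @param train labelled [EpochSet-class] (possibly a [labelMask()]
#'   subset).
#' @param validation [EpochSet-class] used for the plateau monitor and
#'   accuracy history.
#' @param config a [trainConfig()].
#' @param verbose emit one log line per epoch to standard error.
#' @return List with `model` (trained) and `history` (data.frame: epoch,
#'   trainLoss, valLoss, lr, valAccuracy).
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 20,
#'                                 epochLength = 64, seed = 1))
#' sp <- splitEpochs(x, 0.25, seed = 1)
#' m <- buildClassifier(NULL, 2, inputLength = 64,
#'                      widths = c(16, 8, 8, 8), dZ = 4, seed = 1)
#' fit <- trainClassifier(m, sp$train, sp$test,
#'                        trainConfig(maxEpochs = 2, batchSize = 8))
#' fit$history$lr
#' @export
trainClassifier <- function(model, train, validation,
                            config = trainConfig(), verbose = FALSE) {
    stopIfNot(methods::is(model, "ClassifierModel"),
              "model must be a ClassifierModel")
    stopIfNot(nEpochs(train) > 0L, "training set is empty")
    stopIfNot(nEpochs(validation) > 0L, "validation set is empty")
    Xtr <- epochMatrix(train)
    ytr <- epochLabels(train)
    Xval <- epochMatrix(validation)
    yval <- epochLabels(validation)
    stopIfNot(max(c(ytr, yval)) < model@nClasses,
              "a label exceeds the model's number of classes")
    sched <- makePlateau(config$initialLr, config$lrFactor,
                         config$plateauPatience, config$minDelta,
                         config$minLr)
    hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                       valLoss = numeric(), lr = numeric(),
                       valAccuracy = numeric())
    withSeed(config$seed, {
        params <- classifierParams(model)
        opt <- adamInit(params)
        n <- nrow(Xtr)
        for (e in seq_len(config$maxEpochs)) {
            lrNow <- sched$lr()
            ord <- sample.int(n)
            lossSum <- 0; nBatches <- 0L
            for (start in seq(1L, n, by = config$batchSize)) {
                idx <- ord[start:min(start + config$batchSize - 1L, n)]
                fw <- classifierForward(model, Xtr[idx, , drop = FALSE],
                                        mode = "train")
                model@encoder <- fw$enc
                loss <- crossEntropy(fw$P, ytr[idx])
                if (!is.finite(loss))
                    stop("classifier training diverged at epoch ", e,
                         " (non-finite loss)")
                lossSum <- lossSum + loss; nBatches <- nBatches + 1L
                grads <- classifierBackward(model, fw, ytr[idx])
                upd <- adamStep(params, grads, opt, lrNow)
                params <- upd$params; opt <- upd$state
                model <- setClassifierParams(model, params)
            }
            fwVal <- classifierForward(model, Xval, mode = "infer")
            valLoss <- crossEntropy(fwVal$P, yval)
            valAcc <- mean(max.col(fwVal$P) - 1L == yval)
            hist <- rbind(hist, data.frame(
                epoch = e, trainLoss = lossSum / nBatches,
                valLoss = valLoss, lr = lrNow, valAccuracy = valAcc))
            if (verbose)
                logInfo(sprintf(
                    "classifier epoch %d loss=%.4f val_loss=%.4f lr=%.2e val_acc=%.3f",
                    e, lossSum / nBatches, valLoss, lrNow, valAcc))
            sched$observe(valLoss)
        }
    })
    model@config$trainConfig <- unclass(config)
    list(model = model, history = hist)
}

#' Predict classes for epochs
#'
#' Runs the classifier in inference mode (batch normalisation uses running
#' statistics, so predictions are deterministic) and returns the argmax
#' class per epoch together with the full softmax probability matrix.
#'
#' @param model a trained [ClassifierModel-class].
#' @param epochs an [EpochSet-class] or a numeric matrix with one epoch per
#'   row.
#' @return List with `classes` (0-based integer ids) and `probabilities`
#'   (matrix, rows summing to 1).
#' @examples
#' m <- buildClassifier(NULL, 2, inputLength = 64,
#'                      widths = c(16, 8, 8, 8), dZ = 4, seed = 1)
#' out <- classifyEpochs(m, matrix(rnorm(128), nrow = 2))
#' rowSums(out$probabilities)
#' @export
setMethod("classifyEpochs", signature(model = "ClassifierModel"),
    function(model, epochs) {
        X <- if (methods::is(epochs, "EpochSet")) epochMatrix(epochs)
             else as.matrix(epochs)
        if (ncol(X) != model@dims$inputLength)
            stop("epoch length ", ncol(X), " does not match model input ",
                 "width ", model@dims$inputLength)
        fw <- classifierForward(model, X, mode = "infer")
        list(classes = max.col(fw$P) - 1L, probabilities = fw$P)
    })
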