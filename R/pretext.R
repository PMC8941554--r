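#' Create an untrained CPC pretext model
#'
#' Builds the pretext model of the two-step framework: a 4-block dense
#' encoder `g_enc` (each block is a dense layer, batch normalisation and a
#' rectified-linear activation, followed by a final dense projection to the
#' latent width `dZ`), a GRU summariser `g_ar` with hidden width `dC`, and
#' one linear prediction map `W_k` per prediction step.
#'
#' @param inputLength samples per epoch the encoder accepts.
#' @param widths dense widths of the four encoder blocks.
#' @param dZ latent (coding feature) width.
#' @param dC GRU context width.
#' @param steps prediction steps per pair; equals the pair block size
#'   (4 epochs) by default.
#' @param seed optional integer seed for weight initialisation.
#' @return A [PretextModel-class].
#' @examples
#' m <- newPretextModel(inputLength = 64, widths = c(32, 16, 16, 16),
#'                      dZ = 8, dC = 8, seed = 1)
#' m
#' @export
newPretextModel <- function(inputLength, widths = c(256, 128, 128, 128),
                            dZ = 64, dC = 64, steps = 4L, seed = NULL) {
    stopIfNot(length(widths) >= 1L, "at least one encoder block is required")
    steps <- as.integer(steps)
    withSeed(seed, {
        enc <- encoderInit(inputLength, as.integer(widths), as.integer(dZ))
        gru <- gruInit(dZ, dC)
        preds <- lapply(seq_len(steps),
                        function(k) glorotInit(dC, dZ) * 0.1)
        methods::new("PretextModel", encoder = enc, gru = gru,
                     predictors = preds,
                     dims = list(inputLength = as.integer(inputLength),
                                 widths = as.integer(widths),
                                 dZ = as.integer(dZ), dC = as.integer(dC),
                                 steps = steps),
                     config = list(seed = seed))
    })
}

#' Encode epochs into latent coding features
#'
#' Applies the encoder `g_enc` to one or more epochs, producing the latent
#' coding features `z` of width `dZ`. In `"infer"` mode batch normalisation
#' uses the stored running statistics, so the encoding is a deterministic
#' function of the input; `"train"` mode normalises by batch statistics
#' (running buffers are not modified by this function -- only the training
#' loops update them).
#'
#' @param x a numeric vector (one epoch), a matrix with one epoch per row,
#'   or an [EpochSet-class].
#' @param encoder an `EncoderParams` object (from [loadEncoder()] or a
#'   model slot) or a [PretextModel-class] / [ClassifierModel-class].
#' @param mode `"infer"` (default) or `"train"`.
#' @return Numeric matrix of latents, one row per epoch.
#' @examples
#' m <- newPretextModel(64, widths = c(16, 8, 8, 8), dZ = 4, dC = 4,
#'                      seed = 1)
#' z <- encodeEpochs(rnorm(64), m)
#' length(z)
#' @export
encodeEpochs <- function(x, encoder, mode = c("infer", "train")) {
    mode <- match.arg(mode)
    enc <- asEncoder(encoder)
    X <- if (methods::is(x, "EpochSet")) epochMatrix(x)
         else if (is.matrix(x)) x
         else matrix(x, nrow = 1L)
    if (ncol(X) != enc$dims$inputLength)
        stop("epoch length ", ncol(X), " does not match encoder input ",
             "width ", enc$dims$inputLength)
    encoderForward(enc, X, mode)$Z
}

asEncoder <- function(encoder) {
    if (methods::is(encoder, "PretextModel")) return(encoder@encoder)
    if (methods::is(encoder, "ClassifierModel")) return(encoder@encoder)
    if (inherits(encoder, "EncoderParams")) return(encoder)
    stop("encoder must be an EncoderParams, PretextModel or ClassifierModel")
}

#' Summarise a latent sequence into a context vector
#'
#' Runs the GRU `g_ar` over the left-block latents in order and returns its
#' final hidden state, the context representation `c` used for multistep
#' prediction.
#'
#' @param zSequence latents of the left block: a matrix with `steps` rows
#'   (one latent per row) or a list of `steps` row-batched matrices.
#' @param model a [PretextModel-class].
#' @return Numeric context vector of length `dC` (or a batch matrix when
#'   `zSequence` is a list of batch matrices).
#' @examples
#' m <- newPretextModel(64, widths = c(16, 8, 8, 8), dZ = 4, dC = 4,
#'                      seed = 1)
#' z <- matrix(rnorm(16), 4, 4)
#' c1 <- contextualize(z, m)
#' length(c1)
#' @export
contextualize <- function(zSequence, model) {
    stopIfNot(methods::is(model, "PretextModel"),
              "model must be a PretextModel")
    t <- model@dims$steps
    if (is.matrix(zSequence) && !is.list(zSequence)) {
        if (nrow(zSequence) != t)
            stop("latent sequence must have ", t, " steps, got ",
                 nrow(zSequence))
        Zs <- lapply(seq_len(t),
                     function(k) zSequence[k, , drop = FALSE])
        drop(gruForward(model@gru, Zs)$h)
    } else {
        if (length(zSequence) != t)
            stop("latent sequence must have ", t, " steps, got ",
                 length(zSequence))
        gruForward(model@gru, zSequence)$h
    }
}

#' Probability that a pair is positive
#'
#' Encodes the right ("waiting") block, predicts each of its latents from
#' the context vector of the left block with the per-step linear maps, and
#' scores prediction against truth by inner product:
#' `s_k = <W_k c, z^W_k>`. The pair probability is
#' `sigmoid(mean_k s_k)`, the model's belief that all eight epochs share
#' one class.
#'
#' @param pair a [SamplePair-class].
#' @param model a [PretextModel-class].
#' @param mode batch-normalisation mode for the encoder, `"infer"`
#'   (default) or `"train"`.
#' @return Probability in (0, 1).
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 10,
#'                                 epochLength = 64))
#' m <- newPretextModel(64, widths = c(16, 8, 8, 8), dZ = 4, dC = 4,
#'                      seed = 1)
#' p <- buildPositivePair(x, 0, seed = 1)
#' pairProbability(p, m)
#' @export
setMethod("pairProbability", signature(pair = "SamplePair",
                                       model = "PretextModel"),
    function(pair, model, mode = c("infer", "train")) {
        mode <- match.arg(mode)
        st <- stackPairs(list(pair))
        fw <- pretextForward(model, st, mode = mode)
        as.numeric(fw$p)
    })

#' Binary cross-entropy loss of the pretext task
#'
#' The mean binary cross-entropy
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` over pair
#' probabilities `p` and binary pair labels `y`. Probabilities are clipped
#' to machine-epsilon bounds before the logarithm.
#'
#' @param probabilities numeric vector of pair probabilities in \[0, 1\].
#' @param labels numeric vector of binary pair labels (1 positive,
#'   0 negative).
#' @return Scalar loss; `log(2)` at chance (`p = 0.5` everywhere).
#' @examples
#' pretextLoss(c(0.8, 0.3), c(1, 0))
#' @export
pretextLoss <- function(probabilities, labels) {
    if (length(probabilities) != length(labels))
        stop("probabilities and labels must have equal length")
    if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
        stop("probabilities must lie in [0, 1]")
    if (!all(labels %in% c(0, 1)))
        stop("labels must be binary (0 or 1)")
    eps <- .Machine$double.eps
    p <- pmin(pmax(probabilities, eps), 1 - eps)
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

## ---- vectorised forward/backward over a stacked pair batch -----------

pretextForward <- function(model, st, mode = "train") {
    t <- model@dims$steps
    b <- st$nPairs
    stopIfNot(nrow(st$left) == b * t,
              "pair block size does not match the model's prediction steps")
    X <- rbind(st$left, st$right)
    ef <- encoderForward(model@encoder, X, mode)
    Z <- ef$Z
    nLeft <- nrow(st$left)
    leftRows <- function(k) (seq_len(b) - 1L) * t + k
    Zt <- lapply(seq_len(t), function(k) Z[leftRows(k), , drop = FALSE])
    Zw <- lapply(seq_len(t),
                 function(k) Z[nLeft + leftRows(k), , drop = FALSE])
    gf <- gruForward(model@gru, Zt)
    C <- gf$h
    P <- lapply(seq_len(t), function(k) C %*% model@predictors[[k]])
    sK <- lapply(seq_len(t), function(k) rowSums(P[[k]] * Zw[[k]]))
    s <- Reduce(`+`, sK) / t
    p <- sigmoidAct(s)
    list(p = p, s = s, C = C, P = P, Zt = Zt, Zw = Zw,
         encCache = ef$cache, enc = ef$enc, gruCache = gf$cache,
         nLeft = nLeft, b = b)
}

pretextBackward <- function(model, st, fw) {
    t <- model@dims$steps
    b <- fw$b
    ds <- (fw$p - st$labels) / b          # dL/ds for mean BCE
    dsK <- ds / t
    dC <- matrix(0, b, model@dims$dC)
    gPred <- vector("list", t)
    dZw <- vector("list", t)
    for (k in seq_len(t)) {
        scaled <- fw$Zw[[k]] * dsK
        gPred[[k]] <- crossprod(fw$C, scaled)
        dC <- dC + tcrossprod(scaled, model@predictors[[k]])
        dZw[[k]] <- fw$P[[k]] * dsK
    }
    gb <- gruBackward(model@gru, fw$gruCache, dC)
    dZ <- matrix(0, 2L * fw$nLeft, model@dims$dZ)
    for (k in seq_len(t)) {
        rows <- (seq_len(b) - 1L) * t + k
        dZ[rows, ] <- gb$dZs[[k]]
        dZ[fw$nLeft + rows, ] <- dZw[[k]]
    }
    eb <- encoderBackward(model@encoder, fw$encCache, dZ)
    list(enc = eb$grads, gru = gb$grads, pred = gPred)
}

pretextParams <- function(model) {
    list(enc = model@encoder$par, gru = model@gru, pred = model@predictors)
}

setPretextParams <- function(model, params) {
    model@encoder$par <- params$enc
    model@gru <- params$gru
    model@predictors <- params$pred
    model
}

pairAccuracy <- function(model, sig, lab, nPairs = 128L,
                         positiveFraction = 0.5, seed = NULL) {
    st <- withSeed(seed,
        sampleStackedPairs(sig, lab, nPairs, positiveFraction))
    fw <- pretextForward(model, st, mode = "infer")
    mean((fw$p > 0.5) == (st$labels == 1))
}

#' Train the CPC pretext task
#'
#' Runs mini-batch gradient descent (adaptive moment estimation) on the
#' binary cross-entropy pair loss. Each training epoch draws
#' `iterationsPerEpoch` fresh random pair batches, so every signal epoch is
#' revisited many times; defaults (20 epochs of 1000 iterations) follow the
#' regime under which the pretext task trains to convergence. After each
#' epoch, pair accuracy (probability thresholded at 0.5 against the pair
#' label) is measured on freshly drawn train-set and test-set pairs with
#' the encoder in inference mode.
#'
#' @param train,test [EpochSet-class] training and held-out epochs; pairs
#'   for the accuracy history are drawn from each respectively.
#' @param epochs training epochs (default 20).
#' @param iterationsPerEpoch pair batches per epoch (default 1000).
#' @param batchSize pairs per batch.
#' @param positiveFraction proportion of positive pairs per batch.
#' @param lr learning rate of the adaptive-moment optimiser.
#' @param widths,dZ,dC,steps architecture, see [newPretextModel()].
#' @param evalPairs pairs drawn per accuracy evaluation.
#' @param seed integer seed covering initialisation and batch sampling.
#' @param verbose emit one log line per epoch to standard error.
#' @return List with `model` (a trained [PretextModel-class]) and
#'   `history` (data.frame: epoch, loss, trainAccuracy, testAccuracy).
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 20,
#'                                 epochLength = 64, seed = 1))
#' sp <- splitEpochs(x, 0.25, seed = 1)
#' fit <- trainPretext(sp$train, sp$test, epochs = 1,
#'                     iterationsPerEpoch = 5, batchSize = 4,
#'                     widths = c(16, 8, 8, 8), dZ = 4, dC = 4, seed = 1)
#' fit$history
#' @export
trainPretext <- function(train, test, epochs = 20L,
                         iterationsPerEpoch = 1000L, batchSize = 16L,
                         positiveFraction = 0.5, lr = 1e-3,
                         widths = c(256, 128, 128, 128), dZ = 64, dC = 64,
                         steps = 4L, evalPairs = 128L, seed = 1L,
                         verbose = FALSE) {
    stopIfNot(nEpochs(train) > 0L && nEpochs(test) > 0L,
              "train and test sets must be nonempty")
    epochs <- as.integer(epochs)
    model <- newPretextModel(epochLength(train), widths = widths, dZ = dZ,
                             dC = dC, steps = steps, seed = seed)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       trainAccuracy = numeric(), testAccuracy = numeric())
    if (epochs < 1L) {
        model@config <- c(model@config, list(trainedEpochs = 0L,
                                             iterationsPerEpoch = 0L))
        return(list(model = model, history = hist))
    }
    sigTrain <- SummarizedExperiment::assay(train, "signal")
    labTrain <- epochLabels(train)
    sigTest <- SummarizedExperiment::assay(test, "signal")
    labTest <- epochLabels(test)
    withSeed(seed, {
        params <- pretextParams(model)
        opt <- adamInit(params)
        for (e in seq_len(epochs)) {
            lossSum <- 0
            for (it in seq_len(iterationsPerEpoch)) {
                st <- sampleStackedPairs(sigTrain, labTrain, batchSize,
                                         positiveFraction)
                fw <- pretextForward(model, st, mode = "train")
                model@encoder <- fw$enc   # updated batch-norm buffers
                loss <- pretextLoss(fw$p, st$labels)
                if (!is.finite(loss))
                    stop("pretext training diverged at epoch ", e,
                         " (non-finite loss)")
                lossSum <- lossSum + loss
                grads <- pretextBackward(model, st, fw)
                upd <- adamStep(params, grads, opt, lr)
                params <- upd$params
                opt <- upd$state
                model <- setPretextParams(model, params)
            }
            accTr <- pairAccuracy(model, sigTrain, labTrain, evalPairs,
                                  positiveFraction)
            accTe <- pairAccuracy(model, sigTest, labTest, evalPairs,
                                  positiveFraction)
            hist <- rbind(hist, data.frame(
                epoch = e, loss = lossSum / iterationsPerEpoch,
                trainAccuracy = accTr, testAccuracy = accTe))
            if (verbose)
                logInfo(sprintf(
                    "pretext epoch %d loss=%.4f train_acc=%.3f test_acc=%.3f",
                    e, lossSum / iterationsPerEpoch, accTr, accTe))
        }
    })
    model@config <- c(model@config,
                      list(trainedEpochs = epochs,
                           iterationsPerEpoch = as.integer(iterationsPerEpoch),
                           batchSize = as.integer(batchSize),
                           positiveFraction = positiveFraction, lr = lr))
    list(model = model, history = hist)
}
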