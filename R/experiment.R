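#' Label-fraction experiment: pretrained encoder versus training from
#' scratch
#'
#' For each seed the dataset is split 9:1 into training and held-out test
#' epochs and the contrastive pretext task is trained once on the training
#' half (pretraining is label-free, so one encoder serves every fraction).
#' Then, for each labelled fraction and each mode, a classifier is built --
#' `"pretrained"` starts from the pretext encoder, `"scratch"` trains the
#' same architecture directly -- fine-tuned on the stratified
#' [labelMask()] subset, and evaluated. The headline property this
#' experiment probes: with few labels (e.g. 10%), the pretrained classifier
#' maintains accuracy that plain supervised training cannot.
#'
#' @param dataset an [EpochSet-class].
#' @param fractions labelled fractions in (0, 1]; default the conventional
#'   grid 10%, 30%, 50%, 70%, 100%.
#' @param seeds integer vector; the whole pipeline is repeated per seed.
#' @param testFraction held-out proportion of the 9:1-style split.
#' @param pretext named list of [trainPretext()] arguments (epochs,
#'   iterationsPerEpoch, batchSize, widths, dZ, dC, lr, ...).
#' @param classifier named list of [trainConfig()] arguments.
#' @param arch named list of [buildClassifier()] architecture arguments
#'   (conv1, conv2, widths, dZ).
#' @param evalScope `"heldout"` evaluates on the held-out test split;
#'   `"full"` additionally evaluates on the complete dataset (reported as
#'   separate rows in column `scope`).
#' @param verbose log progress to standard error.
#' @return data.frame with columns fraction, mode, seed, scope, accuracy,
#'   macroF1 (percent).
#' @examples
#' \donttest{
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 30,
#'                                 epochLength = 64, seed = 1))
#' res <- labelFractionExperiment(x, fractions = 1, seeds = 1,
#'     pretext = list(epochs = 1, iterationsPerEpoch = 20, batchSize = 8,
#'                    widths = c(32, 16, 16, 16), dZ = 8, dC = 8),
#'     classifier = list(maxEpochs = 3, batchSize = 8),
#'     arch = list(widths = c(32, 16, 16, 16), dZ = 8))
#' res
#' }
#' @export
labelFractionExperiment <- function(dataset,
                                    fractions = c(0.1, 0.3, 0.5, 0.7, 1),
                                    seeds = 1:3, testFraction = 0.1,
                                    pretext = list(),
                                    classifier = list(),
                                    arch = list(),
                                    evalScope = c("heldout", "full"),
                                    verbose = FALSE) {
    evalScope <- match.arg(evalScope)
    stopIfNot(all(fractions > 0 & fractions <= 1),
              "fractions must lie in (0, 1]")
    k <- nClasses(dataset)
    archDefaults <- list(conv1 = list(filters = 64L, kernel = 3L),
                         conv2 = list(filters = 32L, kernel = 2L),
                         widths = c(256, 128, 128, 128), dZ = 64)
    arch <- utils::modifyList(archDefaults, arch)
    rows <- list()
    for (seed in seeds) {
        sp <- splitEpochs(dataset, testFraction, seed = seed)
        if (verbose) logInfo("seed ", seed, ": pretraining encoder")
        preArgs <- utils::modifyList(
            list(train = sp$train, test = sp$test, seed = seed,
                 widths = arch$widths, dZ = arch$dZ, verbose = verbose),
            pretext)
        pre <- do.call(trainPretext, preArgs)
        for (fraction in fractions) {
            mask <- labelMask(sp$train, fraction, seed = seed)
            labelled <- sp$train[, mask]
            for (mode in c("pretrained", "scratch")) {
                enc <- if (mode == "pretrained") pre$model else NULL
                cls <- buildClassifier(enc, nClasses = k,
                                       inputLength = epochLength(dataset),
                                       conv1 = arch$conv1,
                                       conv2 = arch$conv2,
                                       widths = arch$widths, dZ = arch$dZ,
                                       seed = seed)
                cfgArgs <- utils::modifyList(list(seed = seed), classifier)
                fit <- trainClassifier(cls, labelled, sp$test,
                                       do.call(trainConfig, cfgArgs))
                scopes <- if (evalScope == "full") c("heldout", "full")
                          else "heldout"
                for (scope in scopes) {
                    target <- if (scope == "heldout") sp$test else dataset
                    pred <- classifyEpochs(fit$model, target)
                    rep <- reportMetrics(confusionMatrix(
                        epochLabels(target), pred$classes, nClasses = k,
                        classNames = classNames(dataset)))
                    rows[[length(rows) + 1L]] <- data.frame(
                        fraction = fraction, mode = mode, seed = seed,
                        scope = scope, accuracy = accuracy(rep),
                        macroF1 = macroF1(rep))
                }
                if (verbose)
                    logInfo(sprintf(
                        "seed %d fraction %.2f %s: acc=%.2f%%",
                        seed, fraction, mode,
                        rows[[length(rows)]]$accuracy))
            }
        }
    }
    do.call(rbind, rows)
}
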