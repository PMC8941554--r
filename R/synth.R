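#' Configuration for the synthetic epoch generator
#'
#' Each class is a single sinusoid with a class-specific frequency and
#' amplitude, a phase drawn uniformly per epoch, and additive Gaussian
#' noise. This is the simplest generative family in which epochs of one
#' class share latent structure (their oscillation) while individual epochs
#' differ (phase and noise) -- the premise the contrastive pretext task
#' relies on. Defaults loosely follow EEG conventions: frequencies spanning
#' the delta-to-beta range with amplitude decreasing as frequency rises.
#'
#' @param nClasses number of classes (>= 2).
#' @param nPerClass epochs generated per class.
#' @param epochLength samples per epoch (>= 8); default 3000 mirrors
#'   30 s at 100 Hz.
#' @param samplingRate sampling rate in Hz.
#' @param classFreqs one oscillation frequency (Hz) per class; pairwise
#'   distinct and below the Nyquist limit. Default: 2, 6, 10, 14, 25 Hz for
#'   five classes, extended in 4-Hz steps otherwise.
#' @param classAmps one amplitude per class (arbitrary units).
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; identical configurations reproduce identical
#'   datasets bit for bit.
#'
#' @return A validated `SynthConfig` list.
#' @examples
#' cfg <- synthConfig(nClasses = 3, nPerClass = 10, epochLength = 128)
#' x <- generateEpochs(cfg)
#' @export
synthConfig <- function(nClasses = 5L, nPerClass = 100L, epochLength = 3000L,
                        samplingRate = 100, classFreqs = NULL,
                        classAmps = NULL, noiseSd = 0.3, seed = 1L) {
    nClasses <- as.integer(nClasses)
    nPerClass <- as.integer(nPerClass)
    epochLength <- as.integer(epochLength)
    if (is.na(nClasses) || nClasses < 2L)
        stop("invalid SynthConfig: nClasses must be >= 2")
    if (is.na(nPerClass) || nPerClass < 1L)
        stop("invalid SynthConfig: nPerClass must be >= 1")
    if (is.na(epochLength) || epochLength < 8L)
        stop("invalid SynthConfig: epochLength must be >= 8")
    if (!is.numeric(samplingRate) || samplingRate <= 0)
        stop("invalid SynthConfig: samplingRate must be positive")
    if (is.null(classFreqs)) {
        base <- c(2, 6, 10, 14, 25)
        classFreqs <- if (nClasses <= 5L) base[seq_len(nClasses)]
                      else c(base, 25 + 4 * seq_len(nClasses - 5L))
    }
    if (is.null(classAmps)) {
        base <- c(2, 1.6, 1.2, 1, 0.8)
        classAmps <- if (nClasses <= 5L) base[seq_len(nClasses)]
                     else c(base, rep(0.8, nClasses - 5L))
    }
    if (length(classFreqs) != nClasses)
        stop("invalid SynthConfig: classFreqs must have one entry per class")
    if (anyDuplicated(classFreqs))
        stop("invalid SynthConfig: classFreqs must be pairwise distinct")
    if (any(classFreqs <= 0) || any(classFreqs >= samplingRate / 2))
        stop("invalid SynthConfig: classFreqs must lie in (0, Nyquist)")
    if (length(classAmps) != nClasses)
        stop("invalid SynthConfig: classAmps must have one entry per class")
    if (any(classAmps <= 0))
        stop("invalid SynthConfig: classAmps must be positive")
    if (!is.numeric(noiseSd) || noiseSd < 0)
        stop("invalid SynthConfig: noiseSd must be >= 0")
    structure(list(nClasses = nClasses, nPerClass = nPerClass,
                   epochLength = epochLength, samplingRate = samplingRate,
                   classFreqs = as.numeric(classFreqs),
                   classAmps = as.numeric(classAmps),
                   noiseSd = as.numeric(noiseSd),
                   seed = as.integer(seed)),
              class = "SynthConfig")
}

#' Generate a synthetic multi-class epoch dataset
#'
#' Epoch i of class c is
#' `classAmps[c] * sin(2 * pi * classFreqs[c] * t + phi_i) + eps`,
#' with `phi_i` uniform on `[0, 2*pi)` and `eps` i.i.d. Gaussian noise.
#' Classes are balanced; with `noiseSd = 0` every epoch is an exact sinusoid
#' and the per-epoch dominant spectral peak recovers the class perfectly.
#'
#' @param config a [synthConfig()] object (or arguments for one).
#' @param ... passed to [synthConfig()] when `config` is not supplied.
#' @return An [EpochSet-class] with `nClasses * nPerClass` epochs.
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 5,
#'                                 epochLength = 64))
#' table(epochLabels(x))
#' @export
generateEpochs <- function(config = synthConfig(...), ...) {
    if (!inherits(config, "SynthConfig"))
        stop("config must be created by synthConfig()")
    k <- config$nClasses; n <- config$nPerClass; L <- config$epochLength
    tt <- (seq_len(L) - 1L) / config$samplingRate
    withSeed(config$seed, {
        rows <- vector("list", k)
        for (c in seq_len(k)) {
            phi <- runif(n, 0, 2 * pi)
            m <- config$classAmps[c] *
                sin(outer(phi, 2 * pi * config$classFreqs[c] * tt, "+"))
            if (config$noiseSd > 0)
                m <- m + matrix(rnorm(n * L, sd = config$noiseSd), n, L)
            rows[[c]] <- m
        }
        EpochSet(do.call(rbind, rows),
                 labels = rep(seq_len(k) - 1L, each = n),
                 samplingRate = config$samplingRate)
    })
}

#' Stratified train/test split of an EpochSet
#'
#' Splits epochs into a training and a test set with per-class proportions
#' preserved up to rounding; the two parts are disjoint and exhaustive.
#' The conventional ratio for this family of experiments is 9:1
#' (`testFraction = 0.1`).
#'
#' @param x an [EpochSet-class].
#' @param testFraction proportion of epochs held out per class, in (0, 1).
#' @param seed optional integer seed for the random assignment.
#' @return A list with elements `train` and `test`, both [EpochSet-class].
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 20,
#'                                 epochLength = 64))
#' sp <- splitEpochs(x, testFraction = 0.1, seed = 7)
#' nEpochs(sp$train); nEpochs(sp$test)
#' @export
splitEpochs <- function(x, testFraction = 0.1, seed = NULL) {
    stopIfNot(testFraction > 0 && testFraction < 1,
              "testFraction must lie strictly between 0 and 1")
    lab <- epochLabels(x)
    withSeed(seed, {
        testIdx <- integer()
        for (cl in sort(unique(lab))) {
            idx <- which(lab == cl)
            if (length(idx) < 2L)
                stop("cannot stratify: class ", cl, " has fewer than 2 epochs")
            nTest <- round(testFraction * length(idx))
            nTest <- max(1L, min(length(idx) - 1L, nTest))
            testIdx <- c(testIdx, sampleInt(idx, nTest))
        }
        testIdx <- sort(testIdx)
        list(train = x[, setdiff(seq_along(lab), testIdx)],
             test = x[, testIdx])
    })
}

#' Class-stratified labelled-subset indices
#'
#' Selects a stratified subset of epoch indices of size approximately
#' `labeledFraction * nEpochs(x)` to be treated as labelled during
#' downstream training, as used by label-efficiency experiments over the
#' fraction grid 10%, 30%, 50%, 70%, 100%.
#'
#' @param x an [EpochSet-class].
#' @param labeledFraction proportion of labels to keep, in (0, 1].
#' @param seed optional integer seed.
#' @return Sorted integer vector of 1-based epoch indices.
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 20,
#'                                 epochLength = 64))
#' length(labelMask(x, 0.5, seed = 1))
#' @export
labelMask <- function(x, labeledFraction, seed = NULL) {
    stopIfNot(labeledFraction > 0 && labeledFraction <= 1,
              "labeledFraction must lie in (0, 1]")
    lab <- epochLabels(x)
    if (labeledFraction == 1) return(seq_along(lab))
    withSeed(seed, {
        keep <- integer()
        for (cl in sort(unique(lab))) {
            idx <- which(lab == cl)
            nSel <- round(labeledFraction * length(idx))
            if (nSel < 1L)
                stop("labeledFraction ", labeledFraction,
                     " yields zero labelled epochs for class ", cl)
            keep <- c(keep, sampleInt(idx, nSel))
        }
        sort(keep)
    })
}
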