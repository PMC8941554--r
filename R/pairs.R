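#' Build a positive sample pair
#'
#' Draws 8 distinct epochs of one class uniformly without replacement and
#' splits them 4 left ("training set") / 4 right ("waiting training set").
#' A positive pair carries label 1: all 8 epochs belong to the same
#' category, so the context summarised from the left block should predict
#' latents similar to the right block's.
#'
#' @param x an [EpochSet-class].
#' @param classId 0-based class id to draw from.
#' @param seed optional integer seed.
#' @return A [SamplePair-class] with `pairLabel = 1`.
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 10,
#'                                 epochLength = 64))
#' p <- buildPositivePair(x, classId = 1, seed = 3)
#' pairLabel(p)
#' @export
buildPositivePair <- function(x, classId, seed = NULL) {
    classId <- as.integer(classId)
    idx <- which(epochLabels(x) == classId)
    if (length(idx) < 8L)
        stop("cannot build positive pair: class ", classId, " has only ",
             length(idx), " epochs (8 required)")
    withSeed(seed, {
        pick <- sampleInt(idx, 8L)
        sig <- SummarizedExperiment::assay(x, "signal")
        methods::new("SamplePair",
            left = t(sig[, pick[1:4], drop = FALSE]),
            right = t(sig[, pick[5:8], drop = FALSE]),
            pairLabel = 1L, leftClass = classId, rightClass = classId,
            leftIndex = pick[1:4], rightIndex = pick[5:8])
    })
}

#' Build a negative sample pair
#'
#' The left block holds 4 distinct epochs of one class and the right block
#' 4 distinct epochs of a different class; within each block epochs share a
#' category, but left and right categories differ, so the pair carries
#' label 0.
#'
#' @param x an [EpochSet-class].
#' @param classA 0-based class id of the left block.
#' @param classB 0-based class id of the right block; must differ from
#'   `classA`.
#' @param seed optional integer seed.
#' @return A [SamplePair-class] with `pairLabel = 0`.
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 10,
#'                                 epochLength = 64))
#' p <- buildNegativePair(x, 0, 1, seed = 3)
#' pairLabel(p)
#' @export
buildNegativePair <- function(x, classA, classB, seed = NULL) {
    classA <- as.integer(classA); classB <- as.integer(classB)
    if (classA == classB)
        stop("negative pair requires two different classes (got ",
             classA, " twice)")
    lab <- epochLabels(x)
    idxA <- which(lab == classA); idxB <- which(lab == classB)
    if (length(idxA) < 4L)
        stop("cannot build negative pair: class ", classA, " has only ",
             length(idxA), " epochs (4 required)")
    if (length(idxB) < 4L)
        stop("cannot build negative pair: class ", classB, " has only ",
             length(idxB), " epochs (4 required)")
    withSeed(seed, {
        pickA <- sampleInt(idxA, 4L)
        pickB <- sampleInt(idxB, 4L)
        sig <- SummarizedExperiment::assay(x, "signal")
        methods::new("SamplePair",
            left = t(sig[, pickA, drop = FALSE]),
            right = t(sig[, pickB, drop = FALSE]),
            pairLabel = 0L, leftClass = classA, rightClass = classB,
            leftIndex = pickA, rightIndex = pickB)
    })
}

#' Sample a shuffled batch of positive and negative pairs
#'
#' Draws `round(positiveFraction * batchSize)` positive pairs (class drawn
#' uniformly over classes with at least 8 epochs) and the remainder as
#' negative pairs (ordered class pair drawn uniformly over unequal pairs
#' with at least 4 epochs each), then shuffles the batch. Epochs recur
#' freely across pairs -- each training epoch is revisited many times over
#' an epoch of pretext training -- but never within one pair.
#'
#' @param x an [EpochSet-class].
#' @param batchSize number of pairs (>= 2).
#' @param positiveFraction proportion of positive pairs; the default 0.5
#'   makes chance-level loss `ln 2` and chance pair accuracy 50%.
#' @param seed optional integer seed.
#' @return List of [SamplePair-class] objects of length `batchSize`.
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 10,
#'                                 epochLength = 64))
#' batch <- pairBatch(x, batchSize = 4, seed = 1)
#' vapply(batch, pairLabel, integer(1))
#' @export
pairBatch <- function(x, batchSize, positiveFraction = 0.5, seed = NULL) {
    batchSize <- as.integer(batchSize)
    stopIfNot(batchSize >= 2L, "batchSize must be >= 2")
    stopIfNot(positiveFraction >= 0 && positiveFraction <= 1,
              "positiveFraction must lie in [0, 1]")
    lab <- epochLabels(x)
    counts <- table(lab)
    posClasses <- as.integer(names(counts)[counts >= 8L])
    negClasses <- as.integer(names(counts)[counts >= 4L])
    nPos <- as.integer(round(positiveFraction * batchSize))
    if (nPos > 0L && length(posClasses) == 0L)
        stop("no class has the 8 epochs required for a positive pair")
    if (nPos < batchSize && length(negClasses) < 2L)
        stop("fewer than 2 classes have the 4 epochs required for a ",
             "negative pair")
    withSeed(seed, {
        recs <- samplePairIndices(lab, batchSize, nPos,
                                  posClasses, negClasses)
        sig <- SummarizedExperiment::assay(x, "signal")
        lapply(recs, function(r)
            methods::new("SamplePair",
                left = t(sig[, r$left, drop = FALSE]),
                right = t(sig[, r$right, drop = FALSE]),
                pairLabel = r$y,
                leftClass = r$leftClass, rightClass = r$rightClass,
                leftIndex = r$left, rightIndex = r$right))
    })
}

# draw the index structure of a shuffled pair batch: classes uniform over
# the eligible sets, epochs uniform without replacement within a pair
samplePairIndices <- function(lab, batchSize, nPos, posClasses,
                              negClasses) {
    byClass <- split(seq_along(lab), lab)
    classOf <- function(cl) byClass[[as.character(cl)]]
    recs <- vector("list", batchSize)
    for (i in seq_len(nPos)) {
        cl <- sampleInt(posClasses, 1L)
        pick <- sampleInt(classOf(cl), 8L)
        recs[[i]] <- list(left = pick[1:4], right = pick[5:8],
                          leftClass = cl, rightClass = cl, y = 1L)
    }
    for (i in seq_len(batchSize - nPos)) {
        ab <- sampleInt(negClasses, 2L)
        recs[[nPos + i]] <- list(left = sampleInt(classOf(ab[1L]), 4L),
                                 right = sampleInt(classOf(ab[2L]), 4L),
                                 leftClass = ab[1L], rightClass = ab[2L],
                                 y = 0L)
    }
    recs[sample.int(batchSize)]
}

# fast path for the training loop: draws the same pair structure as
# pairBatch() but materialises the stacked arrays directly (pair-major:
# pair 1 rows 1..4, pair 2 rows 5..8, ...) without SamplePair objects
sampleStackedPairs <- function(sig, lab, batchSize, positiveFraction) {
    counts <- tabulate(lab + 1L)
    classes <- which(counts > 0L) - 1L
    posClasses <- classes[counts[classes + 1L] >= 8L]
    negClasses <- classes[counts[classes + 1L] >= 4L]
    nPos <- as.integer(round(positiveFraction * batchSize))
    if (nPos > 0L && length(posClasses) == 0L)
        stop("no class has the 8 epochs required for a positive pair")
    if (nPos < batchSize && length(negClasses) < 2L)
        stop("fewer than 2 classes have the 4 epochs required for a ",
             "negative pair")
    recs <- samplePairIndices(lab, batchSize, nPos, posClasses,
                              negClasses)
    leftIdx <- unlist(lapply(recs, `[[`, "left"), use.names = FALSE)
    rightIdx <- unlist(lapply(recs, `[[`, "right"), use.names = FALSE)
    list(left = t(sig[, leftIdx, drop = FALSE]),
         right = t(sig[, rightIdx, drop = FALSE]),
         labels = vapply(recs, function(r) as.numeric(r$y), numeric(1)),
         nPairs = batchSize)
}

# stack a list of SamplePair objects into the same dense-array layout
stackPairs <- function(pairs) {
    b <- length(pairs)
    left <- do.call(rbind, lapply(pairs, function(p) p@left))
    right <- do.call(rbind, lapply(pairs, function(p) p@right))
    list(left = left, right = right,
         labels = vapply(pairs, function(p) as.numeric(p@pairLabel),
                         numeric(1)),
         nPairs = b)
}
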