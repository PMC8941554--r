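checkPairInvariants <- function(p, labels) {
    expect_equal(nrow(p@left), 4)
    expect_equal(nrow(p@right), 4)
    idx <- c(p@leftIndex, p@rightIndex)
    expect_equal(anyDuplicated(idx), 0)
    expect_true(all(labels[p@leftIndex] == p@leftClass))
    expect_true(all(labels[p@rightIndex] == p@rightClass))
    if (p@pairLabel == 1L) expect_equal(p@leftClass, p@rightClass)
    else expect_true(p@leftClass != p@rightClass)
}

test_that("positive pairs hold 8 distinct epochs of one category", {
    x <- tinySet(nClasses = 5, nPerClass = 10)
    lab <- epochLabels(x)
    p <- buildPositivePair(x, classId = 2, seed = 1)
    expect_s4_class(p, "SamplePair")
    expect_equal(pairLabel(p), 1L)
    expect_true(all(lab[c(p@leftIndex, p@rightIndex)] == 2L))
    checkPairInvariants(p, lab)
    # block content matches the source epochs
    expect_equal(p@left, epochMatrix(x)[p@leftIndex, , drop = FALSE])
})

test_that("a class with exactly 8 epochs is drawn in full", {
    x <- EpochSet(matrix(rnorm(10 * 16), 10),
                  labels = c(rep(0L, 8), 1L, 1L))
    p <- buildPositivePair(x, 0, seed = 4)
    expect_setequal(c(p@leftIndex, p@rightIndex), 1:8)
    expect_error(buildPositivePair(x, 1), "class 1")
})

test_that("negative pairs keep categories homogeneous within blocks but distinct across", {
    x <- tinySet(nClasses = 5, nPerClass = 10)
    lab <- epochLabels(x)
    p <- buildNegativePair(x, 0, 3, seed = 2)
    expect_equal(pairLabel(p), 0L)
    expect_true(all(lab[p@leftIndex] == 0L))
    expect_true(all(lab[p@rightIndex] == 3L))
    expect_error(buildNegativePair(x, 2, 2), "different classes")
    y <- EpochSet(matrix(rnorm(6 * 8), 6), labels = c(0L, 0L, 0L, 0L, 1L, 1L))
    expect_error(buildNegativePair(y, 0, 1), "class 1")
})

test_that("positive-pair epoch sampling is uniform within the class", {
    # frequency-count oracle: every eligible epoch of the class should be
    # drawn equally often across many pairs (chi-square on counts)
    x <- tinySet(nClasses = 2, nPerClass = 12)
    withr::with_seed(42, {
        counts <- integer(nEpochs(x))
        for (i in 1:4000) {
            p <- buildPositivePair(x, 0)
            idx <- c(p@leftIndex, p@rightIndex)
            counts[idx] <- counts[idx] + 1L
        }
    })
    eligible <- which(epochLabels(x) == 0L)
    expect_true(all(counts[-eligible] == 0))
    chi <- stats::chisq.test(counts[eligible])
    expect_gt(chi$p.value, 0.001)
})

test_that("negative class pairs cover ordered unequal pairs near-uniformly", {
    x <- tinySet(nClasses = 4, nPerClass = 8)
    withr::with_seed(43, {
        keys <- character(4000)
        for (i in 1:4000) {
            b <- pairBatch(x, 2, positiveFraction = 0)
            keys[i] <- paste(b[[1]]@leftClass, b[[1]]@rightClass,
                             sep = "-")
        }
    })
    tab <- table(keys)
    expect_equal(length(tab), 12)  # all 4*3 ordered unequal pairs occur
    chi <- stats::chisq.test(as.vector(tab))
    expect_gt(chi$p.value, 0.001)
})

test_that("batches honour composition, shuffling and determinism", {
    x <- tinySet(nClasses = 3, nPerClass = 12)
    lab <- epochLabels(x)
    b <- pairBatch(x, batchSize = 32, positiveFraction = 0.5, seed = 9)
    expect_length(b, 32)
    labs <- vapply(b, pairLabel, integer(1))
    expect_equal(sum(labs), 16)
    expect_equal(mean(labs), 0.5)
    for (p in b) checkPairInvariants(p, lab)
    b2 <- pairBatch(x, batchSize = 32, positiveFraction = 0.5, seed = 9)
    expect_equal(lapply(b, function(p) p@leftIndex),
                 lapply(b2, function(p) p@leftIndex))
    expect_equal(vapply(b2, pairLabel, integer(1)), labs)
    # rounding of the positive share
    b3 <- pairBatch(x, batchSize = 5, positiveFraction = 0.5, seed = 1)
    expect_equal(sum(vapply(b3, pairLabel, integer(1))), 2)
})

test_that("the stacked fast path draws the same pairs as pairBatch", {
    x <- tinySet(nClasses = 3, nPerClass = 12)
    sig <- SummarizedExperiment::assay(x, "signal")
    lab <- epochLabels(x)
    b <- pairBatch(x, 8, seed = 77)
    st2 <- withr::with_seed(77, EpochCPC:::sampleStackedPairs(sig, lab, 8, 0.5))
    st1 <- EpochCPC:::stackPairs(b)
    expect_equal(st1$left, st2$left)
    expect_equal(st1$right, st2$right)
    expect_equal(st1$labels, st2$labels)
})

test_that("pair invariants hold over many random datasets and batches", {
    # property sweep: random class counts, sizes and mixes
    withr::with_seed(123, {
        for (rep in 1:25) {
            k <- sample(2:5, 1)
            x <- generateEpochs(synthConfig(
                nClasses = k, nPerClass = sample(8:15, 1),
                epochLength = 16,
                classFreqs = 2 + 3 * (seq_len(k) - 1),
                classAmps = rep(1, k), noiseSd = 0.5,
                seed = sample.int(1e6, 1)))
            lab <- epochLabels(x)
            batch <- pairBatch(x, sample(2:10, 1), runif(1))
            for (p in batch) checkPairInvariants(p, lab)
        }
    })
    succeed()
})
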