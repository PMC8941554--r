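test_that("generated datasets have the forced shape and balanced labels", {
    x <- generateEpochs(synthConfig(nClasses = 5, nPerClass = 100,
                                    epochLength = 300, seed = 2))
    expect_s4_class(x, "EpochSet")
    expect_equal(nEpochs(x), 500)
    expect_equal(epochLength(x), 300)
    expect_equal(as.vector(table(epochLabels(x))), rep(100, 5))
    expect_true(all(epochLabels(x) %in% 0:4))
})

test_that("identical configurations reproduce identical datasets", {
    cfg <- synthConfig(nClasses = 3, nPerClass = 8, epochLength = 64,
                       noiseSd = 0.4, seed = 99)
    x1 <- generateEpochs(cfg)
    x2 <- generateEpochs(cfg)
    expect_identical(epochMatrix(x1), epochMatrix(x2))
    expect_identical(epochLabels(x1), epochLabels(x2))
    x3 <- generateEpochs(synthConfig(nClasses = 3, nPerClass = 8,
                                     epochLength = 64, noiseSd = 0.4,
                                     seed = 100))
    expect_false(identical(epochMatrix(x1), epochMatrix(x3)))
})

test_that("noiseless classes are perfectly separable by spectral peak", {
    # independent oracle: discrete Fourier transform argmax per epoch,
    # mapped to the nearest class frequency
    cfg <- synthConfig(nClasses = 5, nPerClass = 20, epochLength = 256,
                       samplingRate = 100, noiseSd = 0, seed = 3)
    x <- generateEpochs(cfg)
    m <- epochMatrix(x)
    n <- ncol(m)
    freqs <- (seq_len(n %/% 2)) * cfg$samplingRate / n
    recovered <- apply(m, 1, function(ep) {
        sp <- Mod(stats::fft(ep))[2:(n %/% 2 + 1)]
        peak <- freqs[which.max(sp)]
        which.min(abs(cfg$classFreqs - peak)) - 1L
    })
    expect_equal(recovered, epochLabels(x))
})

test_that("invalid configurations are rejected naming the field", {
    expect_error(synthConfig(nClasses = 1), "nClasses")
    expect_error(synthConfig(epochLength = 4), "epochLength")
    expect_error(synthConfig(nClasses = 3, classFreqs = c(2, 2, 6)),
                 "distinct")
    expect_error(synthConfig(nClasses = 2, classFreqs = c(10, 80),
                             samplingRate = 100), "Nyquist")
    expect_error(synthConfig(noiseSd = -1), "noiseSd")
    expect_error(generateEpochs(list(nClasses = 2)), "synthConfig")
})

test_that("stratified split preserves class shares and partitions the set", {
    x <- generateEpochs(synthConfig(nClasses = 5, nPerClass = 100,
                                    epochLength = 32, seed = 4))
    sp <- splitEpochs(x, testFraction = 0.1, seed = 5)
    expect_equal(nEpochs(sp$train), 450)
    expect_equal(nEpochs(sp$test), 50)
    expect_equal(as.vector(table(epochLabels(sp$test))), rep(10, 5))
    expect_equal(as.vector(table(epochLabels(sp$train))), rep(90, 5))
    # union of both halves restores the dataset exactly
    merged <- rbind(epochMatrix(sp$train), epochMatrix(sp$test))
    ord <- order(c(rowSums(epochMatrix(sp$train)) * 0,
                   rowSums(epochMatrix(sp$test)) * 0 + 1))
    expect_equal(sort(c(epochLabels(sp$train), epochLabels(sp$test))),
                 sort(epochLabels(x)))
    key <- function(m) sort(apply(m, 1, function(r) paste(r[1:4],
                                                          collapse = ",")))
    expect_equal(key(merged), key(epochMatrix(x)))
})

test_that("splitting fails when a class cannot be stratified", {
    x <- EpochSet(matrix(rnorm(3 * 16), 3), labels = c(0L, 0L, 1L))
    expect_error(splitEpochs(x, 0.5), "class 1")
})

test_that("label masks are stratified, reproducible, and reject empty classes", {
    x <- generateEpochs(synthConfig(nClasses = 5, nPerClass = 100,
                                    epochLength = 32, seed = 6))
    expect_identical(labelMask(x, 1.0), seq_len(500))
    m <- labelMask(x, 0.1, seed = 8)
    expect_length(m, 50)
    expect_equal(as.vector(table(epochLabels(x)[m])), rep(10, 5))
    expect_identical(m, labelMask(x, 0.1, seed = 8))
    expect_error(labelMask(x, 0.001), "zero labelled")
    expect_error(labelMask(x, 0), "labeledFraction")
    # the canonical experiment grid is valid on a balanced 500-epoch set
    for (f in c(0.1, 0.3, 0.5, 0.7, 1.0))
        expect_length(labelMask(x, f, seed = 1), round(500 * f))
})

test_that("train/test split and label mask never share epochs", {
    x <- tinySet(nClasses = 4, nPerClass = 20)
    for (seed in 1:5) {
        sp <- splitEpochs(x, 0.2, seed = seed)
        mask <- labelMask(sp$train, 0.5, seed = seed)
        # the mask indexes the training set only; reconstruct raw epochs
        # and verify none coincides with a test epoch
        trainRows <- epochMatrix(sp$train)[mask, , drop = FALSE]
        testRows <- epochMatrix(sp$test)
        keys <- function(m) apply(m, 1, function(r)
            paste(format(r, digits = 15), collapse = ","))
        expect_length(intersect(keys(trainRows), keys(testRows)), 0)
    }
})
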