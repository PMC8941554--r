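test_that("replicated inputs produce four identical rows and identical latents", {
    r <- replicateInput(c(1, 2, 3))
    expect_equal(dim(r), c(4, 3))
    expect_true(all(r[1, ] == r[2, ] & r[2, ] == r[3, ] & r[3, ] == r[4, ]))
    expect_equal(replicateInput(numeric(5)), matrix(0, 4, 5))
    m <- tinyModel()
    z <- encodeEpochs(replicateInput(rnorm(32)), m)
    expect_equal(z[1, ], z[2, ])
    expect_equal(z[1, ], z[4, ])
})

test_that("classifier assembly enforces distinct convolution layers and class count", {
    m <- tinyModel()
    cls <- buildClassifier(m, nClasses = 5, seed = 1)
    expect_s4_class(cls, "ClassifierModel")
    out <- classifyEpochs(cls, matrix(rnorm(3 * 32), 3))
    expect_equal(ncol(out$probabilities), 5)
    cls3 <- buildClassifier(m, nClasses = 3, seed = 1)
    expect_equal(ncol(classifyEpochs(cls3,
                                     matrix(rnorm(32), 1))$probabilities),
                 3)
    expect_error(buildClassifier(m, nClasses = 5,
                                 conv1 = list(filters = 32, kernel = 2),
                                 conv2 = list(filters = 32, kernel = 2)),
                 "differ")
    expect_error(buildClassifier(m, nClasses = 1), "nClasses")
    expect_error(buildClassifier(NULL, nClasses = 3), "inputLength")
})

test_that("predictions are normalised, argmax-consistent and deterministic", {
    cls <- buildClassifier(NULL, nClasses = 4, inputLength = 32,
                           widths = c(16, 8, 8, 8), dZ = 6, seed = 2)
    X <- matrix(rnorm(6 * 32), 6)
    out <- classifyEpochs(cls, X)
    expect_equal(rowSums(out$probabilities), rep(1, 6), tolerance = 1e-6)
    expect_true(all(out$probabilities >= 0))
    expect_equal(out$classes,
                 apply(out$probabilities, 1, which.max) - 1L)
    expect_identical(out$probabilities,
                     classifyEpochs(cls, X)$probabilities)
    expect_error(classifyEpochs(cls, matrix(rnorm(10), 1)),
                 "does not match")
})

test_that("analytic classifier gradients match finite differences", {
    x <- tinySet(nClasses = 3, nPerClass = 8, epochLength = 16)
    cls <- buildClassifier(NULL, nClasses = 3, inputLength = 16,
                           conv1 = list(filters = 5, kernel = 3),
                           conv2 = list(filters = 4, kernel = 2),
                           widths = c(8, 6, 6, 6), dZ = 4, seed = 3)
    X <- epochMatrix(x)[1:8, ]
    y <- epochLabels(x)[1:8]
    lossOf <- function(params) {
        m <- EpochCPC:::setClassifierParams(cls, params)
        fw <- EpochCPC:::classifierForward(m, X, mode = "train")
        EpochCPC:::crossEntropy(fw$P, y)
    }
    params <- EpochCPC:::classifierParams(cls)
    fw <- EpochCPC:::classifierForward(cls, X, mode = "train")
    analytic <- EpochCPC:::classifierBackward(cls, fw, y)[names(params)]
    analytic <- flatten(analytic)
    idx <- withr::with_seed(17, sort(sample(length(analytic), 80)))
    numeric <- numericalGradient(lossOf, params, idx)
    relErr <- abs(numeric - analytic[idx]) /
        pmax(1e-6, abs(numeric) + abs(analytic[idx]))
    expect_lt(max(relErr), 1e-4)
})

test_that("plateau schedule follows the reduce-to-a-third rule", {
    # strictly improving validation loss keeps the initial rate
    expect_equal(lrPlateauSchedule(c(1, 0.9, 0.8, 0.7)),
                 rep(0.001, 4))
    # flat epochs 3-4 trigger the reduction at epoch 5
    lrs <- lrPlateauSchedule(c(1, 0.9, 0.9, 0.9, 0.8))
    expect_equal(lrs, c(0.001, 0.001, 0.001, 0.001, 0.001 / 3))
    # rate halts at the floor
    lrs <- lrPlateauSchedule(rep(1, 60), minLr = 1e-6)
    expect_equal(min(lrs), 1e-6)
    expect_equal(lrs[60], 1e-6)
})

test_that("plateau schedule matches an independent step-by-step simulator", {
    # reference simulator written directly from the rule: track the best
    # loss; after `patience` consecutive non-improving epochs multiply the
    # rate by `factor`, bounded below by the floor
    referenceSchedule <- function(losses, lr0 = 0.001, factor = 1 / 3,
                                  patience = 2, minDelta = 1e-4,
                                  minLr = 1e-6) {
        lr <- lr0; best <- Inf; bad <- 0
        out <- numeric(length(losses))
        for (i in seq_along(losses)) {
            out[i] <- lr
            if (losses[i] < best - minDelta) {
                best <- losses[i]; bad <- 0
            } else {
                bad <- bad + 1
                if (bad == patience) {
                    lr <- max(minLr, lr * factor)
                    bad <- 0
                }
            }
        }
        out
    }
    withr::with_seed(29, {
        for (rep in 1:200) {
            n <- sample(3:40, 1)
            losses <- round(cumsum(rnorm(n, -0.02, 0.2)) + 2, 3)
            expect_identical(lrPlateauSchedule(losses),
                             referenceSchedule(losses))
        }
    })
})

test_that("training applies the scheduled rate and records history", {
    x <- tinySet(nClasses = 2, nPerClass = 20, epochLength = 16)
    sp <- splitEpochs(x, 0.25, seed = 3)
    cls <- buildClassifier(NULL, nClasses = 2, inputLength = 16,
                           widths = c(8, 6, 6, 6), dZ = 4, seed = 3)
    fit <- trainClassifier(cls, sp$train, sp$test,
                           trainConfig(maxEpochs = 6, batchSize = 8,
                                       seed = 3))
    h <- fit$history
    expect_equal(nrow(h), 6)
    expect_true(all(is.finite(h$trainLoss)))
    expect_true(all(is.finite(h$valLoss)))
    # the recorded rates replay exactly from the recorded validation
    # losses (lr at epoch e depends on losses before e)
    expect_equal(h$lr, lrPlateauSchedule(h$valLoss))
    expect_error(trainClassifier(cls, sp$train[, 0], sp$test,
                                 trainConfig(maxEpochs = 1)),
                 "empty")
})

test_that("classifier checkpoints round-trip and keep predictions", {
    cls <- buildClassifier(NULL, nClasses = 3, inputLength = 16,
                           widths = c(8, 6, 6, 6), dZ = 4, seed = 5)
    f <- withr::local_tempfile(fileext = ".rds")
    saveClassifier(cls, f)
    cls2 <- loadClassifier(f)
    X <- matrix(rnorm(4 * 16), 4)
    expect_identical(classifyEpochs(cls, X)$probabilities,
                     classifyEpochs(cls2, X)$probabilities)
    expect_error(loadClassifier(file.path(tempdir(), "none.rds")),
                 "not found")
})
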