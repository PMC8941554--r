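test_that("encoding is deterministic in inference mode and shape-checked", {
    m <- tinyModel()
    ep <- rnorm(32)
    z1 <- encodeEpochs(ep, m)
    z2 <- encodeEpochs(ep, m)
    expect_identical(z1, z2)
    expect_equal(ncol(z1), 6)
    expect_equal(nrow(z1), 1)
    expect_error(encodeEpochs(rnorm(16), m), "does not match")
    # batch encoding agrees with row-by-row encoding in infer mode
    X <- matrix(rnorm(3 * 32), 3)
    zb <- encodeEpochs(X, m)
    for (i in 1:3)
        expect_equal(zb[i, ], as.vector(encodeEpochs(X[i, ], m)))
})

test_that("contextualize returns the GRU final state with fixed-point and determinism properties", {
    m <- tinyModel()
    z <- matrix(rnorm(4 * 6), 4)
    c1 <- contextualize(z, m)
    expect_length(c1, 5)
    expect_identical(c1, contextualize(z, m))
    expect_error(contextualize(z[1:3, ], m), "4 steps")
    # zero latents with zero-weight GRU give a zero context (fixed point)
    m0 <- m
    m0@gru <- EpochCPC:::treeZero(m0@gru)
    expect_equal(contextualize(matrix(0, 4, 6), m0), rep(0, 5))
})

test_that("pair probability follows the inner-product scoring closed forms", {
    x <- tinySet()
    m <- tinyModel()
    p <- buildPositivePair(x, 0, seed = 1)
    # zero prediction maps force every score to 0, hence p = 0.5 exactly
    m0 <- m
    m0@predictors <- lapply(m0@predictors, function(w) w * 0)
    expect_equal(pairProbability(p, m0), 0.5)
    # a generic model gives a probability strictly inside (0, 1)
    pr <- pairProbability(p, m)
    expect_true(pr > 0 && pr < 1)
    # mean score of 1 maps to sigmoid(1)
    expect_equal(stats::plogis(1), 0.7310586, tolerance = 1e-6)
    # manual recomputation of the scoring head from its pieces
    zL <- encodeEpochs(p@left, m)
    zR <- encodeEpochs(p@right, m)
    cc <- contextualize(zL, m)
    sK <- vapply(1:4, function(k)
        sum((cc %*% m@predictors[[k]]) * zR[k, ]), numeric(1))
    expect_equal(pr, as.numeric(stats::plogis(mean(sK))), tolerance = 1e-10)
})

test_that("pretext loss matches its closed forms and brute-force oracle", {
    expect_equal(pretextLoss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
    expect_equal(pretextLoss(c(0.8, 0.3), c(1, 0)),
                 -0.5 * (log(0.8) + log(0.7)), tolerance = 1e-12)
    expect_lt(pretextLoss(c(1, 0), c(1, 0)), 1e-10)
    expect_error(pretextLoss(c(0.5), c(1, 0)), "equal length")
    expect_error(pretextLoss(c(1.2, 0.5), c(1, 0)), "\\[0, 1\\]")
    # element-wise oracle on random vectors
    withr::with_seed(5, {
        for (rep in 1:20) {
            n <- sample(1:200, 1)
            p <- runif(n)
            y <- rbinom(n, 1, 0.5)
            oracle <- -sum(vapply(seq_len(n), function(i)
                y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]),
                numeric(1))) / n
            expect_equal(pretextLoss(p, y), oracle, tolerance = 1e-12)
        }
    })
})

test_that("analytic pretext gradients match finite differences", {
    x <- tinySet(nClasses = 3, nPerClass = 12, epochLength = 16)
    model <- newPretextModel(16, widths = c(8, 6, 6, 6), dZ = 4, dC = 5,
                             seed = 7)
    st <- EpochCPC:::stackPairs(pairBatch(x, 6, seed = 3))
    lossOf <- function(params) {
        m <- EpochCPC:::setPretextParams(model, params)
        fw <- EpochCPC:::pretextForward(m, st, mode = "train")
        pretextLoss(fw$p, st$labels)
    }
    params <- EpochCPC:::pretextParams(model)
    fw <- EpochCPC:::pretextForward(model, st, mode = "train")
    analytic <- flatten(EpochCPC:::pretextBackward(model, st, fw))
    expect_length(analytic, length(flatten(params)))
    idx <- withr::with_seed(11, sort(sample(length(analytic), 80)))
    numeric <- numericalGradient(lossOf, params, idx)
    relErr <- abs(numeric - analytic[idx]) /
        pmax(1e-6, abs(numeric) + abs(analytic[idx]))
    expect_lt(max(relErr), 1e-4)
})

test_that("an untrained zero-predictor model sits at chance loss ln 2", {
    x <- tinySet(nClasses = 3, nPerClass = 12)
    m <- tinyModel()
    m@predictors <- lapply(m@predictors, function(w) w * 0)
    batch <- pairBatch(x, 32, positiveFraction = 0.5, seed = 21)
    st <- EpochCPC:::stackPairs(batch)
    fw <- EpochCPC:::pretextForward(m, st, mode = "infer")
    expect_equal(fw$p, rep(0.5, 32))
    expect_equal(pretextLoss(fw$p, st$labels), log(2))
})

test_that("requesting zero training epochs yields an untrained model and empty history", {
    x <- tinySet(nClasses = 2, nPerClass = 10, epochLength = 16)
    sp <- splitEpochs(x, 0.2, seed = 1)
    fit <- trainPretext(sp$train, sp$test, epochs = 0,
                        widths = c(8, 6, 6, 6), dZ = 4, dC = 4, seed = 1)
    expect_s4_class(fit$model, "PretextModel")
    expect_equal(nrow(fit$history), 0)
})

test_that("short training on separable data reduces loss and separates pair probabilities", {
    x <- generateEpochs(synthConfig(nClasses = 3, nPerClass = 40,
                                    epochLength = 32,
                                    classFreqs = c(3, 9, 15),
                                    classAmps = c(1.4, 1.1, 0.9),
                                    noiseSd = 0.05, seed = 31))
    sp <- splitEpochs(x, 0.2, seed = 31)
    fit <- trainPretext(sp$train, sp$test, epochs = 3,
                        iterationsPerEpoch = 60, batchSize = 8,
                        widths = c(32, 16, 16, 16), dZ = 8, dC = 8,
                        seed = 31)
    h <- fit$history
    expect_true(all(is.finite(h$loss)))
    expect_lt(h$loss[3], h$loss[1])
    expect_lt(h$loss[3], log(2))
    # positive pairs score higher than negative pairs after training
    pos <- vapply(1:20, function(i)
        pairProbability(buildPositivePair(sp$test, i %% 3, seed = i),
                        fit$model), numeric(1))
    neg <- vapply(1:20, function(i)
        pairProbability(buildNegativePair(sp$test, i %% 3,
                                          (i + 1) %% 3, seed = i),
                        fit$model), numeric(1))
    expect_gt(mean(pos), mean(neg))
    # same-class latents are closer (cosine) than cross-class latents
    z <- encodeEpochs(sp$test, fit$model)
    lab <- epochLabels(sp$test)
    zn <- z / sqrt(rowSums(z^2))
    cs <- tcrossprod(zn)
    same <- outer(lab, lab, "==") & upper.tri(cs)
    diff <- outer(lab, lab, "!=") & upper.tri(cs)
    expect_gt(mean(cs[same]), mean(cs[diff]))
})

test_that("encoder checkpoints round-trip bit-exactly", {
    m <- tinyModel(seed = 13)
    f <- withr::local_tempfile(fileext = ".rds")
    saveEncoder(m, f)
    enc <- loadEncoder(f)
    probe <- matrix(rnorm(2 * 32), 2)
    expect_identical(encodeEpochs(probe, enc), encodeEpochs(probe, m))
    expect_identical(enc$par, m@encoder$par)
    expect_error(loadEncoder(file.path(tempdir(), "absent.rds")),
                 "not found")
    junk <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(a = 1), junk)
    expect_error(loadEncoder(junk), "not an encoder checkpoint")
    # the downstream classifier consumes the encoder alone (GRU and
    # predictor maps are discarded with the pretext task)
    cls <- buildClassifier(enc, nClasses = 3, seed = 1)
    expect_true(cls@config$pretrainedEncoder)
    expect_identical(cls@encoder$par, m@encoder$par)
})
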