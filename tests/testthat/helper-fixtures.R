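# small fixtures and utilities shared across the suite

tinySet <- function(nClasses = 3, nPerClass = 12, epochLength = 32,
                    noiseSd = 0.2, seed = 101) {
    generateEpochs(synthConfig(
        nClasses = nClasses, nPerClass = nPerClass,
        epochLength = epochLength,
        classFreqs = 2 + 4 * (seq_len(nClasses) - 1),
        classAmps = seq(1.5, 0.8, length.out = nClasses),
        noiseSd = noiseSd, seed = seed))
}

tinyModel <- function(inputLength = 32, seed = 7) {
    newPretextModel(inputLength, widths = c(16, 8, 8, 8), dZ = 6, dC = 5,
                    seed = seed)
}

# the printed five-stage sleep confusion matrix shipped with the package
sleepConfusion <- function() {
    f <- system.file("extdata", "sleep_stage_confusion.tsv",
                     package = "EpochCPC")
    as.matrix(read.table(f, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE))
}

sleepTotals <- function() {
    f <- system.file("extdata", "sleep_stage_totals.tsv",
                     package = "EpochCPC")
    read.table(f, sep = "\t", header = TRUE)
}

# flatten/unflatten parameter trees for finite-difference gradient checks
flatten <- function(p) unlist(p, use.names = FALSE)
unflatten <- function(p, v) utils::relist(v, p)

numericalGradient <- function(lossFn, params, idx, eps = 1e-6) {
    fa <- flatten(params)
    vapply(idx, function(i) {
        up <- fa; up[i] <- up[i] + eps
        dn <- fa; dn[i] <- dn[i] - eps
        (lossFn(unflatten(params, up)) - lossFn(unflatten(params, dn))) /
            (2 * eps)
    }, numeric(1))
}
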