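# internal helpers

# round half away from zero, as conventional in printed clinical tables
# (base round() rounds half to even)
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# run expr with a locally seeded RNG when seed is given, restoring the
# caller's RNG state afterwards; with seed = NULL the global stream is used
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# sample() without its size-1 surprise (sample(5L, 1) != sample from {5})
sampleInt <- function(x, size, replace = FALSE) {
    x[sample.int(length(x), size, replace = replace)]
}

logInfo <- function(...) {
    message("[epochcpc] ", ...)
}

stopIfNot <- function(cond, ...) {
    if (!cond) stop(..., call. = FALSE)
}
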