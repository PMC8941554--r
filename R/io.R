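EPOCH_MATRIX_FORMAT <- "epochcpc-epoch-matrix"

#' Write / read an epoch-matrix file
#'
#' The native on-disk representation of an [EpochSet-class]. Two dialects
#' are supported and chosen from the file extension:
#' \describe{
#'   \item{text (default)}{`#`-prefixed header lines (format version,
#'     n_epochs, epoch_length, sampling_rate, class_names), then one epoch
#'     per line: the integer label followed by the amplitude values,
#'     space-separated. Values are printed with 17 significant digits, so
#'     the round trip is lossless to full double precision. Greppable and
#'     language-neutral.}
#'   \item{binary (`.rds` / `.epb`)}{a compressed self-describing
#'     container with the same header fields; the round trip is
#'     bit-exact.}
#' }
#'
#' @param x an [EpochSet-class].
#' @param path file path; extension `.rds` or `.epb` selects the binary
#'   dialect.
#' @param format `"auto"` (by extension), `"text"` or `"binary"`.
#' @return `writeEpochMatrix` returns `path` invisibly; `readEpochMatrix`
#'   returns an [EpochSet-class].
#' @examples
#' x <- generateEpochs(synthConfig(nClasses = 2, nPerClass = 3,
#'                                 epochLength = 16))
#' f <- tempfile(fileext = ".txt")
#' writeEpochMatrix(x, f)
#' y <- readEpochMatrix(f)
#' all.equal(epochMatrix(x), epochMatrix(y))
#' @export
writeEpochMatrix <- function(x, path, format = c("auto", "text",
                                                 "binary")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.(rds|epb)$", path)) "binary" else "text"
    stopIfNot(methods::is(x, "EpochSet"), "x must be an EpochSet")
    if (format == "binary") {
        saveRDS(list(format = EPOCH_MATRIX_FORMAT, version = 1L,
                     nEpochs = nEpochs(x), epochLength = epochLength(x),
                     samplingRate = samplingRate(x),
                     classNames = classNames(x),
                     epochs = epochMatrix(x), labels = epochLabels(x)),
                path)
        return(invisible(path))
    }
    m <- epochMatrix(x)
    lab <- epochLabels(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("# ", EPOCH_MATRIX_FORMAT, " v1"),
        paste0("# n_epochs: ", nEpochs(x)),
        paste0("# epoch_length: ", epochLength(x)),
        paste0("# sampling_rate: ",
               format(samplingRate(x), digits = 17)),
        paste0("# class_names: ", paste(classNames(x), collapse = ","))),
        con)
    for (i in seq_len(nrow(m)))
        writeLines(paste(lab[i],
                         paste(sprintf("%.17g", m[i, ]), collapse = " ")),
                   con)
    invisible(path)
}

#' @rdname writeEpochMatrix
#' @export
readEpochMatrix <- function(path, format = c("auto", "text", "binary")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("epoch-matrix file not found: ", path)
    if (format == "auto")
        format <- if (grepl("\\.(rds|epb)$", path)) "binary" else "text"
    if (format == "binary") {
        obj <- readRDS(path)
        if (!is.list(obj) || !identical(obj$format, EPOCH_MATRIX_FORMAT))
            stop("file is not a binary epoch-matrix container: ", path)
        return(EpochSet(obj$epochs, obj$labels,
                        samplingRate = obj$samplingRate,
                        classNames = obj$classNames))
    }
    lines <- readLines(path)
    isHeader <- grepl("^#", lines)
    header <- lines[isHeader]
    body <- lines[!isHeader & nzchar(lines)]
    bodyLineNo <- which(!isHeader & nzchar(lines))
    hdr <- list()
    for (h in header) {
        m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1L]]
        if (length(m) == 3L) hdr[[m[2L]]] <- m[3L]
    }
    if (length(body) == 0L)
        stop("epoch-matrix file has no data rows: ", path)
    parsed <- strsplit(trimws(body), "\\s+")
    lens <- lengths(parsed)
    expLen <- if (!is.null(hdr$epoch_length))
        as.integer(hdr$epoch_length) + 1L else lens[1L]
    bad <- which(lens != expLen)
    if (length(bad))
        stop("ragged epoch row at line ", bodyLineNo[bad[1L]],
             " of ", path, ": expected ", expLen - 1L,
             " values, found ", lens[bad[1L]] - 1L)
    if (!is.null(hdr$n_epochs) &&
        as.integer(hdr$n_epochs) != length(body))
        stop("header declares ", hdr$n_epochs, " epochs but file has ",
             length(body))
    vals <- suppressWarnings(
        matrix(as.numeric(unlist(parsed)), nrow = length(parsed),
               byrow = TRUE))
    if (anyNA(vals)) {
        badRow <- which(apply(is.na(vals), 1L, any))[1L]
        stop("unparseable number at line ", bodyLineNo[badRow], " of ",
             path)
    }
    labels <- vals[, 1L]
    if (any(labels != floor(labels)) || any(labels < 0))
        stop("labels must be nonnegative integers in ", path)
    classNames <- if (!is.null(hdr$class_names))
        strsplit(hdr$class_names, ",")[[1L]] else NULL
    if (!is.null(classNames) && max(labels) >= length(classNames))
        stop("label ", max(labels), " exceeds the ", length(classNames),
             " classes declared in the header of ", path)
    EpochSet(vals[, -1L, drop = FALSE], as.integer(labels),
             samplingRate = if (!is.null(hdr$sampling_rate))
                 as.numeric(hdr$sampling_rate) else 100,
             classNames = classNames)
}

#' Band-limited resampling of an epoch
#'
#' Polyphase resampling from `rateIn` to `rateOut` Hz (e.g. the 128 to
#' 251 Hz conversion conventional for ECG beat epochs). The output length
#' is `round(length(epoch) * rateOut / rateIn)`; the energy of a pure tone
#' below both Nyquist limits is preserved within 1%.
#'
#' @param epoch numeric signal vector.
#' @param rateIn,rateOut positive sampling rates in Hz.
#' @return Resampled numeric vector.
#' @examples
#' x <- sin(2 * pi * 10 * (0:127) / 128)
#' length(resampleEpoch(x, 128, 251))
#' @export
resampleEpoch <- function(epoch, rateIn, rateOut) {
    stopIfNot(is.numeric(rateIn) && rateIn > 0,
              "rateIn must be positive")
    stopIfNot(is.numeric(rateOut) && rateOut > 0,
              "rateOut must be positive")
    targetLen <- as.integer(round(length(epoch) * rateOut / rateIn))
    if (rateIn == rateOut) return(epoch)
    # integer p/q ratio for the polyphase filter
    scale <- 10000L
    p <- as.integer(round(rateOut * scale))
    q <- as.integer(round(rateIn * scale))
    g <- gcdInt(p, q)
    y <- as.numeric(signal::resample(epoch, p / g, q / g))
    if (length(y) > targetLen) y <- y[seq_len(targetLen)]
    else if (length(y) < targetLen)
        y <- c(y, rep(y[length(y)], targetLen - length(y)))
    y
}

gcdInt <- function(a, b) {
    while (b != 0L) { t <- b; b <- a %% b; a <- t }
    a
}

#' Per-epoch standardisation
#'
#' Centres and scales each epoch to mean 0 and standard deviation 1.
#' Constant epochs map to all zeros. Idempotent up to floating tolerance.
#'
#' @param epoch numeric vector, or a matrix with one epoch per row.
#' @return Standardised vector or matrix of the same shape.
#' @examples
#' normalizeEpoch(c(1, 2, 3, 4))
#' @export
normalizeEpoch <- function(epoch) {
    if (is.matrix(epoch))
        return(t(apply(epoch, 1L, normalizeEpoch)))
    stopIfNot(length(epoch) > 0L, "epoch must be nonempty")
    s <- stats::sd(epoch)
    if (!is.finite(s) || s == 0) return(epoch * 0)
    (epoch - mean(epoch)) / s
}
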