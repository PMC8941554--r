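#' Confusion matrix with true classes in rows
#'
#' Entry (i, j) counts epochs of true class i predicted as class j.
#'
#' @param trueLabels,predictedLabels integer vectors of 0-based class ids.
#' @param nClasses number of classes; defaults to 1 + the largest label
#'   observed.
#' @param classNames optional class display names.
#' @return Integer matrix with class-name dimnames.
#' @examples
#' confusionMatrix(c(0, 0, 1), c(0, 1, 1), nClasses = 2)
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, nClasses = NULL,
                            classNames = NULL) {
    if (length(trueLabels) != length(predictedLabels))
        stop("label vectors must have equal length")
    if (is.null(nClasses))
        nClasses <- max(c(trueLabels, predictedLabels)) + 1L
    nClasses <- as.integer(nClasses)
    bad <- c(trueLabels, predictedLabels)
    if (anyNA(bad) || any(bad < 0L) || any(bad >= nClasses))
        stop("labels must lie in 0..", nClasses - 1L)
    if (is.null(classNames))
        classNames <- paste0("class", seq_len(nClasses) - 1L)
    lev <- seq_len(nClasses) - 1L
    cm <- table(factor(trueLabels, levels = lev),
                factor(predictedLabels, levels = lev))
    cm <- matrix(as.integer(cm), nClasses, nClasses,
                 dimnames = list(true = classNames,
                                 predicted = classNames))
    cm
}

#' Per-class and aggregate metrics from a confusion matrix
#'
#' Computes per-class precision (`100 * diagonal / column sum`), recall
#' (`100 * diagonal / row sum`), their harmonic-mean F1, the unweighted
#' macro-averaged F1, and overall accuracy (`100 * trace / total`).
#' Percentages are held at full precision; `show()` rounds half-up to
#' 2 decimals as printed in clinical tables. A class that is never
#' predicted (zero column) or never present (zero row) gets the undefined
#' ratio reported as 0 and is flagged in the `degenerate` slot.
#'
#' @param confusion square nonnegative integer matrix, rows = true class.
#' @param classNames optional class display names; defaults to the matrix
#'   dimnames.
#' @return An [EvalReport-class].
#' @examples
#' cm <- confusionMatrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' rep <- reportMetrics(cm)
#' accuracy(rep)
#' @export
reportMetrics <- function(confusion, classNames = NULL) {
    cm <- as.matrix(confusion)
    if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
    if (any(cm < 0) || any(cm != floor(cm)))
        stop("confusion entries must be nonnegative integers")
    total <- sum(cm)
    if (total <= 0) stop("confusion matrix is empty")
    if (is.null(classNames))
        classNames <- if (!is.null(rownames(cm))) rownames(cm)
                      else paste0("class", seq_len(nrow(cm)) - 1L)
    diagc <- diag(cm)
    colS <- colSums(cm)
    rowS <- rowSums(cm)
    degenerate <- character()
    precision <- ifelse(colS > 0, 100 * diagc / colS, 0)
    recall <- ifelse(rowS > 0, 100 * diagc / rowS, 0)
    if (any(colS == 0)) {
        degenerate <- c(degenerate, classNames[colS == 0])
        warning("class never predicted: ",
                paste(classNames[colS == 0], collapse = ", "),
                "; precision reported as 0")
    }
    if (any(rowS == 0)) {
        degenerate <- c(degenerate, classNames[rowS == 0])
        warning("class never present: ",
                paste(classNames[rowS == 0], collapse = ", "),
                "; recall reported as 0")
    }
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    methods::new("EvalReport",
                 confusion = cm,
                 perClass = data.frame(precision = as.numeric(precision),
                                       recall = as.numeric(recall),
                                       f1 = as.numeric(f1),
                                       row.names = classNames),
                 accuracy = 100 * sum(diagc) / total,
                 macroF1 = mean(f1),
                 classNames = as.character(classNames),
                 degenerate = unique(degenerate))
}

#' @describeIn reportMetrics overall accuracy in percent (full precision).
#' @param x an [EvalReport-class].
#' @export
accuracy <- function(x) {
    stopIfNot(methods::is(x, "EvalReport"), "x must be an EvalReport")
    x@accuracy
}

#' @describeIn reportMetrics macro-averaged F1 in percent (full
#'   precision).
#' @export
macroF1 <- function(x) {
    stopIfNot(methods::is(x, "EvalReport"), "x must be an EvalReport")
    x@macroF1
}

#' @describeIn reportMetrics per-class precision/recall/F1 data.frame in
#'   percent (full precision).
#' @export
perClassMetrics <- function(x) {
    stopIfNot(methods::is(x, "EvalReport"), "x must be an EvalReport")
    x@perClass
}

#' @rdname classNames
#' @export
setMethod("classNames", "EvalReport", function(x) x@classNames)

setMethod("show", "EvalReport", function(object) {
    cm <- object@confusion
    pc <- object@perClass
    df <- as.data.frame(cm)
    df <- cbind(df,
                `PR (%)` = sprintf("%.2f", roundHalfUp(pc$precision)),
                `RE (%)` = sprintf("%.2f", roundHalfUp(pc$recall)),
                `F1 (%)` = sprintf("%.2f", roundHalfUp(pc$f1)))
    rownames(df) <- object@classNames
    print(df)
    cat(sprintf("Macro avg F1: %.2f\n", roundHalfUp(object@macroF1)))
    cat(sprintf("ACC: %.2f%%\n", roundHalfUp(object@accuracy)))
    if (length(object@degenerate))
        cat("degenerate classes (undefined ratios reported as 0): ",
            paste(object@degenerate, collapse = ", "), "\n", sep = "")
    invisible(NULL)
})

#' Write an evaluation report to delimited text
#'
#' Writes a tab-separated file mirroring the printed report layout: the
#' confusion-matrix columns followed by the PR/RE/F1 columns (rounded
#' half-up to 2 decimals), then macro-average-F1 and accuracy footer rows.
#' Header comment lines record provenance (seed, scope) when supplied.
#'
#' @param report an [EvalReport-class].
#' @param path output file path.
#' @param provenance optional named list written as `# key: value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path, provenance = list()) {
    stopIfNot(methods::is(report, "EvalReport"),
              "report must be an EvalReport")
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(provenance))
        writeLines(sprintf("# %s: %s", k,
                           paste(provenance[[k]], collapse = ",")), con)
    pc <- report@perClass
    header <- c("class", colnames(report@confusion), "PR", "RE", "F1")
    writeLines(paste(header, collapse = "\t"), con)
    for (i in seq_len(nrow(report@confusion)))
        writeLines(paste(c(report@classNames[i], report@confusion[i, ],
                           sprintf("%.2f", roundHalfUp(pc$precision[i])),
                           sprintf("%.2f", roundHalfUp(pc$recall[i])),
                           sprintf("%.2f", roundHalfUp(pc$f1[i]))),
                         collapse = "\t"), con)
    writeLines(sprintf("macro_f1\t%.2f", roundHalfUp(report@macroF1)), con)
    writeLines(sprintf("accuracy\t%.2f", roundHalfUp(report@accuracy)),
               con)
    invisible(path)
}
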