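#' @describeIn ScreenExperiment-class perturbation class labels, in row order.
#' @param x a \linkS4class{ScreenExperiment}.
#' @export
perturbClass <- function(x) {
    stopifnot(methods::is(x, "ScreenExperiment"))
    stats::setNames(as.character(SummarizedExperiment::rowData(x)$class),
                    rownames(x))
}

#' Row ids of a given perturbation class
#' @param x a \linkS4class{ScreenExperiment}.
#' @param class one of the allowed perturbation classes.
#' @return character vector of row ids.
#' @export
rowsOfClass <- function(x, class) {
    class <- match.arg(class, .PERTURB_CLASSES)
    names(which(perturbClass(x) == class))
}

#' Screen values assay (raw measurements, NA = missing)
#' @param x a \linkS4class{ScreenExperiment}.
#' @export
screenValues <- function(x) SummarizedExperiment::assay(x, "values")

#' Z-score assay (available after \code{\link{zTransform}})
#' @param x a \linkS4class{ScreenExperiment}.
#' @export
zScores <- function(x) {
    if (!"zscore" %in% SummarizedExperiment::assayNames(x))
        stop("no 'zscore' assay; run zTransform() first")
    SummarizedExperiment::assay(x, "zscore")
}

## Coerce curve input: accept a ZetaCurveSet-shaped matrix or the object
.curveMatrix <- function(x) {
    if (methods::is(x, "ZetaCurveSet")) x@P else as.matrix(x)
}

## Accept a Z matrix, or a ScreenExperiment carrying a zscore assay
.asZMatrix <- function(x) {
    if (methods::is(x, "ScreenExperiment")) zScores(x) else as.matrix(x)
}

#' @describeIn ZetaCurveSet-class survival-fraction matrix
#'   (perturbations x cutoffs).
#' @param x a \code{ZetaCurveSet}.
#' @export
curveMatrix <- function(x) x@P

#' @describeIn ZetaCurveSet-class cutoff grid (bin edges).
#' @export
curveCutoffs <- function(x) x@cutoffs

#' @describeIn ZetaCurveSet-class direction of the curve set.
#' @export
curveDirection <- function(x) x@direction

#' @describeIn ZetaBoundary-class boundary survival fraction per cutoff.
#' @param x a \code{ZetaBoundary}.
#' @export
boundaryValues <- function(x) x@S

#' @describeIn ScreenStrengthCurve-class the per-cutoff SS table.
#' @param x a \code{ScreenStrengthCurve}.
#' @export
ssTable <- function(x) x@curve

#' @describeIn ScreenStrengthCurve-class baseline FDR.
#' @export
baselineFDR <- function(x) x@bFDR

#' @describeIn ScreenStrengthCurve-class zeta cutoffs of the balance points.
#' @export
balancePoints <- function(x) x@balancePoints

#' @describeIn ScreenStrengthCurve-class named empirical false-positive-level
#'   cutoffs.
#' @export
fplCutoffValues <- function(x) x@fpl

setMethod("show", "ScreenExperiment", function(object) {
    methods::callNextMethod()
    tab <- table(perturbClass(object))
    cat("perturbation classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    nmiss <- sum(is.na(screenValues(object)))
    cat("missing values:", nmiss, "\n")
})

setMethod("show", "ZetaCurveSet", function(object) {
    cat("ZetaCurveSet:", nrow(object@P), "perturbations,",
        length(object@cutoffs), "cutoffs,", object@direction,
        "direction\n  Z range [", min(object@cutoffs), ",",
        max(object@cutoffs), "], step", signif(object@step, 4), "\n")
})

setMethod("show", "ZetaBoundary", function(object) {
    cat("ZetaBoundary (radial SVM):", length(object@S), "cutoffs,",
        object@direction, "direction; training accuracy",
        signif(object@params$accuracy, 4), "\n")
})

setMethod("show", "ScreenStrengthCurve", function(object) {
    cat("ScreenStrengthCurve:", nrow(object@curve), "cutoffs, bFDR =",
        signif(object@bFDR, 4), "\n")
    if (length(object@balancePoints))
        cat("  balance points at zeta =",
            paste(signif(object@balancePoints, 4), collapse = ", "), "\n")
    else cat("  no balance points detected\n")
    if (length(object@fpl))
        cat("  FPL cutoffs:",
            paste(names(object@fpl), signif(object@fpl, 4),
                  sep = " -> ", collapse = ", "), "\n")
})
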