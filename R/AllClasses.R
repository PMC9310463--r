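#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats predict
NULL

.PERTURB_CLASSES <- c("sample", "positive_control", "negative_control",
                      "non_expressor", "killer_control")

#' Container for a perturbation-by-readout screen
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding the raw
#' screen matrix (rows = perturbations, e.g. siRNA pools; columns =
#' functional readouts, e.g. log2 splicing isoform ratios) together with a
#' per-row class annotation in \code{rowData(x)$class}. Missing measurements
#' are stored as \code{NA} in the assay. After \code{\link{zTransform}} the
#' object additionally carries a \code{"zscore"} assay.
#'
#' Row classes are one of \code{sample}, \code{positive_control},
#' \code{negative_control}, \code{non_expressor}, \code{killer_control}.
#' Negative controls define the column-wise Z-scaling; non-expressors (genes
#' not expressed in the assayed cell type) act as internal true negatives
#' for Screen Strength.
#'
#' @aliases ScreenExperiment-class
#' @exportClass ScreenExperiment
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    msg <- NULL
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "perturbation (row) ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "readout (column) ids must be present and unique")
    if (!"class" %in% colnames(SummarizedExperiment::rowData(object))) {
        msg <- c(msg, "rowData must contain a 'class' column")
    } else {
        cls <- SummarizedExperiment::rowData(object)$class
        bad <- setdiff(unique(cls), .PERTURB_CLASSES)
        if (length(bad))
            msg <- c(msg, paste0("unknown perturbation class(es): ",
                                 paste(bad, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a ScreenExperiment
#'
#' @param values numeric matrix, perturbations x readouts, with \code{NA}
#'   marking missing measurements. Must have unique dimnames.
#' @param annotation data.frame with columns \code{row_id} and \code{class};
#'   every matrix row must be annotated exactly once.
#' @return A \linkS4class{ScreenExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("r", 1:4)))
#' ann <- data.frame(row_id = rownames(m),
#'                   class = c("sample", "negative_control", "non_expressor"))
#' ScreenExperiment(m, ann)
#' @export
ScreenExperiment <- function(values, annotation) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("screen values must be numeric")
    if (anyDuplicated(annotation$row_id))
        stop("duplicated row ids in annotation: ",
             paste(unique(annotation$row_id[duplicated(annotation$row_id)]),
                   collapse = ", "))
    missing_ann <- setdiff(rownames(values), annotation$row_id)
    if (length(missing_ann))
        stop("annotation missing for row(s): ",
             paste(missing_ann, collapse = ", "))
    cls <- annotation$class[match(rownames(values), annotation$row_id)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = values),
        rowData = S4Vectors::DataFrame(class = as.character(cls),
                                       row.names = rownames(values)))
    methods::new("ScreenExperiment", se)
}

#' Per-perturbation survival curves over a grid of Z cutoffs
#'
#' For each perturbation the curve records, at each Z-score cutoff, the
#' fraction of readouts whose Z score lies beyond the cutoff (\code{>=} in
#' the positive direction, \code{<=} in the negative). Cutoffs span
#' \code{[2, Zmax]} (positive) or \code{[-Zmax, -2]} (negative), where
#' \code{Zmax} is the 99.9th-percentile rank of |Z| over all matrix entries,
#' divided into \code{nbin} equal bins; the fractions are evaluated at all
#' \code{nbin + 1} bin edges so that trapezoid areas can be formed per bin.
#'
#' @slot P numeric matrix, perturbations x (nbin + 1) survival fractions.
#' @slot cutoffs numeric vector of bin-edge Z cutoffs, ascending.
#' @slot direction "positive" or "negative".
#' @slot step bin width (Zmax - Zmin) / nbin.
#' @aliases ZetaCurveSet-class
#' @exportClass ZetaCurveSet
setClass("ZetaCurveSet",
         representation(P = "matrix", cutoffs = "numeric",
                        direction = "character", step = "numeric"))

setValidity("ZetaCurveSet", function(object) {
    msg <- NULL
    if (ncol(object@P) != length(object@cutoffs))
        msg <- c(msg, "ncol(P) must equal length(cutoffs)")
    if (!object@direction %in% c("positive", "negative"))
        msg <- c(msg, "direction must be 'positive' or 'negative'")
    if (any(object@P < 0 | object@P > 1, na.rm = TRUE))
        msg <- c(msg, "survival fractions must lie in [0, 1]")
    if (is.unsorted(object@cutoffs))
        msg <- c(msg, "cutoffs must be ascending")
    if (is.null(msg)) TRUE else msg
})

#' Background survival boundary separating control curve classes
#'
#' Stores, on the same cutoff grid as a \linkS4class{ZetaCurveSet}, the
#' survival fraction at which a radial-kernel SVM trained on (cutoff,
#' fraction) points from positive- versus negative-control curves changes
#' its decision: the screen's background level to be subtracted when
#' integrating zeta areas.
#'
#' @slot S numeric boundary fraction per cutoff, in [0, 1].
#' @slot cutoffs cutoff grid shared with the curves.
#' @slot direction "positive" or "negative".
#' @slot params list: kernel description, hyperparameters, seed,
#'   training accuracy.
#' @aliases ZetaBoundary-class
#' @exportClass ZetaBoundary
setClass("ZetaBoundary",
         representation(S = "numeric", cutoffs = "numeric",
                        direction = "character", params = "list"))

setValidity("ZetaBoundary", function(object) {
    msg <- NULL
    if (length(object@S) != length(object@cutoffs))
        msg <- c(msg, "S and cutoffs must have equal length")
    if (any(object@S < 0 | object@S > 1))
        msg <- c(msg, "boundary fractions must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Screen Strength curve with balance points and FPL cutoffs
#'
#' Screen Strength is \code{SS = 1 - aFDR / bFDR}: the improvement of a
#' zeta cutoff over a random draw, where aFDR is the fraction of hits at
#' the cutoff that are non-expressors and bFDR the overall non-expressor
#' fraction among scored genes.
#'
#' @slot curve data.frame with columns \code{cutoff}, \code{n_hits},
#'   \code{n_ne_hits}, \code{aFDR}, \code{SS} (one row per zeta cutoff on a
#'   100-point even grid, tail cutoffs without hits trimmed).
#' @slot bFDR baseline FDR (non-expressors / scored genes).
#' @slot balancePoints zeta cutoffs of detected balance points (BP1, BP2,
#'   ...), possibly empty.
#' @slot fpl named numeric: zeta cutoff per empirical false-positive level.
#' @aliases ScreenStrengthCurve-class
#' @exportClass ScreenStrengthCurve
setClass("ScreenStrengthCurve",
         representation(curve = "data.frame", bFDR = "numeric",
                        balancePoints = "numeric", fpl = "numeric"))

setValidity("ScreenStrengthCurve", function(object) {
    msg <- NULL
    need <- c("cutoff", "n_hits", "n_ne_hits", "aFDR", "SS")
    if (!all(need %in% names(object@curve)))
        msg <- c(msg, paste("curve must have columns",
                            paste(need, collapse = ", ")))
    if (length(object@bFDR) != 1 || object@bFDR <= 0 || object@bFDR >= 1)
        msg <- c(msg, "bFDR must be a scalar in (0, 1)")
    if (is.null(msg)) TRUE else msg
})
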