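#' Read a screen matrix and its row annotation from delimited text
#'
#' The matrix file must have a header row of readout ids and a first column
#' of perturbation ids; empty cells and NA tokens mark missing measurements.
#' The annotation file has columns \code{row_id} and \code{class}.
#'
#' @param path path to the matrix file (TSV by default).
#' @param annotationPath path to the annotation table.
#' @param sep field separator for both files.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
readScreenMatrix <- function(path, annotationPath, sep = "\t") {
    raw <- utils::read.delim(path, sep = sep, header = TRUE,
                             check.names = FALSE, row.names = NULL,
                             na.strings = c("NA", "", "NaN"))
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids))
        stop("duplicated perturbation id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyDuplicated(colnames(m)))
        stop("duplicated readout id(s) in ", path)
    ann <- utils::read.delim(annotationPath, sep = sep, header = TRUE,
                             check.names = FALSE,
                             colClasses = "character")
    if (!all(c("row_id", "class") %in% names(ann)))
        stop("annotation file must have columns row_id and class")
    ScreenExperiment(m, ann)
}

#' Write a screen matrix (and optionally its annotation) as TSV
#'
#' Finite values round-trip bit-exactly through \code{\link{readScreenMatrix}}
#' (written with full precision); missing entries are written as \code{NA}.
#'
#' @param x a \linkS4class{ScreenExperiment} or numeric matrix.
#' @param path output path for the matrix.
#' @param annotationPath optional output path for the annotation table.
#' @return invisibly, \code{path}.
#' @export
writeScreenMatrix <- function(x, path, annotationPath = NULL) {
    m <- if (methods::is(x, "ScreenExperiment")) screenValues(x) else x
    df <- data.frame(row_id = rownames(m),
                     format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    if (!is.null(annotationPath) && methods::is(x, "ScreenExperiment")) {
        ann <- data.frame(row_id = rownames(m), class = perturbClass(x))
        utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
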