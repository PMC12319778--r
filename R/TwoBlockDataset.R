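#' Construct a two-block dataset
#'
#' Bundles a "brain" matrix \code{X} and a "behaviour" matrix \code{Y}
#' with matched rows into a validated [TwoBlockDataset-class]. Inputs
#' may be matrices or data frames of numeric columns; feature names are
#' taken from column names (defaults \code{x1..xp}, \code{y1..yq} are
#' assigned when absent).
#'
#' @param X n x p numeric matrix or data frame.
#' @param Y n x q numeric matrix or data frame (same n).
#' @return A [TwoBlockDataset-class].
#' @examples
#' set.seed(1)
#' d <- TwoBlockDataset(matrix(rnorm(40), 10), matrix(rnorm(20), 10))
#' nObs(d)
#' @export
TwoBlockDataset <- function(X, Y) {
  X <- .asNumericMatrix(X, "X")
  Y <- .asNumericMatrix(Y, "Y")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  new("TwoBlockDataset", X = X, Y = Y)
}

.asNumericMatrix <- function(M, label) {
  if (is.data.frame(M)) M <- as.matrix(M)
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!is.numeric(M))
    stop(label, " must be numeric", call. = FALSE)
  storage.mode(M) <- "double"
  M
}

#' @rdname accessors
setMethod("xBlock", "TwoBlockDataset", function(object) object@X)
#' @rdname accessors
setMethod("yBlock", "TwoBlockDataset", function(object) object@Y)
#' @rdname accessors
setMethod("nObs", "TwoBlockDataset", function(object) nrow(object@X))
#' @rdname accessors
setMethod("featureNamesX", "TwoBlockDataset",
          function(object) colnames(object@X))
#' @rdname accessors
setMethod("featureNamesY", "TwoBlockDataset",
          function(object) colnames(object@Y))

setMethod("show", "TwoBlockDataset", function(object) {
  cat("TwoBlockDataset:", nrow(object@X), "observations\n")
  cat("  X block:", ncol(object@X), "features\n")
  cat("  Y block:", ncol(object@Y), "features\n")
})

#' Read a two-block dataset from delimited text
#'
#' Reads the two blocks from delimited text files, each with a header
#' row of feature names and one row per observation, and returns a
#' validated [TwoBlockDataset-class]. Rows must be in the same
#' observation order in both files.
#'
#' @param xFile,yFile paths to the X and Y files.
#' @param sep field separator (default comma; use \code{"\t"} for TSV).
#' @return A [TwoBlockDataset-class].
#' @export
readTwoBlockDataset <- function(xFile, yFile, sep = ",") {
  X <- utils::read.table(xFile, header = TRUE, sep = sep,
                         check.names = FALSE)
  Y <- utils::read.table(yFile, header = TRUE, sep = sep,
                         check.names = FALSE)
  TwoBlockDataset(X, Y)
}
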