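#' Construct a gene-by-chip expression matrix
#'
#' Container for a genes x chips matrix of expression values together with
#' the experiment (batch) each chip belongs to.  Expression values are
#' arbitrary real numbers after normalization; before \code{\link{log_center}}
#' they are raw (strictly positive) intensities.
#'
#' @param values numeric matrix, one row per gene, one column per chip;
#'   rownames are gene ids, colnames chip ids (both required, no duplicates).
#' @param experiment character vector of experiment labels, one per chip
#'   (recycled from length 1).
#' @return an object of class \code{expr_matrix}: a list with elements
#'   \code{values} (the matrix) and \code{experiment} (named character
#'   vector keyed by chip id).
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' expression_matrix(m, c("e1", "e1", "e2"))
#' @export
expression_matrix <- function(values, experiment) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and chip ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate chip ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (length(experiment) == 1L) experiment <- rep(experiment, ncol(values))
  if (length(experiment) != ncol(values))
    stop("'experiment' must supply one label per chip")
  if (anyNA(experiment)) stop("every chip needs an experiment label")
  experiment <- stats::setNames(as.character(experiment), colnames(values))
  structure(list(values = values, experiment = experiment),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d chips (%d experiments)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$experiment))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or chip
#'
#' @param x an \code{expr_matrix}.
#' @param i,j gene / chip indices (integer, logical or names).
#' @param ... ignored.
#' @return an \code{expr_matrix}.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, x$experiment[colnames(v)])
}
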