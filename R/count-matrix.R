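#' Gene-by-unit count matrix with unit metadata
#'
#' Lightweight container pairing a non-negative integer count matrix
#' (genes in rows, units -- nuclei or samples -- in columns) with a
#' per-unit metadata table. Units can be single nuclei (before
#' aggregation) or samples (after [aggregate_pseudobulk()]).
#'
#' @param counts numeric matrix, genes x units, non-negative integers;
#'   must carry rownames (gene ids) and colnames (unit ids). A sparse
#'   `Matrix::dgCMatrix` is accepted and kept sparse.
#' @param meta data.frame with one row per unit (matched to columns of
#'   `counts` by order). Must contain a `sample` column; typical further
#'   columns are `genotype` ("WT"/"HET"), `sex` ("M"/"F"/"unknown"),
#'   `batch`, `pool`, and the cell-type hierarchy columns
#'   `cell_type_1`..`cell_type_3`.
#' @return An object of class `count_matrix` (list with `counts`, `meta`).
#' @export
count_matrix <- function(counts, meta) {
  if (nrow(counts) > 0 && is.null(rownames(counts)) ||
      ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must have rownames (genes) and colnames (units)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate unit identifiers")
  if (!is.data.frame(meta))
    stop("meta must be a data.frame")
  if (nrow(meta) != ncol(counts))
    stop("meta must have one row per unit")
  if (!"sample" %in% names(meta))
    stop("meta must contain a 'sample' column")
  v <- if (inherits(counts, "Matrix")) counts@x else counts
  if (length(v) && (min(v) < 0 || any(v != floor(v))))
    stop("counts must be non-negative integers")
  rownames(meta) <- colnames(counts)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d units\n",
              nrow(x$counts), ncol(x$counts)))
  cat("meta columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by units
#' @param x a [count_matrix()]
#' @param units logical, integer or character index into units
#' @return a `count_matrix` restricted to the selected units
#' @export
subset_units <- function(x, units) {
  count_matrix(x$counts[, units, drop = FALSE],
               x$meta[units, , drop = FALSE])
}
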