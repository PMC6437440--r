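#' Construct a cell-by-species abundance matrix
#'
#' The basic container for single-cell abundance data: a numeric matrix of
#' `n_cells` rows (cells) by `d` columns (species: proteins for cytometry,
#' transcripts or reduced dimensions for scRNA-seq), with optional per-cell
#' identifiers and category labels (manual gates or ground-truth branches).
#' Missing values are rejected: imputation is out of scope and loaders must
#' deliver complete matrices.
#'
#' @param values numeric matrix, cells in rows, species in columns.
#' @param species character vector of column (species) names; defaults to
#'   existing column names or `V1..Vd`.
#' @param cell_ids identifiers, one per cell; defaults to 0-based row indices.
#' @param labels optional per-cell category labels (gates, fates).
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `species`, `cell_ids` and `labels`.
#' @export
cell_matrix <- function(values, species = NULL, cell_ids = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(is.finite(values)))
    stop("cell matrix contains missing or non-finite values")
  if (is.null(species)) species <- colnames(values)
  if (is.null(species)) species <- paste0("V", seq_len(ncol(values)))
  if (length(species) != ncol(values))
    stop("species names do not match number of columns")
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(values)) - 1L
  if (length(cell_ids) != nrow(values))
    stop("cell_ids do not match number of rows")
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("labels do not match number of rows")
  colnames(values) <- species
  structure(list(values = values, species = as.character(species),
                 cell_ids = cell_ids, labels = labels),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " species", if (!is.null(x$labels)) ", labelled", "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Subset cells of a cell matrix
#'
#' @param x a `cell_matrix`.
#' @param i cell (row) indices or logical mask.
#' @param ... ignored.
#' @return A `cell_matrix` holding the selected cells; identifiers and
#'   labels follow the subset.
#' @export
`[.cell_matrix` <- function(x, i, ...) {
  cell_matrix(x$values[i, , drop = FALSE], species = x$species,
              cell_ids = x$cell_ids[i],
              labels = if (!is.null(x$labels)) x$labels[i])
}

.as_cell_matrix <- function(x) {
  if (inherits(x, "cell_matrix")) x else cell_matrix(x)
}
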