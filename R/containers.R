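#' Count matrix container
#'
#' Bundles a sparse genes x cells matrix of raw UMI counts with per-cell
#' metadata.  `cell_meta` always has a `barcode` column matching the matrix
#' column names, plus `sample` and `stage` labels; simulated data carry
#' additional ground-truth columns (`truth_type`, `truth_tissue`,
#' `truth_class`, `sex`).
#'
#' @param counts genes x cells matrix (coerced to sparse integer
#'   `dgCMatrix`); must have unique row and column names.
#' @param cell_meta data.frame with one row per cell.
#' @return an `sc_counts` object (list with elements `counts`, `cell_meta`).
#' @export
sc_counts <- function(counts, cell_meta) {
  counts <- as_count_matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene row names and barcode column names")
  if (anyDuplicated(rownames(counts))) stopf("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stopf("cell barcodes must be unique")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"barcode" %in% names(cell_meta)) stopf("cell_meta needs a 'barcode' column")
  if (!identical(cell_meta$barcode, colnames(counts)))
    stopf("cell_meta barcodes must match counts column names (same order)")
  for (col in c("sample", "stage"))
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "sample1"
  structure(list(counts = counts, cell_meta = cell_meta), class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells (%d samples, %.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample)),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Concatenate count objects over cells
#'
#' All objects must share an identical gene set and ordering.
#'
#' @param x list of `sc_counts` objects.
#' @return a single `sc_counts`.
#' @export
bind_counts <- function(x) {
  if (!length(x)) stopf("empty list of counts")
  genes <- rownames(x[[1L]]$counts)
  for (cm in x)
    if (!identical(rownames(cm$counts), genes))
      stopf("gene sets differ between count objects")
  meta_all <- lapply(x, `[[`, "cell_meta")
  cols <- Reduce(intersect, lapply(meta_all, names))
  meta <- do.call(rbind, lapply(meta_all, function(m) m[, cols, drop = FALSE]))
  rownames(meta) <- NULL
  sc_counts(do.call(cbind, lapply(x, `[[`, "counts")), meta)
}

# Subset cells by barcode or logical/integer index.
subset_cells <- function(cm, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(cm$counts))
  sc_counts(cm$counts[, idx, drop = FALSE],
            cm$cell_meta[idx, , drop = FALSE])
}
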