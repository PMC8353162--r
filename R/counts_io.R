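#' Read and write count matrices
#'
#' Two plain-text formats are supported.  `"mtx_triplet"` is the 10x-style
#' triplet directory: `matrix.mtx` (Matrix Market coordinate integer
#' general), `features.tsv` (gene_id, gene_name; headerless), `barcodes.tsv`
#' (headerless) and an optional `cells.tsv` with per-cell metadata
#' (`barcode`, `sample`, `stage`, plus any truth columns).  `"dense_tsv"` is
#' a genes x cells table whose first column is the gene name and whose
#' header row holds barcodes; metadata travel in a sidecar `<path>.cells.tsv`
#' when present.
#'
#' @param path directory (`mtx_triplet`) or file (`dense_tsv`).
#' @param format one of `"mtx_triplet"`, `"dense_tsv"`.
#' @return `read_counts` returns an [sc_counts()]; `write_counts` returns
#'   `path` invisibly.  The pair round-trips exactly.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") read_counts_mtx(path) else read_counts_dense(path)
}

read_counts_mtx <- function(dir) {
  files <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (f in files) if (!file.exists(f)) stopf("missing triplet file: %s", f)
  header <- readLines(files[1L], n = 1L)
  if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general", header))
    stopf("malformed Matrix Market header: %s", header)
  m <- Matrix::readMM(files[1L])
  feats <- utils::read.delim(files[2L], header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(files[3L], header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
  if (nrow(feats) != nrow(m))
    stopf("feature count (%d) != matrix rows (%d)", nrow(feats), nrow(m))
  if (length(bcs) != ncol(m))
    stopf("barcode count (%d) != matrix columns (%d)", length(bcs), ncol(m))
  rownames(m) <- feats[[2L]] %||% feats[[1L]]
  colnames(m) <- bcs
  meta_path <- file.path(dir, "cells.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  else data.frame(barcode = bcs, stringsAsFactors = FALSE)
  sc_counts(m, meta)
}

read_counts_dense <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric entries in dense count table")
  if (any(m != round(m))) stopf("non-integer entries in dense count table")
  rownames(m) <- genes
  meta_path <- paste0(path, ".cells.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  else data.frame(barcode = colnames(m), stringsAsFactors = FALSE)
  sc_counts(m, meta)
}

#' @rdname read_counts
#' @param cm an [sc_counts()].
#' @export
write_counts <- function(cm, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- cm$counts
    con <- file(file.path(path, "matrix.mtx"), "w")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
    tm <- methods::as(m, "TsparseMatrix")
    ord <- order(tm@j, tm@i)
    writeLines(sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L,
                       as.integer(tm@x[ord])), con)
    close(con)
    utils::write.table(data.frame(rownames(m), rownames(m)),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    utils::write.table(cm$cell_meta, file.path(path, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(gene = rownames(cm$counts),
                     as.matrix(cm$counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", colnames(cm$counts))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cm$cell_meta, paste0(path, ".cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Per-cell quality-control metrics
#'
#' @param cm an [sc_counts()].
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return data.frame with columns `barcode`, `n_genes` (genes with count
#'   > 0), `n_umis` (total counts) and `mito_frac` (mitochondrial fraction;
#'   0 for all-zero cells, with a warning).
#' @export
compute_qc <- function(cm, mito_prefix = "MT-") {
  m <- cm$counts
  n_umis <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_umis <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else 0
  zero <- n_umis == 0
  if (any(zero)) warnf("%d cell(s) have zero counts; mito_frac set to 0",
                       sum(zero))
  mito_frac <- ifelse(zero, 0, mito_umis / pmax(n_umis, 1))
  data.frame(barcode = colnames(m), n_genes = as.integer(n_genes),
             n_umis = as.integer(n_umis), mito_frac = mito_frac,
             stringsAsFactors = FALSE)
}

#' QC thresholds
#'
#' Bounds applied per replicate by [filter_cells()].  The shipped defaults
#' (`min_genes = 500`, `max_genes = 9000`, `max_mito_frac = 0.1`, UMI bounds
#' unset) are package defaults for typical 10x libraries, not values taken
#' from any particular study; real analyses should supply per-replicate
#' thresholds chosen by inspection.
#'
#' @param min_genes,max_genes bounds on detected genes per cell.
#' @param min_umis,max_umis bounds on total UMIs per cell.
#' @param max_mito_frac maximum mitochondrial fraction in `[0, 1]`.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 9000, min_umis = 0,
                          max_umis = Inf, max_mito_frac = 0.1) {
  if (min_genes > max_genes) stopf("min_genes > max_genes")
  if (min_umis > max_umis) stopf("min_umis > max_umis")
  assert_scalar_num(max_mito_frac, "max_mito_frac", lower = 0, upper = 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umis = min_umis, max_umis = max_umis,
                 max_mito_frac = max_mito_frac), class = "qc_thresholds")
}

#' Filter droplets on QC metrics
#'
#' Retains cells with `min_genes <= n_genes <= max_genes`,
#' `min_umis <= n_umis <= max_umis` and `mito_frac <= max_mito_frac`.
#' Filtering is idempotent.
#'
#' @param cm an [sc_counts()].
#' @param thresholds a [qc_thresholds()].
#' @param metrics optional precomputed [compute_qc()] table.
#' @param mito_prefix passed to [compute_qc()] when `metrics` is `NULL`.
#' @return list with `counts` (filtered [sc_counts()]), `kept` (barcodes)
#'   and `report` (data.frame `criterion`, `n_removed`; criterion counts are
#'   cells failing that criterion, `total` is the overall removal so that
#'   `removed_total = n_before - n_after`).
#' @export
filter_cells <- function(cm, thresholds = qc_thresholds(), metrics = NULL,
                         mito_prefix = "MT-") {
  if (!inherits(thresholds, "qc_thresholds"))
    stopf("thresholds must come from qc_thresholds()")
  if (is.null(metrics)) metrics <- compute_qc(cm, mito_prefix)
  fail_low_genes <- metrics$n_genes < thresholds$min_genes
  fail_high_genes <- metrics$n_genes > thresholds$max_genes
  fail_low_umis <- metrics$n_umis < thresholds$min_umis
  fail_high_umis <- metrics$n_umis > thresholds$max_umis
  fail_mito <- metrics$mito_frac > thresholds$max_mito_frac
  keep <- !(fail_low_genes | fail_high_genes | fail_low_umis |
              fail_high_umis | fail_mito)
  if (!any(keep))
    stopf("QC thresholds remove all %d cells", ncol(cm$counts))
  report <- data.frame(
    criterion = c("low_genes", "high_genes", "low_umis", "high_umis",
                  "high_mito", "total"),
    n_removed = c(sum(fail_low_genes), sum(fail_high_genes),
                  sum(fail_low_umis), sum(fail_high_umis), sum(fail_mito),
                  sum(!keep)),
    stringsAsFactors = FALSE)
  list(counts = subset_cells(cm, which(keep)),
       kept = metrics$barcode[keep], report = report)
}

#' Infer sample sex from a male-specific gene
#'
#' A sample is labelled `male` when the sex gene is detected (count > 0) in
#' at least `min_cells` of its cells, `female` otherwise.
#'
#' @param cm an [sc_counts()].
#' @param sex_gene gene name (default `"SRY"`); must be present.
#' @param min_cells detection threshold in cells (default 3).
#' @return data.frame with columns `sample`, `n_positive_cells`, `sex`.
#' @export
infer_sex <- function(cm, sex_gene = "SRY", min_cells = 3) {
  if (!sex_gene %in% rownames(cm$counts))
    stopf("sex gene '%s' not present in the gene list", sex_gene)
  pos <- cm$counts[sex_gene, ] > 0
  samples <- cm$cell_meta$sample
  n_pos <- tapply(pos, samples, sum)
  data.frame(sample = names(n_pos),
             n_positive_cells = as.integer(n_pos),
             sex = ifelse(n_pos >= min_cells, "male", "female"),
             stringsAsFactors = FALSE, row.names = NULL)
}
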