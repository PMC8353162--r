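#' Reduce raw ortholog pairs to a strict 1:1 map
#'
#' Keeps only pairs whose genes each occur exactly once across the whole
#' input; genes with no unique counterpart are discarded.
#'
#' @param raw_pairs data.frame with columns `gene_a`, `gene_b` (extra
#'   columns ignored).
#' @return data.frame (`gene_a`, `gene_b`) of the surviving 1:1 pairs, with
#'   class `ortholog_map`.
#' @export
map_orthologs <- function(raw_pairs) {
  if (is.null(raw_pairs) || nrow(raw_pairs) == 0L)
    stopf("empty ortholog pair input")
  if (!all(c("gene_a", "gene_b") %in% names(raw_pairs)))
    stopf("raw_pairs needs columns gene_a and gene_b")
  ta <- table(raw_pairs$gene_a)
  tb <- table(raw_pairs$gene_b)
  keep <- ta[raw_pairs$gene_a] == 1L & tb[raw_pairs$gene_b] == 1L
  out <- raw_pairs[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Restrict a gene list by an annotation table
#'
#' Intersection of `genes` with the genes of an annotation table (for
#' example a transcription-factor set defined by a GO term), deduplicated
#' and order-stable in `genes`.
#'
#' @param genes character vector.
#' @param tf_table data.frame with a `gene` column (e.g. gene/term pairs).
#' @return character vector.
#' @export
restrict_gene_set <- function(genes, tf_table) {
  if (is.null(tf_table) || nrow(tf_table) == 0L) return(character())
  unique(genes[genes %in% tf_table$gene])
}

#' Mean expression profiles per assigned cell type
#'
#' @param nm an `sc_norm` (or genes x cells matrix).
#' @param assignment an assignment data.frame with `barcode` and `subtype`
#'   (cells labelled `Unassigned` or `NA` are skipped).
#' @param gene_set optional gene restriction.
#' @param min_cells minimum cells per type (default 10); smaller types are
#'   excluded and recorded in `attr(, "excluded")`.
#' @param km optional [knowledge_matrix()]; when given, rows are ordered by
#'   `dv_rank`.
#' @return types x genes matrix with attribute `n_cells`.
#' @export
mean_profiles <- function(nm, assignment, gene_set = NULL, min_cells = 10,
                          km = NULL) {
  m <- norm_mat(nm)
  if (!is.null(gene_set)) {
    gene_set <- intersect(gene_set, rownames(m))
    m <- m[gene_set, , drop = FALSE]
  }
  lab <- assignment$subtype[match(colnames(m), assignment$barcode)]
  ok <- !is.na(lab) & lab != "Unassigned"
  counts <- table(lab[ok])
  keep_types <- names(counts)[counts >= min_cells]
  if (length(keep_types) == 0L)
    stopf("no cell type reaches min_cells = %d", min_cells)
  prof <- t(vapply(keep_types, function(t) {
    Matrix::rowMeans(m[, ok & lab == t, drop = FALSE])
  }, numeric(nrow(m))))
  if (!is.null(km)) {
    rk <- km$dv_rank[match(rownames(prof), km$type)]
    prof <- prof[order(is.na(rk), rk, rownames(prof)), , drop = FALSE]
  }
  attr(prof, "n_cells") <- as.integer(counts[rownames(prof)])
  attr(prof, "excluded") <- setdiff(names(counts), keep_types)
  prof
}

#' Cross-species per-type correlation
#'
#' Translates species-B genes through a 1:1 ortholog map, intersects the
#' gene sets and computes the correlation of every pair of type profiles.
#' Constant profiles give undefined coefficients, reported as `NA` (never
#' 0) with a warning.
#'
#' @param profiles_a,profiles_b types x genes matrices (species A / B).
#' @param map an [map_orthologs()] result (`gene_a` = A names, `gene_b` =
#'   B names); `NULL` for same-namespace comparisons.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return matrix of coefficients, types_A x types_B.
#' @export
cross_correlate <- function(profiles_a, profiles_b, map = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(map)) {
    idx <- match(colnames(profiles_b), map$gene_b)
    keep <- !is.na(idx)
    profiles_b <- profiles_b[, keep, drop = FALSE]
    colnames(profiles_b) <- map$gene_a[idx[keep]]
  }
  shared <- intersect(colnames(profiles_a), colnames(profiles_b))
  if (length(shared) < 2L) stopf("fewer than 2 shared genes after mapping")
  a <- profiles_a[, shared, drop = FALSE]
  b <- profiles_b[, shared, drop = FALSE]
  out <- suppressWarnings(stats::cor(t(a), t(b), method = method))
  if (anyNA(out)) warnf("constant profiles produced undefined coefficients (NA)")
  out
}

#' In vivo / in vitro staging correlation
#'
#' Each time point (row of the stage pseudo-bulk, column of the bulk
#' matrix) is min-max scaled to [0, 1] over the shared gene subset, then
#' Spearman's correlation is computed for every (stage, day) pair.  The
#' scaling is monotone, so Spearman coefficients are unchanged by it; it is
#' kept for comparability of the stored profiles.
#'
#' @param pseudobulk stages x genes matrix (e.g. ventral-domain pseudo-bulk
#'   per stage).
#' @param bulk genes x days matrix.
#' @param gene_subset optional gene restriction (default: shared genes).
#' @return stages x days matrix of Spearman coefficients (`NA` for constant
#'   columns).
#' @export
staging_correlation <- function(pseudobulk, bulk, gene_subset = NULL) {
  shared <- intersect(colnames(pseudobulk), rownames(bulk))
  if (!is.null(gene_subset)) shared <- intersect(shared, gene_subset)
  if (length(shared) < 2L) stopf("shared gene subset is empty or too small")
  minmax <- function(x) {
    r <- range(x)
    if (diff(r) < .Machine$double.eps) return(rep(NA_real_, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  a <- apply(pseudobulk[, shared, drop = FALSE], 1L, minmax)  # genes x stages
  b <- apply(bulk[shared, , drop = FALSE], 2L, minmax)        # genes x days
  out <- suppressWarnings(stats::cor(a, b, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rownames(out) <- rownames(pseudobulk)
  colnames(out) <- colnames(bulk)
  if (anyNA(out)) warnf("constant profiles produced undefined coefficients (NA)")
  out
}

#' Ventral-domain pseudo-bulk per stage
#'
#' Mean expression over cells assigned to the given domains, per stage --
#' the pseudo-bulk used for in vivo / in vitro staging comparisons.
#'
#' @param nm an `sc_norm`.
#' @param assignment assignment data.frame with `barcode`, `subtype`,
#'   `stage`.
#' @param domains subtypes to include (default: ventral progenitor domains
#'   and their neurons).
#' @return stages x genes matrix.
#' @export
stage_pseudobulk <- function(nm, assignment,
                             domains = c("p0", "p1", "p2", "pMN", "p3",
                                         "V0", "V1", "V2", "MN", "V3")) {
  m <- norm_mat(nm)
  idx <- match(colnames(m), assignment$barcode)
  lab <- assignment$subtype[idx]
  stage <- assignment$stage[idx]
  ok <- !is.na(lab) & lab %in% domains
  if (!any(ok)) stopf("no cells assigned to the requested domains")
  stages <- sort(unique(stage[ok]))
  out <- t(vapply(stages, function(s) {
    Matrix::rowMeans(m[, ok & stage == s, drop = FALSE])
  }, numeric(nrow(m))))
  rownames(out) <- stages
  out
}

#' Genes most correlated with a target gene
#'
#' Spearman correlation of every other gene against the target within a
#' cell subset; the top `k` positive correlates are returned in descending
#' order, ties broken by gene name.
#'
#' @param nm an `sc_norm` (or genes x cells matrix).
#' @param target_gene gene name; must be expressed (count > 0) in at least
#'   3 subset cells.
#' @param cell_subset barcodes (or indices) defining the subset; `NULL`
#'   uses all cells.
#' @param k number of genes to return (default 30); fewer are returned when
#'   there are fewer positive correlates, without padding.
#' @return data.frame `gene`, `rho`, sorted by decreasing `rho`.
#' @export
correlated_genes <- function(nm, target_gene, cell_subset = NULL, k = 30) {
  m <- norm_mat(nm)
  if (!target_gene %in% rownames(m)) stopf("target gene '%s' not found",
                                           target_gene)
  if (!is.null(cell_subset)) {
    if (is.character(cell_subset)) cell_subset <- match(cell_subset, colnames(m))
    m <- m[, cell_subset, drop = FALSE]
  }
  target <- as.numeric(m[target_gene, ])
  if (sum(target > 0) < 3L)
    stopf("target gene expressed in fewer than 3 subset cells")
  others <- setdiff(rownames(m), target_gene)
  rho <- suppressWarnings(
    as.numeric(stats::cor(as.matrix(Matrix::t(m[others, , drop = FALSE])),
                          target, method = "spearman")))
  names(rho) <- others
  rho <- rho[!is.na(rho) & rho > 0]
  ord <- order(-rho, names(rho))
  top <- utils::head(ord, k)
  data.frame(gene = names(rho)[top], rho = unname(rho[top]),
             stringsAsFactors = FALSE)
}
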