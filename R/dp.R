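#' Gate OLIG2/NKX2-2 single- and double-positive progenitors
#'
#' Within SOX2-positive cells (binarised), partitions the cells expressing
#' OLIG2 or NKX2-2 into: `dp` (both markers), `pmn_like` (OLIG2 only) and
#' `p3_like` (NKX2-2 only).  SOX2-negative cells are excluded.  The three
#' sets are pairwise disjoint by construction.
#'
#' @param bm a `binary_matrix` containing SOX2, OLIG2 and NKX2-2 rows.
#' @return a `gate_groups` list of barcode vectors `dp`, `pmn_like`,
#'   `p3_like`.
#' @export
gate_cells <- function(bm) {
  for (g in c("SOX2", "OLIG2", "NKX2-2"))
    if (!g %in% rownames(bm$mat)) stopf("gate gene '%s' missing from binary matrix", g)
  sox2 <- bm$mat["SOX2", ] > 0L
  olig2 <- bm$mat["OLIG2", ] > 0L
  nkx22 <- bm$mat["NKX2-2", ] > 0L
  bc <- colnames(bm$mat)
  structure(list(dp = bc[sox2 & olig2 & nkx22],
                 pmn_like = bc[sox2 & olig2 & !nkx22],
                 p3_like = bc[sox2 & !olig2 & nkx22]),
            class = "gate_groups")
}

#' @export
print.gate_groups <- function(x, ...) {
  cat(sprintf("gate_groups: dp=%d, pmn_like=%d, p3_like=%d\n",
              length(x$dp), length(x$pmn_like), length(x$p3_like)))
  invisible(x)
}

#' Double-positive ratio
#'
#' Ratio of OLIG2/NKX2-2 double-positive cells within all gated cells
#' (those expressing either marker), overall or per stage.
#'
#' @param groups a [gate_cells()] result.
#' @param cell_meta optional data.frame with `barcode` and `stage`; when
#'   given, ratios are computed per stage.
#' @return when `cell_meta` is `NULL`, a single ratio; otherwise a
#'   data.frame `stage`, `n_dp`, `n_gated`, `ratio` (`NA` when a stage has
#'   no gated cells).
#' @export
dp_ratio <- function(groups, cell_meta = NULL) {
  if (is.null(cell_meta)) {
    n_gated <- length(groups$dp) + length(groups$pmn_like) +
      length(groups$p3_like)
    return(if (n_gated == 0) NA_real_ else length(groups$dp) / n_gated)
  }
  stage_of <- stats::setNames(cell_meta$stage, cell_meta$barcode)
  stages <- sort(unique(cell_meta$stage))
  out <- data.frame(stage = stages, n_dp = 0L, n_gated = 0L,
                    ratio = NA_real_, stringsAsFactors = FALSE)
  all_gated <- c(groups$dp, groups$pmn_like, groups$p3_like)
  for (i in seq_along(stages)) {
    s <- stages[i]
    n_dp <- sum(stage_of[groups$dp] == s, na.rm = TRUE)
    n_gated <- sum(stage_of[all_gated] == s, na.rm = TRUE)
    out$n_dp[i] <- n_dp
    out$n_gated[i] <- n_gated
    out$ratio[i] <- if (n_gated > 0) n_dp / n_gated else NA_real_
  }
  out
}

#' Transcriptional similarity of double-positive cells to pMN and p3
#'
#' Mean expression profiles are computed per stage for the double-positive
#' cells and for the cells assigned to each reference population; the
#' similarity of each pair of profiles is mapped into [0, 1].  The default
#' metric is `(Pearson r + 1) / 2` (bounded and scale-free); a
#' Euclidean-distance alternative `1 / (1 + d)` is available.  Identical
#' profiles give similarity 1, and symmetric mixtures are equidistant from
#' both references.
#'
#' @param nm an `sc_norm`.
#' @param groups a [gate_cells()] result (`dp` barcodes are used).
#' @param assignment assignment data.frame locating the reference
#'   populations.
#' @param gene_space genes over which profiles are compared (default: the
#'   knowledge-matrix markers plus the gliogenic list; `NULL` for all
#'   genes).
#' @param references subtypes to compare against (default pMN and p3).
#' @param min_cells minimum cells per profile per stage (default 10);
#'   under-powered entries are `NA`.
#' @param method `"pearson"` (default) or `"euclidean"`.
#' @return data.frame `stage`, `reference`, `n_dp`, `n_ref`, `similarity`.
#' @export
dp_similarity <- function(nm, groups, assignment,
                          gene_space = c(km_marker_genes(default_knowledge_matrix()),
                                         gliogenic_genes()),
                          references = c("pMN", "p3"), min_cells = 10,
                          method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  m <- norm_mat(nm)
  if (!is.null(gene_space))
    m <- m[intersect(unique(gene_space), rownames(m)), , drop = FALSE]
  idx <- match(colnames(m), assignment$barcode)
  stage <- assignment$stage[idx]
  lab <- assignment$subtype[idx]
  is_dp <- colnames(m) %in% groups$dp
  stages <- sort(unique(stage[is_dp]))
  grid <- expand.grid(stage = stages, reference = references,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L)
    return(data.frame(stage = character(), reference = character(),
                      n_dp = integer(), n_ref = integer(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  grid$n_dp <- NA_integer_; grid$n_ref <- NA_integer_
  grid$similarity <- NA_real_
  for (i in seq_len(nrow(grid))) {
    s <- grid$stage[i]; ref <- grid$reference[i]
    dp_cells <- which(is_dp & stage == s)
    ref_cells <- which(!is.na(lab) & lab == ref & stage == s)
    grid$n_dp[i] <- length(dp_cells)
    grid$n_ref[i] <- length(ref_cells)
    if (length(dp_cells) < min_cells || length(ref_cells) < min_cells) next
    p_dp <- Matrix::rowMeans(m[, dp_cells, drop = FALSE])
    p_ref <- Matrix::rowMeans(m[, ref_cells, drop = FALSE])
    grid$similarity[i] <- profile_similarity(p_dp, p_ref, method)
  }
  grid
}

profile_similarity <- function(a, b, method) {
  if (method == "pearson") {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    (stats::cor(a, b) + 1) / 2
  } else {
    1 / (1 + sqrt(sum((a - b)^2)))
  }
}
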