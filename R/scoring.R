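#' Depth-scaled log normalisation
#'
#' `expression = log1p(count * target_depth / cell_total / pseudo_count)`,
#' a monotone per-cell normalisation: counts of 0 map to 0 and cells whose
#' total equals `target_depth` get plain `log1p(count)` (at the default
#' pseudo-count of 1).  Cells with zero total counts are left at zero.
#'
#' @param cm an [sc_counts()].
#' @param target_depth scale factor; `NULL` (default) uses the median cell
#'   total, the convention that keeps normalised values on the raw count
#'   scale.
#' @param pseudo_count pseudo-count (default 1).
#' @return an `sc_norm` object: sparse genes x cells expression plus the
#'   normalisation descriptor and the cell metadata.
#' @export
normalize_log <- function(cm, target_depth = NULL, pseudo_count = 1) {
  totals <- Matrix::colSums(cm$counts)
  if (is.null(target_depth)) target_depth <- stats::median(totals[totals > 0])
  assert_scalar_num(target_depth, "target_depth", lower = 1e-12)
  assert_scalar_num(pseudo_count, "pseudo_count", lower = 1e-12)
  scale <- ifelse(totals > 0, target_depth / totals, 0)
  m <- cm$counts %*% Matrix::Diagonal(x = scale / pseudo_count)
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(cm$counts)
  structure(list(mat = methods::as(m, "CsparseMatrix"),
                 target_depth = target_depth, pseudo_count = pseudo_count,
                 cell_meta = cm$cell_meta), class = "sc_norm")
}

#' @export
print.sc_norm <- function(x, ...) {
  cat(sprintf("sc_norm: %d genes x %d cells (target_depth %.1f)\n",
              nrow(x$mat), ncol(x$mat), x$target_depth))
  invisible(x)
}

# Accept an sc_norm or a plain genes x cells matrix.
norm_mat <- function(nm) {
  if (inherits(nm, "sc_norm")) nm$mat
  else if (is.matrix(nm) || methods::is(nm, "Matrix")) nm
  else stopf("expected an sc_norm or a genes x cells matrix")
}

#' Gene-module score with expression-matched controls
#'
#' Per cell: mean expression of the module genes minus the mean expression
#' of a control pool.  All dataset genes are ranked by dataset-wide mean
#' expression (ties broken by gene name, making the score invariant to gene
#' ordering) and cut into `n_bins` equal-size bins; each module gene
#' contributes `n_ctrl` control genes drawn with replacement from its bin
#' under `seed`.  A module whose genes all have identical expression to
#' their bins scores 0, and adding a constant to every expression value
#' leaves scores unchanged.
#'
#' @param nm an `sc_norm` (or genes x cells matrix).
#' @param module a [gene_module()].
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes per module gene (default 100); a value at
#'   least the bin size uses the whole bin, deterministically.
#' @param seed RNG seed for control sampling.
#' @param control subtract the expression-matched control pool (default
#'   `TRUE`).  With `FALSE` the score is the plain mean module expression:
#'   control matching centres ubiquitously active programmes at zero, so
#'   absolute programme activity (used for broad tissue assignment) needs
#'   the unsubtracted mean.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(nm, module, n_bins = 24, n_ctrl = 100, seed = 0L,
                         control = TRUE) {
  m <- norm_mat(nm)
  if (!inherits(module, "gene_module")) stopf("module must be a gene_module")
  present <- intersect(module$genes, rownames(m))
  if (length(present) == 0L)
    stopf("none of the %d genes of module '%s' are in the dataset",
          length(module$genes), module$name)
  if (length(present) < length(module$genes))
    warnf("module '%s': %d of %d genes absent from the dataset",
          module$name, length(module$genes) - length(present),
          length(module$genes))
  if (!control) {
    sig <- Matrix::colMeans(m[present, , drop = FALSE])
    return(stats::setNames(as.numeric(sig), colnames(m)))
  }
  means <- Matrix::rowMeans(m)
  ord <- order(means, rownames(m))
  n_gene <- nrow(m)
  bins <- integer(n_gene)
  bins[ord] <- ceiling(seq_len(n_gene) * min(n_bins, n_gene) / n_gene)
  names(bins) <- rownames(m)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- sort(rownames(m)[bins == bins[[g]]])
      # a request for at least the whole bin is served exhaustively, making
      # the score deterministic and equal to a mean-difference over the bin
      if (n_ctrl >= length(pool)) pool
      else pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })
  sig <- Matrix::colMeans(m[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(sig - ctrl_mean), colnames(m))
}

#' Cell-cycle scores and phase calls
#'
#' S and G2M scores via [module_score()], a phase call (G1 when both scores
#' are <= 0, otherwise the larger score's phase with ties going to G2M), and
#' the S - G2M difference used as the regression covariate.
#'
#' @param nm an `sc_norm`.
#' @param s_genes,g2m_genes [gene_module()]s (defaults: the shipped
#'   canonical lists).
#' @param seed RNG seed for control sampling.
#' @param n_bins,n_ctrl passed to [module_score()].
#' @return data.frame with `barcode`, `s_score`, `g2m_score`, `difference`
#'   (`s_score - g2m_score`, exactly) and `phase`.
#' @export
cell_cycle_scores <- function(nm, s_genes = cell_cycle_modules()$s,
                              g2m_genes = cell_cycle_modules()$g2m,
                              seed = 0L, n_bins = 24, n_ctrl = 100) {
  s <- module_score(nm, s_genes, n_bins, n_ctrl, seed = derive_seed(seed, 1L))
  g2m <- module_score(nm, g2m_genes, n_bins, n_ctrl,
                      seed = derive_seed(seed, 2L))
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(g2m >= s, "G2M", "S"))
  data.frame(barcode = names(s), s_score = unname(s),
             g2m_score = unname(g2m), difference = unname(s - g2m),
             phase = unname(phase), stringsAsFactors = FALSE)
}

#' Residualise expression on a per-cell covariate
#'
#' Per gene, ordinary least-squares regression of expression on the
#' covariate; the fitted covariate effect is subtracted while the gene mean
#' is kept (mean-preserving residualisation).  A constant covariate returns
#' the input unchanged with a warning.
#'
#' @param nm an `sc_norm`.
#' @param covariate finite numeric vector, one value per cell.
#' @return an `sc_norm` with dense residualised expression.
#' @export
regress_covariate <- function(nm, covariate) {
  m <- norm_mat(nm)
  if (length(covariate) != ncol(m))
    stopf("covariate length (%d) != number of cells (%d)", length(covariate),
          ncol(m))
  if (any(!is.finite(covariate))) stopf("covariate must be finite")
  cc <- covariate - mean(covariate)
  ss <- sum(cc^2)
  if (ss < 1e-12) {
    warnf("constant covariate: returning input unchanged")
    return(nm)
  }
  beta <- as.numeric(m %*% cc) / ss     # per-gene slope
  out <- as.matrix(m) - outer(beta, cc)
  res <- structure(list(mat = out,
                        target_depth = if (inherits(nm, "sc_norm")) nm$target_depth else NA,
                        pseudo_count = if (inherits(nm, "sc_norm")) nm$pseudo_count else NA,
                        cell_meta = if (inherits(nm, "sc_norm")) nm$cell_meta else NULL),
                   class = "sc_norm")
  res
}

#' Gliogenic programme score
#'
#' [module_score()] over the fixed 11-gene gliogenic marker list (FABP7,
#' SOX9, SOX10, PDGFRA, CSPG4, FGFR3, FGFBP3, DBI, SLC1A3, HOPX, ALDH1L1).
#'
#' @param nm an `sc_norm`.
#' @param seed RNG seed for control sampling.
#' @param n_bins,n_ctrl passed to [module_score()].
#' @return per-cell score vector.
#' @export
gliogenic_score <- function(nm, seed = 0L, n_bins = 24, n_ctrl = 100) {
  module_score(nm, gene_module("gliogenic", gliogenic_genes()),
               n_bins, n_ctrl, seed = seed)
}
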