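#' Binarise marker expression
#'
#' Per marker gene, a threshold is chosen and a cell is called positive
#' (`1`) iff its normalised expression exceeds it.  The default method is
#' Otsu's criterion on the histogram of the gene's expression values, with
#' documented special cases: genes positive (expression > 0) in fewer than
#' `min_pos_frac` of cells are set all-zero; genes positive in more than
#' `ubiquitous_frac` of cells are treated as ubiquitously expressed and
#' thresholded at 0 (detection); a degenerate Otsu solution falls back to
#' the midpoint of the min/max.  A gene is only considered expressed when
#' the cells above its threshold average at least `min_on_mean` normalised
#' units (default `log1p(2)`, i.e. about two transcripts in a typical cell
#' under median-depth scaling): Otsu always finds a split, and without this
#' guard a marker with no genuinely expressing population would call every
#' cell with a single stray transcript positive.  Marker genes absent from
#' the dataset are listed in a warning and returned as all-zero rows.
#'
#' @param nm an `sc_norm` (or genes x cells matrix).
#' @param marker_genes character vector of marker genes (non-empty).
#' @param method `"otsu"` (default) or `"midpoint"`.
#' @param min_pos_frac below this positive fraction a gene is all-zero
#'   (default 0.01).
#' @param ubiquitous_frac above this positive fraction the threshold is 0
#'   (default 0.99).
#' @param n_hist_bins histogram resolution for Otsu (default 256).
#' @param min_on_mean minimum mean normalised expression of the positive
#'   class (default `log1p(2)`); set to 0 to disable the guard.
#' @return a `binary_matrix`: list with `mat` (markers x cells, 0/1 integer)
#'   and `thresholds` (named numeric; `Inf` marks all-zero genes).
#' @export
binarize_expression <- function(nm, marker_genes,
                                method = c("otsu", "midpoint"),
                                min_pos_frac = 0.01, ubiquitous_frac = 0.99,
                                n_hist_bins = 256, min_on_mean = log1p(2)) {
  method <- match.arg(method)
  if (length(marker_genes) == 0L) stopf("empty marker gene list")
  m <- norm_mat(nm)
  missing <- setdiff(marker_genes, rownames(m))
  if (length(missing))
    warnf("%d marker gene(s) absent from the dataset, treated as all-zero: %s",
          length(missing), paste(missing, collapse = ", "))
  out <- matrix(0L, length(marker_genes), ncol(m),
                dimnames = list(marker_genes, colnames(m)))
  thresholds <- stats::setNames(rep(Inf, length(marker_genes)), marker_genes)
  for (g in setdiff(marker_genes, missing)) {
    v <- as.numeric(m[g, ])
    pos_frac <- mean(v > 0)
    if (pos_frac < min_pos_frac) next
    if (pos_frac > ubiquitous_frac) {
      t <- 0
    } else if (method == "midpoint") {
      t <- (min(v) + max(v)) / 2
    } else {
      t <- otsu_threshold(v, n_hist_bins)
      if (is.na(t)) t <- (min(v) + max(v)) / 2
    }
    on <- v > t
    if (any(on) && mean(v[on]) < min_on_mean) next  # no real on-population
    thresholds[[g]] <- t
    out[g, ] <- as.integer(on)
  }
  structure(list(mat = out, thresholds = thresholds),
            class = "binary_matrix")
}

# Otsu's threshold: maximises between-class variance on a fixed-width
# histogram.  Returns NA when degenerate (constant input).
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  if (!is.finite(bcv[k])) return(NA_real_)
  breaks[k + 1L]
}

# rows of a binary matrix, defaulting to all-zero when the gene is missing
bm_row <- function(bm, gene) {
  if (gene %in% rownames(bm$mat)) bm$mat[gene, ] > 0L
  else rep(FALSE, ncol(bm$mat))
}

#' Assign broad tissue labels from module scores
#'
#' `label = argmax module score` when that maximum is at least `min_score`
#' and unique; otherwise `"other"`.
#'
#' @param scores cells x modules numeric matrix (or data.frame) of module
#'   scores; column names are the tissue labels.
#' @param min_score minimum winning score (default 0).
#' @return character vector of tissue labels, named by cell.
#' @export
assign_broad_type <- function(scores, min_score = 0) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1L) stopf("need >= 1 scored tissue module")
  top <- apply(scores, 1L, max)
  n_top <- rowSums(scores == top)
  label <- colnames(scores)[apply(scores, 1L, which.max)]
  label[top < min_score | n_top > 1L] <- "other"
  stats::setNames(label, rownames(scores))
}

#' Assign CNS subtypes from binarised markers and a knowledge matrix
#'
#' For each cell, every eligible knowledge-matrix row is scored by
#' `mismatches = (# required markers absent) + (# forbidden markers
#' present)`.  The cell takes the type with the minimal mismatch count when
#' that minimum is at most `max_mismatch` and is achieved by a single row;
#' otherwise it is `"Unassigned"`.  Pan-marker gating prunes the candidate
#' set: cells binarised SOX2-positive and ELAVL3-negative compete only
#' against progenitor (and glia) rows, ELAVL3-positive/SOX2-negative cells
#' only against neuronal rows, and cells positive for both or neither
#' compete across all rows.  Assignment is deterministic and independent of
#' knowledge-matrix row order.
#'
#' @param bm a `binary_matrix` covering the km marker genes (absent genes
#'   count as 0).
#' @param km a [knowledge_matrix()].
#' @param max_mismatch tolerated mismatches (default 0, strict).
#' @param classes km classes eligible for assignment.
#' @param tie_break `"unassigned"` (default) leaves ties unassigned;
#'   `"dv_rank"` resolves them toward the lowest dv_rank.
#' @param gate apply SOX2/ELAVL3 pan-marker gating (default TRUE).
#' @return data.frame `barcode`, `subtype`, `class`, `n_mismatches` (best
#'   mismatch count), `score` (fraction of the winning row's constraints
#'   satisfied; `NA` when unassigned).
#' @export
assign_subtype <- function(bm, km, max_mismatch = 0,
                           classes = c("progenitor", "neuron", "glia"),
                           tie_break = c("unassigned", "dv_rank"),
                           gate = TRUE) {
  tie_break <- match.arg(tie_break)
  kms <- km[km$class %in% classes, , drop = FALSE]
  if (nrow(kms) == 0L) stopf("knowledge matrix has no rows of class %s",
                             paste(classes, collapse = "/"))
  genes <- km_marker_genes(km)
  n_cells <- ncol(bm$mat)
  B <- matrix(0L, length(genes), n_cells, dimnames = list(genes, colnames(bm$mat)))
  shared <- intersect(genes, rownames(bm$mat))
  B[shared, ] <- bm$mat[shared, , drop = FALSE]
  V <- km_values(kms)[, genes, drop = FALSE]
  Rpos <- (V == 1L) + 0
  Rneg <- (V == -1L) + 0
  mism <- Rpos %*% (1 - B) + Rneg %*% B      # types x cells
  n_constraints <- rowSums(Rpos) + rowSums(Rneg)

  if (gate) {
    sox2 <- bm_row(bm, "SOX2"); elav <- bm_row(bm, "ELAVL3")
    prog_rows <- kms$class %in% c("progenitor", "glia")
    neur_rows <- kms$class == "neuron"
    prog_only <- sox2 & !elav
    neur_only <- elav & !sox2
    mism[neur_rows, prog_only] <- Inf
    mism[prog_rows, neur_only] <- Inf
  }

  best <- apply(mism, 2L, min)
  n_best <- colSums(mism == rep(best, each = nrow(mism)))
  pick <- apply(mism, 2L, which.min)
  if (tie_break == "dv_rank") {
    rk <- kms$dv_rank
    rk[is.na(rk)] <- .Machine$integer.max
    for (j in which(n_best > 1L)) {
      tied <- which(mism[, j] == best[j])
      pick[j] <- tied[which.min(rk[tied])]
    }
    n_best[n_best > 1L] <- 1L
  }
  assigned <- is.finite(best) & best <= max_mismatch & n_best == 1L
  subtype <- ifelse(assigned, kms$type[pick], "Unassigned")
  cls <- ifelse(assigned, kms$class[pick], NA_character_)
  score <- ifelse(assigned, 1 - best / n_constraints[pick], NA_real_)
  data.frame(barcode = colnames(bm$mat), subtype = subtype, class = cls,
             n_mismatches = ifelse(is.finite(best), best, NA_real_),
             score = score, stringsAsFactors = FALSE)
}

#' Classify peripheral (neural crest / sensory) cells
#'
#' Three-way staging: cells expressing any of NEUROG1/NEUROG2/NEUROD1 are
#' sensory neuron precursors; remaining ELAVL3-positive cells are
#' postmitotic sensory neurons; remaining SOX10-positive cells (alone or
#' with SOX2) are neural-crest progenitors.  Postmitotic cells are then
#' refined into the knowledge matrix's `pns_neuron` subtypes by the same
#' mismatch rule as [assign_subtype()]; unrefined postmitotic cells keep
#' the generic label `"SensoryNeuron"`.
#'
#' @param bm a `binary_matrix`.
#' @param km a [knowledge_matrix()] containing PNS rows.
#' @param max_mismatch tolerated mismatches in the subtype refinement.
#' @return data.frame as in [assign_subtype()].
#' @export
classify_pns <- function(bm, km, max_mismatch = 0) {
  if (!any(km$class %in% c("pns_progenitor", "pns_precursor", "pns_neuron")))
    stopf("knowledge matrix has no PNS rows")
  prog_label <- km$type[km$class == "pns_progenitor"][1L] %||% "pns_progenitor"
  prec_label <- km$type[km$class == "pns_precursor"][1L] %||% "pns_precursor"
  prec <- bm_row(bm, "NEUROG1") | bm_row(bm, "NEUROG2") | bm_row(bm, "NEUROD1")
  post <- bm_row(bm, "ELAVL3") & !prec
  prog <- bm_row(bm, "SOX10") & !prec & !post

  out <- data.frame(barcode = colnames(bm$mat), subtype = "Unassigned",
                    class = NA_character_, n_mismatches = NA_real_,
                    score = NA_real_, stringsAsFactors = FALSE)
  out$subtype[prog] <- prog_label
  out$class[prog] <- "pns_progenitor"
  out$subtype[prec] <- prec_label
  out$class[prec] <- "pns_precursor"
  if (any(post) && any(km$class == "pns_neuron")) {
    sub_bm <- list(mat = bm$mat[, post, drop = FALSE],
                   thresholds = bm$thresholds)
    class(sub_bm) <- "binary_matrix"
    refined <- assign_subtype(sub_bm, km, max_mismatch = max_mismatch,
                              classes = "pns_neuron", gate = FALSE)
    lab <- ifelse(refined$subtype == "Unassigned", "SensoryNeuron",
                  refined$subtype)
    out$subtype[post] <- lab
    out$class[post] <- "pns_neuron"
    out$n_mismatches[post] <- refined$n_mismatches
    out$score[post] <- refined$score
  } else if (any(post)) {
    out$subtype[post] <- "SensoryNeuron"
    out$class[post] <- "pns_neuron"
  }
  out
}

#' Two-step knowledge-matrix classification
#'
#' The full classification pipeline: depth-scaled log normalisation, tissue
#' module scoring, broad tissue assignment, marker binarisation restricted
#' to the neural cells, and subtype assignment -- CNS cells via
#' [assign_subtype()], peripheral cells (binarised SIX1-positive, or
#' SOX10-positive without OLIG2) via [classify_pns()].  Non-neural cells
#' never receive a subtype.
#'
#' @param cm an [sc_counts()].
#' @param km a [knowledge_matrix()].
#' @param modules named list of tissue [gene_module()]s for the broad step.
#' @param params list of optional overrides: `target_depth`, `pseudo_count`,
#'   `n_bins`, `n_ctrl`, `seed`, `min_score`, `max_mismatch`,
#'   `binarize_method`, `min_pos_frac`, `ubiquitous_frac`, `tie_break`,
#'   `binarize_scope` (`"combined"`, default, or `"per_sample"`).
#' @param verbose print the per-step cell-count log.
#' @return an `sc_assignment` data.frame: `barcode`, `sample`, `stage`,
#'   `tissue`, `subtype`, `class`, `n_mismatches`, `score`, plus any truth
#'   columns from the input metadata.  The per-step log is in
#'   `attr(, "log")`.
#' @export
two_step_classify <- function(cm, km = default_knowledge_matrix(),
                              modules = default_tissue_modules(),
                              params = list(), verbose = FALSE) {
  p <- utils::modifyList(
    list(target_depth = NULL, pseudo_count = 1, n_bins = 24, n_ctrl = 100,
         seed = 0L, min_score = 0, max_mismatch = 0,
         binarize_method = "otsu", min_pos_frac = 0.01,
         ubiquitous_frac = 0.99, min_on_mean = log1p(2),
         tie_break = "unassigned",
         binarize_scope = "combined"),
    params)
  nm <- normalize_log(cm, p$target_depth, p$pseudo_count)
  # broad step: absolute programme activity (no control subtraction), so a
  # homogeneous dataset still gets its tissue called correctly
  scores <- vapply(seq_along(modules), function(i) {
    module_score(nm, modules[[i]], p$n_bins, p$n_ctrl,
                 seed = derive_seed(p$seed, i), control = FALSE)
  }, numeric(ncol(nm$mat)))
  colnames(scores) <- names(modules)
  rownames(scores) <- colnames(nm$mat)
  tissue <- assign_broad_type(scores, p$min_score)

  out <- data.frame(barcode = colnames(cm$counts),
                    sample = cm$cell_meta$sample,
                    stage = cm$cell_meta$stage,
                    tissue = unname(tissue), subtype = NA_character_,
                    class = NA_character_, n_mismatches = NA_real_,
                    score = NA_real_, stringsAsFactors = FALSE)
  neural <- which(tissue == "neural")
  log <- data.frame(step = c("input", "neural"),
                    n_cells = c(ncol(cm$counts), length(neural)))

  if (length(neural)) {
    genes <- km_marker_genes(km)
    nm_neural <- structure(list(
      mat = nm$mat[, neural, drop = FALSE], target_depth = nm$target_depth,
      pseudo_count = nm$pseudo_count,
      cell_meta = nm$cell_meta[neural, , drop = FALSE]), class = "sc_norm")
    bm <- binarize_neural(nm_neural, genes, p)
    pns <- bm_row(bm, "SIX1") | (bm_row(bm, "SOX10") & !bm_row(bm, "OLIG2"))
    fill <- function(idx, res) {
      out$subtype[idx] <<- res$subtype
      out$class[idx] <<- res$class
      out$n_mismatches[idx] <<- res$n_mismatches
      out$score[idx] <<- res$score
    }
    if (any(!pns)) {
      sub <- subset_binary(bm, !pns)
      fill(neural[!pns], assign_subtype(sub, km, p$max_mismatch,
                                        tie_break = p$tie_break))
    }
    if (any(pns) && any(km$class %in% c("pns_progenitor", "pns_precursor",
                                        "pns_neuron"))) {
      fill(neural[pns], classify_pns(subset_binary(bm, pns), km,
                                     p$max_mismatch))
    } else if (any(pns)) {
      out$subtype[neural[pns]] <- "Unassigned"
    }
    log <- rbind(log, data.frame(
      step = c("cns_branch", "pns_branch", "assigned"),
      n_cells = c(sum(!pns), sum(pns),
                  sum(!is.na(out$subtype) & out$subtype != "Unassigned"))))
    attr(out, "binary") <- bm
  }
  truth_cols <- grep("^(truth_|sex$)", names(cm$cell_meta), value = TRUE)
  for (col in truth_cols) out[[col]] <- cm$cell_meta[[col]]
  if (verbose) {
    for (i in seq_len(nrow(log)))
      message(sprintf("  %-12s %d cells", log$step[i], log$n_cells[i]))
  }
  attr(out, "log") <- log
  class(out) <- c("sc_assignment", "data.frame")
  out
}

binarize_neural <- function(nm_neural, genes, p) {
  if (identical(p$binarize_scope, "per_sample")) {
    samples <- nm_neural$cell_meta$sample
    parts <- lapply(unique(samples), function(s) {
      idx <- samples == s
      sub <- structure(list(mat = nm_neural$mat[, idx, drop = FALSE]),
                       class = "sc_norm")
      binarize_expression(sub, genes, p$binarize_method, p$min_pos_frac,
                          p$ubiquitous_frac, min_on_mean = p$min_on_mean)
    })
    mat <- do.call(cbind, lapply(parts, function(b) b$mat))
    mat <- mat[, colnames(nm_neural$mat), drop = FALSE]
    structure(list(mat = mat, thresholds = parts[[1L]]$thresholds),
              class = "binary_matrix")
  } else {
    binarize_expression(nm_neural, genes, p$binarize_method, p$min_pos_frac,
                        p$ubiquitous_frac, min_on_mean = p$min_on_mean)
  }
}

subset_binary <- function(bm, idx) {
  structure(list(mat = bm$mat[, idx, drop = FALSE],
                 thresholds = bm$thresholds), class = "binary_matrix")
}
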