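#' Simulation parameters
#'
#' Parameters of the negative-binomial count generator.  Counts for a cell of
#' type `t` are drawn as `NB(mu * depth, size = dispersion)` where `mu` is
#' `mu_on` for the type's required markers (and pan-programme genes) and
#' `mu_off` for every other marker, and `depth` is a per-cell log-normal
#' library-size multiplier with unit mean.  `dispersion` is the NB size
#' parameter (variance `mu + mu^2/size`); `Inf` gives the Poisson limit.
#'
#' @param mu_on mean UMI count of a required marker in its own type.
#' @param mu_off mean count of a non-required marker (`< mu_on`).
#' @param dispersion NB size parameter (> 0, may be `Inf`).
#' @param n_housekeeping number of always-on background genes.
#' @param mito_frac_mean mean mitochondrial UMI fraction in `[0, 1)`.
#' @param depth_sdlog log-sd of the per-cell depth multiplier (0 disables).
#' @param sry_mu mean count of the male-specific SRY gene in male samples.
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @return a `sim_params` list.
#' @export
sim_params <- function(mu_on = 20, mu_off = 0.05, dispersion = 10,
                       n_housekeeping = 50, mito_frac_mean = 0.05,
                       depth_sdlog = 0.35, sry_mu = 0.2, seed = 1L) {
  assert_scalar_num(mu_on, "mu_on", lower = 1e-12)
  assert_scalar_num(mu_off, "mu_off", lower = 0)
  if (mu_off >= mu_on) stopf("mu_off must be < mu_on")
  assert_scalar_num(dispersion, "dispersion", lower = 1e-12, allow_inf = TRUE)
  assert_scalar_num(n_housekeeping, "n_housekeeping", lower = 0)
  assert_scalar_num(mito_frac_mean, "mito_frac_mean", lower = 0, upper = 1 - 1e-9)
  assert_scalar_num(depth_sdlog, "depth_sdlog", lower = 0)
  assert_scalar_num(sry_mu, "sry_mu", lower = 0)
  structure(list(mu_on = mu_on, mu_off = mu_off, dispersion = dispersion,
                 n_housekeeping = as.integer(n_housekeeping),
                 mito_frac_mean = mito_frac_mean, depth_sdlog = depth_sdlog,
                 sry_mu = sry_mu, seed = as.integer(seed)),
            class = "sim_params")
}

#' Noise-free simulation parameters
#'
#' Poisson counts (`dispersion = Inf`), `mu_off = 0`, no depth variation and
#' no mitochondrial contamination: every cell expresses exactly its required
#' markers, so the downstream classifier must recover 100% of truth labels.
#'
#' @param mu_on on-marker mean (default 50).
#' @param seed RNG seed.
#' @return a `sim_params` list.
#' @export
noise_free_params <- function(mu_on = 50, seed = 1L) {
  sim_params(mu_on = mu_on, mu_off = 0, dispersion = Inf,
             mito_frac_mean = 0, depth_sdlog = 0, seed = seed)
}

#' Stage composition
#'
#' The requested cell-type mixture of one developmental stage sample.
#'
#' @param stage_label stage name, e.g. `"CS12"`.
#' @param type_proportions named numeric vector of cell-type proportions
#'   (non-negative, summing to 1 within 1e-9).
#' @param n_cells positive integer number of cells to draw.
#' @param sex `"male"` or `"female"`; male samples express SRY.
#' @param sample sample label (defaults to the stage label).
#' @return a `stage_composition` list.
#' @export
stage_composition <- function(stage_label, type_proportions, n_cells,
                              sex = c("female", "male"),
                              sample = stage_label) {
  sex <- match.arg(sex)
  if (!is.numeric(type_proportions) || is.null(names(type_proportions)))
    stopf("type_proportions must be a named numeric vector")
  if (any(type_proportions < 0)) stopf("proportions must be >= 0")
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stopf("proportions must sum to 1 (got %.12f)", sum(type_proportions))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells))
    stopf("n_cells must be a positive integer")
  structure(list(stage_label = as.character(stage_label),
                 type_proportions = type_proportions,
                 n_cells = as.integer(n_cells), sex = sex,
                 sample = as.character(sample)),
            class = "stage_composition")
}

# ---------------------------------------------------------------------------
# Gene universe and per-type mean profiles

# Extra pan-programme genes expressed by whole classes of cells, on top of
# the knowledge-matrix markers: broad tissue programmes, the neuronal
# STMN2/MAP2 module, and the gliogenic programme for glia.
sim_class_programmes <- function() {
  mods <- default_gene_modules()
  list(neural = mods$neural$genes,
       neuron_extra = setdiff(mods$neuron$genes, "ELAVL3"),
       gliogenic = mods$gliogenic$genes)
}

sim_gene_universe <- function(km, params) {
  prog <- sim_class_programmes()
  markers <- km_marker_genes(km)
  extra <- setdiff(unique(c(prog$neural, prog$neuron_extra, prog$gliogenic)),
                   markers)
  hk <- if (params$n_housekeeping > 0)
    sprintf("HK%03d", seq_len(params$n_housekeeping)) else character()
  mt <- sprintf("MT-%d", 1:10)
  list(markers = markers, extra = extra, hk = hk, mt = mt, sry = "SRY",
       all = c(markers, extra, hk, mt, "SRY"))
}

# genes x types matrix of NB means (excluding SRY/mito, which depend on the
# sample sex and the realised totals).
sim_mu_matrix <- function(km, params, universe = sim_gene_universe(km, params)) {
  prog <- sim_class_programmes()
  vals <- km_values(km)
  types <- km$type
  n_gene <- length(universe$all)
  mu <- matrix(0, n_gene, nrow(km), dimnames = list(universe$all, types))
  body_genes <- c(universe$markers, universe$extra)
  mu[body_genes, ] <- params$mu_off
  mu[universe$hk, ] <- params$mu_on
  for (i in seq_len(nrow(km))) {
    req <- colnames(vals)[vals[i, ] == 1L]
    mu[req, i] <- params$mu_on
    cls <- km$class[i]
    if (cls %in% c("progenitor", "neuron", "glia", "pns_progenitor",
                   "pns_precursor", "pns_neuron"))
      mu[prog$neural, i] <- params$mu_on
    if (cls %in% c("neuron", "pns_neuron"))
      mu[prog$neuron_extra, i] <- params$mu_on
    if (cls == "glia")
      mu[prog$gliogenic, i] <- params$mu_on
  }
  # mitochondrial block: scaled so the expected mito fraction per type is
  # mito_frac_mean.
  if (params$mito_frac_mean > 0) {
    f <- params$mito_frac_mean
    tot <- colSums(mu)
    mu[universe$mt, ] <- rep(tot * f / (1 - f) / length(universe$mt),
                             each = length(universe$mt))
  }
  mu
}

# Draw a genes x cells NB count matrix for the given per-cell mean columns.
rnb_matrix <- function(mu_mat, dispersion) {
  n <- length(mu_mat)
  x <- if (is.infinite(dispersion)) stats::rpois(n, lambda = as.vector(mu_mat))
       else stats::rnbinom(n, size = dispersion, mu = as.vector(mu_mat))
  matrix(x, nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
}

# ---------------------------------------------------------------------------

#' Simulate a ground-truthed count matrix
#'
#' Draws negative-binomial UMI counts for a mixture of cell types defined by
#' a knowledge matrix: each cell expresses its type's required markers (and
#' class-level programmes: broad tissue genes, STMN2/MAP2 for neurons, the
#' gliogenic set for glia) at mean `mu_on * depth` and every other marker at
#' `mu_off * depth`.  Housekeeping genes (`HK001`...), a 10-gene
#' mitochondrial block (`MT-` prefix) targeting `mito_frac_mean`, and the
#' male-specific `SRY` gene are appended.  Ground-truth labels are recorded
#' in `cell_meta`.
#'
#' @param km a [knowledge_matrix()]; every composition type must be a row.
#' @param comp a [stage_composition()].
#' @param params a [sim_params()].
#' @return an [sc_counts()] whose `cell_meta` carries `truth_type`,
#'   `truth_class`, `truth_tissue` and `sex`.
#' @examples
#' km <- default_knowledge_matrix()
#' comp <- stage_composition("CS12", c(pMN = 0.5, p3 = 0.5), 100)
#' cm <- simulate_counts(km, comp, noise_free_params())
#' @export
simulate_counts <- function(km, comp, params = sim_params()) {
  if (!inherits(comp, "stage_composition"))
    stopf("comp must be a stage_composition")
  types <- names(comp$type_proportions)
  missing <- setdiff(types, km$type)
  if (length(missing))
    stopf("composition types not in knowledge matrix: %s",
          paste(missing, collapse = ", "))
  universe <- sim_gene_universe(km, params)
  mu <- sim_mu_matrix(km, params, universe)
  if (comp$sex == "male") mu[universe$sry, ] <- params$sry_mu

  with_seed(params$seed, {
    type_draw <- sample(types, comp$n_cells, replace = TRUE,
                        prob = comp$type_proportions)
    depth <- if (params$depth_sdlog > 0)
      stats::rlnorm(comp$n_cells, meanlog = -params$depth_sdlog^2 / 2,
                    sdlog = params$depth_sdlog) else rep(1, comp$n_cells)
    mu_cells <- mu[, match(type_draw, km$type), drop = FALSE] *
      rep(depth, each = nrow(mu))
    counts <- rnb_matrix(mu_cells, params$dispersion)
  })

  colnames(counts) <- sprintf("%s_C%05d", comp$sample, seq_len(comp$n_cells))
  meta <- data.frame(
    barcode = colnames(counts), sample = comp$sample,
    stage = comp$stage_label, sex = comp$sex, truth_type = type_draw,
    truth_class = km$class[match(type_draw, km$type)],
    stringsAsFactors = FALSE)
  meta$truth_tissue <- km_tissue(km)[match(type_draw, km$type)]
  sc_counts(counts, meta)
}

# ---------------------------------------------------------------------------
# Stage presets

#' Default multi-stage composition presets
#'
#' Four Carnegie stages (CS12, CS14, CS17, CS19) spanning gestational weeks
#' 4-7.  The `"cns"` preset contains only CNS progenitors and neurons; the
#' `"full"` preset adds the peripheral sensory lineage, oligodendrocyte
#' precursors and mesoderm/blood/skin contaminants.  Across stages the
#' progenitor share falls (0.85 to 0.40) as neurons accumulate, the ventral
#' pMN+p3 share of progenitors falls (22% at CS12, 11% at CS14, 3% later),
#' and neurons shift from ventral- to dorsal-biased; CS12 and CS17 are male.
#'
#' @param kind `"cns"` or `"full"`.
#' @param n_cells cells per stage (default 1500).
#' @return list of [stage_composition()] objects.
#' @export
stage_preset <- function(kind = c("cns", "full"), n_cells = 1500) {
  kind <- match.arg(kind)
  stages <- c("CS12", "CS14", "CS17", "CS19")
  sexes <- c("male", "female", "male", "female")
  prog_frac <- c(0.85, 0.75, 0.55, 0.40)
  # within-progenitor territory shares: pD, pI, pMN, p3, FP, RP
  prog_split <- rbind(
    CS12 = c(0.30, 0.25, 0.12, 0.10, 0.13, 0.10),
    CS14 = c(0.38, 0.30, 0.06, 0.05, 0.11, 0.10),
    CS17 = c(0.48, 0.36, 0.02, 0.01, 0.065, 0.065),
    CS19 = c(0.52, 0.34, 0.02, 0.01, 0.055, 0.055))
  dorsal_neuron_share <- c(0.20, 0.35, 0.55, 0.65)
  mnv_share <- 0.04

  cns_prop <- function(i) {
    ps <- prog_split[i, ]
    prog <- c(stats::setNames(rep(ps[1] / 6, 6), paste0("dp", 1:6)),
              stats::setNames(rep(ps[2] / 3, 3), paste0("p", 0:2)),
              pMN = ps[3], p3 = ps[4], FP = ps[5], RP = ps[6])
    d <- dorsal_neuron_share[i]
    ventral <- 1 - d - mnv_share
    neur <- c(stats::setNames(rep(d / 6, 6), paste0("dI", 1:6)),
              stats::setNames(rep(ventral / 5, 5),
                              c("V0", "V1", "V2", "MN", "V3")),
              MNV = mnv_share)
    c(prog * prog_frac[i], neur * (1 - prog_frac[i]))
  }

  if (kind == "cns") {
    out <- lapply(seq_along(stages), function(i) {
      p <- cns_prop(i)
      stage_composition(stages[i], p / sum(p), n_cells, sex = sexes[i])
    })
    return(out)
  }

  mesoderm <- c(0.30, 0.25, 0.12, 0.06)
  blood <- c(0.06, 0.05, 0.04, 0.03)
  skin <- c(0.04, 0.04, 0.03, 0.03)
  pns <- c(0.06, 0.08, 0.10, 0.12)
  olp <- c(0.004, 0.004, 0.006, 0.008)
  pns_split <- rbind(  # NCC, precursor, sensory neurons
    CS12 = c(0.80, 0.20, 0.00),
    CS14 = c(0.55, 0.25, 0.20),
    CS17 = c(0.40, 0.25, 0.35),
    CS19 = c(0.30, 0.20, 0.50))
  sens <- c("Mechanoreceptor", "Proprioceptor", "Peptidergic",
            "NonPeptidergic")
  lapply(seq_along(stages), function(i) {
    cns_share <- 1 - mesoderm[i] - blood[i] - skin[i] - pns[i] - olp[i]
    p <- c(cns_prop(i) * cns_share,
           NCC = unname(pns[i] * pns_split[i, 1]),
           SensoryPrec = unname(pns[i] * pns_split[i, 2]),
           stats::setNames(rep(pns[i] * pns_split[i, 3] / 4, 4), sens),
           OLP = olp[i], mesoderm = mesoderm[i], blood = blood[i],
           skin = skin[i])
    stage_composition(stages[i], p / sum(p), n_cells, sex = sexes[i])
  })
}

#' Simulate a multi-stage time course
#'
#' One dataset per stage, each drawn with a sub-seed derived from
#' `params$seed` so the whole course is reproducible.
#'
#' @param stages list of [stage_composition()] (>= 2 stages).
#' @param km a [knowledge_matrix()] (default the shipped one).
#' @param params a [sim_params()].
#' @return named list of [sc_counts()], one per stage.
#' @export
simulate_timecourse <- function(stages, km = default_knowledge_matrix(),
                                params = sim_params()) {
  if (!length(stages)) stopf("empty stage list")
  if (length(stages) < 2L) stopf("need >= 2 stages")
  out <- lapply(seq_along(stages), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    simulate_counts(km, stages[[i]], p)
  })
  names(out) <- vapply(stages, `[[`, "", "stage_label")
  out
}

# ---------------------------------------------------------------------------

# Mouse-style gene symbol: first letter upper-case, remainder lower-case.
species_b_name <- function(g) {
  paste0(toupper(substr(g, 1, 1)), tolower(substr(g, 2, nchar(g))))
}

#' Simulate a cross-species dataset pair with a 1:1 ortholog map
#'
#' Generates two datasets over disjoint gene namespaces (species B uses
#' mouse-style capitalisation) sharing the same per-type mean structure, so
#' cells of the same type correlate across the pair.  `n_signature_genes`
#' extra genes with random type-specific means are added to both species to
#' emulate a transcription-factor panel.  A fraction `ortholog_noise` of
#' genes receives corrupted (duplicate-target) map entries, exercising the
#' 1:1 discard logic downstream.
#'
#' @param km a [knowledge_matrix()].
#' @param comp_a,comp_b [stage_composition()] for each species.
#' @param ortholog_noise fraction in `[0, 1]` of genes with corrupted
#'   mappings.
#' @param params a [sim_params()].
#' @param n_signature_genes extra shared identity genes (default 200).
#' @return list with elements `a`, `b` ([sc_counts()]) and `map`, a
#'   data.frame of raw pairs (`gene_a`, `gene_b`, `one2one_truth`).
#' @export
simulate_ortholog_pair <- function(km, comp_a, comp_b, ortholog_noise = 0,
                                   params = sim_params(),
                                   n_signature_genes = 200) {
  assert_scalar_num(ortholog_noise, "ortholog_noise", lower = 0, upper = 1)
  universe <- sim_gene_universe(km, params)
  sig_names <- if (n_signature_genes > 0)
    sprintf("SIG%04d", seq_len(n_signature_genes)) else character()

  sig_mu <- with_seed(derive_seed(params$seed, 91L), {
    u <- matrix(stats::runif(length(sig_names) * nrow(km)),
                length(sig_names), nrow(km),
                dimnames = list(sig_names, km$type))
    params$mu_on * u^3  # right-skewed: a few strongly expressing types
  })

  pa <- params; pa$seed <- derive_seed(params$seed, 92L)
  pb <- params; pb$seed <- derive_seed(params$seed, 93L)
  a <- simulate_counts_extra(km, comp_a, pa, sig_mu)
  b <- simulate_counts_extra(km, comp_b, pb, sig_mu)
  rownames(b$counts) <- species_b_name(rownames(b$counts))
  b$counts@Dimnames[[1L]] <- make.unique(rownames(b$counts))

  genes_a <- rownames(a$counts)
  map <- data.frame(gene_a = genes_a, gene_b = species_b_name(genes_a),
                    stringsAsFactors = FALSE)
  if (ortholog_noise > 0) {
    k <- round(ortholog_noise * nrow(map))
    corrupt <- with_seed(derive_seed(params$seed, 94L), {
      idx <- sample(nrow(map), k)
      tgt <- sample(setdiff(seq_len(nrow(map)), idx), k, replace = TRUE)
      data.frame(gene_a = map$gene_a[idx], gene_b = map$gene_b[tgt],
                 stringsAsFactors = FALSE)
    })
    map <- rbind(map, corrupt)
  }
  ta <- table(map$gene_a); tb <- table(map$gene_b)
  map$one2one_truth <- ta[map$gene_a] == 1L & tb[map$gene_b] == 1L
  list(a = a, b = b, map = map)
}

# simulate_counts with additional genes x types mean rows (shared identity
# signature used by the ortholog-pair generator).
simulate_counts_extra <- function(km, comp, params, extra_mu) {
  base <- simulate_counts(km, comp, params)
  if (is.null(extra_mu) || nrow(extra_mu) == 0L) return(base)
  type_draw <- base$cell_meta$truth_type
  extra <- with_seed(derive_seed(params$seed, 95L), {
    depth <- rep(1, length(type_draw))  # depth already absorbed by base
    mu_cells <- extra_mu[, match(type_draw, colnames(extra_mu)), drop = FALSE]
    rnb_matrix(mu_cells, params$dispersion)
  })
  colnames(extra) <- colnames(base$counts)
  sc_counts(rbind(base$counts, methods::as(extra, "CsparseMatrix")),
            base$cell_meta)
}

#' Simulate a bulk in-vitro differentiation time course
#'
#' A genes x days matrix whose columns linearly interpolate between the
#' pure-progenitor and pure-neuron pseudo-bulk mean profiles of the given
#' trajectory types, so day `d` is most similar to an in vivo stage with the
#' matching progenitor:neuron balance.  Day 1 (`mix weight 0`) equals the
#' pure-progenitor profile exactly when `noise_sd = 0` (the default).
#'
#' @param km a [knowledge_matrix()].
#' @param trajectory_types character vector of km types; their classes
#'   define the progenitor and neuron poles (default: ventral domains).
#' @param n_days number of days (>= 2).
#' @param params a [sim_params()].
#' @param noise_sd log-normal multiplicative noise sd (default 0:
#'   deterministic).
#' @return genes x days matrix with attribute `mix_weight` (per-day neuron
#'   weight).
#' @export
simulate_bulk_timecourse <- function(km,
                                     trajectory_types = c("p0", "p1", "p2",
                                                          "pMN", "p3", "V0",
                                                          "V1", "V2", "MN",
                                                          "V3"),
                                     n_days = 10, params = sim_params(),
                                     noise_sd = 0) {
  if (n_days < 2) stopf("n_days must be >= 2")
  missing <- setdiff(trajectory_types, km$type)
  if (length(missing))
    stopf("unknown trajectory types: %s", paste(missing, collapse = ", "))
  mu <- sim_mu_matrix(km, params)
  cls <- km$class[match(trajectory_types, km$type)]
  prog <- rowMeans(mu[, trajectory_types[cls == "progenitor"], drop = FALSE])
  neur <- rowMeans(mu[, trajectory_types[cls == "neuron"], drop = FALSE])
  w <- seq(0, 1, length.out = n_days)
  bulk <- outer(prog, 1 - w) + outer(neur, w)
  colnames(bulk) <- sprintf("day%02d", seq_len(n_days))
  if (noise_sd > 0) {
    bulk <- with_seed(derive_seed(params$seed, 96L), {
      bulk * matrix(stats::rlnorm(length(bulk), -noise_sd^2 / 2, noise_sd),
                    nrow(bulk))
    })
  }
  attr(bulk, "mix_weight") <- w
  # genes that actually vary along the progenitor -> neuron trajectory; the
  # natural comparison subset for staging correlations
  attr(bulk, "varying_genes") <- rownames(bulk)[abs(prog - neur) > 1e-9]
  bulk
}

#' Simulate mixture cells between two knowledge-matrix types
#'
#' Cells whose NB mean profile is `w * mu(type_a) + (1 - w) * mu(type_b)`,
#' used to probe similarity statistics against a designed mixing weight.
#'
#' @param km a [knowledge_matrix()].
#' @param type_a,type_b km type names.
#' @param w mixing weight in `[0, 1]` toward `type_a`.
#' @param n number of cells.
#' @param params a [sim_params()].
#' @param stage,sample labels recorded in the metadata.
#' @return an [sc_counts()] with `truth_type = "mix"`.
#' @export
simulate_mixture_cells <- function(km, type_a, type_b, w, n,
                                   params = sim_params(), stage = "CS12",
                                   sample = "mix") {
  assert_scalar_num(w, "w", lower = 0, upper = 1)
  mu <- sim_mu_matrix(km, params)
  for (t in c(type_a, type_b))
    if (!t %in% km$type) stopf("unknown cell type '%s'", t)
  mu_mix <- w * mu[, type_a] + (1 - w) * mu[, type_b]
  counts <- with_seed(params$seed, {
    rnb_matrix(matrix(rep(mu_mix, n), nrow = length(mu_mix), ncol = n,
                      dimnames = list(names(mu_mix), NULL)),
               params$dispersion)
  })
  colnames(counts) <- sprintf("%s_w%03d_C%05d", sample, round(100 * w),
                              seq_len(n))
  sc_counts(counts, data.frame(
    barcode = colnames(counts), sample = sample, stage = stage,
    sex = "female", truth_type = "mix", truth_class = "mix",
    truth_tissue = "neural", stringsAsFactors = FALSE))
}
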