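#' Validate a pipeline configuration
#'
#' Configurations are JSON files (or lists) with optional keys; defaults
#' are filled in and every referenced path is checked.  Unknown keys
#' produce a warning, not an error.  Known keys:
#' \describe{
#'   \item{counts / counts_format}{input counts (triplet directory or dense
#'     TSV); when absent, data are simulated from `simulate`.}
#'   \item{simulate}{list: `preset` ("cns"/"full"), `n_cells` per stage,
#'     plus any [sim_params()] override.}
#'   \item{knowledge_matrix, modules}{TSV paths (defaults: shipped files).}
#'   \item{qc}{[qc_thresholds()] fields.  Pipeline defaults are permissive
#'     (min_genes 10), sized for the synthetic gene universe; real 10x runs
#'     should supply per-replicate values.}
#'   \item{classify}{params list passed to [two_step_classify()].}
#'   \item{compare}{`min_cells`, `ortholog_noise`, `n_signature_genes`.}
#'   \item{correlates}{`target_gene`, `subset_subtype`, `k`.}
#'   \item{skip}{character vector of stages to skip (among "compare",
#'     "dynamics", "dp", "correlates").}
#'   \item{seed, outdir, verbose}{run-level settings.}
#' }
#'
#' @param config path to a JSON file, or a list.
#' @return a `pipeline_config` list with a validation report in
#'   `attr(, "report")`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a file path or a list")
  known <- c("counts", "counts_format", "simulate", "knowledge_matrix",
             "modules", "qc", "classify", "compare", "correlates", "skip",
             "seed", "outdir", "verbose")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warnf("unknown config key(s) ignored: %s", paste(unknown, collapse = ", "))
  defaults <- list(
    counts = NULL, counts_format = "mtx_triplet",
    simulate = list(preset = "cns", n_cells = 1500),
    knowledge_matrix = NULL, modules = NULL,
    qc = list(min_genes = 10, max_genes = 1e6, min_umis = 0, max_umis = Inf,
              max_mito_frac = 0.25),
    classify = list(), compare = list(min_cells = 10, ortholog_noise = 0.1,
                                      n_signature_genes = 200),
    correlates = list(target_gene = "PAX7", subset_subtype = "FP", k = 30),
    skip = character(), seed = 1L, outdir = "spinalatlas_out",
    verbose = FALSE)
  # manual merge: unlike modifyList, this keeps NULL-valued keys so that a
  # resolved config re-validates to itself
  cfg <- defaults
  nested <- c("simulate", "qc", "classify", "compare", "correlates")
  for (k in intersect(names(config), known)) {
    if (k %in% nested && is.list(config[[k]]))
      cfg[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
    else cfg[k] <- list(config[[k]])
  }
  notes <- character()
  for (key in c("counts", "knowledge_matrix", "modules")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stopf("config key '%s' points at a missing path: %s", key, cfg[[key]])
    if (is.null(cfg[[key]]))
      notes <- c(notes, sprintf("%s: using package default", key))
  }
  bad <- setdiff(cfg$skip, c("compare", "dynamics", "dp", "correlates"))
  if (length(bad)) stopf("cannot skip unknown stage(s): %s",
                         paste(bad, collapse = ", "))
  attr(cfg, "report") <- notes
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the analysis in order: input (load or simulate), droplet
#' QC and sex inference, normalisation and module scoring, two-step
#' classification, cross-species and staging comparisons (simulated inputs
#' only, unless skipped), composition/neurogenesis dynamics, targeted
#' correlate discovery, and the OLIG2/NKX2-2 double-positive analysis.
#' All outputs are TSV files under `config$outdir` plus a machine-readable
#' `run_report.json`; reruns with an identical config reproduce identical
#' outputs (only `run.log` carries timings).
#'
#' @param config a [validate_config()] result, config path, or list.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  cat(sprintf("spinalatlas %s\n",
              as.character(utils::packageVersion("spinalatlas"))),
      file = log_path)
  t_all <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%7.2fs] %s\n", proc.time()[["elapsed"]] - t_all, msg),
        file = log_path, append = TRUE)
    if (isTRUE(cfg$verbose)) message(msg)
  }
  report <- list(version = as.character(utils::packageVersion("spinalatlas")),
                 seed = cfg$seed, stages = list())

  km <- if (is.null(cfg$knowledge_matrix)) default_knowledge_matrix()
        else read_knowledge_matrix(cfg$knowledge_matrix)
  modules <- if (is.null(cfg$modules)) default_tissue_modules()
             else read_gene_modules(cfg$modules)

  # --- input -------------------------------------------------------------
  sim_cfg <- cfg$simulate
  simulated <- is.null(cfg$counts)
  if (simulated) {
    par_fields <- intersect(names(sim_cfg), names(formals(sim_params)))
    params <- do.call(sim_params, sim_cfg[par_fields])
    params$seed <- derive_seed(cfg$seed, 1L)
    stages <- stage_preset(sim_cfg$preset %||% "cns",
                           n_cells = sim_cfg$n_cells %||% 1500)
    cm <- bind_counts(simulate_timecourse(stages, km, params))
    say("simulated %d cells over %d stages (preset %s)", ncol(cm$counts),
        length(stages), sim_cfg$preset %||% "cns")
  } else {
    cm <- read_counts(cfg$counts, cfg$counts_format)
    say("loaded %d cells from %s", ncol(cm$counts), cfg$counts)
  }
  report$stages$input <- list(n_cells = ncol(cm$counts),
                              n_genes = nrow(cm$counts),
                              simulated = simulated)

  # --- qc ----------------------------------------------------------------
  thr <- do.call(qc_thresholds, cfg$qc)
  metrics <- compute_qc(cm)
  filt <- filter_cells(cm, thr, metrics)
  cm <- filt$counts
  write_tsv(metrics, file.path(cfg$outdir, "qc_metrics.tsv"))
  write_tsv(filt$report, file.path(cfg$outdir, "qc_report.tsv"))
  if ("SRY" %in% rownames(cm$counts))
    write_tsv(infer_sex(cm), file.path(cfg$outdir, "sex_inference.tsv"))
  say("QC kept %d cells (removed %d)", ncol(cm$counts),
      filt$report$n_removed[filt$report$criterion == "total"])
  report$stages$qc <- list(n_cells = ncol(cm$counts),
                           removed = filt$report$n_removed[
                             filt$report$criterion == "total"])

  # --- scoring + classification ------------------------------------------
  cl_params <- utils::modifyList(list(seed = derive_seed(cfg$seed, 2L)),
                                 cfg$classify)
  assignment <- two_step_classify(cm, km, modules, cl_params)
  nm <- normalize_log(cm, cl_params$target_depth, cl_params$pseudo_count %||% 1)
  cc <- cell_cycle_modules()
  if (any(cc$s$genes %in% rownames(cm$counts)) &&
      any(cc$g2m$genes %in% rownames(cm$counts))) {
    ccs <- suppressWarnings(
      cell_cycle_scores(nm, seed = derive_seed(cfg$seed, 3L)))
    write_tsv(ccs, file.path(cfg$outdir, "cell_cycle_scores.tsv"))
  } else say("cell-cycle genes absent; skipping cell-cycle scoring")
  write_tsv(as.data.frame(assignment),
            file.path(cfg$outdir, "assignment.tsv"))
  n_assigned <- sum(!is.na(assignment$subtype) &
                      assignment$subtype != "Unassigned")
  say("classified %d/%d cells to a subtype", n_assigned, nrow(assignment))
  report$stages$classify <- list(n_neural = sum(assignment$tissue == "neural"),
                                 n_assigned = n_assigned)
  if ("truth_type" %in% names(assignment)) {
    neural <- assignment$truth_tissue == "neural"
    rec <- mean(assignment$subtype[neural] == assignment$truth_type[neural],
                na.rm = TRUE)
    report$stages$classify$truth_recovery <- rec
    say("truth recovery (neural cells): %.3f", rec)
  }

  # --- comparisons -------------------------------------------------------
  if (!"compare" %in% cfg$skip && simulated) {
    cmp <- cfg$compare
    pair_comp <- stage_composition(
      "pair", stats::setNames(rep(1 / sum(km$class %in% c("progenitor", "neuron")),
                                  sum(km$class %in% c("progenitor", "neuron"))),
                              km$type[km$class %in% c("progenitor", "neuron")]),
      n_cells = 2000, sex = "female")
    pp <- do.call(sim_params, sim_cfg[intersect(names(sim_cfg),
                                                names(formals(sim_params)))])
    pp$seed <- derive_seed(cfg$seed, 4L)
    pair <- simulate_ortholog_pair(km, pair_comp, pair_comp,
                                   ortholog_noise = cmp$ortholog_noise %||% 0.1,
                                   params = pp,
                                   n_signature_genes = cmp$n_signature_genes %||% 200)
    map <- map_orthologs(pair$map)
    truth_a <- data.frame(barcode = pair$a$cell_meta$barcode,
                          subtype = pair$a$cell_meta$truth_type,
                          stringsAsFactors = FALSE)
    truth_b <- data.frame(barcode = pair$b$cell_meta$barcode,
                          subtype = pair$b$cell_meta$truth_type,
                          stringsAsFactors = FALSE)
    prof_a <- mean_profiles(normalize_log(pair$a), truth_a,
                            min_cells = cmp$min_cells %||% 10, km = km)
    prof_b <- mean_profiles(normalize_log(pair$b), truth_b,
                            min_cells = cmp$min_cells %||% 10, km = km)
    tf <- utils::read.delim(system.file("extdata",
                                        "tf_annotation_synthetic.tsv",
                                        package = "spinalatlas"),
                            stringsAsFactors = FALSE)
    tf_set <- unique(c(restrict_gene_set(colnames(prof_a), tf),
                       grep("^SIG", colnames(prof_a), value = TRUE)))
    cc_mat <- cross_correlate(prof_a[, tf_set, drop = FALSE], prof_b, map)
    write_tsv(data.frame(type_a = rownames(cc_mat), cc_mat,
                         check.names = FALSE),
              file.path(cfg$outdir, "species_correlation.tsv"))
    same_top <- mean(colnames(cc_mat)[apply(cc_mat, 1L, which.max)] ==
                       rownames(cc_mat))
    report$stages$compare <- list(n_orthologs = nrow(map),
                                  same_type_argmax = same_top)
    say("cross-species: %d 1:1 orthologs, same-type argmax %.2f",
        nrow(map), same_top)

    bulk <- simulate_bulk_timecourse(km, n_days = 10, params = pp)
    pb <- stage_pseudobulk(nm, assignment)
    sc_mat <- staging_correlation(pb, bulk)
    write_tsv(data.frame(stage = rownames(sc_mat), sc_mat,
                         check.names = FALSE),
              file.path(cfg$outdir, "staging_correlation.tsv"))
    report$stages$staging <- list(n_stages = nrow(sc_mat),
                                  n_days = ncol(sc_mat))
  } else if (!"compare" %in% cfg$skip) {
    say("compare stage needs simulated input or explicit paths; skipped")
  }

  # --- dynamics ----------------------------------------------------------
  if (!"dynamics" %in% cfg$skip) {
    comp <- composition_table(assignment)
    write_tsv(comp, file.path(cfg$outdir, "composition.tsv"))
    terr <- tryCatch(group_territories(assignment), error = function(e) NULL)
    if (!is.null(terr))
      write_tsv(terr, file.path(cfg$outdir, "territories.tsv"))
    rate <- neurogenesis_rate(assignment)
    write_tsv(rate, file.path(cfg$outdir, "neurogenesis_rate.tsv"))
    report$stages$dynamics <- list(n_types = length(unique(comp$type)))
    say("dynamics: composition over %d stages", length(unique(comp$stage)))
  }

  # --- correlates --------------------------------------------------------
  if (!"correlates" %in% cfg$skip) {
    cr <- cfg$correlates
    subset <- assignment$barcode[!is.na(assignment$subtype) &
                                   assignment$subtype == cr$subset_subtype]
    res <- tryCatch(
      correlated_genes(nm, cr$target_gene, subset, cr$k %||% 30),
      error = function(e) { say("correlates: %s", conditionMessage(e)); NULL })
    if (!is.null(res)) {
      write_tsv(res, file.path(cfg$outdir, "correlated_genes.tsv"))
      report$stages$correlates <- list(n_genes = nrow(res))
    }
  }

  # --- double-positive analysis ------------------------------------------
  if (!"dp" %in% cfg$skip) {
    bm <- attr(assignment, "binary")
    if (!is.null(bm) && all(c("SOX2", "OLIG2", "NKX2-2") %in%
                              rownames(bm$mat))) {
      groups <- gate_cells(bm)
      ratio <- dp_ratio(groups, assignment)
      write_tsv(ratio, file.path(cfg$outdir, "dp_ratio.tsv"))
      sim <- dp_similarity(nm, groups, assignment, gene_space =
                             c(km_marker_genes(km), gliogenic_genes()))
      write_tsv(sim, file.path(cfg$outdir, "dp_similarity.tsv"))
      report$stages$dp <- list(n_dp = length(groups$dp))
      say("dp analysis: %d double-positive cells", length(groups$dp))
    } else say("dp stage skipped: gate genes not binarised")
  }

  report$elapsed_stages <- NULL
  jsonlite::write_json(report, file.path(cfg$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  say("done")
  invisible(report)
}
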