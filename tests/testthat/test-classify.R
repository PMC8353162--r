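test_that("binarisation separates clean on/off patterns", {
  m <- matrix(c(0, 0, 5, 5,
                0, 0, 0, 0,
                3, 3, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("bi", "zero", "flat"), sprintf("c%d", 1:4)))
  bm <- binarize_expression(m, c("bi", "zero", "flat"))
  expect_equal(unname(bm$mat["bi", ]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(bm$mat["zero", ]), rep(0L, 4))
  # ubiquitous gene: threshold at detection, all positive
  expect_equal(unname(bm$mat["flat", ]), rep(1L, 4))
  expect_error(binarize_expression(m, character()), "empty marker")
  expect_warning(binarize_expression(m, c("bi", "nope")), "absent")
})

test_that("binarisation recovers truth on a bimodal NB mixture", {
  set.seed(31)
  n <- 2000
  truth <- stats::rbinom(n, 1, 0.4)
  counts <- ifelse(truth == 1, stats::rnbinom(n, size = 10, mu = 20),
                   stats::rnbinom(n, size = 10, mu = 0.1))
  m <- matrix(log1p(counts), 1, n,
              dimnames = list("g", sprintf("c%04d", 1:n)))
  bm <- binarize_expression(m, "g")
  expect_gt(mean(bm$mat["g", ] == truth), 0.98)
})

test_that("the on-population guard suppresses noise-only genes", {
  set.seed(8)
  n <- 1000
  noise <- stats::rnbinom(n, size = 10, mu = 0.05)
  m <- matrix(log1p(noise), 1, n, dimnames = list("g", sprintf("c%d", 1:n)))
  bm <- binarize_expression(m, "g")
  expect_equal(sum(bm$mat), 0L)
  # disabling the guard exposes the raw Otsu behaviour
  bm2 <- binarize_expression(m, "g", min_on_mean = 0)
  expect_gt(sum(bm2$mat), 0L)
})

test_that("subtype assignment implements the mismatch rule and gating", {
  km <- default_km()
  genes <- km_marker_genes(km)
  mk_bm <- function(pos_list) {
    mat <- matrix(0L, length(genes), length(pos_list),
                  dimnames = list(genes, names(pos_list)))
    for (j in seq_along(pos_list)) mat[pos_list[[j]], j] <- 1L
    structure(list(mat = mat,
                   thresholds = stats::setNames(rep(0, length(genes)),
                                                genes)),
              class = "binary_matrix")
  }
  pmn_req <- c("SOX2", "OLIG2", "NKX6-1")
  bm <- mk_bm(list(
    pmn = pmn_req,                                   # exact pMN profile
    none = c("SOX2", "LHX2"),                        # matches nothing
    dp = c("SOX2", "OLIG2", "NKX6-1", "NKX2-2")))    # pMN + forbidden NKX2-2
  res <- assign_subtype(bm, km)
  expect_equal(res$subtype[res$barcode == "pmn"], "pMN")
  expect_equal(res$n_mismatches[res$barcode == "pmn"], 0)
  expect_equal(res$subtype[res$barcode == "none"], "Unassigned")
  expect_equal(res$subtype[res$barcode == "dp"], "Unassigned")
  # the dp profile is exactly one mismatch from both pMN and p3 rows:
  # equidistant ties stay Unassigned even with a tolerance
  res1 <- assign_subtype(bm, km, max_mismatch = 2)
  expect_equal(res1$subtype[res1$barcode == "dp"], "Unassigned")
  # opt-in dv_rank tie-break resolves toward the dorsal-most row (pMN)
  res2 <- assign_subtype(bm, km, max_mismatch = 2, tie_break = "dv_rank")
  expect_equal(res2$subtype[res2$barcode == "dp"], "pMN")
})

test_that("raising the mismatch tolerance never unassigns cells", {
  km <- default_km()
  cm <- cns_noisy_course()
  idx <- seq(1, ncol(cm$counts), by = 8)
  nm <- normalize_log(spinalatlas:::subset_cells(cm, idx))
  bm <- binarize_expression(nm, km_marker_genes(km))
  n_assigned <- vapply(0:3, function(mm) {
    sum(assign_subtype(bm, km, max_mismatch = mm)$subtype != "Unassigned")
  }, numeric(1L))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("assignment is invariant to knowledge-matrix row order", {
  km <- default_km()
  cm <- cns_noise_free()
  nm <- normalize_log(cm)
  bm <- binarize_expression(nm, km_marker_genes(km))
  ref <- assign_subtype(bm, km)
  set.seed(2)
  km_perm <- knowledge_matrix(as.data.frame(km)[sample(nrow(km)), ])
  expect_equal(assign_subtype(bm, km_perm)$subtype, ref$subtype)
})

test_that("assignment equals the brute-force enumerator on random fixtures", {
  km <- default_km()
  genes <- km_marker_genes(km)[1:40]
  small_km <- knowledge_matrix(as.data.frame(km)[
    rowSums(as.data.frame(km)[, genes, drop = FALSE] == 1L) > 0,
    c("type", "class", "dv_rank", genes)])
  set.seed(13)
  for (rep in 1:3) {
    mat <- matrix(stats::rbinom(40 * 50, 1, 0.25), 40, 50,
                  dimnames = list(genes, sprintf("c%02d", 1:50)))
    bm <- structure(list(mat = mat, thresholds = NULL),
                    class = "binary_matrix")
    for (mm in c(0, 2)) {
      expect_equal(assign_subtype(bm, small_km, max_mismatch = mm)$subtype,
                   brute_force_assign(bm, small_km, max_mismatch = mm))
    }
  }
})

test_that("broad typing takes the argmax above min_score", {
  s <- rbind(c(0.8, -0.1), c(-0.2, -0.3), c(0.5, 0.5))
  colnames(s) <- c("neural", "mesoderm")
  rownames(s) <- c("a", "b", "c")
  lab <- assign_broad_type(s, min_score = 0)
  expect_equal(unname(lab), c("neural", "other", "other"))  # tie -> other
  expect_equal(unname(assign_broad_type(s, min_score = -1)[2]), "neural")
})

test_that("PNS staging follows the three quoted rules then refines", {
  km <- default_km()
  genes <- km_marker_genes(km)
  mk <- function(...) {
    pos <- list(...)
    mat <- matrix(0L, length(genes), length(pos),
                  dimnames = list(genes, names(pos)))
    for (j in seq_along(pos)) mat[pos[[j]], j] <- 1L
    structure(list(mat = mat, thresholds = NULL), class = "binary_matrix")
  }
  bm <- mk(prog = c("SOX10", "SOX2", "TFAP2A"),
           prec = c("NEUROG1", "NEUROD1", "SIX1"),
           prop = c("ELAVL3", "SIX1", "NTRK3", "RUNX3"),
           generic = c("ELAVL3", "SIX1"),
           nothing = "PAX6")
  res <- classify_pns(bm, km)
  expect_equal(res$subtype[res$barcode == "prog"], "NCC")
  expect_equal(res$class[res$barcode == "prog"], "pns_progenitor")
  expect_equal(res$subtype[res$barcode == "prec"], "SensoryPrec")
  expect_equal(res$subtype[res$barcode == "prop"], "Proprioceptor")
  expect_equal(res$subtype[res$barcode == "generic"], "SensoryNeuron")
  expect_equal(res$subtype[res$barcode == "nothing"], "Unassigned")
})

test_that("two-step classification recovers all labels without noise", {
  km <- default_km()
  cm <- cns_noise_free()
  a <- two_step_classify(cm, km)
  expect_equal(mean(a$subtype == a$truth_type), 1)
  expect_true(all(a$tissue == "neural"))
  log <- attr(a, "log")
  expect_equal(log$n_cells[log$step == "assigned"], ncol(cm$counts))
})

test_that("two-step recovery stays above the frozen noisy regression bound", {
  km <- default_km()
  cm <- cns_noisy_course()
  a <- two_step_classify(cm, km)
  expect_gte(mean(a$subtype == a$truth_type), 0.9)
})

test_that("non-neural cells never receive CNS subtypes", {
  km <- default_km()
  comp <- stage_composition(
    "CS12", c(pMN = 0.4, MN = 0.3, mesoderm = 0.2, blood = 0.1), 600)
  cm <- simulate_counts(km, comp, sim_params(seed = 17))
  a <- two_step_classify(cm, km)
  non_neural <- a$truth_tissue != "neural"
  expect_gt(mean(a$tissue[non_neural] != "neural"), 0.99)
  expect_true(all(is.na(a$subtype[a$tissue != "neural"])))
})

test_that("classification is deterministic given counts and matrix", {
  km <- default_km()
  cm <- simulate_counts(km, uniform_comp(c("pMN", "p3", "MN"), 300),
                        sim_params(seed = 23))
  a1 <- two_step_classify(cm, km)
  a2 <- two_step_classify(cm, km)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})
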