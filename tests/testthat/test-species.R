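test_that("ortholog maps keep exactly the 1:1 pairs", {
  raw <- data.frame(gene_a = c("a", "b"), gene_b = c("x", "y"))
  expect_equal(nrow(map_orthologs(raw)), 2L)
  dup <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("x", "y", "z"))
  kept <- map_orthologs(dup)
  expect_equal(kept$gene_a, "b")     # both pairs involving 'a' dropped
  expect_error(map_orthologs(data.frame()), "empty")

  # 100-pair fixture with injected duplicates vs a set-arithmetic oracle
  set.seed(19)
  raw <- data.frame(gene_a = sprintf("a%03d", 1:100),
                    gene_b = sprintf("b%03d", 1:100),
                    stringsAsFactors = FALSE)
  inject <- data.frame(gene_a = raw$gene_a[1:20],
                       gene_b = raw$gene_b[sample(21:100, 20)],
                       stringsAsFactors = FALSE)
  full <- rbind(raw, inject)
  kept <- map_orthologs(full)
  bad_a <- names(which(table(full$gene_a) > 1))
  bad_b <- names(which(table(full$gene_b) > 1))
  oracle <- full[!(full$gene_a %in% bad_a) & !(full$gene_b %in% bad_b), ]
  expect_equal(kept$gene_a, oracle$gene_a)
})

test_that("gene-set restriction is an order-stable intersection", {
  tf <- data.frame(gene = c("SOX2", "PAX6"), term = "GO:0003700")
  expect_equal(restrict_gene_set(c("PAX6", "ACTB", "SOX2", "PAX6"), tf),
               c("PAX6", "SOX2"))
  expect_equal(restrict_gene_set(c("a", "b"), data.frame(gene = character())),
               character())
  all_in <- data.frame(gene = c("a", "b"))
  expect_equal(restrict_gene_set(c("a", "b"), all_in), c("a", "b"))
})

test_that("mean profiles average assigned cells and respect min_cells", {
  m <- matrix(c(1, 2, 3,
                1, 2, 3,
                5, 6, 7), nrow = 3, byrow = FALSE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  a <- data.frame(barcode = c("c1", "c2", "c3"),
                  subtype = c("t1", "t1", "t2"))
  prof <- mean_profiles(m, a, min_cells = 1)
  expect_equal(unname(prof["t1", ]), rowMeans(m[, 1:2])[c(1, 2, 3)],
               ignore_attr = TRUE)
  expect_equal(unname(prof["t2", "g1"]), 5)
  # identical cells average to either one
  a2 <- data.frame(barcode = c("c1", "c2"), subtype = "t")
  prof2 <- mean_profiles(m[, c(1, 1)], a2, min_cells = 2)
  expect_equal(unname(prof2["t", ]), unname(m[, 1]))
  # min_cells excludes and records small types
  prof3 <- mean_profiles(m, a, min_cells = 2)
  expect_equal(rownames(prof3), "t1")
  expect_equal(attr(prof3, "excluded"), "t2")
  expect_error(mean_profiles(m, a, min_cells = 5), "min_cells")
})

test_that("cross correlation matches closed form and is symmetric", {
  a <- rbind(t1 = c(1, 2, 3), t2 = c(3, 1, 2))
  colnames(a) <- c("g1", "g2", "g3")
  cc <- cross_correlate(a, a)
  expect_equal(diag(cc), c(t1 = 1, t2 = 1))
  b <- rbind(u1 = c(2, 4, 6.5))
  colnames(b) <- colnames(a)
  expect_equal(cross_correlate(a, b)["t1", "u1"],
               stats::cor(c(1, 2, 3), c(2, 4, 6.5)))
  # transpose symmetry under swapping the two species
  set.seed(4)
  pa <- matrix(stats::runif(12), 3, 4,
               dimnames = list(c("x", "y", "z"), sprintf("g%d", 1:4)))
  pb <- matrix(stats::runif(8), 2, 4,
               dimnames = list(c("u", "v"), sprintf("g%d", 1:4)))
  expect_equal(cross_correlate(pa, pb), t(cross_correlate(pb, pa)))
  # constant profile -> NA, never 0
  pc <- rbind(flat = rep(1, 4)); colnames(pc) <- colnames(pa)
  expect_warning(ccn <- cross_correlate(pa, pc), "undefined")
  expect_true(all(is.na(ccn)))
  expect_error(cross_correlate(pa[, 1, drop = FALSE],
                               pb[, 1, drop = FALSE]), "fewer than 2")
})

test_that("correlation routines agree with brute force on small instances", {
  set.seed(9)
  pa <- matrix(stats::rexp(10 * 10), 10, 10,
               dimnames = list(sprintf("t%02d", 1:10), sprintf("g%d", 1:10)))
  pb <- matrix(stats::rexp(10 * 10), 10, 10,
               dimnames = list(sprintf("u%02d", 1:10), sprintf("g%d", 1:10)))
  expect_equal(cross_correlate(pa, pb), brute_force_cor(pa, pb),
               tolerance = 1e-10)
  expect_equal(cross_correlate(pa, pb, method = "spearman"),
               brute_force_cor(pa, pb, "spearman"), tolerance = 1e-10)
})

test_that("ortholog translation drops non-mapped genes cleanly", {
  set.seed(6)
  pa <- matrix(stats::runif(6), 2, 3,
               dimnames = list(c("t1", "t2"), c("A1", "A2", "A3")))
  pb <- matrix(stats::runif(6), 2, 3,
               dimnames = list(c("t1", "t2"), c("B1", "B2", "B3")))
  full_map <- data.frame(gene_a = c("A1", "A2", "A3"),
                         gene_b = c("B1", "B2", "B3"))
  partial <- full_map[1:2, ]
  cc_full_on_shared <- cross_correlate(pa[, 1:2], pb[, 1:2],
                                       map_orthologs(partial))
  cc_partial <- cross_correlate(pa, pb, map_orthologs(partial))
  expect_equal(cc_partial, cc_full_on_shared)
})

test_that("same-type profiles correlate highest across a species pair", {
  km <- default_km()
  cns <- km$type[km$class %in% c("progenitor", "neuron")]
  pair <- cached("ortho_pair", {
    comp <- uniform_comp(cns, 2000, stage = "S")
    simulate_ortholog_pair(km, comp, comp, ortholog_noise = 0.1,
                           sim_params(seed = 5), n_signature_genes = 200)
  })
  map <- map_orthologs(pair$map)
  ta <- data.frame(barcode = pair$a$cell_meta$barcode,
                   subtype = pair$a$cell_meta$truth_type)
  tb <- data.frame(barcode = pair$b$cell_meta$barcode,
                   subtype = pair$b$cell_meta$truth_type)
  pa <- mean_profiles(normalize_log(pair$a), ta, km = km)
  pb <- mean_profiles(normalize_log(pair$b), tb, km = km)
  sig <- grep("^SIG", colnames(pa), value = TRUE)
  cc <- cross_correlate(pa[, sig, drop = FALSE], pb, map)
  hit <- colnames(cc)[apply(cc, 1L, which.max)]
  expect_equal(hit, rownames(cc))
})

test_that("staging correlation is rank-invariant to min-max scaling", {
  set.seed(10)
  pb <- matrix(stats::rexp(3 * 20), 3, 20,
               dimnames = list(c("s1", "s2", "s3"), sprintf("g%02d", 1:20)))
  bulk <- matrix(stats::rexp(20 * 4), 20, 4,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("d%d", 1:4)))
  sc <- staging_correlation(pb, bulk)
  # oracle: plain Spearman without scaling (monotone invariance)
  oracle <- stats::cor(t(pb), bulk, method = "spearman")
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-12)
  # identical matrices give a unit diagonal
  self <- staging_correlation(pb, t(pb))
  expect_equal(unname(diag(self)), rep(1, 3))
})

test_that("matched in vivo / in vitro series align as designed", {
  km <- default_km()
  vp <- c("p0", "p1", "p2", "pMN", "p3")
  vn <- c("V0", "V1", "V2", "MN", "V3")
  fs <- c(0.1, 0.35, 0.65, 0.9)
  stages <- lapply(seq_along(fs), function(i) {
    p <- c(stats::setNames(rep((1 - fs[i]) / 5, 5), vp),
           stats::setNames(rep(fs[i] / 5, 5), vn))
    stage_composition(sprintf("S%d", i), p, 800)
  })
  cm <- bind_counts(simulate_timecourse(stages, km, sim_params(seed = 3)))
  a <- two_step_classify(cm, km)
  pb <- stage_pseudobulk(normalize_log(cm), a)
  bulk <- simulate_bulk_timecourse(km, n_days = 9)
  w <- attr(bulk, "mix_weight")
  sc <- staging_correlation(pb, bulk,
                            gene_subset = attr(bulk, "varying_genes"))
  best_w <- w[apply(sc, 1L, which.max)]
  # argmax day tracks the designed neuron fraction and is ordered
  expect_true(all(abs(best_w - fs) <= 0.2))
  expect_true(all(diff(best_w) > 0))
})

test_that("correlate discovery ranks a duplicated target first", {
  set.seed(14)
  m <- matrix(stats::rexp(20 * 60), 20, 60,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:60)))
  m <- rbind(m, target = m["g05", ] * 2)   # monotone copy of g05
  res <- correlated_genes(m, "target", k = 5)
  expect_equal(res$gene[1], "g05")
  expect_equal(res$rho[1], 1)
  # brute-force all-pairs oracle on the full ranking
  res_all <- correlated_genes(m, "target", k = 100)
  rho <- apply(m[rownames(m) != "target", ], 1,
               function(x) stats::cor(x, m["target", ], method = "spearman"))
  rho <- sort(rho[rho > 0], decreasing = TRUE)
  expect_equal(nrow(res_all), length(rho))
  expect_equal(res_all$rho, unname(rho), tolerance = 1e-12)
  # k beyond the positive-correlate count shortens the list, no padding
  expect_lt(nrow(res_all), 100)
  expect_error(correlated_genes(m, "nope"), "not found")
  z <- m; z["target", ] <- 0
  expect_error(correlated_genes(z, "target"), "fewer than 3")
})
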