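test_that("simulation parameters enforce their invariants", {
  expect_error(sim_params(mu_on = 1, mu_off = 2), "mu_off")
  expect_error(sim_params(dispersion = 0), "dispersion")
  expect_error(sim_params(mito_frac_mean = 1), "mito_frac_mean")
  expect_silent(sim_params(dispersion = Inf))
  expect_error(stage_composition("s", c(a = 0.5, b = 0.6), 10), "sum to 1")
  expect_error(stage_composition("s", c(a = 1), 0), "positive integer")
})

test_that("identical seed and parameters give bit-identical output", {
  km <- default_km()
  comp <- uniform_comp(c("pMN", "p3", "MN"), 200)
  a <- simulate_counts(km, comp, sim_params(seed = 3))
  b <- simulate_counts(km, comp, sim_params(seed = 3))
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)
  c <- simulate_counts(km, comp, sim_params(seed = 4))
  expect_false(identical(a$counts, c$counts))
})

test_that("unknown composition types error", {
  km <- default_km()
  expect_error(simulate_counts(km, uniform_comp(c("pMN", "nope"), 10)),
               "nope")
})

test_that("noise-free cells express exactly their required markers", {
  km <- default_km()
  cm <- simulate_counts(km, uniform_comp(c("pMN", "p3"), 100),
                        noise_free_params(mu_on = 50, seed = 1))
  markers <- km_marker_genes(km)
  for (type in c("pMN", "p3")) {
    cells <- cm$cell_meta$truth_type == type
    req <- names(which(unlist(km[km$type == type, markers]) == 1L))
    sub <- cm$counts[markers, cells, drop = FALSE]
    on <- rownames(sub)[Matrix::rowSums(sub) > 0]
    expect_setequal(on, req)
  }
})

test_that("marker moments match the analytic NB values at n = 5000", {
  km <- default_km()
  # fixed depth isolates the pure NB moments
  p <- sim_params(mu_on = 10, dispersion = 10, depth_sdlog = 0, seed = 5)
  cm <- simulate_counts(km, uniform_comp("pMN", 5000), p)
  x <- as.numeric(cm$counts["OLIG2", ])
  expect_lt(abs(mean(x) - 10) / 10, 0.05)
  var_expected <- 10 + 10^2 / 10   # mu + mu^2/size
  expect_lt(abs(stats::var(x) - var_expected) / var_expected, 0.05)
  # with log-normal depth the mean is mu_on * E[depth] = mu_on
  p2 <- sim_params(mu_on = 10, dispersion = 10, depth_sdlog = 0.35, seed = 6)
  cm2 <- simulate_counts(km, uniform_comp("pMN", 5000), p2)
  expect_lt(abs(mean(cm2$counts["OLIG2", ]) - 10) / 10, 0.05)
})

test_that("truth proportions match the composition within multinomial error", {
  km <- default_km()
  types <- c(paste0("dp", 1:6), paste0("p", 0:3), "pMN", "FP", "RP")
  prop <- stats::setNames(seq_along(types) / sum(seq_along(types)), types)
  comp <- stage_composition("CS14", prop, 5000)
  cm <- simulate_counts(km, comp, sim_params(seed = 9))
  obs <- table(factor(cm$cell_meta$truth_type, levels = types))
  pval <- stats::chisq.test(obs, p = prop)$p.value
  expect_gt(pval, 0.01)
})

test_that("timecourse presets shift from progenitor- to neuron-rich", {
  stages <- stage_preset("cns")
  neuron_types <- c(paste0("dI", 1:6), "V0", "V1", "V2", "MN", "MNV", "V3")
  nfrac <- vapply(stages, function(s)
    sum(s$type_proportions[names(s$type_proportions) %in% neuron_types]),
    numeric(1L))
  expect_true(all(diff(nfrac) > 0))
  full <- stage_preset("full")
  for (s in full) expect_equal(sum(s$type_proportions), 1, tolerance = 1e-9)
  # sexes follow the stated male/female stage pattern
  expect_equal(vapply(stages, `[[`, "", "sex"),
               c("male", "female", "male", "female"))
})

test_that("timecourse honours stage list contracts", {
  km <- default_km()
  expect_error(simulate_timecourse(list(), km), "empty stage list")
  expect_error(simulate_timecourse(stage_preset("cns")[1], km), ">= 2")
  comp <- uniform_comp(c("pMN", "p3"), 300)
  two <- simulate_timecourse(list(comp, comp), km, sim_params(seed = 2))
  # same composition, different draws, but identical expected proportions
  expect_equal(names(two[[1]]$cell_meta), names(two[[2]]$cell_meta))
  p1 <- mean(two[[1]]$cell_meta$truth_type == "pMN")
  p2 <- mean(two[[2]]$cell_meta$truth_type == "pMN")
  expect_lt(abs(p1 - p2), 0.15)
})

test_that("ortholog pair generator bookkeeping matches set arithmetic", {
  km <- default_km()
  comp <- uniform_comp(c("pMN", "p3"), 50)
  clean <- simulate_ortholog_pair(km, comp, comp, ortholog_noise = 0,
                                  sim_params(seed = 4),
                                  n_signature_genes = 20)
  expect_true(all(clean$map$one2one_truth))
  expect_equal(nrow(map_orthologs(clean$map)), nrow(clean$map))
  noisy <- simulate_ortholog_pair(km, comp, comp, ortholog_noise = 0.2,
                                  sim_params(seed = 4),
                                  n_signature_genes = 20)
  kept <- map_orthologs(noisy$map)
  # independent oracle: count gene occurrences on both sides
  ta <- table(noisy$map$gene_a); tb <- table(noisy$map$gene_b)
  oracle <- noisy$map[ta[noisy$map$gene_a] == 1 &
                        tb[noisy$map$gene_b] == 1, c("gene_a", "gene_b")]
  expect_equal(kept$gene_a, oracle$gene_a)
  expect_equal(kept$gene_b, oracle$gene_b)
  expect_true(nrow(kept) < nrow(noisy$map))
  expect_error(simulate_ortholog_pair(km, comp, comp, ortholog_noise = 1.2),
               "ortholog_noise")
})

test_that("species namespaces are disjoint and mapped 1:1", {
  km <- default_km()
  comp <- uniform_comp(c("pMN", "p3"), 30)
  pair <- simulate_ortholog_pair(km, comp, comp, 0, sim_params(seed = 8),
                                 n_signature_genes = 10)
  expect_length(intersect(rownames(pair$a$counts), rownames(pair$b$counts)),
                0)
  expect_equal(pair$map$gene_b[match("SOX2", pair$map$gene_a)], "Sox2")
})

test_that("bulk time course interpolates progenitor to neuron poles", {
  km <- default_km()
  bulk <- simulate_bulk_timecourse(km, n_days = 5)
  w <- attr(bulk, "mix_weight")
  expect_equal(w, seq(0, 1, length.out = 5))
  # day 1 is the pure-progenitor pseudo-bulk by construction
  mu <- spinalatlas:::sim_mu_matrix(km, sim_params())
  prog <- rowMeans(mu[, c("p0", "p1", "p2", "pMN", "p3")])
  expect_equal(unname(bulk[, 1]), unname(prog))
  # reproducibility under a fixed seed (with noise enabled)
  b1 <- simulate_bulk_timecourse(km, n_days = 4, params = sim_params(seed = 3),
                                 noise_sd = 0.1)
  b2 <- simulate_bulk_timecourse(km, n_days = 4, params = sim_params(seed = 3),
                                 noise_sd = 0.1)
  expect_identical(b1, b2)
  expect_error(simulate_bulk_timecourse(km, n_days = 1), "n_days")
})

test_that("mixture cells interpolate the two parent mean profiles", {
  km <- default_km()
  p <- sim_params(mu_on = 30, dispersion = Inf, depth_sdlog = 0, seed = 2)
  mix <- simulate_mixture_cells(km, "pMN", "p3", 0.75, 3000, p)
  # OLIG2 comes from pMN (weight w), NKX2-2 from p3 (weight 1 - w)
  expect_lt(abs(mean(mix$counts["OLIG2", ]) - 0.75 * 30) / (0.75 * 30), 0.1)
  expect_lt(abs(mean(mix$counts["NKX2-2", ]) - 0.25 * 30) / (0.25 * 30), 0.1)
  expect_error(simulate_mixture_cells(km, "pMN", "p3", 1.5, 10), "'w'")
})
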