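# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# tiny sc_counts from a dense matrix, with default metadata
toy_counts <- function(m, stage = "CS12", sample = "s1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  sc_counts(m, data.frame(barcode = colnames(m), sample = sample,
                          stage = stage, stringsAsFactors = FALSE))
}

# an equal-proportion composition over the given types
uniform_comp <- function(types, n_cells, stage = "CS12", ...) {
  stage_composition(stage, stats::setNames(rep(1 / length(types),
                                               length(types)), types),
                    n_cells, ...)
}

# noise-free dataset covering all 25 CNS types (10 cells each)
cns_noise_free <- function() {
  cached("cns_noise_free", {
    km <- default_knowledge_matrix()
    cns <- km$type[km$class %in% c("progenitor", "neuron")]
    simulate_counts(km, uniform_comp(cns, 10L * length(cns)),
                    noise_free_params(seed = 7))
  })
}

# default-noise 4-stage CNS time course (the regression-bound dataset)
cns_noisy_course <- function() {
  cached("cns_noisy_course", {
    km <- default_knowledge_matrix()
    bind_counts(simulate_timecourse(stage_preset("cns", n_cells = 1000),
                                    km, sim_params(seed = 42)))
  })
}

default_km <- function() cached("default_km", default_knowledge_matrix())

# brute-force assignment oracle: enumerate all rows per cell
brute_force_assign <- function(bm, km, max_mismatch = 0,
                               classes = c("progenitor", "neuron", "glia"),
                               gate = TRUE) {
  kms <- km[km$class %in% classes, , drop = FALSE]
  genes <- km_marker_genes(km)
  get_bit <- function(g, j) {
    if (g %in% rownames(bm$mat)) bm$mat[g, j] > 0 else FALSE
  }
  out <- character(ncol(bm$mat))
  for (j in seq_len(ncol(bm$mat))) {
    sox2 <- get_bit("SOX2", j); elav <- get_bit("ELAVL3", j)
    mism <- vapply(seq_len(nrow(kms)), function(i) {
      if (gate) {
        if (sox2 && !elav && kms$class[i] == "neuron") return(Inf)
        if (elav && !sox2 && kms$class[i] %in% c("progenitor", "glia"))
          return(Inf)
      }
      mm <- 0
      for (g in genes) {
        v <- kms[i, g]
        if (v == 1L && !get_bit(g, j)) mm <- mm + 1
        if (v == -1L && get_bit(g, j)) mm <- mm + 1
      }
      mm
    }, numeric(1L))
    best <- min(mism)
    hits <- which(mism == best)
    out[j] <- if (is.finite(best) && best <= max_mismatch &&
                    length(hits) == 1L) kms$type[hits] else "Unassigned"
  }
  out
}

# brute-force Pearson/Spearman of two profile matrices over shared genes
brute_force_cor <- function(a, b, method = "pearson") {
  shared <- intersect(colnames(a), colnames(b))
  out <- matrix(NA_real_, nrow(a), nrow(b),
                dimnames = list(rownames(a), rownames(b)))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    x <- a[i, shared]; y <- b[j, shared]
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    out[i, j] <- if (den > 0) num / den else NA_real_
  }
  out
}
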