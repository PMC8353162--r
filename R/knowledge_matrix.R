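#' Knowledge matrices: trinary marker inventories of cell types
#'
#' A knowledge matrix is the central object of the marker-driven classifier:
#' one row per cell type, with a `class` (progenitor, neuron, pns_progenitor,
#' pns_precursor, pns_neuron, glia or contaminant), an integer `dv_rank`
#' ordering CNS types along the dorsoventral axis (`NA` elsewhere), and one
#' column per marker gene holding `1` (required), `-1` (forbidden) or `0`
#' (irrelevant).
#'
#' @param df a data.frame with columns `type`, `class`, `dv_rank` followed by
#'   one integer column per marker gene with values in `{-1, 0, 1}`.
#' @return a validated `knowledge_matrix` (a data.frame subclass).
#' @export
knowledge_matrix <- function(df) {
  meta_cols <- c("type", "class", "dv_rank")
  if (!all(meta_cols %in% names(df)))
    stopf("knowledge matrix needs columns %s", paste(meta_cols, collapse = ", "))
  gene_cols <- setdiff(names(df), meta_cols)
  if (length(gene_cols) == 0L) stopf("knowledge matrix has no marker columns")
  if (anyDuplicated(df$type)) stopf("cell type names must be unique")
  vals <- as.matrix(df[, gene_cols, drop = FALSE])
  if (!all(vals %in% c(-1L, 0L, 1L)))
    stopf("marker values must be in {-1, 0, 1}")
  req_per_row <- rowSums(vals == 1L)
  if (any(req_per_row == 0L))
    stopf("every cell type needs >= 1 required marker (violated by: %s)",
          paste(df$type[req_per_row == 0L], collapse = ", "))
  both <- rowSums(vals == 1L & vals == -1L)  # impossible, kept for clarity
  prog <- df$dv_rank[df$class == "progenitor"]
  if (anyDuplicated(prog[!is.na(prog)]))
    stopf("dv_rank must be unique within progenitors")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df[gene_cols] <- lapply(df[gene_cols], as.integer)
  class(df) <- c("knowledge_matrix", "data.frame")
  df
}

#' @export
print.knowledge_matrix <- function(x, ...) {
  cat(sprintf("knowledge_matrix: %d cell types x %d marker genes\n",
              nrow(x), length(km_marker_genes(x))))
  tab <- table(x$class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Marker genes of a knowledge matrix
#' @param km a `knowledge_matrix`.
#' @return character vector of marker gene names (column order).
#' @export
km_marker_genes <- function(km) {
  setdiff(names(km), c("type", "class", "dv_rank"))
}

# required / forbidden marker sets for one type
km_required <- function(km, type) {
  row <- km[km$type == type, km_marker_genes(km), drop = FALSE]
  if (nrow(row) != 1L) stopf("unknown cell type '%s'", type)
  names(row)[as.integer(row[1L, ]) == 1L]
}

km_forbidden <- function(km, type) {
  row <- km[km$type == type, km_marker_genes(km), drop = FALSE]
  if (nrow(row) != 1L) stopf("unknown cell type '%s'", type)
  names(row)[as.integer(row[1L, ]) == -1L]
}

# types x genes integer matrix of the trinary values
km_values <- function(km) {
  m <- as.matrix(km[, km_marker_genes(km), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- km$type
  m
}

# broad tissue implied by each row's class
km_tissue <- function(km) {
  ifelse(km$class %in% c("progenitor", "neuron", "glia", "pns_progenitor",
                         "pns_precursor", "pns_neuron"),
         "neural", km$type)
}

#' Read / write knowledge matrices as TSV
#'
#' The on-disk format is one header row (`type`, `class`, `dv_rank`, then one
#' column per gene) and one row per cell type; marker entries are `1`
#' (required), `-1` (forbidden) or `0` (irrelevant).  `dv_rank` may be empty
#' (`NA`) for non-CNS rows.
#'
#' @param path file path.
#' @return `read_knowledge_matrix` returns a `knowledge_matrix`.
#' @export
read_knowledge_matrix <- function(path) {
  if (!file.exists(path)) stopf("knowledge matrix file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  knowledge_matrix(df)
}

#' @rdname read_knowledge_matrix
#' @param km a `knowledge_matrix`.
#' @export
write_knowledge_matrix <- function(km, path) {
  utils::write.table(as.data.frame(km), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The shipped default knowledge matrix
#'
#' Returns the package's default marker inventory for the developing spinal
#' cord and dorsal root ganglia: 13 CNS progenitor domains (RP, dp1-dp6,
#' p0-p2, pMN, p3, FP, ordered dorsal to ventral by `dv_rank`), 12 neuronal
#' classes (dI1-dI6, V0-V2, MN, the visceral motor neuron class MNV, and V3),
#' the peripheral sensory lineage (neural-crest progenitor, sensory
#' precursor and four postmitotic sensory subtypes), an oligodendrocyte
#' precursor row (`OLP`, class `glia`), and optionally three contaminant
#' tissues (mesoderm, blood, skin) used by the mixed-tissue simulations.
#'
#' The matrix is shipped as a TSV under `inst/extdata` so it can be replaced
#' wholesale by a user-supplied inventory via [read_knowledge_matrix()].  The
#' 12th neuronal row is the visceral motor neuron class `MNV` (PHOX2B/ISL1/
#' TBX2/TBX3); it is a named row that users can rename or drop.
#'
#' @param include_contaminants logical; keep the mesoderm/blood/skin rows
#'   (default `TRUE`).
#' @return a `knowledge_matrix`.
#' @examples
#' km <- default_knowledge_matrix()
#' sum(km$class == "progenitor")  # 13
#' @export
default_knowledge_matrix <- function(include_contaminants = TRUE) {
  path <- system.file("extdata", "knowledge_matrix_default.tsv",
                      package = "spinalatlas", mustWork = TRUE)
  km <- read_knowledge_matrix(path)
  if (!include_contaminants) {
    km <- km[km$class != "contaminant", , drop = FALSE]
    keep <- colSums(abs(km_values(km))) > 0L
    km <- knowledge_matrix(
      as.data.frame(km)[, c("type", "class", "dv_rank",
                            km_marker_genes(km)[keep])])
  }
  km
}

# Grouping of progenitor domains into broad territories.
territory_of <- function(subtype) {
  map <- c(dp1 = "pD", dp2 = "pD", dp3 = "pD", dp4 = "pD", dp5 = "pD",
           dp6 = "pD", p0 = "pI", p1 = "pI", p2 = "pI",
           pMN = "pMN", p3 = "p3", FP = "FP", RP = "RP")
  out <- unname(map[subtype])
  bad <- is.na(out) & !is.na(subtype)
  if (any(bad))
    stopf("unknown progenitor subtype label(s): %s",
          paste(unique(subtype[bad]), collapse = ", "))
  out
}

# Canonical neuron -> progenitor domain pairing used for neurogenesis rates.
default_domain_pairing <- function() {
  c(dI1 = "dp1", dI2 = "dp2", dI3 = "dp3", dI4 = "dp4", dI5 = "dp5",
    dI6 = "dp6", V0 = "p0", V1 = "p1", V2 = "p2", MN = "pMN", MNV = "pMN",
    V3 = "p3")
}
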