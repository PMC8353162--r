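#' Gene modules
#'
#' A gene module is a named, non-empty list of marker genes whose joint
#' activity is summarised per cell by [module_score()].  Modules are stored
#' on disk as a two-column TSV (`module`, `gene`).
#'
#' @param name module name.
#' @param genes character vector of unique gene names.
#' @return a `gene_module` object.
#' @export
gene_module <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("module name must be a non-empty string")
  genes <- as.character(genes)
  if (length(genes) == 0L) stopf("module '%s' has no genes", name)
  if (anyDuplicated(genes)) stopf("module '%s' has duplicated genes", name)
  structure(list(name = name, genes = genes), class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene modules from a two-column TSV
#'
#' @param path TSV with header columns `module` and `gene`.
#' @return named list of [gene_module()] objects.
#' @export
read_gene_modules <- function(path) {
  if (!file.exists(path)) stopf("module file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("module", "gene") %in% names(df)))
    stopf("module TSV needs columns 'module' and 'gene'")
  sp <- split(df$gene, df$module)
  out <- lapply(names(sp), function(n) gene_module(n, unique(sp[[n]])))
  names(out) <- names(sp)
  out
}

#' Default gene modules shipped with the package
#'
#' Tissue programmes (`neural`, `mesoderm`, `blood`, `skin`) used for broad
#' cell-type assignment, the `progenitor` and `neuron` pan-modules (the
#' neuronal module carries STMN2 and MAP2 in place of TUBB3, whose levels
#' are low in human), and the 11-gene `gliogenic` module.
#'
#' @return named list of [gene_module()] objects.
#' @export
default_gene_modules <- function() {
  read_gene_modules(system.file("extdata", "gene_modules_default.tsv",
                                package = "spinalatlas", mustWork = TRUE))
}

# Tissue modules used by the broad-assignment step.
default_tissue_modules <- function() {
  default_gene_modules()[c("neural", "mesoderm", "blood", "skin")]
}

#' Canonical cell-cycle gene lists
#'
#' The standard human S-phase and G2M-phase marker lists used for cell-cycle
#' scoring.
#'
#' @return list with `gene_module` elements `s` and `g2m`.
#' @export
cell_cycle_modules <- function() {
  read_gene_modules(system.file("extdata", "cell_cycle_genes.tsv",
                                package = "spinalatlas", mustWork = TRUE))
}

# Fixed gliogenic marker list.
gliogenic_genes <- function() {
  c("FABP7", "SOX9", "SOX10", "PDGFRA", "CSPG4", "FGFR3", "FGFBP3", "DBI",
    "SLC1A3", "HOPX", "ALDH1L1")
}
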