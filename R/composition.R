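#' Stage-by-type composition table
#'
#' Counts and proportions of assigned subtypes per stage.  `Unassigned`
#' cells are tracked as their own category but excluded from the proportion
#' denominator by default.
#'
#' @param assignment assignment data.frame with `stage` and `subtype`.
#' @param denominator `"assigned"` (default: proportions over assigned
#'   cells) or `"all"` (include Unassigned in the denominator).
#' @param label_col column holding the labels (default `"subtype"`).
#' @return data.frame `stage`, `type`, `n`, `proportion`; proportions per
#'   stage sum to 1 over the chosen denominator.
#' @export
composition_table <- function(assignment, denominator = c("assigned", "all"),
                              label_col = "subtype") {
  denominator <- match.arg(denominator)
  if (nrow(assignment) == 0L) stopf("empty assignment")
  lab <- assignment[[label_col]]
  lab[is.na(lab)] <- "Unassigned"
  tab <- as.data.frame(table(stage = assignment$stage, type = lab),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tab <- tab[order(tab$stage, tab$type), , drop = FALSE]
  denom <- vapply(split(tab, tab$stage), function(d) {
    if (denominator == "assigned") sum(d$n[d$type != "Unassigned"])
    else sum(d$n)
  }, numeric(1L))
  tab$proportion <- ifelse(
    tab$type == "Unassigned" & denominator == "assigned", NA_real_,
    tab$n / denom[tab$stage])
  rownames(tab) <- NULL
  tab
}

#' Group progenitor domains into broad territories
#'
#' The 11 dorsoventral progenitor domains are grouped into dorsal
#' interneuron progenitors (pD: dp1-dp6), intermediate interneuron
#' progenitors (pI: p0-p2), pMN and p3; floor plate and roof plate are
#' reported separately.  Grouped counts conserve the member counts exactly.
#'
#' @param assignment assignment data.frame; only cells of class
#'   `progenitor` are used.
#' @return data.frame `stage`, `territory`, `n`, `proportion` (per-stage
#'   proportions over all progenitors).
#' @export
group_territories <- function(assignment) {
  prog <- assignment[!is.na(assignment$class) &
                       assignment$class == "progenitor", , drop = FALSE]
  if (nrow(prog) == 0L) stopf("no progenitor cells in assignment")
  prog$territory <- territory_of(prog$subtype)
  tab <- as.data.frame(table(stage = prog$stage, territory = prog$territory),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  denom <- tapply(tab$n, tab$stage, sum)
  tab$proportion <- tab$n / as.numeric(denom[tab$stage])
  tab <- tab[order(tab$stage, tab$territory), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Neurogenesis-rate proxy: neuron/progenitor ratio per domain and stage
#'
#' For each (stage, domain) the ratio of neurons assigned to a domain's
#' neuronal class over its progenitors.  Zero progenitors with neurons
#' present give `Inf`; zero of both gives `NA`.
#'
#' @param assignment assignment data.frame.
#' @param domain_pairing named character vector mapping each neuronal class
#'   to its progenitor domain (default: dI1-dp1 ... V3-p3, MN/MNV-pMN).
#' @return data.frame `stage`, `domain` (progenitor label), `n_neurons`,
#'   `n_progenitors`, `ratio`.
#' @export
neurogenesis_rate <- function(assignment,
                              domain_pairing = default_domain_pairing()) {
  stages <- sort(unique(assignment$stage))
  domains <- unique(unname(domain_pairing))
  grid <- expand.grid(stage = stages, domain = domains,
                      stringsAsFactors = FALSE)
  grid$n_neurons <- mapply(function(s, d) {
    neur <- names(domain_pairing)[domain_pairing == d]
    sum(assignment$stage == s & assignment$subtype %in% neur, na.rm = TRUE)
  }, grid$stage, grid$domain)
  grid$n_progenitors <- mapply(function(s, d) {
    sum(assignment$stage == s & assignment$subtype %in% d, na.rm = TRUE)
  }, grid$stage, grid$domain)
  grid$ratio <- ifelse(
    grid$n_progenitors > 0, grid$n_neurons / grid$n_progenitors,
    ifelse(grid$n_neurons > 0, Inf, NA_real_))
  grid[order(grid$stage, grid$domain), , drop = FALSE]
}

#' Per-group expression summaries (dot-plot statistics)
#'
#' For every (stage, group, gene): the fraction of cells expressing the
#' gene (raw count > `detect_threshold`), the mean normalised expression,
#' and the mean raw transcripts per cell.  Genes whose mean transcripts per
#' cell reach `highlight_threshold` in at least one group are flagged; the
#' threshold is on the raw count scale because that is the scale on which
#' such cut-offs are conventionally quoted.
#'
#' @param nm an `sc_norm`.
#' @param cm the matching [sc_counts()] (raw counts).
#' @param assignment assignment data.frame (`barcode`, `stage`, group
#'   column).
#' @param genes genes to summarise; missing genes are kept as zero rows and
#'   listed in a warning.
#' @param detect_threshold raw-count detection cut-off (default 0, i.e.
#'   count > 0).
#' @param highlight_threshold mean transcripts/cell flag level (default
#'   0.10).
#' @param group_col grouping column of `assignment` (default `"subtype"`).
#' @return data.frame over the full stage x group x gene grid with columns
#'   `fraction_expressing`, `mean_expression`, `mean_counts_per_cell` and a
#'   per-gene logical `highlight`.
#' @export
expression_summary <- function(nm, cm, assignment, genes,
                               detect_threshold = 0,
                               highlight_threshold = 0.10,
                               group_col = "subtype") {
  m_norm <- norm_mat(nm)
  m_raw <- cm$counts
  missing <- setdiff(genes, rownames(m_raw))
  if (length(missing))
    warnf("%d gene(s) absent, summarised as zero: %s", length(missing),
          paste(missing, collapse = ", "))
  idx <- match(colnames(m_raw), assignment$barcode)
  stage <- assignment$stage[idx]
  group <- assignment[[group_col]][idx]
  ok <- !is.na(group) & group != "Unassigned"
  cells_of <- split(which(ok), paste(stage[ok], group[ok], sep = "\r"))
  grid_keys <- names(cells_of)
  rows <- lapply(grid_keys, function(key) {
    cells <- cells_of[[key]]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    raw <- m_raw[intersect(genes, rownames(m_raw)), cells, drop = FALSE]
    nrm <- m_norm[intersect(genes, rownames(m_norm)), cells, drop = FALSE]
    frac <- stats::setNames(rep(0, length(genes)), genes)
    mexp <- frac; mcnt <- frac
    frac[rownames(raw)] <- Matrix::rowMeans(raw > detect_threshold)
    mexp[rownames(nrm)] <- Matrix::rowMeans(nrm)
    mcnt[rownames(raw)] <- Matrix::rowMeans(raw)
    data.frame(stage = parts[1L], group = parts[2L], gene = genes,
               fraction_expressing = unname(frac),
               mean_expression = unname(mexp),
               mean_counts_per_cell = unname(mcnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  top <- tapply(out$mean_counts_per_cell, out$gene, max)
  out$highlight <- as.logical(top[out$gene] >= highlight_threshold)
  rownames(out) <- NULL
  out
}
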