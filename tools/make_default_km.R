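# Builds the shipped default knowledge matrix and gene-module tables under
# inst/extdata/.  Run from the repository root:
#   Rscript tools/make_default_km.R
# The generated TSVs are committed; this script is kept so the tables can be
# regenerated or audited.

rows <- list(
  # CNS progenitor domains, dorsal -> ventral.  All require SOX2.
  list("RP",  "progenitor", 1,  req = c("SOX2","LMX1A","MSX1"),            forb = character()),
  list("dp1", "progenitor", 2,  req = c("SOX2","ATOH1","OLIG3","PAX3","PAX7"), forb = character()),
  list("dp2", "progenitor", 3,  req = c("SOX2","NEUROG1","OLIG3","PAX3","PAX7"), forb = "ATOH1"),
  list("dp3", "progenitor", 4,  req = c("SOX2","ASCL1","OLIG3","PAX3","PAX7"), forb = c("ATOH1","NEUROG1")),
  list("dp4", "progenitor", 5,  req = c("SOX2","ASCL1","GSX2","PAX3","PAX7"), forb = c("OLIG3","GSX1")),
  list("dp5", "progenitor", 6,  req = c("SOX2","ASCL1","GSX1","PAX3","PAX7"), forb = "OLIG3"),
  list("dp6", "progenitor", 7,  req = c("SOX2","DBX2","PAX3","PAX7"),      forb = c("ASCL1","NKX6-1")),
  list("p0",  "progenitor", 8,  req = c("SOX2","DBX1","DBX2","PAX6"),      forb = c("PAX3","PAX7")),
  list("p1",  "progenitor", 9,  req = c("SOX2","PRDM12","DBX2","NKX6-2","PAX6"), forb = "DBX1"),
  list("p2",  "progenitor", 10, req = c("SOX2","NKX6-1","IRX3","PAX6","FOXN4"), forb = c("OLIG2","DBX2")),
  list("pMN", "progenitor", 11, req = c("SOX2","OLIG2","NKX6-1"),          forb = c("NKX2-2","IRX3")),
  list("p3",  "progenitor", 12, req = c("SOX2","NKX2-2","NKX6-1"),         forb = c("OLIG2","PAX6")),
  # FP carries PAX7: a human-specific floor-plate feature.
  list("FP",  "progenitor", 13, req = c("SOX2","FOXA2","ARX","SHH","PAX7"), forb = "PAX6"),

  # CNS neuronal classes.  All require ELAVL3.
  list("dI1", "neuron", 14, req = c("ELAVL3","LHX2","LHX9"),               forb = "LBX1"),
  list("dI2", "neuron", 15, req = c("ELAVL3","FOXD3","POU4F1","LHX1"),     forb = c("ISL1","LBX1")),
  list("dI3", "neuron", 16, req = c("ELAVL3","ISL1","TLX3","POU4F1"),      forb = c("LBX1","PHOX2B","MNX1")),
  list("dI4", "neuron", 17, req = c("ELAVL3","LBX1","PAX2","LHX1"),        forb = c("LMX1B","DMRT3","POU4F1")),
  list("dI5", "neuron", 18, req = c("ELAVL3","LBX1","LMX1B","TLX3","POU4F1"), forb = "PAX2"),
  list("dI6", "neuron", 19, req = c("ELAVL3","LBX1","PAX2","DMRT3","WT1"), forb = "LMX1B"),
  list("V0",  "neuron", 20, req = c("ELAVL3","EVX1","EVX2"),               forb = "EN1"),
  list("V1",  "neuron", 21, req = c("ELAVL3","EN1","PAX2","FOXP2"),        forb = c("EVX1","LBX1")),
  list("V2",  "neuron", 22, req = c("ELAVL3","VSX2","SOX14","LHX3"),       forb = "ISL1"),
  list("MN",  "neuron", 23, req = c("ELAVL3","ISL1","MNX1","LHX3"),        forb = c("PHOX2B","TLX3","VSX2")),
  # 12th neuronal class: visceral motor neurons (PHOX2B/ISL1/TBX2/TBX3).
  list("MNV", "neuron", 24, req = c("ELAVL3","ISL1","PHOX2B","TBX2","TBX3"), forb = c("MNX1","TLX3")),
  list("V3",  "neuron", 25, req = c("ELAVL3","SIM1"),                      forb = "PAX2"),

  # Peripheral (neural crest / dorsal root ganglia) lineage.
  list("NCC",            "pns_progenitor", NA, req = c("SOX10","TFAP2A"),
       forb = c("ELAVL3","NEUROG1","NEUROG2","NEUROD1")),
  list("SensoryPrec",    "pns_precursor",  NA, req = c("SIX1","NEUROG1","NEUROG2","NEUROD1"),
       forb = character()),
  list("Mechanoreceptor","pns_neuron",     NA, req = c("SIX1","ELAVL3","RET","MAF"),
       forb = c("RUNX1","NTRK1")),
  list("Proprioceptor",  "pns_neuron",     NA, req = c("SIX1","ELAVL3","NTRK3","RUNX3"),
       forb = "NTRK1"),
  list("Peptidergic",    "pns_neuron",     NA, req = c("SIX1","ELAVL3","NTRK1","TAC1"),
       forb = c("RUNX1","RET")),
  list("NonPeptidergic", "pns_neuron",     NA, req = c("SIX1","ELAVL3","RET","RUNX1"),
       forb = c("MAF","NTRK1")),

  # Oligodendrocyte precursors.
  list("OLP", "glia", NA, req = c("SOX2","SOX10","OLIG2","NKX2-2","PDGFRA"),
       forb = "ELAVL3"),

  # Contaminant tissues used by the mixed-tissue simulations.
  list("mesoderm", "contaminant", NA, req = c("TBX6","MEOX1","MSGN1","PAX1","TWIST1"), forb = character()),
  list("blood",    "contaminant", NA, req = c("HBA1","HBG1","GATA1","KLF1"),  forb = character()),
  list("skin",     "contaminant", NA, req = c("KRT5","KRT8","KRT18","TP63"),  forb = character())
)

genes <- unique(unlist(lapply(rows, function(r) c(r$req, r$forb))))
km <- data.frame(type = vapply(rows, `[[`, "", 1L),
                 class = vapply(rows, `[[`, "", 2L),
                 dv_rank = vapply(rows, function(r) as.integer(r[[3L]]), 1L),
                 stringsAsFactors = FALSE, check.names = FALSE)
for (g in genes) km[[g]] <- 0L
for (i in seq_along(rows)) {
  km[i, rows[[i]]$req] <- 1L
  if (length(rows[[i]]$forb)) km[i, rows[[i]]$forb] <- -1L
}
utils::write.table(km, "inst/extdata/knowledge_matrix_default.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# Gene modules: broad tissue programmes plus convenience modules.
mods <- rbind(
  data.frame(module = "neural",   gene = c("NCAM1","TUBB2B","MAP1B","CRABP1")),
  data.frame(module = "mesoderm", gene = c("TBX6","MEOX1","MSGN1","PAX1","TWIST1")),
  data.frame(module = "blood",    gene = c("HBA1","HBG1","GATA1","KLF1")),
  data.frame(module = "skin",     gene = c("KRT5","KRT8","KRT18","TP63")),
  data.frame(module = "progenitor", gene = "SOX2"),
  # TUBB3 is deliberately absent from the neuronal module; STMN2 and MAP2
  # stand in for it.
  data.frame(module = "neuron",   gene = c("ELAVL3","STMN2","MAP2")),
  data.frame(module = "gliogenic",
             gene = c("FABP7","SOX9","SOX10","PDGFRA","CSPG4","FGFR3",
                      "FGFBP3","DBI","SLC1A3","HOPX","ALDH1L1"))
)
utils::write.table(mods, "inst/extdata/gene_modules_default.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# Canonical human S-phase and G2M-phase marker lists.
s_genes <- c("MCM5","PCNA","TYMS","FEN1","MCM2","MCM4","RRM1","UNG","GINS2",
             "MCM6","CDCA7","DTL","PRIM1","UHRF1","CENPU","HELLS","RFC2",
             "RPA2","NASP","RAD51AP1","GMNN","WDR76","SLBP","CCNE2","UBR7",
             "POLD3","MSH2","ATAD2","RAD51","RRM2","CDC45","CDC6","EXO1",
             "TIPIN","DSCC1","BLM","CASP8AP2","USP1","CLSPN","POLA1",
             "CHAF1B","BRIP1","E2F8")
g2m_genes <- c("HMGB2","CDK1","NUSAP1","UBE2C","BIRC5","TPX2","TOP2A",
               "NDC80","CKS2","NUF2","CKS1B","MKI67","TMPO","CENPF","TACC3",
               "PIMREG","SMC4","CCNB2","CKAP2L","CKAP2","AURKB","BUB1",
               "KIF11","ANP32E","TUBB4B","GTSE1","KIF20B","HJURP","CDCA3",
               "JPT1","CDC20","TTK","CDC25C","KIF2C","RANGAP1","NCAPD2",
               "DLGAP5","CDCA2","CDCA8","ECT2","KIF23","HMMR","AURKA",
               "PSRC1","ANLN","LBR","CKAP5","CENPE","CTCF","NEK2","G2E3",
               "GAS2L3","CBX5","CENPA")
cc <- rbind(data.frame(module = "s", gene = s_genes),
            data.frame(module = "g2m", gene = g2m_genes))
utils::write.table(cc, "inst/extdata/cell_cycle_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# Synthetic transcription-factor annotation (gene -> GO term) used by the
# gene-set restriction tests.  Covers the DNA-binding TFs of the marker set.
tfs <- c("SOX2","LMX1A","MSX1","ATOH1","OLIG3","PAX3","PAX7","NEUROG1",
         "ASCL1","GSX1","GSX2","DBX1","DBX2","PAX6","PRDM12","NKX6-1",
         "NKX6-2","IRX3","FOXN4","OLIG2","NKX2-2","FOXA2","ARX","LHX2",
         "LHX9","FOXD3","POU4F1","LHX1","ISL1","TLX3","PHOX2B","MNX1",
         "LBX1","PAX2","LMX1B","DMRT3","WT1","EVX1","EVX2","EN1","FOXP2",
         "VSX2","SOX14","LHX3","TBX2","TBX3","SIM1","SOX10","TFAP2A",
         "NEUROG2","NEUROD1","SIX1","RUNX3","RUNX1","MAF","SOX9")
tf <- data.frame(gene = tfs, term = "GO:0003700")
utils::write.table(tf, "inst/extdata/tf_annotation_synthetic.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote", nrow(km), "knowledge-matrix rows,", length(genes),
    "marker genes\n")
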