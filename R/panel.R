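#' Default 136-gene targeted panel
#'
#' A pediatric solid-tumor style targeted panel of 136 genes with chromosome
#' arm assignments and probe counts. Arms carrying recurrent neuroblastoma
#' segmental aberrations (1p, 11q, 17q) and the focal MYCN locus on 2p are
#' represented; the remaining genes populate other arms so that arm-level
#' events shift coherent blocks of genes. Probes total 2998 (22 per gene, one
#' extra on the first six genes).
#'
#' @param probes_per_gene baseline number of probes per gene.
#' @return A data.frame of class `gene_panel` with columns `gene_id`, `chrom`,
#'   `arm` (`"p"`/`"q"`), `arm_id` (e.g. `"17q"`) and `n_probes`.
#' @export
#' @examples
#' panel <- default_gene_panel()
#' nrow(panel)            # 136
#' sum(panel$n_probes)    # 2998
default_gene_panel <- function(probes_per_gene = 22L) {
  arm_genes <- list(
    "1p"  = c("MTOR", "ID3", "ARID1A", "CSF3R", "MPL", "JAK1", "NRAS",
              "SDHB", "KIF1B", "CHD5", "CAMTA1", "MYCL"),
    "1q"  = c("H3F3A", "MDM4", "ABL2", "FASLG", "NTRK1"),
    "2p"  = c("MYCN", "ALK", "DNMT3A", "ASXL2"),
    "2q"  = c("ERBB4", "SF3B1", "IDH1", "ACVR1"),
    "3p"  = c("CCR5", "SETD2", "RHOA", "VHL", "CTNNB1"),
    "3q"  = c("PIK3CA"),
    "4p"  = c("FGFR3"),
    "4q"  = c("FBXW7", "KDR", "KIT", "PDGFRA"),
    "5p"  = c("TERT", "IL7R"),
    "5q"  = c("APC", "CSF1R", "EBF1", "FGFR4", "PIK3R1", "CCNB1"),
    "6p"  = c("DAXX", "HIST1H3B", "CCND3", "VEGFA"),
    "6q"  = c("ARID1B", "ESR1", "MYB", "ROS1"),
    "7p"  = c("EGFR"),
    "7q"  = c("BRAF", "EZH2", "MET", "SMO", "CDK6"),
    "8p"  = c("FGFR1"),
    "8q"  = c("MYC"),
    "9p"  = c("JAK2", "KDM4C", "CDKN2A"),
    "9q"  = c("ABL1", "NOTCH1", "NTRK2", "TSC1"),
    "10q" = c("PTEN", "FGFR2", "RET"),
    "11p" = c("HRAS", "WT1", "EXT2"),
    "11q" = c("EED", "CBL", "ATM", "MEN1", "BIRC3", "SDHD", "CCND1"),
    "12p" = c("KRAS", "CCND2", "ETV6", "CDKN1B"),
    "12q" = c("PTPN11", "CDK4", "MDM2", "ARID2"),
    "13q" = c("RB1", "FLT3", "FLT1"),
    "14q" = c("AKT1", "DICER1", "MAX", "FOXA1"),
    "15q" = c("NTRK3", "IGF1R"),
    "16p" = c("TSC2", "CREBBP"),
    "17p" = c("TP53", "MAP2K4"),
    "17q" = c("GNA13", "PPM1D", "STAT3", "STAT5B", "SUZ12", "NF1", "ERBB2",
              "TOP2A", "BRCA1"),
    "18q" = c("SETBP1", "BCL2", "SMAD4"),
    "19p" = c("GNA11", "MAP2K2", "TCF3", "SMARCA4", "JAK3", "CALR", "CRLF1"),
    "19q" = c("CEBPA", "CIC"),
    "20q" = c("ASXL1", "AURKA", "GNAS"),
    "21q" = c("RUNX1"),
    "22q" = c("NF2", "SMARCB1"),
    "Xp"  = c("CRLF2", "DDX3X", "KDM6A"),
    "Xq"  = c("PHF6", "ATRX", "GATA1", "SH2D1A", "XIAP")
  )
  arm_id <- rep(names(arm_genes), lengths(arm_genes))
  panel <- data.frame(
    gene_id = unlist(arm_genes, use.names = FALSE),
    chrom   = sub("[pq]$", "", arm_id),
    arm     = sub("^.*([pq])$", "\\1", arm_id),
    arm_id  = arm_id,
    n_probes = probes_per_gene,
    stringsAsFactors = FALSE
  )
  # top up to 2998 probes at the default density
  if (probes_per_gene == 22L) {
    panel$n_probes[seq_len(6L)] <- probes_per_gene + 1L
  }
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Gene panel with one pseudo-arm per gene
#'
#' Builds a panel in which every gene sits on its own pseudo-arm, so arm-level
#' events perturb genes independently. Useful for null simulations and
#' false-discovery-rate calibration, where copy-number correlation between
#' genes (as induced by shared arms) would confound the truth partition.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene probes per gene.
#' @return A `gene_panel` data.frame; arm ids are `A001p`, `A002p`, ...
#' @export
independent_gene_panel <- function(n_genes = 131L, probes_per_gene = 3L) {
  ids <- sprintf("G%03d", seq_len(n_genes))
  panel <- data.frame(
    gene_id = ids,
    chrom   = sprintf("A%03d", seq_len(n_genes)),
    arm     = "p",
    arm_id  = sprintf("A%03dp", seq_len(n_genes)),
    n_probes = probes_per_gene,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

validate_gene_panel <- function(panel) {
  required <- c("gene_id", "chrom", "arm", "arm_id", "n_probes")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("gene panel is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(panel$gene_id)) {
    stop("gene panel has duplicated gene_ids")
  }
  if (any(panel$n_probes < 1L)) {
    stop("every panel gene needs at least one probe")
  }
  invisible(panel)
}

#' Default 418-compound kinase-inhibitor library
#'
#' A single-concentration targeted-inhibitor library with mechanism classes
#' and expected gene targets. The first block carries named compounds with
#' curated target annotations (PI3K/mTOR, CDK, JAK and receptor tyrosine
#' kinase inhibitors commonly screened against neuroblastoma models); the
#' remainder are generic library members whose targets cycle through the gene
#' panel, giving an expected-pair annotation of roughly one gene per drug.
#' The construction is fully deterministic.
#'
#' @param n_drugs library size.
#' @param panel gene panel whose genes are used as targets.
#' @return A data.frame of class `drug_library` with columns `compound_id`,
#'   `name`, `mechanism_class` and `target_genes` (semicolon-separated).
#' @export
default_drug_library <- function(n_drugs = 418L, panel = default_gene_panel()) {
  validate_gene_panel(panel)
  named <- list(
    list("BGT226",            "PI3K/Akt/mTOR",          "PIK3CA;MTOR"),
    list("P276-00",           "Cell Cycle",             "CDK4"),
    list("PIK-75",            "PI3K/Akt/mTOR",          "PIK3CA"),
    list("Tivantinib",        "Protein T.K.",           "MET"),
    list("Flavopiridol",      "Cell Cycle",             "CDK4;CDK6"),
    list("Flavopiridol HCl",  "Cell Cycle",             "CDK4;CDK6"),
    list("SNS-032",           "Cell Cycle",             "CDK4"),
    list("Dinaciclib",        "Cell Cycle",             "CDK4;CDK6"),
    list("INK 128",           "PI3K/Akt/mTOR",          "MTOR"),
    list("Torin 2",           "PI3K/Akt/mTOR",          "MTOR"),
    list("AT7519",            "Cell Cycle",             "CDK4"),
    list("PF-04691502",       "PI3K/Akt/mTOR",          "PIK3CA;MTOR"),
    list("GSK2126458",        "PI3K/Akt/mTOR",          "PIK3CA;MTOR"),
    list("AZD8055",           "PI3K/Akt/mTOR",          "MTOR"),
    list("WYE-125132",        "PI3K/Akt/mTOR",          "MTOR"),
    list("VS-5584",           "PI3K/Akt/mTOR",          "PIK3CA;MTOR"),
    list("AZD3463",           "Protein T.K.",           "ALK;IGF1R"),
    list("GDC-0980",          "PI3K/Akt/mTOR",          "PIK3CA;MTOR"),
    list("AT9283",            "JAK/STAT",               "JAK3;JAK1"),
    list("AZD2014",           "PI3K/Akt/mTOR",          "MTOR"),
    list("PP242",             "PI3K/Akt/mTOR",          "MTOR"),
    list("Rigosertib",        "Cell Cycle",             "PIK3CA"),
    list("PF-477736",         "Cell Cycle",             "BRCA1"),
    list("JNK Inhibitor IX",  "MAPK",                   "MAP2K4"),
    list("PF-3758309",        "Cytoskeletal Signaling", "RHOA"),
    list("Milciclib",         "Cell Cycle",             "CDK4"),
    list("HMN-214",           "Cell Cycle",             "TOP2A"),
    list("TAK-901",           "Cell Cycle",             "AURKA"),
    list("KX2-391",           "Angiogenesis",           "ABL1"),
    list("Pelitinib",         "Protein T.K.",           "EGFR"),
    list("CHIR-124",          "Cell Cycle",             "CDK6"),
    list("OSI-027",           "PI3K/Akt/mTOR",          "MTOR"),
    list("TG101209",          "JAK/STAT",               "JAK2;FLT3"),
    list("GDC-0349",          "PI3K/Akt/mTOR",          "MTOR"),
    list("KU-0063794",        "PI3K/Akt/mTOR",          "MTOR"),
    list("HS-173",            "PI3K/Akt/mTOR",          "PIK3CA"),
    list("IMD 0354",          "NF-KB",                  "CIC"),
    list("AP26113",           "Protein T.K.",           "ALK;EGFR"),
    list("LDK378",            "Protein T.K.",           "ALK"),
    list("TG101348",          "JAK/STAT",               "JAK2"),
    list("BI 2536",           "Cell Cycle",             "TOP2A"),
    list("FIIN-2",            "Protein T.K.",           "FGFR1;FGFR2;FGFR3;FGFR4"),
    list("AZ20",              "PI3K/Akt/mTOR",          "ATM"),
    list("Pacritinib",        "JAK/STAT",               "JAK2;FLT3"),
    list("R547",              "Cell Cycle",             "CDK4"),
    list("R406",              "Angiogenesis",           "KDR"),
    list("AZD7762",           "Cell Cycle",             "BRCA1"),
    list("Volasertib",        "Cell Cycle",             "TOP2A"),
    list("CYT387",            "JAK/STAT",               "JAK1;JAK2"),
    list("Sunitinib",         "Angiogenesis",           "KDR;KIT;FLT3;RET;PDGFRA"),
    list("Vandetanib",        "Angiogenesis",           "KDR;EGFR;RET"),
    list("Crizotinib",        "Protein T.K.",           "ALK;MET;ROS1"),
    list("Ruxolitinib",       "JAK/STAT",               "JAK1;JAK2"),
    list("Saracatinib",       "Protein T.K.",           "ABL1"),
    list("Ponatinib",         "Protein T.K.",           "ABL1;FGFR1;KDR"),
    list("Tyrphostin AG1296", "Protein T.K.",           "FGFR1;PDGFRA;KIT"),
    list("Brivanib",          "Angiogenesis",           "FGFR3;KDR"),
    list("PI-103",            "PI3K/Akt/mTOR",          "PIK3CA;MTOR")
  )
  if (n_drugs < length(named)) named <- named[seq_len(n_drugs)]
  classes <- c("PI3K/Akt/mTOR", "Cell Cycle", "JAK/STAT", "Protein T.K.",
               "Angiogenesis", "MAPK", "NF-KB", "Cytoskeletal Signaling",
               "Epigenetics", "DNA Damage")
  n_named <- length(named)
  n_fill <- n_drugs - n_named
  fill_idx <- seq_len(max(n_fill, 0L))
  lib <- data.frame(
    compound_id = sprintf("D%03d", seq_len(n_drugs)),
    name = c(vapply(named, `[[`, "", 1L),
             sprintf("KI-%03d", n_named + fill_idx)[seq_len(n_fill)]),
    mechanism_class = c(vapply(named, `[[`, "", 2L),
                        classes[((fill_idx - 1L) %% length(classes)) + 1L][seq_len(n_fill)]),
    target_genes = c(vapply(named, `[[`, "", 3L),
                     panel$gene_id[((n_named + fill_idx - 1L) %% nrow(panel)) + 1L][seq_len(n_fill)]),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("drug_library", "data.frame")
  lib
}

#' Expected gene-drug pairs from a drug library
#'
#' Expands the semicolon-separated `target_genes` annotation into one row per
#' expected gene-drug pair, optionally restricted to genes present in a panel.
#'
#' @param drug_library a `drug_library` data.frame.
#' @param panel optional gene panel; pairs whose gene is absent are dropped.
#' @return data.frame with columns `gene_id`, `drug_id`.
#' @export
expected_pairs_from_library <- function(drug_library, panel = NULL) {
  targets <- strsplit(drug_library$target_genes, ";", fixed = TRUE)
  out <- data.frame(
    gene_id = unlist(targets, use.names = FALSE),
    drug_id = rep(drug_library$compound_id, lengths(targets)),
    stringsAsFactors = FALSE
  )
  out <- out[out$gene_id != "", , drop = FALSE]
  if (!is.null(panel)) out <- out[out$gene_id %in% panel$gene_id, , drop = FALSE]
  unique(out)
}

#' Bundled toy pathway gene sets
#'
#' Small gene sets over the default panel, used for optional hypergeometric
#' enrichment of network modules. These are stand-ins constructed from the
#' panel's pathway-themed gene groups, not a curated pathway database.
#'
#' @return named list of character vectors of gene ids.
#' @export
toy_pathway_sets <- function() {
  list(
    PI3K_MTOR   = c("PIK3CA", "PIK3R1", "MTOR", "AKT1", "PTEN", "TSC1", "TSC2"),
    JAK_STAT    = c("JAK1", "JAK2", "JAK3", "STAT3", "STAT5B", "CRLF2", "MPL", "CALR"),
    CELL_CYCLE  = c("CDK4", "CDK6", "CCND1", "CCND2", "CCND3", "CCNB1",
                    "CDKN1B", "CDKN2A", "RB1"),
    RTK         = c("ALK", "EGFR", "ERBB2", "ERBB4", "MET", "KIT", "KDR",
                    "RET", "FGFR1", "FGFR2", "FGFR3", "FGFR4", "FLT1",
                    "FLT3", "NTRK1", "NTRK2", "NTRK3", "IGF1R", "PDGFRA", "ROS1"),
    CHROMATIN   = c("ARID1A", "ARID1B", "ARID2", "SMARCA4", "SMARCB1",
                    "CREBBP", "EZH2", "EED", "SUZ12", "ASXL1", "ASXL2",
                    "KDM4C", "KDM6A", "DNMT3A", "CHD5"),
    SEVENTEEN_Q = c("GNA13", "PPM1D", "STAT3", "STAT5B", "SUZ12", "NF1",
                    "ERBB2", "TOP2A", "BRCA1")
  )
}
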