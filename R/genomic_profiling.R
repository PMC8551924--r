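#' Segment probe-level log2 ratios to gene level
#'
#' Collapses normalized probe log2 ratios to gene-level mean log2 ratios (mean
#' of probe log ratios per gene and sample) and converts them to copy numbers
#' at the given ploidy. Genes whose probes are all missing in every sample are
#' dropped and reported with a warning.
#'
#' @param probe_log2 data.frame with columns `probe_id`, `gene`, `chrom`,
#'   `arm` followed by one numeric column per sample (the layout written by
#'   [write_probe_tsv()]).
#' @param panel gene panel; probes must map to panel genes.
#' @param ploidy baseline ploidy used for the copies conversion (default 2).
#' @return object of class `copy_number_profile`: list with `log2_ratio`
#'   (gene x sample), `copies`, `ploidy`, `dropped_genes`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' prof <- segment_probes_to_genes(cohort$probe_log2, cohort$panel)
#' prof$log2_ratio[1:3, 1:3]
segment_probes_to_genes <- function(probe_log2, panel, ploidy = 2) {
  validate_gene_panel(panel)
  meta_cols <- c("probe_id", "gene", "chrom", "arm")
  missing_meta <- setdiff(meta_cols, names(probe_log2))
  if (length(missing_meta)) {
    stop("probe matrix is missing columns: ", paste(missing_meta, collapse = ", "))
  }
  unknown <- !probe_log2$gene %in% panel$gene_id
  if (any(unknown)) {
    stop("probes reference genes absent from the panel: ",
         paste(utils::head(probe_log2$probe_id[unknown], 5L), collapse = ", "))
  }
  sample_cols <- setdiff(names(probe_log2), meta_cols)
  vals <- as.matrix(probe_log2[, sample_cols, drop = FALSE])
  genes <- factor(probe_log2$gene, levels = unique(panel$gene_id[panel$gene_id %in% probe_log2$gene]))
  log2_ratio <- rowsum(vals, genes, na.rm = TRUE) /
    rowsum((!is.na(vals)) + 0, genes)
  # rowsum over zero usable probes yields 0/0 = NaN; such cells become NA
  log2_ratio[is.nan(log2_ratio)] <- NA_real_
  dropped <- rownames(log2_ratio)[rowSums(!is.na(log2_ratio)) == 0L]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " gene(s) with no usable probes: ",
            paste(dropped, collapse = ", "))
    log2_ratio <- log2_ratio[!rownames(log2_ratio) %in% dropped, , drop = FALSE]
  }
  structure(list(
    log2_ratio = log2_ratio,
    copies = log_ratio_to_copies(log2_ratio, ploidy),
    ploidy = ploidy,
    dropped_genes = dropped
  ), class = "copy_number_profile")
}

#' Convert log2 ratios to absolute copy numbers
#'
#' `copies = ploidy * 2 ^ log2_ratio`. A log2 ratio of 0 is diploid (2
#' copies at the default ploidy); a ratio of 1 is 4 copies.
#'
#' @param log2_ratio numeric vector or matrix of log2 copy ratios.
#' @param ploidy baseline ploidy (default 2).
#' @return copies, same shape as the input.
#' @export
log_ratio_to_copies <- function(log2_ratio, ploidy = 2) {
  ploidy * 2^log2_ratio
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat("Copy-number profile:", nrow(x$log2_ratio), "genes x",
      ncol(x$log2_ratio), "samples (ploidy ", x$ploidy, ")\n", sep = "")
  if (length(x$dropped_genes)) {
    cat("  dropped (no usable probes):",
        paste(x$dropped_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter somatic variant candidates
#'
#' Applies the somatic SNV candidate criteria: coverage strictly above
#' `min_coverage` reads, allele fraction at least `min_af` (inclusive), a
#' COSMIC-reported variant, and population frequency strictly below
#' `max_popfreq`. Every rejected record lists all criteria it failed.
#'
#' @param records data.frame of variant records (see [generate_variants()] for
#'   the expected columns).
#' @param min_coverage coverage must exceed this (strict; default 100).
#' @param min_af minimum allele fraction (inclusive; default 0.10).
#' @param require_cosmic require the COSMIC flag (default TRUE).
#' @param max_popfreq population frequency must be below this (strict;
#'   default 0.01).
#' @return list with `passing` and `rejected` data.frames; `rejected` gains a
#'   `reasons` column (comma-separated failed criteria). Every input record
#'   appears in exactly one of the two.
#' @export
filter_somatic_variants <- function(records, min_coverage = 100,
                                    min_af = 0.10, require_cosmic = TRUE,
                                    max_popfreq = 0.01) {
  needed <- c("coverage", "allele_fraction", "cosmic_reported",
              "population_frequency")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("variant records are missing fields: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(records[needed])
  if (any(bad)) {
    stop("variant record(s) with missing field values at rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  fails <- cbind(
    coverage = !(records$coverage > min_coverage),
    allele_fraction = !(records$allele_fraction >= min_af),
    cosmic = if (require_cosmic) !records$cosmic_reported else FALSE,
    population_frequency = !(records$population_frequency < max_popfreq)
  )
  pass <- rowSums(fails) == 0L
  rejected <- records[!pass, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reasons <- apply(fails[!pass, , drop = FALSE], 1L, function(f)
      paste(colnames(fails)[f], collapse = ","))
  } else {
    rejected$reasons <- character(0)
  }
  list(passing = records[pass, , drop = FALSE], rejected = rejected)
}

#' Exclude recurrent population SNPs
#'
#' Removes records flagged as recurrent single-nucleotide polymorphisms, either
#' via a logical flag column (`is_population_snp`) or an explicit exclusion
#' list of `gene_id:pos` keys. Bookkeeping is conserved:
#' `nrow(input) == nrow(remaining) + nrow(excluded)`.
#'
#' @param records variant records.
#' @param snp_list optional character vector of `gene_id:pos` keys to exclude;
#'   when `NULL`, the `is_population_snp` column is used.
#' @return list with `remaining` and `excluded` data.frames.
#' @export
exclude_population_snps <- function(records, snp_list = NULL) {
  if (is.null(snp_list)) {
    if (!"is_population_snp" %in% names(records)) {
      stop("records lack an is_population_snp column and no snp_list was given")
    }
    flagged <- records$is_population_snp
  } else {
    flagged <- paste0(records$gene_id, ":", records$pos) %in% snp_list
  }
  list(remaining = records[!flagged, , drop = FALSE],
       excluded = records[flagged, , drop = FALSE])
}
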