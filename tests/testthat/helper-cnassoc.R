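# Shared fixture builders; everything is generated in code.

# A small panel: three eventful arms plus fillers.
small_panel <- function() {
  panel <- data.frame(
    gene_id = c("A1", "A2", "B1", "B2", "C1", "C2", "N1", "N2"),
    chrom   = c("1", "1", "11", "11", "17", "17", "5", "5"),
    arm     = c("p", "p", "q", "q", "q", "q", "q", "q"),
    arm_id  = c("1p", "1p", "11q", "11q", "17q", "17q", "5q", "5q"),
    n_probes = 3L,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

small_rates <- function(p1 = 0.31, p11 = 0.38, p17 = 0.69) {
  list("1p" = list(event = "loss", probability = p1),
       "11q" = list(event = "loss", probability = p11),
       "17q" = list(event = "gain", probability = p17))
}

small_config <- function(seed = 1, n_samples = 6, probe_noise_sd = 0.05,
                         response_noise_sd = 5, n_drugs = 12, ...) {
  panel <- small_panel()
  cohort_config(n_samples = n_samples, panel = panel,
                arm_event_rates = small_rates(),
                focal_amp = list(gene = "C1", probability = 0.2,
                                 copy_range = c(10, 40)),
                probe_noise_sd = probe_noise_sd,
                drug_library = default_drug_library(n_drugs, panel),
                response_noise_sd = response_noise_sd,
                seed = seed, ...)
}

# One plate data.frame from named compound RLUs plus controls.
toy_plate <- function(compound_rlu, dmso = rep(1000, 4), stauro = rep(40, 2)) {
  data.frame(
    plate_id = "P1", sample_id = "S01",
    well = sprintf("W%02d", seq_len(length(compound_rlu) + length(dmso) + length(stauro))),
    compound_id = c(names(compound_rlu), rep("DMSO", length(dmso)),
                    rep("STAUROSPORINE", length(stauro))),
    rlu = c(unname(compound_rlu), dmso, stauro),
    stringsAsFactors = FALSE
  )
}

# Literal step-up definition of Benjamini-Hochberg, used as the independent
# oracle for bh_fdr(): find the largest i with p_(i) <= i q / m and reject
# everything at or below that order statistic.
bh_brute_force <- function(p, q) {
  keep <- !is.na(p)
  m <- sum(keep)
  reject <- logical(length(p))
  if (m == 0L) return(reject)
  ps <- p[keep]
  o <- order(ps)
  ok <- ps[o] <= seq_len(m) * q / m
  if (any(ok)) {
    k <- max(which(ok))
    reject[keep][o[seq_len(k)]] <- TRUE
  }
  reject
}

# Variant record constructor with passing defaults.
variant_record <- function(n = 1, coverage = 150, af = 0.12, cosmic = TRUE,
                           popfreq = 0.005, snp = FALSE) {
  out <- data.frame(sample_id = "S01", gene_id = "A1", chrom = "1",
                    pos = seq_len(max(n, 1L)), ref = "A", alt = "T",
                    coverage = coverage, allele_fraction = af,
                    cosmic_reported = cosmic, population_frequency = popfreq,
                    is_population_snp = snp, stringsAsFactors = FALSE)
  out[seq_len(n), , drop = FALSE]
}
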