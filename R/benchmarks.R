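#' False-discovery-rate benchmark of the association screen
#'
#' Simulates seeded cohorts with planted gene-drug effects, runs the full
#' profiling + screening pipeline on each, and measures the false-discovery
#' proportion of the BH-thresholded discovery set against the planted truth
#' (FDP = 0 when nothing is discovered), together with sensitivity for the
#' planted pairs.
#'
#' The benchmark cohort uses a panel with one pseudo-arm per gene so genes
#' vary independently. The planted pairs are spread over `n_planted_genes`
#' eventful genes (gain probability 0.5 each), every planted gene paired with
#' an equal share of distinct drugs at slope `slope` %/copy, giving a true
#' planted correlation magnitude of
#' `slope * 0.5 / sqrt((slope * 0.5)^2 + response_noise_sd^2)` (~0.95 at the
#' defaults). Every non-planted gene carries only probe noise (i.i.d. normal
#' across samples), so all non-planted pairs are exactly null and their
#' correlation test statistics are exactly calibrated: the measured FDP
#' reflects the multiple-testing procedure itself.
#'
#' The number of planted genes balances two finite-sample artifacts at a
#' dozen samples. Many distinct binary-event genes collide: two independent
#' 13-sample gain patterns coincide (or complement) with probability
#' ~2.4e-4, and a colliding nominally-null gene genuinely correlates with
#' another gene's planted drugs, biasing the measured FDP upward. A single
#' planted gene avoids collisions but makes the false-discovery count heavy
#' tailed, because one noise gene whose sample correlation with the lone gain
#' pattern lands in the far tail sweeps in all planted drugs at once. A
#' handful of planted genes keeps the collision bias negligible while capping
#' such clusters at `n_planted / n_planted_genes` pairs.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param seed root seed; cohort i uses `seed * 1000 + i`.
#' @param n_samples,n_genes,n_drugs cohort dimensions.
#' @param n_planted number of planted gene-drug pairs.
#' @param n_planted_genes number of distinct genes carrying the planted
#'   pairs (must divide `n_planted`).
#' @param slope planted effect, cytotoxicity-% per copy.
#' @param response_noise_sd response noise SD (%); the default 3.3 targets
#'   planted |r| of about 0.95.
#' @param fdr_threshold BH level (default 0.1).
#' @return data.frame with one row per cohort: `seed`, `n_discoveries`,
#'   `n_false`, `fdp`, `sensitivity`, `n_pairs`.
#' @export
#' @examples
#' fdr_benchmark(n_cohorts = 2, seed = 1, n_genes = 30, n_drugs = 40)
fdr_benchmark <- function(n_cohorts = 20L, seed = 1L, n_samples = 13L,
                          n_genes = 131L, n_drugs = 418L, n_planted = 50L,
                          n_planted_genes = 5L, slope = 20,
                          response_noise_sd = 3.3, fdr_threshold = 0.1) {
  if (n_planted %% n_planted_genes != 0L) {
    stop("n_planted_genes must divide n_planted")
  }
  panel <- independent_gene_panel(n_genes)
  lib <- default_drug_library(n_drugs, panel)
  planted <- data.frame(
    gene_id = rep(panel$gene_id[seq_len(n_planted_genes)],
                  each = n_planted %/% n_planted_genes),
    drug_id = lib$compound_id[seq_len(n_planted)],
    slope = slope, stringsAsFactors = FALSE)
  rates <- setNames(
    lapply(seq_len(n_planted_genes),
           function(i) list(event = "gain", probability = 0.5)),
    panel$arm_id[seq_len(n_planted_genes)])
  pkey <- paste(planted$gene_id, planted$drug_id)
  scfg <- screen_config(fdr_threshold = fdr_threshold)
  rows <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cfg <- cohort_config(
      n_samples = n_samples, panel = panel, arm_event_rates = rates,
      focal_amp = NULL, probe_noise_sd = 0.05, drug_library = lib,
      planted_pairs = planted, response_noise_sd = response_noise_sd,
      seed = seed * 1000L + i)
    cohort <- simulate_cohort(cfg)
    profile <- segment_probes_to_genes(cohort$probe_log2, panel)
    cyto <- build_cytotoxicity_matrix(cohort$plates, lib)
    screen <- run_screen(profile, cyto, scfg)
    tab <- screen$table
    key <- paste(tab$gene_id, tab$drug_id)
    sig <- tab$significant
    n_disc <- sum(sig)
    n_false <- sum(sig & !(key %in% pkey))
    rows[[i]] <- data.frame(
      seed = cfg$seed,
      n_discoveries = n_disc,
      n_false = n_false,
      fdp = if (n_disc > 0L) n_false / n_disc else 0,
      sensitivity = sum(sig & key %in% pkey) / nrow(planted),
      n_pairs = nrow(tab))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
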