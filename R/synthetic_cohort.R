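#' Configure a synthetic cohort
#'
#' Defines the study conditions for a simulated tumor cohort: cohort size,
#' gene panel, arm-level copy-number event rates, focal amplification of a
#' single oncogene, planted gene-drug effects, screening-plate behaviour, and
#' the somatic mutation rate. Defaults follow the prevalences reported for
#' high-risk neuroblastoma cohorts: 13 samples, 1p loss in 31%, 11q loss in
#' 38%, 17q gain in 69%, focal MYCN amplification (10-40 copies) in 23%, a
#' 418-compound library, and a mean of 3.1 somatic variants per case.
#'
#' `baseline_potency` (mean 16.7, sd 16.8, in % cytotoxicity) is calibrated so
#' that about 84% of compounds show positive mean cytotoxicity and about 17%
#' exceed the 33% hit threshold, matching the marginal behaviour of a
#' single-dose 1 uM kinase-inhibitor screen.
#'
#' @param n_samples number of tumors/cultures.
#' @param panel gene panel (see [default_gene_panel()]).
#' @param arm_event_rates named list: arm id -> `list(event, probability)`
#'   where event is `"loss"` or `"gain"`.
#' @param focal_amp `list(gene, probability, copy_range)` focal amplification;
#'   overrides (does not add to) arm events for that gene.
#' @param probe_noise_sd per-probe log2-ratio noise SD.
#' @param drug_library compound library (see [default_drug_library()]).
#' @param planted_pairs data.frame `gene_id`, `drug_id`, `slope` — slope in
#'   cytotoxicity-% per copy above diploid.
#' @param baseline_potency `c(mean, sd)` of per-drug baseline cytotoxicity (%).
#' @param response_noise_sd per-well cytotoxicity noise SD (%).
#' @param mutation_rate Poisson mean of somatic variants per sample.
#' @param snp_fraction fraction of variant records flagged as recurrent
#'   population SNPs.
#' @param filter_fail_rates named numeric: per-criterion probability that a
#'   variant record is drawn to fail that filter (`coverage`, `af`, `cosmic`,
#'   `popfreq`).
#' @param rlu_scale luminescence units corresponding to untreated viability.
#' @param dmso_cv relative SD of the DMSO control wells.
#' @param n_dmso_wells,n_staurosporine_wells control wells per plate.
#' @param seed root seed; per-component streams are derived from it with
#'   fixed labels, so e.g. enlarging the drug library never perturbs the
#'   copy-number draws.
#' @return object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$true_copies)
cohort_config <- function(n_samples = 13L,
                          panel = default_gene_panel(),
                          arm_event_rates = list(
                            "1p"  = list(event = "loss", probability = 0.31),
                            "11q" = list(event = "loss", probability = 0.38),
                            "17q" = list(event = "gain", probability = 0.69)
                          ),
                          focal_amp = list(gene = "MYCN", probability = 0.23,
                                           copy_range = c(10, 40)),
                          probe_noise_sd = 0.1,
                          drug_library = default_drug_library(panel = panel),
                          planted_pairs = NULL,
                          baseline_potency = c(mean = 16.7, sd = 16.8),
                          response_noise_sd = 10,
                          mutation_rate = 3.1,
                          snp_fraction = 0.38,
                          filter_fail_rates = c(coverage = 0.15, af = 0.1,
                                                cosmic = 0.2, popfreq = 0.1),
                          rlu_scale = 1e6,
                          dmso_cv = 0.02,
                          n_dmso_wells = 8L,
                          n_staurosporine_wells = 4L,
                          seed = 1L) {
  validate_gene_panel(panel)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  probs <- vapply(arm_event_rates, function(a) a$probability, 0)
  if (any(probs < 0 | probs > 1)) stop("arm event probabilities must lie in [0, 1]")
  events <- vapply(arm_event_rates, function(a) a$event, "")
  if (!all(events %in% c("loss", "gain"))) stop("arm events must be 'loss' or 'gain'")
  unknown_arms <- setdiff(names(arm_event_rates), panel$arm_id)
  if (length(unknown_arms)) {
    stop("arm_event_rates reference arms absent from the panel: ",
         paste(unknown_arms, collapse = ", "))
  }
  if (!is.null(focal_amp)) {
    if (!focal_amp$gene %in% panel$gene_id) {
      stop("focal_amp gene not in panel: ", focal_amp$gene)
    }
    if (focal_amp$probability < 0 || focal_amp$probability > 1) {
      stop("focal_amp probability must lie in [0, 1]")
    }
  }
  if (probe_noise_sd < 0 || response_noise_sd < 0) stop("noise SDs must be >= 0")
  if (mutation_rate < 0) stop("mutation_rate must be >= 0")
  if (!is.null(planted_pairs)) {
    bad_gene <- setdiff(planted_pairs$gene_id, panel$gene_id)
    if (length(bad_gene)) stop("planted pair references unknown gene: ",
                               paste(bad_gene, collapse = ", "))
    bad_drug <- setdiff(planted_pairs$drug_id, drug_library$compound_id)
    if (length(bad_drug)) stop("planted pair references unknown drug: ",
                               paste(bad_drug, collapse = ", "))
  }
  structure(list(
    n_samples = as.integer(n_samples), panel = panel,
    arm_event_rates = arm_event_rates, focal_amp = focal_amp,
    probe_noise_sd = probe_noise_sd, drug_library = drug_library,
    planted_pairs = planted_pairs, baseline_potency = baseline_potency,
    response_noise_sd = response_noise_sd, mutation_rate = mutation_rate,
    snp_fraction = snp_fraction, filter_fail_rates = filter_fail_rates,
    rlu_scale = rlu_scale, dmso_cv = dmso_cv,
    n_dmso_wells = as.integer(n_dmso_wells),
    n_staurosporine_wells = as.integer(n_staurosporine_wells),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

sample_ids <- function(config) sprintf("S%02d", seq_len(config$n_samples))

#' Generate true copies and probe-level log2 ratios
#'
#' Samples arm-level events (all-or-none per arm), applies the focal
#' amplification override, and emits per-probe log2 ratios
#' `log2(copies / 2) + N(0, probe_noise_sd)`. Copies are clipped at zero;
#' the diploid baseline is 2.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of the derived copy-number stream seed.
#' @return list with `true_copies` (gene x sample), `probe_log2` (data.frame:
#'   probe_id, gene, chrom, arm plus one column per sample) and `arm_events`
#'   (data.frame sample_id, arm_id, event).
#' @export
generate_copy_number <- function(config, seed = child_seed(config$seed, "cnv")) {
  panel <- config$panel
  samples <- sample_ids(config)
  with_seed(seed, {
    copies <- matrix(2, nrow = nrow(panel), ncol = length(samples),
                     dimnames = list(panel$gene_id, samples))
    ev_list <- list()
    for (arm in names(config$arm_event_rates)) {
      spec <- config$arm_event_rates[[arm]]
      hit <- stats::rbinom(length(samples), 1L, spec$probability) == 1L
      if (any(hit)) {
        shift <- if (spec$event == "loss") -1 else 1
        rows <- panel$arm_id == arm
        copies[rows, hit] <- copies[rows, hit] + shift
        ev_list[[arm]] <- data.frame(sample_id = samples[hit], arm_id = arm,
                                     event = spec$event, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(config$focal_amp)) {
      fa <- config$focal_amp
      amp <- stats::rbinom(length(samples), 1L, fa$probability) == 1L
      if (any(amp)) {
        copies[fa$gene, amp] <- stats::runif(sum(amp), fa$copy_range[1],
                                             fa$copy_range[2])
        ev_list[["focal"]] <- data.frame(sample_id = samples[amp],
                                         arm_id = paste0("focal:", fa$gene),
                                         event = "amplification",
                                         stringsAsFactors = FALSE)
      }
    }
    copies <- pmax(copies, 0)
    arm_events <- if (length(ev_list)) do.call(rbind, ev_list) else
      data.frame(sample_id = character(), arm_id = character(),
                 event = character(), stringsAsFactors = FALSE)
    rownames(arm_events) <- NULL

    gene_rows <- rep(seq_len(nrow(panel)), panel$n_probes)
    probe_ids <- sprintf("P%04d", seq_along(gene_rows))
    # floor protects log2 against a (pathological) homozygous loss to 0 copies
    base <- log2(pmax(copies[gene_rows, , drop = FALSE], 0.05) / 2)
    noise <- matrix(stats::rnorm(length(base), 0, config$probe_noise_sd),
                    nrow = nrow(base))
    probe_log2 <- data.frame(
      probe_id = probe_ids,
      gene = panel$gene_id[gene_rows],
      chrom = panel$chrom[gene_rows],
      arm = panel$arm[gene_rows],
      stringsAsFactors = FALSE
    )
    probe_log2 <- cbind(probe_log2,
                        as.data.frame(base + noise, optional = TRUE))
    names(probe_log2)[-(1:4)] <- samples
    rownames(probe_log2) <- NULL
    list(true_copies = copies, probe_log2 = probe_log2, arm_events = arm_events)
  })
}

#' Generate drug-screen plate readings
#'
#' Latent cytotoxicity for drug d in sample s is
#' `baseline(d) + sum(slope * (copies(g, s) - 2)) + N(0, response_noise_sd)`,
#' clipped to `[-20, 100]` (mild growth stimulation is allowed; a minority of
#' compounds show negative cytotoxicity). Readings are emitted as one plate
#' per sample: `RLU = rlu_scale * (1 - cytotoxicity / 100)` for compound
#' wells, DMSO wells near `rlu_scale`, and staurosporine wells near zero
#' (around 95% kill).
#'
#' @param true_copies gene x sample copy matrix.
#' @param config a [cohort_config()] (supplies the drug library and noise).
#' @param seed optional override of the derived drug-response stream seed.
#' @return list with `plates` (long data.frame: plate_id, sample_id, well,
#'   compound_id, rlu) and `latent` (drug x sample latent cytotoxicity, after
#'   clipping, before plate normalization).
#' @export
generate_drug_response <- function(true_copies, config,
                                   seed = child_seed(config$seed, "drug")) {
  lib <- config$drug_library
  samples <- colnames(true_copies)
  n_d <- nrow(lib); n_s <- length(samples)
  planted <- config$planted_pairs
  if (!is.null(planted)) {
    bad <- setdiff(planted$drug_id, lib$compound_id)
    if (length(bad)) stop("planted pair references unknown drug: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(planted$gene_id, rownames(true_copies))
    if (length(bad)) stop("planted pair references unknown gene: ",
                          paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    baseline <- stats::rnorm(n_d, config$baseline_potency[["mean"]],
                             config$baseline_potency[["sd"]])
    latent <- matrix(baseline, nrow = n_d, ncol = n_s,
                     dimnames = list(lib$compound_id, samples))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        d <- planted$drug_id[i]; g <- planted$gene_id[i]
        latent[d, ] <- latent[d, ] + planted$slope[i] * (true_copies[g, ] - 2)
      }
    }
    latent <- latent + matrix(stats::rnorm(n_d * n_s, 0, config$response_noise_sd),
                              nrow = n_d)
    latent <- pmin(pmax(latent, -20), 100)

    plates <- vector("list", n_s)
    for (j in seq_len(n_s)) {
      dmso <- config$rlu_scale *
        (1 + stats::rnorm(config$n_dmso_wells, 0, config$dmso_cv))
      stauro_kill <- pmin(stats::rnorm(config$n_staurosporine_wells, 95.7, 2), 100)
      stauro <- config$rlu_scale * (1 - stauro_kill / 100)
      comp <- config$rlu_scale * (1 - latent[, j] / 100)
      plates[[j]] <- data.frame(
        plate_id = paste0("PLATE_", samples[j]),
        sample_id = samples[j],
        well = sprintf("W%03d", seq_len(n_d + length(dmso) + length(stauro))),
        compound_id = c(lib$compound_id,
                        rep("DMSO", length(dmso)),
                        rep("STAUROSPORINE", length(stauro))),
        rlu = pmax(c(comp, dmso, stauro), 0),
        stringsAsFactors = FALSE
      )
    }
    list(plates = do.call(rbind, plates), latent = latent)
  })
}

#' Generate sparse somatic variant records
#'
#' Draws Poisson(`mutation_rate`) variants per sample over the panel genes.
#' Each record carries coverage, allele fraction, a COSMIC flag and a
#' population frequency; `filter_fail_rates` sets the probability that a
#' record is drawn on the failing side of each downstream filter criterion,
#' and `snp_fraction` flags recurrent population SNPs.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of the derived variant stream seed.
#' @return data.frame with one row per variant: sample_id, gene_id, chrom,
#'   pos, ref, alt, coverage, allele_fraction, cosmic_reported,
#'   population_frequency, is_population_snp.
#' @export
generate_variants <- function(config, seed = child_seed(config$seed, "variants")) {
  panel <- config$panel
  samples <- sample_ids(config)
  fr <- config$filter_fail_rates
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_per_sample <- stats::rpois(length(samples), config$mutation_rate)
    n <- sum(n_per_sample)
    if (n == 0L) {
      return(data.frame(sample_id = character(), gene_id = character(),
                        chrom = character(), pos = integer(), ref = character(),
                        alt = character(), coverage = integer(),
                        allele_fraction = numeric(), cosmic_reported = logical(),
                        population_frequency = numeric(),
                        is_population_snp = logical(), stringsAsFactors = FALSE))
    }
    gi <- sample.int(nrow(panel), n, replace = TRUE)
    fail_cov <- stats::runif(n) < fr[["coverage"]]
    fail_af <- stats::runif(n) < fr[["af"]]
    fail_cos <- stats::runif(n) < fr[["cosmic"]]
    fail_pop <- stats::runif(n) < fr[["popfreq"]]
    ref <- bases[sample.int(4L, n, replace = TRUE)]
    alt_shift <- sample.int(3L, n, replace = TRUE)
    alt <- bases[((match(ref, bases) - 1L + alt_shift) %% 4L) + 1L]
    out <- data.frame(
      sample_id = rep(samples, n_per_sample),
      gene_id = panel$gene_id[gi],
      chrom = panel$chrom[gi],
      pos = gi * 100000L + sample.int(99999L, n, replace = TRUE),
      ref = ref,
      alt = alt,
      coverage = ifelse(fail_cov,
                        as.integer(round(stats::runif(n, 20, 100))),
                        as.integer(round(stats::runif(n, 101, 1500)))),
      allele_fraction = ifelse(fail_af, stats::runif(n, 0.01, 0.0999),
                               stats::runif(n, 0.10, 0.95)),
      cosmic_reported = !fail_cos,
      population_frequency = ifelse(fail_pop, stats::runif(n, 0.01, 0.20),
                                    stats::runif(n, 0, 0.0099)),
      is_population_snp = stats::runif(n) < config$snp_fraction,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the copy-number, drug-response and variant generators under their
#' derived seed streams and assembles the ground truth used by downstream
#' power and FDR evaluations. The same configuration and seed always produce
#' a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: the generator outputs plus a
#'   `truth` element holding planted pairs, the count of null pairs, and arm
#'   events.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cn <- generate_copy_number(config)
  dr <- generate_drug_response(cn$true_copies, config)
  variants <- generate_variants(config)
  planted <- config$planted_pairs
  n_pairs <- nrow(config$panel) * nrow(config$drug_library)
  n_planted <- if (is.null(planted)) 0L else nrow(unique(planted[c("gene_id", "drug_id")]))
  structure(list(
    config = config,
    panel = config$panel,
    drug_library = config$drug_library,
    true_copies = cn$true_copies,
    probe_log2 = cn$probe_log2,
    arm_events = cn$arm_events,
    plates = dr$plates,
    latent_cytotoxicity = dr$latent,
    variants = variants,
    truth = list(planted_pairs = planted,
                 n_pairs = n_pairs,
                 n_null_pairs = n_pairs - n_planted,
                 arm_events = cn$arm_events)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$true_copies), "samples,",
      nrow(x$panel), "genes (", nrow(x$probe_log2), "probes ),",
      nrow(x$drug_library), "drugs\n")
  cat("  arm events:", nrow(x$arm_events),
      "| variants:", nrow(x$variants),
      "| planted pairs:", x$truth$n_pairs - x$truth$n_null_pairs, "\n")
  invisible(x)
}
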