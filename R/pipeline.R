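#' Hierarchical clustering order for heatmaps
#'
#' Agglomerative clustering with complete linkage on Euclidean distance by
#' default, applied to rows and columns. `hclust`'s merge order is
#' deterministic (ties resolve by original index), so the serialized
#' orderings make heatmaps reproducible.
#'
#' @param m finite numeric matrix.
#' @param linkage agglomeration method (default `"complete"`).
#' @param metric distance metric (default `"euclidean"`).
#' @return list with `row_order`, `col_order` (integer permutations) and the
#'   two `hclust` trees.
#' @export
hierarchical_cluster_order <- function(m, linkage = "complete",
                                       metric = "euclidean") {
  m <- as.matrix(m)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop("non-finite entries at [row,col]: ",
         paste(apply(utils::head(bad, 5L), 1L,
                     function(rc) paste0("[", rc[1], ",", rc[2], "]")),
               collapse = " "))
  }
  tree_or_trivial <- function(mm) {
    if (nrow(mm) < 2L) return(NULL)
    stats::hclust(stats::dist(mm, method = metric), method = linkage)
  }
  row_tree <- tree_or_trivial(m)
  col_tree <- tree_or_trivial(t(m))
  list(row_order = if (is.null(row_tree)) seq_len(nrow(m)) else row_tree$order,
       col_order = if (is.null(col_tree)) seq_len(ncol(m)) else col_tree$order,
       row_tree = row_tree, col_tree = col_tree)
}

#' Run the full pipeline
#'
#' Executes simulate -> profile -> screen -> associate -> network, writing
#' each stage's outputs to `out_dir` before the next stage reads them back
#' (so ingest-mode reruns on the serialized outputs reproduce the same
#' results), and finishes with a JSON run manifest recording the
#' configuration, seeds, stage counts and file digests. Two runs with the
#' same configuration and seed produce byte-identical manifests.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param screen_cfg a [screen_config()].
#' @param hit_cfg a [hit_call_config()].
#' @param coupling_scale MRF edge-potential scale.
#' @param n_permutations MRF permutation replicates.
#' @param fi_within_p,fi_between_p synthetic FI network block densities.
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the in-memory stage results and the manifest.
#' @export
run_all <- function(config, out_dir,
                    screen_cfg = screen_config(),
                    hit_cfg = hit_call_config(),
                    coupling_scale = 1,
                    n_permutations = 100L,
                    fi_within_p = 0.5, fi_between_p = 0.02,
                    quiet = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cnassoc] ", ...)
  pth <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  say("simulate: ", config$n_samples, " samples, ", nrow(config$panel),
      " genes, ", nrow(config$drug_library), " drugs (seed ", config$seed, ")")
  cohort <- stage("simulate", simulate_cohort(config))
  stage("simulate", {
    write_probe_tsv(cohort$probe_log2, pth("probes.tsv"))
    write_plate_csv(cohort$plates, pth("plates.csv"))
    write_variants_vcf(cohort$variants, pth("variants.vcf"))
    write_drug_library_tsv(cohort$drug_library, pth("drug_library.tsv"))
    if (!is.null(cohort$truth$planted_pairs)) {
      write_tsv_impl(cohort$truth$planted_pairs, pth("planted_pairs.tsv"))
    }
  })

  say("profile: probe segmentation and variant filtering")
  profile <- stage("profile", {
    probes <- read_probe_tsv(pth("probes.tsv"))
    segment_probes_to_genes(probes, config$panel)
  })
  variant_report <- stage("profile", {
    vcf <- read_variants_vcf(pth("variants.vcf"))
    snp <- exclude_population_snps(vcf)
    filt <- filter_somatic_variants(snp$remaining)
    write_matrix_tsv(profile$log2_ratio, pth("gene_log2.tsv"))
    report <- rbind(
      if (nrow(filt$passing)) cbind(filt$passing, status = "pass", reasons = ""),
      if (nrow(filt$rejected)) cbind(filt$rejected[names(filt$passing)],
                                     status = "reject",
                                     reasons = filt$rejected$reasons),
      if (nrow(snp$excluded)) cbind(snp$excluded, status = "population_snp",
                                    reasons = "is_population_snp")
    )
    write_tsv_impl(report, pth("variant_filter_report.tsv"))
    list(n_candidates = nrow(vcf), n_snp_excluded = nrow(snp$excluded),
         n_pass = nrow(filt$passing), n_reject = nrow(filt$rejected))
  })

  say("screen: plate normalization, QC, hit calling")
  cyto <- stage("screen", {
    plates <- read_plate_csv(pth("plates.csv"))
    build_cytotoxicity_matrix(plates, config$drug_library, hit_cfg)
  })
  hits <- stage("screen", {
    h <- call_hits(cyto, hit_cfg)
    write_matrix_tsv(cyto$values, pth("cytotoxicity.tsv"), id_col = "drug_id")
    write_tsv_impl(h, pth("hits.tsv"))
    h
  })

  say("associate: all-pairs correlation screen at FDR ",
      screen_cfg$fdr_threshold)
  screen <- stage("associate", run_screen(profile, cyto, screen_cfg))
  expected <- expected_pairs_from_library(config$drug_library, config$panel)
  venn <- stage("associate", classify_against_expected(screen, expected))
  drug_means <- setNames(hits$mean_cytotoxicity, hits$drug_id)
  ranked <- stage("associate", rank_by_effect(venn$table, drug_means))
  stage("associate", {
    write_association_tsv(ranked, pth("associations.tsv"))
    write_manifest(as.list(venn$counts), pth("venn.json"))
  })

  say("network: MRF impact analysis (", n_permutations, " permutations)")
  fi <- stage("network", make_fi_network(config$panel, within_p = fi_within_p,
                                         between_p = fi_between_p,
                                         seed = child_seed(config$seed, "fi")))
  impact <- stage("network", mrf_impact_analysis(
    fi, profile, coupling_scale = coupling_scale,
    n_permutations = n_permutations,
    seed = child_seed(config$seed, "perm")))
  selected_genes <- impact$gene_id[impact$selected]
  pgm_net <- stage("network", overlay_drugs(
    igraph::induced_subgraph(fi, intersect(selected_genes,
                                           igraph::V(fi)$name)),
    data.frame(drug_id = expected$drug_id, gene_id = expected$gene_id,
               stringsAsFactors = FALSE)))
  z_net <- stage("network", build_zscore_network(screen, drug_means))
  stage("network", {
    write_tsv_impl(impact, pth("impact_scores.tsv"))
    write_edge_list_tsv(fi, pth("fi_network.tsv"))
    write_graphml(pgm_net, pth("pgm_network.graphml"))
    write_graphml(z_net, pth("zscore_network.graphml"))
  })

  manifest <- list(
    package = "cnassoc",
    version = as.character(utils::packageVersion("cnassoc")),
    seed = config$seed,
    config = list(
      n_samples = config$n_samples,
      n_genes = nrow(config$panel),
      n_drugs = nrow(config$drug_library),
      arm_event_rates = lapply(config$arm_event_rates, function(a)
        list(event = a$event, probability = a$probability)),
      probe_noise_sd = config$probe_noise_sd,
      response_noise_sd = config$response_noise_sd,
      mutation_rate = config$mutation_rate,
      fdr_threshold = screen_cfg$fdr_threshold,
      correlate_on = screen_cfg$use,
      hit_threshold = hit_cfg$hit_threshold,
      coupling_scale = coupling_scale,
      n_permutations = n_permutations
    ),
    counts = list(
      pairs_enumerated = nrow(screen$table),
      pairs_testable = screen$n_testable,
      pairs_undefined = screen$n_undefined,
      pairs_significant = sum(screen$table$significant),
      venn = as.list(venn$counts),
      hits = sum(hits$hit),
      plates_pass_qc = sum(cyto$qc$pass),
      variants = variant_report,
      genes_selected = length(selected_genes)
    ),
    file_digests = as.list(tools::md5sum(sort(list.files(out_dir,
                                                         full.names = TRUE))))
  )
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  write_manifest(manifest, pth("manifest.json"))
  say("done: ", sum(screen$table$significant), " significant pairs, ",
      sum(hits$hit), " hits, ", length(selected_genes), " impacted genes")
  invisible(list(cohort = cohort, profile = profile, cytotoxicity = cyto,
                 hits = hits, screen = screen, venn = venn, ranked = ranked,
                 impact = impact, fi_network = fi, pgm_network = pgm_net,
                 zscore_network = z_net, manifest = manifest,
                 out_dir = out_dir))
}
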