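#' Synthetic functional-interaction network over a gene panel
#'
#' Generates an undirected weighted gene-gene interaction graph as a
#' stochastic block model with chromosome arms as blocks: genes on the same
#' arm are densely connected, genes on different arms sparsely. Edge
#' confidence weights are uniform on `weight_range`. A stand-in for a curated
#' functional-interaction network; user-provided edge lists can be loaded
#' with [read_edge_list_tsv()].
#'
#' @param panel a gene panel.
#' @param within_p edge probability within an arm block.
#' @param between_p edge probability between blocks.
#' @param weight_range range of the uniform edge-weight draw.
#' @param seed RNG seed.
#' @return an undirected `igraph` with vertex names = gene ids and edge
#'   attribute `fi_weight`.
#' @export
make_fi_network <- function(panel, within_p = 0.5, between_p = 0.02,
                            weight_range = c(0.5, 1), seed = 1L) {
  validate_gene_panel(panel)
  n <- nrow(panel)
  with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same_arm <- panel$arm_id[idx[, 1]] == panel$arm_id[idx[, 2]]
    p <- ifelse(same_arm, within_p, between_p)
    keep <- stats::runif(nrow(idx)) < p
    edges <- data.frame(from = panel$gene_id[idx[keep, 1]],
                        to = panel$gene_id[idx[keep, 2]],
                        fi_weight = stats::runif(sum(keep), weight_range[1],
                                                 weight_range[2]),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = panel$gene_id))
    g
  })
}

validate_fi_network <- function(network) {
  if (!igraph::is_igraph(network)) stop("network must be an igraph object")
  if (igraph::is_directed(network)) stop("the FI network must be undirected")
  if (any(igraph::which_loop(network))) stop("the FI network must have no self-loops")
  if (any(igraph::which_multiple(network))) stop("the FI network must be a simple graph")
  w <- igraph::E(network)$fi_weight
  if (is.null(w)) stop("the FI network needs an fi_weight edge attribute")
  if (any(!is.finite(w) | w <= 0)) stop("fi_weight values must be finite and positive")
  invisible(network)
}

# Per-gene rank-based normal scores across samples (the "empirical
# distribution" observation link). Ties get average ranks, so a constant row
# maps to all-zero scores.
rank_normal_scores <- function(x) {
  n <- ncol(x)
  t(apply(x, 1L, function(row) stats::qnorm((rank(row, ties.method = "average") - 0.5) / n)))
}

#' Build a Gaussian pairwise MRF over an FI network
#'
#' Hidden per-gene activity carries a standard-normal prior; each observed
#' gene contributes a Gaussian observation of its activity, where the
#' observation is the rank-based normal score of the gene's copy-number value
#' across samples (continuous, never discretized); each FI edge contributes a
#' pairwise potential penalizing `(a_g - a_h)^2` with precision
#' `coupling_scale * fi_weight`. The posterior is jointly Gaussian, so
#' inference is an exact linear solve. Genes in the network but absent from
#' the profile enter as unobserved nodes; genes with a constant profile row
#' (no CNV) are recorded for later removal from impact-score selection.
#'
#' @param network an FI network (igraph with `fi_weight`).
#' @param cnv_profile a `copy_number_profile` or bare gene x sample matrix.
#' @param coupling_scale scales all edge potentials; 0 decouples the genes.
#' @param obs_noise_sd observation noise SD (default 1).
#' @return object of class `cnv_mrf`: precision matrix `J`, information
#'   vectors `h` (genes x samples), node order `genes`, `observed` flags,
#'   `no_cnv_genes`, and the inputs.
#' @export
build_mrf <- function(network, cnv_profile, coupling_scale = 1,
                      obs_noise_sd = 1) {
  validate_fi_network(network)
  if (coupling_scale < 0) stop("coupling_scale must be >= 0")
  x <- if (inherits(cnv_profile, "copy_number_profile")) cnv_profile$log2_ratio
       else as.matrix(cnv_profile)
  genes <- igraph::V(network)$name
  shared <- intersect(genes, rownames(x))
  if (!length(shared)) stop("no genes shared between the network and the profile")
  samples <- colnames(x)
  scores <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  scores[shared, ] <- rank_normal_scores(x[shared, , drop = FALSE])
  observed <- genes %in% shared
  no_cnv <- shared[apply(x[shared, , drop = FALSE], 1L,
                         function(r) stats::sd(r) == 0)]

  L <- as.matrix(igraph::laplacian_matrix(network, weights = igraph::E(network)$fi_weight))
  L <- L[genes, genes, drop = FALSE]
  tau <- 1 / obs_noise_sd^2
  J <- coupling_scale * L
  diag(J) <- diag(J) + 1 + observed * tau
  h <- scores * tau
  h[!observed, ] <- 0
  structure(list(J = J, h = h, genes = genes, samples = samples,
                 observed = observed, no_cnv_genes = no_cnv,
                 coupling_scale = coupling_scale, obs_noise_sd = obs_noise_sd,
                 network = network),
            class = "cnv_mrf")
}

#' Exact posterior-mean inference for the Gaussian MRF
#'
#' Returns the posterior mean of the hidden activities — the per-gene impact
#' score — for one sample or for all samples at once (a linear solve against
#' the fixed posterior precision; exact on any graph). A sample whose
#' observations are all zero yields all-zero impacts.
#'
#' @param model a `cnv_mrf`.
#' @param sample sample id or index; `NULL` (default) returns the full
#'   genes x samples impact matrix.
#' @return numeric vector (one sample) or matrix (all samples).
#' @export
infer_impact <- function(model, sample = NULL) {
  stopifnot(inherits(model, "cnv_mrf"))
  rhs <- if (is.null(sample)) model$h else model$h[, sample, drop = FALSE]
  out <- tryCatch(solve(model$J, rhs),
                  error = function(e) stop("degenerate MRF system: ",
                                           conditionMessage(e)))
  rownames(out) <- model$genes
  if (!is.null(sample) && length(sample) == 1L) out[, 1L] else out
}

#' Per-gene impact summary of an MRF
#'
#' Summarizes each gene's inferred activity across samples as the mean
#' absolute posterior activity. The signed per-sample posterior mean is linear
#' in the observations, so its across-sample average is invariant under any
#' within-gene relabeling of samples; the magnitude summary instead responds
#' to the cross-gene alignment that the permutation null destroys, which is
#' what the real-versus-permuted comparison is meant to detect.
#'
#' @param model a `cnv_mrf`.
#' @return named numeric vector, one value per gene.
#' @export
impact_scores <- function(model) {
  imp <- infer_impact(model)
  setNames(rowMeans(abs(imp)), model$genes)
}

#' Permutation null for MRF impact scores
#'
#' Each replicate independently permutes sample labels within every gene's
#' observation row (preserving each gene's marginal score distribution while
#' destroying gene-sample linkage), re-infers impacts, and records the
#' per-gene mean absolute activity. Returns the per-gene mean over
#' replicates. Deterministic at a fixed seed.
#'
#' @param model a `cnv_mrf`.
#' @param n_permutations number of permutation replicates (default 100).
#' @param seed RNG seed for the permutation stream.
#' @return named numeric vector of permuted mean impact per gene.
#' @export
permutation_null <- function(model, n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(model, "cnv_mrf"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  n_s <- length(model$samples)
  obs_idx <- which(model$observed)
  # factor once; every replicate reuses the same posterior precision
  ch <- chol(model$J)
  acc <- numeric(length(model$genes))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      h <- model$h
      for (i in obs_idx) h[i, ] <- h[i, sample.int(n_s)]
      imp <- backsolve(ch, forwardsolve(t(ch), h))
      acc <- acc + rowMeans(abs(imp))
    }
  })
  setNames(acc / n_permutations, model$genes)
}

#' Select impacted genes by real-versus-permuted difference
#'
#' A gene is selected when the difference between its real and permuted mean
#' impact score lies strictly outside `[-0.01, 0.01]` (both inequalities
#' strict). Genes with no CNV (constant profile row) are removed before the
#' comparison.
#'
#' @param real named vector of real mean impact scores.
#' @param permuted named vector of permuted mean impact scores.
#' @param thresholds length-2 numeric `(lower, upper)`.
#' @param no_cnv_genes genes to remove before selection.
#' @return data.frame `gene_id`, `real_mean`, `perm_mean`, `diff`, `selected`.
#' @export
select_impacted_genes <- function(real, permuted,
                                  thresholds = c(-0.01, 0.01),
                                  no_cnv_genes = character()) {
  genes <- intersect(names(real), names(permuted))
  genes <- setdiff(genes, no_cnv_genes)
  d <- real[genes] - permuted[genes]
  data.frame(gene_id = genes,
             real_mean = as.numeric(real[genes]),
             perm_mean = as.numeric(permuted[genes]),
             diff = as.numeric(d),
             selected = as.numeric(d) < thresholds[1] | as.numeric(d) > thresholds[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full MRF impact analysis
#'
#' Builds the MRF, infers real impact scores, runs the permutation null, and
#' selects impacted genes. Deterministic given the inputs and seed.
#'
#' @param network FI network.
#' @param cnv_profile copy-number profile.
#' @param coupling_scale edge-potential scale (default 1).
#' @param n_permutations permutation replicates (default 100).
#' @param seed RNG seed for the permutation stream.
#' @param thresholds selection thresholds (default `c(-0.01, 0.01)`).
#' @return the [select_impacted_genes()] data.frame; the fitted model is
#'   attached as attribute `"model"`.
#' @export
mrf_impact_analysis <- function(network, cnv_profile, coupling_scale = 1,
                                n_permutations = 100L, seed = 1L,
                                thresholds = c(-0.01, 0.01)) {
  model <- build_mrf(network, cnv_profile, coupling_scale)
  real <- impact_scores(model)
  perm <- permutation_null(model, n_permutations, seed)
  out <- select_impacted_genes(real, perm, thresholds, model$no_cnv_genes)
  attr(out, "model") <- model
  out
}

#' Overlay drugs onto a selected gene set
#'
#' Bipartite augmentation: each drug is linked to its annotated target genes
#' that are in the selected set; drugs with no selected target are omitted.
#'
#' @param gene_network an igraph of genes (e.g. the FI subgraph of selected
#'   genes) or a character vector of selected gene ids.
#' @param drug_targets data.frame `drug_id`, `gene_id` target annotation.
#' @return igraph with a vertex attribute `type` (`"gene"`/`"drug"`).
#' @export
overlay_drugs <- function(gene_network, drug_targets) {
  if (igraph::is_igraph(gene_network)) {
    genes <- igraph::V(gene_network)$name
    gene_edges <- igraph::as_data_frame(gene_network, what = "edges")
  } else {
    genes <- as.character(gene_network)
    gene_edges <- data.frame(from = character(), to = character(),
                             stringsAsFactors = FALSE)
  }
  hits <- drug_targets[drug_targets$gene_id %in% genes, , drop = FALSE]
  drug_edges <- data.frame(from = hits$drug_id, to = hits$gene_id,
                           stringsAsFactors = FALSE)
  drugs <- unique(hits$drug_id)
  verts <- data.frame(name = c(genes, drugs),
                      type = c(rep("gene", length(genes)),
                               rep("drug", length(drugs))),
                      stringsAsFactors = FALSE)
  edges <- merge_edge_frames(gene_edges, drug_edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

merge_edge_frames <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- if (nrow(a)) NA else logical(0)
  for (cn in setdiff(cols, names(b))) b[[cn]] <- if (nrow(b)) NA else logical(0)
  rbind(a[cols], b[cols])
}

#' z-score-weighted gene-drug network
#'
#' One edge per significant gene-drug pair, weighted by the pair's Fisher z;
#' drug vertices carry their mean cytotoxicity as an attribute.
#'
#' @param screen a `gene_drug_screen` or its table (needs `significant`, `z`).
#' @param drug_means named numeric vector of per-drug mean cytotoxicity.
#' @return igraph with vertex attributes `type` and `mean_cytotoxicity`, and
#'   edge attribute `z`.
#' @export
build_zscore_network <- function(screen, drug_means) {
  tab <- if (inherits(screen, "gene_drug_screen")) screen$table else screen
  sig <- tab[tab$significant, , drop = FALSE]
  genes <- unique(sig$gene_id)
  drugs <- unique(sig$drug_id)
  verts <- data.frame(
    name = c(genes, drugs),
    type = c(rep("gene", length(genes)), rep("drug", length(drugs))),
    mean_cytotoxicity = c(rep(NA_real_, length(genes)),
                          as.numeric(drug_means[drugs])),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = sig$gene_id, to = sig$drug_id, z = sig$z,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Deterministic modularity clustering of a network
#'
#' Greedy modularity community detection (seedless and deterministic for a
#' fixed vertex order), using `fi_weight` edge weights when present, else
#' `abs(z)`, else unweighted. Module ids are assigned by decreasing module
#' size, ties broken by the lexicographically smallest member (the module
#' anchor). Optionally tests each module's gene set for hypergeometric
#' enrichment against supplied gene sets, BH-corrected.
#'
#' @param network an igraph.
#' @param gene_sets optional named list of gene-id vectors for enrichment.
#' @param enrich_fdr BH threshold for reported enrichments (default 0.1).
#' @return list with `membership` (named integer), `modules` (data.frame
#'   module, size, anchor) and `enrichment` (data.frame or NULL).
#' @export
cluster_subnetworks <- function(network, gene_sets = NULL, enrich_fdr = 0.1) {
  if (igraph::vcount(network) == 0L) stop("network is empty")
  w <- igraph::E(network)$fi_weight
  if (is.null(w)) {
    z <- igraph::E(network)$z
    if (!is.null(z)) w <- abs(z)
  }
  comm <- igraph::cluster_fast_greedy(network, weights = w)
  # pick the cut with maximal modularity, ties broken toward fewer modules
  mods <- comm$modularity
  best_step <- max(which(mods >= max(mods) - 1e-12)) - 1L
  memb <- igraph::cut_at(comm, steps = best_step)
  names(memb) <- igraph::V(network)$name
  # reorder module ids: size desc, then lexicographic anchor
  anchors <- tapply(names(memb), memb, function(v) sort(v)[1L])
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), anchors)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  memb <- setNames(as.integer(relabel[as.character(memb)]), names(memb))
  modules <- data.frame(module = seq_along(ord),
                        size = as.integer(sizes[ord]),
                        anchor = unname(anchors[ord]),
                        stringsAsFactors = FALSE)
  enrichment <- NULL
  if (!is.null(gene_sets)) {
    types <- igraph::V(network)$type
    universe <- if (is.null(types)) names(memb) else names(memb)[types == "gene"]
    rows <- list()
    for (m in modules$module) {
      mod_genes <- intersect(names(memb)[memb == m], universe)
      for (s in names(gene_sets)) {
        set_genes <- intersect(gene_sets[[s]], universe)
        k <- length(intersect(mod_genes, set_genes))
        p <- stats::phyper(k - 1L, length(set_genes),
                           length(universe) - length(set_genes),
                           length(mod_genes), lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, gene_set = s, overlap = k, p = p,
          stringsAsFactors = FALSE)
      }
    }
    enrichment <- do.call(rbind, rows)
    if (!is.null(enrichment) && nrow(enrichment)) {
      enrichment$q <- stats::p.adjust(enrichment$p, method = "BH")
      enrichment$significant <- enrichment$q <= enrich_fdr
    }
  }
  list(membership = memb, modules = modules, enrichment = enrichment)
}

#' Compare drug neighborhoods between two networks
#'
#' For each focus drug, reports its first-degree gene neighbors in each
#' network, their intersection, and the Jaccard index. Drugs absent from both
#' networks are skipped with a warning.
#'
#' @param net_a,net_b igraphs sharing a node id space (e.g. the MRF-derived
#'   drug overlay and the z-score-weighted network).
#' @param focus_drugs character vector of drug ids.
#' @return list with `summary` (data.frame drug_id, n_a, n_b, n_intersect,
#'   jaccard) and `neighbors` (per-drug list of the two gene sets).
#' @export
compare_networks <- function(net_a, net_b, focus_drugs) {
  gene_neighbors <- function(g, d) {
    if (!d %in% igraph::V(g)$name) return(NULL)
    nb <- igraph::neighbors(g, d)
    types <- nb$type
    nms <- nb$name
    if (!is.null(types)) nms[types == "gene"] else nms
  }
  rows <- list(); nbrs <- list()
  for (d in focus_drugs) {
    a <- gene_neighbors(net_a, d)
    b <- gene_neighbors(net_b, d)
    if (is.null(a) && is.null(b)) {
      warning("drug absent from both networks, skipped: ", d)
      next
    }
    a <- if (is.null(a)) character() else a
    b <- if (is.null(b)) character() else b
    uni <- union(a, b)
    jac <- if (length(uni)) length(intersect(a, b)) / length(uni) else NA_real_
    rows[[d]] <- data.frame(drug_id = d, n_a = length(a), n_b = length(b),
                            n_intersect = length(intersect(a, b)),
                            jaccard = jac, stringsAsFactors = FALSE)
    nbrs[[d]] <- list(a = a, b = b)
  }
  list(summary = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                 else data.frame(),
       neighbors = nbrs)
}
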