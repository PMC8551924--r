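# Dense, literal construction of the MRF posterior used as the independent
# oracle: prior I + observation precision on observed nodes + sum over edges
# of coupling * w * (e_i - e_j)(e_i - e_j)^T, solved directly.
dense_posterior <- function(edges, genes, obs, coupling, obs_sd = 1) {
  n <- length(genes)
  J <- diag(n)
  dimnames(J) <- list(genes, genes)
  for (g in names(obs)) J[g, g] <- J[g, g] + 1 / obs_sd^2
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$from[k]; j <- edges$to[k]; w <- coupling * edges$fi_weight[k]
      J[i, i] <- J[i, i] + w; J[j, j] <- J[j, j] + w
      J[i, j] <- J[i, j] - w; J[j, i] <- J[j, i] - w
    }
  }
  h <- setNames(numeric(n), genes)
  h[names(obs)] <- obs / obs_sd^2
  solve(J, h)
}

graph_from_edges <- function(edges, genes) {
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = genes))
}

# Build an MRF whose observation scores are a fixed matrix by inverting the
# rank-normal link: feed a profile whose per-gene ranks produce those scores.
# For oracle tests we instead construct observations directly through a
# profile with two samples of opposite sign, then check individual samples.

test_that("coupling zero decouples genes: impact depends only on own score", {
  genes <- c("A", "B", "C")
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"), fi_weight = c(1, 2))
  g <- graph_from_edges(edges, genes)
  set.seed(1)
  x <- matrix(rnorm(3 * 7), nrow = 3, dimnames = list(genes, sprintf("S%d", 1:7)))
  m0 <- build_mrf(g, x, coupling_scale = 0)
  imp0 <- infer_impact(m0)
  # closed form at zero coupling: score / (1 + 1/sd^2) with sd = 1
  expect_equal(imp0, m0$h * 1 / 2, tolerance = 1e-12)
  # decoupling limit: tiny coupling approaches the zero-coupling solution
  m_eps <- build_mrf(g, x, coupling_scale = 1e-8)
  expect_equal(infer_impact(m_eps), imp0, tolerance = 1e-6)
})

test_that("inference equals the closed-form Gaussian posterior on small graphs", {
  # two-node chain, hand 2x2 algebra
  genes <- c("A", "B")
  w <- 0.8; c_s <- 1.5
  edges <- data.frame(from = "A", to = "B", fi_weight = w)
  g <- graph_from_edges(edges, genes)
  x <- matrix(c(1, 2, 4, 3,
                3, 1, 2, 4), nrow = 2, byrow = TRUE,
              dimnames = list(genes, sprintf("S%d", 1:4)))
  model <- build_mrf(g, x, coupling_scale = c_s)
  for (s in 1:4) {
    y <- model$h[, s]  # already scaled by 1/sd^2 = 1
    a <- 2 + c_s * w; b <- -c_s * w
    det <- a * a - b * b
    mu <- c((a * y["A"] - b * y["B"]) / det, (a * y["B"] - b * y["A"]) / det)
    expect_equal(unname(infer_impact(model, s)), unname(mu), tolerance = 1e-8)
  }

  # chains and stars up to 5 nodes against the dense literal construction
  set.seed(42)
  shapes <- list(
    chain5 = data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E"),
                        fi_weight = runif(4, 0.5, 1)),
    star5 = data.frame(from = "A", to = c("B", "C", "D", "E"),
                       fi_weight = runif(4, 0.5, 1))
  )
  for (edges in shapes) {
    genes <- sort(unique(c(edges$from, edges$to)))
    g <- graph_from_edges(edges, genes)
    x <- matrix(rnorm(5 * 6), nrow = 5, dimnames = list(genes, sprintf("S%d", 1:6)))
    model <- build_mrf(g, x, coupling_scale = 1.2)
    for (s in c(1, 4)) {
      obs <- model$h[, s]
      oracle <- dense_posterior(edges, genes, obs[genes], coupling = 1.2)
      expect_equal(unname(infer_impact(model, s)), unname(oracle),
                   tolerance = 1e-8)
    }
  }
})

test_that("impact propagates through a star and is odd in the observations", {
  genes <- c("HUB", "L1", "L2", "L3")
  edges <- data.frame(from = "HUB", to = c("L1", "L2", "L3"), fi_weight = 1)
  g <- graph_from_edges(edges, genes)
  # hub amplified in sample 2; leaves have no CNV of their own (score 0), so
  # any positive leaf impact is coupling-propagated from the hub
  x <- matrix(0, 4, 5, dimnames = list(genes, sprintf("S%d", 1:5)))
  x["HUB", ] <- c(0, 3, 0.1, -0.1, 0.05)
  model <- build_mrf(g, x, coupling_scale = 1)
  imp <- infer_impact(model, 2)
  expect_gt(imp["HUB"], max(imp[c("L1", "L2", "L3")]))
  expect_true(all(imp > 0))  # propagation reaches the leaves

  # oddness: negating the information vector negates the posterior
  m2 <- model
  m2$h <- -model$h
  expect_equal(infer_impact(m2), -infer_impact(model), tolerance = 1e-12)
})

test_that("relabeling nodes relabels impact scores unchanged", {
  genes <- c("A", "B", "C", "D")
  edges <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "D"),
                      fi_weight = c(1, 0.5, 0.7))
  set.seed(9)
  x <- matrix(rnorm(4 * 6), 4, dimnames = list(genes, sprintf("S%d", 1:6)))
  m1 <- build_mrf(graph_from_edges(edges, genes), x)
  relabel <- c(A = "W", B = "X", C = "Y", D = "Z")
  edges2 <- data.frame(from = unname(relabel[edges$from]),
                       to = unname(relabel[edges$to]),
                       fi_weight = edges$fi_weight)
  x2 <- x; rownames(x2) <- unname(relabel[rownames(x)])
  m2 <- build_mrf(graph_from_edges(edges2, unname(relabel[genes])), x2)
  i1 <- infer_impact(m1); i2 <- infer_impact(m2)
  expect_equal(unname(i1[genes, ]), unname(i2[unname(relabel[genes]), ]),
               tolerance = 1e-12)
})

test_that("network validation and empty intersection raise errors", {
  genes <- c("A", "B")
  edges <- data.frame(from = "A", to = "B", fi_weight = 1)
  g <- graph_from_edges(edges, genes)
  x <- matrix(rnorm(4), 2, dimnames = list(c("Q", "R"), c("S1", "S2")))
  expect_error(build_mrf(g, x), "no genes shared")
  bad <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", fi_weight = -1), directed = FALSE)
  expect_error(build_mrf(bad, x), "positive")
})

test_that("constant profiles give zero observations, zero impacts, zero diff", {
  genes <- c("A", "B", "C")
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"), fi_weight = 1)
  g <- graph_from_edges(edges, genes)
  x <- matrix(5, 3, 6, dimnames = list(genes, sprintf("S%d", 1:6)))
  model <- build_mrf(g, x)
  expect_true(all(infer_impact(model) == 0))
  real <- impact_scores(model)
  perm <- permutation_null(model, n_permutations = 10, seed = 1)
  expect_equal(unname(real - perm), rep(0, 3))
  expect_equal(model$no_cnv_genes, genes)
})

test_that("permutation null is deterministic and centered for i.i.d. profiles", {
  set.seed(31)
  panel <- independent_gene_panel(30)
  g <- make_fi_network(panel, within_p = 0, between_p = 0.15, seed = 2)
  x <- matrix(rnorm(30 * 13), 30,
              dimnames = list(panel$gene_id, sprintf("S%02d", 1:13)))
  model <- build_mrf(g, x)
  p1 <- permutation_null(model, n_permutations = 25, seed = 4)
  p2 <- permutation_null(model, n_permutations = 25, seed = 4)
  expect_identical(p1, p2)

  real <- impact_scores(model)
  perm <- permutation_null(model, n_permutations = 400, seed = 9)
  d <- real - perm
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("impact-gene selection uses strict thresholds and drops no-CNV genes", {
  # C sits exactly on the lower threshold: diff = -0.01 - 0 = -0.01
  real <- c(A = 0.105, B = 0.12, C = -0.01, D = 0.5, E = 0.2)
  perm <- c(A = 0.1, B = 0.1, C = 0, D = 0.3, E = 0.2)
  sel <- select_impacted_genes(real, perm, no_cnv_genes = "E")
  expect_false("E" %in% sel$gene_id)
  expect_equal(sel$selected[sel$gene_id == "A"], FALSE)  # 0.005 inside band
  expect_equal(sel$selected[sel$gene_id == "B"], TRUE)   # 0.02 outside
  expect_equal(sel$selected[sel$gene_id == "C"], FALSE)  # -0.01 exactly: strict
  expect_equal(sel$selected[sel$gene_id == "D"], TRUE)
})

test_that("drug overlay links drugs only to selected target genes", {
  targets <- data.frame(drug_id = c("DR1", "DR1", "DR2", "DR3"),
                        gene_id = c("A", "B", "B", "Q"))
  net <- overlay_drugs(c("A", "B", "C"), targets)
  expect_false("DR3" %in% igraph::V(net)$name)  # no selected target
  expect_equal(igraph::degree(net, "DR1"), c(DR1 = 2))
  expect_equal(igraph::degree(net, "DR2"), c(DR2 = 1))
  expect_setequal(igraph::V(net)$name[igraph::V(net)$type == "gene"],
                  c("A", "B", "C"))

  empty <- overlay_drugs(c("A", "B"), targets[0, ])
  expect_equal(igraph::ecount(empty), 0L)
  expect_setequal(igraph::V(empty)$name, c("A", "B"))
})

test_that("z-score network mirrors the significant pairs exactly", {
  tab <- data.frame(gene_id = c("G1", "G2", "G3"),
                    drug_id = c("D1", "D1", "D2"),
                    z = c(1.2, -0.8, 0.5),
                    significant = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  net <- build_zscore_network(tab, c(D1 = 60, D2 = 20))
  expect_equal(igraph::ecount(net), 2L)
  expect_setequal(igraph::E(net)$z, c(1.2, -0.8))
  d1 <- igraph::V(net)[igraph::V(net)$name == "D1"]
  expect_equal(d1$mean_cytotoxicity, 60)

  none <- build_zscore_network(tab[tab$z > 10, ], c(D1 = 60))
  expect_equal(igraph::ecount(none), 0L)
})

test_that("clustering separates disconnected cliques and planted blocks", {
  clique_edges <- function(genes, w = 1) {
    cmb <- t(combn(genes, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], fi_weight = w)
  }
  edges <- rbind(clique_edges(c("A1", "A2", "A3")),
                 clique_edges(c("B1", "B2", "B3", "B4")))
  g <- graph_from_edges(edges, c(paste0("A", 1:3), paste0("B", 1:4)))
  cl <- cluster_subnetworks(g)
  expect_equal(nrow(cl$modules), 2L)
  expect_equal(cl$modules$size, c(4L, 3L))  # size-ordered
  expect_length(unique(cl$membership[paste0("B", 1:4)]), 1L)
  expect_length(unique(cl$membership[paste0("A", 1:3)]), 1L)

  one <- cluster_subnetworks(graph_from_edges(
    data.frame(from = "A", to = "B", fi_weight = 1), c("A", "B")))
  expect_equal(nrow(one$modules), 1L)

  # planted two-block graph is recovered
  panel <- default_gene_panel()[1:24, ]
  panel$arm_id <- rep(c("blk1", "blk2"), each = 12)
  class(panel) <- c("gene_panel", "data.frame")
  g2 <- make_fi_network(panel, within_p = 0.9, between_p = 0.05, seed = 3)
  cl2 <- cluster_subnetworks(g2)
  blk <- cl2$membership[panel$gene_id]
  agree <- table(rep(c("blk1", "blk2"), each = 12), blk)
  purity <- sum(apply(agree, 1, max)) / 24
  expect_gte(purity, 23 / 24)
})

test_that("module enrichment finds a planted gene set", {
  clique_edges <- function(genes, w = 1) {
    cmb <- t(combn(genes, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], fi_weight = w)
  }
  edges <- rbind(clique_edges(paste0("A", 1:5)), clique_edges(paste0("B", 1:5)))
  g <- graph_from_edges(edges, c(paste0("A", 1:5), paste0("B", 1:5)))
  sets <- list(hit = paste0("A", 1:5), miss = c("B1", "A1"))
  cl <- cluster_subnetworks(g, gene_sets = sets)
  hit_rows <- cl$enrichment[cl$enrichment$gene_set == "hit", ]
  expect_equal(min(hit_rows$p), hit_rows$p[which.max(hit_rows$overlap)])
  expect_true(any(hit_rows$overlap == 5))
})

test_that("network comparison reports Jaccard overlap of drug neighborhoods", {
  mk <- function(pairs) {
    genes <- unique(pairs$gene_id); drugs <- unique(pairs$drug_id)
    igraph::graph_from_data_frame(
      data.frame(from = pairs$drug_id, to = pairs$gene_id),
      directed = FALSE,
      vertices = data.frame(name = c(genes, drugs),
                            type = c(rep("gene", length(genes)),
                                     rep("drug", length(drugs)))))
  }
  na <- mk(data.frame(gene_id = c("A", "B", "C"), drug_id = "DR"))
  nb <- mk(data.frame(gene_id = c("B", "C", "D"), drug_id = "DR"))
  res <- compare_networks(na, nb, "DR")
  expect_equal(res$summary$jaccard, 0.5)  # {A,B,C} vs {B,C,D} -> 2/4
  expect_equal(res$summary$n_intersect, 2L)

  same <- compare_networks(na, na, "DR")
  expect_equal(same$summary$jaccard, 1)

  disj <- mk(data.frame(gene_id = c("X", "Y"), drug_id = "DR"))
  expect_equal(compare_networks(na, disj, "DR")$summary$jaccard, 0)

  expect_warning(res <- compare_networks(na, nb, c("DR", "NOPE")),
                 "absent from both")
  expect_equal(nrow(res$summary), 1L)
})
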