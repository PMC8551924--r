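test_that("pearson_r matches hand-computed values and flags undefined pairs", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)  # hand: cov 1, sd 1.29^2
  expect_true(is.na(pearson_r(c(1, 1, 1, 1), x)))          # constant, not 0
  expect_true(is.na(pearson_r(c(1, 2, NA, NA), c(1, 2, 3, 4))))  # too few
})

test_that("fisher_z is atanh with clamping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.4722, tolerance = 1e-4)
  expect_equal(fisher_z(-0.9), -fisher_z(0.9))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("pair p-values standardize z and are monotone in |z|", {
  expect_equal(pair_pvalue(0, 13)$p, 1)
  zs <- pair_pvalue(atanh(0.745), 13)
  expect_equal(zs$z_std, 3.040919, tolerance = 1e-5)  # ~3.04
  expect_true(is.na(pair_pvalue(0.5, 3)$z_std))
  for (method in c("exact", "normal")) {
    grid <- seq(0.05, 2.5, by = 0.05)
    p <- pair_pvalue(grid, rep(13, length(grid)), method = method)$p
    expect_true(all(diff(p) < 0))
    expect_equal(p, pair_pvalue(-grid, rep(13, length(grid)), method = method)$p)
  }
})

test_that("the exact p-value matches the classical correlation test", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- cor(x, y)
    p_pkg <- pair_pvalue(atanh(r), n, method = "exact")$p
    p_ref <- stats::cor.test(x, y)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("bh_fdr reproduces the step-up definition on fixed examples", {
  res <- bh_fdr(c(0.001, 0.02, 0.03, 0.5), 0.1)
  expect_equal(res$discovered, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(bh_fdr(rep(1, 10), 0.1)$discovered), 0L)
  expect_true(bh_fdr(0.05, 0.1)$discovered)
  expect_equal(bh_fdr(numeric(0), 0.1)$q, numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_fdr equals the brute-force step-up on random inputs", {
  set.seed(7)
  for (i in 1:500) {
    m <- sample(1:50, 1)
    p <- if (i %% 2) runif(m) else rbeta(m, 0.3, 4)
    if (i %% 5 == 0) p[sample(m, 1)] <- NA
    q <- sample(c(0.05, 0.1, 0.2), 1)
    res <- bh_fdr(p, q)
    expect_identical(res$discovered, bh_brute_force(p, q))
    expect_true(all(res$q >= p, na.rm = TRUE))
  }
})

test_that("run_screen enumerates all pairs and partitions testable/undefined", {
  set.seed(21)
  x <- matrix(rnorm(8 * 6), nrow = 8,
              dimnames = list(paste0("G", 1:8), sprintf("S%02d", 1:6)))
  x[3, ] <- 5  # constant gene -> undefined everywhere
  y <- matrix(rnorm(5 * 6), nrow = 5,
              dimnames = list(paste0("D", 1:5), sprintf("S%02d", 1:6)))
  scr <- run_screen(x, y)
  expect_equal(nrow(scr$table), 40L)
  expect_equal(scr$n_testable + scr$n_undefined, 40L)
  expect_equal(scr$n_undefined, 5L)
  und <- scr$table[!scr$table$testable, ]
  expect_true(all(und$gene_id == "G3"))
  expect_true(all(is.na(und$q)))
  expect_false(any(und$significant))
  expect_equal(sign(scr$table$z[scr$table$testable]),
               sign(scr$table$r[scr$table$testable]))
})

test_that("no shared samples is an input error", {
  x <- matrix(1:4, 2, dimnames = list(c("G1", "G2"), c("S01", "S02")))
  y <- matrix(1:4, 2, dimnames = list(c("D1", "D2"), c("T01", "T02")))
  expect_error(run_screen(x, y), "shared sample")
})

test_that("screen results are invariant to a common sample permutation", {
  cfg <- small_config(seed = 14)
  co <- simulate_cohort(cfg)
  prof <- segment_probes_to_genes(co$probe_log2, co$panel)
  cyto <- build_cytotoxicity_matrix(co$plates, co$drug_library)
  scr1 <- run_screen(prof, cyto)
  perm <- c(4, 1, 6, 3, 2, 5)
  scr2 <- run_screen(prof$log2_ratio[, perm], cyto$values[, perm])
  for (col in c("r", "z", "p", "q", "significant")) {
    expect_equal(scr1$table[[col]], scr2$table[[col]], tolerance = 1e-12)
  }
})

test_that("venn classification is consistent and conserves counts", {
  tab <- data.frame(gene_id = rep(paste0("G", 1:4), each = 3),
                    drug_id = rep(paste0("D", 1:3), times = 4),
                    significant = rep(c(TRUE, FALSE), times = 6),
                    stringsAsFactors = FALSE)
  expected <- data.frame(gene_id = c("G1", "G1", "G4"),
                         drug_id = c("D1", "D2", "D3"))
  res <- classify_against_expected(tab, expected)
  expect_equal(sum(res$counts), nrow(tab))
  expect_equal(unname(res$counts["TP"] + res$counts["FN"]), 3L)
  with(res$table, {
    expect_true(all(venn_class[significant & expected] == "TP"))
    expect_true(all(venn_class[!significant & !expected] == "TN"))
  })

  all_exp <- classify_against_expected(tab, tab[c("gene_id", "drug_id")])
  expect_equal(unname(all_exp$counts[c("FP", "TN")]), c(0L, 0L))
  none <- classify_against_expected(tab, expected[0, ])
  expect_equal(unname(none$counts[c("TP", "FN")]), c(0L, 0L))

  expect_warning(res <- classify_against_expected(
    tab, data.frame(gene_id = "GX", drug_id = "D1")), "not in the enumerated")
  expect_equal(res$unknown_expected, "GX:D1")
})

test_that("effect ranking is the signed product of cytotoxicity and z", {
  tab <- data.frame(gene_id = c("GNA13", "A", "B"),
                    drug_id = c("PIK75", "PIK75", "PIK75"),
                    z = c(1.4, 0, -1.4),
                    significant = TRUE, stringsAsFactors = FALSE)
  ranked <- rank_by_effect(tab, c(PIK75 = 78.9))
  expect_equal(ranked$rank_score[ranked$gene_id == "GNA13"], 110.46,
               tolerance = 1e-9)
  expect_equal(ranked$rank_score[ranked$gene_id == "A"], 0)
  expect_equal(ranked$rank_score[ranked$gene_id == "B"], -110.46,
               tolerance = 1e-9)
  expect_equal(ranked$gene_id, c("GNA13", "A", "B"))  # descending order
  expect_error(rank_by_effect(tab, c(OTHER = 1)), "no mean cytotoxicity")
})

test_that("annotation-set verification counts per-set and union matches", {
  tab <- data.frame(gene_id = rep(paste0("G", 1:5), each = 2),
                    drug_id = rep(c("D1", "D2"), times = 5),
                    significant = TRUE, stringsAsFactors = FALSE)
  s1 <- data.frame(gene_id = c("G1", "G2", "G3"), drug_id = "D1")
  s2 <- data.frame(gene_id = c("G2", "G3", "G4", "G5"), drug_id = "D1")
  res <- verify_against_annotation_sets(tab, list(a = s1, b = s2))
  expect_equal(unname(res$per_set_counts), c(3L, 4L))
  expect_equal(res$union_count, 5L)  # 3 + 4 sharing 2
  expect_equal(sum(res$table$verified), 5L)

  none <- verify_against_annotation_sets(tab, list())
  expect_equal(sum(none$table$verified), 0L)
  all_sig <- verify_against_annotation_sets(tab, list(all = tab))
  expect_true(all(all_sig$table$verified[all_sig$table$significant]))
})

test_that("null cohorts keep the false-discovery proportion near the BH level", {
  fdps <- vapply(1:30, function(i) {
    cfg <- small_config(seed = 40000 + i, n_samples = 8, n_drugs = 30)
    co <- simulate_cohort(cfg)
    prof <- segment_probes_to_genes(co$probe_log2, co$panel)
    cyto <- build_cytotoxicity_matrix(co$plates, co$drug_library)
    scr <- run_screen(prof, cyto)
    nd <- sum(scr$table$significant)
    if (nd > 0) 1 else 0  # every discovery on a null cohort is false
  }, 0)
  mc_se <- stats::sd(fdps) / sqrt(length(fdps))
  expect_lte(mean(fdps), 0.1 + 2 * max(mc_se, 0.05))
})

test_that("planted strong pairs are detected with matching sign", {
  b <- fdr_benchmark(n_cohorts = 3, seed = 5, n_genes = 40, n_drugs = 60,
                     n_planted = 10, n_planted_genes = 2)
  expect_true(all(b$sensitivity >= 0.8))

  for (slope in c(25, -25)) {
    panel <- small_panel()
    lib <- default_drug_library(6, panel)
    cfg <- cohort_config(n_samples = 10, panel = panel,
                         arm_event_rates = list("17q" = list(event = "gain",
                                                             probability = 0.5)),
                         focal_amp = NULL, probe_noise_sd = 0.02,
                         drug_library = lib,
                         planted_pairs = data.frame(gene_id = "C1",
                                                    drug_id = "D003",
                                                    slope = slope),
                         response_noise_sd = 2, seed = 77)
    co <- simulate_cohort(cfg)
    prof <- segment_probes_to_genes(co$probe_log2, panel)
    cyto <- build_cytotoxicity_matrix(co$plates, co$drug_library)
    scr <- run_screen(prof, cyto)
    row <- scr$table[scr$table$gene_id == "C1" & scr$table$drug_id == "D003", ]
    expect_equal(sign(row$z), sign(slope))
  }
})
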