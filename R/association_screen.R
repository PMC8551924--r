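#' Association-screen configuration
#'
#' @param fdr_threshold Benjamini-Hochberg FDR level; pairs with adjusted
#'   q <= this are significant (default 0.1, inclusive).
#' @param min_samples minimum pairwise-complete observations per pair
#'   (default 5).
#' @param use correlate gene `"log2_ratio"` (default) or absolute `"copies"`.
#' @param p_method `"exact"` (default): two-sided p from the exact null
#'   distribution of the Pearson correlation (Student t with n-2 df);
#'   `"normal"`: two-sided standard-normal tail of `z * sqrt(n - 3)`. With a
#'   dozen samples and tens of thousands of tests the BH threshold sits deep
#'   in the tail, where the normal approximation to the Fisher z null is
#'   anti-conservative and inflates the realized FDR several-fold; the exact
#'   null restores the nominal guarantee.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(fdr_threshold = 0.1, min_samples = 5L,
                          use = c("log2_ratio", "copies"),
                          p_method = c("exact", "normal")) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie strictly between 0 and 1")
  }
  structure(list(fdr_threshold = fdr_threshold,
                 min_samples = as.integer(min_samples),
                 use = match.arg(use),
                 p_method = match.arg(p_method)),
            class = "screen_config")
}

#' Pearson correlation on pairwise-complete observations
#'
#' Standard product-moment correlation over jointly non-missing entries.
#' Returns `NA` (the pair is "undefined", never coerced to zero) when fewer
#' than `min_n` complete pairs remain or either vector is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum complete pairs.
#' @return correlation in `[-1, 1]`, or `NA_real_`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
pearson_r <- function(x, y, min_n = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Fisher z-transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform of the Pearson correlation. Correlations at exactly +/-1 are
#' clamped to magnitude `1 - 1e-7` with a warning.
#'
#' @param r correlations.
#' @return Fisher z values.
#' @export
#' @examples
#' fisher_z(0.9)  # ~1.4722
fisher_z <- function(r) {
  at_limit <- !is.na(r) & abs(r) >= 1
  if (any(at_limit)) {
    warning(sum(at_limit), " correlation(s) at |r| = 1 clamped to 1 - 1e-7")
    r[at_limit] <- sign(r[at_limit]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Two-sided p-value for a correlation's Fisher z
#'
#' Always reports the standardized statistic `z_std = z * sqrt(n - 3)`
#' (approximately standard normal under the null). The p-value is two-sided,
#' from either the exact null distribution of the Pearson correlation
#' (`method = "exact"`, Student t with n-2 df on `r sqrt(n-2)/sqrt(1-r^2)`,
#' the default) or the standard-normal tail of `z_std`
#' (`method = "normal"`). Both are monotone decreasing in `|z|` at fixed n.
#' Pairs with `n < 4` are undefined.
#'
#' @param z Fisher z values.
#' @param n sample counts.
#' @param method `"exact"` or `"normal"` (see [screen_config()] for why the
#'   exact null is the default).
#' @return list with `z_std` and `p`.
#' @export
pair_pvalue <- function(z, n, method = c("exact", "normal")) {
  method <- match.arg(method)
  z_std <- ifelse(n >= 4L, z * sqrt(n - 3), NA_real_)
  if (method == "normal") {
    p <- 2 * stats::pnorm(-abs(z_std))
  } else {
    r <- tanh(z)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- ifelse(n >= 4L, 2 * stats::pt(-abs(tstat), n - 2), NA_real_)
  }
  list(z_std = z_std, p = p)
}

#' Benjamini-Hochberg FDR adjustment and discovery set
#'
#' Classic step-up control of the false discovery rate: with ordered p-values
#' p(1) <= ... <= p(m), reject 1..k where k = max{i : p(i) <= i q / m}. The
#' adjusted q-values are the monotone cumulative-minimum form
#' (`stats::p.adjust(method = "BH")`), and the discovery set is exactly the
#' step-up rejection set. `NA` p-values (undefined pairs) are excluded from m
#' and never discovered.
#'
#' @param p p-values in `[0, 1]` (NAs allowed).
#' @param q_threshold FDR level (default 0.1).
#' @return list with `q` (adjusted values, same length as `p`) and
#'   `discovered` (logical).
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.03, 0.5), 0.1)$discovered  # T T T F
bh_fdr <- function(p, q_threshold = 0.1) {
  if (!length(p)) return(list(q = numeric(), discovered = logical()))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  discovered <- !is.na(q) & q <= q_threshold
  list(q = q, discovered = discovered)
}

#' All-pairs gene-drug correlation screen
#'
#' Correlates every panel gene's copy-number profile against every drug's
#' normalized cytotoxicity across the shared samples, applies the Fisher
#' z-transformation, standardizes by `sqrt(n - 3)`, and controls the FDR at
#' `fdr_threshold` by Benjamini-Hochberg over all testable pairs. Pairs with
#' a constant copy-number or cytotoxicity vector (e.g. genes with no CNV) or
#' fewer than `min_samples` complete observations are kept in the table as
#' "undefined" and excluded from the multiplicity count m, so
#' `testable + undefined = n_genes * n_drugs`.
#'
#' @param cnv_profile a `copy_number_profile` (or a bare gene x sample
#'   matrix, interpreted per `config$use`).
#' @param cyto a `cytotoxicity_matrix` (or bare drug x sample matrix).
#' @param config a [screen_config()].
#' @return object of class `gene_drug_screen`: list with `table` (one row per
#'   pair: gene_id, drug_id, n, r, z, z_std, p, q, significant, testable),
#'   `n_testable`, `n_undefined`, `config`.
#' @export
run_screen <- function(cnv_profile, cyto, config = screen_config()) {
  x <- if (inherits(cnv_profile, "copy_number_profile")) {
    cnv_profile[[config$use]]
  } else {
    as.matrix(cnv_profile)
  }
  y <- if (inherits(cyto, "cytotoxicity_matrix")) cyto$values else as.matrix(cyto)
  shared <- intersect(colnames(x), colnames(y))
  if (!length(shared)) stop("no shared sample ids between the matrices")
  x <- x[, shared, drop = FALSE]
  y <- y[, shared, drop = FALSE]

  r <- suppressWarnings(stats::cor(t(x), t(y), use = "pairwise.complete.obs"))
  n <- (!is.na(x)) %*% t(!is.na(y))
  # pairwise-complete sd can still be zero when missingness trims a vector to
  # a constant; cor() already yields NA there.
  testable <- !is.na(r) & n >= config$min_samples
  z <- matrix(NA_real_, nrow(r), ncol(r))
  z[testable] <- fisher_z(r[testable])
  pv <- pair_pvalue(z, n, method = config$p_method)

  tab <- data.frame(
    gene_id = rep(rownames(x), times = ncol(r)),
    drug_id = rep(colnames(r), each = nrow(x)),
    n = as.integer(n),
    r = as.numeric(r),
    z = as.numeric(z),
    z_std = as.numeric(pv$z_std),
    p = as.numeric(pv$p),
    stringsAsFactors = FALSE
  )
  tab$testable <- as.logical(testable)
  tab$p[!tab$testable] <- NA_real_
  bh <- bh_fdr(tab$p, config$fdr_threshold)
  tab$q <- bh$q
  tab$significant <- bh$discovered
  structure(list(table = tab,
                 n_testable = sum(tab$testable),
                 n_undefined = sum(!tab$testable),
                 config = config),
            class = "gene_drug_screen")
}

#' @export
print.gene_drug_screen <- function(x, ...) {
  cat("Gene-drug screen:", nrow(x$table), "pairs enumerated;",
      x$n_testable, "testable,", x$n_undefined, "undefined;",
      sum(x$table$significant), "significant at q <=",
      x$config$fdr_threshold, "\n")
  invisible(x)
}

#' Classify significant pairs against expected drug targets
#'
#' Cross-classifies every enumerated pair by statistical significance versus
#' presence in the expected-target annotation: TP = significant and expected,
#' FP = significant only, FN = expected only, TN = neither. Counts always sum
#' to the number of enumerated pairs.
#'
#' @param screen a `gene_drug_screen` (or its `table`).
#' @param expected_pairs data.frame `gene_id`, `drug_id` of expected pairs.
#' @return list with `table` (the association table plus `expected` and
#'   `venn_class` columns), `counts` (named TP/FP/FN/TN),
#'   `unknown_expected` (expected pairs outside the enumerated universe,
#'   warned about and ignored).
#' @export
classify_against_expected <- function(screen, expected_pairs) {
  tab <- if (inherits(screen, "gene_drug_screen")) screen$table else screen
  key <- paste(tab$gene_id, tab$drug_id, sep = "\r")
  ekey <- unique(paste(expected_pairs$gene_id, expected_pairs$drug_id, sep = "\r"))
  unknown <- setdiff(ekey, key)
  if (length(unknown)) {
    warning(length(unknown), " expected pair(s) not in the enumerated universe; ignored")
  }
  tab$expected <- key %in% ekey
  tab$venn_class <- ifelse(tab$significant,
                           ifelse(tab$expected, "TP", "FP"),
                           ifelse(tab$expected, "FN", "TN"))
  counts <- c(TP = sum(tab$venn_class == "TP"),
              FP = sum(tab$venn_class == "FP"),
              FN = sum(tab$venn_class == "FN"),
              TN = sum(tab$venn_class == "TN"))
  list(table = tab, counts = counts,
       unknown_expected = sub("\r", ":", unknown, fixed = TRUE))
}

#' Rank pairs by the product of cytotoxicity and z-score
#'
#' `rank_score = mean cytotoxicity of the drug x Fisher z of the pair`, with
#' signed z, so strongly negative associations of potent drugs land at the
#' bottom. Sorted descending; ties broken by (gene_id, drug_id).
#'
#' @param screen a `gene_drug_screen` or its table.
#' @param drug_means named numeric vector of per-drug mean cytotoxicity.
#' @return the table with a `mean_cytotoxicity` and `rank_score` column, in
#'   rank order.
#' @export
rank_by_effect <- function(screen, drug_means) {
  tab <- if (inherits(screen, "gene_drug_screen")) screen$table else screen
  missing_drugs <- setdiff(unique(tab$drug_id), names(drug_means))
  if (length(missing_drugs)) {
    stop("no mean cytotoxicity for drug(s): ",
         paste(utils::head(missing_drugs, 5L), collapse = ", "))
  }
  tab$mean_cytotoxicity <- as.numeric(drug_means[tab$drug_id])
  tab$rank_score <- tab$mean_cytotoxicity * tab$z
  tab <- tab[order(-tab$rank_score, tab$gene_id, tab$drug_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Verify pairs against external annotation sets
#'
#' Marks each pair verified when it appears in at least one user-supplied
#' annotation set (named lists of gene-drug pairs), and reports per-set and
#' union counts.
#'
#' @param screen a `gene_drug_screen` or its table.
#' @param annotation_sets named list of data.frames with `gene_id`, `drug_id`.
#' @return list with `table` (plus a `verified` column), `per_set_counts`
#'   (matches within the screen universe per set) and `union_count` (distinct
#'   annotated pairs across sets, within the universe).
#' @export
verify_against_annotation_sets <- function(screen, annotation_sets) {
  tab <- if (inherits(screen, "gene_drug_screen")) screen$table else screen
  if (is.null(names(annotation_sets)) && length(annotation_sets)) {
    names(annotation_sets) <- paste0("set", seq_along(annotation_sets))
  }
  key <- paste(tab$gene_id, tab$drug_id, sep = "\r")
  set_keys <- lapply(annotation_sets, function(s) {
    if (!all(c("gene_id", "drug_id") %in% names(s))) {
      stop("annotation set lacks gene_id/drug_id columns")
    }
    unique(paste(s$gene_id, s$drug_id, sep = "\r"))
  })
  union_keys <- unique(unlist(set_keys, use.names = FALSE))
  tab$verified <- key %in% union_keys
  per_set <- vapply(set_keys, function(k) sum(key %in% k), 0L)
  list(table = tab, per_set_counts = per_set,
       union_count = sum(unique(key) %in% union_keys))
}
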