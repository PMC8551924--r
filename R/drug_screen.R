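#' Hit-calling and plate-QC configuration
#'
#' @param hit_threshold mean cytotoxicity (%) a drug must strictly exceed to
#'   be called a hit (default 33).
#' @param qc_staurosporine_min minimum normalized cytotoxicity (%) of the
#'   staurosporine positive control for a plate to pass QC (default 80).
#' @param qc_dmso_cv_max maximum coefficient of variation of the DMSO control
#'   RLUs (default 0.2). These two thresholds are numeric stand-ins for the
#'   qualitative requirement of high positive-control kill and minimal
#'   vehicle effect.
#' @return object of class `hit_call_config`.
#' @export
hit_call_config <- function(hit_threshold = 33, qc_staurosporine_min = 80,
                            qc_dmso_cv_max = 0.2) {
  if (qc_dmso_cv_max <= 0) stop("qc_dmso_cv_max must be positive")
  structure(list(hit_threshold = hit_threshold,
                 qc_staurosporine_min = qc_staurosporine_min,
                 qc_dmso_cv_max = qc_dmso_cv_max),
            class = "hit_call_config")
}

plate_split <- function(plates) split(plates, plates$plate_id)

#' Normalize one plate's RLUs to percent cytotoxicity
#'
#' `cytotoxicity = 100 * (1 - RLU / median(DMSO RLU))`, using the median of
#' the DMSO vehicle wells as the plate's live-cell reference. Replicate wells
#' of the same compound are averaged at the RLU level before normalization.
#' Values can be negative (growth stimulation) and never exceed 100 for
#' non-negative RLUs. A plate with no DMSO wells or a non-positive DMSO
#' median is marked unusable rather than silently scaled.
#'
#' @param plate data.frame of one plate's wells: columns `compound_id`, `rlu`.
#' @return list with `usable` (flag), `values` (named vector of % cytotoxicity
#'   per compound, controls included under `DMSO`/`STAUROSPORINE`),
#'   `dmso_rlus` (the vehicle wells) and `reason` when unusable.
#' @export
#' @examples
#' plate <- data.frame(compound_id = c("D1", "D2", "DMSO", "DMSO"),
#'                     rlu = c(500, 2000, 1000, 1000))
#' normalize_cytotoxicity(plate)$values
normalize_cytotoxicity <- function(plate) {
  dmso <- plate$rlu[plate$compound_id == "DMSO"]
  if (!length(dmso)) {
    return(list(usable = FALSE, values = NULL, dmso_rlus = numeric(),
                reason = "no DMSO wells"))
  }
  ref <- stats::median(dmso)
  if (!is.finite(ref) || ref <= 0) {
    return(list(usable = FALSE, values = NULL, dmso_rlus = dmso,
                reason = "non-positive DMSO median"))
  }
  mean_rlu <- tapply(plate$rlu, plate$compound_id, mean)
  values <- 100 * (1 - mean_rlu / ref)
  list(usable = TRUE, values = setNames(as.numeric(values), names(mean_rlu)),
       dmso_rlus = dmso, reason = NULL)
}

#' Plate quality control
#'
#' A plate passes when the staurosporine positive control shows at least
#' `qc_staurosporine_min` % normalized cytotoxicity and the DMSO wells'
#' coefficient of variation stays at or below `qc_dmso_cv_max`.
#'
#' @param plate one plate's wells (as in [normalize_cytotoxicity()]).
#' @param config a [hit_call_config()].
#' @return list with `pass` (flag) and `reasons` (character, empty when
#'   passing).
#' @export
qc_plate <- function(plate, config = hit_call_config()) {
  norm <- normalize_cytotoxicity(plate)
  reasons <- character()
  if (!norm$usable) {
    return(list(pass = FALSE, reasons = norm$reason))
  }
  stauro <- norm$values[["STAUROSPORINE"]]
  if (is.null(stauro) || is.na(stauro)) {
    reasons <- c(reasons, "no staurosporine wells")
  } else if (stauro < config$qc_staurosporine_min) {
    reasons <- c(reasons, "positive control below threshold")
  }
  cv <- stats::sd(norm$dmso_rlus) / mean(norm$dmso_rlus)
  if (length(norm$dmso_rlus) > 1L && cv > config$qc_dmso_cv_max) {
    reasons <- c(reasons, "excessive DMSO variability")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Build the drug x sample cytotoxicity matrix
#'
#' Normalizes every plate, applies QC, and assembles the normalized
#' cytotoxicity matrix. Plates failing QC propagate as missing columns
#' (excluded pairwise downstream), never as fabricated values.
#'
#' @param plates long data.frame of well readings across plates (columns
#'   `plate_id`, `sample_id`, `compound_id`, `rlu`).
#' @param drug_library the compound library; fixes row order and supplies
#'   mechanism classes.
#' @param config a [hit_call_config()].
#' @return object of class `cytotoxicity_matrix`: list with `values` (drug x
#'   sample % cytotoxicity), `qc` (per-plate data.frame), `drug_class` (named
#'   character).
#' @export
build_cytotoxicity_matrix <- function(plates, drug_library,
                                      config = hit_call_config()) {
  by_plate <- plate_split(plates)
  samples <- vapply(by_plate, function(p) p$sample_id[1L], "")
  values <- matrix(NA_real_, nrow = nrow(drug_library), ncol = length(by_plate),
                   dimnames = list(drug_library$compound_id, unname(samples)))
  qc <- data.frame(plate_id = names(by_plate), sample_id = unname(samples),
                   pass = FALSE, reasons = "", stringsAsFactors = FALSE)
  for (i in seq_along(by_plate)) {
    plate <- by_plate[[i]]
    q <- qc_plate(plate, config)
    qc$pass[i] <- q$pass
    qc$reasons[i] <- paste(q$reasons, collapse = "; ")
    if (q$pass) {
      norm <- normalize_cytotoxicity(plate)
      keep <- intersect(names(norm$values), drug_library$compound_id)
      values[keep, i] <- norm$values[keep]
    }
  }
  structure(list(values = values, qc = qc,
                 drug_class = setNames(drug_library$mechanism_class,
                                       drug_library$compound_id)),
            class = "cytotoxicity_matrix")
}

#' @export
print.cytotoxicity_matrix <- function(x, ...) {
  cat("Cytotoxicity matrix:", nrow(x$values), "drugs x", ncol(x$values),
      "samples;", sum(x$qc$pass), "of", nrow(x$qc), "plates passed QC\n")
  invisible(x)
}

#' Call drug hits
#'
#' A drug is a hit when its mean normalized cytotoxicity across QC-passing
#' samples strictly exceeds the hit threshold. Output is sorted by descending
#' mean, ties broken lexicographically by compound id.
#'
#' @param cyto a `cytotoxicity_matrix` or a bare drug x sample matrix.
#' @param config a [hit_call_config()].
#' @return data.frame `drug_id`, `mean_cytotoxicity`, `sd_cytotoxicity`,
#'   `n_samples`, `hit`, sorted as above.
#' @export
call_hits <- function(cyto, config = hit_call_config()) {
  values <- if (inherits(cyto, "cytotoxicity_matrix")) cyto$values else cyto
  means <- rowMeans(values, na.rm = TRUE)
  sds <- apply(values, 1L, stats::sd, na.rm = TRUE)
  ns <- rowSums(!is.na(values))
  out <- data.frame(drug_id = rownames(values),
                    mean_cytotoxicity = as.numeric(means),
                    sd_cytotoxicity = as.numeric(sds),
                    n_samples = as.integer(ns),
                    hit = as.numeric(means) > config$hit_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_cytotoxicity, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize cytotoxicity by mechanism class
#'
#' Class mean = mean over member drugs' per-drug mean cytotoxicity, ranked in
#' descending order with deterministic (lexicographic) tie-breaks.
#'
#' @param cyto a `cytotoxicity_matrix`, or a bare matrix together with
#'   `drug_class`.
#' @param drug_class named character vector mapping drug id to class (taken
#'   from `cyto` when it is a `cytotoxicity_matrix`).
#' @return data.frame `mechanism_class`, `mean_cytotoxicity`, `n_drugs`.
#' @export
summarize_by_class <- function(cyto, drug_class = NULL) {
  values <- if (inherits(cyto, "cytotoxicity_matrix")) cyto$values else cyto
  if (is.null(drug_class) && inherits(cyto, "cytotoxicity_matrix")) {
    drug_class <- cyto$drug_class
  }
  cls <- drug_class[rownames(values)]
  if (any(is.na(cls) | cls == "")) {
    stop("missing mechanism class for drug(s): ",
         paste(utils::head(rownames(values)[is.na(cls) | cls == ""], 5L),
               collapse = ", "))
  }
  drug_means <- rowMeans(values, na.rm = TRUE)
  agg <- tapply(drug_means, cls, mean)
  out <- data.frame(mechanism_class = names(agg),
                    mean_cytotoxicity = as.numeric(agg),
                    n_drugs = as.integer(table(cls)[names(agg)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_cytotoxicity, out$mechanism_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
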