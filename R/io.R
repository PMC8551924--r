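#' Readers and writers for the pipeline's plain-text formats
#'
#' All tables are tab-separated with a header row; missing values are written
#' as empty fields. Writers and readers form lossless round trips (up to
#' floating-point printing at 15 significant digits). Malformed inputs raise
#' parse errors naming the offending file/columns; nothing is silently
#' coerced.
#'
#' @param x object to write (format-specific, see each function).
#' @param path file path.
#' @name pipeline_io
NULL

write_tsv_impl <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv_impl <- function(path, required, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname pipeline_io
#' @export
write_probe_tsv <- function(x, path) write_tsv_impl(x, path)

#' @rdname pipeline_io
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "",
                          colClasses = c(probe_id = "character",
                                         gene = "character",
                                         chrom = "character",
                                         arm = "character"))
  missing_cols <- setdiff(c("probe_id", "gene", "chrom", "arm"), names(df))
  if (length(missing_cols)) {
    stop("probe matrix file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write/read a gene-by-sample numeric matrix as TSV
#'
#' First column holds the row ids (`gene_id` by default); remaining columns
#' are samples.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param id_col name of the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(m), as.data.frame(m, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv_impl(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id_col = "gene_id") {
  df <- read_tsv_impl(path, id_col, "matrix")
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  storage.mode(m) <- "double"
  m
}

#' @rdname pipeline_io
#' @export
write_plate_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname pipeline_io
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("plate_id", "sample_id", "well", "compound_id", "rlu")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("plate file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$rlu)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$rlu))))
    stop("plate file ", path, ": non-numeric RLU at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df
}

#' @rdname pipeline_io
#' @export
write_drug_library_tsv <- function(x, path) write_tsv_impl(x, path)

#' @rdname pipeline_io
#' @export
read_drug_library_tsv <- function(path) {
  df <- read_tsv_impl(path, c("compound_id", "name", "mechanism_class",
                              "target_genes"), "drug library")
  df$target_genes[is.na(df$target_genes)] <- ""
  class(df) <- c("drug_library", "data.frame")
  df
}

#' @rdname pipeline_io
#' @export
write_association_tsv <- function(x, path) write_tsv_impl(x, path)

#' @rdname pipeline_io
#' @export
read_association_tsv <- function(path) {
  read_tsv_impl(path, c("gene_id", "drug_id", "n", "r", "z"), "association")
}

#' Write variant records as a minimal VCF
#'
#' Sites-style VCF with INFO keys `DP` (coverage), `AF` (allele fraction),
#' `COSMIC` (0/1), `POPFREQ` (population frequency), `SNP` (recurrent
#' population SNP flag, 0/1), `SAMPLE` and `GENE`.
#'
#' @param variants variant records data.frame (see [generate_variants()]).
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnassoc",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Coverage depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=COSMIC,Number=1,Type=Integer,Description=\"COSMIC reported (0/1)\">",
    "##INFO=<ID=POPFREQ,Number=1,Type=Float,Description=\"Population frequency\">",
    "##INFO=<ID=SNP,Number=1,Type=Integer,Description=\"Recurrent population SNP (0/1)\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(variants)) {
    info <- sprintf("DP=%d;AF=%s;COSMIC=%d;POPFREQ=%s;SNP=%d;SAMPLE=%s;GENE=%s",
                    variants$coverage,
                    format(variants$allele_fraction, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    as.integer(variants$cosmic_reported),
                    format(variants$population_frequency, digits = 15,
                           trim = TRUE, scientific = FALSE),
                    as.integer(variants$is_population_snp),
                    variants$sample_id, variants$gene_id)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    variants$chrom, variants$pos, variants$ref, variants$alt,
                    info)
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
}

#' Read a minimal variant VCF
#'
#' Parses the VCF with `vcfR` and reconstructs the variant-record data.frame.
#' Missing required INFO keys raise a parse error naming the key.
#'
#' @param path VCF path.
#' @return variant records data.frame.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(sample_id = character(), gene_id = character(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character(), coverage = integer(),
                      allele_fraction = numeric(), cosmic_reported = logical(),
                      population_frequency = numeric(),
                      is_population_snp = logical(), stringsAsFactors = FALSE))
  }
  grab <- function(key, as_numeric = FALSE) {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = as_numeric)
    if (all(is.na(v))) {
      stop("VCF ", path, ": required INFO key missing: ", key)
    }
    v
  }
  data.frame(
    sample_id = grab("SAMPLE"),
    gene_id = grab("GENE"),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    coverage = as.integer(grab("DP", TRUE)),
    allele_fraction = grab("AF", TRUE),
    cosmic_reported = grab("COSMIC", TRUE) == 1,
    population_frequency = grab("POPFREQ", TRUE),
    is_population_snp = grab("SNP", TRUE) == 1,
    stringsAsFactors = FALSE
  )
}

#' Write/read a weighted edge list
#'
#' Tab-separated `gene_a`, `gene_b`, `fi_weight`; isolated vertices are
#' carried in a `#vertices:` comment line so round trips preserve the vertex
#' set.
#'
#' @param network an igraph with `fi_weight`.
#' @param path file path.
#' @export
write_edge_list_tsv <- function(network, path) {
  edges <- igraph::as_data_frame(network, what = "edges")
  df <- data.frame(gene_a = edges$from, gene_b = edges$to,
                   fi_weight = edges$fi_weight, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#vertices:", paste(igraph::V(network)$name, collapse = ",")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_edge_list_tsv
#' @export
read_edge_list_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  verts <- NULL
  if (startsWith(first, "#vertices:")) {
    verts <- strsplit(sub("^#vertices:", "", first), ",", fixed = TRUE)[[1]]
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("gene_a", "gene_b", "fi_weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("edge list ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) && !is.numeric(df$fi_weight)) {
    stop("edge list ", path, ": fi_weight column is not numeric")
  }
  if (is.null(verts)) verts <- unique(c(df$gene_a, df$gene_b))
  igraph::graph_from_data_frame(
    data.frame(from = df$gene_a, to = df$gene_b, fi_weight = df$fi_weight,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = verts))
}

#' Write a network as GraphML
#'
#' @param network an igraph (node attributes such as impact/selected/mean
#'   cytotoxicity and edge attributes fi_weight or z are preserved).
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
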