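#' Read an expression matrix from TSV or GCT
#'
#' Reads a genes-by-samples matrix in the Xena dialect: a header row of
#' sample ids and a first column of gene ids. A GCT header (version line
#' `#1.2` followed by a dimensions line) is detected and skipped, and a
#' `Description` column, when present, is dropped.
#'
#' @param path file path.
#' @param scale abundance scale to stamp on the result.
#' @param meta optional per-sample metadata passed to [expr_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(path, scale = "tpm", meta = NULL) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 2L && tolower(names(df)[2]) == "description") {
    df <- df[, -2L, drop = FALSE]
  }
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[1L]])
  expr_matrix(v, scale = scale, meta = meta)
}

#' Write an expression matrix as TSV
#' @param x an `expr_matrix`.
#' @param path output path.
#' @param id_column name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene") {
  df <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF-like mutation table
#'
#' Accepts tab-separated files with at least `Tumor_Sample_Barcode`,
#' `Hugo_Symbol` and `Variant_Classification` columns (comment lines
#' starting with `#` are skipped), and returns them under the neutral names
#' used throughout the package.
#'
#' @param path file path.
#' @return `data.frame` with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("MAF lacks columns: ", paste(missing, collapse = ", "))
  }
  data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
             gene_symbol = as.character(df$Hugo_Symbol),
             variant_classification = as.character(df$Variant_Classification),
             stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. The description field is kept as the pathway category
#' when it matches a known category label, otherwise `"other"`.
#'
#' @param path file path.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- names
  categories <- ifelse(desc %in% pathway_categories(), desc, "other")
  names(categories) <- names
  pathway_collection(sets, categories)
}

#' Write gene sets to a GMT file
#' @param coll a `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$categories[[nm]], coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a lncRNA-miRNA / miRNA-gene interaction table
#'
#' Tab-separated with columns `source`, `target`, `type`, where `type` is
#' `lnc_mirna` (source lncRNA, target miRNA) or `mirna_gene` (source miRNA,
#' target coding gene). miRNA identifiers are normalized with
#' [normalize_mirna_id()].
#'
#' @param path file path.
#' @param alias_map optional named character vector mapping normalized ids
#'   to canonical ids.
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path, alias_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("source", "target", "type")
  if (!all(required %in% names(df))) {
    stop("interaction table lacks columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  is_lm <- df$type == "lnc_mirna"
  df$target[is_lm] <- normalize_mirna_id(df$target[is_lm], alias_map)
  df$source[!is_lm] <- normalize_mirna_id(df$source[!is_lm], alias_map)
  interaction_table(df)
}

#' Read a sparse count matrix in MatrixMarket layout
#'
#' Reads a 10x-style directory holding `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (or `genes.tsv`), or a dense TSV with genes in rows.
#'
#' @param path directory with the three MTX files, or a dense TSV file.
#' @return genes-by-cells integer matrix with dimnames.
#' @export
read_sc_counts <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    ff <- file.path(path, "features.tsv")
    if (!file.exists(ff)) ff <- file.path(path, "genes.tsv")
    features <- utils::read.delim(ff, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    m <- as.matrix(m)
    dimnames(m) <- list(features, barcodes)
    m
  } else {
    x <- read_expression_tsv(path, scale = "tpm")
    x$values
  }
}

#' Write a sparse count matrix in MatrixMarket layout
#' @param counts genes-by-cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc_counts <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(rownames(counts)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
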