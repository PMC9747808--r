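#' Expression matrix container
#'
#' A lightweight genes-by-samples expression container carrying the
#' abundance scale (`"tpm"` or `"log2_tpm1"`) and optional per-sample
#' metadata. Gene identifiers are the row names, sample identifiers the
#' column names.
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names required.
#' @param scale abundance scale of `values`: raw TPM (`"tpm"`) or
#'   log2(TPM + 1) (`"log2_tpm1"`).
#' @param meta optional `data.frame` of per-sample metadata with columns
#'   `sample_id`, `cohort` (`"tumor"` or `"cell_line"`) and `disease_code`;
#'   rows must cover every column of `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `meta`.
#' @export
expr_matrix <- function(values, scale = c("tpm", "log2_tpm1"), meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    missing <- setdiff(colnames(values), meta$sample_id)
    if (length(missing) > 0L) {
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    }
    meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(values = values, scale = scale, meta = meta),
            class = "expr_matrix")
}

validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  required <- c("sample_id", "cohort", "disease_code")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$cohort <- as.character(meta$cohort)
  meta$disease_code <- as.character(meta$disease_code)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(meta$cohort %in% c("tumor", "cell_line"))) {
    stop("cohort must be 'tumor' or 'cell_line'")
  }
  if (any(!nzchar(meta$disease_code))) stop("empty disease codes")
  meta
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$meta)) {
    tab <- table(x$meta$cohort)
    cat("  cohorts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  meta <- x$meta
  if (!is.null(meta)) {
    meta <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  expr_matrix(v, scale = x$scale, meta = meta)
}
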