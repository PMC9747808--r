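#' Log-transform TPM values and collapse duplicate genes
#'
#' Applies log2(TPM + 1) to every entry and then averages rows that share a
#' gene identifier (arithmetic mean on the log scale), so the result has
#' unique gene ids.
#'
#' @param x an [expr_matrix()] on the `"tpm"` scale.
#' @return an `expr_matrix` on the `"log2_tpm1"` scale with unique gene ids.
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "tpm") stop("input must be on the tpm scale")
  v <- log2(x$values + 1)
  ids <- rownames(v)
  if (anyDuplicated(ids)) {
    # mean after transform: rowsum over duplicate ids / multiplicity,
    # keeping first-occurrence order
    first <- !duplicated(ids)
    counts <- table(ids)
    v <- rowsum(v, group = ids, reorder = FALSE)
    v <- v / as.vector(counts[rownames(v)])
    v <- v[ids[first], , drop = FALSE]
  }
  expr_matrix(v, scale = "log2_tpm1", meta = x$meta)
}

#' Remove unexpressed and low-variance genes
#'
#' Two-stage filter on a log-scale matrix: first drops every gene whose
#' fraction of zero-valued samples is at least `zero_frac_remove`
#' (inclusive boundary; a TPM of exactly 0 counts as "not expressed"), then
#' ranks the surviving genes by variance and drops the
#' `floor(low_var_frac * n_remaining)` lowest-variance genes, with ties at
#' the cutoff broken by lexicographic gene id.
#'
#' @param x an `expr_matrix` on the `"log2_tpm1"` scale.
#' @param zero_frac_remove fraction of zero samples at or above which a gene
#'   is removed; in \[0, 1\].
#' @param low_var_frac fraction of the remaining (lowest-variance) genes to
#'   remove; in \[0, 1\].
#' @return the filtered `expr_matrix`, with an attribute `"filter_report"`:
#'   a list with `n_zero_removed` and `n_low_var_removed`.
#' @export
filter_genes <- function(x, zero_frac_remove = 0.8, low_var_frac = 0.2) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2_tpm1") stop("input must be on the log2_tpm1 scale")
  if (!is.numeric(zero_frac_remove) || zero_frac_remove < 0 ||
      zero_frac_remove > 1) {
    stop("`zero_frac_remove` must lie in [0, 1]")
  }
  if (!is.numeric(low_var_frac) || low_var_frac < 0 || low_var_frac > 1) {
    stop("`low_var_frac` must lie in [0, 1]")
  }
  v <- x$values
  zero_frac <- rowMeans(v == 0)
  keep1 <- zero_frac < zero_frac_remove
  n_zero_removed <- sum(!keep1)
  v <- v[keep1, , drop = FALSE]

  n_drop <- floor(low_var_frac * nrow(v))
  if (n_drop > 0L) {
    vars <- apply(v, 1L, stats::var)
    ord <- order(vars, rownames(v))   # ascending variance, ties by gene id
    v <- v[sort(ord[-seq_len(n_drop)]), , drop = FALSE]
  }
  out <- expr_matrix(v, scale = "log2_tpm1", meta = x$meta)
  attr(out, "filter_report") <- list(n_zero_removed = n_zero_removed,
                                     n_low_var_removed = n_drop)
  out
}

#' Merge tumor and cell-line cohorts on shared genes and diseases
#'
#' Restricts both matrices to the intersection of their gene lists (sorted)
#' and to samples whose disease code occurs in both cohorts, then joins them
#' into one labeled matrix.
#'
#' @param tumor,cellline `expr_matrix` objects on the `"log2_tpm1"` scale,
#'   each carrying sample metadata (cohort, disease code).
#' @return a merged `expr_matrix` whose `meta` carries the cohort label per
#'   sample, with attribute `"harmonize_report"` listing the numbers of
#'   dropped genes and samples per cohort and the retained disease codes.
#' @export
harmonize_cohorts <- function(tumor, cellline) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(cellline, "expr_matrix"))
  if (tumor$scale != "log2_tpm1" || cellline$scale != "log2_tpm1") {
    stop("both cohorts must be on the log2_tpm1 scale")
  }
  if (is.null(tumor$meta) || is.null(cellline$meta)) {
    stop("both cohorts need sample metadata")
  }
  genes <- sort(intersect(gene_ids(tumor), gene_ids(cellline)))
  if (length(genes) == 0L) stop("gene intersection of the two cohorts is empty")
  diseases <- sort(intersect(tumor$meta$disease_code,
                             cellline$meta$disease_code))
  if (length(diseases) == 0L) {
    stop("no disease code occurs in both cohorts")
  }
  ts <- tumor$meta$sample_id[tumor$meta$disease_code %in% diseases]
  cs <- cellline$meta$sample_id[cellline$meta$disease_code %in% diseases]
  v <- cbind(tumor$values[genes, ts, drop = FALSE],
             cellline$values[genes, cs, drop = FALSE])
  meta <- rbind(tumor$meta[match(ts, tumor$meta$sample_id), , drop = FALSE],
                cellline$meta[match(cs, cellline$meta$sample_id), ,
                              drop = FALSE])
  rownames(meta) <- NULL
  out <- expr_matrix(v, scale = "log2_tpm1", meta = meta)
  attr(out, "harmonize_report") <- list(
    diseases = diseases,
    n_genes_dropped_tumor = nrow(tumor$values) - length(genes),
    n_genes_dropped_cellline = nrow(cellline$values) - length(genes),
    n_samples_dropped_tumor = ncol(tumor$values) - length(ts),
    n_samples_dropped_cellline = ncol(cellline$values) - length(cs))
  out
}

#' Subset samples by non-silent mutation status
#'
#' Keeps exactly the samples carrying at least one non-silent variant
#' (`Variant_Classification != "Silent"`) in the queried gene. Samples
#' absent from the mutation table are treated as wild-type, as in MAF-style
#' files that only list observed variants.
#'
#' @param x an `expr_matrix`.
#' @param mut a mutation table: `data.frame` with columns `sample_id`,
#'   `gene_symbol`, `variant_classification` (see [read_maf()]).
#' @param gene_symbol gene to query, e.g. `"KRAS"`.
#' @return the subset `expr_matrix` (possibly with zero samples, in which
#'   case a warning is raised and `NULL` is returned).
#' @export
subset_by_mutation <- function(x, mut, gene_symbol) {
  stopifnot(inherits(x, "expr_matrix"), is.data.frame(mut))
  required <- c("sample_id", "gene_symbol", "variant_classification")
  if (!all(required %in% names(mut))) {
    stop("mutation table lacks columns: ",
         paste(setdiff(required, names(mut)), collapse = ", "))
  }
  if (!gene_symbol %in% mut$gene_symbol) {
    warning(sprintf("gene '%s' absent from the mutation table; empty subset",
                    gene_symbol))
    return(NULL)
  }
  hits <- mut[mut$gene_symbol == gene_symbol &
                mut$variant_classification != "Silent", , drop = FALSE]
  keep <- intersect(sample_ids(x), unique(hits$sample_id))
  if (length(keep) == 0L) {
    warning("no sample carries a non-silent mutation in ", gene_symbol)
    return(NULL)
  }
  subset_expr(x, samples = keep)
}

#' Partition genes into coding and lncRNA sets
#'
#' @param genes character vector of gene ids.
#' @param ann gene annotation `data.frame` with columns `gene_id` and
#'   `biotype` (`"coding"` or `"lncRNA"`); one row per gene.
#' @return list with elements `coding` and `lncRNA` (disjoint character
#'   vectors whose union is the annotated input) and `n_unannotated`.
#'   Unannotated genes are excluded with a warning.
#' @export
partition_by_biotype <- function(genes, ann) {
  stopifnot(is.character(genes), is.data.frame(ann))
  if (anyDuplicated(ann$gene_id)) stop("annotation has duplicate gene ids")
  idx <- match(genes, ann$gene_id)
  n_un <- sum(is.na(idx))
  if (n_un > 0L) {
    warning(sprintf("%d gene(s) without annotation excluded", n_un))
  }
  biotype <- ann$biotype[idx[!is.na(idx)]]
  annotated <- genes[!is.na(idx)]
  list(coding = annotated[biotype == "coding"],
       lncRNA = annotated[biotype == "lncRNA"],
       n_unannotated = n_un)
}
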