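#' Single-cell dataset container
#'
#' Genes-by-cells integer counts with per-cell QC metrics computed at
#' construction: number of genes detected and number of distinct
#' mitochondrial genes detected (plus percent of counts from them).
#'
#' @param counts nonnegative integer matrix, genes in rows, cells in
#'   columns, with dimnames.
#' @param sample_id character vector (or single value recycled) of sample
#'   ids per cell.
#' @param mito_genes character vector of mitochondrial gene ids, or `NULL`
#'   to flag genes by `mito_prefix`.
#' @param mito_prefix symbol prefix marking mitochondrial genes.
#' @return an object of class `sc_dataset`: list with `counts`,
#'   `cell_meta` (`cell_id`, `sample_id`, `n_genes`, `n_mito_genes`,
#'   `pct_mito`, later `cluster`, `cell_type`) and `gene_meta`
#'   (`gene_id`, `mito`).
#' @export
sc_dataset <- function(counts, sample_id = "sample1", mito_genes = NULL,
                       mito_prefix = "MT-") {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need gene row names and cell column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, ncol(counts))
  stopifnot(length(sample_id) == ncol(counts))
  mito <- if (is.null(mito_genes)) {
    startsWith(rownames(counts), mito_prefix)
  } else {
    rownames(counts) %in% mito_genes
  }
  detected <- counts > 0
  total <- colSums(counts)
  cell_meta <- data.frame(
    cell_id = colnames(counts), sample_id = as.character(sample_id),
    n_genes = colSums(detected),
    n_mito_genes = colSums(detected[mito, , drop = FALSE]),
    pct_mito = 100 * colSums(counts[mito, , drop = FALSE]) / pmax(total, 1),
    stringsAsFactors = FALSE)
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = data.frame(gene_id = rownames(counts),
                                        mito = mito,
                                        stringsAsFactors = FALSE)),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id))))
  invisible(x)
}

subset_cells <- function(d, keep) {
  out <- d
  out$counts <- d$counts[, keep, drop = FALSE]
  out$cell_meta <- d$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  out
}

#' QC-filter cells by detected genes and mitochondrial load
#'
#' Removes cells detecting more than `max_genes` genes and/or exceeding the
#' mitochondrial threshold. The default mitochondrial metric is the count
#' of distinct mitochondrial genes detected (`"n_genes"`); percent of
#' counts from mitochondrial genes (`"percent_counts"`) is also available.
#'
#' @param d an [sc_dataset()].
#' @param max_genes cells with `n_genes > max_genes` are removed.
#' @param mito_threshold cells with mito metric `> mito_threshold` are
#'   removed.
#' @param mito_metric `"n_genes"` or `"percent_counts"`.
#' @return the filtered `sc_dataset` with attribute `"qc_report"`: list
#'   with `n_removed_genes`, `n_removed_mito`, `n_removed` (cells can fail
#'   both criteria). All cells failing yields an empty dataset with a
#'   warning.
#' @export
qc_filter_cells <- function(d, max_genes = 5000, mito_threshold = 30,
                            mito_metric = c("n_genes", "percent_counts")) {
  stopifnot(inherits(d, "sc_dataset"))
  mito_metric <- match.arg(mito_metric)
  if (is.finite(mito_threshold) && !any(d$gene_meta$mito)) {
    stop("mitochondrial filtering requested but no mito gene is flagged")
  }
  metric <- switch(mito_metric, n_genes = d$cell_meta$n_mito_genes,
                   percent_counts = d$cell_meta$pct_mito)
  fail_genes <- d$cell_meta$n_genes > max_genes
  fail_mito <- metric > mito_threshold
  keep <- !(fail_genes | fail_mito)
  if (!any(keep)) warning("QC removed every cell")
  out <- subset_cells(d, keep)
  attr(out, "qc_report") <- list(n_removed_genes = sum(fail_genes),
                                 n_removed_mito = sum(fail_mito),
                                 n_removed = sum(!keep))
  out
}

# median-library-size scaling then log1p, the standard toolkit default
sc_lognorm <- function(counts) {
  lib <- colSums(counts)
  target <- stats::median(lib)
  log1p(sweep(counts, 2L, pmax(lib, 1), "/") * target)
}

#' Cluster cells and assign marker-based cell types
#'
#' Normalizes counts per cell (median library size, log1p), computes the
#' top principal components, builds a k-nearest-neighbor graph and applies
#' modularity-based community detection (Leiden, via igraph). Each cluster
#' is labeled with the marker set attaining the highest mean z-scored
#' expression over its cells, ties broken by marker-set name. Cluster ids
#' are contiguous from 0 in decreasing cluster-size order.
#'
#' @param d a filtered [sc_dataset()].
#' @param markers a [signature_set()] of cell-type marker genes.
#' @param n_pcs number of principal components (reduced with a warning if
#'   the dataset is smaller).
#' @param k_neighbors neighbors for the kNN graph.
#' @param resolution community-detection resolution.
#' @param seed integer seed (community detection is stochastic).
#' @return the `sc_dataset` with `cluster` (integer from 0) and
#'   `cell_type` columns added to `cell_meta`, and attribute
#'   `"cluster_types"` (named character vector: cluster -> label).
#' @export
cluster_and_type <- function(d, markers, n_pcs = 40, k_neighbors = 15,
                             resolution = 1, seed = 0L) {
  stopifnot(inherits(d, "sc_dataset"), inherits(markers, "signature_set"))
  n_cells <- ncol(d$counts)
  if (n_cells < 3L) stop("too few cells to cluster")
  ln <- sc_lognorm(d$counts)
  max_pcs <- min(n_cells - 1L, nrow(ln) - 1L)
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs reduced from %d to %d (dataset size)", n_pcs,
                    max_pcs))
    n_pcs <- max_pcs
  }
  keep <- apply(ln, 1L, stats::sd) > 0
  pcs <- stats::prcomp(t(ln[keep, , drop = FALSE]), center = TRUE,
                       scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  k <- min(k_neighbors, n_cells - 1L)
  dm <- as.matrix(stats::dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    nn <- order(dm[i, ])[2:(k + 1L)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  raw <- igraph::membership(comm)
  # contiguous ids from 0, largest cluster first (ties by first appearance)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- unname(relabel[as.character(raw)])

  z <- t(scale(t(ln[keep, , drop = FALSE])))
  z[!is.finite(z)] <- 0
  labels <- vapply(sort(unique(cluster)), function(cl) {
    cells <- cluster == cl
    score <- vapply(names(markers$sets), function(nm) {
      genes <- intersect(markers$sets[[nm]], rownames(z))
      if (length(genes) == 0L) return(-Inf)
      mean(z[genes, cells, drop = FALSE])
    }, numeric(1))
    names(score)[order(-score, names(score))][1L]
  }, character(1))
  d$cell_meta$cluster <- cluster
  d$cell_meta$cell_type <- labels[cluster + 1L]
  attr(d, "cluster_types") <- stats::setNames(labels,
                                              sort(unique(cluster)))
  d
}

#' Top up-regulated genes by one-sided rank-sum test
#'
#' Per-gene Wilcoxon rank-sum test of group A greater than group B on
#' normalized log counts; genes are ranked by p ascending, ties broken by
#' effect size (mean log difference, descending) and then gene id, and the
#' top `top_n` are returned. Exact p-values are used for small tie-free
#' comparisons, the tie-corrected normal approximation otherwise.
#'
#' @param d an [sc_dataset()].
#' @param cells_a,cells_b logical or character index of the two cell groups
#'   (each with at least 3 cells).
#' @param top_n number of genes to return.
#' @return `data.frame` with columns `gene`, `p`, `q` (BH over all genes),
#'   `effect` (mean A - mean B on the log scale), sorted; top `top_n` rows.
#' @export
rank_sum_top_genes <- function(d, cells_a, cells_b, top_n = 100) {
  stopifnot(inherits(d, "sc_dataset"))
  ln <- sc_lognorm(d$counts)
  a <- ln[, cells_a, drop = FALSE]
  b <- ln[, cells_b, drop = FALSE]
  if (ncol(a) < 3L || ncol(b) < 3L) stop("both groups need >= 3 cells")
  res <- rank_sum_matrix(a, b)
  out <- data.frame(gene = rownames(ln), p = res$p,
                    q = stats::p.adjust(res$p, method = "BH"),
                    effect = rowMeans(a) - rowMeans(b),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$effect, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

# vectorized one-sided (A > B) rank-sum p-values over the rows of two
# matrices; exact null when tie-free and cheap, else normal approximation
rank_sum_matrix <- function(a, b, exact_max = 400) {
  n1 <- ncol(a); n2 <- ncol(b)
  p <- numeric(nrow(a))
  for (g in seq_len(nrow(a))) {
    x <- a[g, ]; y <- b[g, ]
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties && n1 * n2 <= exact_max) {
      p[g] <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      mu <- n1 * n2 / 2
      tt <- table(c(x, y))
      n <- n1 + n2
      s2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
      if (s2 <= 0) { p[g] <- 1; next }
      p[g] <- stats::pnorm((U - mu - 0.5) / sqrt(s2), lower.tail = FALSE)
    }
  }
  list(p = p)
}

#' Signature set container
#'
#' @param sets named list of non-empty character vectors (gene ids), e.g.
#'   molecular-subtype programs or cell-type markers.
#' @return an object of class `signature_set`.
#' @export
signature_set <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("signature names must be unique and non-empty")
  }
  if (any(lengths(sets) == 0L)) stop("every signature must be non-empty")
  structure(list(sets = lapply(sets, function(s) unique(as.character(s)))),
            class = "signature_set")
}

#' Per-sample signature enrichment of top gene lists
#'
#' Hypergeometric upper-tail enrichment of each sample's top-gene list in
#' each signature (signatures intersected with the universe first),
#' returned as a samples-by-signatures matrix of -log10 p.
#'
#' @param top_genes named list of character vectors: top differentially
#'   expressed genes per sample.
#' @param signatures a [signature_set()].
#' @param universe background gene ids.
#' @return numeric matrix (samples x signatures) of -log10 p-values, with
#'   attribute `"p"` holding the raw p-value matrix.
#' @export
signature_enrichment <- function(top_genes, signatures, universe) {
  stopifnot(is.list(top_genes), inherits(signatures, "signature_set"))
  universe <- unique(as.character(universe))
  sig <- lapply(signatures$sets, intersect, y = universe)
  p <- matrix(NA_real_, length(top_genes), length(sig),
              dimnames = list(names(top_genes), names(sig)))
  for (s in seq_along(top_genes)) {
    query <- intersect(unique(top_genes[[s]]), universe)
    for (j in seq_along(sig)) {
      k <- length(intersect(query, sig[[j]]))
      p[s, j] <- hypergeom_pvalue(k, length(query), length(sig[[j]]),
                                  length(universe))
    }
  }
  out <- -log10(p)
  attr(out, "p") <- p
  out
}
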