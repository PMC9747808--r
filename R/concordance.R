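#' Two-sided Mann-Whitney comparison of two groups
#'
#' Computes the Mann-Whitney U statistic (number of (x, y) pairs with
#' x > y, ties counted 1/2) and a two-sided p-value. The exact null
#' distribution is used when `n1 * n2 <= exact_max` and no ties are
#' present; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param feature optional feature name carried into the result.
#' @param exact_max largest `n1 * n2` for which the exact distribution is
#'   used.
#' @return an object of class `group_comparison`: list with `feature`,
#'   `n1`, `n2`, `U` (for the first group), `p`, `direction` (`"x"`,
#'   `"y"` or `"tie"`, by group median), `stars` and `method`.
#' @export
mannwhitney_compare <- function(x, y, feature = "", exact_max = 400) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 * n2 <= exact_max) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    zval <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zval)))
    method <- "normal_approx"
  }
  mx <- stats::median(x); my <- stats::median(y)
  direction <- if (mx > my) "x" else if (my > mx) "y" else "tie"
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  structure(list(feature = feature, n1 = n1, n2 = n2, U = U, p = p,
                 direction = direction, stars = stars, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney %s: U = %g, p = %.4g %s (higher: %s; %s)\n",
              x$feature, x$U, x$p, x$stars, x$direction, x$method))
  invisible(x)
}

#' Per-disease pairwise Spearman correlation over pathway genes
#'
#' For each disease present in both cohorts, computes the Spearman
#' correlation of the pathway-gene expression vectors for every
#' (tumor sample, cell-line sample) pair, summarizing each disease by its
#' mean correlation. Diseases are returned sorted by mean correlation
#' descending (ties by disease code).
#'
#' @param tumor,cellline `expr_matrix` objects with sample metadata.
#' @param pathway_genes character vector of gene ids; genes missing from
#'   either matrix are dropped with a warning, and fewer than 3 shared
#'   genes is an error.
#' @return list with `pairs` (long `data.frame`: disease, tumor_sample,
#'   cellline_sample, rho) and `summary` (`data.frame`: disease, n_pairs,
#'   mean_rho, sorted).
#' @export
pairwise_pathway_correlation <- function(tumor, cellline, pathway_genes) {
  stopifnot(inherits(tumor, "expr_matrix"), inherits(cellline, "expr_matrix"))
  if (is.null(tumor$meta) || is.null(cellline$meta)) {
    stop("both cohorts need sample metadata")
  }
  shared <- intersect(pathway_genes,
                      intersect(gene_ids(tumor), gene_ids(cellline)))
  if (length(shared) < length(unique(pathway_genes))) {
    warning(sprintf("%d pathway gene(s) missing from the matrices dropped",
                    length(unique(pathway_genes)) - length(shared)))
  }
  if (length(shared) < 3L) {
    stop("fewer than 3 shared pathway genes; correlation is degenerate")
  }
  diseases <- sort(intersect(tumor$meta$disease_code,
                             cellline$meta$disease_code))
  pairs <- lapply(diseases, function(d) {
    ts <- tumor$meta$sample_id[tumor$meta$disease_code == d]
    cs <- cellline$meta$sample_id[cellline$meta$disease_code == d]
    tv <- apply(tumor$values[shared, ts, drop = FALSE], 2L, rank)
    cv <- apply(cellline$values[shared, cs, drop = FALSE], 2L, rank)
    rho <- stats::cor(tv, cv)   # Pearson of ranks = Spearman
    data.frame(disease = d,
               tumor_sample = rep(ts, times = length(cs)),
               cellline_sample = rep(cs, each = length(ts)),
               rho = as.vector(rho), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  agg <- stats::aggregate(rho ~ disease, data = pairs, FUN = mean)
  names(agg)[2] <- "mean_rho"
  agg$n_pairs <- stats::aggregate(rho ~ disease, data = pairs,
                                  FUN = length)$rho
  agg <- agg[order(-agg$mean_rho, agg$disease), , drop = FALSE]
  rownames(agg) <- NULL
  list(pairs = pairs, summary = agg)
}

#' Mutation frequency per disease
#'
#' Fraction of each disease's samples carrying at least one non-silent
#' variant in the queried gene; samples absent from the table count as
#' wild-type.
#'
#' @param mut mutation table (`sample_id`, `gene_symbol`,
#'   `variant_classification`).
#' @param meta sample metadata (`sample_id`, `disease_code`).
#' @param gene_symbol gene to query.
#' @return named numeric vector of frequencies keyed by disease code.
#' @export
mutation_frequency <- function(mut, meta, gene_symbol) {
  stopifnot(is.data.frame(mut), is.data.frame(meta))
  hits <- unique(mut$sample_id[mut$gene_symbol == gene_symbol &
                                 mut$variant_classification != "Silent"])
  mutated <- meta$sample_id %in% hits
  tapply(mutated, meta$disease_code, mean)
}

#' Correlation of per-disease mutation burden with concordance
#'
#' Spearman correlation (with two-sided p) between a per-disease mutation
#' frequency vector and a per-disease mean tumor/cell-line correlation
#' vector, matched by disease code.
#'
#' @param burden named numeric vector of mutation frequencies per disease.
#' @param concordance named numeric vector of mean correlations per
#'   disease; names must match `burden` as a set, with at least 3 diseases.
#' @return list with `rho`, `p` and `n`.
#' @export
burden_vs_concordance <- function(burden, concordance) {
  if (is.null(names(burden)) || is.null(names(concordance))) {
    stop("both vectors must be named by disease code")
  }
  if (!setequal(names(burden), names(concordance)) ||
      length(burden) != length(concordance)) {
    stop("disease codes of the two vectors do not match")
  }
  if (length(burden) < 3L) stop("at least 3 diseases are required")
  concordance <- concordance[names(burden)]
  ct <- suppressWarnings(
    stats::cor.test(burden, concordance, method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(burden))
}
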