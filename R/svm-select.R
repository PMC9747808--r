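#' Rank genes by linear-SVM weight magnitude on one resampled split
#'
#' Draws a seeded, cohort-stratified 80/20 train/test split, standardizes
#' each gene using the training-split mean and SD, fits an L2-regularized
#' linear hinge-loss (maximum-margin) classifier, and ranks genes by the
#' magnitude of their weight-vector coefficients (rank 1 = largest |w|,
#' ties broken by gene id). The held-out accuracy on the 20% split is
#' recorded alongside the ranking.
#'
#' @param x a merged, labeled `expr_matrix` (see [harmonize_cohorts()]), or
#'   a plain genes-by-samples matrix if `labels` is given.
#' @param labels optional two-level factor/character vector of cohort labels
#'   per sample; defaults to `x$meta$cohort`.
#' @param seed integer seed for the split.
#' @param train_frac fraction of each class assigned to the training split.
#' @param cost SVM regularization constant C.
#' @param class_weights `"balanced"` (weights inversely proportional to
#'   class size), `NULL` for none, or a named numeric vector.
#' @param standardize standardize each gene on train-split statistics
#'   before fitting.
#' @return an object of class `feature_ranking`: list with `seed`, `abs_w`
#'   (named, per gene), `rank` (permutation of 1..G), `accuracy`,
#'   `train_samples`, `test_samples`.
#' @export
rank_features_single_split <- function(x, labels = NULL, seed = 1L,
                                       train_frac = 0.8, cost = 1,
                                       class_weights = "balanced",
                                       standardize = TRUE) {
  prep <- labeled_matrix(x, labels)
  v <- prep$values; y <- prep$labels
  split <- stratified_split(y, train_frac = train_frac, seed = seed)
  tr <- split$train; te <- split$test
  if (min(table(y[tr])) < 2L) stop("a class has <2 training samples")

  xt <- t(v[, tr, drop = FALSE])   # samples x genes
  xe <- t(v[, te, drop = FALSE])
  if (standardize) {
    mu <- colMeans(xt)
    sdv <- apply(xt, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xt <- sweep(sweep(xt, 2L, mu), 2L, sdv, "/")
    xe <- sweep(sweep(xe, 2L, mu), 2L, sdv, "/")
  }
  cw <- NULL
  if (identical(class_weights, "balanced")) {
    tab <- table(y[tr])
    cw <- stats::setNames(as.numeric(length(tr) / (2 * tab)), names(tab))
  } else if (is.numeric(class_weights)) {
    cw <- class_weights
  }
  fit <- e1071::svm(xt, y[tr], kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  w <- drop(crossprod(fit$coefs, fit$SV))
  abs_w <- stats::setNames(abs(as.numeric(w)), colnames(xt))
  ord <- order(-abs_w, names(abs_w))
  rank <- integer(length(abs_w))
  rank[ord] <- seq_along(ord)
  names(rank) <- names(abs_w)
  acc <- mean(stats::predict(fit, xe) == y[te])
  structure(list(seed = seed, abs_w = abs_w, rank = rank, accuracy = acc,
                 train_samples = colnames(v)[tr], test_samples = colnames(v)[te]),
            class = "feature_ranking")
}

labeled_matrix <- function(x, labels) {
  if (inherits(x, "expr_matrix")) {
    v <- x$values
    if (is.null(labels)) {
      if (is.null(x$meta)) stop("no labels supplied and no sample metadata")
      labels <- x$meta$cohort
    }
  } else {
    v <- x
    if (is.null(labels)) stop("labels required for a plain matrix")
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  if (length(labels) != ncol(v)) stop("one label per sample is required")
  list(values = v, labels = labels)
}

stratified_split <- function(y, train_frac, seed) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- floor(train_frac * length(idx))
    if (n_tr < 1L || n_tr >= length(idx)) {
      stop("class '", lev, "' cannot be split ", train_frac, "/",
           1 - train_frac)
    }
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Stability selection over resampled SVM rankings
#'
#' Repeats [rank_features_single_split()] on `n_splits` independently
#' resampled splits (split seeds derived deterministically from
#' `master_seed`), takes each split's top `ceil(top_frac * G)` genes by
#' weight magnitude, and merges the per-split top sets by intersection
#' (default: genes in the top fraction of *every* split) or union.
#'
#' @inheritParams rank_features_single_split
#' @param n_splits number of resampled splits.
#' @param top_frac fraction of genes kept per split.
#' @param merge_rule `"intersection"` or `"union"`.
#' @param master_seed integer master seed; split seeds are drawn from it.
#' @param ... passed on to [rank_features_single_split()].
#' @return an object of class `stable_feature_set`: list with `genes`
#'   (sorted), `n_splits`, `top_frac`, `merge_rule`, `master_seed`,
#'   `accuracies`, `k` (per-split top-set size) and `n_top_splits` (per
#'   selected gene, in how many splits it made the top fraction).
#' @export
stable_feature_set <- function(x, labels = NULL, n_splits = 50,
                               top_frac = 0.10,
                               merge_rule = c("intersection", "union"),
                               master_seed = 1L, ...) {
  merge_rule <- match.arg(merge_rule)
  stopifnot(n_splits >= 1L, top_frac > 0, top_frac <= 1)
  prep <- labeled_matrix(x, labels)
  G <- nrow(prep$values)
  k <- ceiling(top_frac * G)
  seeds <- derive_seeds(master_seed, n_splits)
  top_sets <- vector("list", n_splits)
  accuracies <- numeric(n_splits)
  for (i in seq_len(n_splits)) {
    r <- rank_features_single_split(prep$values, prep$labels,
                                    seed = seeds[i], ...)
    top_sets[[i]] <- names(r$rank)[r$rank <= k]
    accuracies[i] <- r$accuracy
  }
  genes <- switch(merge_rule,
                  intersection = Reduce(intersect, top_sets),
                  union = Reduce(union, top_sets))
  if (merge_rule == "intersection" && length(genes) == 0L) {
    warning("the intersection of per-split top sets is empty")
  }
  counts <- table(unlist(top_sets))
  genes <- sort(genes)
  structure(list(genes = genes, n_splits = n_splits, top_frac = top_frac,
                 merge_rule = merge_rule, master_seed = master_seed,
                 accuracies = accuracies, k = k,
                 n_top_splits = stats::setNames(as.integer(counts[genes]),
                                                genes)),
            class = "stable_feature_set")
}

# Split seeds drawn without replacement so the first m of n are shared by
# any run with the same master seed (nested seed sequences).
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.stable_feature_set <- function(x, ...) {
  cat(sprintf(
    "stable_feature_set: %d genes (%s of %d splits, top %.0f%%), accuracy %.3f-%.3f\n",
    length(x$genes), x$merge_rule, x$n_splits, 100 * x$top_frac,
    min(x$accuracies), max(x$accuracies)))
  invisible(x)
}

#' Build an immune blocklist from first-pass enrichment
#'
#' Among the `top_n` pathways ranked by enrichment p-value, takes those
#' significant at `q < alpha` whose category is `"immune"` and returns the
#' union of their member genes restricted to the dataset's genes.
#'
#' @param enr an `enrichment_result` computed on the first-pass stable set.
#' @param coll the [pathway_collection()] used for `enr`.
#' @param dataset_genes character vector of genes present in the dataset.
#' @param top_n window of top pathways (by p) considered.
#' @param alpha FDR threshold.
#' @param category category label treated as immune.
#' @return list with `genes` (sorted) and `provenance` (contributing
#'   pathway names). Empty blocklist yields a message, not an error.
#' @export
build_immune_blocklist <- function(enr, coll, dataset_genes, top_n = 100,
                                   alpha = 0.05, category = "immune") {
  stopifnot(inherits(enr, "enrichment_result"),
            inherits(coll, "pathway_collection"))
  window <- utils::head(enr, top_n)
  hit <- window$pathway[window$significant & window$category == category]
  if (length(hit) == 0L) {
    message("no enriched immune pathway; empty blocklist")
    return(list(genes = character(0), provenance = character(0)))
  }
  genes <- sort(intersect(unique(unlist(coll$sets[hit])), dataset_genes))
  list(genes = genes, provenance = hit)
}

#' Two-pass stability selection with immune-blocklist removal
#'
#' Pass 1 runs stability selection on all genes; the pass-1 set is tested
#' for pathway over-representation; the genes of every enriched immune
#' pathway form a blocklist; pass 2 reruns the selection with blocklisted
#' genes removed from the matrix. The final set is therefore disjoint from
#' the blocklist by construction.
#'
#' @inheritParams stable_feature_set
#' @param coll a [pathway_collection()] with category labels.
#' @param universe background gene set for the enrichment step; defaults to
#'   all genes in `x`.
#' @param alpha FDR threshold for the enrichment/blocklist step.
#' @param top_n_pathways window of top pathways scanned for immune sets.
#' @param ... passed on to [stable_feature_set()].
#' @return list of class `two_pass_selection` with `final` and `pass1`
#'   (both `stable_feature_set`), `blocklist`, and `enrichment` (the pass-1
#'   `enrichment_result`).
#' @export
two_pass_selection <- function(x, labels = NULL, coll, universe = NULL,
                               n_splits = 50, top_frac = 0.10,
                               master_seed = 1L, alpha = 0.05,
                               top_n_pathways = 100, ...) {
  prep <- labeled_matrix(x, labels)
  if (is.null(universe)) universe <- rownames(prep$values)
  pass1 <- stable_feature_set(prep$values, prep$labels, n_splits = n_splits,
                              top_frac = top_frac, master_seed = master_seed,
                              ...)
  enr <- enrich_collection(pass1$genes, coll, universe, alpha = alpha)
  blocklist <- build_immune_blocklist(enr, coll, rownames(prep$values),
                                      top_n = top_n_pathways, alpha = alpha)
  keep <- setdiff(rownames(prep$values), blocklist$genes)
  if (length(keep) == 0L) stop("blocklist removes every gene in the dataset")
  pass2 <- stable_feature_set(prep$values[keep, , drop = FALSE], prep$labels,
                              n_splits = n_splits, top_frac = top_frac,
                              master_seed = master_seed, ...)
  structure(list(final = pass2, pass1 = pass1, blocklist = blocklist,
                 enrichment = enr),
            class = "two_pass_selection")
}

#' Write a stability-selection summary table
#'
#' TSV with one row per gene that entered any split's top fraction: mean
#' weight magnitude, number of splits in the top fraction, and final-set
#' membership. A JSON run manifest (seeds, parameters, accuracies) is
#' written alongside.
#'
#' @param sfs a `stable_feature_set`.
#' @param path output TSV path; the manifest is written to
#'   `sub(".tsv", "_manifest.json", path)`.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(sfs, path) {
  df <- data.frame(gene = sfs$genes,
                   n_top_splits = sfs$n_top_splits,
                   in_final_set = TRUE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(master_seed = sfs$master_seed, n_splits = sfs$n_splits,
                   top_frac = sfs$top_frac, merge_rule = sfs$merge_rule,
                   k = sfs$k, accuracies = sfs$accuracies)
  jsonlite::write_json(manifest, sub("\\.tsv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
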