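#' miRNA matrix container
#'
#' Features-by-samples quantification (sequencing counts or probe
#' intensities) with per-sample batch and cohort labels.
#'
#' @param values nonnegative numeric matrix, miRNA in rows, samples in
#'   columns, with dimnames.
#' @param batch character/factor of batch labels, one per sample.
#' @param cohort character/factor of cohort labels (`"tumor"` /
#'   `"cell_line"`), one per sample.
#' @param log_scale whether `values` are already log2(x + 1) transformed.
#' @return an object of class `mirna_matrix`.
#' @export
mirna_matrix <- function(values, batch, cohort, log_scale = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values need miRNA row names and sample column names")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (!log_scale && any(values < 0)) stop("raw quantifications must be >= 0")
  batch <- as.character(batch); cohort <- as.character(cohort)
  if (length(batch) != ncol(values) || length(cohort) != ncol(values)) {
    stop("one batch and one cohort label per sample is required")
  }
  if (any(!nzchar(batch))) stop("batch labels must be non-empty")
  structure(list(values = values, batch = batch, cohort = cohort,
                 log_scale = log_scale), class = "mirna_matrix")
}

#' Harmonize and merge two miRNA matrices
#'
#' Normalizes identifiers on both matrices ([normalize_mirna_id()] plus an
#' optional alias map), averages duplicate rows (on the raw scale), joins
#' the matrices on the identifier intersection, and applies log2(x + 1).
#'
#' @param a,b `mirna_matrix` objects on the raw scale.
#' @param alias_map optional named character vector of id aliases.
#' @return a merged, log-scale `mirna_matrix` with attribute
#'   `"n_shared"` (size of the id intersection).
#' @export
prepare_mirna <- function(a, b, alias_map = NULL) {
  stopifnot(inherits(a, "mirna_matrix"), inherits(b, "mirna_matrix"))
  if (a$log_scale || b$log_scale) stop("inputs must be on the raw scale")
  norm_one <- function(m) {
    v <- m$values
    rownames(v) <- normalize_mirna_id(rownames(v), alias_map)
    if (anyDuplicated(rownames(v))) {
      ids <- rownames(v)
      counts <- table(ids)
      v <- rowsum(v, group = ids, reorder = FALSE)
      v <- v / as.vector(counts[rownames(v)])
    }
    v
  }
  va <- norm_one(a); vb <- norm_one(b)
  shared <- sort(intersect(rownames(va), rownames(vb)))
  if (length(shared) == 0L) stop("no miRNA identifier shared after harmonization")
  v <- log2(cbind(va[shared, , drop = FALSE], vb[shared, , drop = FALSE]) + 1)
  out <- mirna_matrix(v, batch = c(a$batch, b$batch),
                      cohort = c(a$cohort, b$cohort), log_scale = TRUE)
  attr(out, "n_shared") <- length(shared)
  out
}

#' Empirical-Bayes location-scale batch correction
#'
#' Parametric empirical-Bayes adjustment of per-feature batch effects in
#' the style long established for expression microarrays: each feature is
#' standardized against its grand mean and pooled variance (optionally
#' after removing group means supplied via `group`), per-batch additive
#' (gamma) and multiplicative (delta) effects are estimated and shrunk
#' toward batch-level priors (normal prior on gamma, inverse-gamma on
#' delta, solved iteratively), the shrunk effects are subtracted/rescaled,
#' and each feature's grand mean and pooled variance are restored exactly.
#'
#' With a single batch the input is returned unchanged.
#'
#' @param m a log-scale `mirna_matrix`, or a plain features-by-samples
#'   matrix if `batch` is given.
#' @param batch batch labels (defaults to `m$batch`).
#' @param group optional biological group labels (e.g. cohort) whose mean
#'   differences are preserved: batch effects are estimated on residuals
#'   from group means. Requires batches and groups not to be confounded.
#' @return an object like `m` with corrected values, carrying attribute
#'   `"batch_model"`: list with `gamma_star`, `delta_star` (features x
#'   batches), `shrinkage` hyperparameters and `grand_mean`/`pooled_sd`.
#' @export
eb_batch_correct <- function(m, batch = NULL, group = NULL) {
  is_container <- inherits(m, "mirna_matrix")
  v <- if (is_container) m$values else m
  if (is_container && is.null(batch)) batch <- m$batch
  stopifnot(is.matrix(v), !is.null(batch), length(batch) == ncol(v))
  batch <- factor(batch)
  if (nlevels(batch) < 2L) {
    message("single batch: nothing to correct")
    return(m)
  }
  if (min(table(batch)) < 2L) stop("every batch needs >= 2 samples")

  # joint two-way fit: per-batch intercepts plus (optional) group effects,
  # so batch estimates are not contaminated by unequal group composition
  bx <- stats::model.matrix(~ 0 + batch)
  design <- bx
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) >= 2L) {
      gx <- stats::model.matrix(~group)[, -1, drop = FALSE]
      design <- cbind(bx, gx)
      if (qr(design)$rank < ncol(design)) {
        stop("batch and group are confounded; effects are not separable")
      }
    }
  }
  beta <- t(solve(crossprod(design), crossprod(design, t(v))))
  nb <- nlevels(batch)
  n_per <- as.integer(table(batch))
  grand_mean <- drop(beta[, seq_len(nb), drop = FALSE] %*% (n_per / ncol(v)))
  fitted <- matrix(grand_mean, nrow(v), ncol(v))
  if (ncol(design) > nb) {
    extra <- seq.int(nb + 1L, ncol(design))
    fitted <- fitted + beta[, extra, drop = FALSE] %*%
      t(design[, extra, drop = FALSE])
  }
  pooled_sd <- sqrt(rowMeans((v - beta %*% t(design))^2))
  pooled_sd[pooled_sd == 0] <- 1
  z <- (v - fitted) / pooled_sd

  nb <- nlevels(batch)
  gamma_hat <- matrix(0, nrow(v), nb, dimnames = list(rownames(v),
                                                      levels(batch)))
  delta_hat <- gamma_hat
  for (j in seq_len(nb)) {
    zi <- z[, batch == levels(batch)[j], drop = FALSE]
    gamma_hat[, j] <- rowMeans(zi)
    delta_hat[, j] <- apply(zi, 1L, stats::var)
  }
  delta_hat[delta_hat <= 0 | !is.finite(delta_hat)] <- 1e-8

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  shrinkage <- vector("list", nb)
  names(shrinkage) <- levels(batch)
  n_per <- as.integer(table(batch))
  for (j in seq_len(nb)) {
    sol <- eb_prior_solve(z[, batch == levels(batch)[j], drop = FALSE],
                          gamma_hat[, j], delta_hat[, j], n_per[j])
    gamma_star[, j] <- sol$gamma_star
    delta_star[, j] <- sol$delta_star
    shrinkage[[j]] <- sol$prior
  }

  adj <- z
  for (j in seq_len(nb)) {
    sel <- batch == levels(batch)[j]
    adj[, sel] <- (z[, sel, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta_star[, j])
  }
  out <- fitted + adj * pooled_sd
  # restore each feature's grand mean and pooled residual variance exactly
  res2 <- out - fitted
  sd2 <- sqrt(rowMeans((res2 - rowMeans(res2))^2))
  sd2[sd2 == 0] <- 1
  out <- fitted + (res2 - rowMeans(res2)) / sd2 * pooled_sd

  model <- list(gamma_star = gamma_star, delta_star = delta_star,
                shrinkage = shrinkage, grand_mean = grand_mean,
                pooled_sd = pooled_sd)
  if (is_container) {
    res <- mirna_matrix(out, batch = m$batch, cohort = m$cohort,
                        log_scale = TRUE)
  } else {
    res <- out
  }
  attr(res, "batch_model") <- model
  res
}

# Parametric EB priors and the standard iterative joint solution for the
# shrunk location (normal prior) and scale (inverse-gamma prior) effects.
eb_prior_solve <- function(zb, g_hat, d_hat, n, tol = 1e-4, max_iter = 200L) {
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
  # inverse-gamma moments across features
  v_bar <- mean(d_hat)
  s2 <- stats::var(d_hat)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1e-8
  lambda <- (2 * s2 + v_bar^2) / s2
  theta <- (v_bar * s2 + v_bar^3) / s2

  g_star <- g_hat
  d_star <- d_hat
  ss <- rowSums(sweep(zb, 1L, g_hat)^2)
  for (it in seq_len(max_iter)) {
    g_new <- (n * t2 * g_hat + d_star * g_bar) / (n * t2 + d_star)
    sum2 <- ss + n * (g_hat - g_new)^2
    d_new <- (theta + 0.5 * sum2) / (n / 2 + lambda - 1)
    change <- max(abs(g_new - g_star) / (abs(g_star) + 1e-8),
                  abs(d_new - d_star) / (abs(d_star) + 1e-8))
    g_star <- g_new
    d_star <- d_new
    if (change < tol) break
  }
  d_star[d_star <= 0 | !is.finite(d_star)] <- 1e-8
  list(gamma_star = g_star, delta_star = d_star,
       prior = list(gamma_bar = g_bar, tau2 = t2, lambda = lambda,
                    theta = theta))
}

#' Directional log fold changes between cohorts
#'
#' Per-feature LFC on the log scale: mean over cell-line samples minus mean
#' over tumor samples, so a positive LFC means higher expression in cell
#' lines.
#'
#' @param m a log-scale `mirna_matrix`, or a plain matrix if `cohort` is
#'   given.
#' @param cohort cohort labels (defaults to `m$cohort`); must contain both
#'   `"tumor"` and `"cell_line"`.
#' @return `data.frame` of class `lfc_table` with columns `feature`, `lfc`,
#'   `mean_cell_line`, `mean_tumor`, `sign`, plus attribute `"counts"`
#'   (numbers of positive/negative/zero features).
#' @export
group_lfc <- function(m, cohort = NULL) {
  v <- if (inherits(m, "mirna_matrix")) m$values else m
  if (inherits(m, "mirna_matrix") && is.null(cohort)) cohort <- m$cohort
  stopifnot(is.matrix(v), length(cohort) == ncol(v))
  if (!all(c("tumor", "cell_line") %in% cohort)) {
    stop("both 'tumor' and 'cell_line' cohorts are required")
  }
  mc <- rowMeans(v[, cohort == "cell_line", drop = FALSE])
  mt <- rowMeans(v[, cohort == "tumor", drop = FALSE])
  lfc <- mc - mt
  out <- data.frame(feature = rownames(v), lfc = lfc, mean_cell_line = mc,
                    mean_tumor = mt, sign = sign(lfc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- c(positive = sum(lfc > 0), negative = sum(lfc < 0),
                           zero = sum(lfc == 0))
  class(out) <- c("lfc_table", "data.frame")
  out
}
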