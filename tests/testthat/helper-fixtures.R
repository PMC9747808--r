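# Small programmatic fixtures shared across test files.

toy_expr <- function(values, scale = "log2_tpm1", cohort = NULL,
                     disease = NULL) {
  if (is.null(cohort)) cohort <- rep("tumor", ncol(values))
  if (is.null(disease)) disease <- rep("BRCA", ncol(values))
  expr_matrix(values, scale = scale,
              meta = data.frame(sample_id = colnames(values),
                                cohort = cohort, disease_code = disease,
                                stringsAsFactors = FALSE))
}

named_matrix <- function(data, genes, samples) {
  matrix(data, length(genes), length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# a separable two-class expression matrix: `n_signal` genes carry a mean
# shift of `delta` between cohorts, the rest are noise
toy_labeled_cohort <- function(n_genes = 60, n_signal = 6, n1 = 40, n2 = 20,
                               delta = 3, sigma = 1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  v <- matrix(stats::rnorm(n_genes * (n1 + n2), 5, sigma), n_genes, n1 + n2,
              dimnames = list(genes, sprintf("s%03d", seq_len(n1 + n2))))
  labels <- rep(c("tumor", "cell_line"), c(n1, n2))
  v[seq_len(n_signal), labels == "cell_line"] <-
    v[seq_len(n_signal), labels == "cell_line"] - delta
  list(values = v, labels = labels, signal = genes[seq_len(n_signal)])
}
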