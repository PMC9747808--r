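test_that("log2(TPM+1) transform is applied entrywise and is monotone", {
  v <- named_matrix(c(0, 1, 3, 7), c("g1", "g2"), c("s1", "s2"))
  x <- expr_matrix(v, scale = "tpm")
  out <- normalize_expression(x)
  expect_equal(out$scale, "log2_tpm1")
  expect_equal(as.vector(out$values), c(0, 2, 1, 3))
  # monotone per entry
  v2 <- v + 1
  out2 <- normalize_expression(expr_matrix(v2, scale = "tpm"))
  expect_true(all(out2$values > out$values))
})

test_that("duplicate gene rows are averaged after the log transform", {
  # rows [1,3] and [3,1] on TPM scale -> log rows [1,2],[2,1] -> mean [1.5,1.5]
  v <- matrix(c(1, 3, 3, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("g", "g"), c("s1", "s2")))
  out <- normalize_expression(expr_matrix(v, scale = "tpm"))
  expect_equal(nrow(out$values), 1L)
  expect_equal(unname(out$values["g", ]), c(1.5, 1.5))
  # idempotent on already-unique genes: transform only, gene set unchanged
  v3 <- named_matrix(c(1, 3, 0, 7), c("a", "b"), c("s1", "s2"))
  out3 <- normalize_expression(expr_matrix(v3, scale = "tpm"))
  expect_identical(rownames(out3$values), c("a", "b"))
})

test_that("negative and empty inputs are rejected with coordinates", {
  v <- named_matrix(c(1, -2, 3, 4), c("g1", "g2"), c("s1", "s2"))
  expect_error(expr_matrix(v, scale = "tpm"), "g1.*s2|negative")
  expect_error(expr_matrix(matrix(numeric(0), 0, 0), scale = "tpm"), "empty")
})

test_that("zero-fraction filter removes at the inclusive boundary", {
  # gene zero in 8 of 10 samples is removed at zero_frac_remove = 0.8
  genes <- c("mostly_zero", "expressed")
  v <- rbind(c(rep(0, 8), 1, 2), seq(1, 10) / 2)
  dimnames(v) <- list(genes, sprintf("s%02d", 1:10))
  out <- filter_genes(toy_expr(v), zero_frac_remove = 0.8, low_var_frac = 0)
  expect_identical(rownames(out$values), "expressed")
  expect_equal(attr(out, "filter_report")$n_zero_removed, 1L)
})

test_that("variance filter removes floor(frac * remaining) lowest, ties by id", {
  set.seed(4)
  genes <- c("g1", "g2", "g3", "g4", "g5")
  v <- rbind(c(1, 1, 1, 1.1),          # lowest variance
             c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 5, 0, 5), c(1, 1, 5, 5))
  dimnames(v) <- list(genes, sprintf("s%d", 1:4))
  out <- filter_genes(toy_expr(v), zero_frac_remove = 1, low_var_frac = 0.2)
  expect_equal(nrow(out$values), 4L)        # floor(0.2 * 5) = 1 removed
  expect_false("g1" %in% rownames(out$values))
  # tie at the cutoff: identical variance rows, lexicographically first goes
  vt <- rbind(b_tied = c(1, 2, 1, 2), a_tied = c(2, 3, 2, 3),
              high = c(0, 9, 0, 9))
  colnames(vt) <- sprintf("s%d", 1:4)
  out2 <- filter_genes(toy_expr(vt), zero_frac_remove = 1, low_var_frac = 1 / 3)
  expect_false("a_tied" %in% rownames(out2$values))
  expect_true("b_tied" %in% rownames(out2$values))
})

test_that("filter is a no-op when configured off, rejects bad thresholds, and
           removal counts partition the gene set", {
  set.seed(5)
  v <- matrix(abs(rnorm(40)) + 0.1, 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  x <- toy_expr(v)
  expect_identical(filter_genes(x, 1, 0)$values, v)
  expect_error(filter_genes(x, 1.2, 0), "\\[0, 1\\]")
  expect_error(filter_genes(x, 0.8, -0.1), "\\[0, 1\\]")
  v[1, ] <- 0
  out <- filter_genes(toy_expr(v), 0.8, 0.3)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_zero_removed + rep$n_low_var_removed,
               nrow(v) - nrow(out$values))
  expect_true(all(rownames(out$values) %in% rownames(v)))
})

test_that("cohort harmonization intersects genes and diseases symmetrically", {
  vt <- named_matrix(rep(1, 9), c("a", "b", "c"),
                     c("t1", "t2", "t3"))
  vc <- named_matrix(rep(2, 6), c("b", "c", "d"), c("c1", "c2"))
  t <- toy_expr(vt, disease = c("BRCA", "GBM", "GBM"))
  c <- toy_expr(vc, cohort = rep("cell_line", 2), disease = c("GBM", "OV"))
  m <- harmonize_cohorts(t, c)
  expect_identical(rownames(m$values), c("b", "c"))
  expect_identical(sort(colnames(m$values)), c("c1", "t2", "t3"))
  expect_setequal(m$meta$cohort[match(c("t2", "c1"), m$meta$sample_id)],
                  c("tumor", "cell_line"))
  # symmetric gene intersection
  m2 <- harmonize_cohorts(c, t)
  expect_identical(rownames(m2$values), rownames(m$values))
  # identical structures: sample count is the sum of both cohorts
  c3 <- toy_expr(named_matrix(rep(1, 6), c("a", "b", "c"), c("x1", "x2")),
                 cohort = rep("cell_line", 2), disease = rep("BRCA", 2))
  t3 <- toy_expr(vt[, 1:2], disease = rep("BRCA", 2))
  expect_equal(ncol(harmonize_cohorts(t3, c3)$values), 4L)
  # empty intersections are rejected with diagnostics
  c4 <- toy_expr(named_matrix(rep(1, 2), "zzz", c("y1", "y2")),
                 cohort = rep("cell_line", 2), disease = rep("BRCA", 2))
  expect_error(harmonize_cohorts(t3, c4), "gene intersection")
  c5 <- toy_expr(vc, cohort = rep("cell_line", 2), disease = rep("XX", 2))
  expect_error(harmonize_cohorts(t, c5), "disease")
})

test_that("mutation subsetting keeps exactly non-silent carriers", {
  v <- named_matrix(rep(1, 10), c("g1", "g2"),
                    sprintf("s%d", 1:5))
  x <- toy_expr(v)
  mut <- data.frame(
    sample_id = c("s1", "s2", "s2", "s3", "s4"),
    gene_symbol = c("KRAS", "KRAS", "TP53", "KRAS", "KRAS"),
    variant_classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation", "Frame_Shift_Del",
                               "Splice_Site"),
    stringsAsFactors = FALSE)
  out <- subset_by_mutation(x, mut, "KRAS")
  expect_setequal(sample_ids(out), c("s1", "s3", "s4"))   # s2 only Silent
  # kept/dropped partition the sample space
  expect_setequal(c(sample_ids(out), setdiff(sample_ids(x), sample_ids(out))),
                  sample_ids(x))
  expect_warning(res <- subset_by_mutation(x, mut, "EGFR"), "absent")
  expect_null(res)
})

test_that("biotype partition is disjoint, complete, and reports unannotated", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    biotype = c("coding", "lncRNA", "coding"),
                    stringsAsFactors = FALSE)
  p <- partition_by_biotype(c("g1", "g2", "g3"), ann)
  expect_setequal(p$coding, c("g1", "g3"))
  expect_identical(p$lncRNA, "g2")
  expect_length(intersect(p$coding, p$lncRNA), 0)
  p2 <- partition_by_biotype(c("g1", "g3"), ann)
  expect_length(p2$lncRNA, 0)
  expect_warning(p3 <- partition_by_biotype(c("g1", "unknown"), ann),
                 "without annotation")
  expect_equal(p3$n_unannotated, 1L)
})

test_that("expression TSV and GCT dialects round-trip", {
  v <- named_matrix(c(0, 1.5, 2, 3), c("g1", "g2"), c("s1", "s2"))
  x <- expr_matrix(v, scale = "tpm")
  tsv <- tempfile(fileext = ".tsv")
  write_expression_tsv(x, tsv)
  back <- read_expression_tsv(tsv)
  expect_equal(back$values, v)
  # GCT: version and dims lines skipped, Description column dropped
  gct <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t2",
               "Name\tDescription\ts1\ts2",
               "g1\tna\t0\t1.5", "g2\tna\t2\t3"), gct)
  expect_equal(read_expression_tsv(gct)$values, v)
})

test_that("MAF reader maps the standard columns and rejects bad files", {
  maf <- tempfile(fileext = ".maf")
  writeLines(c("#version 2.4",
               "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode",
               "KRAS\tSilent\ts1", "TP53\tMissense_Mutation\ts2"), maf)
  mut <- read_maf(maf)
  expect_identical(mut$sample_id, c("s1", "s2"))
  expect_identical(mut$variant_classification[1], "Silent")
  bad <- tempfile()
  writeLines("a\tb", bad)
  expect_error(read_maf(bad), "lacks columns")
})
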