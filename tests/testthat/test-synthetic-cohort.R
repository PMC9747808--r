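small_cfg <- function(...) {
  synthetic_config(n_genes = 400, n_driver_pathways = 4,
                   driver_pathway_size = 10, control_pathway_size = 10,
                   immune_program_size = 15, n_decoy_pathways = 3,
                   decoy_pathway_size = 10, n_lnc = 20, n_lnc_planted = 8,
                   n_tumor = 60, n_cellline = 30, n_diseases = 3,
                   sc_n_genes = 200, sc_n_mito = 20, sc_program_size = 12,
                   sc_cells_per_tumor_sample = 60, sc_cells_cellline = 40,
                   ...)
}

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- small_cfg()
  b1 <- generate_bulk_cohort(cfg, seed = 5)
  b2 <- generate_bulk_cohort(cfg, seed = 5)
  expect_identical(b1$tumor$values, b2$tumor$values)
  expect_identical(b1$truth, b2$truth)
  s1 <- generate_sponge_system(cfg, seed = 5)
  s2 <- generate_sponge_system(cfg, seed = 5)
  expect_identical(s1$mirna_b$values, s2$mirna_b$values)
  c1 <- generate_sc_cohort(cfg, seed = 5)
  c2 <- generate_sc_cohort(cfg, seed = 5)
  expect_identical(c1$dataset$counts, c2$dataset$counts)
  # different seeds differ
  expect_false(identical(b1$tumor$values,
                         generate_bulk_cohort(cfg, seed = 6)$tumor$values))
})

test_that("emitted dimensions and annotations match the configuration", {
  cfg <- small_cfg()
  b <- generate_bulk_cohort(cfg, seed = 9)
  expect_equal(dim(b$tumor$values), c(400, 60))
  expect_equal(dim(b$cellline$values), c(400, 30))
  expect_equal(sum(b$annotation$biotype == "lncRNA"), 20)
  expect_equal(length(b$truth$planted_de), 40)
  expect_equal(length(b$truth$immune_genes), 15)
  expect_setequal(unique(b$tumor$meta$disease_code),
                  unique(b$cellline$meta$disease_code))
  # pathway collection holds drivers, control, immune program and decoys
  expect_equal(sum(b$pathways$categories == "cancer driver"), 5) # 4 + control
  expect_equal(sum(b$pathways$categories == "immune"), 1)
})

test_that("planted group-mean differences concentrate around -delta", {
  cfg <- small_cfg()
  b <- generate_bulk_cohort(cfg, seed = 21)
  t <- normalize_expression(b$tumor); c <- normalize_expression(b$cellline)
  diff <- rowMeans(c$values[b$truth$planted_de, ]) -
    rowMeans(t$values[b$truth$planted_de, ])
  se <- cfg$sigma * sqrt(1 / cfg$n_tumor + 1 / cfg$n_cellline)
  expect_true(all(abs(diff + cfg$delta) < 3 * se + 0.05))
  # immune program: tumor-only expression
  expect_true(all(b$cellline$values[b$truth$immune_genes, ] == 0))
  expect_gt(mean(b$tumor$values[b$truth$immune_genes, ] > 0), 0.99)
})

test_that("with delta = 0 the planted genes behave as null features", {
  cfg <- suppressWarnings(small_cfg(delta = 0))
  b <- suppressWarnings(generate_bulk_cohort(cfg, seed = 33))
  t <- normalize_expression(b$tumor)$values
  c <- normalize_expression(b$cellline)$values
  tstats <- vapply(b$truth$planted_de, function(g) {
    stats::t.test(c[g, ], t[g, ], var.equal = TRUE)$statistic
  }, numeric(1))
  ks <- stats::ks.test(tstats, "pt", df = cfg$n_tumor + cfg$n_cellline - 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("the sponge interaction tables bridge exactly the planted miRNA", {
  cfg <- small_cfg()
  sp <- generate_sponge_system(cfg, seed = 13)
  b <- generate_bulk_cohort(cfg, seed = 13)
  br <- bridge_mirna(sp$truth$planted_lnc, b$truth$planted_de,
                     sp$interactions)
  expect_setequal(br$mirna, sp$truth$bridging)
  # decoy miRNA never bridge
  expect_length(intersect(br$mirna, sp$truth$decoys), 0)
  # planted consistency fraction is honored
  expect_equal(length(sp$truth$consistent_up),
               round(cfg$sponge_consistency * cfg$n_bridging))
})

test_that("full consistency gives all-positive bridging LFC after correction
           and decoys stay null", {
  cfg <- synthetic_config(sponge_consistency = 1)
  sp <- generate_sponge_system(cfg, seed = 17)
  m <- prepare_mirna(sp$mirna_a, sp$mirna_b, sp$alias_map)
  corr <- eb_batch_correct(m, group = m$cohort)
  lfc <- group_lfc(corr)
  bridging <- lfc$lfc[match(sp$truth$bridging, lfc$feature)]
  expect_true(all(bridging > 0))
  decoy <- lfc$lfc[match(sp$truth$decoys, lfc$feature)]
  expect_lt(abs(mean(decoy)), 3 * stats::sd(decoy) / sqrt(length(decoy)))
})

test_that("without planted batch effects the correction leaves feature
           means essentially unchanged", {
  cfg <- synthetic_config(batch_shift = 0, batch_shift_sd = 0,
                          batch_scale = 1)
  sp <- generate_sponge_system(cfg, seed = 19)
  m <- prepare_mirna(sp$mirna_a, sp$mirna_b, sp$alias_map)
  corr <- eb_batch_correct(m, group = m$cohort)
  pooled <- attr(corr, "batch_model")$pooled_sd
  drift <- abs(rowMeans(corr$values) - rowMeans(m$values))
  expect_true(all(drift <= 0.05 * pooled))
})

test_that("single-cell truth matches the emitted cells, outliers and
           proportions", {
  cfg <- small_cfg()
  sc <- generate_sc_cohort(cfg, seed = 23)
  tr <- sc$truth
  expect_equal(ncol(sc$dataset$counts), length(tr$population))
  expect_equal(sum(tr$is_outlier),
               cfg$sc_n_outlier_genes + cfg$sc_n_outlier_mito)
  # QC removes exactly the injected outliers
  f <- qc_filter_cells(sc$dataset, max_genes = tr$qc_max_genes,
                       mito_threshold = tr$qc_mito_threshold)
  expect_setequal(setdiff(tr$cell_id, f$cell_meta$cell_id),
                  tr$cell_id[tr$is_outlier])
  # subtype proportions within 3 SE of the configuration (per tumor sample)
  props <- cfg$sc_subtype_props / sum(cfg$sc_subtype_props)
  mal <- tr$population %in% names(props) &
    sc$dataset$cell_meta$sample_id == "tumor1" & !tr$is_outlier
  obs <- table(tr$population[mal]) / sum(mal)
  for (st in names(props)) {
    se <- sqrt(props[[st]] * (1 - props[[st]]) / sum(mal))
    expect_lt(abs(obs[[st]] - props[[st]]), 3 * se + 2 / sum(mal))
  }
  # the cell-line sample is pure S1
  cl <- sc$dataset$cell_meta$sample_id == "cellline"
  expect_true(all(tr$population[cl] == "S1"))
})

test_that("zero normal-infiltrate fraction yields only malignant cells", {
  cfg <- small_cfg(sc_normal_fraction = 0, sc_n_outlier_genes = 0,
                   sc_n_outlier_mito = 0)
  sc <- generate_sc_cohort(cfg, seed = 29)
  expect_true(all(sc$truth$population %in% c("S1", "S2", "S3")))
})

test_that("invalid configurations are rejected or flagged", {
  expect_error(synthetic_config(sponge_consistency = 1.5), "sponge")
  expect_error(synthetic_config(n_genes = 100), "exceed")
  expect_warning(synthetic_config(delta = 0), "delta = 0")
})
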