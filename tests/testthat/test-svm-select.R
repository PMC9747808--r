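test_that("a separating gene outranks a noise gene", {
  set.seed(2)
  n <- 60
  v <- rbind(A = c(rnorm(n / 2, -2, 0.2), rnorm(n / 2, 2, 0.2)),
             B = rnorm(n))
  colnames(v) <- sprintf("s%02d", seq_len(n))
  labels <- rep(c("tumor", "cell_line"), each = n / 2)
  r <- rank_features_single_split(v, labels, seed = 3)
  expect_equal(unname(r$rank["A"]), 1L)
  expect_gt(r$abs_w["A"], r$abs_w["B"])
  expect_equal(r$accuracy, 1)
  expect_true(all(sort(r$rank) == seq_len(2)))
})

test_that("duplicated features receive adjacent ranks with near-equal weight", {
  set.seed(3)
  toy <- toy_labeled_cohort(n_genes = 20, n_signal = 2, seed = 3)
  v <- rbind(toy$values, A_copy = toy$values["g001", ])
  r <- rank_features_single_split(v, toy$labels, seed = 5)
  expect_equal(abs(unname(diff(r$rank[c("g001", "A_copy")]))), 1L)
  expect_equal(unname(r$abs_w["g001"]), unname(r$abs_w["A_copy"]),
               tolerance = 1e-6)
})

test_that("permuted labels yield no classification skill", {
  set.seed(9)
  G <- 50; n <- 100
  v <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%03d", 1:n)))
  y <- rep(c("tumor", "cell_line"), c(70, 30))
  accs <- vapply(1:20, function(s) {
    rank_features_single_split(v, sample(y), seed = s)$accuracy
  }, numeric(1))
  expect_lte(mean(accs), 0.7 + 0.05)   # majority fraction, no skill above it
  expect_gte(mean(accs), 0.35)
})

test_that("stability selection is deterministic and respects the top-k bound", {
  toy <- toy_labeled_cohort(seed = 11)
  s1 <- stable_feature_set(toy$values, toy$labels, n_splits = 4,
                           master_seed = 7)
  s2 <- stable_feature_set(toy$values, toy$labels, n_splits = 4,
                           master_seed = 7)
  expect_identical(s1$genes, s2$genes)   # bit-for-bit reproducible
  expect_lte(length(s1$genes), ceiling(0.1 * nrow(toy$values)))
  expect_true(all(toy$signal %in% s1$genes))
  expect_length(s1$accuracies, 4)
})

test_that("a dominant signal block gives a full-size intersection set", {
  # signal genes fill the whole top fraction in every split
  toy <- toy_labeled_cohort(n_genes = 40, n_signal = 4, delta = 6,
                            sigma = 0.3, seed = 13)
  s <- stable_feature_set(toy$values, toy$labels, n_splits = 2,
                          top_frac = 0.1, master_seed = 1)
  expect_equal(length(s$genes), ceiling(0.1 * 40))
  expect_setequal(s$genes, toy$signal)
})

test_that("union merge contains the intersection merge", {
  toy <- toy_labeled_cohort(seed = 17)
  si <- stable_feature_set(toy$values, toy$labels, n_splits = 3,
                           merge_rule = "intersection", master_seed = 3)
  su <- stable_feature_set(toy$values, toy$labels, n_splits = 3,
                           merge_rule = "union", master_seed = 3)
  expect_true(all(si$genes %in% su$genes))
  expect_gte(length(su$genes), length(si$genes))
})

test_that("intersection set size is non-increasing in n_splits (nested seeds)", {
  toy <- toy_labeled_cohort(seed = 19)
  sizes <- vapply(c(1, 3, 5), function(ns) {
    length(stable_feature_set(toy$values, toy$labels, n_splits = ns,
                              master_seed = 21)$genes)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("immune blocklist is the dataset-restricted union of enriched
           immune pathways", {
  universe <- sprintf("g%03d", 1:50)
  coll <- pathway_collection(
    list(imm1 = c(universe[1:5], "offdata1"),
         imm2 = c(universe[4:8], "offdata2"),
         drv = universe[20:30]),
    c(imm1 = "immune", imm2 = "immune", drv = "cancer driver"))
  enr <- enrich_collection(universe[1:8], coll, universe)
  bl <- build_immune_blocklist(enr, coll, universe)
  expect_setequal(bl$genes, universe[1:8])     # union, deduplicated,
  expect_false(any(c("offdata1", "offdata2") %in% bl$genes))  # on-dataset only
  expect_setequal(bl$provenance, c("imm1", "imm2"))
  # no enriched immune pathway -> empty blocklist with a notice
  enr2 <- enrich_collection(universe[20:30], coll, universe)
  expect_message(bl2 <- build_immune_blocklist(enr2, coll, universe),
                 "empty blocklist")
  expect_length(bl2$genes, 0)
})

test_that("two-pass selection removes the immune program and matches a
           single pass when the blocklist is empty", {
  set.seed(23)
  toy <- toy_labeled_cohort(n_genes = 80, n_signal = 8, seed = 23)
  v <- toy$values
  # an immune program expressed only in tumors, strongly selected in pass 1
  immune <- sprintf("imm%02d", 1:6)
  vi <- matrix(0, 6, ncol(v), dimnames = list(immune, colnames(v)))
  vi[, toy$labels == "tumor"] <- 6 + rnorm(sum(toy$labels == "tumor") * 6, 0, 0.3)
  v <- rbind(v, vi)
  coll <- pathway_collection(list(IMM = immune, DRV = toy$signal),
                             c(IMM = "immune", DRV = "cancer driver"))
  tp <- two_pass_selection(v, toy$labels, coll = coll, n_splits = 3,
                           master_seed = 5)
  expect_length(intersect(tp$final$genes, tp$blocklist$genes), 0)
  expect_setequal(tp$blocklist$genes, immune)
  expect_true(all(toy$signal %in% tp$final$genes))
  # empty blocklist: pass-2 equals a single-pass run with the same seeds
  coll2 <- pathway_collection(list(DRV = toy$signal),
                              c(DRV = "cancer driver"))
  tp2 <- two_pass_selection(v, toy$labels, coll = coll2, n_splits = 3,
                            master_seed = 5)
  single <- stable_feature_set(v, toy$labels, n_splits = 3, master_seed = 5)
  expect_identical(tp2$final$genes, single$genes)
  # a blocklist covering every gene is a degenerate input; the dataset is
  # a strict subset of the universe so the all-gene pathway can be enriched
  coll3 <- pathway_collection(list(ALL = rownames(v)), c(ALL = "immune"))
  expect_error(
    two_pass_selection(v, toy$labels, coll = coll3,
                       universe = c(rownames(v), sprintf("pad%03d", 1:500)),
                       n_splits = 2, master_seed = 5),
    "every gene")
})

test_that("feature-set export writes the table and run manifest", {
  toy <- toy_labeled_cohort(seed = 29)
  s <- stable_feature_set(toy$values, toy$labels, n_splits = 2,
                          master_seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_feature_set(s, f)
  tab <- read.delim(f)
  expect_setequal(tab$gene, s$genes)
  manifest <- jsonlite::read_json(sub("\\.tsv$", "_manifest.json", f))
  expect_equal(manifest$n_splits, 2L)
  expect_equal(manifest$master_seed, 1L)
})
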