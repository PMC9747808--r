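#' Configuration for the synthetic multi-omic cohort generator
#'
#' Default sizes describe a desk-scale two-cohort study: 2000 genes of
#' which 100 (four 25-gene "cancer driver" programs) are shifted down by
#' `delta` log2 units in cell lines, a 25-gene non-differential control
#' pathway, a 50-gene immune program expressed in tumors only, 60 lncRNA
#' of which 20 are planted down in cell lines, a sponge network of 20
#' lncRNA x 60 miRNA x up to 100 driver-gene targets, batched miRNA
#' matrices, and a small single-cell cohort with molecular-subtype
#' programs.
#'
#' @param n_genes total genes in the bulk cohort (coding + lncRNA).
#' @param n_driver_pathways number of planted driver pathways.
#' @param driver_pathway_size genes per driver pathway.
#' @param control_pathway_size genes in the non-differential control
#'   pathway.
#' @param immune_program_size genes in the tumor-only immune program.
#' @param n_decoy_pathways number of non-planted decoy pathways.
#' @param decoy_pathway_size genes per decoy pathway.
#' @param n_lnc total lncRNA genes.
#' @param n_lnc_planted lncRNA planted down in cell lines (sponge members).
#' @param n_tumor,n_cellline samples per cohort.
#' @param n_diseases shared disease codes.
#' @param delta planted effect size in log2 units.
#' @param sigma per-sample noise SD in log2 units.
#' @param n_mirna total miRNA; the first `n_bridging` bridge the planted
#'   lncRNA to the driver pathways.
#' @param n_bridging bridging miRNA.
#' @param sponge_consistency fraction of bridging miRNA planted up in cell
#'   lines (the rest are planted down).
#' @param batch_shift mean additive batch effect (log2 units) on the second
#'   miRNA platform.
#' @param batch_shift_sd cross-feature SD of the additive batch effect
#'   (platform effects differ per feature, as probe affinities do).
#' @param batch_scale multiplicative batch effect on the second platform's
#'   noise SD.
#' @param n_mirna_tumor_a,n_mirna_cl_a,n_mirna_tumor_b,n_mirna_cl_b miRNA
#'   samples per cohort on platforms A and B.
#' @param sc_n_genes single-cell genes (including `sc_n_mito` MT- genes).
#' @param sc_n_mito mitochondrial genes.
#' @param sc_program_size genes per subtype/marker program.
#' @param sc_cells_per_tumor_sample,sc_cells_cellline cells per sample.
#' @param sc_n_tumor_samples tumor samples.
#' @param sc_subtype_props mixing proportions of the malignant subtypes
#'   within tumor samples (named over `S1`, `S2`, `S3`).
#' @param sc_normal_fraction fraction of tumor-sample cells that are
#'   normal infiltrate.
#' @param sc_n_outlier_genes,sc_n_outlier_mito injected QC-outlier cells
#'   (high detected-gene count / high mitochondrial count).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_driver_pathways = 4,
                             driver_pathway_size = 25,
                             control_pathway_size = 25,
                             immune_program_size = 50,
                             n_decoy_pathways = 6,
                             decoy_pathway_size = 25,
                             n_lnc = 60,
                             n_lnc_planted = 20,
                             n_tumor = 200,
                             n_cellline = 60,
                             n_diseases = 6,
                             delta = 1.5,
                             sigma = 1,
                             n_mirna = 60,
                             n_bridging = 30,
                             sponge_consistency = 0.9,
                             batch_shift = 5,
                             batch_shift_sd = 3,
                             batch_scale = 2,
                             n_mirna_tumor_a = 120, n_mirna_cl_a = 60,
                             n_mirna_tumor_b = 80, n_mirna_cl_b = 40,
                             sc_n_genes = 500,
                             sc_n_mito = 40,
                             sc_program_size = 25,
                             sc_cells_per_tumor_sample = 250,
                             sc_cells_cellline = 150,
                             sc_n_tumor_samples = 2,
                             sc_subtype_props = c(S1 = 0.35, S2 = 0.35,
                                                  S3 = 0.30),
                             sc_normal_fraction = 0.2,
                             sc_n_outlier_genes = 5,
                             sc_n_outlier_mito = 5) {
  cfg <- as.list(environment())
  stopifnot(cfg$sigma > 0, cfg$delta >= 0,
            cfg$sponge_consistency >= 0, cfg$sponge_consistency <= 1,
            cfg$n_bridging <= cfg$n_mirna,
            cfg$n_lnc_planted <= cfg$n_lnc,
            cfg$sc_normal_fraction >= 0, cfg$sc_normal_fraction < 1)
  n_coding <- cfg$n_genes - cfg$n_lnc
  need <- cfg$n_driver_pathways * cfg$driver_pathway_size +
    cfg$control_pathway_size + cfg$immune_program_size +
    cfg$n_decoy_pathways * cfg$decoy_pathway_size
  if (need > n_coding) stop("planted programs exceed the coding gene count")
  if (cfg$delta == 0) {
    warning("delta = 0: planted effects are absent; ",
            "recovery assertions will fail")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic gene layout shared by the bulk and sponge generators
gene_layout <- function(cfg) {
  n_coding <- cfg$n_genes - cfg$n_lnc
  coding <- sprintf("G%04d", seq_len(n_coding))
  lnc <- sprintf("LNC%02d", seq_len(cfg$n_lnc))
  at <- 0L
  take <- function(n) {
    out <- coding[(at + 1L):(at + n)]
    at <<- at + n
    out
  }
  drivers <- lapply(seq_len(cfg$n_driver_pathways),
                    function(i) take(cfg$driver_pathway_size))
  names(drivers) <- paste0("DRIVER_", seq_len(cfg$n_driver_pathways))
  control <- take(cfg$control_pathway_size)
  immune <- take(cfg$immune_program_size)
  decoys <- lapply(seq_len(cfg$n_decoy_pathways),
                   function(i) take(cfg$decoy_pathway_size))
  names(decoys) <- paste0("DECOY_", seq_len(cfg$n_decoy_pathways))
  list(coding = coding, lnc = lnc, drivers = drivers, control = control,
       immune = immune, decoys = decoys,
       lnc_planted = lnc[seq_len(cfg$n_lnc_planted)],
       driver_genes = unlist(drivers, use.names = FALSE))
}

disease_codes <- function(n) {
  codes <- c("BRCA", "GBM", "LUAD", "COAD", "SKCM", "LIHC", "PRAD", "OV",
             "KIRC", "STAD")
  if (n > length(codes)) codes <- c(codes, sprintf("DIS%02d", seq_len(n)))
  codes[seq_len(n)]
}

#' Generate a synthetic two-cohort bulk expression study
#'
#' Baseline log2 expression is Normal(mu_g, sigma) per gene with gene
#' means drawn uniformly from 2-8. In cell-line samples the driver-pathway
#' genes and the planted lncRNA are shifted down by `delta`; the immune
#' program is expressed in tumors only (cell-line TPM exactly 0). A
#' non-differential control pathway and decoy pathways are included.
#' Matrices are emitted on the TPM scale so they enter the pipeline at
#' [normalize_expression()].
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `tumor` and `cellline` (`expr_matrix`, TPM scale),
#'   `annotation` (gene annotation `data.frame`), `pathways`
#'   ([pathway_collection()] of drivers, control, immune program and
#'   decoys) and `truth` (planted ground truth).
#' @export
generate_bulk_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  lay <- gene_layout(cfg)
  genes <- c(lay$coding, lay$lnc)
  G <- length(genes)
  mu <- stats::setNames(stats::runif(G, 2, 8), genes)

  tumor_ids <- sprintf("TCGA-%04d", seq_len(cfg$n_tumor))
  cl_ids <- sprintf("CL-%04d", seq_len(cfg$n_cellline))
  diseases <- disease_codes(cfg$n_diseases)
  meta_t <- data.frame(sample_id = tumor_ids, cohort = "tumor",
                       disease_code = rep(diseases,
                                          length.out = cfg$n_tumor),
                       stringsAsFactors = FALSE)
  meta_c <- data.frame(sample_id = cl_ids, cohort = "cell_line",
                       disease_code = rep(diseases,
                                          length.out = cfg$n_cellline),
                       stringsAsFactors = FALSE)

  vt <- mu + matrix(stats::rnorm(G * cfg$n_tumor, 0, cfg$sigma), G,
                    cfg$n_tumor)
  vc <- mu + matrix(stats::rnorm(G * cfg$n_cellline, 0, cfg$sigma), G,
                    cfg$n_cellline)
  shifted <- c(lay$driver_genes, lay$lnc_planted)
  vc[match(shifted, genes), ] <- vc[match(shifted, genes), ] - cfg$delta
  vc[match(lay$immune, genes), ] <- 0        # tumor-only immune program
  vt <- pmax(vt, 0); vc <- pmax(vc, 0)
  dimnames(vt) <- list(genes, tumor_ids)
  dimnames(vc) <- list(genes, cl_ids)

  ann <- data.frame(
    gene_id = genes, symbol = genes,
    biotype = ifelse(genes %in% lay$lnc, "lncRNA", "coding"),
    immune_program = genes %in% lay$immune,
    mito = FALSE, stringsAsFactors = FALSE)

  decoy_cats <- rep(c("metabolism", "development", "cellular response",
                      "blood", "other"), length.out = cfg$n_decoy_pathways)
  sets <- c(lay$drivers, list(CONTROL_PW = lay$control,
                              IMMUNE_PROGRAM = lay$immune), lay$decoys)
  cats <- stats::setNames(
    c(rep("cancer driver", cfg$n_driver_pathways), "cancer driver",
      "immune", decoy_cats), names(sets))
  pathways <- pathway_collection(sets, cats)

  truth <- list(planted_de = lay$driver_genes,
                planted_direction = "down_in_cell_line",
                planted_lnc = lay$lnc_planted,
                immune_genes = lay$immune,
                driver_pathways = names(lay$drivers),
                control_pathway = "CONTROL_PW",
                seed = seed)
  list(tumor = expr_matrix(2^vt - 1, scale = "tpm", meta = meta_t),
       cellline = expr_matrix(2^vc - 1, scale = "tpm", meta = meta_c),
       annotation = ann, pathways = pathways, truth = truth)
}

#' Generate a synthetic ceRNA sponge system with batched miRNA matrices
#'
#' Builds lncRNA-miRNA and miRNA-gene interaction tables in which the
#' first `n_bridging` miRNA connect the planted lncRNA to the driver
#' pathway genes while decoy miRNA interact only with non-planted lncRNA
#' and non-pathway genes. Emits two raw miRNA matrices on different
#' platforms (different identifier conventions, resolved by the returned
#' alias map) whose samples cross cohort with platform: the second
#' platform carries an additive log-scale batch shift and a multiplicative
#' inflation of the noise SD. A `sponge_consistency` fraction of bridging
#' miRNA are planted up in cell lines, the remainder down; decoys carry no
#' cohort effect.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `interactions` ([interaction_table()]), `mirna_a`,
#'   `mirna_b` (raw [mirna_matrix()] objects), `alias_map`, and `truth`
#'   (bridging/decoy/consistent miRNA ids, planted lncRNA, targets).
#' @export
generate_sponge_system <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  lay <- gene_layout(cfg)
  mirna <- sprintf("mir-%d-5p", seq_len(cfg$n_mirna))
  bridging <- mirna[seq_len(cfg$n_bridging)]
  decoys <- setdiff(mirna, bridging)

  edges <- list()
  for (m in bridging) {
    lp <- sample(lay$lnc_planted, sample(1:3, 1))
    tg <- sample(lay$driver_genes, sample(3:6, 1))
    edges[[length(edges) + 1L]] <- data.frame(
      source = c(lp, rep(m, length(tg))),
      target = c(rep(m, length(lp)), tg),
      type = rep(c("lnc_mirna", "mirna_gene"), c(length(lp), length(tg))),
      stringsAsFactors = FALSE)
  }
  other_lnc <- setdiff(lay$lnc, lay$lnc_planted)
  nondriver <- setdiff(lay$coding,
                       c(lay$driver_genes, lay$control, lay$immune))
  for (m in decoys) {
    lp <- sample(other_lnc, sample(1:2, 1))
    tg <- sample(nondriver, sample(2:4, 1))
    edges[[length(edges) + 1L]] <- data.frame(
      source = c(lp, rep(m, length(tg))),
      target = c(rep(m, length(lp)), tg),
      type = rep(c("lnc_mirna", "mirna_gene"), c(length(lp), length(tg))),
      stringsAsFactors = FALSE)
  }
  interactions <- interaction_table(do.call(rbind, edges))

  n_up <- round(cfg$sponge_consistency * cfg$n_bridging)
  consistent <- bridging[seq_len(n_up)]
  effect <- stats::setNames(numeric(cfg$n_mirna), mirna)
  effect[consistent] <- cfg$delta
  effect[setdiff(bridging, consistent)] <- -cfg$delta

  mu <- stats::setNames(stats::runif(cfg$n_mirna, 3, 7), mirna)
  # per-feature additive platform effect, as probe affinities differ
  shift_b <- stats::rnorm(cfg$n_mirna, cfg$batch_shift, cfg$batch_shift_sd)
  sim_platform <- function(n_tumor, n_cl, shift, scale, prefix) {
    ids <- c(sprintf("%s-T%03d", prefix, seq_len(n_tumor)),
             sprintf("%s-C%03d", prefix, seq_len(n_cl)))
    cohort <- rep(c("tumor", "cell_line"), c(n_tumor, n_cl))
    n <- n_tumor + n_cl
    v <- mu + shift +
      matrix(stats::rnorm(cfg$n_mirna * n, 0, cfg$sigma * scale),
             cfg$n_mirna, n)
    v[, cohort == "cell_line"] <- v[, cohort == "cell_line"] + effect
    v <- pmax(v, 0)
    dimnames(v) <- list(mirna, ids)
    list(values = 2^v - 1, cohort = cohort)
  }
  a <- sim_platform(cfg$n_mirna_tumor_a, cfg$n_mirna_cl_a, 0, 1, "SEQ")
  b <- sim_platform(cfg$n_mirna_tumor_b, cfg$n_mirna_cl_b,
                    shift_b, cfg$batch_scale, "NST")

  # platform-specific identifier conventions
  va <- a$values
  rownames(va) <- sprintf("hsa-miR-%s", sub("^mir-", "", mirna))
  vb <- b$values
  rownames(vb) <- toupper(sprintf("MIR%s", sub("^mir-", "", mirna)))
  alias_map <- stats::setNames(mirna, tolower(rownames(vb)))

  truth <- list(bridging = bridging, consistent_up = consistent,
                inconsistent_down = setdiff(bridging, consistent),
                decoys = decoys, planted_lnc = lay$lnc_planted,
                targets = sort(unique(
                  interactions$edges$target[
                    interactions$edges$type == "mirna_gene" &
                      interactions$edges$source %in% bridging])),
                seed = seed)
  list(interactions = interactions,
       mirna_a = mirna_matrix(va, batch = rep("platform_a", ncol(va)),
                              cohort = a$cohort),
       mirna_b = mirna_matrix(vb, batch = rep("platform_b", ncol(vb)),
                              cohort = b$cohort),
       alias_map = alias_map, truth = truth)
}

#' Generate a synthetic single-cell cohort with subtype structure
#'
#' Negative-binomial counts for tumor samples mixing malignant
#' subtype populations (programs S1/S2/S3 over a shared malignant marker
#' program) with normal infiltrate (hepatocyte- and T-cell-like marker
#' populations), and one cell-line sample drawing cells only from the
#' S1-like program. QC-outlier cells (high detected-gene count; high
#' mitochondrial gene count) are injected at configured numbers and
#' recorded in the ground truth, together with the QC thresholds that
#' separate them.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `dataset` ([sc_dataset()] incl. outliers),
#'   `signatures` ([signature_set()] of S1/S2/S3 subtype programs),
#'   `markers` ([signature_set()] of cell-type markers), and `truth`
#'   (per-cell `population`, `subtype`, `is_outlier`, plus
#'   `qc_max_genes` / `qc_mito_threshold` and the program gene lists).
#' @export
generate_sc_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  n_mito <- cfg$sc_n_mito
  n_reg <- cfg$sc_n_genes - n_mito
  genes <- c(sprintf("SG%03d", seq_len(n_reg)),
             sprintf("MT-%02d", seq_len(n_mito)))
  ps <- cfg$sc_program_size
  at <- 0L
  take <- function(n) { out <- genes[(at + 1L):(at + n)]; at <<- at + n; out }
  prog <- list(S1 = take(ps), S2 = take(ps), S3 = take(ps),
               malignant = take(ps), hepatocyte = take(ps), tcell = take(ps))

  base_mu <- 0.2; prog_mu <- 3; size <- 2
  mito_expressed <- utils::tail(genes, n_mito)[seq_len(8)]

  cell_mu <- function(population) {
    mu <- rep(base_mu, length(genes))
    names(mu) <- genes
    active <- switch(population,
                     S1 = c(prog$S1, prog$malignant),
                     S2 = c(prog$S2, prog$malignant),
                     S3 = c(prog$S3, prog$malignant),
                     hepatocyte = prog$hepatocyte,
                     tcell = prog$tcell)
    mu[active] <- prog_mu
    mu[mito_expressed] <- prog_mu
    mu
  }

  props <- cfg$sc_subtype_props / sum(cfg$sc_subtype_props)
  cells <- list(); meta <- list()
  add_cells <- function(n, population, sample_id) {
    if (n <= 0L) return()
    mu <- cell_mu(population)
    m <- matrix(stats::rnbinom(length(genes) * n, mu = mu, size = size),
                length(genes), n)
    i <- length(cells) + 1L
    cells[[i]] <<- m
    meta[[i]] <<- data.frame(sample_id = sample_id, population = population,
                             n = n, stringsAsFactors = FALSE)
  }
  for (s in seq_len(cfg$sc_n_tumor_samples)) {
    sid <- sprintf("tumor%d", s)
    n_total <- cfg$sc_cells_per_tumor_sample
    n_normal <- round(cfg$sc_normal_fraction * n_total)
    n_mal <- n_total - n_normal
    n_sub <- round(props * n_mal)
    n_sub[1] <- n_mal - sum(n_sub[-1])
    for (st in names(props)) add_cells(n_sub[[st]], st, sid)
    add_cells(ceiling(n_normal / 2), "hepatocyte", sid)
    add_cells(floor(n_normal / 2), "tcell", sid)
  }
  add_cells(cfg$sc_cells_cellline, "S1", "cellline")

  counts <- do.call(cbind, cells)
  meta <- do.call(rbind, lapply(meta, function(m)
    m[rep(1L, m$n), c("sample_id", "population"), drop = FALSE]))
  is_outlier <- rep(FALSE, nrow(meta))

  # injected QC outliers: near-saturating detection / saturated mito genes
  if (cfg$sc_n_outlier_genes > 0L) {
    m <- matrix(stats::rnbinom(length(genes) * cfg$sc_n_outlier_genes,
                               mu = 8, size = 10),
                length(genes), cfg$sc_n_outlier_genes)
    counts <- cbind(counts, m)
    meta <- rbind(meta, data.frame(
      sample_id = "tumor1", population = "outlier_genes",
      stringsAsFactors = FALSE)[rep(1L, cfg$sc_n_outlier_genes), ])
    is_outlier <- c(is_outlier, rep(TRUE, cfg$sc_n_outlier_genes))
  }
  if (cfg$sc_n_outlier_mito > 0L) {
    mu <- rep(base_mu, length(genes))
    mu[(n_reg + 1L):length(genes)] <- 8    # every mito gene detected
    m <- matrix(stats::rnbinom(length(genes) * cfg$sc_n_outlier_mito,
                               mu = mu, size = 10),
                length(genes), cfg$sc_n_outlier_mito)
    counts <- cbind(counts, m)
    meta <- rbind(meta, data.frame(
      sample_id = "tumor1", population = "outlier_mito",
      stringsAsFactors = FALSE)[rep(1L, cfg$sc_n_outlier_mito), ])
    is_outlier <- c(is_outlier, rep(TRUE, cfg$sc_n_outlier_mito))
  }
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  rownames(meta) <- NULL

  d <- sc_dataset(counts, sample_id = meta$sample_id, mito_prefix = "MT-")
  subtype <- ifelse(meta$population %in% c("S1", "S2", "S3"),
                    meta$population, NA_character_)
  truth <- list(cell_id = colnames(counts), population = meta$population,
                subtype = subtype, is_outlier = is_outlier,
                qc_max_genes = round(0.8 * cfg$sc_n_genes),
                qc_mito_threshold = min(30L, n_mito - 3L),
                tumor_specific_program = c(prog$S2, prog$S3),
                programs = prog, seed = seed)
  list(dataset = d,
       signatures = signature_set(prog[c("S1", "S2", "S3")]),
       markers = signature_set(prog[c("malignant", "hepatocyte", "tcell")]),
       truth = truth)
}
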