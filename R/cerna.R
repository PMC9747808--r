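#' Normalize miRNA identifiers
#'
#' Lowercases, strips a three-letter species prefix (e.g. `hsa-`), and
#' resolves aliases; arm suffixes (`-5p`/`-3p`) are preserved because the
#' two arms of a hairpin are biologically distinct.
#'
#' @param ids character vector of miRNA identifiers.
#' @param alias_map optional named character vector mapping (normalized)
#'   source ids to canonical ids, e.g. `c("mir21-5p" = "mir-21-5p")`.
#' @return normalized identifiers.
#' @export
normalize_mirna_id <- function(ids, alias_map = NULL) {
  out <- tolower(as.character(ids))
  out <- sub("^[a-z]{3}-(?=(mir|let))", "", out, perl = TRUE)
  if (!is.null(alias_map)) {
    names(alias_map) <- tolower(names(alias_map))
    hit <- out %in% names(alias_map)
    out[hit] <- unname(alias_map[out[hit]])
  }
  out
}

#' Interaction table container
#'
#' Typed edges between lncRNA, miRNA and coding genes. Self-edges are
#' rejected and duplicate edges collapsed.
#'
#' @param edges `data.frame` with columns `source`, `target`, `type`
#'   (`"lnc_mirna"` or `"mirna_gene"`) and optionally `provenance`.
#' @return an object of class `interaction_table`.
#' @export
interaction_table <- function(edges) {
  stopifnot(is.data.frame(edges))
  required <- c("source", "target", "type")
  if (!all(required %in% names(edges))) {
    stop("edges need columns source, target, type")
  }
  if (!all(edges$type %in% c("lnc_mirna", "mirna_gene"))) {
    stop("edge type must be 'lnc_mirna' or 'mirna_gene'")
  }
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  if (!"provenance" %in% names(edges)) {
    edges$provenance <- character(nrow(edges))
  }
  edges <- edges[!duplicated(edges[, required]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "interaction_table")
}

#' Identify miRNA bridging a lncRNA set to a pathway gene set
#'
#' Under the ceRNA sponge model, a miRNA "bridges" the two sets when it has
#' at least one known interaction with a lncRNA in `lnc_set` and at least
#' one target among `pathway_genes`. Returns the bridging miRNA together
#' with the lncRNA and pathway genes incident to them.
#'
#' @param lnc_set character vector of lncRNA ids.
#' @param pathway_genes character vector of coding gene ids.
#' @param tables an [interaction_table()].
#' @return list with `mirna`, `lnc` (bridging lncRNA subset) and `genes`
#'   (targeted pathway-gene subset), each sorted.
#' @export
bridge_mirna <- function(lnc_set, pathway_genes, tables) {
  stopifnot(inherits(tables, "interaction_table"))
  e <- tables$edges
  if (nrow(e) == 0L) {
    warning("empty interaction table")
    return(list(mirna = character(0), lnc = character(0),
                genes = character(0)))
  }
  lm <- e[e$type == "lnc_mirna" & e$source %in% lnc_set, , drop = FALSE]
  mg <- e[e$type == "mirna_gene" & e$target %in% pathway_genes, , drop = FALSE]
  mirna <- sort(intersect(lm$target, mg$source))
  list(mirna = mirna,
       lnc = sort(unique(lm$source[lm$target %in% mirna])),
       genes = sort(unique(mg$target[mg$source %in% mirna])))
}

#' Hypergeometric test of miRNA-target overlap with a candidate gene set
#'
#' Finds the candidate genes targeted by at least one miRNA in `mirna_set`
#' and asks whether the candidate set is enriched for such targets relative
#' to the universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with
#' `N` the universe size, `K` the universe genes targeted by the miRNA set,
#' `n` the candidate-set size and `k` the targeted candidates.
#'
#' @param mirna_set character vector of miRNA ids.
#' @param candidate_genes candidate gene ids (subset of `universe`).
#' @param universe background gene ids.
#' @param tables an [interaction_table()].
#' @return list with `targeted` (sorted candidate genes with >= 1 incoming
#'   edge), `p`, and the test's `k`, `n`, `K`, `N`.
#' @export
target_overlap_test <- function(mirna_set, candidate_genes, universe,
                                tables) {
  stopifnot(inherits(tables, "interaction_table"))
  universe <- unique(as.character(universe))
  candidate_genes <- unique(as.character(candidate_genes))
  if (!all(candidate_genes %in% universe)) {
    stop("candidate genes must be a subset of the universe")
  }
  e <- tables$edges
  targets <- unique(e$target[e$type == "mirna_gene" &
                               e$source %in% mirna_set])
  targeted <- sort(intersect(candidate_genes, targets))
  K <- length(intersect(universe, targets))
  k <- length(targeted)
  n <- length(candidate_genes)
  N <- length(universe)
  list(targeted = targeted, p = hypergeom_pvalue(k, n, K, N),
       k = k, n = n, K = K, N = N)
}

#' ceRNA network container
#'
#' @param nodes `data.frame` with columns `id`, `type` (`"lncRNA"`,
#'   `"miRNA"` or `"coding"`) and optionally `lfc`.
#' @param edges `data.frame` with columns `source`, `type`
#'   (interaction type), `target`; every endpoint must appear in `nodes`.
#' @return an object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "type") %in% names(nodes))) {
    stop("nodes need columns id, type")
  }
  if (!all(nodes$type %in% c("lncRNA", "miRNA", "coding"))) {
    stop("node type must be lncRNA, miRNA or coding")
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!"lfc" %in% names(nodes)) nodes$lfc <- NA_real_
  nodes$lfc <- as.numeric(nodes$lfc)
  if (nrow(edges) > 0L) {
    if (!all(c("source", "type", "target") %in% names(edges))) {
      stop("edges need columns source, type, target")
    }
    dangling <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(dangling) > 0L) {
      stop("dangling edge endpoint(s): ", paste(dangling, collapse = ", "))
    }
  }
  nodes <- nodes[order(nodes$id), c("id", "type", "lfc"), drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$source, edges$target),
                   c("source", "type", "target"), drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(0), type = character(0),
                        target = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Assemble a ceRNA network from bridging results
#'
#' @param bridge result of [bridge_mirna()].
#' @param tables the [interaction_table()] the bridge was computed from.
#' @param lfc optional named numeric vector of log2 fold changes keyed by
#'   node id.
#' @return a [cerna_network()] containing the bridging lncRNA, miRNA and
#'   targeted genes with the interaction edges among them.
#' @export
build_cerna_network <- function(bridge, tables, lfc = NULL) {
  e <- tables$edges
  keep <- (e$type == "lnc_mirna" & e$source %in% bridge$lnc &
             e$target %in% bridge$mirna) |
    (e$type == "mirna_gene" & e$source %in% bridge$mirna &
       e$target %in% bridge$genes)
  edges <- data.frame(source = e$source[keep], type = e$type[keep],
                      target = e$target[keep], stringsAsFactors = FALSE)
  nodes <- data.frame(
    id = c(bridge$lnc, bridge$mirna, bridge$genes),
    type = rep(c("lncRNA", "miRNA", "coding"),
               c(length(bridge$lnc), length(bridge$mirna),
                 length(bridge$genes))),
    stringsAsFactors = FALSE)
  nodes$lfc <- if (is.null(lfc)) NA_real_ else unname(lfc[nodes$id])
  cerna_network(nodes, edges)
}

#' Export a ceRNA network as SIF plus node attributes
#'
#' Writes a Cytoscape-style SIF edge file (`source TAB interaction-type TAB
#' target`) and a node-attribute TSV (`id`, `type`, `lfc`). The pair
#' round-trips through [read_cerna_network()] to the identical network.
#'
#' @param net a [cerna_network()].
#' @param sif_path,nodes_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
export_network <- function(net, sif_path, nodes_path) {
  stopifnot(inherits(net, "cerna_network"))
  sif <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$type,
                 net$edges$target)
  writeLines(sif, sif_path)
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sif = sif_path, nodes = nodes_path))
}

#' Read a ceRNA network from SIF plus node attributes
#' @param sif_path,nodes_path paths written by [export_network()].
#' @return a [cerna_network()].
#' @export
read_cerna_network <- function(sif_path, nodes_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  lines <- readLines(sif_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- data.frame(source = vapply(parts, `[[`, character(1), 1L),
                        type = vapply(parts, `[[`, character(1), 2L),
                        target = vapply(parts, `[[`, character(1), 3L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(0), type = character(0),
                        target = character(0), stringsAsFactors = FALSE)
  }
  cerna_network(nodes, edges)
}
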