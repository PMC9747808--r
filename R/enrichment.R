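#' Recognized pathway category labels
#' @return character vector of category labels.
#' @export
pathway_categories <- function() {
  c("cellular response", "development", "cancer driver", "metabolism",
    "blood", "immune", "other")
}

#' Pathway collection container
#'
#' Named gene sets with one category label per pathway, in the spirit of a
#' GMT-backed collection such as the mSigDB Hallmark sets.
#'
#' @param sets named list of character vectors (gene ids); names unique,
#'   every set non-empty.
#' @param categories named character vector (or single label recycled) of
#'   category labels, one of [pathway_categories()].
#' @return an object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, categories = "other") {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("pathway names must be unique and non-empty")
  }
  if (any(lengths(sets) == 0L)) stop("every pathway set must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (length(categories) == 1L && is.null(names(categories))) {
    categories <- stats::setNames(rep(categories, length(sets)), names(sets))
  }
  if (!all(names(sets) %in% names(categories))) {
    stop("every pathway needs a category label")
  }
  categories <- categories[names(sets)]
  if (!all(categories %in% pathway_categories())) {
    stop("unknown category label(s): ",
         paste(setdiff(categories, pathway_categories()), collapse = ", "))
  }
  structure(list(sets = sets, categories = categories),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d sets (%s)\n", length(x$sets),
              paste(sprintf("%s=%d", names(table(x$categories)),
                            table(x$categories)), collapse = ", ")))
  invisible(x)
}

#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a draw
#' of `n` genes from a universe of `N` containing `K` pathway members
#' overlaps the pathway in at least `k` genes. Summation is done in log
#' space for numerical stability of extreme tails.
#'
#' @param k observed overlap.
#' @param n query-set size.
#' @param K pathway size within the universe.
#' @param N universe size.
#' @return the upper-tail p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K)) {
    stop("hypergeometric parameters violate 0 <= K <= N, 0 <= n <= N, ",
         "0 <= k <= min(n, K)")
  }
  if (k == 0) return(1)
  hi <- min(n, K)
  lp <- stats::dhyper(k:hi, K, N - K, n, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Over-representation of a gene set against a pathway collection
#'
#' One hypergeometric upper-tail test per pathway, with Benjamini-Hochberg
#' adjustment across all tested pathways. Query genes outside the universe
#' are dropped with a warning; pathway sets are intersected with the
#' universe before testing.
#'
#' @param query character vector of query gene ids.
#' @param coll a [pathway_collection()].
#' @param universe character vector of background gene ids.
#' @param alpha FDR threshold for the `significant` flag.
#' @return `data.frame` with one row per pathway, sorted by p ascending
#'   (ties by name): `pathway`, `category`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `significant`; class `enrichment_result`.
#' @export
enrich_collection <- function(query, coll, universe, alpha = 0.05) {
  stopifnot(inherits(coll, "pathway_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(coll$sets), function(nm) {
    members <- intersect(coll$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(pathway = nm, category = unname(coll$categories[[nm]]),
               N = N, K = K, n = n, k = k,
               p = hypergeom_pvalue(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Shared significant pathways between two enrichment analyses
#'
#' @param resA,resB `enrichment_result` objects computed against the same
#'   pathway collection.
#' @return `data.frame` of shared significant pathways with their category,
#'   with attribute `"category_counts"` (a table of shared pathways per
#'   category).
#' @export
overlap_enrichments <- function(resA, resB) {
  stopifnot(inherits(resA, "enrichment_result"),
            inherits(resB, "enrichment_result"))
  if (!setequal(resA$pathway, resB$pathway)) {
    stop("the two enrichment results cover different pathway collections")
  }
  shared <- sort(intersect(resA$pathway[resA$significant],
                           resB$pathway[resB$significant]))
  out <- data.frame(pathway = shared,
                    category = resA$category[match(shared, resA$pathway)],
                    stringsAsFactors = FALSE)
  attr(out, "category_counts") <- table(out$category)
  out
}
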