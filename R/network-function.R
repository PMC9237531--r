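#' Construct a regulatory network for function prediction
#'
#' @param edges Data frame with columns `tf_id`, `target_id`.
#' @param go_annotation Data frame with columns `gene_id`, `term_id` (direct
#'   GO biological-process annotations; no graph propagation).
#' @param universe Character vector of background gene ids; defaults to the
#'   union of edge targets and annotated genes.
#' @return Object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, go_annotation, universe = NULL) {
  stopifnot(all(c("tf_id", "target_id") %in% names(edges)),
            all(c("gene_id", "term_id") %in% names(go_annotation)))
  if (is.null(universe))
    universe <- sort(unique(c(edges$target_id, go_annotation$gene_id)))
  if (!all(edges$target_id %in% universe))
    stop("edge target(s) outside the gene universe")
  if (!all(go_annotation$gene_id %in% universe))
    stop("annotated gene(s) outside the gene universe")
  structure(list(edges = edges, go = go_annotation, universe = universe),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", length(unique(x$edges$tf_id)), " TFs, ",
      length(x$universe), " genes, ", length(unique(x$go$term_id)),
      " GO terms\n", sep = "")
  invisible(x)
}

#' GO-BP enrichment of one TF's target set
#'
#' For each term annotating at least `min_term_size` universe genes, tests
#' overrepresentation of the term among the TF's targets with the upper-tail
#' hypergeometric test (`k` = annotated targets, `n` = targets, `K` =
#' annotated universe genes, `N` = universe size), Bonferroni-corrected over
#' the terms actually tested for this TF.
#'
#' @param tf TF id.
#' @param network A [regulatory_network()].
#' @param threshold Adjusted-p cutoff used by callers to declare enrichment
#'   (recorded; all tested terms are returned).
#' @param min_term_size Minimum universe annotation count for a term to be
#'   tested (noise guard, default 3).
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_adjusted`, `enriched`; zero rows when the TF has no targets or no
#'   annotated targets.
#' @export
go_enrich <- function(tf, network, threshold = 0.05, min_term_size = 3) {
  targets <- unique(network$edges$target_id[network$edges$tf_id == tf])
  empty <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  if (!length(targets)) {
    attr(empty, "reason") <- "TF has no targets"
    return(empty)
  }
  go <- network$go
  N <- length(network$universe)
  n <- length(targets)
  term_sizes <- table(go$term_id[!duplicated(paste(go$gene_id, go$term_id))])
  terms <- names(term_sizes)[term_sizes >= min_term_size]
  target_go <- go[go$gene_id %in% targets & go$term_id %in% terms, ,
                  drop = FALSE]
  if (!nrow(target_go)) {
    attr(empty, "reason") <- "no annotated targets"
    return(empty)
  }
  tested <- unique(target_go$term_id)
  k <- vapply(tested, function(tm)
    length(unique(target_go$gene_id[target_go$term_id == tm])), integer(1))
  K <- as.integer(term_sizes[tested])
  p_raw <- mapply(hypergeom_upper_tail, k = k, K = K,
                  MoreArgs = list(n = n, N = N))
  p_adj <- bonferroni(p_raw, length(tested))
  out <- data.frame(term = tested, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_adjusted = p_adj,
                    enriched = p_adj < threshold, stringsAsFactors = FALSE)
  out[order(out$p_adjusted, out$p_raw, out$term), , drop = FALSE]
}

#' Binary TF x enriched-term function matrix
#'
#' Runs [go_enrich()] for every TF in the network and assembles the binary
#' matrix of enriched terms (adjusted p below the threshold). TFs with no
#' enriched term are dropped; the per-cell adjusted p-values are kept
#' alongside.
#'
#' @param network A [regulatory_network()].
#' @param threshold Adjusted-p cutoff.
#' @param min_term_size Passed to [go_enrich()].
#' @return Object of class `function_matrix`: list with `matrix` (logical,
#'   TFs x terms), `p_adjusted` (numeric matrix, NA where untested) and
#'   `threshold`.
#' @export
build_function_matrix <- function(network, threshold = 0.05,
                                  min_term_size = 3) {
  tfs <- sort(unique(network$edges$tf_id))
  res <- lapply(tfs, go_enrich, network = network, threshold = threshold,
                min_term_size = min_term_size)
  names(res) <- tfs
  keep <- vapply(res, function(r) any(r$enriched), logical(1))
  res <- res[keep]
  terms <- sort(unique(unlist(lapply(res, function(r) r$term[r$enriched]))))
  m <- matrix(FALSE, length(res), length(terms),
              dimnames = list(names(res), terms))
  p <- matrix(NA_real_, length(res), length(terms),
              dimnames = list(names(res), terms))
  for (tf in names(res)) {
    r <- res[[tf]]
    hit <- r$term[r$enriched & r$term %in% terms]
    m[tf, hit] <- TRUE
    idx <- r$term %in% terms
    p[tf, r$term[idx]] <- r$p_adjusted[idx]
  }
  structure(list(matrix = m, p_adjusted = p, threshold = threshold),
            class = "function_matrix")
}

#' @export
print.function_matrix <- function(x, ...) {
  cat("<function_matrix> ", nrow(x$matrix), " TFs x ", ncol(x$matrix),
      " enriched terms (adjusted p < ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Average-linkage clustering of TFs by enriched-term profiles
#'
#' Hierarchically clusters TFs by Jaccard distance between their binary
#' enriched-term profiles (`stats::dist(method = "binary")`) with average
#' linkage, and optionally cuts the dendrogram into flat clusters.
#'
#' @param fm A [build_function_matrix()] result (>= 2 TFs).
#' @param k Optional flat cluster count for `stats::cutree`.
#' @return List of class `tf_clustering`: `hclust` (the dendrogram),
#'   `order` (TF ids in dendrogram order) and `clusters` (named integer
#'   vector when `k` given, else `NULL`).
#' @export
cluster_tfs <- function(fm, k = NULL) {
  m <- fm$matrix
  if (nrow(m) < 2) stop("need at least 2 TFs with an enriched term")
  d <- stats::dist(m * 1L, method = "binary")
  hc <- stats::hclust(d, method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, order = rownames(m)[hc$order],
                 clusters = clusters), class = "tf_clustering")
}

#' @export
print.tf_clustering <- function(x, ...) {
  cat("<tf_clustering> ", length(x$order), " TFs, average linkage\n",
      sep = "")
  invisible(x)
}

#' @export
plot.tf_clustering <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two flat clusterings of the same items, corrected for
#' chance (1 = identical partitions, ~0 = random agreement).
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
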