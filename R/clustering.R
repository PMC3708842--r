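#' Build the weighted clustering matrix of fitness profiles
#'
#' Restricts the normalized data to genes significant in at least one
#' condition and assembles, per condition, the normalized value of every
#' biological replicate plus a per-condition average column. Average
#' columns carry ten times the weight of individual replicate columns when
#' clustering, so a gene's consensus behaviour dominates its
#' replicate-to-replicate scatter.
#'
#' @param calls a [footprint_significance()] result.
#' @param normalized a [normalize_footprint()] result (defaults to the one
#'   stored inside `calls`).
#' @return object of class `cluster_matrix`: list with `x` (gene x column
#'   matrix), `weights` (positive, per column), `columns` (data.frame of
#'   column metadata) and `genes`.
#' @export
build_cluster_matrix <- function(calls, normalized = calls$normalized) {
  stopifnot(inherits(calls, "significance_calls"),
            inherits(normalized, "normalized_footprint"))
  genes <- significant_genes(calls)
  if (!length(genes)) stop("no gene is significant in any condition")
  a <- normalized$arrays
  conds <- unique(a$condition[a$role == "sel"])

  blocks <- list(); weights <- numeric(); meta <- list()
  for (cond in conds) {
    cols <- a$array[a$role == "sel" & a$condition == cond]
    rep_block <- normalized$values[genes, cols, drop = FALSE]
    avg <- rowMeans(rep_block)
    blk <- cbind(rep_block, avg)
    colnames(blk) <- c(cols, paste0("avg_", cond))
    blocks[[cond]] <- blk
    weights <- c(weights, rep(1, length(cols)), 10)
    meta[[cond]] <- data.frame(
      column = colnames(blk), condition = cond,
      kind = c(rep("replicate", length(cols)), "average"),
      weight = c(rep(1, length(cols)), 10), stringsAsFactors = FALSE)
  }
  structure(list(x = do.call(cbind, blocks), weights = weights,
                 columns = do.call(rbind, c(meta, make.row.names = FALSE)),
                 genes = genes),
            class = "cluster_matrix")
}

# k-means++ initial centers on a plain matrix
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
    for (i in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[i, ] <- x[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[i, ])^2))
    }
  }
  centers
}

#' Weighted k-means clustering of fitness profiles
#'
#' Euclidean-distance k-means where each column's weight w enters the
#' squared distance linearly, implemented by scaling the column by sqrt(w)
#' and running standard k-means in the scaled space. Initialization is
#' seeded k-means++; the best of `restarts` runs by within-cluster sum of
#' squares is kept, and cluster labels are canonicalized by descending
#' cluster mean so runs are comparable.
#'
#' @param matrix a [build_cluster_matrix()] result.
#' @param k number of clusters (default 9); must not exceed the number of
#'   genes.
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 50).
#' @return object of class `cluster_result`: list with `assignments`
#'   (named integer vector gene -> cluster), `centroids` (k x columns, in
#'   the original unweighted space), `wcss`, `k`, `seed`.
#' @export
weighted_kmeans <- function(matrix, k = 9L, seed = 1L, restarts = 50L) {
  stopifnot(inherits(matrix, "cluster_matrix"))
  n <- nrow(matrix$x)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of genes")
  sw <- sqrt(matrix$weights)
  xs <- sweep(matrix$x, 2L, sw, "*")

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(xs, k)
      fit <- suppressWarnings(
        stats::kmeans(xs, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    ord <- order(rowMeans(best$centers), decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    assignments <- relabel[best$cluster]
    names(assignments) <- matrix$genes
    centroids <- sweep(best$centers[ord, , drop = FALSE], 2L, sw, "/")
    rownames(centroids) <- seq_len(k)
    structure(list(assignments = assignments, centroids = centroids,
                   wcss = best$tot.withinss, k = as.integer(k),
                   seed = seed),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d genes in %d clusters (WCSS %.3f)\n",
              length(x$assignments), x$k, x$wcss))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Clip enrichment values for display
#'
#' Restricts values to the range `[-3, 3]`; interior values are unchanged
#' and extremes are shown at the boundary. Display convention only - no
#' statistic is computed on clipped values.
#'
#' @param values numeric vector or matrix of log2 enrichments.
#' @return object of the same shape with values in `[-3, 3]`.
#' @export
clip_for_display <- function(values) {
  pmin(pmax(values, -3), 3)
}

#' Hypergeometric category enrichment per cluster
#'
#' Simple upper-tail hypergeometric enrichment of gene categories within
#' clusters, with Benjamini-Hochberg q-values computed across all
#' cluster x category pairs. The universe is the set of clustered genes.
#'
#' @param assignments named integer vector gene -> cluster (e.g.
#'   `cluster_result$assignments`).
#' @param categories data.frame with columns `gene` and `category`; a gene
#'   may appear under several categories.
#' @return data.frame with columns cluster, category, overlap,
#'   cluster_size, category_size, universe, p, q.
#' @export
cluster_category_enrichment <- function(assignments, categories) {
  if (is.null(names(assignments))) stop("'assignments' must be named by gene")
  if (!all(c("gene", "category") %in% names(categories)))
    stop("'categories' needs columns 'gene' and 'category'")
  universe <- names(assignments)
  categories <- categories[categories$gene %in% universe, , drop = FALSE]
  if (!nrow(categories))
    stop("no category covers any clustered gene")
  n_u <- length(universe)
  out <- list()
  for (cl in sort(unique(assignments))) {
    cl_genes <- names(assignments)[assignments == cl]
    for (cat_name in sort(unique(categories$category))) {
      cat_genes <- unique(categories$gene[categories$category == cat_name])
      ov <- length(intersect(cl_genes, cat_genes))
      p <- stats::phyper(ov - 1L, length(cat_genes),
                         n_u - length(cat_genes), length(cl_genes),
                         lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, category = cat_name, overlap = ov,
        cluster_size = length(cl_genes), category_size = length(cat_genes),
        universe = n_u, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
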