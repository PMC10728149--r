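#' Pairwise cell-cell distances
#'
#' @param m an `ExpressionMatrix`, typically log2 FPKM.
#' @param metric `"pearson-dissimilarity"` (d = 1 - Pearson r across genes;
#'   the scRNA-seq convention used by default downstream) or `"euclidean"`.
#'   A zero-variance cell has undefined correlation; its r is defined as 0
#'   (d = 1) and a warning names it.
#' @return A symmetric `DistanceMatrix` object (matrix with a `metric`
#'   attribute, zero diagonal).
#' @export
pairwise_distance <- function(m, metric = c("pearson-dissimilarity", "euclidean")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  metric <- match.arg(metric)
  if (length(m$cell_ids) < 2) stop("need at least 2 cells", call. = FALSE)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(t(m$values), method = "euclidean"))
  } else {
    sds <- apply(m$values, 2, stats::sd)
    flat <- which(sds == 0)
    if (length(flat))
      warning("zero-variance cell(s), correlation set to 0: ",
              paste(utils::head(m$cell_ids[flat], 5), collapse = ", "),
              call. = FALSE)
    r <- suppressWarnings(stats::cor(m$values))
    r[!is.finite(r)] <- 0
    d <- 1 - r
    diag(d) <- 0
    d[d < 0] <- 0 # guard tiny negatives from floating point
  }
  dimnames(d) <- list(m$cell_ids, m$cell_ids)
  structure(d, metric = metric, class = c("DistanceMatrix", "matrix", "array"))
}

as_dist_checked <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(!is.finite(d))) stop("non-finite distance entries", call. = FALSE)
  stats::as.dist(d)
}

hclust_method <- function(linkage) {
  switch(linkage, average = "average", complete = "complete",
         ward = "ward.D2",
         stop("unknown linkage '", linkage, "'", call. = FALSE))
}

#' Cut an agglomerative tree into K clusters
#'
#' @param d a `DistanceMatrix` (or plain symmetric matrix).
#' @param K number of clusters, `2 <= K <= n_cells`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (Ward on
#'   squared dissimilarities, i.e. ward.D2).
#' @return Named integer vector of cluster labels in `1..K` (named by cell id).
#' @export
hierarchical_cluster <- function(d, K, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  if (K > n) stop("K (", K, ") exceeds number of cells (", n, ")", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  hc <- stats::hclust(as_dist_checked(d), method = hclust_method(linkage))
  stats::cutree(hc, k = K)
}

#' Per-cell silhouette coefficients
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance of cell
#' i to the other members of its cluster and b(i) the smallest mean distance
#' to any other cluster. Cells in singleton clusters get s(i) = 0.
#'
#' @param d distance matrix over cells.
#' @param labels integer cluster labels, one per cell, at least two clusters.
#' @return List with `per_cell` (named numeric) and `mean`.
#' @export
silhouette_scores <- function(d, labels) {
  n <- nrow(d)
  stopifnot(length(labels) == n)
  labs <- unique(labels)
  if (length(labs) < 2)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  idx <- split(seq_len(n), labels)
  sizes <- vapply(idx, length, 1L)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(labels[i])
    if (sizes[[own]] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, idx[[own]]]) / (sizes[[own]] - 1L)
    b <- min(vapply(setdiff(names(idx), own),
                    function(k) mean(d[i, idx[[k]]]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- rownames(d)
  list(per_cell = s, mean = mean(s))
}

#' Choose the number of clusters by mean silhouette
#'
#' Cuts the agglomerative tree at each K in `k_range`, scores the mean
#' silhouette, and returns the K that maximises it (ties broken toward
#' smaller K). The full silhouette-vs-K table is kept for reporting.
#'
#' @param d a `DistanceMatrix`.
#' @param k_range candidate cluster numbers, default `2:10`.
#' @param linkage linkage passed to [hierarchical_cluster()].
#' @return A `ClusterResult`: list with `labels`, `K`, `per_cell_silhouette`,
#'   `mean_silhouette`, `silhouette_table` (K vs mean silhouette), `linkage`,
#'   `metric`.
#' @export
select_k <- function(d, k_range = 2:10, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n))
    stop("k_range must lie within 2..n_cells (= ", n, ")", call. = FALSE)
  hc <- stats::hclust(as_dist_checked(d), method = hclust_method(linkage))
  cuts <- stats::cutree(hc, k = k_range)
  if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1)
  tab <- data.frame(K = k_range, mean_silhouette = NA_real_)
  sil_by_k <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    sil_by_k[[j]] <- silhouette_scores(d, cuts[, j])
    tab$mean_silhouette[j] <- sil_by_k[[j]]$mean
  }
  best <- which.max(tab$mean_silhouette) # which.max takes the first maximum,
  # and k_range is ascending, so ties resolve toward smaller K
  res <- list(labels = cuts[, best], K = k_range[best],
              per_cell_silhouette = sil_by_k[[best]]$per_cell,
              mean_silhouette = tab$mean_silhouette[best],
              silhouette_table = tab,
              linkage = linkage,
              metric = attr(d, "metric") %||% "unknown")
  class(res) <- "ClusterResult"
  res
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: K = %d, mean silhouette = %.3f (%s linkage, %s)\n",
              x$K, x$mean_silhouette, x$linkage, x$metric))
  print(table(cluster = x$labels))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
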