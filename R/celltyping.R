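#' Per-gene dropout statistics
#'
#' For every gene: S, the arithmetic mean FPKM over cells, and P, the
#' fraction of cells in which it is not detected (zero). Genes with P of 0 or
#' 1 carry no dropout information and are flagged untestable.
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`.
#' @return A `data.frame` (class `DropoutTable`) with columns `gene_id`, `S`,
#'   `P`, `testable`.
#' @export
dropout_stats <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "fpkm")
    stop("dropout_stats expects unit 'fpkm', got '", m$unit, "'", call. = FALSE)
  if (length(m$cell_ids) < 2) stop("need at least 2 cells", call. = FALSE)
  S <- rowMeans(m$values)
  P <- rowMeans(m$values == 0)
  out <- data.frame(gene_id = m$gene_ids, S = S, P = P,
                    testable = P > 0 & P < 1, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("DropoutTable", "data.frame")
  attr(out, "n_cells") <- length(m$cell_ids)
  out
}

#' Fit the global Michaelis-Menten dropout constant
#'
#' Models the dropout probability of a gene with mean expression S as
#' P = 1 - S / (K + S) and finds the K > 0 minimising the least-squares
#' misfit over all testable genes (1-D bounded optimisation). The standard
#' error comes from the Gauss-Newton curvature at the optimum.
#'
#' @param t a `DropoutTable` from [dropout_stats()].
#' @return List with `K`, `se`, `rss`, `n_genes`.
#' @export
fit_michaelis_menten <- function(t) {
  tt <- t[t$testable & t$S > 0, , drop = FALSE]
  if (nrow(tt) < 10)
    stop("need at least 10 testable genes to fit the dropout model (have ",
         nrow(tt), ")", call. = FALSE)
  S <- tt$S; P <- tt$P
  ssr <- function(K) sum((P - (1 - S / (K + S)))^2)
  upper <- max(S) * 100
  opt <- stats::optimize(ssr, interval = c(1e-9, upper), tol = 1e-10)
  K <- opt$minimum
  if (K >= upper * 0.999)
    stop("Michaelis-Menten fit did not converge: K ran to the bracket ",
         "boundary (", signif(K, 4), "); dropout pattern may be degenerate ",
         "(median P = ", signif(stats::median(P), 3), ")", call. = FALSE)
  grad <- S / (K + S)^2            # d/dK of the model curve
  sigma2 <- opt$objective / max(1, length(S) - 1)
  se <- sqrt(sigma2 / sum(grad^2))
  list(K = K, se = se, rss = opt$objective, n_genes = length(S))
}

#' Significantly variable genes from the dropout model
#'
#' Each testable gene gets its own Michaelis constant K_j = S_j P_j / (1 - P_j)
#' (the K solving P_j = 1 - S_j/(K + S_j)). Genes whose K_j significantly
#' exceeds the global K show more dropout than their mean expression predicts,
#' the signature of genes expressed in only a subset of cells. The right-tailed
#' test uses a normal approximation with Var(P_j) = P_j(1-P_j)/n propagated to
#' K_j by the delta method, followed by Benjamini-Hochberg correction.
#'
#' @param t a `DropoutTable`.
#' @param fit result of [fit_michaelis_menten()] (or a number, the global K).
#' @param q_cutoff BH-adjusted significance cut-off, default 0.05.
#' @return Character vector of selected gene ids, with the full per-gene test
#'   table in `attr(, "stats")` (columns `gene_id`, `S`, `P`, `K_j`, `z`, `p`,
#'   `q`, `selected`).
#' @export
variable_genes <- function(t, fit, q_cutoff = 0.05) {
  K_M <- if (is.list(fit)) fit$K else fit
  n <- attr(t, "n_cells")
  if (is.null(n)) stop("DropoutTable lost its n_cells attribute", call. = FALSE)
  tt <- t[t$testable & t$S > 0, , drop = FALSE]
  n_excluded <- nrow(t) - nrow(tt)
  if (n_excluded > 0)
    message(n_excluded, " untestable gene(s) excluded from the dropout test")
  S <- tt$S; P <- tt$P
  K_j <- S * P / (1 - P)
  # delta method: dK/dP = S/(1-P)^2
  sd_K <- sqrt(P * (1 - P) / n) * S / (1 - P)^2
  z <- (K_j - K_M) / sd_K
  p <- stats::pnorm(z, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  stats_tab <- data.frame(gene_id = tt$gene_id, S = S, P = P, K_j = K_j,
                          z = z, p = p, q = q, selected = q < q_cutoff,
                          row.names = NULL, stringsAsFactors = FALSE)
  out <- stats_tab$gene_id[stats_tab$selected]
  attr(out, "stats") <- stats_tab
  out
}

#' Rank cluster-specific genes one-vs-rest
#'
#' Restricts the variable-gene list to each cluster by ranking genes on their
#' log2 mean-expression difference between the cluster's cells and all other
#' cells, keeping the top `top_n` among genes actually elevated in the
#' cluster (log-fc above `min_lfc`): a cluster's genes are the ones it
#' over-expresses, so genes ranked by a negative contrast never qualify.
#' These per-cluster lists feed the marker database comparison in
#' [assign_cell_types()].
#'
#' @param m an `ExpressionMatrix` (fpkm or log2fpkm).
#' @param labels named integer cluster labels (names = cell ids).
#' @param var_genes character vector of variable genes to rank within.
#' @param top_n genes kept per cluster, default 200.
#' @param min_lfc minimum one-vs-rest log2 difference, default 0.
#' @return Named list: cluster label -> character vector of gene ids.
#' @export
cluster_gene_lists <- function(m, labels, var_genes, top_n = 200,
                               min_lfc = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(names(labels))) names(labels) <- m$cell_ids
  genes <- intersect(var_genes, m$gene_ids)
  v <- m$values[genes, , drop = FALSE]
  out <- list()
  for (k in sort(unique(labels))) {
    in_k <- names(labels)[labels == k]
    out_k <- setdiff(m$cell_ids, in_k)
    if (!length(genes)) { out[[as.character(k)]] <- character(); next }
    lfc <- log2(rowMeans(v[, in_k, drop = FALSE]) + 1) -
      log2(rowMeans(v[, out_k, drop = FALSE]) + 1)
    up <- lfc > min_lfc
    ord <- order(-lfc[up], genes[up]) # deterministic: score then gene id
    out[[as.character(k)]] <- genes[up][ord][seq_len(min(top_n, sum(up)))]
  }
  out
}

#' Assign clusters to cell types by marker adherence
#'
#' For each cluster, overlaps its gene list with every marker set and runs a
#' chi-squared goodness-of-fit (adherence) test of the observed overlap counts
#' O_t against expectations proportional to marker-set size (scaled so the
#' expected counts sum to the observed total). The cluster is assigned the
#' type with the largest standardised residual (O - E)/sqrt(E) when the
#' BH-corrected test is significant and the winning overlap reaches
#' `min_overlap`; otherwise it is "Unknown". Ties break by larger raw overlap,
#' then lexicographic type name. A per-type hypergeometric enrichment p-value
#' is reported alongside as a cross-check when `universe` is given.
#'
#' @param cluster_genes named list: cluster -> gene ids
#'   (see [cluster_gene_lists()]).
#' @param db a `MarkerDatabase`.
#' @param alpha significance level on BH-corrected p, default 0.05.
#' @param min_overlap minimum overlap at the winning type, default 2.
#' @param universe optional character vector of background genes for the
#'   hypergeometric cross-check.
#' @return A `CellTypeAssignment`: list with `table` (one row per cluster:
#'   `cluster`, `assigned_type`, `chi2`, `df`, `p`, `q`, `top_overlap`,
#'   `reason`), `overlap_counts` (cluster x type matrix) and `cluster_markers`
#'   (genes driving each call).
#' @export
assign_cell_types <- function(cluster_genes, db, alpha = 0.05, min_overlap = 2,
                              universe = NULL) {
  stopifnot(inherits(db, "MarkerDatabase"))
  types <- sort(names(db$entries))
  sizes <- vapply(db$entries[types], length, 1L)
  clusters <- names(cluster_genes)
  O <- matrix(0L, length(clusters), length(types),
              dimnames = list(clusters, types))
  chi2 <- p <- rep(NA_real_, length(clusters))
  cand <- character(length(clusters))
  reason <- character(length(clusters))
  hyper <- if (!is.null(universe))
    matrix(NA_real_, length(clusters), length(types),
           dimnames = list(clusters, types))
  for (i in seq_along(clusters)) {
    g <- cluster_genes[[i]]
    O[i, ] <- vapply(types, function(t) length(intersect(g, db$entries[[t]])), 1L)
    tot <- sum(O[i, ])
    if (!length(g)) { cand[i] <- NA; reason[i] <- "no variable genes"; next }
    if (tot == 0) { cand[i] <- NA; reason[i] <- "no marker overlap"; next }
    E <- tot * sizes / sum(sizes)
    chi2[i] <- sum((O[i, ] - E)^2 / E)
    p[i] <- stats::pchisq(chi2[i], df = length(types) - 1, lower.tail = FALSE)
    resid <- (O[i, ] - E) / sqrt(E)
    ord <- order(-resid, -O[i, ], types)
    cand[i] <- types[ord[1]]
    if (!is.null(universe)) {
      nq <- length(intersect(g, universe))
      for (t in seq_along(types)) {
        Ks <- length(intersect(db$entries[[types[t]]], universe))
        hyper[i, t] <- stats::phyper(O[i, t] - 1, Ks,
                                     length(universe) - Ks, nq,
                                     lower.tail = FALSE)
      }
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  assigned <- rep("Unknown", length(clusters))
  markers <- vector("list", length(clusters))
  names(markers) <- clusters
  for (i in seq_along(clusters)) {
    ok <- !is.na(cand[i]) && !is.na(q[i]) && q[i] < alpha &&
      O[i, cand[i]] >= min_overlap
    if (ok) {
      assigned[i] <- cand[i]
      markers[[i]] <- intersect(cluster_genes[[i]], db$entries[[cand[i]]])
      reason[i] <- ""
    } else if (reason[i] == "") {
      reason[i] <- if (!is.na(q[i]) && q[i] >= alpha) "not significant"
      else "overlap below min_overlap"
    }
  }
  tab <- data.frame(cluster = clusters, assigned_type = assigned,
                    chi2 = chi2, df = length(types) - 1, p = p, q = q,
                    top_overlap = vapply(seq_along(clusters), function(i)
                      if (is.na(cand[i])) 0L else O[i, cand[i]], 1L),
                    reason = reason, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, overlap_counts = O, cluster_markers = markers,
                 hypergeom_p = hyper),
            class = "CellTypeAssignment")
}

#' @export
print.CellTypeAssignment <- function(x, ...) {
  cat("CellTypeAssignment:\n")
  print(x$table[, c("cluster", "assigned_type", "chi2", "p", "q",
                    "top_overlap")], row.names = FALSE)
  invisible(x)
}

#' Count markers per biotype class
#'
#' @param markers character vector of marker gene ids, or a named list of such
#'   vectors (e.g. per cell type).
#' @param ann a `GeneAnnotation`; every marker must be annotated.
#' @return For a vector, a named integer vector `(coding, lncRNA, pcRNA)`;
#'   for a list, a matrix with one row per list element.
#' @export
classify_markers_by_biotype <- function(markers, ann) {
  classes <- c("coding", "lncRNA", "pcRNA")
  one <- function(g) {
    g <- as.character(g)
    bt <- stats::setNames(ann$biotype, ann$gene_id)[g]
    if (anyNA(bt))
      stop("unannotated marker gene(s): ",
           paste(utils::head(g[is.na(bt)], 5), collapse = ", "), call. = FALSE)
    vapply(classes, function(cl) sum(bt == cl), 1L)
  }
  if (is.list(markers)) {
    out <- t(vapply(markers, one, integer(3)))
    colnames(out) <- classes
    out
  } else one(markers)
}

#' Shared and unique markers across compartments
#'
#' Full inclusion-exclusion (Venn) region counts for 2 to 4 marker sets,
#' e.g. shared vs compartment-unique transcripts.
#'
#' @param sets named list of 2-4 character vectors.
#' @return `data.frame` with columns `region` (set names joined by `&`),
#'   `count`, and `genes` (comma-joined ids). Regions with zero members are
#'   included.
#' @export
compare_marker_sets <- function(sets) {
  k <- length(sets)
  if (k < 2) stop("need at least 2 sets", call. = FALSE)
  if (k > 4)
    stop("Venn region counts support at most 4 sets (got ", k,
         "); compare pairwise instead", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  all_genes <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1)
  out <- list()
  for (code in seq_len(2^k - 1)) {
    in_set <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    sel <- if (length(all_genes))
      apply(memb, 1, function(row) all(row == in_set)) else logical(0)
    out[[length(out) + 1]] <- data.frame(
      region = paste(names(sets)[in_set], collapse = "&"),
      count = sum(sel),
      genes = paste(sort(all_genes[sel]), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
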