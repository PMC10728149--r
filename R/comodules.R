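#' Scale-free topology fit of a connectivity distribution
#'
#' Discretises connectivity into `nbins` equal-width bins, regresses
#' log10(frequency) on log10(bin-mean k), and returns the R^2 of the fit
#' signed by the slope: positive only when the degree distribution decays
#' (negative slope), the scale-free signature.
#'
#' @param k positive connectivity values.
#' @param nbins histogram bins, default 10.
#' @return List with `r2` (signed), `slope`.
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < 3 || length(unique(k)) < 3)
    return(list(r2 = 0, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = nbins + 1)
  breaks[1] <- breaks[1] * (1 - 1e-9)
  bin <- cut(k, breaks, labels = FALSE, include.lowest = TRUE)
  xs <- log10(tapply(k, bin, mean))
  ys <- log10(tapply(k, bin, length) / length(k))
  if (length(xs) < 3 || length(unique(xs)) < 3)
    return(list(r2 = 0, slope = NA_real_))
  slope <- stats::cov(xs, ys) / stats::var(xs)
  r2 <- stats::cor(xs, ys)^2
  list(r2 = -sign(slope) * r2, slope = slope)
}

#' Select the soft-thresholding power
#'
#' For each candidate power beta, raises |correlation| to beta, computes each
#' gene's connectivity k_i = sum_j |corr_ij|^beta (j != i), and scores how
#' well the connectivity distribution follows a power law
#' (see [scale_free_fit()]). Returns the smallest beta whose signed R^2
#' reaches `r2_min` while the network retains nontrivial connectivity
#' (mean k >= `min_mean_k`), or `NA` when none qualifies — the explicit
#' "no scale-free fit" outcome. The connectivity floor matters: raising beta
#' far enough makes any correlation matrix — including pure noise — look
#' scale-free in the binned log-log fit, but only because the network has
#' evaporated (mean k near 0), so such powers must not qualify.
#'
#' @param corr gene x gene correlation matrix.
#' @param betas candidate powers, default `1:20`.
#' @param r2_min minimum signed R^2, default 0.8.
#' @param min_mean_k minimum mean connectivity for a power to qualify,
#'   default 0.5.
#' @return List with `beta` (integer or `NA`), and `table` (beta, r2, slope,
#'   mean_k).
#' @export
select_soft_threshold <- function(corr, betas = 1:20, r2_min = 0.8,
                                  min_mean_k = 0.5) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (nrow(corr) < 50)
    warning("fewer than 50 genes; soft-threshold selection is unstable",
            call. = FALSE)
  a <- abs(corr); diag(a) <- 0
  tab <- data.frame(beta = as.integer(betas), r2 = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(betas)) {
    k <- rowSums(a^betas[i])
    f <- scale_free_fit(k)
    tab$r2[i] <- f$r2; tab$slope[i] <- f$slope; tab$mean_k[i] <- mean(k)
  }
  ok <- which(tab$r2 >= r2_min & tab$mean_k >= min_mean_k)
  list(beta = if (length(ok)) tab$beta[min(ok)] else NA_integer_, table = tab)
}

#' Adjacency and topological-overlap dissimilarity
#'
#' Unsigned adjacency a_ij = |corr_ij|^beta; topological overlap
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_u a_iu a_uj; dissimilarity 1 - TOM with zero diagonal.
#'
#' @param corr gene x gene correlation matrix.
#' @param beta soft power >= 1.
#' @return List with `adjacency` and `dissimilarity` matrices.
#' @export
adjacency_tom <- function(corr, beta) {
  stopifnot(beta >= 1)
  a <- abs(corr)^beta
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  diag(d) <- 0
  dimnames(d) <- dimnames(a) <- dimnames(corr)
  list(adjacency = a, dissimilarity = d)
}

#' Detect co-expression modules by tree cut
#'
#' Average-linkage tree on the TOM dissimilarity, statically cut at height
#' `cut_height`; branches smaller than `min_size` go to `not_assigned`. When
#' no branch survives — or when no soft power gave a scale-free fit
#' (`beta = NA`) — the result is the explicit no-modules outcome with a
#' machine-readable reason, mirroring datasets where guilt-by-association
#' retrieves no modular pattern.
#'
#' @param dissim TOM dissimilarity matrix (or `NULL` when `beta` is `NA`).
#' @param min_size minimum module size, default 30.
#' @param cut_height static cut height, default 0.998.
#' @param beta the selected soft power (recorded; pass `NA` for the
#'   no-scale-free-fit outcome).
#' @param scale_free_r2 the achieved signed R^2 (recorded).
#' @return A `ModuleSet`: list with `modules` (label -> gene ids, ordered by
#'   decreasing size), `not_assigned`, `beta`, `scale_free_r2`, `status`
#'   (`"ok"` or `"no-modules"`), `reason`.
#' @export
detect_modules <- function(dissim, min_size = 30, cut_height = 0.998,
                           beta = NA_integer_, scale_free_r2 = NA_real_) {
  if (is.na(beta)) {
    return(structure(list(modules = list(), not_assigned =
                            if (is.null(dissim)) character() else rownames(dissim),
                          beta = NA_integer_, scale_free_r2 = scale_free_r2,
                          hubs = list(), status = "no-modules",
                          reason = "no scale-free fit"),
                     class = "ModuleSet"))
  }
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  genes <- rownames(dissim)
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  # tied distances can leave merge heights epsilon-decreasing, which cutree
  # rejects; enforce monotone heights
  hc$height <- cummax(hc$height)
  branch <- stats::cutree(hc, h = cut_height)
  sizes <- table(branch)
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep)) {
    return(structure(list(modules = list(), not_assigned = genes,
                          beta = beta, scale_free_r2 = scale_free_r2,
                          hubs = list(), status = "no-modules",
                          reason = paste0("no branch >= ", min_size, " genes")),
                     class = "ModuleSet"))
  }
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  modules <- stats::setNames(
    lapply(keep, function(b) sort(genes[branch == as.integer(b)])),
    paste0("M", seq_along(keep)))
  structure(list(modules = modules,
                 not_assigned = sort(setdiff(genes, unlist(modules))),
                 beta = beta, scale_free_r2 = scale_free_r2,
                 hubs = list(), status = "ok", reason = ""),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  if (x$status == "no-modules") {
    cat("ModuleSet: no modules (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("ModuleSet: %d modules (beta = %d, scale-free R2 = %.2f)\n",
                length(x$modules), x$beta, x$scale_free_r2))
    for (nm in names(x$modules))
      cat(sprintf("  %s: %d genes\n", nm, length(x$modules[[nm]])))
    cat("  not assigned:", length(x$not_assigned), "genes\n")
  }
  invisible(x)
}

#' Hub genes of a module
#'
#' Ranks module members by intramodular connectivity (row sum of adjacency
#' restricted to the module), lexicographic tie-break.
#'
#' @param adjacency gene x gene adjacency matrix.
#' @param module character vector of module member gene ids.
#' @param n number of hubs to return, default 10.
#' @return Character vector of up to `n` gene ids, most connected first.
#' @export
hub_genes <- function(adjacency, module, n = 10) {
  miss <- setdiff(module, rownames(adjacency))
  if (length(miss))
    stop("module gene(s) absent from adjacency: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  a <- adjacency[module, module, drop = FALSE]
  k_in <- rowSums(a)
  module[order(-k_in, module)][seq_len(min(n, length(module)))]
}

#' Full co-expression module discovery on an expression matrix
#'
#' Convenience wrapper: variance pre-filter (top `var_quantile` of genes),
#' Pearson correlation on log2 FPKM, soft-threshold selection, TOM, tree cut,
#' hub extraction.
#'
#' @param m an `ExpressionMatrix` with unit `"log2fpkm"`.
#' @param var_quantile keep genes above this variance quantile, default 0.25
#'   (i.e. top 75 percent by variance).
#' @param betas,r2_min passed to [select_soft_threshold()].
#' @param min_size,cut_height passed to [detect_modules()].
#' @param n_hubs hubs per module, default 10.
#' @return A `ModuleSet` with `hubs` filled in.
#' @export
find_modules <- function(m, var_quantile = 0.25, betas = 1:20, r2_min = 0.8,
                         min_size = 30, cut_height = 0.998, n_hubs = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "log2fpkm")
    stop("find_modules expects unit 'log2fpkm'", call. = FALSE)
  vars <- apply(m$values, 1, stats::var)
  keep <- vars >= stats::quantile(vars, var_quantile) & vars > 0
  v <- m$values[keep, , drop = FALSE]
  corr <- suppressWarnings(stats::cor(t(v)))
  corr[!is.finite(corr)] <- 0
  sel <- select_soft_threshold(corr, betas, r2_min)
  if (is.na(sel$beta)) {
    ms <- detect_modules(NULL, min_size, cut_height, beta = NA_integer_,
                         scale_free_r2 = max(sel$table$r2))
    ms$not_assigned <- rownames(corr)
    return(ms)
  }
  at <- adjacency_tom(corr, sel$beta)
  ms <- detect_modules(at$dissimilarity, min_size, cut_height,
                       beta = sel$beta,
                       scale_free_r2 = sel$table$r2[sel$table$beta == sel$beta])
  if (ms$status == "ok")
    ms$hubs <- lapply(ms$modules, function(g) hub_genes(at$adjacency, g, n_hubs))
  attr(ms, "adjacency") <- at$adjacency
  ms
}

#' Profile modules: ORA, per-cell-type GSEA, biotype mix, network overlay
#'
#' For every module: over-representation against a gene-set collection
#' (universe = all genes of `m`), one-vs-rest permutation GSEA per assigned
#' cell type, biotype composition counts, and (optionally) the user-supplied
#' interaction edges falling inside the module merged with the module's top
#' co-expression pairs.
#'
#' @param ms a `ModuleSet` with status `"ok"`.
#' @param m an `ExpressionMatrix` (log2fpkm) over the same cells.
#' @param cell_types named vector: cell id -> assigned cell-type label
#'   (e.g. planted truth or [assign_cell_types()] labels propagated to cells).
#' @param sets a `GeneSetCollection` (may be empty; ORA table is then empty).
#' @param ann a `GeneAnnotation` for biotype composition.
#' @param net optional `InteractionNetwork` overlay.
#' @param n_perm,seed GSEA permutation settings.
#' @param top_pairs number of top co-expression pairs in the overlay,
#'   default 20.
#' @return Named list (one entry per module): `ora`, `gsea` (rows per cell
#'   type), `biotype_counts`, `edges`.
#' @export
module_profile <- function(ms, m, cell_types, sets, ann, net = NULL,
                           n_perm = 200, seed = 1, top_pairs = 20) {
  stopifnot(inherits(ms, "ModuleSet"))
  if (ms$status != "ok")
    stop("module_profile requires status 'ok' (got '", ms$status, "': ",
         ms$reason, ")", call. = FALSE)
  if (is.null(names(cell_types))) names(cell_types) <- m$cell_ids
  universe <- m$gene_ids
  adj <- attr(ms, "adjacency")
  out <- list()
  for (lab in names(ms$modules)) {
    genes <- ms$modules[[lab]]
    mod_ora <- ora(genes, sets, universe)
    gsc_one <- gene_set_collection(stats::setNames(list(genes), lab))
    gsea_rows <- list()
    for (ct in sort(unique(cell_types))) {
      n_t <- sum(cell_types == ct)
      if (n_t < 3 || n_t > length(cell_types) - 3) next
      cls <- ifelse(cell_types[m$cell_ids] == ct, "target", "rest")
      names(cls) <- m$cell_ids
      gr <- gsea_permutation(m, cls, gsc_one, n_perm = n_perm, seed = seed)
      gr$cell_type <- ct
      gsea_rows[[ct]] <- gr
    }
    gsea_tab <- if (length(gsea_rows)) do.call(rbind, gsea_rows) else NULL
    edges <- NULL
    if (!is.null(adj)) {
      sub <- adj[genes, genes, drop = FALSE]
      iu <- which(upper.tri(sub), arr.ind = TRUE)
      ord <- order(-sub[iu], genes[iu[, 1]], genes[iu[, 2]])
      pick <- iu[ord[seq_len(min(top_pairs, nrow(iu)))], , drop = FALSE]
      edges <- data.frame(from = genes[pick[, 1]], to = genes[pick[, 2]],
                          weight = sub[pick], source = "coexpression",
                          stringsAsFactors = FALSE)
    }
    if (!is.null(net)) {
      inside <- net$edges[net$edges$from %in% genes & net$edges$to %in% genes, ,
                          drop = FALSE]
      if (nrow(inside)) {
        inside$source <- "interaction"
        edges <- rbind(edges, inside[, c("from", "to", "weight", "source")])
      }
    } else if (is.null(net)) {
      message("no interaction network supplied; overlay limited to ",
              "co-expression pairs")
    }
    out[[lab]] <- list(ora = mod_ora, gsea = gsea_tab,
                       biotype_counts = classify_markers_by_biotype(genes, ann),
                       edges = edges)
  }
  out
}
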