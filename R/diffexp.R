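#' Median-of-ratios size factors
#'
#' Per-cell scaling factors computed the DESeq way: the reference profile is
#' the genewise geometric mean over cells (genes with any zero excluded), and
#' each cell's factor is the median over genes of count/reference. If no gene
#' is nonzero in all cells, falls back to total-count scaling (normalised to
#' geometric mean 1) with a warning.
#'
#' @param counts an `ExpressionMatrix` with unit `"counts"`.
#' @return Named positive numeric vector, one factor per cell.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts")
    stop("size_factors expects unit 'counts'", call. = FALSE)
  v <- counts$values
  all_nz <- rowSums(v == 0) == 0
  if (!any(all_nz)) {
    warning("no gene has nonzero counts in every cell; ",
            "falling back to total-count scaling", call. = FALSE)
    totals <- colSums(v)
    sf <- totals / exp(mean(log(totals)))
  } else {
    vv <- v[all_nz, , drop = FALSE]
    ref <- exp(rowMeans(log(vv)))
    sf <- apply(vv / ref, 2, stats::median)
  }
  stats::setNames(sf, counts$cell_ids)
}

#' Method-of-moments negative-binomial dispersion
#'
#' On size-factor-normalised counts, estimates a per-gene dispersion under the
#' NB2 parameterisation Var = mu + phi * mu^2 by pooling the within-group
#' moment estimates (s^2 - mu)/mu^2 across the two groups (weights n_k - 1),
#' floored at `phi_min`.
#'
#' @param counts an `ExpressionMatrix` with unit `"counts"`.
#' @param groups two-level factor/vector over cells.
#' @param sf size factors from [size_factors()].
#' @param phi_min floor, default 1e-8.
#' @return Named per-gene numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, groups, sf, phi_min = 1e-8) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs >= 2 cells", call. = FALSE)
  y <- sweep(counts$values, 2, sf, "/")
  num <- 0; den <- 0
  for (g in levels(groups)) {
    yk <- y[, groups == g, drop = FALSE]
    nk <- ncol(yk)
    mu <- rowMeans(yk)
    s2 <- row_sds(yk)^2
    phi_k <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    num <- num + (nk - 1) * phi_k
    den <- den + (nk - 1)
  }
  phi <- pmax(phi_min, num / den)
  stats::setNames(phi, counts$gene_ids)
}

#' Negative-binomial Wald test between two subpopulations
#'
#' For each gene, compares the group means of normalised counts on the log
#' scale. The log2 fold change uses a 0.5 pseudocount on each group mean; the
#' Wald statistic z = log(mu2/mu1)/SE uses the raw means with the delta-method
#' variance Var(log mu_hat) = (1/mu_hat + phi)/n per group. When exactly one
#' group mean is zero the raw statistic is undefined, so the pseudocounted
#' means are used for z as well (flagged in the `degenerate` column). Genes
#' zero in both groups are excluded.
#'
#' @param counts an `ExpressionMatrix` with unit `"counts"`.
#' @param groups two-level factor over cells; fold changes are level 2 vs
#'   level 1.
#' @param sf size factors; computed if `NULL`.
#' @param phi per-gene dispersions; estimated if `NULL`.
#' @return A `DEResult`: `data.frame` with `gene_id`, `base_mean`, `log2fc`,
#'   `se`, `wald_z`, `p`, `q`, `degenerate`, plus attributes `groups`
#'   (level names) and `group_sizes`.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL, phi = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(phi)) phi <- estimate_dispersion(counts, groups, sf)
  y <- sweep(counts$values, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(y[, g1, drop = FALSE])
  mu2 <- rowMeans(y[, g2, drop = FALSE])
  keep <- mu1 > 0 | mu2 > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) zero in both groups excluded from DE")
  mu1 <- mu1[keep]; mu2 <- mu2[keep]; phi_k <- phi[keep]
  log2fc <- log2((mu2 + 0.5) / (mu1 + 0.5))
  degenerate <- mu1 == 0 | mu2 == 0
  m1 <- ifelse(degenerate, mu1 + 0.5, mu1)
  m2 <- ifelse(degenerate, mu2 + 0.5, mu2)
  se <- sqrt((1 / m1 + phi_k) / n1 + (1 / m2 + phi_k) / n2)
  z <- log(m2 / m1) / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = counts$gene_ids[keep],
                    base_mean = (n1 * mu1 + n2 * mu2) / (n1 + n2),
                    log2fc = log2fc, se = se, wald_z = z, p = p, q = q,
                    degenerate = degenerate, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  attr(out, "groups") <- levels(groups)
  attr(out, "group_sizes") <- c(n1, n2)
  out
}

#' Volcano-style DE counts per biotype
#'
#' Classifies every tested gene as up, down or not significant at the given
#' fold-change and significance cut-offs (defaults 1.5 and 0.05) and counts
#' by direction within each biotype class. A gene is `up` when its adjusted
#' p (or raw p with `use_raw_p = TRUE`) is below `p_cut` and its log2 fold
#' change is at least `log2(fc_cut)`; `down` is symmetric.
#'
#' @param r a `DEResult`.
#' @param ann a `GeneAnnotation` for the biotype split.
#' @param fc_cut fold-change cut-off (linear scale), default 1.5.
#' @param p_cut significance cut-off, default 0.05.
#' @param use_raw_p use raw p instead of BH-adjusted q.
#' @return List with `direction` (named per-gene factor up/down/ns) and
#'   `counts` (`data.frame`: biotype x n_up/n_down/n_total_de).
#' @export
volcano_summary <- function(r, ann, fc_cut = 1.5, p_cut = 0.05,
                            use_raw_p = FALSE) {
  stopifnot(inherits(r, "DEResult"))
  sig <- if (use_raw_p) r$p else r$q
  lfc_cut <- log2(fc_cut)
  dir <- ifelse(sig < p_cut & r$log2fc >= lfc_cut, "up",
                ifelse(sig < p_cut & r$log2fc <= -lfc_cut, "down", "ns"))
  bt <- stats::setNames(ann$biotype, ann$gene_id)[r$gene_id]
  classes <- c("coding", "lncRNA", "pcRNA")
  counts <- do.call(rbind, lapply(classes, function(cl) {
    sel <- !is.na(bt) & bt == cl
    data.frame(biotype = cl,
               n_up = sum(dir[sel] == "up"),
               n_down = sum(dir[sel] == "down"),
               stringsAsFactors = FALSE)
  }))
  counts$n_total_de <- counts$n_up + counts$n_down
  list(direction = stats::setNames(factor(dir, c("up", "down", "ns")),
                                   r$gene_id),
       counts = counts)
}

#' Name subpopulations after their top coding gene
#'
#' Each subpopulation is labelled "<Symbol>-CM" after the coding gene with the
#' highest mean FPKM among its cells. If both groups share the same top gene,
#' each falls back to the coding gene maximising the between-group mean
#' difference in its favour (lexicographic symbol tie-break), so the two names
#' always differ.
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`.
#' @param ann a `GeneAnnotation` identifying coding genes.
#' @param groups two-level factor over cells.
#' @param suffix name suffix, default `"-CM"` (cardiomyocyte).
#' @return Character vector of two names, in level order of `groups`.
#' @export
name_subpopulations <- function(m, ann, groups, suffix = "-CM") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  coding <- ann$gene_id[ann$biotype == "coding"]
  coding <- intersect(m$gene_ids, coding)
  if (!length(coding)) stop("no coding genes in the matrix", call. = FALSE)
  sym <- stats::setNames(ann$symbol, ann$gene_id)
  v <- m$values[coding, , drop = FALSE]
  mu1 <- rowMeans(v[, groups == levels(groups)[1], drop = FALSE])
  mu2 <- rowMeans(v[, groups == levels(groups)[2], drop = FALSE])
  top <- function(score) coding[order(-score, sym[coding])][1]
  t1 <- top(mu1); t2 <- top(mu2)
  if (t1 == t2) { # shared top gene: use the most group-distinguishing gene
    t1 <- top(mu1 - mu2)
    t2 <- top(mu2 - mu1)
  }
  paste0(sym[c(t1, t2)], suffix)
}
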