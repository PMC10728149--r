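# fast row standard deviations (equivalent to apply(x, 1, sd))
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(0, (rowSums(x * x) - n * m^2) / (n - 1)))
}

#' Over-representation analysis (hypergeometric)
#'
#' Tests each gene set for enrichment in a query list against a background
#' universe with the upper-tail hypergeometric P(X >= k), BH-corrected across
#' sets. The gene ratio is observed/expected overlap, k / (n_q * K_s / N).
#'
#' @param query character vector of genes of interest (intersected with the
#'   universe).
#' @param sets a `GeneSetCollection`.
#' @param universe character vector of background genes (typically all
#'   post-filter genes of the dataset).
#' @param q_cut reporting cut-off stored alongside (results are not filtered).
#' @return `data.frame` (class `EnrichmentResult`) with one row per set:
#'   `set`, `k`, `K_s`, `n_q`, `N`, `p`, `q`, `gene_ratio`, `genes`; sorted by
#'   `q` then decreasing `gene_ratio`. Sets with no member in the universe are
#'   dropped.
#' @export
ora <- function(query, sets, universe, q_cut = 0.05) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe); n_q <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    if (!length(s)) return(NULL)
    ov <- intersect(query, s)
    k <- length(ov); K_s <- length(s)
    p <- stats::phyper(k - 1, K_s, N - K_s, n_q, lower.tail = FALSE)
    data.frame(set = nm, k = k, K_s = K_s, n_q = n_q, N = N, p = p,
               gene_ratio = if (n_q > 0) k / (n_q * K_s / N) else 0,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), k = integer(), K_s = integer(),
                      n_q = integer(), N = integer(), p = numeric(),
                      gene_ratio = numeric(), genes = character(),
                      stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, -out$gene_ratio, out$set), ,
             drop = FALSE]
  out <- out[, c("set", "k", "K_s", "n_q", "N", "p", "q", "gene_ratio", "genes")]
  rownames(out) <- NULL
  attr(out, "q_cut") <- q_cut
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Signal-to-noise ranking statistic
#'
#' Per-gene signed score contrasting a target cell class against the rest:
#' (mu_t - mu_r) / (sd_t + sd_r), with each standard deviation floored at
#' 0.125 * max(|class mean|, 1) to keep near-constant genes from exploding
#' the ratio. Ordering ties break lexicographically by gene id.
#'
#' @param m an `ExpressionMatrix` (typically log2fpkm).
#' @param class_labels named vector over cells with two levels, `"target"`
#'   and `"rest"` (or any two levels; the first sorted level is the target —
#'   pass a factor to control this).
#' @return Named per-gene numeric vector, sorted decreasing (target-high
#'   genes first).
#' @export
rank_statistic <- function(m, class_labels) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(names(class_labels))) names(class_labels) <- m$cell_ids
  f <- as.factor(class_labels[m$cell_ids])
  if (nlevels(f) != 2) stop("class_labels needs exactly two levels", call. = FALSE)
  target <- if ("target" %in% levels(f)) "target" else levels(f)[1]
  t_cells <- m$cell_ids[f == target]
  r_cells <- m$cell_ids[f != target]
  if (length(t_cells) < 3 || length(r_cells) < 3)
    stop("both classes need >= 3 cells", call. = FALSE)
  vt <- m$values[, t_cells, drop = FALSE]
  vr <- m$values[, r_cells, drop = FALSE]
  mu_t <- rowMeans(vt); mu_r <- rowMeans(vr)
  sd_t <- row_sds(vt); sd_r <- row_sds(vr)
  sd_t <- pmax(sd_t, 0.125 * pmax(abs(mu_t), 1))
  sd_r <- pmax(sd_r, 0.125 * pmax(abs(mu_r), 1))
  score <- (mu_t - mu_r) / (sd_t + sd_r)
  names(score) <- m$gene_ids
  score[order(-score, names(score))]
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked gene list; set members ("hits") add |score|^weight
#' normalised by the total hit weight, non-members subtract 1/(N - m). The ES
#' is the signed extremum of the running sum. When the set covers the whole
#' ranking there are no misses and the ES is 0 by convention.
#'
#' @param ranked named numeric vector of scores, in ranking order
#'   (e.g. from [rank_statistic()]).
#' @param set character vector of gene ids; must intersect the ranking.
#' @param weight exponent on |score| for hit increments, default 1
#'   (`weight = 0` gives the unweighted Kolmogorov-Smirnov form).
#' @return The enrichment score in [-1, 1].
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  genes <- names(ranked)
  hit <- genes %in% set
  m <- sum(hit)
  if (m == 0) stop("gene set is disjoint from the ranking", call. = FALSE)
  N <- length(genes)
  if (m == N) return(0)
  w <- abs(ranked)^weight
  inc <- numeric(N)
  wsum <- sum(w[hit])
  inc[hit] <- if (wsum > 0) w[hit] / wsum else 1 / m
  inc[!hit] <- -1 / (N - m)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Permutation GSEA over cell classes
#'
#' For each gene set, computes the observed ES from the signal-to-noise
#' ranking of `class_labels`, then permutes the class labels `n_perm` times
#' (seeded, degenerate single-class permutations resampled) and recomputes
#' the ES. The permutation p-value compares against same-sign permuted ES:
#' p = (1 + #{|ES_perm| >= |ES_obs|, same sign}) / (n_same_sign + 1); the NES
#' divides the ES by the mean |same-sign permuted ES|. BH correction across
#' sets.
#'
#' @param m an `ExpressionMatrix`.
#' @param class_labels named two-level vector over cells
#'   (see [rank_statistic()]).
#' @param sets a `GeneSetCollection`.
#' @param n_perm number of permutations, >= 100; default 1000.
#' @param seed integer seed; identical inputs and seed reproduce the result.
#' @param weight hit-weight exponent for [gsea_es()].
#' @return `data.frame` (class `GseaResult`): `set`, `es`, `nes`, `p_perm`,
#'   `q`, `n_perm`, `seed`. Sets disjoint from the ranking are skipped.
#' @export
gsea_permutation <- function(m, class_labels, sets, n_perm = 1000, seed = 1,
                             weight = 1) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(names(class_labels))) names(class_labels) <- m$cell_ids
  obs_rank <- rank_statistic(m, class_labels)
  keep <- names(sets$sets)[vapply(sets$sets, function(s)
    length(intersect(s, names(obs_rank))) > 0, logical(1))]
  es_obs <- vapply(keep, function(nm) gsea_es(obs_rank, sets$sets[[nm]], weight),
                   numeric(1))
  labs <- class_labels[m$cell_ids]
  es_perm <- matrix(NA_real_, n_perm, length(keep),
                    dimnames = list(NULL, keep))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  b <- 1
  while (b <= n_perm) {
    pl <- sample(labs)
    if (length(unique(pl)) < 2) next # degenerate permutation, resample
    names(pl) <- m$cell_ids
    pr <- rank_statistic(m, pl)
    es_perm[b, ] <- vapply(keep, function(nm)
      gsea_es(pr, sets$sets[[nm]], weight), numeric(1))
    b <- b + 1
  }
  p_perm <- nes <- numeric(length(keep))
  for (j in seq_along(keep)) {
    same <- es_perm[, j] * sign(es_obs[j]) >= 0
    if (es_obs[j] == 0) same <- rep(TRUE, n_perm)
    n_same <- sum(same)
    p_perm[j] <- (1 + sum(abs(es_perm[same, j]) >= abs(es_obs[j]))) /
      (n_same + 1)
    mean_abs <- mean(abs(es_perm[same, j]))
    nes[j] <- if (n_same > 0 && mean_abs > 0) es_obs[j] / mean_abs else NA_real_
  }
  out <- data.frame(set = keep, es = unname(es_obs), nes = nes,
                    p_perm = p_perm, q = stats::p.adjust(p_perm, "BH"),
                    n_perm = n_perm, seed = seed, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("GseaResult", "data.frame")
  out
}
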