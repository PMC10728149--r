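#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: several cell types with elevated (planted) marker genes, two
#' cardiomyocyte-like subpopulations with planted fold changes, co-expression
#' modules driven by per-cell latent factors, negative-binomial counts and
#' Michaelis-Menten-shaped dropout.
#'
#' @param n_types number of planted cell types (default 5).
#' @param cells_per_type cells per type (default 100).
#' @param n_genes named integer vector of gene counts per biotype class,
#'   default `c(coding = 1200, lncRNA = 600, pcRNA = 200)`.
#' @param markers_per_type planted (disjoint) marker genes per type, default 20.
#' @param marker_log2_shift log2 mean elevation of a marker in its own type,
#'   default 3.
#' @param marker_baseline_log2_offset log2 offset applied to the baselines of
#'   restricted transcripts (markers and subpopulation-DE genes), default
#'   -2.5: cell-type-restricted transcripts are less abundant overall than
#'   broadly expressed genes, which places their off state near the dropout
#'   half-point.
#' @param subpop_de_count genes with a planted fold change between the two
#'   cardiomyocyte-like subpopulations, default 40 (0 disables the split).
#' @param subpop_log2fc magnitude of the planted subpopulation log2 fold
#'   change, default 2.5 (0 disables the split).
#' @param n_bg_factors number of weak background co-regulation factors shared
#'   by all non-planted genes, default 20. Real transcriptomes are pervasively
#'   co-regulated; these factors give the co-expression network its
#'   heavy-tailed connectivity without forming discrete modules. 0 disables
#'   background co-regulation (a "pure noise" co-expression structure).
#' @param bg_loading_rate exponential rate for per-gene background loading
#'   strengths (larger = weaker background), default 2.
#' @param nb_mean_baseline median baseline mean count per gene, default 50.
#' @param baseline_sdlog log-sd of the lognormal gene baseline spread,
#'   default 1.
#' @param nb_dispersion NB dispersion phi (Var = mu + phi mu^2), default 0.4.
#' @param mm_K Michaelis-Menten dropout half-point in FPKM units, default 10
#'   (0 disables extra dropout).
#' @param module_count planted co-expression modules, default 3.
#' @param module_size genes per module, default 60.
#' @param module_latent_sd sd of the per-cell module latent factor (log2
#'   scale), default 1.
#' @param gene_length_range transcript length range in bp, default
#'   `c(500, 5000)`.
#' @param seed RNG seed, default 1.
#' @return A validated `GeneratorConfig` list.
#' @export
generator_config <- function(n_types = 5, cells_per_type = 100,
                             n_genes = c(coding = 1200, lncRNA = 600, pcRNA = 200),
                             markers_per_type = 20, marker_log2_shift = 3,
                             marker_baseline_log2_offset = -2.5,
                             subpop_de_count = 40, subpop_log2fc = 2.5,
                             n_bg_factors = 20, bg_loading_rate = 2,
                             nb_mean_baseline = 50, baseline_sdlog = 1,
                             nb_dispersion = 0.4, mm_K = 10,
                             module_count = 3, module_size = 60,
                             module_latent_sd = 1,
                             gene_length_range = c(500, 5000), seed = 1) {
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = n_genes, markers_per_type = as.integer(markers_per_type),
              marker_log2_shift = marker_log2_shift,
              marker_baseline_log2_offset = marker_baseline_log2_offset,
              subpop_de_count = as.integer(subpop_de_count),
              subpop_log2fc = subpop_log2fc,
              n_bg_factors = as.integer(n_bg_factors),
              bg_loading_rate = bg_loading_rate,
              nb_mean_baseline = nb_mean_baseline,
              baseline_sdlog = baseline_sdlog,
              nb_dispersion = nb_dispersion, mm_K = mm_K,
              module_count = as.integer(module_count),
              module_size = as.integer(module_size),
              module_latent_sd = module_latent_sd,
              gene_length_range = gene_length_range, seed = as.integer(seed))
  if (!all(c("coding", "lncRNA", "pcRNA") %in% names(cfg$n_genes)))
    stop("n_genes must name coding, lncRNA and pcRNA counts", call. = FALSE)
  if (cfg$n_types < 1 || cfg$cells_per_type < 1 || any(cfg$n_genes < 1))
    stop("all counts must be >= 1", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (cfg$mm_K < 0) stop("mm_K must be >= 0", call. = FALSE)
  n_special <- cfg$n_types * cfg$markers_per_type +
    cfg$module_count * cfg$module_size + cfg$subpop_de_count
  if (n_special > sum(cfg$n_genes))
    stop("marker/module/DE gene demand (", n_special,
         ") exceeds total gene count (", sum(cfg$n_genes), ")", call. = FALSE)
  class(cfg) <- "GeneratorConfig"
  cfg
}

type_name_pool <- c("cardiomyocyte", "endothelial", "fibroblast",
                    "macrophage", "myoblast", "T-cell", "dendritic", "mural")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Inject Michaelis-Menten-shaped dropout into a count matrix
#'
#' Targets a total zero fraction of P = 1 - S/(mm_K + S). Since sampling
#' noise already produces zeros at a realised per-gene rate p_nb, entries are
#' independently zeroed with the excess probability
#' max(0, P - p_nb)/(1 - p_nb), so the expected zero fraction matches the
#' target. `fpkm_means` may be a per-gene vector (one target per gene) or a
#' gene x cell matrix of underlying per-cell means — dropout in a cell is then
#' driven by how strongly the cell expresses the gene, the premise the
#' dropout-based variable-gene detector rests on. `mm_K = 0` is the
#' no-extra-dropout limit.
#'
#' @param counts an `ExpressionMatrix` with unit `"counts"`.
#' @param fpkm_means named per-gene mean FPKM (S), or a gene x cell matrix of
#'   underlying mean FPKM.
#' @param mm_K dropout half-point, >= 0.
#' @param seed RNG seed.
#' @return The counts matrix with zeros injected.
#' @export
apply_dropout <- function(counts, fpkm_means, mm_K, seed = 1) {
  stopifnot(inherits(counts, "ExpressionMatrix"), mm_K >= 0)
  if (mm_K == 0) return(counts)
  v <- counts$values
  if (is.matrix(fpkm_means)) {
    stopifnot(all(dim(fpkm_means) == dim(v)))
    S <- fpkm_means[counts$gene_ids, counts$cell_ids, drop = FALSE]
  } else {
    S <- fpkm_means[counts$gene_ids]
  }
  p_target <- 1 - S / (mm_K + S) # recycles per gene when S is a vector
  p_nb <- rowMeans(v == 0)
  p_extra <- pmax(0, (p_target - p_nb) / (1 - p_nb))
  p_extra[!is.finite(p_extra)] <- 0 # genes already all-zero
  with_seed(seed, {
    drop <- matrix(stats::runif(length(v)), nrow(v), ncol(v)) < p_extra
  })
  v[drop] <- 0
  expression_matrix(v, counts$gene_ids, counts$cell_ids, unit = "counts",
                    meta = counts$meta)
}

#' Generate a synthetic single-cell dataset with planted ground truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' mu_gc = baseline_g x 2^(shift if g marks the cell's type)
#' x 2^(+-fc for planted subpopulation DE genes in subpopulation B)
#' x 2^(latent module factor), Var = mu + phi mu^2. FPKM is derived from the
#' counts and the sampled gene lengths; dropout is then injected so the
#' expected zero fraction of a gene with mean FPKM S is 1 - S/(mm_K + S).
#' Identical configuration and seed reproduce the outputs bit-for-bit.
#'
#' Planted marker sets are disjoint across types and disjoint from module and
#' subpopulation-DE genes. The first type ("cardiomyocyte") is split into two
#' equal subpopulations A/B when both `subpop_de_count` and `subpop_log2fc`
#' are positive; half of the DE genes go up in B, half down.
#'
#' @param cfg a [generator_config()].
#' @return List with `counts`, `fpkm` (both `ExpressionMatrix`), `annotation`
#'   (`GeneAnnotation`), `markers` (`MarkerDatabase`) and `truth`
#'   (`SyntheticTruth`: `cell_type_of`, `subpop_of`, `markers_of`, `de_genes`,
#'   `modules_of`, `params`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  n_gene <- sum(cfg$n_genes)
  n_cell <- cfg$n_types * cfg$cells_per_type
  gene_ids <- sprintf("G%05d", seq_len(n_gene))
  cell_ids <- sprintf("C%04d", seq_len(n_cell))
  biotype <- rep(c("coding", "lncRNA", "pcRNA"),
                 times = cfg$n_genes[c("coding", "lncRNA", "pcRNA")])
  types <- rep(type_name_pool, length.out = cfg$n_types)
  cell_type <- rep(types, each = cfg$cells_per_type)
  names(cell_type) <- cell_ids

  with_seed(cfg$seed, {
    lengths_bp <- as.integer(round(stats::runif(
      n_gene, cfg$gene_length_range[1], cfg$gene_length_range[2])))
    baseline <- stats::rlnorm(n_gene, log(cfg$nb_mean_baseline),
                              cfg$baseline_sdlog)

    # disjoint gene roles: markers, modules, subpopulation DE
    pool <- sample.int(n_gene)
    take <- function(n) {
      if (n == 0) return(integer(0))
      out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out
    }
    markers_of <- list()
    for (t in types)
      markers_of[[t]] <- sort(gene_ids[take(cfg$markers_per_type)])
    modules_of <- list()
    for (mlab in seq_len(cfg$module_count))
      modules_of[[paste0("M", mlab)]] <- sort(gene_ids[take(cfg$module_size)])
    split_on <- cfg$subpop_de_count > 0 && cfg$subpop_log2fc != 0
    de_idx <- if (cfg$subpop_de_count > 0) take(cfg$subpop_de_count) else integer()
    de_lfc <- if (length(de_idx))
      stats::setNames(rep(c(cfg$subpop_log2fc, -cfg$subpop_log2fc),
                          length.out = length(de_idx)), gene_ids[de_idx])
    else stats::setNames(numeric(0), character(0))

    # subpopulation split of the first type
    subpop_of <- stats::setNames(rep(NA_character_, n_cell), cell_ids)
    if (split_on) {
      cm_cells <- cell_ids[cell_type == types[1]]
      half <- ceiling(length(cm_cells) / 2)
      subpop_of[cm_cells] <- c(rep("A", half),
                               rep("B", length(cm_cells) - half))
    }

    # restricted transcripts (markers, subpopulation-distinguishing genes)
    # sit lower overall than broadly expressed genes
    marker_idx <- match(unlist(markers_of), gene_ids)
    baseline[marker_idx] <- baseline[marker_idx] *
      2^cfg$marker_baseline_log2_offset
    baseline[de_idx] <- baseline[de_idx] * 2^cfg$marker_baseline_log2_offset

    # log2-scale mean model
    log2mu <- matrix(log2(baseline), n_gene, n_cell,
                     dimnames = list(gene_ids, cell_ids))
    for (t in types) {
      gi <- match(markers_of[[t]], gene_ids)
      ci <- which(cell_type == t)
      log2mu[gi, ci] <- log2mu[gi, ci] + cfg$marker_log2_shift
    }
    if (split_on) {
      b_cells <- which(!is.na(subpop_of) & subpop_of == "B")
      gi <- match(names(de_lfc), gene_ids)
      log2mu[gi, b_cells] <- log2mu[gi, b_cells] + de_lfc
    }
    for (mlab in names(modules_of)) {
      # heterogeneous loadings: some members are hubs, giving the
      # co-expression network its heavy-tailed connectivity
      z <- stats::rnorm(n_cell, 0, cfg$module_latent_sd)
      gi <- match(modules_of[[mlab]], gene_ids)
      # bounded away from 0 (every member carries detectable signal) and
      # above (no single gene can blow up a cell's library size)
      lam <- stats::runif(length(gi), 0.6, 2)
      log2mu[gi, ] <- log2mu[gi, , drop = FALSE] + outer(lam, z)
    }
    special_idx <- c(marker_idx, de_idx)
    module_idx <- match(unlist(modules_of), gene_ids)
    if (cfg$n_bg_factors > 0) {
      # diffuse weak co-regulation over all non-planted genes: every gene
      # loads a random combination of shared factors
      bg_idx <- setdiff(seq_len(n_gene), c(special_idx, module_idx))
      Z <- matrix(stats::rnorm(cfg$n_bg_factors * n_cell), cfg$n_bg_factors)
      U <- matrix(stats::rnorm(length(bg_idx) * cfg$n_bg_factors,
                               0, 1 / sqrt(cfg$n_bg_factors)),
                  length(bg_idx))
      s <- pmin(stats::rexp(length(bg_idx), cfg$bg_loading_rate), 1.5)
      log2mu[bg_idx, ] <- log2mu[bg_idx, , drop = FALSE] + (s * U) %*% Z
    }

    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     n_gene, n_cell, dimnames = dimnames(mu))
    dropout_seed <- sample.int(.Machine$integer.max, 1)
  })

  ann <- gene_annotation(gene_ids, symbol = sub("^G0*", "Sym", gene_ids),
                         biotype = biotype, length_bp = lengths_bp)
  counts_em <- expression_matrix(counts, gene_ids, cell_ids, unit = "counts")
  if (cfg$mm_K > 0) {
    # underlying per-cell FPKM of the mean model
    fpkm_mu <- sweep(mu / (lengths_bp / 1e3), 2, colSums(mu) / 1e6, "/")
    phi <- cfg$nb_dispersion
    p_nb_th <- (1 + phi * mu)^(-1 / phi)
    # dropout tracks the cell-level underlying mean for genes with planted
    # on/off states (markers, subpopulation-DE genes); broadly expressed
    # genes are targeted at their gene-level mean, so they land exactly on
    # the MM curve the detector fits
    flat <- setdiff(seq_len(n_gene), special_idx)
    fpkm_mu[flat, ] <- rowMeans(fpkm_mu[flat, , drop = FALSE])
    p_nb_th[flat, ] <- rowMeans(p_nb_th[flat, , drop = FALSE])
    # post-dropout self-consistent targets: survive with probability q so the
    # realised (mean, zero fraction) pair lands on the MM curve
    # dropout shrinks per-cell totals, inflating every surviving gene's FPKM
    # by rho = old/new total; fold that into the fixed point
    rho <- rep(1, n_cell)
    for (it in 1:3) {
      q <- pmin(1, pmax(0, 1 / (1 - p_nb_th) -
                          cfg$mm_K / sweep(fpkm_mu, 2, rho, "*")))
      rho <- colSums(mu) / colSums(mu * q) # NB zeros carry no mass
    }
    counts_em <- apply_dropout(counts_em, sweep(fpkm_mu * q, 2, rho, "*"),
                               cfg$mm_K, seed = dropout_seed)
  }
  fpkm <- counts_to_fpkm(counts_em, ann)

  src <- stats::setNames(rep("synthetic", length(unlist(markers_of))),
                         unlist(markers_of))
  truth <- list(cell_type_of = cell_type, subpop_of = subpop_of,
                markers_of = markers_of, de_genes = de_lfc,
                modules_of = modules_of, params = cfg)
  class(truth) <- "SyntheticTruth"
  list(counts = counts_em, fpkm = fpkm, annotation = ann,
       markers = marker_database(markers_of, src), truth = truth)
}

#' Write the generator outputs to a directory
#'
#' Writes `counts.tsv`, `fpkm.tsv`, `annotation.tsv`, `markers.tsv`,
#' `truth_cell_types.tsv`, `truth_de_genes.tsv`, `truth_modules.gmt`.
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(ds$counts, file.path(dir, "counts.tsv"))
  write_expression_matrix(ds$fpkm, file.path(dir, "fpkm.tsv"))
  write_gene_annotation(ds$annotation, file.path(dir, "annotation.tsv"))
  write_marker_db(ds$markers, file.path(dir, "markers.tsv"))
  ct <- data.frame(cell_id = names(ds$truth$cell_type_of),
                   cell_type = unname(ds$truth$cell_type_of),
                   subpop = unname(ds$truth$subpop_of),
                   stringsAsFactors = FALSE)
  utils::write.table(ct, file.path(dir, "truth_cell_types.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  de <- data.frame(gene_id = names(ds$truth$de_genes),
                   log2fc = unname(ds$truth$de_genes), stringsAsFactors = FALSE)
  utils::write.table(format_num_df(de), file.path(dir, "truth_de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(gene_set_collection(ds$truth$modules_of),
            file.path(dir, "truth_modules.gmt"))
  invisible(dir)
}
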