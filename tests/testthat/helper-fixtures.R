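# shared fixtures, all built in code

mk_counts <- function(mat, unit = "counts") {
  expression_matrix(mat,
                    gene_ids = sprintf("g%03d", seq_len(nrow(mat))),
                    cell_ids = sprintf("c%03d", seq_len(ncol(mat))),
                    unit = unit)
}

# four cells on a line at 0, 1, 10, 11 (euclidean distance = coordinate gap)
line_distance <- function() {
  x <- c(0, 1, 10, 11)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("c", 1:4), paste0("c", 1:4))
  structure(d, metric = "euclidean",
            class = c("DistanceMatrix", "matrix", "array"))
}

# annotation covering ids g001.. with a chosen biotype pattern
mk_annotation <- function(n, biotypes = "coding", lengths = 1000,
                          symbols = NULL) {
  ids <- sprintf("g%03d", seq_len(n))
  gene_annotation(ids,
                  symbol = if (is.null(symbols)) sub("^g0*", "Sym", ids)
                  else symbols,
                  biotype = rep_len(biotypes, n),
                  length_bp = rep_len(lengths, n))
}

# NB count matrix with per-gene means mu (vector) and dispersion phi
mk_nb <- function(mu, n_cells, phi, seed) {
  withr::with_seed(seed, {
    matrix(stats::rnbinom(length(mu) * n_cells, mu = mu, size = 1 / phi),
           length(mu), n_cells)
  })
}

# small generator config for fast tests
quick_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_types = 3, cells_per_type = 50,
         n_genes = c(coding = 300, lncRNA = 120, pcRNA = 60),
         markers_per_type = 10, module_count = 2, module_size = 30,
         subpop_de_count = 10),
    list(...))
  do.call(generator_config, args)
}
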