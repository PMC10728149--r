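#' Remove genes expressed in too few cells
#'
#' A transcript is kept only if it is expressed (value strictly above
#' `expressed_threshold`) in at least `min_frac` of cells. The boundary is
#' inclusive: with 100 cells and `min_frac = 0.05`, expression in exactly 5
#' cells keeps the gene.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_frac minimum fraction of expressing cells, default 0.05.
#' @param expressed_threshold value above which a cell counts as expressing
#'   the gene, default 0.
#' @return The filtered `ExpressionMatrix`; cell set and gene order unchanged.
#' @export
filter_low_prevalence <- function(m, min_frac = 0.05, expressed_threshold = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            min_frac >= 0, min_frac <= 1)
  frac <- rowMeans(m$values > expressed_threshold)
  keep <- frac >= min_frac
  if (!any(keep))
    stop("no gene passes the prevalence filter (min_frac = ", min_frac,
         ", expressed_threshold = ", expressed_threshold,
         "); review the thresholds", call. = FALSE)
  em_subset(m, genes = m$gene_ids[keep])
}

#' Convert raw counts to FPKM
#'
#' FPKM_gc = counts_gc / ((length_bp_g / 1e3) * (total counts of cell c / 1e6)).
#'
#' @param counts an `ExpressionMatrix` with unit `"counts"`.
#' @param ann a `GeneAnnotation` covering every gene of `counts`.
#' @return An `ExpressionMatrix` with unit `"fpkm"`.
#' @export
counts_to_fpkm <- function(counts, ann) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts")
    stop("counts_to_fpkm expects unit 'counts', got '", counts$unit, "'",
         call. = FALSE)
  len <- stats::setNames(ann$length_bp, ann$gene_id)[counts$gene_ids]
  missing <- counts$gene_ids[is.na(len)]
  if (length(missing))
    stop("no annotated length for gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  totals <- colSums(counts$values)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(counts$cell_ids[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  fpkm <- counts$values / (len / 1e3) # per-kilobase
  fpkm <- sweep(fpkm, 2, totals / 1e6, "/") # per-million mapped
  expression_matrix(fpkm, counts$gene_ids, counts$cell_ids, unit = "fpkm",
                    meta = counts$meta)
}

#' Log-transform an FPKM matrix
#'
#' Applies `log2(x + 1)` (pseudocount of 1 FPKM) and retags the unit.
#'
#' @param m an `ExpressionMatrix` with unit `"fpkm"`.
#' @return An `ExpressionMatrix` with unit `"log2fpkm"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "fpkm")
    stop("log_transform expects unit 'fpkm', got '", m$unit, "'", call. = FALSE)
  expression_matrix(log2(m$values + 1), m$gene_ids, m$cell_ids,
                    unit = "log2fpkm", meta = m$meta)
}
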