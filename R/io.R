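#' Read an expression matrix from disk
#'
#' Two on-disk dialects are supported. `"tsv"` is a dense table whose first
#' column holds gene ids and whose header row holds cell ids ('.' decimal,
#' tab separated). `"mtx-triplet"` is MatrixMarket coordinate format (1-based
#' indices) with two one-column sidecar files next to it: `genes.txt` and
#' `cells.txt` (overridable).
#'
#' @param path path to the matrix file.
#' @param fmt `"tsv"` or `"mtx-triplet"`.
#' @param unit unit tag to attach (`"counts"`, `"fpkm"`, `"log2fpkm"`).
#' @param genes_file,cells_file sidecar paths for `"mtx-triplet"`; default
#'   `genes.txt` / `cells.txt` in the matrix directory.
#' @param meta optional metadata list, see [expression_matrix()].
#' @return An [expression_matrix()] with file order preserved.
#' @export
read_expression_matrix <- function(path, fmt = c("tsv", "mtx-triplet"),
                                   unit = "fpkm",
                                   genes_file = NULL, cells_file = NULL,
                                   meta = list()) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             comment.char = "", quote = "")
    gene_ids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    expression_matrix(vals, gene_ids, colnames(tab)[-1], unit = unit, meta = meta)
  } else {
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.txt")
    if (is.null(cells_file)) cells_file <- file.path(dir, "cells.txt")
    for (f in c(genes_file, cells_file))
      if (!file.exists(f)) stop("sidecar file not found: ", f, call. = FALSE)
    mm <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_file)
    cell_ids <- readLines(cells_file)
    if (nrow(mm) != length(gene_ids) || ncol(mm) != length(cell_ids))
      stop("matrix dimensions (", nrow(mm), " x ", ncol(mm),
           ") do not match sidecar files (", length(gene_ids), " genes, ",
           length(cell_ids), " cells)", call. = FALSE)
    expression_matrix(mm, gene_ids, cell_ids, unit = unit, meta = meta)
  }
}

#' Write an expression matrix
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file.
#' @param fmt `"tsv"` (dense, diffable) or `"mtx-triplet"` (sparse, writes
#'   `genes.txt` / `cells.txt` next to the matrix).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, fmt = c("tsv", "mtx-triplet")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    tab <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("gene_id", m$cell_ids)
    utils::write.table(format_num_df(tab), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(m$cell_ids, file.path(dirname(path), "cells.txt"))
  }
  invisible(path)
}

# deterministic, locale-independent numeric formatting for diffable TSVs
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], format = "g", digits = 15)
  df
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id  symbol  biotype  length_bp`; biotype
#' must be one of coding, lncRNA, pcRNA.
#'
#' @param path input TSV.
#' @return A [gene_annotation()] table.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("gene_id", "symbol", "biotype", "length_bp")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gene_annotation(tab$gene_id, tab$symbol, tab$biotype,
                  as.integer(tab$length_bp))
}

#' Write a gene annotation table
#' @param ann a `GeneAnnotation`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker database
#'
#' TSV with header `cell_type  gene_id  source`, one marker per row.
#'
#' @param path input TSV.
#' @return A [marker_database()].
#' @export
read_marker_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("cell_type", "gene_id", "source")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("marker DB is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  entries <- split(tab$gene_id, factor(tab$cell_type, levels = unique(tab$cell_type)))
  src <- stats::setNames(tab$source, tab$gene_id)
  src <- src[!duplicated(names(src))]
  marker_database(as.list(entries), src)
}

#' Write a marker database
#' @param db a `MarkerDatabase`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_marker_db <- function(db, path) {
  rows <- do.call(rbind, lapply(names(db$entries), function(ct)
    data.frame(cell_type = ct, gene_id = db$entries[[ct]],
               source = unname(db$source[db$entries[[ct]]]),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' After optional restriction to `universe`, sets with fewer than `min_size`
#' members are dropped with a warning.
#'
#' @param path GMT file.
#' @param universe optional character vector; sets are intersected with it.
#' @param min_size minimum surviving set size (default 1).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL, min_size = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  dropped <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) { dropped <- c(dropped, f[1]); next }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!is.null(universe)) genes <- intersect(genes, universe)
    if (length(genes) < min_size) { dropped <- c(dropped, f[1]); next }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " GMT set(s) with < ", min_size,
            " member(s) after filtering: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  gene_set_collection(sets, desc)
}

#' Write gene sets in GMT format
#' @param gsc a `GeneSetCollection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network edge list
#'
#' TSV with header `from  to` and an optional `weight` column.
#'
#' @param path input TSV.
#' @return An [interaction_network()].
#' @export
read_interaction_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% colnames(tab)))
    stop("edge list needs 'from' and 'to' columns", call. = FALSE)
  interaction_network(tab$from, tab$to,
                      if ("weight" %in% colnames(tab)) tab$weight else NULL)
}
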