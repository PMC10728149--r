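#' Construct an expression matrix
#'
#' The central container of the pipeline: a non-negative genes x cells matrix
#' with unique gene and cell identifiers, a unit tag, and optional dataset
#' metadata (heart compartment, developmental stage).
#'
#' @param values numeric matrix, genes in rows, cells in columns; all entries
#'   must be finite and non-negative.
#' @param gene_ids character vector of unique gene identifiers (row names).
#' @param cell_ids character vector of unique cell identifiers (column names).
#' @param unit one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @param meta named list of dataset-level labels. Recognised entries are
#'   `compartment` (one of ventricle, atrium, left ventricle, right ventricle,
#'   left atrium) and `stage` (E9.5, E11.5, E14.5, E18.5, P0, P3, P7, P21);
#'   both optional.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              unit = c("counts", "fpkm", "log2fpkm"),
                              meta = list()) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")", call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")", call. = FALSE)
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c))
    stop("duplicate cell id(s): ", paste(dup_c, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite value at gene '", gene_ids[bad[1, 1]],
         "', cell '", cell_ids[bad[1, 2]], "'", call. = FALSE)
  known_comp <- c("ventricle", "atrium", "left ventricle", "right ventricle",
                  "left atrium")
  known_stage <- c("E9.5", "E11.5", "E14.5", "E18.5", "P0", "P3", "P7", "P21")
  if (!is.null(meta$compartment) && !meta$compartment %in% known_comp)
    stop("unknown compartment '", meta$compartment, "'; expected one of: ",
         paste(known_comp, collapse = ", "), call. = FALSE)
  if (!is.null(meta$stage) && !meta$stage %in% known_stage)
    stop("unknown stage '", meta$stage, "'; expected one of: ",
         paste(known_stage, collapse = ", "), call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 unit = unit, meta = meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d cells\n",
              x$unit, length(x$gene_ids), length(x$cell_ids)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or cell ids
#'
#' @param m an `ExpressionMatrix`.
#' @param genes,cells character vectors of ids to keep (in the given order);
#'   `NULL` keeps all.
#' @return An `ExpressionMatrix` with the same unit and metadata.
#' @export
em_subset <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(genes)) genes <- m$gene_ids
  if (is.null(cells)) cells <- m$cell_ids
  missing_g <- setdiff(genes, m$gene_ids)
  if (length(missing_g))
    stop("unknown gene id(s): ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  missing_c <- setdiff(cells, m$cell_ids)
  if (length(missing_c))
    stop("unknown cell id(s): ", paste(utils::head(missing_c, 5), collapse = ", "),
         call. = FALSE)
  expression_matrix(m$values[genes, cells, drop = FALSE], genes, cells,
                    unit = m$unit, meta = m$meta)
}

#' Construct a gene annotation table
#'
#' @param gene_id character, unique gene identifiers.
#' @param symbol character, display symbols (may repeat; all matching is by id).
#' @param biotype character, each one of `"coding"`, `"lncRNA"`, `"pcRNA"`.
#' @param length_bp positive integer transcript lengths in base pairs.
#' @return A `data.frame` of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, symbol, biotype, length_bp) {
  gene_id <- as.character(gene_id)
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop("duplicate gene id(s) in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  allowed <- c("coding", "lncRNA", "pcRNA")
  bad <- setdiff(unique(biotype), allowed)
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "),
         "; allowed classes are: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  length_bp <- as.integer(length_bp)
  if (any(is.na(length_bp) | length_bp < 1))
    stop("length_bp must be a positive integer for every gene", call. = FALSE)
  ann <- data.frame(gene_id = gene_id, symbol = as.character(symbol),
                    biotype = as.character(biotype), length_bp = length_bp,
                    stringsAsFactors = FALSE)
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

#' Construct a marker database
#'
#' Maps cell-type names to non-empty marker gene sets, with a free-text
#' provenance tag per gene. A gene may mark several cell types.
#'
#' @param entries named list: cell type -> character vector of gene ids.
#' @param source named character vector: gene id -> provenance tag. Genes
#'   without an entry get `"unspecified"`.
#' @return An object of class `MarkerDatabase`.
#' @export
marker_database <- function(entries, source = character()) {
  if (!length(entries) || is.null(names(entries)) || any(names(entries) == ""))
    stop("marker database needs named, non-empty cell-type entries", call. = FALSE)
  dup <- unique(names(entries)[duplicated(names(entries))])
  if (length(dup))
    stop("duplicate cell type(s): ", paste(dup, collapse = ", "), call. = FALSE)
  entries <- lapply(entries, function(g) unique(as.character(g)))
  empty <- names(entries)[vapply(entries, length, 1L) == 0]
  if (length(empty))
    stop("empty marker set for cell type(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  all_genes <- unique(unlist(entries, use.names = FALSE))
  src <- stats::setNames(rep("unspecified", length(all_genes)), all_genes)
  src[names(source)[names(source) %in% all_genes]] <-
    source[names(source) %in% all_genes]
  structure(list(entries = entries, source = src), class = "MarkerDatabase")
}

#' @export
print.MarkerDatabase <- function(x, ...) {
  cat("MarkerDatabase:", length(x$entries), "cell types,",
      length(x$source), "marker genes\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list: set name -> character vector of gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == ""))
      stop("all gene sets must be named", call. = FALSE)
    dup <- unique(names(sets)[duplicated(names(sets))])
    if (length(dup))
      stop("duplicate gene set name(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (any(vapply(sets, length, 1L) == 0))
      stop("empty gene set(s) after loading", call. = FALSE)
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets\n")
  invisible(x)
}

#' Construct an interaction network
#'
#' Undirected gene-gene edge list (e.g. protein-protein interactions supplied
#' by the user), used only as an overlay in module reports.
#'
#' @param from,to character vectors of gene ids.
#' @param weight optional numeric edge weights.
#' @return An object of class `InteractionNetwork` holding a canonicalised
#'   (lexicographically ordered, deduplicated) edge table.
#' @export
interaction_network <- function(from, to, weight = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  if (any(from == to))
    stop("self-loop edge(s) not allowed: ",
         paste(utils::head(from[from == to], 5), collapse = ", "), call. = FALSE)
  a <- pmin(from, to); b <- pmax(from, to)
  if (is.null(weight)) weight <- rep(NA_real_, length(a))
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate undirected edge(s): ",
         paste(utils::head(paste(a, b, sep = "-")[duplicated(key)], 5),
               collapse = ", "), call. = FALSE)
  edges <- data.frame(from = a, to = b, weight = as.numeric(weight),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges), class = "InteractionNetwork")
}
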