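#' Build a run configuration
#'
#' All stage parameters with their defaults; unknown names are rejected so a
#' typo in a config file cannot silently fall back to a default.
#'
#' @param ... overrides of the defaults listed below.
#' @return A validated `RunConfig` list.
#' @details Fields: `counts`, `fpkm`, `annotation`, `markers`, `gmt`,
#'   `network` (input paths; `counts` + `annotation` or `fpkm` required when
#'   running from files), `min_frac` (0.05), `expressed_threshold` (0),
#'   `metric`, `linkage` (ward), `cluster_on` ("variable" genes, or "all"),
#'   `k_min` (2), `k_max` (10), `var_gene_q` (0.05),
#'   `top_n_cluster_genes` (50), `alpha` (0.05), `min_overlap` (2),
#'   `fc_cut` (1.5), `p_cut` (0.05), `use_raw_p` (FALSE), `module_min_size`
#'   (30), `cut_height` (0.998), `r2_min` (0.8), `var_quantile` (0.25),
#'   `gsea_n_perm` (200), `seed` (1), `outdir` (NULL = nothing written).
#' @export
run_config <- function(...) {
  defaults <- list(
    counts = NULL, fpkm = NULL, annotation = NULL, markers = NULL,
    gmt = NULL, network = NULL,
    min_frac = 0.05, expressed_threshold = 0,
    metric = "pearson-dissimilarity", linkage = "ward",
    cluster_on = "variable", k_min = 2, k_max = 10,
    var_gene_q = 0.05, top_n_cluster_genes = 50,
    alpha = 0.05, min_overlap = 2,
    fc_cut = 1.5, p_cut = 0.05, use_raw_p = FALSE,
    module_min_size = 30, cut_height = 0.998, r2_min = 0.8,
    var_quantile = 0.25, gsea_n_perm = 200,
    seed = 1, outdir = NULL)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all config entries must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(over)] <- over
  }
  structure(defaults, class = "RunConfig")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()] field-for-field.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a `RunConfig`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

write_stage_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(format_num_df(df), file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full per-dataset analysis
#'
#' Executes preprocess -> cluster -> celltype -> subpopulation DE (only when
#' at least two clusters share an assigned cell type) -> ORA -> modules ->
#' report. With `cfg$outdir` set, every intermediate is written as a
#' deterministic TSV and the report as JSON, so a re-run with the same config
#' and seed reproduces byte-identical files.
#'
#' @param cfg a [run_config()].
#' @param data optional in-memory inputs overriding the config paths: a list
#'   with `counts` (or `fpkm`), `annotation`, `markers`, and optionally
#'   `gene_sets` (`GeneSetCollection`) and `network`.
#' @return A `RunReport` (see [build_report()]) with the stage objects
#'   attached in `$stages`.
#' @export
run_pipeline <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  stage <- "load inputs"
  res <- tryCatch({
    if (is.null(data)) {
      data <- list()
      if (!is.null(cfg$counts))
        data$counts <- read_expression_matrix(cfg$counts, "tsv", unit = "counts")
      if (!is.null(cfg$fpkm))
        data$fpkm <- read_expression_matrix(cfg$fpkm, "tsv", unit = "fpkm")
      if (is.null(cfg$annotation)) stop("annotation path is required")
      data$annotation <- read_gene_annotation(cfg$annotation)
      if (!is.null(cfg$markers)) data$markers <- read_marker_db(cfg$markers)
      if (!is.null(cfg$gmt)) data$gene_sets <- read_gmt(cfg$gmt)
      if (!is.null(cfg$network))
        data$network <- read_interaction_network(cfg$network)
    }
    if (is.null(data$annotation)) stop("annotation is required")
    if (is.null(data$markers)) stop("marker database is required")
    outdir <- cfg$outdir
    # hash the configuration minus the output location, so re-running the
    # same analysis into a different directory reports the same hash
    tmp <- tempfile(fileext = ".yaml")
    cfg_hashable <- cfg
    cfg_hashable$outdir <- NULL
    write_run_config(cfg_hashable, tmp)
    config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_run_config(cfg, file.path(outdir, "config.yaml"))
    }

    stage <- "preprocess"
    fpkm <- if (!is.null(data$fpkm)) data$fpkm
    else counts_to_fpkm(data$counts, data$annotation)
    fpkm_f <- filter_low_prevalence(fpkm, cfg$min_frac, cfg$expressed_threshold)
    counts_f <- if (!is.null(data$counts))
      em_subset(data$counts, genes = fpkm_f$gene_ids) else NULL
    logm <- log_transform(fpkm_f)

    stage <- "variable genes"
    dt <- dropout_stats(fpkm_f)
    mm <- fit_michaelis_menten(dt)
    vg <- variable_genes(dt, mm, cfg$var_gene_q)

    stage <- "cluster"
    feat <- if (identical(cfg$cluster_on, "variable") && length(vg) >= 2)
      em_subset(logm, genes = vg) else logm
    d <- pairwise_distance(feat, cfg$metric)
    clust <- select_k(d, seq(cfg$k_min, min(cfg$k_max, ncol(d) - 1)),
                      cfg$linkage)
    write_stage_tsv(data.frame(cell_id = names(clust$labels),
                               cluster = unname(clust$labels),
                               silhouette = unname(clust$per_cell_silhouette)),
                    outdir, "clusters.tsv")
    write_stage_tsv(clust$silhouette_table, outdir, "silhouette.tsv")

    stage <- "celltype"
    cl_genes <- cluster_gene_lists(logm, clust$labels, vg,
                                   cfg$top_n_cluster_genes)
    assign <- assign_cell_types(cl_genes, data$markers, cfg$alpha,
                                cfg$min_overlap, universe = fpkm_f$gene_ids)
    write_stage_tsv(assign$table, outdir, "assignment.tsv")
    marker_biotypes <- classify_markers_by_biotype(
      lapply(assign$cluster_markers, function(g) if (is.null(g)) character() else g),
      data$annotation)

    stage <- "differential expression"
    de_runs <- list()
    tab <- assign$table
    typed <- tab$assigned_type[tab$assigned_type != "Unknown"]
    for (ty in unique(typed[duplicated(typed)])) {
      cl_of_type <- tab$cluster[tab$assigned_type == ty]
      sizes <- table(clust$labels)[cl_of_type]
      pair <- cl_of_type[order(-sizes)][1:2] # two largest clusters of the type
      cells <- names(clust$labels)[clust$labels %in% as.integer(pair)]
      grp <- factor(clust$labels[cells], levels = as.integer(pair))
      if (is.null(counts_f)) break
      sub_counts <- em_subset(counts_f, cells = cells)
      de <- nb_wald_test(sub_counts, grp)
      volc <- volcano_summary(de, data$annotation, cfg$fc_cut, cfg$p_cut,
                              cfg$use_raw_p)
      suffix <- if (startsWith(ty, "cardiomyocyte")) "-CM"
      else paste0("-", toupper(substr(ty, 1, 2)))
      nm <- name_subpopulations(em_subset(fpkm_f, cells = cells),
                                data$annotation, grp, suffix = suffix)
      de_ora <- NULL
      if (!is.null(data$gene_sets)) {
        de_hits <- de$gene_id[volc$direction != "ns"]
        de_ora <- ora(de_hits, data$gene_sets, fpkm_f$gene_ids)
      }
      de_runs[[ty]] <- list(type = ty, clusters = pair, names = nm,
                            result = de, volcano = volc$counts,
                            direction = volc$direction, ora = de_ora)
      write_stage_tsv(de[, setdiff(colnames(de), "degenerate")],
                      outdir, paste0("de_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv"))
      write_stage_tsv(volc$counts, outdir,
                      paste0("volcano_", gsub("[^A-Za-z0-9]", "_", ty), ".tsv"))
    }

    stage <- "modules"
    ms <- find_modules(logm, var_quantile = cfg$var_quantile,
                       r2_min = cfg$r2_min, min_size = cfg$module_min_size,
                       cut_height = cfg$cut_height)
    profiles <- NULL
    if (ms$status == "ok") {
      cl2type <- stats::setNames(tab$assigned_type, tab$cluster)
      cell_types <- cl2type[as.character(clust$labels)]
      names(cell_types) <- names(clust$labels)
      profiles <- module_profile(
        ms, logm, cell_types,
        data$gene_sets %||% gene_set_collection(list()),
        data$annotation, net = data$network,
        n_perm = cfg$gsea_n_perm, seed = cfg$seed)
      memb <- do.call(rbind, lapply(names(ms$modules), function(lab)
        data.frame(module = lab, gene_id = ms$modules[[lab]],
                   stringsAsFactors = FALSE)))
      write_stage_tsv(memb, outdir, "modules.tsv")
      hubs <- do.call(rbind, lapply(names(ms$hubs), function(lab)
        data.frame(module = lab, rank = seq_along(ms$hubs[[lab]]),
                   gene_id = ms$hubs[[lab]], stringsAsFactors = FALSE)))
      write_stage_tsv(hubs, outdir, "hubs.tsv")
    }

    stage <- "report"
    report <- build_report(list(
      annotation = data$annotation, filtered = fpkm_f, cluster = clust,
      dropout_fit = mm, variable_genes = vg, assignment = assign,
      marker_biotypes = marker_biotypes, de_runs = de_runs, modules = ms,
      profiles = profiles, config_hash = config_hash, seed = cfg$seed))
    if (!is.null(outdir))
      jsonlite::write_json(report_as_list(report),
                           file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
    report
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  res
}

#' Assemble the run report
#'
#' Tabulates each stage's outputs without recomputation: post-filter
#' transcript counts per biotype, the selected K and mean silhouette, the
#' cluster-to-cell-type table, marker counts per biotype, DE counts at the
#' cut-offs per subpopulation pair, and the module summary.
#'
#' @param stages named list of stage outputs (see [run_pipeline()]).
#' @return A `RunReport` list.
#' @export
build_report <- function(stages) {
  need <- c("annotation", "filtered", "cluster", "assignment", "modules")
  miss <- setdiff(need, names(stages))
  if (length(miss))
    stop("missing stage output(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann <- stages$annotation
  bt <- stats::setNames(ann$biotype, ann$gene_id)[stages$filtered$gene_ids]
  expressed <- vapply(c("coding", "lncRNA", "pcRNA"),
                      function(cl) sum(bt == cl, na.rm = TRUE), 1L)
  de_summary <- if (length(stages$de_runs)) lapply(stages$de_runs, function(r)
    list(type = r$type, subpop_names = r$names,
         clusters = as.character(r$clusters), counts = r$volcano))
  else NULL
  report <- list(
    expressed_per_biotype = expressed,
    n_cells = length(stages$filtered$cell_ids),
    K = stages$cluster$K,
    mean_silhouette = stages$cluster$mean_silhouette,
    assignments = stages$assignment$table,
    marker_counts_per_biotype = stages$marker_biotypes,
    n_variable_genes = length(stages$variable_genes %||% character()),
    dropout_K = (stages$dropout_fit %||% list(K = NA_real_))$K,
    de = de_summary,
    module_status = stages$modules$status,
    module_reason = stages$modules$reason,
    n_modules = length(stages$modules$modules),
    module_sizes = vapply(stages$modules$modules, length, 1L),
    config_hash = stages$config_hash %||% NA_character_,
    seed = stages$seed %||% NA_integer_,
    version = as.character(utils::packageVersion("cardiolinc")))
  class(report) <- "RunReport"
  attr(report, "stages") <- stages
  report
}

report_as_list <- function(report) {
  x <- unclass(report)
  x$assignments <- as.data.frame(x$assignments)
  x$marker_counts_per_biotype <- as.data.frame(x$marker_counts_per_biotype)
  x
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (cardiolinc", x$version, ")\n")
  cat("  expressed transcripts:",
      paste(names(x$expressed_per_biotype), x$expressed_per_biotype,
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  clustering: K = %d, mean silhouette = %.3f\n",
              x$K, x$mean_silhouette))
  cat("  assignments:",
      paste(x$assignments$cluster, x$assignments$assigned_type,
            sep = "->", collapse = ", "), "\n")
  if (!is.null(x$de))
    for (r in x$de)
      cat(sprintf("  subpopulations of %s: %s vs %s (DE coding up/down = %d/%d)\n",
                  r$type, r$subpop_names[1], r$subpop_names[2],
                  r$counts$n_up[r$counts$biotype == "coding"],
                  r$counts$n_down[r$counts$biotype == "coding"]))
  if (x$module_status == "ok")
    cat("  modules:", x$n_modules,
        paste0("(sizes ", paste(x$module_sizes, collapse = ","), ")"), "\n")
  else cat("  modules: none (", x$module_reason, ")\n", sep = "")
  invisible(x)
}
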