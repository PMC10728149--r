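test_that("an exact power-law degree sequence scores R2 = 1", {
  # ten equally spaced connectivity values whose frequencies are exactly
  # proportional to 1/k: log-log fit is a perfect line of slope -1
  k <- rep(1:10, times = 2520 / (1:10))
  f <- scale_free_fit(k)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$slope, -1, tolerance = 1e-9)
})

test_that("the returned beta is the smallest qualifying one", {
  withr::with_seed(1, {
    v <- matrix(rnorm(150 * 80), 150, 80)
    z <- rnorm(80)
    lam <- runif(50, 0.6, 2)
    v <- rbind(v, outer(lam, z) + matrix(rnorm(50 * 80), 50))
  })
  rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
  sel <- select_soft_threshold(cor(t(v)))
  ok <- sel$table$beta[sel$table$r2 >= 0.8 & sel$table$mean_k >= 0.5]
  if (length(ok)) expect_identical(sel$beta, min(ok))
  else expect_true(is.na(sel$beta))
})

test_that("iid noise genes yield no scale-free power in most runs", {
  nones <- vapply(1:10, function(s) {
    withr::with_seed(s, m <- matrix(rnorm(200 * 100), 200, 100))
    rownames(m) <- sprintf("g%03d", 1:200)
    is.na(select_soft_threshold(cor(t(m)))$beta)
  }, logical(1))
  expect_gte(sum(nones), 8)
})

test_that("TOM follows its closed forms", {
  # isolated pair with a_12 = 1 and nothing else: TOM = 1, dissimilarity 0
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 1
  dimnames(corr) <- list(paste0("g", 1:3), paste0("g", 1:3))
  at <- adjacency_tom(corr, beta = 2)
  expect_equal(at$dissimilarity[1, 2], 0, tolerance = 1e-12)
  # zero adjacency everywhere -> dissimilarity 1 off-diagonal
  corr0 <- diag(4)
  dimnames(corr0) <- list(paste0("g", 1:4), paste0("g", 1:4))
  d0 <- adjacency_tom(corr0, 3)$dissimilarity
  expect_true(all(d0[upper.tri(d0)] == 1))
  expect_equal(unname(diag(d0)), rep(0, 4))
})

test_that("TOM stays within [0, 1] on random correlation matrices", {
  for (s in 1:20) {
    withr::with_seed(s, {
      x <- matrix(rnorm(30 * 15), 30, 15)
      corr <- cor(t(x))
    })
    dimnames(corr) <- list(sprintf("g%02d", 1:30), sprintf("g%02d", 1:30))
    at <- adjacency_tom(corr, sample(1:8, 1))
    expect_true(all(at$dissimilarity >= -1e-12 & at$dissimilarity <= 1 + 1e-12))
  }
})

test_that("hub ranking follows intramodular connectivity with lexical ties", {
  # star: center connected to all leaves
  a <- matrix(0, 5, 5)
  a[1, 2:5] <- a[2:5, 1] <- 0.9
  dimnames(a) <- list(paste0("g", 1:5), paste0("g", 1:5))
  expect_identical(hub_genes(a, paste0("g", 1:5), 1), "g1")
  # complete equal-weight module: ranking is purely lexicographic
  ac <- matrix(0.5, 4, 4); diag(ac) <- 0
  dimnames(ac) <- list(c("gb", "ga", "gd", "gc"), c("gb", "ga", "gd", "gc"))
  expect_identical(hub_genes(ac, c("gb", "ga", "gd", "gc")),
                   c("ga", "gb", "gc", "gd"))
  # invariant under gene reordering
  perm <- c(3, 1, 4, 2, 5)
  expect_identical(hub_genes(a[perm, perm], paste0("g", 1:5)),
                   hub_genes(a, paste0("g", 1:5)))
  expect_error(hub_genes(a, "gX"), "absent")
})

test_that("no-modules outcomes carry machine-readable reasons", {
  ms <- detect_modules(NULL, beta = NA_integer_)
  expect_identical(ms$status, "no-modules")
  expect_match(ms$reason, "no scale-free fit")
  # min_size larger than the gene count forces the size reason
  d <- matrix(0.999, 10, 10); diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:10), paste0("g", 1:10))
  ms2 <- detect_modules(d, min_size = 30, beta = 3)
  expect_identical(ms2$status, "no-modules")
  expect_match(ms2$reason, "no branch >= 30")
})

test_that("raising min_size never increases the number of modules", {
  ds <- generate_dataset(quick_cfg(seed = 9, module_latent_sd = 1.5,
                                   cells_per_type = 80))
  logm <- log_transform(filter_low_prevalence(ds$fpkm))
  ms <- lapply(c(10, 25, 60), function(msz)
    find_modules(logm, min_size = msz))
  ns <- vapply(ms, function(x) length(x$modules), 1L)
  expect_true(all(diff(ns) <= 0))
})

test_that("planted modules are recovered on the module benchmark", {
  ds <- generate_dataset(generator_config(
    seed = 2, n_types = 1, cells_per_type = 300, markers_per_type = 2,
    marker_log2_shift = 0, subpop_log2fc = 0,
    n_genes = c(coding = 600, lncRNA = 300, pcRNA = 100),
    module_count = 3, module_size = 60, module_latent_sd = 1.5))
  logm <- log_transform(filter_low_prevalence(ds$fpkm))
  ms <- find_modules(logm)
  expect_identical(ms$status, "ok")
  expect_equal(length(ms$modules), 3L)
  truth <- ds$truth$modules_of
  tg <- unlist(truth)
  tl <- rep(names(truth), vapply(truth, length, 1L))
  det <- rep("none", length(logm$gene_ids))
  names(det) <- logm$gene_ids
  for (nm in names(ms$modules)) det[ms$modules[[nm]]] <- nm
  expect_gte(mclust::adjustedRandIndex(tl, det[tg]), 0.8)
  # hubs are module members ranked within their module
  for (nm in names(ms$hubs))
    expect_true(all(ms$hubs[[nm]] %in% ms$modules[[nm]]))
})

test_that("module membership is invariant under cell permutation", {
  ds <- generate_dataset(quick_cfg(seed = 10, module_latent_sd = 1.5,
                                   cells_per_type = 80))
  logm <- log_transform(filter_low_prevalence(ds$fpkm))
  ms1 <- find_modules(logm)
  perm <- withr::with_seed(99, sample(length(logm$cell_ids)))
  logm2 <- expression_matrix(logm$values[, perm], logm$gene_ids,
                             logm$cell_ids[perm], unit = "log2fpkm")
  ms2 <- find_modules(logm2)
  expect_identical(ms1$status, ms2$status)
  expect_equal(ms1$modules, ms2$modules)
})

test_that("pure-noise expression returns the no-modules outcome", {
  st <- vapply(1:2, function(s) {
    ds <- generate_dataset(generator_config(
      seed = s, module_latent_sd = 0, n_bg_factors = 0, n_types = 1,
      cells_per_type = 150, markers_per_type = 2, marker_log2_shift = 0,
      subpop_log2fc = 0, n_genes = c(coding = 300, lncRNA = 150, pcRNA = 50),
      module_count = 1, module_size = 30))
    find_modules(log_transform(filter_low_prevalence(ds$fpkm)))$status
  }, character(1))
  expect_true(all(st == "no-modules"))
})

test_that("module profiles report enrichment, GSEA, biotypes and edges", {
  # planted module elevated in one cell type
  withr::with_seed(11, {
    v <- matrix(rnorm(150 * 40, 5), 150, 40)
    z <- rnorm(40)
    v[1:30, ] <- v[1:30, , drop = FALSE] + outer(runif(30, 0.6, 2), z)
    v[1:30, 1:12] <- v[1:30, 1:12] + 2 # elevated in the first type
  })
  m <- mk_counts(abs(v), unit = "log2fpkm")
  corr <- cor(t(m$values))
  at <- adjacency_tom(corr, 4)
  ms <- detect_modules(at$dissimilarity, min_size = 20, beta = 4L)
  expect_identical(ms$status, "ok")
  attr(ms, "adjacency") <- at$adjacency
  ann <- mk_annotation(150, biotypes = c("coding", "lncRNA", "pcRNA"))
  types <- stats::setNames(rep(c("cardiomyocyte", "endothelial", "fibroblast"),
                               c(12, 14, 14)), m$cell_ids)
  gsc <- gene_set_collection(list(planted = m$gene_ids[1:30],
                                  other = m$gene_ids[100:120]))
  net <- interaction_network(m$gene_ids[1], m$gene_ids[2])
  prof <- suppressMessages(
    module_profile(ms, m, types, gsc, ann, net = net, n_perm = 100, seed = 3))
  big <- which.max(vapply(ms$modules, function(g)
    length(intersect(g, m$gene_ids[1:30])), 1L))
  p1 <- prof[[names(big)]]
  # ORA flags the planted set
  expect_equal(p1$ora$set[1], "planted")
  expect_lt(p1$ora$q[1], 0.05)
  # the planted-elevated type is the minimum-p GSEA contrast
  expect_equal(p1$gsea$cell_type[which.min(p1$gsea$p_perm)], "cardiomyocyte")
  # biotype composition partitions the module
  expect_equal(sum(p1$biotype_counts), length(ms$modules[[names(big)]]))
  expect_true(all(c("coexpression") %in% p1$edges$source))
  # empty collection degrades gracefully
  prof2 <- suppressMessages(
    module_profile(ms, m, types, gene_set_collection(list()), ann,
                   n_perm = 100, seed = 3))
  expect_equal(nrow(prof2[[1]]$ora), 0)
})
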