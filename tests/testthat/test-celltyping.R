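test_that("dropout statistics are plain arithmetic with untestable flags", {
  m <- mk_counts(matrix(c(0, 0, 4, 4,   # S = 2, P = 0.5
                          0, 0, 0, 0,   # all zero
                          1, 2, 3, 4),  # never zero
                        3, 4, byrow = TRUE), unit = "fpkm")
  t <- dropout_stats(m)
  expect_equal(t$S, c(2, 0, 2.5))
  expect_equal(t$P, c(0.5, 1, 0))
  expect_equal(t$testable, c(TRUE, FALSE, FALSE))
})

test_that("noiseless curve data recover K exactly; symmetry point gives K = s0", {
  K <- 10
  S <- seq(0.5, 200, length.out = 60)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:60), S = S,
                    P = 1 - S / (K + S), testable = TRUE)
  class(tab) <- c("DropoutTable", "data.frame")
  attr(tab, "n_cells") <- 100
  fit <- fit_michaelis_menten(tab)
  expect_equal(fit$K, 10, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # all genes at P = 0.5, S = s0 -> K = s0
  tab2 <- data.frame(gene_id = sprintf("g%03d", 1:20), S = 7, P = 0.5,
                     testable = TRUE)
  class(tab2) <- c("DropoutTable", "data.frame")
  attr(tab2, "n_cells") <- 100
  expect_equal(fit_michaelis_menten(tab2)$K, 7, tolerance = 1e-6)
})

test_that("gene-wise K and its null behaviour follow the algebra", {
  K <- 10
  tab <- data.frame(gene_id = c("on_curve", "high"),
                    S = c(10, 10), P = c(0.5, 0.9), testable = TRUE)
  class(tab) <- c("DropoutTable", "data.frame")
  attr(tab, "n_cells") <- 400
  out <- suppressMessages(variable_genes(tab, K))
  st <- attr(out, "stats")
  # S = 10, P = 0.5 -> K_j = 10; exactly on the curve -> z = 0, p = 0.5
  expect_equal(st$K_j[st$gene_id == "on_curve"], 10)
  expect_equal(st$z[st$gene_id == "on_curve"], 0)
  expect_equal(st$p[st$gene_id == "on_curve"], 0.5)
  expect_false("on_curve" %in% out)
  expect_true("high" %in% out)
})

test_that("planted markers are recovered by the dropout test at defaults", {
  ds <- generate_dataset(generator_config(seed = 21))
  dt <- dropout_stats(filter_low_prevalence(ds$fpkm))
  vg <- suppressMessages(variable_genes(dt, fit_michaelis_menten(dt)))
  expect_gte(mean(unlist(ds$truth$markers_of) %in% vg), 0.7)
})

test_that("null generator keeps the selected fraction under control", {
  rates <- vapply(31:32, function(s) {
    ds <- generate_dataset(generator_config(seed = s, marker_log2_shift = 0,
                                            subpop_log2fc = 0))
    dt <- dropout_stats(filter_low_prevalence(ds$fpkm))
    vg <- suppressMessages(variable_genes(dt, fit_michaelis_menten(dt)))
    length(vg) / sum(dt$testable)
  }, numeric(1))
  expect_true(all(rates <= 0.07))
})

test_that("adherence test matches hand arithmetic on the O=(10,0,0) fixture", {
  db <- marker_database(list(alpha = sprintf("a%02d", 1:12),
                             beta = sprintf("b%02d", 1:12),
                             gamma = sprintf("c%02d", 1:12)))
  cl_genes <- list(`1` = sprintf("a%02d", 1:10)) # overlaps 10 of alpha only
  a <- assign_cell_types(cl_genes, db, alpha = 0.05)
  # E = (10/3, 10/3, 10/3); X2 = (10 - 10/3)^2/(10/3) + 2 * 10/3 = 20
  expect_equal(a$table$chi2, 20, tolerance = 1e-12)
  expect_equal(a$table$df, 2L)
  expect_identical(a$table$assigned_type, "alpha")
  expect_equal(sum(a$overlap_counts), 10)
})

test_that("uniform or empty overlaps give Unknown", {
  db <- marker_database(list(alpha = c("a1", "a2", "a3"),
                             beta = c("b1", "b2", "b3")))
  # identical overlap with every type -> zero statistic
  a1 <- assign_cell_types(list(`1` = c("a1", "a2", "b1", "b2")), db)
  expect_identical(a1$table$assigned_type, "Unknown")
  expect_equal(a1$table$chi2, 0)
  # empty overlap with every set
  a2 <- assign_cell_types(list(`1` = c("x1", "x2")), db)
  expect_identical(a2$table$assigned_type, "Unknown")
  expect_match(a2$table$reason, "no marker overlap")
  # no variable genes at all
  a3 <- assign_cell_types(list(`1` = character()), db)
  expect_identical(a3$table$assigned_type, "Unknown")
  expect_match(a3$table$reason, "no variable genes")
})

test_that("expected totals conserve the observed total and order is immaterial", {
  db1 <- marker_database(list(a = paste0("a", 1:5), b = paste0("b", 1:10)))
  db2 <- marker_database(list(b = paste0("b", 1:10), a = paste0("a", 1:5)))
  genes <- list(`1` = c(paste0("a", 1:4), "b1"))
  r1 <- assign_cell_types(genes, db1)
  r2 <- assign_cell_types(genes, db2)
  expect_identical(r1$table$assigned_type, r2$table$assigned_type)
  expect_equal(r1$table$chi2, r2$table$chi2)
  # sum of expected = sum of observed is implied by chi2 construction:
  O <- r1$overlap_counts[1, ]
  E <- sum(O) * c(5, 10) / 15
  expect_equal(sum(E), sum(O))
})

test_that("cluster gene lists keep only genes elevated in the cluster", {
  vals <- rbind(c(8, 8, 1, 1),   # up in cluster 1
                c(1, 1, 8, 8),   # up in cluster 2
                c(4, 4, 4, 4))   # flat
  m <- mk_counts(vals, unit = "log2fpkm")
  labs <- stats::setNames(c(1, 1, 2, 2), m$cell_ids)
  cg <- cluster_gene_lists(m, labs, m$gene_ids, top_n = 10)
  expect_identical(cg$`1`, "g001")
  expect_identical(cg$`2`, "g002")
})

test_that("biotype classification partitions marker counts", {
  ann <- mk_annotation(5, biotypes = c("coding", "coding", "coding",
                                       "lncRNA", "pcRNA"))
  counts <- classify_markers_by_biotype(sprintf("g%03d", 1:5), ann)
  expect_equal(unname(counts), c(3L, 1L, 1L))
  expect_equal(sum(counts), 5L)
  # empty list -> zeros; list input -> matrix; permutation invariance
  expect_equal(unname(classify_markers_by_biotype(character(), ann)),
               c(0L, 0L, 0L))
  two <- classify_markers_by_biotype(list(x = c("g001", "g004"),
                                          y = "g005"), ann)
  expect_equal(unname(two["x", ]), c(1L, 1L, 0L))
  perm <- ann[sample(nrow(ann)), ]
  class(perm) <- class(ann)
  expect_equal(classify_markers_by_biotype(sprintf("g%03d", 1:5), perm),
               counts)
  expect_error(classify_markers_by_biotype("gX", ann), "unannotated")
})

test_that("venn region counts cover shared and unique markers", {
  r <- compare_marker_sets(list(v = c("A", "B"), a = c("B", "C")))
  expect_equal(r$count[r$region == "v"], 1L)
  expect_equal(r$count[r$region == "a"], 1L)
  expect_equal(r$count[r$region == "v&a"], 1L)
  expect_equal(r$genes[r$region == "v&a"], "B")
  # identical sets sit entirely in the intersection
  r2 <- compare_marker_sets(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(r2$count[r2$region == "x&y"], 2L)
  expect_equal(sum(r2$count[r2$region != "x&y"]), 0L)
  # disjoint triple: only unique cells populated
  r3 <- compare_marker_sets(list(p = "A", q = "B", s = "C"))
  expect_equal(sum(r3$count), 3L)
  expect_true(all(r3$count[grepl("&", r3$region)] == 0))
  expect_error(compare_marker_sets(as.list(setNames(letters[1:5], letters[1:5]))),
               "at most 4")
})
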