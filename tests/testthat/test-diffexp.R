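test_that("size factors match the doubled-cell closed form", {
  withr::with_seed(1, base <- rpois(50, 40) + 1)
  m <- mk_counts(cbind(base, 2 * base))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf), c(0.70710678, 1.41421356), tolerance = 1e-8)
  # identical cells -> all ones
  m2 <- mk_counts(cbind(base, base, base))
  expect_equal(unname(size_factors(m2)), rep(1, 3))
  # invariant under gene reordering
  perm <- sample(nrow(m$values))
  m3 <- expression_matrix(m$values[perm, ], m$gene_ids[perm], m$cell_ids,
                          unit = "counts")
  expect_equal(unname(size_factors(m3)), unname(sf))
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  # odd gene count: the median of ratios and the geometric median coincide
  withr::with_seed(2, v <- matrix(rnbinom(201 * 10, mu = 50, size = 2), 201, 10))
  v <- v + 1 # keep every gene nonzero so both methods use the same gene set
  m <- mk_counts(v)
  ref <- DESeq2::estimateSizeFactorsForMatrix(v)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("all-zero-containing genes trigger the total-count fallback", {
  v <- matrix(c(0, 5, 3, 4, 0, 0), 3, 2) # every gene has a zero somewhere
  expect_warning(sf <- size_factors(mk_counts(v)), "total-count")
  totals <- colSums(v)
  expect_equal(unname(sf), totals / exp(mean(log(totals))))
})

test_that("dispersion estimates recover the simulation truth", {
  groups <- rep(1:2, each = 200)
  # NB with phi = 0.5
  withr::with_seed(3, {
    mu <- rlnorm(400, log(50), 1)
    v <- matrix(rnbinom(400 * 400, mu = mu, size = 2), 400, 400)
  })
  m <- mk_counts(v)
  phi <- estimate_dispersion(m, groups, size_factors(m))
  expect_gt(median(phi), 0.35)
  expect_lt(median(phi), 0.65)
  # Poisson data collapse to the floor
  withr::with_seed(4, vp <- matrix(rpois(400 * 400, mu), 400, 400))
  phip <- estimate_dispersion(mk_counts(vp), groups, rep(1, 400))
  expect_lt(median(phip), 1e-3)
  # constant gene -> floor exactly
  vc <- rbind(matrix(5, 1, 400), v[1:3, ])
  phic <- estimate_dispersion(mk_counts(vc), groups, rep(1, 400))
  expect_equal(unname(phic[1]), 1e-8)
})

test_that("identical constant groups give the exact null", {
  m <- mk_counts(matrix(7, 5, 20))
  de <- nb_wald_test(m, rep(1:2, each = 10), sf = rep(1, 20),
                     phi = rep(0.1, 5))
  expect_equal(de$log2fc, rep(0, 5))
  expect_equal(de$wald_z, rep(0, 5))
  expect_equal(de$p, rep(1, 5))
})

test_that("swapping group labels negates fold changes and preserves p", {
  withr::with_seed(5, v <- matrix(rnbinom(100 * 40, mu = 30, size = 2), 100, 40))
  m <- mk_counts(v)
  g <- rep(c("x", "y"), each = 20)
  d1 <- suppressMessages(nb_wald_test(m, factor(g, c("x", "y"))))
  d2 <- suppressMessages(nb_wald_test(m, factor(g, c("y", "x"))))
  common <- intersect(d1$gene_id, d2$gene_id)
  i1 <- match(common, d1$gene_id); i2 <- match(common, d2$gene_id)
  expect_equal(d1$log2fc[i1], -d2$log2fc[i2], tolerance = 1e-12)
  expect_equal(d1$p[i1], d2$p[i2], tolerance = 1e-12)
})

test_that("null type-I error and planted power sit in their bands", {
  withr::with_seed(6, {
    mu <- rlnorm(4000, log(30), 1)
    v <- matrix(rnbinom(4000 * 200, mu = mu, size = 1 / 0.4), 4000, 200)
  })
  de <- suppressMessages(nb_wald_test(mk_counts(v), rep(1:2, each = 100)))
  t1 <- mean(de$p < 0.05)
  expect_gt(t1, 0.03); expect_lt(t1, 0.07)
  # planted log2fc = 2 at phi = 0.4, 100 cells/group
  withr::with_seed(7, {
    mu <- rlnorm(1000, log(30), 1)
    mu2 <- mu; mu2[1:100] <- mu2[1:100] * 4
    v2 <- cbind(matrix(rnbinom(1000 * 100, mu = mu, size = 2.5), 1000),
                matrix(rnbinom(1000 * 100, mu = mu2, size = 2.5), 1000))
  })
  de2 <- suppressMessages(nb_wald_test(mk_counts(v2), rep(1:2, each = 100)))
  power <- mean(de2$q[match(sprintf("g%03d", 1:100), de2$gene_id)] < 0.05,
                na.rm = TRUE)
  expect_gte(power, 0.8)
})

test_that("BH q-values are monotone in p within the tested set", {
  withr::with_seed(8, v <- matrix(rnbinom(200 * 30, mu = 20, size = 2), 200, 30))
  de <- suppressMessages(nb_wald_test(mk_counts(v), rep(1:2, each = 15)))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  expect_equal(max(de$q), max(de$p))
})

test_that("volcano direction logic applies both cut-offs per biotype", {
  de <- data.frame(gene_id = c("g001", "g002", "g003", "g004"),
                   base_mean = 10,
                   log2fc = c(1, log2(1.4), log2(3), -1),
                   se = 1, wald_z = 1,
                   p = c(0.001, 0.0005, 0.2, 0.01),
                   q = c(0.01, 0.001, 0.2, 0.04),
                   degenerate = FALSE, stringsAsFactors = FALSE)
  class(de) <- c("DEResult", "data.frame")
  ann <- mk_annotation(4, biotypes = c("coding", "coding", "lncRNA", "lncRNA"))
  v <- volcano_summary(de, ann, fc_cut = 1.5, p_cut = 0.05)
  # fc 2 & q 0.01 -> up; fc 1.4 below fold cut -> ns; fc 3 but q 0.2 -> ns;
  # fc 0.5 & q 0.04 -> down
  expect_equal(as.character(v$direction), c("up", "ns", "ns", "down"))
  expect_equal(v$counts$n_up, c(1L, 0L, 0L))
  expect_equal(v$counts$n_down, c(0L, 1L, 0L))
  expect_equal(v$counts$n_total_de, v$counts$n_up + v$counts$n_down)
  # counts are non-increasing in the fold cut
  v2 <- volcano_summary(de, ann, fc_cut = 2.5, p_cut = 0.05)
  expect_true(all(v2$counts$n_total_de <= v$counts$n_total_de))
})

test_that("subpopulations are named after the top coding gene per group", {
  ann <- gene_annotation(paste0("g", 1:4),
                         symbol = c("Pln", "Tpm1", "Lnc1", "Malat1"),
                         biotype = c("coding", "coding", "lncRNA", "lncRNA"),
                         length_bp = rep(1000, 4))
  vals <- rbind(c(90, 90, 5, 5),     # Pln tops group 1
                c(10, 10, 80, 80),   # Tpm1 tops group 2
                c(100, 100, 100, 100), # lncRNA: ignored despite being top
                c(1, 1, 1, 1))
  m <- expression_matrix(vals, paste0("g", 1:4), paste0("c", 1:4), unit = "fpkm")
  grp <- factor(c(1, 1, 2, 2))
  expect_identical(name_subpopulations(m, ann, grp), c("Pln-CM", "Tpm1-CM"))
  # swapping the group order swaps the names
  expect_identical(name_subpopulations(m, ann, factor(c(1, 1, 2, 2),
                                                      levels = c(2, 1))),
                   c("Tpm1-CM", "Pln-CM"))
})

test_that("naming handles the Myh6/Sln fixture and top-gene collisions", {
  ann <- gene_annotation(paste0("g", 1:3),
                         symbol = c("Myh6", "Sln", "Actb"),
                         biotype = "coding", length_bp = rep(1000, 3))
  vals <- rbind(c(80, 80, 10, 10),
                c(5, 5, 60, 60),
                c(20, 20, 20, 20))
  m <- expression_matrix(vals, paste0("g", 1:3), paste0("c", 1:4), unit = "fpkm")
  grp <- factor(c(1, 1, 2, 2))
  expect_identical(name_subpopulations(m, ann, grp), c("Myh6-CM", "Sln-CM"))
  # shared top gene: fall back to the most group-distinguishing coding genes
  vals2 <- rbind(c(100, 100, 100, 100),
                 c(50, 50, 10, 10),
                 c(10, 10, 50, 50))
  m2 <- expression_matrix(vals2, paste0("g", 1:3), paste0("c", 1:4),
                          unit = "fpkm")
  nm <- name_subpopulations(m2, ann, grp)
  expect_identical(nm, c("Sln-CM", "Actb-CM"))
  expect_false(nm[1] == nm[2])
  # no coding genes at all is a hard error
  ann3 <- gene_annotation(paste0("g", 1:3), symbol = c("a", "b", "c"),
                          biotype = "lncRNA", length_bp = rep(1000, 3))
  expect_error(name_subpopulations(m, ann3, grp), "no coding genes")
})
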