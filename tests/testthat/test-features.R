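test_that("peak-to-gene flags follow the 1-bp-overlap and promoter-window rules", {
  ann <- toy_annotation(starts = c(1000, 10000), ends = c(2000, 12000),
                        ids = c("gA", "gB"))
  pk <- tibble::tibble(chrom = "chr1", start = 999, end = 1000, assay = "ATAC")
  expect_equal(annotate_peaks_to_genes(pk, ann)$flag, c(1, 0))

  other <- tibble::tibble(chrom = "chr9", start = 1500, end = 1600, assay = "ATAC")
  expect_error(annotate_peaks_to_genes(other, ann), "chr9")

  # peak 1500 bp upstream of gB's start: in with window 2000, out with 1000
  up <- tibble::tibble(chrom = "chr1", start = 8400, end = 8500, assay = "ATAC")
  expect_equal(annotate_peaks_to_genes(up, ann, promoter_window = 2000)$flag, c(0, 1))
  expect_equal(annotate_peaks_to_genes(up, ann, promoter_window = 1000)$flag, c(0, 0))
})

test_that("peak flags are invariant to peak order and to splitting abutting peaks", {
  ann <- toy_annotation(starts = c(1000, 5000, 9000),
                        ends = c(2000, 6000, 9500))
  whole <- tibble::tibble(chrom = "chr1", start = c(1500, 5500),
                          end = c(1800, 5800), assay = "ATAC")
  split_ <- tibble::tibble(chrom = "chr1", start = c(5650, 1500, 5500),
                           end = c(5800, 1800, 5649), assay = "ATAC")
  expect_equal(annotate_peaks_to_genes(whole, ann),
               annotate_peaks_to_genes(split_, ann))
})

test_that("active enhancers are intergenic H3K27ac/ATAC intersections", {
  ann <- toy_annotation(starts = c(1000, 10000), ends = c(2000, 12000),
                        ids = c("gA", "gB"))
  k27 <- tibble::tibble(chrom = "chr1", start = c(5000, 1200),
                        end = c(6000, 1300), assay = "H3K27ac")
  atac <- tibble::tibble(chrom = "chr1", start = 5500, end = 7000, assay = "ATAC")
  enh <- call_active_enhancers(k27, atac, ann)
  expect_equal(nrow(enh), 1)  # the peak inside gA's body is excluded
  expect_equal(c(enh$start, enh$end), c(5500, 6000))
  expect_equal(sort(c(enh$nearest_gene, enh$second_gene)), c("gA", "gB"))

  # planted simulation: recovered count equals planted count
  sim <- simulate_genomes(2, 200, 0, seed = 61)
  expr <- simulate_expression(sim$annotations$focal, seed = 62)
  pk <- simulate_peaks(sim$annotations$focal, expr, peak_prob = 0.3,
                       n_enhancers = 8, seed = 63)
  got <- call_active_enhancers(pk$h3k27ac, pk$atac, sim$annotations$focal)
  expect_equal(nrow(got), 8)
})

test_that("ICE normalization equalizes marginals, is idempotent, and fixes balanced input", {
  # already balanced: returned unchanged up to the convergence tolerance
  bal <- matrix(c(0, 3, 3, 0), 2, 2)
  out <- ice_normalize(bal)
  expect_equal(out$values, bal)
  expect_true(attr(out, "converged"))

  a <- matrix(c(0, 7, 7, 0), 2, 2)
  expect_equal(ice_normalize(a)$values, a)  # symmetric 2x2 is a fixed point

  set.seed(71)
  for (s in 1:3) {
    m <- matrix(runif(100, 0.1, 5), 10, 10)
    m <- (m + t(m)) / 2
    n1 <- ice_normalize(m)
    rs <- rowSums(n1$values)
    expect_lt(sd(rs) / mean(rs), 1e-6)
    n2 <- ice_normalize(n1$values)
    expect_lt(max(abs(attr(n2, "bias") - 1)), 1e-6)  # idempotence
  }

  expect_error(ice_normalize(matrix(0, 3, 3)), "all-zero")

  # masked zero-marginal bins are left untouched
  mz <- matrix(runif(16, 1, 2), 4, 4); mz <- (mz + t(mz)) / 2
  mz[3, ] <- 0; mz[, 3] <- 0
  nm <- ice_normalize(mz)
  expect_true(attr(nm, "mask")[3])
  expect_true(all(nm$values[3, ] == 0))
  live <- rowSums(nm$values)[-3]
  expect_lt(sd(live) / mean(live), 1e-6)
})

test_that("Hi-C contact extraction picks the TSS bins (strand-aware)", {
  v <- matrix(0, 4, 4)
  v[1, 3] <- v[3, 1] <- 7; diag(v) <- c(9, 1, 1, 1)
  cm <- contact_matrix(v, bin_size = 5000)
  g_same1 <- list(chrom = "chr1", start = 1, end = 400, strand = "+")
  g_same2 <- list(chrom = "chr1", start = 4999, end = 5200, strand = "+")
  expect_equal(hic_contact_for_pair(g_same1, g_same2, cm)$contact, 9)

  g3 <- list(chrom = "chr1", start = 10001, end = 14000, strand = "+")
  expect_equal(hic_contact_for_pair(g_same1, g3, cm)$contact, 7)

  # minus-strand TSS is the end coordinate
  g_minus <- list(chrom = "chr1", start = 8000, end = 10001, strand = "-")
  expect_equal(hic_contact_for_pair(g_same1, g_minus, cm)$contact, 7)

  miss <- list(chrom = "chr2", start = 1, end = 10, strand = "+")
  h <- hic_contact_for_pair(g_same1, miss, cm)
  expect_equal(h$contact, 0)
  expect_true(h$missing)

  # planted power-law matrix: contact decreases with bin separation
  sim_cm <- simulate_hic(c(chr1 = 5e5), 5000, decay_exponent = 1, seed = 72)
  n <- nrow(sim_cm$values)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m1 <- mean(sim_cm$values[d == 1]); m10 <- mean(sim_cm$values[d == 10])
  expect_gt(m1, m10)
})

test_that("GO and promoter sharing count exact distinct intersections", {
  go <- tibble::tibble(
    gene_id = c("a", "a", "a", "b", "b", "b", "c", "a", "b"),
    go_id = c("GO:1", "GO:2", "GO:3", "GO:1", "GO:2", "GO:3", "GO:9",
              "GO:5", "GO:5"),
    namespace = c(rep("BP", 7), "MF", "MF"))
  expect_equal(shared_go_terms("a", "b", go), 3)  # MF ignored
  expect_equal(shared_go_terms("a", "c", go), 0)
  expect_equal(shared_go_terms("a", "zzz", go), 0)

  el <- tibble::tibble(
    gene_id = c(rep("a", 5), "b"),
    element = c("TATA", "TATA", "TATA", "CAAT", "MYB", "TATA"))
  expect_equal(shared_promoter_elements("a", "b", el), 1)  # distinct names
  both <- tibble::tibble(gene_id = c("a", "a", "a", "b", "b", "b"),
                         element = rep(c("TATA", "CAAT", "MYB"), 2))
  expect_equal(shared_promoter_elements("a", "b", both), 3)
  expect_equal(shared_promoter_elements("a", "b", el[0, ]), 0)
})

test_that("expression difference is symmetric, scale-invariant, and bounded", {
  expect_equal(expression_difference(3, 3), 0)
  expect_equal(expression_difference(4, 2), 2 / 3)
  expect_equal(expression_difference(2, 4), 2 / 3)
  expect_equal(expression_difference(0, 5), 2)
  expect_equal(expression_difference(40, 20), expression_difference(4, 2))
  expect_error(expression_difference(0, 0), "zero")
})

test_that("expression comparison by peak flag reports medians and U-test", {
  # arithmetic on the printed medians
  expect_equal(relative_change(4.57, 3.69), 23.85)
  expect_equal(relative_change(4.55, 3.45), 31.88)

  sim <- simulate_genomes(2, 300, 0, seed = 81)
  ann <- sim$annotations$focal
  expr <- simulate_expression(ann, seed = 82)
  pk <- simulate_peaks(ann, expr, peak_prob = 0.4, peak_boost = 1.5, seed = 83)
  fl <- tibble::tibble(gene_id = ann$gene_id,
                       flag = as.integer(ann$gene_id %in% pk$truth$peak_genes))
  cmp <- compare_expression_by_flag(pk$expression, fl)
  expect_gt(cmp$median_with, cmp$median_without)
  expect_lt(cmp$p_value, 0.05)

  same <- tibble::tibble(gene_id = rownames(expr), flag = rep(c(0L, 1L), length.out = nrow(expr)))
  set.seed(84)
  cmp0 <- compare_expression_by_flag(expr, same)
  expect_gt(cmp0$p_value, 0.05)
})

test_that("the assembled feature table carries all nine covariates", {
  sim <- simulate_genomes(3, 200, 0.2, seed = 91)
  ann <- sim$annotations$focal
  expr <- simulate_expression(ann, seed = 92)
  pk <- simulate_peaks(ann, expr, peak_prob = 0.3, n_enhancers = 5, seed = 93)
  cm <- simulate_hic(setNames(vapply(split(ann$end, ann$chrom), max, 0),
                              sort(unique(ann$chrom))),
                     bin_size = 5000, decay_exponent = 1, seed = 94)
  go <- tibble::tibble(gene_id = sample(ann$gene_id, 100, replace = TRUE),
                       go_id = paste0("GO:", sample(20, 100, replace = TRUE)),
                       namespace = "BP")
  el <- tibble::tibble(gene_id = sample(ann$gene_id, 100, replace = TRUE),
                       element = sample(c("TATA", "CAAT"), 100, replace = TRUE))
  sngs <- find_sngs(ann, sim$annotations[-1], sim$orthologs)
  rec <- pair_records(sngs, pk$expression, ann)
  ft <- build_feature_table(rec, ann, pk$expression, atac = pk$atac,
                            h3k27ac = pk$h3k27ac, contacts = cm,
                            go = go, elements = el)
  expect_true(all(c("distance", "mean_length", "atac", "h3k27ac", "hic",
                    "go_shared", "promoter_shared", "enhancer_shared",
                    "expr_diff") %in% names(ft)))
  expect_true(all(ft$expr_diff >= 0 & ft$expr_diff <= 2))
  expect_true(all(ft$hic >= 0))
  expect_true(all(ft$atac %in% 0:1))

  # AND rule is at least as strict as OR
  ft_or <- build_feature_table(rec, ann, pk$expression, atac = pk$atac,
                               h3k27ac = pk$h3k27ac, pair_flag_rule = "or")
  expect_true(all(ft$atac <= ft_or$atac))
})
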