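test_that("pearson_r matches the product-moment formula and rejects bad input", {
  expect_equal(pearson_r(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)

  # independent evaluation of the product-moment formula
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den)
  expect_equal(round(pearson_r(x, y), 3), 0.982)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(1:3, 1:4), "equal length")

  # invariance under positive affine transforms
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearson_r(a, b), pearson_r(3 * a + 2, 0.5 * b - 7))
})

test_that("pair distance and mean length follow the coordinate definitions", {
  g1 <- list(start = 1000, end = 4999)
  g2 <- list(start = 9000, end = 14999)
  expect_equal(pair_distance(g1, g2), 8000)
  expect_equal(pair_distance(g2, g1), 8000)
  expect_equal(pair_distance(g1, g1), 0)
  expect_equal(pair_mean_length(g1, g2), (4000 + 6000) / 2)
  expect_equal(pair_mean_length(g1, g1), 4000)
  expect_equal(pair_mean_length(list(start = 5, end = 5),
                                list(start = 1, end = 9999)), 5000)
})

test_that("binning is left-closed and reproduces printed group percentages", {
  rec <- records_from_counts(distances = c(7999, 8000, 50000),
                             n_pairs = c(1, 1, 1), n_coexpr = c(1, 0, 0))
  bins <- bin_pairs(rec, c(8000, 50000), "distance", n_boot = 0)
  expect_equal(bins$label, c("short", "medium", "long"))
  expect_equal(bins$n_pairs, c(1, 1, 1))  # 8000 is medium, 50000 is long

  # group sizes and co-expressed counts of the distance analysis
  rec <- records_from_counts(distances = c(4000, 20000, 80000),
                             n_pairs = c(212, 264, 295),
                             n_coexpr = c(75, 61, 65))
  bins <- bin_pairs(rec, c(8000, 50000), "distance", n_boot = 200, seed = 1)
  pct <- round(100 * bins$proportion, 2)
  expect_equal(pct, c(35.38, 23.11, 22.03))
  expect_equal(sum(bins$n_pairs), nrow(rec))
  expect_equal(relative_change(pct[1], pct[2]), 53.09)
  # bootstrap SE close to the binomial closed form
  expect_lt(abs(bins$bootstrap_se[1] - sqrt(0.3538 * (1 - 0.3538) / 212)), 0.01)

  low <- records_from_counts(1000, 10, 5)
  b2 <- bin_pairs(low, c(8000, 50000), "distance", n_boot = 0)
  expect_equal(b2$n_pairs, c(10, 0, 0))
  expect_true(is.na(b2$proportion[3]))
})

test_that("relative change reproduces printed derived percentages", {
  expect_equal(relative_change(35.38, 23.11), 53.09)
  expect_equal(relative_change(29.11, 24.71), 17.81)
  expect_equal(relative_change(29.11, 23.61), 23.30)
  expect_equal(relative_change(4.57, 3.69), 23.85)
  expect_equal(relative_change(0.42, 0.42), 0)
  expect_error(relative_change(0.4, 0), "zero")
})

test_that("combined filter groups reduce to the right subsets", {
  rec <- records_from_counts(distances = c(4000, 20000),
                             n_pairs = c(40, 60), n_coexpr = c(16, 12))
  all_grp <- combined_group(rec, distance < Inf, mean_length > 0, n_boot = 0)
  expect_equal(all_grp$proportion, coexpression_proportion(rec))

  short <- combined_group(rec, distance < 8000, n_boot = 0)
  expect_equal(short$proportion, 0.4)
  expect_equal(relative_change(40.00, 29.11), 37.41)

  expect_error(combined_group(rec, distance > 1e9), "no pairs")
})

test_that("randomization null is calibrated against a direct Monte-Carlo oracle", {
  set.seed(7)
  expr <- matrix(exp(rnorm(150 * 10)), 150, 10,
                 dimnames = list(paste0("g", 1:150), paste0("t", 1:10)))
  null <- randomization_null(expr, n_pairs = 50, n_iter = 400, seed = 1)
  expect_length(null$proportions, 400)

  # independent oracle: plain loop over random pairs with cor()
  set.seed(8)
  draws <- replicate(4000, {
    ij <- sample.int(nrow(expr), 2)
    cor(expr[ij[1], ], expr[ij[2], ]) > 0.5
  })
  expect_lt(abs(mean(null$proportions) - mean(draws)), 0.03)

  # all genes sharing one profile: every iteration at proportion 1
  prof <- sweep(matrix(rep(c(1, 5, 2, 8, 3), 20), 20, 5, byrow = TRUE),
                1, seq(1, 2, length.out = 20), "*")
  rownames(prof) <- paste0("g", 1:20); colnames(prof) <- paste0("t", 1:5)
  one <- randomization_null(prof, n_pairs = 5, n_iter = 100, seed = 2)
  expect_true(all(one$proportions == 1))

  # observed above every draw: smoothed p at its lower bound
  top <- randomization_null(expr, n_pairs = 50, n_iter = 400, seed = 3, observed = 1.01)
  expect_equal(top$p_value, 1 / 401)

  expect_error(randomization_null(expr[1, , drop = FALSE], 5, 100), "2 usable genes")
  expect_error(randomization_null(expr, 5, 10), "n_iter")
})

test_that("bootstrap SE matches the binomial closed form and degenerates to zero", {
  expect_equal(bootstrap_se(rep(TRUE, 30), n_boot = 200, seed = 1), 0)
  expect_equal(bootstrap_se(TRUE, n_boot = 200, seed = 1), 0)

  flags <- rep(c(TRUE, FALSE), c(100, 300))
  se <- bootstrap_se(flags, n_boot = 1000, seed = 2)
  closed <- sqrt(0.25 * 0.75 / 400)
  expect_lt(abs(se - closed) / closed, 0.15)

  # insensitivity to flag order (resamples differ only through the shuffle)
  set.seed(3)
  expect_lt(abs(bootstrap_se(sample(flags), n_boot = 500, seed = 4) -
                  bootstrap_se(flags, n_boot = 500, seed = 4)), 0.005)
})

test_that("Mann-Whitney U handles separation, full ties, and matches enumeration", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)

  tie <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tie$p_value, 1)

  # exhaustive orderings oracle for U of a=(1,3,5) vs b=(2,4):
  # count b-values below each a value
  a <- c(1, 3, 5); b <- c(2, 4)
  u_brute <- sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), 0))
  expect_equal(mann_whitney_u(a, b)$U, u_brute)

  # cross-check p against wilcox.test's tie-corrected normal approximation
  set.seed(9)
  x <- round(rnorm(25), 1); y <- round(rnorm(30, 0.4), 1)
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("profile clustering recovers planted archetypes deterministically", {
  set.seed(12)
  arch <- diag(4)[rep(1:4, each = 15), ] * 8
  expr <- arch + matrix(rnorm(60 * 4, sd = 0.4), 60, 4)
  expr <- cbind(expr, expr[, 1] * 0.5 + rnorm(60, sd = 0.4))
  rownames(expr) <- paste0("g", 1:60); colnames(expr) <- paste0("t", 1:5)
  cl <- cluster_profiles(expr, k = 4, seed = 5)
  expect_equal(adjusted_rand(cl$cluster, rep(1:4, each = 15)), 1)
  expect_identical(cl, cluster_profiles(expr, k = 4, seed = 5))
  expect_equal(unique(cluster_profiles(expr, k = 1, seed = 5)$cluster), 1)
})
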