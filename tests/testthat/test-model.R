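# Records with a single planted signal: co-expression probability driven by
# distance only, all other covariates pure noise.
distance_driven_records <- function(n = 400, seed = 1, strength = 2.5) {
  set.seed(seed)
  d <- exp(runif(n, log(1000), log(2e5)))
  eta <- -2 * strength * (log(d) - mean(log(d))) / diff(range(log(d)))
  tibble::tibble(
    gene1 = paste0("a", seq_len(n)), gene2 = paste0("b", seq_len(n)),
    distance = d,
    mean_length = exp(rnorm(n, log(5000), 0.4)),
    atac = rbinom(n, 1, 0.4), h3k27ac = rbinom(n, 1, 0.4),
    hic = rexp(n), go_shared = rpois(n, 0.5),
    promoter_shared = rpois(n, 2), enhancer_shared = rbinom(n, 1, 0.05),
    expr_diff = runif(n, 0, 2),
    coexpressed = runif(n) < plogis(eta))
}

test_that("balanced datasets equalize classes deterministically", {
  rec <- distance_driven_records(600, seed = 2)
  rec$coexpressed <- rep(c(TRUE, FALSE), c(100, 500))
  ds <- build_balanced_dataset(rec, c("distance", "mean_length"), seed = 3)
  expect_equal(length(ds$y), 200)
  expect_equal(sum(ds$y), 100)
  ds2 <- build_balanced_dataset(rec, c("distance", "mean_length"), seed = 3)
  expect_identical(ds$rows, ds2$rows)

  rec2 <- rec[1:150, ]
  rec2$coexpressed <- rep(c(TRUE, FALSE), c(100, 50)) # positives exceed negatives
  expect_error(build_balanced_dataset(rec2, "distance", seed = 1),
               "fewer negatives")
  ds3 <- build_balanced_dataset(rec2, "distance", seed = 1,
                                allow_downsample_positives = TRUE)
  expect_equal(length(ds3$y), 100)

  rec2$z <- 1
  expect_warning(build_balanced_dataset(rec2, c("distance", "z"), seed = 1,
                                        allow_downsample_positives = TRUE),
                 "zero-variance")
})

test_that("IRLS recovers the closed-form log odds ratio on 2x2 designs", {
  for (counts in list(c(30, 10, 15, 25), c(8, 22, 19, 11), c(40, 5, 20, 35))) {
    a <- counts[1]; b <- counts[2]; c_ <- counts[3]; d <- counts[4]
    x <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
    y <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
    fit <- fit_logistic(matrix(x, ncol = 1), y)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients[2]), log(a * d / (b * c_)),
                 tolerance = 1e-6)
  }
})

test_that("IRLS agrees with glm() as an independent likelihood maximizer", {
  set.seed(5)
  X <- cbind(rnorm(50), runif(50), rbinom(50, 1, 0.5))
  y <- rbinom(50, 1, plogis(0.5 * X[, 1] - X[, 2]))
  fit <- fit_logistic(X, y)
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)

  # intercept-only on balanced labels
  fit0 <- fit_logistic(matrix(numeric(0), 20, 0), rep(c(0, 1), 10))
  expect_equal(unname(fit0$coefficients[1]), 0, tolerance = 1e-8)

  # perfect separation is flagged rather than silently reported
  xs <- matrix(c(1:10), ncol = 1)
  ys <- as.integer(xs > 5)
  sepfit <- fit_logistic(xs, ys)
  expect_true(sepfit$separation)
})

test_that("tidy() and glance() expose the fit in broom shape", {
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(40, 1, 0.5)
  fit <- fit_logistic(X, y)
  td <- generics::tidy(fit)
  expect_equal(names(td), c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("(Intercept)", "f1", "f2"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nterms, 3)
})

test_that("rank AUC equals the exhaustive pair-comparison oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_rank(scores, labels), auc_exhaustive(scores, labels))
  }
})

test_that("repeated AUC saturates on a perfect feature and stays null on noise", {
  rec <- distance_driven_records(300, seed = 8)
  rec$oracle_feature <- as.numeric(rec$coexpressed)
  perfect <- repeated_auc(rec, "oracle_feature", n_repeats = 5, seed = 9,
                          allow_downsample_positives = TRUE)
  expect_equal(perfect$mean_auc, 1)

  big <- distance_driven_records(2000, seed = 10, strength = 0)
  big$noise <- rnorm(2000)
  nullm <- repeated_auc(big, "noise", n_repeats = 10, seed = 11,
                        allow_downsample_positives = TRUE)
  expect_gt(nullm$mean_auc, 0.45)
  expect_lt(nullm$mean_auc, 0.55)

  # label permutation destroys a real signal
  perm <- distance_driven_records(1500, seed = 12)
  set.seed(13)
  perm$coexpressed <- sample(perm$coexpressed)
  permm <- repeated_auc(perm, "distance", n_repeats = 10, seed = 14,
                        allow_downsample_positives = TRUE)
  expect_gt(permm$mean_auc, 0.45)
  expect_lt(permm$mean_auc, 0.55)
})

test_that("variable importance ranks the planted signal first", {
  rec <- distance_driven_records(500, seed = 15)
  feats <- c("distance", "mean_length", "atac", "h3k27ac", "hic",
             "go_shared", "promoter_shared", "enhancer_shared", "expr_diff")
  res <- repeated_auc(rec, feats, n_repeats = 10, seed = 16,
                      allow_downsample_positives = TRUE)
  imp <- variable_importance(res)
  expect_equal(imp$feature[1], "distance")
  expect_equal(imp$rank, seq_len(nrow(imp)))
})

test_that("interaction surfaces recover planted sign flips and degenerate cleanly", {
  set.seed(17)
  n <- 1200
  d <- runif(n); f <- runif(n)
  zd <- as.numeric(scale(d)); zf <- as.numeric(scale(f))
  y <- rbinom(n, 1, plogis(3 * zd * zf))  # pure interaction: ordering flips
  rec <- tibble::tibble(gene1 = paste0("a", 1:n), gene2 = paste0("b", 1:n),
                        distance = d, feat = f, coexpressed = y == 1)
  surf <- interaction_surface(rec, "feat", seed = 18,
                              allow_downsample_positives = TRUE)
  lowd <- surf[surf$distance == min(surf$distance), ]
  highd <- surf[surf$distance == max(surf$distance), ]
  ord_low <- lowd$prob[lowd$level == "high"] - lowd$prob[lowd$level == "low"]
  ord_high <- highd$prob[highd$level == "high"] - highd$prob[highd$level == "low"]
  expect_lt(ord_low * ord_high, 0)  # feature-level ordering reverses

  # additive truth: rows stay near-parallel on the logit scale
  y2 <- rbinom(n, 1, plogis(1.5 * zd - 1 * zf))
  rec2 <- dplyr::mutate(rec, coexpressed = y2 == 1)
  surf2 <- interaction_surface(rec2, "feat", seed = 19,
                               allow_downsample_positives = TRUE)
  gap <- function(s, dd) {
    qlogis(s$prob[s$distance == dd & s$level == "high"]) -
      qlogis(s$prob[s$distance == dd & s$level == "low"])
  }
  gaps <- vapply(unique(surf2$distance), function(dd) gap(surf2, dd), 0)
  expect_lt(diff(range(gaps)), 0.5)

  one <- interaction_surface(rec2, "feat", n_distance = 1, seed = 20,
                             allow_downsample_positives = TRUE)
  expect_equal(nrow(one), 3)
  expect_true(all(one$prob >= 0 & one$prob <= 1))
})
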