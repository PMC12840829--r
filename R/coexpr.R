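#' Pearson correlation of two expression profiles
#'
#' Plain product-moment correlation, with the contract that constant vectors
#' are an error rather than silently `NA`: pairs with constant expression are
#' excluded upstream with a logged count, never assigned r = 0.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations for a correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("correlation undefined for a constant expression profile")
  }
  as.numeric(cor(x, y))
}

#' Intergenic distance of a gene pair
#'
#' Absolute difference between the two genes' start coordinates; symmetric
#' in argument order and strand-agnostic.
#'
#' @param g1,g2 One-row gene tibbles or lists with `start`.
#' @return Distance in bp.
#' @export
pair_distance <- function(g1, g2) abs(g1$start - g2$start)

#' Mean transcribed length of a gene pair
#' @param g1,g2 One-row gene tibbles or lists with `start`, `end` (1-based
#'   inclusive).
#' @return Mean of the two gene lengths (bp).
#' @export
pair_mean_length <- function(g1, g2) {
  ((g1$end - g1$start + 1) + (g2$end - g2$start + 1)) / 2
}

#' Build pair records: correlation, co-expression flag, distance, length
#'
#' Joins an SNG pair table with an expression matrix and the focal
#' annotation. Pairs in which either gene has constant (or absent)
#' expression are dropped; the number dropped is recorded in the
#' `"n_excluded"` attribute and a message.
#'
#' @param pairs Tibble with `gene1`, `gene2` (e.g. from [find_sngs()]).
#' @param expr Genes x tissues TPM matrix.
#' @param ann Focal annotation tibble.
#' @param coexpr_threshold Pearson r above which a pair is co-expressed.
#' @param log2p1 If `TRUE`, correlate `log2(TPM + 1)` instead of raw TPM.
#' @return Tibble with `gene1`, `gene2`, `r`, `coexpressed`, `distance`,
#'   `mean_length` (plus any feature columns already present on `pairs`).
#' @export
pair_records <- function(pairs, expr, ann, coexpr_threshold = 0.5, log2p1 = FALSE) {
  if (log2p1) expr <- log2(expr + 1)
  g <- ann[match(c(pairs$gene1, pairs$gene2), ann$gene_id), ]
  n <- nrow(pairs)
  g1 <- g[seq_len(n), ]; g2 <- g[n + seq_len(n), ]
  usable <- function(id) {
    ok <- id %in% rownames(expr)
    ok[ok] <- apply(expr[id[ok], , drop = FALSE], 1, sd) > 0
    ok
  }
  keep <- usable(pairs$gene1) & usable(pairs$gene2)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("excluding %d pair(s) with constant or missing expression", n_excluded))
  }
  idx <- which(keep)
  r <- vapply(idx, function(i) {
    pearson_r(expr[pairs$gene1[i], ], expr[pairs$gene2[i], ])
  }, 0)
  out <- pairs[idx, ] |>
    mutate(r = r,
           coexpressed = r > coexpr_threshold,
           distance = abs(g1$start[idx] - g2$start[idx]),
           mean_length = ((g1$end[idx] - g1$start[idx] + 1) +
                            (g2$end[idx] - g2$start[idx] + 1)) / 2)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Proportion of co-expressed pairs
#' @param records Tibble with logical `coexpressed`.
#' @return Proportion in \[0, 1\].
#' @export
coexpression_proportion <- function(records) {
  if (nrow(records) == 0) stopf("no pairs in group")
  mean(records$coexpressed)
}

#' Relative change between two proportions, as a signed percentage
#'
#' `(p_new / p_ref - 1) * 100`, rounded half-up to 2 decimals at the
#' reporting layer (inputs may be proportions or percentages, consistently).
#'
#' @param p_new,p_ref Proportions (or percentages on a common scale).
#' @return Signed percent change, 2 dp.
#' @export
relative_change <- function(p_new, p_ref) {
  if (any(p_ref == 0)) stopf("reference proportion is zero")
  round_half_up((p_new / p_ref - 1) * 100, 2)
}

#' Bin pair records by distance or mean length and summarise co-expression
#'
#' Left-closed binning: bin 0 is `[0, e1)`, bin 1 `[e1, e2)`, ..., last bin
#' `[e_k, Inf)`, so a value exactly on an edge falls in the upper bin (an
#' 8-kb pair is "medium", matching "< 8 kb" for the short group).
#'
#' @param records Pair-record tibble.
#' @param edges Strictly increasing bin edges (bp).
#' @param field `"distance"` or `"mean_length"`.
#' @param labels Bin labels; defaults to short/medium/long for two edges.
#' @param n_boot Bootstrap resamples for the proportion SE (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return A tibble of bin summaries: `label`, `n_pairs`, `n_coexpressed`,
#'   `proportion`, `bootstrap_se`.
#' @export
bin_pairs <- function(records, edges, field = c("distance", "mean_length"),
                      labels = NULL, n_boot = 1000, seed = 1) {
  field <- match.arg(field)
  if (any(diff(edges) <= 0)) stopf("`edges` must be strictly increasing")
  if (is.null(labels)) {
    labels <- if (length(edges) == 2) c("short", "medium", "long")
    else paste0("bin", seq_len(length(edges) + 1))
  }
  stopifnot(length(labels) == length(edges) + 1)
  x <- records[[field]]
  bin <- findInterval(x, edges)  # left-closed: x == edge goes up
  out <- tibble(label = factor(labels[bin + 1], levels = labels)) |>
    bind_cols(records["coexpressed"]) |>
    group_by(.data$label, .drop = FALSE) |>
    summarise(n_pairs = dplyr::n(), n_coexpressed = sum(.data$coexpressed),
              .groups = "drop") |>
    mutate(proportion = ifelse(.data$n_pairs > 0,
                               .data$n_coexpressed / .data$n_pairs, NA_real_))
  out$bootstrap_se <- NA_real_
  if (n_boot > 0) {
    flags <- split(records$coexpressed, factor(labels[bin + 1], levels = labels))
    out$bootstrap_se <- vapply(seq_len(nrow(out)), function(i) {
      f <- flags[[as.character(out$label[i])]]
      if (length(f) == 0) return(NA_real_)
      bootstrap_se(f, n_boot = n_boot, seed = seed + i)
    }, 0)
  }
  mutate(out, label = as.character(.data$label))
}

#' Co-expression summary of a combined filter group
#'
#' Applies arbitrary dplyr filter expressions (e.g. `distance < 8000,
#' mean_length > 9000`) and summarises the surviving pairs.
#'
#' @param records Pair-record tibble.
#' @param ... Filter expressions evaluated in the data.
#' @param label Group label.
#' @param n_boot,seed Bootstrap control for the SE.
#' @return One-row bin-summary tibble.
#' @export
combined_group <- function(records, ..., label = "combined", n_boot = 1000, seed = 1) {
  sub <- filter(records, ...)
  if (nrow(sub) == 0) stopf("no pairs in group")
  tibble(label = label,
         n_pairs = nrow(sub),
         n_coexpressed = sum(sub$coexpressed),
         proportion = mean(sub$coexpressed),
         bootstrap_se = if (n_boot > 0) bootstrap_se(sub$coexpressed, n_boot, seed) else NA_real_)
}

#' Randomization null for the co-expression proportion
#'
#' Each iteration draws `n_pairs` unordered pairs of distinct genes uniformly
#' from the expression matrix (redrawn every iteration), computes their
#' Pearson correlations across tissues and records the proportion exceeding
#' `threshold`. Genes with constant expression are excluded up front with a
#' message. The empirical p-value for an observed proportion uses add-one
#' smoothing: `(1 + #\{null >= observed\}) / (n_iter + 1)`.
#'
#' @param expr Genes x tissues TPM matrix.
#' @param n_pairs Pairs per iteration (matched to the observed SNG count).
#' @param n_iter Iterations (>= 100).
#' @param threshold Co-expression threshold on r.
#' @param seed Integer seed.
#' @param observed Optional observed proportion for which to report p.
#' @return List: `proportions` (length `n_iter`), `p_value` (or `NA`),
#'   `observed`.
#' @export
randomization_null <- function(expr, n_pairs, n_iter = 10000, threshold = 0.5,
                               seed = 1, observed = NULL) {
  if (n_pairs < 1) stopf("`n_pairs` must be >= 1")
  if (n_iter < 100) stopf("`n_iter` must be >= 100")
  keep <- apply(expr, 1, sd) > 0
  if (sum(!keep) > 0) message(sprintf("excluding %d constant gene(s) from the null", sum(!keep)))
  expr <- expr[keep, , drop = FALSE]
  n <- nrow(expr)
  if (n < 2) stopf("fewer than 2 usable genes")
  z <- expr - rowMeans(expr)
  z <- z / sqrt(rowSums(z^2))
  props <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      while (any(eq <- i == j)) j[eq] <- sample.int(n, sum(eq), replace = TRUE)
      r <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
      mean(r > threshold)
    }, 0)
  })
  p <- if (is.null(observed)) NA_real_ else (1 + sum(props >= observed)) / (n_iter + 1)
  list(proportions = props, p_value = p, observed = observed)
}

#' Bootstrap standard error of a proportion
#'
#' Resamples the binary flags with replacement `n_boot` times (each resample
#' the size of the original vector) and returns the standard deviation of
#' the resampled proportions; converges to `sqrt(p (1 - p) / n)`.
#'
#' @param flags Logical (or 0/1) vector.
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @return Standard error (>= 0).
#' @export
bootstrap_se <- function(flags, n_boot = 1000, seed = 1) {
  flags <- as.logical(flags)
  n <- length(flags)
  if (n == 0) stopf("empty flag vector")
  with_seed(seed, {
    props <- vapply(seq_len(n_boot), function(b) {
      mean(flags[sample.int(n, n, replace = TRUE)])
    }, 0)
    sd(props)
  })
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Returns the U statistic for the first sample and a two-sided p-value from
#' the tie-corrected normal approximation without continuity correction.
#' When every observation is tied the variance is zero and p = 1.
#'
#' @param a,b Numeric vectors.
#' @return List: `U` (for `a`), `p_value`, `z`.
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stopf("both samples must be non-empty")
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = u1, p_value = 1, z = 0))
  }
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  list(U = u1, p_value = min(1, 2 * pnorm(-abs(z))), z = z)
}

#' Cluster SNG expression profiles
#'
#' k-means on row-standardized profiles (each gene centred and scaled across
#' tissues) with many restarts under a fixed seed, so labels are
#' deterministic given the seed.
#'
#' @param expr Genes x tissues matrix (restricted to SNG genes upstream).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Tibble `gene_id`, `cluster` (integers 1..k).
#' @export
cluster_profiles <- function(expr, k = 4, seed = 1, nstart = 25) {
  keep <- apply(expr, 1, sd) > 0
  if (sum(!keep) > 0) message(sprintf("excluding %d constant gene(s) from clustering", sum(!keep)))
  z <- t(scale(t(expr[keep, , drop = FALSE])))
  cl <- with_seed(seed, kmeans(z, centers = k, nstart = nstart))
  tibble(gene_id = rownames(z), cluster = unname(cl$cluster))
}
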