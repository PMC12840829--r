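#' Assemble a balanced model dataset
#'
#' Positives are co-expressed pairs; an equal number of negatives is drawn
#' at random without replacement from the non-co-expressed pairs, then rows
#' are shuffled deterministically. Zero-variance features are dropped with a
#' warning.
#'
#' @param records Pair-record tibble with feature columns and `coexpressed`.
#' @param feature_set Character vector of feature column names.
#' @param seed Integer seed.
#' @param allow_downsample_positives If positives outnumber negatives,
#'   downsample positives instead of erroring.
#' @return List of class `sng_dataset`: `X` (raw feature matrix), `y` (0/1),
#'   `feature_set`, `rows` (the selected record rows).
#' @export
build_balanced_dataset <- function(records, feature_set, seed = 1,
                                   allow_downsample_positives = FALSE) {
  miss <- setdiff(feature_set, names(records))
  if (length(miss)) stopf("feature column(s) not found: %s", paste(miss, collapse = ", "))
  pos <- which(records$coexpressed)
  neg <- which(!records$coexpressed)
  if (length(pos) < 2 || length(neg) < 2) stopf("need at least 2 pairs in each class")
  with_seed(seed, {
    if (length(neg) >= length(pos)) {
      neg <- sample(neg, length(pos))
    } else if (allow_downsample_positives) {
      pos <- sample(pos, length(neg))
    } else {
      stopf("fewer negatives (%d) than positives (%d); set allow_downsample_positives",
            length(neg), length(pos))
    }
    idx <- sample(c(pos, neg))
    X <- as.matrix(records[idx, feature_set, drop = FALSE])
    keep <- apply(X, 2, function(v) sd(v) > 0)
    if (any(!keep)) {
      rlang::warn(sprintf("dropping zero-variance feature(s): %s",
                          paste(feature_set[!keep], collapse = ", ")))
      X <- X[, keep, drop = FALSE]
    }
    structure(list(X = X, y = as.integer(records$coexpressed[idx]),
                   feature_set = colnames(X), rows = idx),
              class = "sng_dataset")
  })
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the binomial log-likelihood of `y ~ X` (intercept added) by
#' IRLS; converged when the largest coefficient change drops below `tol`.
#' Perfect separation is detected from diverging coefficients/vanishing
#' curvature and reported via the `separation` flag, with the fit returned
#' at the iteration cap. Singular designs fall back to a tiny ridge penalty
#' with a warning.
#'
#' @param X Numeric feature matrix (no intercept column).
#' @param y 0/1 response.
#' @param tol Convergence tolerance on max |delta beta|.
#' @param max_iter Iteration cap.
#' @param ridge Ridge penalty added on fallback (default 1e-8).
#' @return Object of class `sng_logit`: `coefficients`, `se`, `converged`,
#'   `separation`, `iterations`, `loglik`, `feature_set`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100, ridge = 1e-8) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  converged <- FALSE
  used_ridge <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    H <- XtW %*% Xd
    rhs <- XtW %*% z
    new_beta <- tryCatch(drop(solve(H, rhs)), error = function(e) {
      used_ridge <<- TRUE
      drop(solve(H + diag(ridge, p), rhs))
    })
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; converged <- TRUE; break }
    beta <- new_beta
  }
  if (used_ridge) rlang::warn("singular information matrix; ridge fallback applied")
  eta <- drop(Xd %*% beta)
  mu <- plogis(eta)
  separation <- !converged && (max(abs(beta)) > 15 || all(abs(y - mu) < 1e-6))
  H <- t(Xd * pmax(mu * (1 - mu), 1e-10)) %*% Xd
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = setNames(beta, colnames(Xd)),
                 se = setNames(se, colnames(Xd)),
                 converged = converged, separation = separation,
                 iterations = it, loglik = loglik,
                 feature_set = colnames(X)),
            class = "sng_logit")
}

#' @export
print.sng_logit <- function(x, ...) {
  cat(sprintf("<sng_logit> %d coefficient(s), %sconverged in %d iteration(s)\n",
              length(x$coefficients), if (x$converged) "" else "NOT ", x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

predict_logit <- function(fit, X) {
  plogis(drop(cbind(1, as.matrix(X)[, fit$feature_set, drop = FALSE]) %*% fit$coefficients))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks, equal to the exhaustive
#' proportion of positive-negative pairs in which the positive scores
#' higher (ties counted 0.5).
#'
#' @param scores Predicted scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes in the test set")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated balanced train/test evaluation of a logistic model
#'
#' Each repeat draws a fresh balanced dataset (negatives resampled, unless
#' `refresh_negatives = FALSE` fixes them once), makes a stratified
#' train/test split (class balance preserved on both sides), z-scores
#' features on the training split only, fits by IRLS and scores the test
#' split by rank-based AUC. The mean AUC across repeats is the headline
#' metric; standardized coefficients and their SEs are averaged across
#' repeats for importance.
#'
#' @param records Pair-record tibble with features and `coexpressed`.
#' @param feature_set Feature column names.
#' @param n_repeats Number of repeats (default 50).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @param refresh_negatives Draw new negatives every repeat (default) or fix
#'   the balanced dataset once.
#' @param allow_downsample_positives Passed to [build_balanced_dataset()].
#' @return Object of class `sng_model_result`: `feature_set`,
#'   `auc_per_repeat`, `mean_auc`, `sd_auc`, `coefficients` (tibble of mean
#'   standardized estimate/SE per term), `importance` (tibble).
#' @export
repeated_auc <- function(records, feature_set, n_repeats = 50,
                         train_fraction = 0.8, seed = 1,
                         refresh_negatives = TRUE,
                         allow_downsample_positives = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1)) stopf("`train_fraction` must be in (0,1)")
  bal <- function(s) build_balanced_dataset(records, feature_set, s,
                                            allow_downsample_positives = allow_downsample_positives)
  fixed <- if (!refresh_negatives) bal(seed) else NULL
  aucs <- numeric(n_repeats)
  coefs <- list()
  for (rep_i in seq_len(n_repeats)) {
    ds <- fixed %||% bal(seed + rep_i)
    split <- with_seed(seed + 100000 + rep_i, {
      tr <- unlist(lapply(c(0, 1), function(cl) {
        idx <- which(ds$y == cl)
        sample(idx, round(train_fraction * length(idx)))
      }))
      list(train = sort(tr), test = setdiff(seq_along(ds$y), tr))
    })
    Xtr <- ds$X[split$train, , drop = FALSE]
    ctr <- colMeans(Xtr); str_ <- apply(Xtr, 2, sd)
    str_[str_ == 0] <- 1
    zs <- function(m) sweep(sweep(m, 2, ctr), 2, str_, "/")
    fit <- fit_logistic(zs(Xtr), ds$y[split$train])
    pred <- predict_logit(fit, zs(ds$X[split$test, , drop = FALSE]))
    aucs[rep_i] <- auc_rank(pred, ds$y[split$test])
    coefs[[rep_i]] <- tibble(term = names(fit$coefficients),
                             estimate = unname(fit$coefficients),
                             se = unname(fit$se))
  }
  co <- bind_rows(coefs) |>
    group_by(.data$term) |>
    summarise(estimate = mean(.data$estimate), se = mean(.data$se),
              .groups = "drop")
  imp <- co |>
    filter(.data$term != "(Intercept)") |>
    mutate(importance = abs(.data$estimate / .data$se)) |>
    arrange(dplyr::desc(.data$importance)) |>
    select(feature = "term", "importance")
  structure(list(feature_set = feature_set, auc_per_repeat = aucs,
                 mean_auc = mean(aucs), sd_auc = sd(aucs),
                 coefficients = co, importance = imp,
                 n_repeats = n_repeats),
            class = "sng_model_result")
}

#' @export
print.sng_model_result <- function(x, ...) {
  cat(sprintf("<sng_model_result> features: %s\n  mean AUC %.3f (sd %.3f) over %d repeats\n",
              paste(x$feature_set, collapse = ", "), x$mean_auc, x$sd_auc, x$n_repeats))
  invisible(x)
}

#' Variable importance from a combined model result
#'
#' Importance is `|standardized coefficient / SE|` averaged over repeats,
#' ranked descending; collinear duplicated features dilute each other's
#' score, which is reported as-is.
#'
#' @param result An `sng_model_result` from [repeated_auc()].
#' @return Tibble `feature`, `importance`, `rank`.
#' @export
variable_importance <- function(result) {
  stopifnot(inherits(result, "sng_model_result"))
  mutate(result$importance, rank = dplyr::row_number())
}

#' Predicted co-expression probability over a distance x feature grid
#'
#' Fits `y ~ distance + feature + distance:feature` on a balanced dataset
#' and evaluates predicted probabilities on a grid: distance at
#' `n_distance` quantiles crossed with the feature at low/mid/high tertile
#' representatives (or its observed levels when binary). A sign-flipping
#' interaction shows as a reversal of the feature-level ordering across the
#' distance grid.
#'
#' @param records Pair-record tibble.
#' @param feature Feature column name.
#' @param n_distance Number of distance quantiles.
#' @param seed Seed for the balanced dataset.
#' @param allow_downsample_positives Passed to [build_balanced_dataset()].
#' @return Tibble `distance`, `feature_value`, `level`, `prob`; the fitted
#'   `sng_logit` is attached as attribute `"fit"`.
#' @export
interaction_surface <- function(records, feature, n_distance = 5, seed = 1,
                                allow_downsample_positives = FALSE) {
  ds <- build_balanced_dataset(records, c("distance", feature), seed,
                               allow_downsample_positives = allow_downsample_positives)
  # fit on z-scores: the model space is identical to the raw-scale
  # interaction model (affine reparameterization) but well conditioned
  ctr <- colMeans(ds$X)
  scl <- apply(ds$X, 2, sd)
  scl[scl == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  Z <- zs(ds$X)
  X <- cbind(Z, interaction = Z[, "distance"] * Z[, feature])
  fit <- fit_logistic(X, ds$y)
  dgrid <- unname(quantile(records$distance, probs = seq(0, 1, length.out = n_distance)))
  fv <- records[[feature]]
  if (all(fv %in% c(0, 1))) {
    fgrid <- sort(unique(fv))
    lev <- c("0", "1")[seq_along(fgrid)]
  } else {
    fgrid <- unname(quantile(fv, probs = c(1, 3, 5) / 6))
    lev <- c("low", "mid", "high")
  }
  grid <- tidyr::expand_grid(distance = dgrid,
                             feature_value = fgrid) |>
    mutate(level = rep(lev, times = n_distance))
  Xg <- cbind(distance = grid$distance, grid$feature_value)
  colnames(Xg)[2] <- feature
  Zg <- zs(Xg)
  Xg <- cbind(Zg, interaction = Zg[, "distance"] * Zg[, feature])
  grid$prob <- predict_logit(fit, Xg)
  attr(grid, "fit") <- fit
  grid
}
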