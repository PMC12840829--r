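#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted logistic model
#'
#' @param x An `sng_logit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.sng_logit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @rdname tidy.sng_logit
#' @exportS3Method generics::glance
glance.sng_logit <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged,
         separation = x$separation, iterations = x$iterations,
         nterms = length(x$coefficients))
}

#' Tidy a repeated-AUC model result
#'
#' @param x An `sng_model_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per repeat (`repeat_id`, `auc`); `glance()`:
#'   one-row summary (`mean_auc`, `sd_auc`, `n_repeats`, `features`).
#' @exportS3Method generics::tidy
tidy.sng_model_result <- function(x, ...) {
  tibble(repeat_id = seq_along(x$auc_per_repeat), auc = x$auc_per_repeat)
}

#' @rdname tidy.sng_model_result
#' @exportS3Method generics::glance
glance.sng_model_result <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
         n_repeats = x$n_repeats,
         features = paste(x$feature_set, collapse = "+"))
}
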