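#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor sd median quantile rnorm runif rlnorm rpois rbinom
#'   pnorm pt plogis qlogis prcomp hclust cutree as.dist kmeans setNames
#'   complete.cases
NULL

# Round half away from zero at `digits` decimals; base round() is
# round-half-even, which disagrees with reported percentages at .5 ties.
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
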