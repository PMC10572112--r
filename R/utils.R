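#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile sd cor pnorm qnorm pt ptukey qbeta rlnorm rnorm
#'   runif median p.adjust kruskal.test setNames complete.cases
#' @importFrom utils head tail
NULL

# truncated normal via inverse-CDF; degenerate sd collapses to clamped mean
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# derive a stream of per-unit seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
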