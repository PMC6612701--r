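#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats approx approxfun lm coef predict pnorm rnorm sd t.test
#'   quantile residuals runif median
#' @importFrom utils head tail
NULL

# internal: fail with a classed condition so tests can target specific errors
stop_breathe4d <- function(msg, class = "breathe4d_error", ...) {
  rlang::abort(msg, class = c(class, "breathe4d_error"), ...)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_breathe4d(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_breathe4d(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_breathe4d(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

# run code under a fixed seed without disturbing the caller's RNG;
# seed = NULL leaves the RNG stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# error function via pnorm (erf(x) = 2*pnorm(x*sqrt(2)) - 1)
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
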