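#' @useDynLib gaitsignatures, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor cor.test dist lm coef fft median pnorm predict
#'   qnorm quantile rnorm runif sd setNames shapiro.test var wilcox.test
#'   residuals fitted cmdscale
#' @importFrom utils write.csv head
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small deterministic seed derived from components, kept within 32-bit range.
derive_seed <- function(...) {
  parts <- c(...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) * 104729) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi
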