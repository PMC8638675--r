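#' @keywords internal
"_PACKAGE"

#' Logit and inverse-logit
#'
#' Numerically safe logit/expit used throughout the package. `expit()`
#' saturates at the extremes rather than returning 0/1 exactly only for
#' infinite input.
#'
#' @param p Proportions in (0,1).
#' @param x Real values.
#' @return Numeric vector.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))

## Deterministic substream seeds: every module draws its randomness through
## a named substream of a single master seed so stages can be re-run
## independently and reproducibly. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

## split-Rhat (Gelman et al.): draws is iterations x chains
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x); nn <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

## crude effective sample size from lag autocorrelations (initial positive
## sequence), adequate as a mixing diagnostic
ess_basic <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_named <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}
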