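# internal numeric helpers

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a

# centered moving average; windows shrink one-sidedly at the record ends
moving_average <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k <= 1L) return(x)
  h <- k %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  ok <- !is.na(x)
  cs <- cumsum(c(0, ifelse(ok, x, 0)))
  cn <- cumsum(c(0L, as.integer(ok)))
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0L] <- NA_real_
  out
}

# Expected deflation of the per-window (divide-by-n) variance when the window
# mean of n AR(1)-correlated samples with lag-1 autocorrelation rho is
# subtracted: E[s^2] = sigma^2 * (1 - S/n^2), S = sum_{i,j} rho^|i-j|.
ar1_var_deflation <- function(rho, n) {
  n <- as.integer(n)
  if (n <= 1L) return(NA_real_)
  if (!is.finite(rho) || rho <= 0) return(1 - 1 / n)
  if (rho >= 1) return(0)
  k <- seq_len(n - 1L)
  S <- n + 2 * sum((n - k) * rho^k)
  max(1 - S / n^2, 0)
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}
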