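# Fractional Gaussian noise: the stationary increment process of
# fractional Brownian motion, parameterised by the Hurst exponent H.
# H = 0.5 is white noise; H > 0.5 gives long-term persistence with
# autocorrelations decaying as a power law.

#' Autocorrelation of fractional Gaussian noise
#'
#' `rho_l = 0.5 * (|l+1|^(2H) - 2|l|^(2H) + |l-1|^(2H))`, the exact lag-l
#' autocorrelation of fGn with Hurst exponent `H`. `rho_0 = 1` for any H;
#' at `H = 0.5` all lags beyond 0 are zero (white noise).
#'
#' @param l Integer lag(s), `l >= 0`. Vectorised.
#' @param H Hurst exponent in (0, 1).
#' @return Autocorrelation value(s).
#' @examples
#' fgn_autocorrelation(1, 0.7) # 0.5 * (2^1.4 - 2) = 0.31951...
#' @export
fgn_autocorrelation <- function(l, H) {
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)", call. = FALSE)
  if (any(l < 0)) stop("lag must be >= 0", call. = FALSE)
  0.5 * (abs(l + 1)^(2 * H) - 2 * abs(l)^(2 * H) + abs(l - 1)^(2 * H))
}

#' Simulate fractional Gaussian noise exactly
#'
#' Draws a stationary Gaussian sequence whose theoretical autocorrelation
#' is exactly [fgn_autocorrelation()] at every lag. The primary method is
#' circulant embedding (Davies-Harte): the autocovariance is embedded in a
#' circulant matrix diagonalised by the FFT; when every eigenvalue of the
#' embedding is non-negative the simulation is exact and O(n log n). If
#' the embedding fails (it can for small n), the generator falls back to a
#' Cholesky factorisation of the n x n correlation matrix, which is always
#' exact at O(n^3).
#'
#' @param n Length of the series, `n >= 2`.
#' @param H Hurst exponent in (0, 1).
#' @param sd Marginal standard deviation (degrees Celsius in the climate
#'   context).
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @return Numeric vector of length `n`, with attribute `method` set to
#'   `"circulant"` or `"cholesky"`.
#' @examples
#' x <- generate_fgn(1000, H = 0.8, sd = 1, seed = 1)
#' attr(x, "method")
#' @export
generate_fgn <- function(n, H, sd = 1, seed = NULL) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)", call. = FALSE)
  local_seed(seed)
  acov <- sd^2 * fgn_autocorrelation(0:(n - 1), H)
  # circulant embedding of size 2(n-1)
  circ <- c(acov, acov[(n - 1):2])
  ev <- Re(stats::fft(circ))
  if (all(ev >= -1e-9 * max(ev))) {
    ev[ev < 0] <- 0
    m <- length(circ)
    z <- stats::rnorm(m) + 1i * stats::rnorm(m)
    w <- stats::fft(sqrt(ev / (2 * m)) * z)
    x <- Re(w)[1:n] * sqrt(2)
    method <- "circulant"
  } else {
    C <- sd^2 * fgn_corr_matrix(n, H)
    L <- chol(C)
    x <- as.numeric(crossprod(L, stats::rnorm(n)))
    method <- "cholesky"
  }
  structure(x, method = method)
}

#' fGn correlation matrix for n time points
#' @param n Dimension.
#' @param H Hurst exponent in (0,1).
#' @return `n x n` Toeplitz correlation matrix.
#' @keywords internal
fgn_corr_matrix <- function(n, H) {
  r <- fgn_autocorrelation(0:(n - 1), H)
  stats::toeplitz(r)
}

# Seed a block of code reproducibly without clobbering the caller's RNG.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  withr::local_seed(seed, .local_envir = env)
  invisible()
}
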