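#' Exact simulation of fractional Gaussian noise
#'
#' Generates a stationary, unit-variance fractional Gaussian noise (fGn)
#' realization by circulant embedding of the exact autocovariance
#' \eqn{\gamma(h) = \tfrac12(|h+1|^{2H} - 2|h|^{2H} + |h-1|^{2H})}
#' (Davies--Harte / Dietrich--Newsam).  Because the embedding is exact, the
#' theoretical autocovariance holds for the output; in particular the lag-1
#' autocorrelation is \eqn{2^{2H-1} - 1}.
#'
#' The embedding length is rounded up to the next 5-smooth integer (factors
#' 2, 3, 5 only) so the FFT stays fast for recording-scale \code{n}; the
#' eigenvalue vector is memoised per \code{(hurst, n)}.
#'
#' @param hurst Hurst exponent, in (0, 1).
#' @param n_samples Number of samples (>= 2).
#' @param seed Optional integer seed.  The caller's RNG state is restored on
#'   exit; the same \code{(hurst, n_samples, seed)} always returns the same
#'   vector.
#' @return Numeric vector of length \code{n_samples}.
#' @examples
#' x <- generate_fgn(0.8, 1000, seed = 1)
#' cor(x[-1], x[-1000])  # close to 2^(2*0.8-1) - 1 = 0.516
#' @seealso [generate_fbm()] for the integrated (motion) process whose
#'   Higuchi dimension is \eqn{2 - H}.
#' @export
generate_fgn <- function(hurst, n_samples, seed = NULL) {
  check_hurst(hurst)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop_param("n_samples must be a single integer >= 2, got %s",
               format(n_samples))
  n <- as.integer(n_samples)
  emb <- fgn_embedding(hurst, n)
  with_seed(seed, {
    z <- rnorm(emb$m)
    .fgn_from_normals(emb$ev, z, n)
  })
}

#' Fractional Brownian motion with known fractal dimension
#'
#' Cumulative sum of exact fractional Gaussian noise, standardized to zero
#' mean and unit sample variance.  The graph of fractional Brownian motion
#' has fractal dimension \eqn{2 - H}, which makes this the ground-truth
#' signal for validating Higuchi dimension estimators: low \code{hurst}
#' gives rough, complex traces (dimension near 2), high \code{hurst} smooth
#' ones (dimension near 1).  Note the distinction from the increment process
#' returned by [generate_fgn()], whose Higuchi dimension is close to 2 for
#' every \code{hurst}.
#'
#' @inheritParams generate_fgn
#' @param standardize Scale to zero mean, unit variance (default TRUE).
#' @return Numeric vector of length \code{n_samples}.
#' @export
generate_fbm <- function(hurst, n_samples, seed = NULL, standardize = TRUE) {
  x <- cumsum(generate_fgn(hurst, n_samples, seed))
  if (standardize) {
    s <- sd(x)
    if (s == 0) stop_param("degenerate fBm realization with zero variance")
    x <- (x - mean(x)) / s
  }
  x
}

check_hurst <- function(hurst) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_param("hurst must be a finite number in (0, 1), got %s",
               format(hurst))
  invisible(hurst)
}

# smallest integer >= n whose prime factors are all in {2, 3, 5}
next_fast_len <- function(n) {
  m <- as.integer(n)
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

.fgn_cache <- new.env(parent = emptyenv())

# circulant eigenvalues of the embedded fGn covariance, memoised
fgn_embedding <- function(hurst, n) {
  key <- sprintf("%.17g_%d", hurst, n)
  hit <- .fgn_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- next_fast_len(max(2L * (n - 1L), 4L))
  h2 <- 2 * hurst
  k <- 0:(m / 2)
  g <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  cvec <- c(g, rev(g[2:(m / 2)]))
  ev <- Re(fft(cvec))
  if (min(ev) < -1e-8 * max(ev))
    stop_param("circulant embedding not nonnegative definite (hurst = %g)",
               hurst)
  out <- list(ev = pmax(ev, 0), m = m)
  .fgn_cache[[key]] <- out
  out
}
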