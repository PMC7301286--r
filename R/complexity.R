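#' Higuchi normalized curve length for one delay and offset
#'
#' For a series \eqn{X(1..N)}, delay \code{k} and start offset
#' \code{m_offset} (1-based, \code{1 <= m_offset <= k}), the normalized
#' length of the decimated curve is
#' \deqn{L_m(k) = \Big[\sum_{i=1}^{\lfloor (N-m)/k \rfloor}
#'   |X(m+ik) - X(m+(i-1)k)|\Big]
#'   \cdot \frac{N-1}{\lfloor (N-m)/k \rfloor \, k} \cdot \frac1k .}
#' The flooring and the \eqn{(N-1)/(\lfloor (N-m)/k\rfloor k)} normalization
#' follow Higuchi's original definition exactly.
#'
#' @param x Numeric signal.
#' @param k Delay (>= 1).
#' @param m_offset Start offset, \code{1..k}.
#' @return Non-negative curve length.
#' @export
higuchi_curve_length <- function(x, k, m_offset) {
  N <- length(x)
  if (m_offset < 1 || m_offset > k)
    stop_param("m_offset must lie in 1..k")
  nmax <- floor((N - m_offset) / k)
  if (nmax < 1)
    stop_param("subsequence too short: N = %d, k = %d, m_offset = %d",
               N, k, m_offset)
  idx <- m_offset + (0:nmax) * k
  sum(abs(diff(x[idx]))) * (N - 1) / (nmax * k) / k
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a waveform's graph from the scaling
#' of mean curve lengths \eqn{L(k)} with delay \eqn{k}: the estimate is the
#' ordinary least-squares slope of \eqn{\ln L(k)} on \eqn{\ln(1/k)} over
#' \eqn{k = 1..k_{max}} (natural logs, unweighted), where \eqn{L(k)}
#' averages [higuchi_curve_length()] over the \eqn{k} start offsets.
#' Waveform dimensions lie between 1 (smooth) and 2 (plane-filling); a unit
#' ramp gives exactly 1 (its curve lengths are \eqn{L(k) = (N-1)/k}), and
#' fractional Brownian motion with Hurst exponent \eqn{H} gives
#' \eqn{2 - H}.
#'
#' @param x Numeric signal, length \code{> 2 * k_max}.
#' @param k_max Largest delay in the regression (default 8).
#' @return A \code{complexity_value}: list with \code{measure = "HFD"},
#'   \code{value}, and \code{defined} (FALSE for degenerate input such as a
#'   constant signal, where every curve length vanishes).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  if (k_max < 2) stop_param("k_max must be >= 2")
  N <- length(x)
  if (N <= 2 * k_max)
    stop_param("signal too short (N = %d) for k_max = %d", N, k_max)
  L <- .higuchi_lengths_cpp(x, as.integer(k_max))
  if (any(L == 0))
    return(complexity_value("HFD", NA_real_, FALSE))
  lk <- log(1 / seq_len(k_max))
  ll <- log(L)
  slope <- sum((lk - mean(lk)) * (ll - mean(ll))) / sum((lk - mean(lk))^2)
  complexity_value("HFD", slope, TRUE)
}

#' Sample-entropy template-match counts
#'
#' Counts, over the \eqn{N - m} template start positions, the unordered
#' pairs \eqn{i < j} whose length-\code{m} templates match within tolerance
#' \code{r_absolute} under the Chebyshev (maximum) norm (\code{B}), and
#' those still matching when extended to length \code{m + 1} (\code{A}).
#' Self-matches are excluded by \eqn{i < j}; the match condition is
#' \code{<= r} (closed), which keeps the constant-signal case well defined
#' at \code{r = 0}.
#'
#' The compiled kernel sorts template heads and sweeps a window over the
#' first coordinate; it returns exactly the counts of the naive
#' \eqn{O(N^2)} enumeration.
#'
#' @param x Numeric signal, length \code{> m + 1}.
#' @param m Template length (>= 1).
#' @param r_absolute Absolute tolerance (>= 0).
#' @return Named numeric vector \code{c(A =, B =)}.
#' @export
sampen_counts <- function(x, m = 2L, r_absolute) {
  if (m < 1) stop_param("m must be >= 1")
  if (r_absolute < 0) stop_param("r_absolute must be >= 0")
  if (length(x) <= m + 1)
    stop_param("signal too short (N = %d) for m = %d", length(x), m)
  ct <- .sampen_counts_cpp(x, as.integer(m), r_absolute)
  c(A = ct[1], B = ct[2])
}

#' Sample entropy
#'
#' \eqn{SampEn = -\ln(A/B)} with \code{A}, \code{B} from
#' [sampen_counts()] and tolerance \code{r = r_factor * SD(x)}, where SD is
#' the uncorrected (population) standard deviation of the epoch.  Higher
#' values mean a less regular, less predictable signal.  When no template
#' pair matches (\code{A = 0} or \code{B = 0}) the statistic is undefined
#' and flagged rather than replaced by a number; a constant signal yields
#' \code{A = B} and SampEn 0.
#'
#' @param x Numeric signal.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a multiple of the signal SD (default 0.15).
#' @return A \code{complexity_value} with \code{measure = "SampEn"}.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.15) {
  if (r_factor <= 0) stop_param("r_factor must be positive")
  sd_pop <- sqrt(mean((x - mean(x))^2))
  ct <- sampen_counts(x, m, r_factor * sd_pop)
  if (ct[["A"]] == 0 || ct[["B"]] == 0)
    return(complexity_value("SampEn", NA_real_, FALSE))
  complexity_value("SampEn", -log(ct[["A"]] / ct[["B"]]), TRUE)
}

complexity_value <- function(measure, value, defined) {
  structure(list(measure = measure, value = value, defined = defined),
            class = "complexity_value")
}

#' @export
print.complexity_value <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$measure,
              if (x$defined) format(x$value) else "undefined"))
  invisible(x)
}

#' Complexity features for a set of epochs
#'
#' Computes Higuchi dimension and sample entropy for every epoch and
#' returns them as long-format rows ready for the statistics stage.
#' Undefined sample-entropy epochs keep \code{defined = FALSE} and an
#' \code{NA} value; downstream statistics exclude them listwise.
#'
#' @param epochs List of \code{eeg_epoch} objects.
#' @param k_max Higuchi delay bound (default 8).
#' @param m,r_factor Sample-entropy parameters (defaults 2 and 0.15).
#' @return A data.frame with columns \code{subject}, \code{group},
#'   \code{channel}, \code{epoch}, \code{measure} ("HFD" or "SampEn"),
#'   \code{value}, \code{defined}: two rows per epoch.
#' @export
features_for_epochs <- function(epochs, k_max = 8L, m = 2L,
                                r_factor = 0.15) {
  if (length(epochs) == 0) return(empty_feature_table())
  rows <- lapply(epochs, function(e) {
    hfd <- higuchi_fd(e$samples, k_max)
    se <- sample_entropy(e$samples, m, r_factor)
    data.frame(subject = e$subject_id, group = e$group,
               channel = e$channel_label, epoch = e$epoch_index,
               measure = c("HFD", "SampEn"),
               value = c(hfd$value, se$value),
               defined = c(hfd$defined, se$defined),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_feature_table <- function() {
  data.frame(subject = character(), group = character(),
             channel = character(), epoch = integer(),
             measure = character(), value = numeric(),
             defined = logical(), stringsAsFactors = FALSE)
}
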