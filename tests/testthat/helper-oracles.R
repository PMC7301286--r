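# Independent oracles used across the suite.  These deliberately take the
# slow, direct route (full pairwise matrices, literal formula sums) so they
# share no code path with the package implementations they check.

# Exhaustive O(N^2) sample-entropy match counts via full Chebyshev distance
# matrices over all template pairs.
sampen_counts_brute <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  emb <- sapply(0:m, function(k) x[(1:nt) + k])  # nt x (m+1)
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = nt)
  D <- matrix(0, nt, nt)
  for (k in 1:m) D <- pmax(D, abs(outer(emb[, k], emb[, k], "-")))
  B <- (sum(D <= r) - nt) / 2
  D1 <- pmax(D, abs(outer(emb[, m + 1], emb[, m + 1], "-")))
  A <- (sum(D1 <= r) - nt) / 2
  c(A = A, B = B)
}

# Literal evaluation of the Higuchi curve-length formula with an explicit
# loop over the decimated subsequence.
higuchi_length_brute <- function(x, k, m) {
  N <- length(x)
  nmax <- floor((N - m) / k)
  s <- 0
  for (i in 1:nmax) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
  s * (N - 1) / (nmax * k) / k
}

# One-way ANOVA from raw sums of squares.
anova_brute <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Evaluate expr under a local seed without touching the global stream.
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Small epoch factory for preprocessing/feature tests.
make_epoch <- function(samples, subject = "S01", group = "C",
                       channel = "Cz", index = 0L, fs = 1000) {
  structure(list(subject_id = subject, group = group,
                 channel_label = channel, epoch_index = index,
                 samples = samples, fs = fs),
            class = "eeg_epoch")
}

# Small two-group cohort for fast end-to-end style tests.
tiny_cohort_config <- function(seed = 1L, hursts = c(C = 0.9, R = 0.6),
                               n_subjects = 3L, duration_s = 4,
                               alpha_amp = 0) {
  groups <- lapply(hursts, function(h)
    list(n_subjects = n_subjects,
         params = signal_model_params(hurst = h, alpha_amp = alpha_amp,
                                      fs = 1000, duration_s = duration_s)))
  cohort_config(groups = groups, seed = seed)
}
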