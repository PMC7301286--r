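test_that("Higuchi curve length matches hand-computed and brute values", {
  ramp <- as.numeric(1:100)
  # unit-step ramp: L_m(k) = (N-1)/k
  expect_equal(higuchi_curve_length(ramp, 2, 1), 49.5)
  expect_equal(higuchi_curve_length(ramp, 2, 2), 49.5)
  expect_equal(higuchi_curve_length(rep(3.7, 50), 4, 2), 0)

  alt <- rep(c(1, -1), 30)
  expect_equal(higuchi_curve_length(alt, 1, 1),
               higuchi_length_brute(alt, 1, 1))
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(50:200, 1))
    k <- sample(1:8, 1)
    m <- sample(1:k, 1)
    expect_equal(higuchi_curve_length(x, k, m),
                 higuchi_length_brute(x, k, m), tolerance = 1e-12)
  }
  expect_error(higuchi_curve_length(rnorm(5), 8, 1), "too short")
})

test_that("Higuchi dimension: ramp exactly 1, noise near 2, fBm at 2 - H", {
  expect_equal(higuchi_fd(as.numeric(1:1000))$value, 1, tolerance = 1e-6)

  wn <- mean(vapply(1:20, function(s)
    with_seed_local(s, higuchi_fd(rnorm(5000))$value), numeric(1)))
  expect_lt(abs(wn - 2), 0.05)

  f07 <- mean(vapply(1:20, function(s)
    higuchi_fd(generate_fbm(0.7, 5000, seed = s))$value, numeric(1)))
  expect_lt(abs(f07 - 1.3), 0.1)
})

test_that("Higuchi dimension flags constant signals as undefined", {
  r <- higuchi_fd(rep(2, 1000))
  expect_false(r$defined)
  expect_true(is.na(r$value))
})

test_that("sample-entropy counts match hand enumerations", {
  expect_identical(unname(sampen_counts(c(0, 1, 0, 2, 0, 1, 0, 2),
                                        m = 1, r_absolute = 0.5)),
                   c(3, 7))
  expect_identical(unname(sampen_counts(c(1, 2, 1, 2, 1, 2, 1, 2),
                                        m = 2, r_absolute = 0.5)),
                   c(6, 6))
  # constant series: all templates identical under <= r at r = 0
  N <- 30; m <- 2
  ct <- sampen_counts(rep(1, N), m = m, r_absolute = 0)
  expect_identical(unname(ct), rep(choose(N - m, 2), 2))
})

test_that("optimized counts equal exhaustive enumeration on random signals", {
  set.seed(321)
  for (i in 1:100) {
    N <- sample(20:300, 1)
    m <- sample(1:3, 1)
    # mix rough and smooth signals so match densities vary widely
    x <- if (i %% 3 == 0) cumsum(rnorm(N)) else rnorm(N)
    if (i %% 5 == 0) x <- round(x, 1)  # ties stress the <= r boundary
    r <- runif(1, 0.05, 0.5) * sd(x)
    expect_identical(unname(sampen_counts(x, m, r)),
                     unname(sampen_counts_brute(x, m, r)))
  }
})

test_that("sample entropy reproduces hand values and degenerate cases", {
  x <- c(0, 1, 0, 2, 0, 1, 0, 2)
  ct <- sampen_counts(x, 1, 0.5)
  expect_equal(-log(ct[["A"]] / ct[["B"]]), log(7 / 3))
  expect_equal(sample_entropy(rep(5, 100))$value, 0)
  # too little data for any match at m+1
  r <- sample_entropy(c(0, 10, -10, 20, -20, 5), m = 2, r_factor = 0.01)
  expect_false(r$defined)
})

test_that("sample entropy of iid Gaussian matches the analytic limit", {
  # for iid data the conditional match probability is P(|X-Y| <= r) with
  # X - Y ~ N(0, 2 sigma^2): SampEn -> -ln(2 Phi(r/(sigma sqrt(2))) - 1)
  analytic <- -log(2 * pnorm(0.15 / sqrt(2)) - 1)
  vals <- vapply(1:20, function(s)
    with_seed_local(s, sample_entropy(rnorm(5000))$value), numeric(1))
  expect_lt(abs(mean(vals) - analytic), 0.15)
})

test_that("sample entropy is scale and offset invariant; HFD offset invariant", {
  set.seed(77)
  x <- rnorm(400)
  s0 <- sample_entropy(x)$value
  expect_equal(sample_entropy(3.7 * x)$value, s0)
  expect_equal(sample_entropy(x + 100)$value, s0)
  h0 <- higuchi_fd(x)$value
  expect_equal(higuchi_fd(x + 100)$value, h0, tolerance = 1e-9)
})

test_that("complexity monotonicity: rougher fBm raises both measures", {
  hs <- c(0.8, 0.5, 0.3)  # decreasing H = increasing complexity
  mh <- ms <- numeric(3)
  for (j in seq_along(hs)) {
    fd <- se <- numeric(10)
    for (s in 1:10) {
      x <- generate_fbm(hs[j], 5000, seed = 900 + 31 * s)
      fd[s] <- higuchi_fd(x)$value
      se[s] <- sample_entropy(x)$value
    }
    mh[j] <- mean(fd); ms[j] <- mean(se)
  }
  expect_true(all(diff(mh) > 0))
  expect_true(all(diff(ms) > 0))
})

test_that("feature extraction emits two rows per epoch with provenance", {
  eps <- list(make_epoch(rnorm(300), channel = "Cz", index = 0L),
              make_epoch(rnorm(300), channel = "Pz", index = 1L))
  ft <- features_for_epochs(eps)
  expect_identical(nrow(ft), 4L)
  expect_identical(sort(unique(ft$measure)), c("HFD", "SampEn"))
  expect_identical(ft$channel[1:2], c("Cz", "Cz"))
  expect_true(all(ft$defined))
  expect_identical(nrow(features_for_epochs(list())), 0L)
})

test_that("one sample-entropy evaluation at N = 5000 is fast", {
  x <- with_seed_local(1, rnorm(5000))
  elapsed <- system.time(sample_entropy(x))["elapsed"]
  expect_lt(unname(elapsed), 2)
})
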