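test_that("log10 normalization transforms and rejects non-positive rows", {
  expect_equal(log10_normalize(1.064), 0.02694, tolerance = 1e-4)
  expect_identical(log10_normalize(1), 0)
  expect_equal(log10_normalize(0.2066), -0.6849, tolerance = 1e-4)
  expect_error(log10_normalize(c(1, 2, 0, 4)), "row\\(s\\): 3")
  expect_error(log10_normalize(c(1, -2)), "positive")
})

test_that("KS normality check covers fixed-reference and estimated modes", {
  expect_error(ks_normality(5), "zero-variance")
  expect_error(ks_normality(rep(2, 10)), "zero-variance")
  # single observation at the reference mean: D = |1 - Phi(0)| = 0.5
  expect_equal(ks_normality(0, mean = 0, sd = 1)$D, 0.5)
  d <- vapply(1:5, function(s)
    with_seed_local(s, ks_normality(rnorm(10000))$D), numeric(1))
  expect_true(all(d < 0.02))
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- one_way_anova(g)
  expect_equal(a$F, 3)
  expect_identical(c(a$df_between, a$df_within), c(2L, 6L))

  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    gr <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1),
                                               mean = runif(1, -1, 1)))
    mine <- one_way_anova(gr)
    ref <- anova_brute(gr)
    expect_equal(mine$F, ref$F, tolerance = 1e-10)
    expect_equal(mine$p, ref$p, tolerance = 1e-10)
    expect_identical(mine$df_between, as.integer(ref$df_between))
    expect_identical(mine$df_within, as.integer(ref$df_within))
  }
})

test_that("ANOVA degenerate and error cases behave", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), c(3))), ">= 2 values")
  sep <- one_way_anova(list(rnorm(20), rnorm(20) + 1000))
  expect_lt(sep$p, 1e-20)
})

test_that("Bonferroni post hoc multiplies by C(g,2) and caps at 1", {
  set.seed(5)
  g <- list(a = rnorm(8), b = rnorm(8) + 0.5, c = rnorm(8) + 1)
  ph <- bonferroni_posthoc(g, alpha = 0.05)
  expect_identical(nrow(ph), 3L)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_adjusted <= 1))
  # mean_difference sign convention: group2 minus group1
  expect_equal(ph$mean_difference[ph$group1 == "a" & ph$group2 == "c"],
               mean(g$c) - mean(g$a))
})

test_that("family-wise error of the corrected pairwise family stays below alpha", {
  set.seed(2026)
  alpha <- 0.05
  n_rep <- 1000
  hits <- 0
  for (i in seq_len(n_rep)) {
    g <- list(rnorm(20), rnorm(11), rnorm(11))  # true null
    ph <- bonferroni_posthoc(g, labels = c("C", "E", "R"), alpha = alpha)
    if (any(ph$significant)) hits <- hits + 1
  }
  expect_lte(hits / n_rep, alpha)
})

test_that("per-electrode ANOVA keys results by channel and flags full separation", {
  set.seed(31)
  mkft <- function(ch, shift) {
    data.frame(subject = rep(sprintf("S%02d", 1:12), each = 3),
               group = rep(c("C", "E", "R"), each = 12),
               channel = ch, epoch = rep(0:2, 12), measure = "HFD",
               value = rnorm(36, mean = rep(c(0, shift, 2 * shift),
                                            each = 12), sd = 0.1),
               defined = TRUE, stringsAsFactors = FALSE)
  }
  ft <- rbind(mkft("Cz", 1), mkft("Pz", 0))
  res <- per_electrode_anova(ft, "HFD")
  expect_identical(res$anova$channel, c("Cz", "Pz"))
  expect_identical(res$fully_significant_channels, "Cz")
  expect_identical(nrow(res$posthoc), 6L)
  single <- per_electrode_anova(mkft("Fz", 1), "HFD")
  expect_identical(nrow(single$anova), 1L)
  # missing cells are reported
  expect_error(per_electrode_anova(ft[ft$group != "R" | ft$channel != "Pz", ],
                                   "HFD"), "Pz/R")
})

test_that("ensemble ANOVA supports raw and electrode-averaged units", {
  # 42 subjects (20/11/11) x 3 epochs x 19 channels
  set.seed(58)
  subj <- sprintf("S%02d", 1:42)
  grp <- rep(c("C", "E", "R"), c(20, 11, 11))
  ft <- expand.grid(subject = subj, epoch = 0:2,
                    channel = MONTAGE_10_20, stringsAsFactors = FALSE)
  ft$group <- grp[match(ft$subject, subj)]
  ft$measure <- "HFD"
  ft$value <- rnorm(nrow(ft), mean = c(C = 1.1, E = 1.2, R = 1.3)[ft$group],
                    sd = 0.05)
  ft$defined <- TRUE

  raw <- ensemble_anova(ft, "HFD", aggregate = "none")
  expect_identical(raw$n_units, 42L * 3L * 19L)
  expect_identical(c(raw$anova$df_between, raw$anova$df_within),
                   c(2L, 2394L - 3L))

  agg <- ensemble_anova(ft, "HFD", aggregate = "electrodes")
  expect_identical(agg$n_units, 126L)
  # channel-averaged ensemble gives the (2, 123) design
  expect_identical(c(agg$anova$df_between, agg$anova$df_within), c(2L, 123L))
  expect_true(all(agg$posthoc$significant))
  expect_equal(sort(names(agg$group_means)), c("C", "E", "R"))
})

test_that("PCA recovers structure, ratio bounds and reconstruction", {
  # rank-1 data in 5-D: one component explains everything
  set.seed(9)
  dir5 <- rnorm(5)
  x1 <- outer(rnorm(40), dir5)
  p1 <- suppressWarnings(pca_top3(x1))
  expect_equal(p1$explained_variance_ratio, 1, tolerance = 1e-10)
  expect_true(p1$rank_deficient)

  # isotropic 10-D Gaussian: top-3 ratio about 3/10
  xi <- with_seed_local(4, matrix(rnorm(10000 * 10), ncol = 10))
  pi3 <- pca_top3(xi)
  expect_lt(abs(pi3$explained_variance_ratio - 0.3), 0.02)
  expect_false(pi3$rank_deficient)
  # component variances non-increasing, loadings orthonormal
  expect_true(all(diff(pi3$sdev) <= 1e-12))
  expect_equal(crossprod(pi3$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # keeping all components reconstructs the centered data
  xs <- matrix(rnorm(50 * 4), ncol = 4)
  pa <- pca_top3(xs, n_components = 4L)
  centered <- sweep(xs, 2, colMeans(xs))
  expect_equal(pa$scores %*% t(pa$loadings), centered, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("explained variance ratio is invariant to reordering and shifts", {
  x <- with_seed_local(6, matrix(rnorm(60 * 6), ncol = 6))
  r0 <- pca_top3(x)$explained_variance_ratio
  expect_equal(pca_top3(x[, c(4, 1, 6, 2, 5, 3)])$explained_variance_ratio,
               r0, tolerance = 1e-12)
  x2 <- x; x2[, 3] <- x2[, 3] + 1000
  expect_equal(pca_top3(x2)$explained_variance_ratio, r0,
               tolerance = 1e-9)
})

test_that("scatter ratio separates split groups and not null groups", {
  set.seed(44)
  s_far <- rbind(matrix(rnorm(60, 0), ncol = 2),
                 matrix(rnorm(60, 10), ncol = 2))
  g <- rep(c("a", "b"), each = 30)
  expect_gt(group_scatter_ratio(s_far, g), 1)
  s_null <- matrix(rnorm(120), ncol = 2)
  expect_lt(group_scatter_ratio(s_null, g), 5)
})

test_that("feature matrix reshapes long rows and drops incomplete cases", {
  ft <- rbind(
    data.frame(subject = "S1", group = "C", channel = c("Cz", "Pz"),
               epoch = 0L, measure = "HFD", value = c(1.1, 1.2),
               defined = TRUE),
    data.frame(subject = "S1", group = "C", channel = c("Cz", "Pz"),
               epoch = 0L, measure = "SampEn", value = c(0.2, 0.3),
               defined = TRUE),
    data.frame(subject = "S2", group = "R", channel = c("Cz", "Pz"),
               epoch = 0L, measure = "HFD", value = c(1.4, 1.5),
               defined = TRUE),
    data.frame(subject = "S2", group = "R", channel = c("Cz", "Pz"),
               epoch = 0L, measure = "SampEn", value = c(NA, 0.5),
               defined = c(FALSE, TRUE)))
  fm <- feature_matrix(ft)
  expect_identical(dim(fm$matrix), c(1L, 4L))  # S2 dropped (undefined cell)
  expect_identical(fm$groups, "C")
  expect_identical(fm$dropped, 1L)
})
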