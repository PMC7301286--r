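test_that("signal model parameters are validated", {
  expect_error(signal_model_params(hurst = 1.2), "hurst")
  expect_error(signal_model_params(0.7, alpha_freq = 600, fs = 1000),
               "twice alpha_freq")
  expect_error(signal_model_params(0.7, fs = 1000, duration_s = 0.0005),
               "integer sample count")
  p <- signal_model_params(0.7, fs = 500, duration_s = 2)
  expect_identical(p$n_samples, 1000L)
})

test_that("synthesized channels honor the degenerate mixtures", {
  p_noise <- signal_model_params(0.7, alpha_amp = 0, fs = 1000,
                                 duration_s = 5)
  x <- synthesize_channel(p_noise, seed = 1)
  expect_equal(var(x), 1, tolerance = 0.1)

  p_sine <- signal_model_params(0.7, alpha_amp = 1, noise_scale = 0,
                                alpha_freq = 10, fs = 1000, duration_s = 5)
  y <- synthesize_channel(p_sine, seed = 1)
  sp <- welch_psd(y, 1000)
  expect_equal(sp$freq[which.max(sp$psd)], 10)
  expect_equal(max(abs(y)), 1, tolerance = 1e-6)
})

test_that("channel Hurst maps monotonically to epoch Higuchi dimension", {
  mean_fd <- function(h) {
    p <- signal_model_params(h, alpha_amp = 0, fs = 1000, duration_s = 5)
    mean(vapply(1:10, function(s)
      higuchi_fd(synthesize_channel(p, seed = 50 + s))$value, numeric(1)))
  }
  expect_gt(mean_fd(0.3), mean_fd(0.9))
})

test_that("cohort configuration is validated", {
  p <- signal_model_params(0.7, fs = 1000, duration_s = 2)
  expect_error(cohort_config(list()), "at least one group")
  expect_error(cohort_config(list(list(n_subjects = 2, params = p))),
               "named list")
  p2 <- signal_model_params(0.7, fs = 500, duration_s = 2)
  expect_error(cohort_config(list(A = list(n_subjects = 2, params = p),
                                  B = list(n_subjects = 2, params = p2))),
               "share fs")
  expect_error(cohort_config(list(A = list(n_subjects = 2, params = p)),
                             n_channels = 25),
               "distinct names")
})

test_that("cohorts have the configured shape, labels and determinism", {
  cfg <- tiny_cohort_config(seed = 7)
  coh <- generate_cohort(cfg)
  expect_length(coh, 6)
  expect_identical(vapply(coh, function(r) r$group, ""),
                   rep(c("C", "R"), each = 3))
  expect_identical(coh[[1]]$subject_id, "C01")
  expect_identical(coh[[4]]$subject_id, "R01")
  for (r in coh) {
    expect_identical(dim(r$data), c(19L, 4000L))
    expect_identical(r$channel_labels, MONTAGE_10_20)
    expect_true(all(is.finite(r$data)))
  }
  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)
  # different master seed changes the data
  coh3 <- generate_cohort(tiny_cohort_config(seed = 8))
  expect_false(identical(coh[[1]]$data, coh3[[1]]$data))
})

test_that("channels within and across subjects are independently seeded", {
  cfg <- tiny_cohort_config(seed = 3)
  rec1 <- generate_recording(cfg, 1)
  rec2 <- generate_recording(cfg, 2)
  expect_false(identical(rec1$data[1, ], rec1$data[2, ]))
  expect_false(identical(rec1$data[1, ], rec2$data[1, ]))
  # per-subject generation is consistent with whole-cohort generation
  expect_identical(generate_cohort(cfg)[[2]], rec2)
})

test_that("study-scale default cohort is 20/11/11 subjects at 180 s, 1 kHz", {
  cfg <- default_cohort_config(seed = 1)
  sizes <- vapply(cfg$groups, function(g) g$n_subjects, numeric(1))
  expect_identical(unname(sizes), c(20, 11, 11))
  expect_identical(names(cfg$groups), c("C", "E", "R"))
  expect_identical(cfg$fs, 1000)
  expect_identical(cfg$duration_s, 180)
  hs <- vapply(cfg$groups, function(g) g$params$hurst, numeric(1))
  expect_true(all(diff(hs) < 0))  # complexity ordering C < E < R via H
})
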