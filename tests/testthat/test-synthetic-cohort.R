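test_that("subject signatures are SPD unit-diagonal and scale with strength", {
  expect_equal(generate_subject_signature(8, 0, seed = 1)$target_correlation,
               diag(8))
  mean_offdiag <- function(strength) {
    cs <- lapply(1:10, function(k)
      generate_subject_signature(12, strength, seed = k)$target_correlation)
    mean(vapply(cs, function(c_mat) mean(abs(vectorize_upper(c_mat))),
                numeric(1)))
  }
  m <- vapply(c(0.2, 0.5, 0.9), mean_offdiag, numeric(1))
  expect_true(all(diff(m) > 0))
  for (k in 1:5) {
    c_mat <- generate_subject_signature(10, 0.7, seed = k)$target_correlation
    expect_gt(min(eigen(c_mat, symmetric = TRUE)$values), 0)
    expect_equal(diag(c_mat), rep(1, 10))
    expect_true(all(abs(vectorize_upper(c_mat)) < 1))
  }
  expect_error(generate_subject_signature(1, 0.5, 1), "n_channels")
})

test_that("distinct seeds give distinct signatures", {
  cors <- vapply(1:50, function(k) {
    a <- generate_subject_signature(10, 0.6, seed = 2 * k)
    b <- generate_subject_signature(10, 0.6, seed = 2 * k + 1)
    stats::cor(vectorize_upper(a$target_correlation),
               vectorize_upper(b$target_correlation))
  }, numeric(1))
  expect_true(all(cors < 0.9))
})

test_that("synthesize_run recovers the signature at large n", {
  sig <- generate_subject_signature(10, 0.7, seed = 5)
  cfg <- cohort_config(n_subjects = 2, n_runs = 2, duration = 1e5 / 7.8,
                       sampling_rate = 7.8, n_channels = 10,
                       signature_strength = 1, global_amplitude = 0)
  run <- synthesize_run(sig, cfg, run_seed = 9)
  expect_gte(ncol(run$data), 1e5)
  dev <- max(abs(stats::cor(t(run$data)) - sig$target_correlation))
  expect_lt(dev, 0.05)
})

test_that("run synthesis contracts: sample count, determinism, realizations", {
  sig <- generate_subject_signature(6, 0.5, seed = 2)
  # informative settings so the FC-similarity contrast is visible over the
  # 15 off-diagonal entries of a 6-channel run
  cfg <- cohort_config(n_subjects = 2, n_runs = 2, duration = 360,
                       sampling_rate = 7.8, n_channels = 6,
                       signature_strength = 0.7, global_amplitude = 0.15)
  run <- synthesize_run(sig, cfg, run_seed = 3)
  expect_equal(ncol(run$data), 2808)  # floor(360 * 7.8)
  expect_identical(synthesize_run(sig, cfg, run_seed = 3)$data, run$data)
  run2 <- synthesize_run(sig, cfg, run_seed = 4)
  expect_false(identical(run$data, run2$data))
  # same-signature runs have correlated FC, above the cross-signature level
  fc_cor <- function(r1, r2)
    stats::cor(vectorize_upper(stats::cor(t(r1$data))),
               vectorize_upper(stats::cor(t(r2$data))))
  other <- generate_subject_signature(6, 0.5, seed = 77)
  run3 <- synthesize_run(other, cfg, run_seed = 5)
  expect_gt(fc_cor(run, run2), fc_cor(run, run3))
  cfg_bad <- cohort_config(n_subjects = 2, n_runs = 2, duration = 1,
                           sampling_rate = 2, n_channels = 6)
  expect_error(synthesize_run(sig, cfg_bad, 1), "10 samples")
})

test_that("identical configs give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 3, n_runs = 2, duration = 30,
                       sampling_rate = 7.8, n_channels = 5, seed = 17)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("hemoglobin_pair imposes the HbO/HbR anticorrelation", {
  set.seed(4)
  neural <- matrix(stats::rnorm(100 * 500), 100)
  hb <- hemoglobin_pair(neural, anticorr_scale = 1, noise_sd = 0,
                        sampling_rate = 7.8)
  expect_equal(max(abs(hb$HbT$data)), 0)
  hb2 <- hemoglobin_pair(neural, anticorr_scale = 0.3, noise_sd = 0,
                         sampling_rate = 7.8)
  cors <- vapply(seq_len(nrow(neural)), function(c_idx)
    stats::cor(hb2$HbO$data[c_idx, ], hb2$HbR$data[c_idx, ]), numeric(1))
  expect_equal(cors, rep(-1, 100), tolerance = 1e-12)
  hb3 <- hemoglobin_pair(neural, noise_sd = 0.3, sampling_rate = 7.8,
                         seed = 8)
  cors3 <- vapply(seq_len(nrow(neural)), function(c_idx)
    stats::cor(hb3$HbO$data[c_idx, ], hb3$HbR$data[c_idx, ]), numeric(1))
  expect_true(all(cors3 > -1 & cors3 < -0.5))
})

test_that("motion-artifact injection: no-op, Poisson counts, step amplitude", {
  run <- od_run(n_ch = 2, n = 500, seed = 21)
  out <- inject_motion_artifacts(run, 0, 0, seed = 1)
  expect_identical(out$run$data, run$data)
  expect_equal(nrow(out$spikes) + nrow(out$shifts), 0)
  # spike_rate 2/min on a 6-min run: mean count 12 over seeds, within 3 SE
  short <- ts_run(matrix(stats::rnorm(2 * 2808), 2), 7.8)
  counts <- vapply(1:300, function(k)
    nrow(inject_motion_artifacts(short, 2, 0, seed = k)$spikes), numeric(1))
  se <- sqrt(12 / 300)
  expect_lt(abs(mean(counts) - 12), 3 * se)
  # one step of amplitude a: post-step minus pre-step mean equals a
  flat <- ts_run(matrix(stats::rnorm(2 * 2000, sd = 1), 2), 7.8)
  sh <- inject_motion_artifacts(flat, 0, 10, seed = 3, shift_amp = 10)
  expect_gt(nrow(sh$shifts), 0)
  ev <- sh$shifts[1, ]
  later <- sh$shifts$sample[sh$shifts$sample > ev$sample]
  upto <- if (length(later)) min(later) else ncol(flat$data)
  ch_sd <- stats::sd(flat$data[1, ])
  jump <- mean(sh$run$data[1, (ev$sample + 1):upto] -
                 flat$data[1, (ev$sample + 1):upto]) -
    mean(sh$run$data[1, 1:ev$sample] - flat$data[1, 1:ev$sample])
  expect_equal(jump, ev$amplitude_sd * ch_sd, tolerance = 1e-8)
})

test_that("raw-intensity forward model is exact and linear in distance", {
  n <- 4; nt <- 200
  zero <- matrix(0, n, nt)
  raw0 <- to_raw_intensity(zero, zero)
  expect_equal(stats::sd(as.numeric(raw0$intensity_760)), 0)
  expect_true(all(raw0$intensity_850 == raw0$intensity_850[1, 1]))
  set.seed(6)
  hbo <- matrix(stats::rnorm(n * nt, sd = 0.5), n)
  hbr <- matrix(stats::rnorm(n * nt, sd = 0.2), n)
  od_of <- function(d) {
    raw <- to_raw_intensity(hbo, hbr, distances = d)
    -log(raw$intensity_760 / 1e6)
  }
  expect_equal(od_of(6), 2 * od_of(3), tolerance = 1e-12)
  expect_error(to_raw_intensity(hbo, hbr, dpf = -1), "dpf")
  expect_error(to_raw_intensity(hbo, hbr[, 1:10]), "shape")
})

test_that("cohort modalities produce the expected contrasts", {
  coh <- small_cohort()
  expect_named(coh$runs[[1]][[1]], c("HbO", "HbR", "HbT"))
  expect_equal(coh$runs[[1]][[1]]$HbT$data,
               coh$runs[[1]][[1]]$HbO$data + coh$runs[[1]][[1]]$HbR$data)
  cfg_b <- cohort_config(n_subjects = 2, n_runs = 2, duration = 30,
                         sampling_rate = 2, n_channels = 4,
                         modality = "fmri_roi", seed = 5)
  expect_named(simulate_cohort(cfg_b)$runs[[1]][[1]], "BOLD")
  cfg_r <- cohort_config(n_subjects = 2, n_runs = 2, duration = 60,
                         sampling_rate = 7.8, n_channels = 4,
                         modality = "fnirs_raw", seed = 5)
  raw <- simulate_cohort(cfg_r)$runs[[1]][[1]]
  expect_named(raw, c("intensity_760", "intensity_850"))
  expect_true(all(raw$intensity_760$data > 0))
})

test_that("seed splitting is collision-free over experiment-sized ranges", {
  seeds <- brainprint:::split_seed(101, 1:5000)
  expect_equal(length(unique(seeds)), 5000)
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
})
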