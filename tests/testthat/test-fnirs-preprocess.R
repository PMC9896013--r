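test_that("channel SNR follows the mean/sd definition with strict pruning", {
  run <- ts_run(matrix(100, 1, 3), 7.8, contrast = "intensity_760")
  expect_equal(unname(compute_channel_snr(run)), Inf)
  set.seed(1)
  z <- stats::rnorm(200)
  mk <- function(mu, s) mu + s * (z - mean(z)) / stats::sd(z)
  run2 <- ts_run(rbind(mk(80, 10), mk(70, 10)), 7.8,
                 contrast = "intensity_760")
  snr <- unname(compute_channel_snr(run2))
  expect_equal(snr, c(8, 7), tolerance = 1e-10)
  # strict "< threshold" rule: 8.0 survives, 7.0 is pruned
  expect_equal(snr < 8, c(FALSE, TRUE))
  expect_error(compute_channel_snr(ts_run(matrix(1, 1, 1), 1)), "2 samples")
})

test_that("quality control: clean pass-through, run exclusion, consistent-bad removal", {
  ok <- function(n_runs, n_ch) replicate(n_runs, rep(FALSE, n_ch),
                                         simplify = FALSE)
  clean <- qc_cohort(list(ok(2, 4), ok(2, 4)))
  res <- apply_quality_control(clean)
  expect_equal(nrow(res$report$dropped_runs), 0)
  expect_length(res$report$removed_channels, 0)
  expect_equal(res$cohort$runs[[1]][[1]]$intensity_760$data,
               clean$runs[[1]][[1]]$intensity_760$data)
  # a run with 3 of 4 channels bad (25% good < 50%) is excluded
  bad_run <- qc_cohort(list(list(c(TRUE, TRUE, TRUE, FALSE),
                                 rep(FALSE, 4)),
                            ok(2, 4)))
  res2 <- apply_quality_control(bad_run)
  expect_equal(res2$report$dropped_runs$run, "r01")
  expect_length(res2$cohort$runs[["s01"]], 1)
  # channel 2 bad in 8 of 10 participants (80% > 70%): removed for everyone
  bad <- lapply(1:10, function(i) {
    flag <- rep(FALSE, 4)
    flag[2] <- i <= 8
    list(flag, flag)
  })
  res3 <- apply_quality_control(qc_cohort(bad))
  expect_equal(res3$report$removed_channels, "ch02")
  expect_true(all(vapply(res3$cohort$runs, function(subj)
    nrow(subj[[1]]$intensity_760$data) == 3, logical(1))))
  expect_error(apply_quality_control(
    qc_cohort(list(list(rep(TRUE, 4)), list(rep(TRUE, 4))))), "every run")
})

test_that("quality control is invariant to subject ordering", {
  bad <- lapply(1:5, function(i)
    list(c(i <= 3, FALSE, FALSE, i == 1), rep(FALSE, 4)))
  coh <- qc_cohort(bad)
  res_fwd <- apply_quality_control(coh)
  perm <- c(4, 2, 5, 1, 3)
  coh_perm <- coh
  coh_perm$runs <- coh$runs[perm]
  coh_perm$subjects <- coh$subjects[perm]
  res_perm <- apply_quality_control(coh_perm)
  expect_setequal(res_perm$report$removed_channels,
                  res_fwd$report$removed_channels)
  expect_setequal(paste(res_perm$report$dropped_runs$subject,
                        res_perm$report$dropped_runs$run),
                  paste(res_fwd$report$dropped_runs$subject,
                        res_fwd$report$dropped_runs$run))
})

test_that("optical-density conversion: closed form, scale invariance, errors", {
  const <- ts_run(matrix(500, 2, 100), 7.8, contrast = "intensity_760")
  expect_equal(max(abs(intensity_to_od(const)$data)), 0)
  n <- 5000
  dat <- matrix(1000, 1, n)
  dat[1, 7] <- 500
  od <- intensity_to_od(ts_run(dat, 7.8, contrast = "intensity_760"))
  expect_equal(unname(od$data[1, 7]), log(2), tolerance = 1e-3)
  run <- ts_run(matrix(abs(stats::rnorm(300, 1000, 50)), 3, 100), 7.8,
                contrast = "intensity_760")
  run_k <- with(run, ts_run(data * 3.7, sampling_rate,
                            contrast = "intensity_760"))
  expect_equal(intensity_to_od(run_k)$data, intensity_to_od(run)$data,
               tolerance = 1e-12)
  bad <- run
  bad$data[2, 50] <- -1
  expect_error(intensity_to_od(bad), "channel ch02, sample 50")
})

test_that("hybrid motion correction: idle on clean data, removes steps and spikes", {
  fs <- 7.8
  run <- od_run(n_ch = 2, seed = 31)
  ch_sd <- stats::sd(run$data[1, ])
  ctrl <- motion_correct_hybrid(run)
  expect_lt(max(abs(ctrl$data - run$data)), 0.05 * ch_sd)
  # 10-sd baseline step reduced below 1 sd (median over channels/seeds)
  resid <- vapply(1:4, function(k) {
    r <- od_run(n_ch = 2, seed = 40 + k)
    s <- stats::sd(r$data[1, ])
    y2 <- r$data
    y2[, 1400:ncol(y2)] <- y2[, 1400:ncol(y2)] + 10 * s
    corr <- motion_correct_hybrid(with(r, ts_run(y2, fs)))
    est <- mean(corr$data[1, 1450:ncol(y2)]) - mean(corr$data[1, 1:1350])
    tru <- mean(r$data[1, 1450:ncol(y2)]) - mean(r$data[1, 1:1350])
    abs(est - tru) / s
  }, numeric(1))
  expect_lt(stats::median(resid), 1)
  expect_lt(mean(resid), 1)
  # spike correction brings kurtosis back toward the artifact-free value
  pair <- t(vapply(1:15, function(k) {
    r <- od_run(n_ch = 1, seed = 60 + k)
    art <- inject_motion_artifacts(r, spike_rate = 2, shift_rate = 0,
                                   seed = k)
    corr <- motion_correct_hybrid(art$run)
    c(art = kurtosis(art$run$data[1, ]), corr = kurtosis(corr$data[1, ]),
      clean = kurtosis(r$data[1, ]))
  }, numeric(3)))
  expect_lt(mean(pair[, "corr"]), mean(pair[, "art"]))
  expect_lt(mean(pair[, "corr"]) - mean(pair[, "clean"]),
            0.2 * (mean(pair[, "art"]) - mean(pair[, "clean"])))
  expect_error(motion_correct_hybrid(ts_run(matrix(1:20, 1), 7.8)),
               "wavelet")
})

test_that("MBLL inversion: zeros, HbT identity, forward-model round trip", {
  z <- ts_run(matrix(0, 3, 50), 7.8, contrast = "intensity_760")
  hb0 <- mbll(z, z)
  expect_equal(max(abs(hb0$HbO$data)), 0)
  set.seed(7)
  n <- 6; nt <- 400
  hbo <- matrix(stats::rnorm(n * nt, sd = 0.5), n)
  hbr <- matrix(stats::rnorm(n * nt, sd = 0.2), n)
  raw <- to_raw_intensity(hbo, hbr)
  hb <- mbll(intensity_to_od(ts_run(raw$intensity_760, 7.8,
                                    contrast = "intensity_760")),
             intensity_to_od(ts_run(raw$intensity_850, 7.8,
                                    contrast = "intensity_850")))
  ctr <- function(m) m - rowMeans(m)
  expect_lt(max(abs(ctr(hb$HbO$data) - ctr(hbo))), 1e-9)
  expect_lt(max(abs(ctr(hb$HbR$data) - ctr(hbr))), 1e-9)
  expect_equal(hb$HbT$data, hb$HbO$data + hb$HbR$data)
  expect_error(mbll_config(extinction = matrix(1, 2, 2)), "invertible")
})

test_that("band-pass filter: passband gain, DC and cardiac rejection", {
  fs <- 7.8
  tt <- seq(0, 600, by = 1 / fs)
  in_band <- sin(2 * pi * 0.03 * tt)
  cardiac <- sin(2 * pi * 0.5 * tt)
  run <- ts_run(rbind(in_band, cardiac, rep(5, length(tt))), fs)
  out <- bandpass(run)
  expect_equal(stats::sd(out$data[1, ]) / stats::sd(in_band), 1,
               tolerance = 0.05)
  expect_gt(20 * log10(stats::sd(cardiac) / stats::sd(out$data[2, ])), 20)
  expect_lt(max(abs(out$data[3, ])), 5 * 10^(-40 / 20))  # > 40 dB down
  expect_error(bandpass(ts_run(matrix(1:10, 1), 0.1)), "Nyquist")
  expect_error(bandpass_spec(0.08, 0.009), "low_cut")
})

test_that("PCA global filter removes the shared component", {
  fs <- 7.8; n <- 2808; n_ch <- 48
  common <- od_channel(n, fs, seed = 71)
  set.seed(72)
  mk <- function() {
    dat <- outer(rep(1, n_ch), common) +
      matrix(stats::rnorm(n_ch * n, sd = 0.8), n_ch)
    ts_run(dat, fs, contrast = "HbO")
  }
  hbo <- mk(); hbr <- mk()
  mean_xc <- function(m) {
    cc <- stats::cor(t(m))
    mean(abs(cc[upper.tri(cc)]))
  }
  expect_gt(mean_xc(hbo$data), 0.5)
  out <- pca_global_filter(hbo, hbr)
  expect_lt(mean_xc(out$HbO$data), 0.15)
  # residuals are orthogonal to the removed component
  x <- hbo$data - rowMeans(hbo$data)
  scores <- svd(x, nu = 1)$u[, 1] %*% x
  expect_lt(max(abs(out$HbO$data %*% t(scores))) / n, 1e-8)
  # all-identical channels collapse to ~0
  same <- ts_run(outer(rep(1, 4), common), fs, contrast = "HbO")
  expect_lt(max(abs(pca_global_filter(same, same)$HbO$data)), 1e-8)
  expect_error(pca_global_filter(ts_run(matrix(1:10, 1), fs),
                                 ts_run(matrix(1:10, 1), fs)), "2 channels")
})

test_that("full chain round trip keeps concentration RMSE under 10% of signal sd", {
  fs <- 7.8; n <- 2808; n_ch <- 4
  set.seed(81)
  tt <- (seq_len(n) - 1) / fs
  # oscillations well inside the 0.009-0.08 Hz analysis band, so the
  # band-pass stage is ~transparent and the chain's own error dominates
  slow <- function() {
    f <- stats::runif(3, 0.02, 0.04)
    ph <- stats::runif(3, 0, 2 * pi)
    s <- sin(2 * pi * f[1] * tt + ph[1]) + 0.6 * sin(2 * pi * f[2] * tt +
                                                       ph[2]) +
      0.4 * sin(2 * pi * f[3] * tt + ph[3])
    0.5 * s / stats::sd(s)
  }
  hbo <- do.call(rbind, replicate(n_ch, slow(), simplify = FALSE))
  hbr <- -hbo / 3
  raw <- to_raw_intensity(hbo, hbr)
  out <- preprocess_run_pair(
    ts_run(raw$intensity_760, fs, contrast = "intensity_760"),
    ts_run(raw$intensity_850, fs, contrast = "intensity_850"),
    pca_filter = FALSE)
  ctr <- function(m) m - rowMeans(m)
  rmse <- sqrt(mean((ctr(out$HbO$data) - ctr(hbo))^2))
  expect_lt(rmse, 0.1 * stats::sd(hbo[1, ]))
  expect_equal(out$HbO$sampling_rate, fs)
  expect_equal(out$HbO$channel_ids, sprintf("ch%02d", 1:n_ch))
})
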