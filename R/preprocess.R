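#' Extinction coefficients for hemoglobin at 760 and 850 nm
#'
#' Standard molar extinction coefficients (Gratzer/Prahl compilation, as
#' distributed with common fNIRS toolchains), in 1/(mM cm). Rows are
#' wavelengths (760, 850 nm), columns chromophores (HbO, HbR). The same
#' table is used by the forward synthetic model and the inverse modified
#' Beer-Lambert step, keeping round trips exact.
#'
#' @return 2 x 2 numeric matrix with dimnames.
#' @export
extinction_coefficients <- function() {
  matrix(c(1.4866, 3.8437,
           2.5264, 1.7986),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

#' Quality-control configuration
#'
#' @param snr_threshold channels with SNR strictly below this are flagged bad
#'   (default 8).
#' @param min_good_channel_fraction runs with a smaller fraction of good
#'   channels are excluded (default 0.5).
#' @param consistent_bad_fraction channels bad in more than this fraction of
#'   participants are removed from everyone (default 0.7).
#' @return list of class `quality_config`.
#' @export
quality_config <- function(snr_threshold = 8, min_good_channel_fraction = 0.5,
                           consistent_bad_fraction = 0.7) {
  if (snr_threshold <= 0) stop_invalid("`snr_threshold` must be positive")
  if (min_good_channel_fraction <= 0 || min_good_channel_fraction > 1 ||
      consistent_bad_fraction <= 0 || consistent_bad_fraction > 1)
    stop_invalid("fractions must lie in (0, 1]")
  structure(list(snr_threshold = snr_threshold,
                 min_good_channel_fraction = min_good_channel_fraction,
                 consistent_bad_fraction = consistent_bad_fraction),
            class = "quality_config")
}

#' Configuration of the modified Beer-Lambert inversion
#'
#' @param dpf differential pathlength factor per wavelength (default 6, 6).
#' @param wavelengths nm, informational (default 760, 850).
#' @param extinction 2 x 2 extinction matrix, 1/(mM cm); rows wavelengths,
#'   columns HbO/HbR. Must be invertible.
#' @param distances source-detector distances in cm (scalar or per channel).
#' @return list of class `mbll_config`.
#' @export
mbll_config <- function(dpf = c(6, 6), wavelengths = c(760, 850),
                        extinction = extinction_coefficients(),
                        distances = 3) {
  dpf <- rep_len(dpf, 2L)
  if (any(dpf <= 0)) stop_invalid("`dpf` must be positive")
  if (any(distances <= 0)) stop_invalid("`distances` must be positive")
  if (!all(dim(extinction) == c(2L, 2L)) ||
      abs(det(extinction)) < .Machine$double.eps * max(abs(extinction))^2 ||
      !is.finite(kappa(extinction)))
    stop_invalid("`extinction` must be an invertible 2 x 2 matrix")
  structure(list(dpf = dpf, wavelengths = wavelengths,
                 extinction = extinction, distances = distances),
            class = "mbll_config")
}

#' Band-pass filter specification
#'
#' @param low_cut,high_cut band edges in Hz; `0 < low_cut < high_cut` and
#'   `high_cut` below the Nyquist frequency of the filtered run. Defaults are
#'   the resting-state band 0.009-0.08 Hz.
#' @param design filter design; `"butterworth_fft"` applies the squared
#'   Butterworth magnitude response in the frequency domain (exactly zero
#'   phase, equivalent in magnitude to a forward-backward IIR pass).
#' @param order Butterworth order (default 3).
#' @return list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_cut = 0.009, high_cut = 0.08,
                          design = "butterworth_fft", order = 3L) {
  if (low_cut <= 0 || high_cut <= low_cut)
    stop_invalid("need 0 < low_cut < high_cut")
  design <- match.arg(design, "butterworth_fft")
  if (order < 1) stop_invalid("`order` must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut, design = design,
                 order = as.integer(order)),
            class = "bandpass_spec")
}

#' Per-channel signal-to-noise ratio
#'
#' SNR of a raw-intensity channel is its temporal mean divided by its
#' temporal standard deviation. Constant channels have zero sd and return
#' `+Inf` (kept by any finite threshold).
#'
#' @param run a [ts_run()] with at least 2 samples per channel.
#' @return named numeric vector, one SNR per channel.
#' @export
compute_channel_snr <- function(run) {
  stopifnot(inherits(run, "ts_run"))
  if (n_samples(run) < 2)
    stop_invalid("SNR needs at least 2 samples per channel")
  m <- rowMeans(run$data)
  s <- apply(run$data, 1L, stats::sd)
  snr <- ifelse(s == 0, Inf, m / s)
  names(snr) <- run$channel_ids
  snr
}

# Contrasts used for SNR-based QC: raw intensities when present,
# otherwise every contrast in the run list.
qc_contrasts <- function(run_list) {
  nm <- names(run_list)
  raw <- grep("^intensity", nm, value = TRUE)
  if (length(raw)) raw else nm
}

#' Cohort-level quality control
#'
#' Three sequential passes over a cohort of raw runs:
#' 1. flag channels whose SNR falls strictly below `qc$snr_threshold` in any
#'    wavelength of a run;
#' 2. exclude runs whose fraction of good channels is below
#'    `qc$min_good_channel_fraction`;
#' 3. remove, from every subject, channels that are bad (flagged in more
#'    than half of a subject's surviving runs) in more than
#'    `qc$consistent_bad_fraction` of participants, so all subjects keep the
#'    same channel set.
#'
#' @param cohort a [simulate_cohort()] result (or any object with the same
#'   `runs[[subject]][[run]][[contrast]]` layout).
#' @param qc a [quality_config()].
#' @return list with `cohort` (filtered copy) and `report` — a list with
#'   `channel_flags` (per run), `dropped_runs` (data frame with reasons) and
#'   `removed_channels` (character).
#' @export
apply_quality_control <- function(cohort, qc = quality_config()) {
  stopifnot(inherits(qc, "quality_config"))
  if (length(cohort$runs) == 0) stop_invalid("empty cohort")
  subjects <- names(cohort$runs)
  flags <- list()      # flags[[subject]][[run]] = logical bad-channel vector
  for (s in subjects) {
    flags[[s]] <- lapply(cohort$runs[[s]], function(run_list) {
      bad <- NULL
      for (ctr in qc_contrasts(run_list)) {
        snr <- compute_channel_snr(run_list[[ctr]])
        b <- snr < qc$snr_threshold
        bad <- if (is.null(bad)) b else bad | b
      }
      bad
    })
  }
  dropped <- data.frame(subject = character(0), run = character(0),
                        reason = character(0))
  out_runs <- cohort$runs
  for (s in subjects) {
    keep <- vapply(flags[[s]], function(b) mean(!b), numeric(1)) >=
      qc$min_good_channel_fraction
    if (any(!keep)) {
      dr <- names(out_runs[[s]])[!keep]
      dropped <- rbind(dropped, data.frame(
        subject = s, run = dr,
        reason = sprintf("good-channel fraction below %.2f",
                         qc$min_good_channel_fraction)))
      out_runs[[s]] <- out_runs[[s]][keep]
      flags[[s]] <- flags[[s]][keep]
    }
  }
  surviving <- subjects[vapply(out_runs, length, integer(1)) > 0]
  if (length(surviving) == 0)
    stop_invalid("quality control removed every run in the cohort")
  # participant-level badness: channel bad in > 50% of the subject's runs
  subj_bad <- vapply(surviving, function(s) {
    m <- do.call(rbind, flags[[s]])
    colMeans(m) > 0.5
  }, logical(length(flags[[surviving[1]]][[1]])))
  bad_frac <- rowMeans(subj_bad)
  remove_ch <- bad_frac > qc$consistent_bad_fraction
  ch_ids <- cohort$runs[[1]][[1]][[1]]$channel_ids
  removed_channels <- ch_ids[remove_ch]
  if (any(remove_ch)) {
    for (s in surviving) {
      out_runs[[s]] <- lapply(out_runs[[s]], function(run_list)
        lapply(run_list, function(run) subset_channels(run, !remove_ch)))
    }
  }
  out <- cohort
  out$runs <- out_runs[surviving]
  out$subjects <- surviving
  list(cohort = out,
       report = list(channel_flags = flags, dropped_runs = dropped,
                     removed_channels = removed_channels))
}

subset_channels <- function(run, keep) {
  ts_run(run$data[keep, , drop = FALSE], run$sampling_rate, run$subject_id,
         run$run_id, run$contrast, run$channel_ids[keep],
         run$quality_flags[keep])
}

#' Convert raw intensities to optical density
#'
#' `OD_c(t) = -ln(I_c(t) / mean_t I_c)`, referenced to the per-channel
#' temporal mean of the run; invariant to rescaling a channel by any
#' positive constant.
#'
#' @param run a [ts_run()] of strictly positive intensities.
#' @return a [ts_run()] of optical densities (contrast label preserved).
#' @export
intensity_to_od <- function(run) {
  stopifnot(inherits(run, "ts_run"))
  bad <- which(run$data <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid(sprintf(
      "non-positive intensity at channel %s, sample %d",
      run$channel_ids[bad[1, 1]], bad[1, 2]))
  od <- -log(run$data / rowMeans(run$data))
  with_data(run, od)
}

#' Hybrid spline + wavelet motion-artifact correction
#'
#' Two stages applied in a fixed order to each channel of an
#' optical-density run:
#'
#' 1. **Spline stage** (baseline shifts): samples whose moving standard
#'    deviation (window `sd_window_s` seconds) exceeds `sd_threshold` times
#'    the channel's robust sd estimate mark artifact segments; within each
#'    segment a smoothing spline models the artifact and is subtracted, the
#'    segment is re-leveled to the pre-segment baseline, and any residual
#'    level change is removed from all later samples.
#' 2. **Wavelet stage** (spikes): a periodized Daubechies-2 decomposition to
#'    `wavelet_levels` levels; at each detail level, coefficients outside
#'    `iqr_mult` interquartile ranges of the level's quartiles are set to
#'    zero before reconstruction.
#'
#' @param od a [ts_run()] of optical densities.
#' @param sd_window_s moving-sd window in seconds (default 1).
#' @param sd_threshold detection threshold as a multiple of the robust
#'   channel sd (default 3).
#' @param spline_spar smoothing parameter passed to
#'   [stats::smooth.spline()] (default 0.7).
#' @param wavelet_levels decomposition depth (default 5).
#' @param iqr_mult IQR multiplier for coefficient rejection (default 1.5).
#' @return corrected [ts_run()].
#' @export
motion_correct_hybrid <- function(od, sd_window_s = 1, sd_threshold = 3,
                                  spline_spar = 0.7, wavelet_levels = 5L,
                                  iqr_mult = 1.5) {
  stopifnot(inherits(od, "ts_run"))
  n <- n_samples(od)
  if (n < 2^wavelet_levels)
    stop_invalid("run shorter than one wavelet decomposition level")
  w <- max(3L, round(sd_window_s * od$sampling_rate))
  x <- od$data
  for (c_idx in seq_len(nrow(x)))
    x[c_idx, ] <- spline_correct_channel(x[c_idx, ], w, sd_threshold,
                                         spline_spar)
  for (c_idx in seq_len(nrow(x)))
    x[c_idx, ] <- wavelet_correct_channel(x[c_idx, ], wavelet_levels,
                                          iqr_mult)
  with_data(od, x)
}

moving_sd <- function(y, w) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  half <- w %/% 2
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- (cs2[hi + 1] - cs2[lo]) / cnt - m^2
  sqrt(pmax(v * cnt / pmax(cnt - 1, 1), 0))
}

spline_correct_channel <- function(y, w, thr, spar) {
  n <- length(y)
  # detect on the differenced series: spikes and baseline jumps turn into
  # isolated large increments, while slow hemodynamics contribute little;
  # the reference sd is MAD-based so the artifacts themselves cannot
  # inflate it
  dy <- diff(y)
  ref_sd <- stats::mad(dy) / sqrt(2)
  if (ref_sd <= 0) return(y)
  msd <- moving_sd(dy, w) / sqrt(2)
  flagged <- c(FALSE, msd > thr * ref_sd)
  if (!any(flagged)) return(y)
  # pad flags by one window and merge into segments
  idx <- which(flagged)
  lo <- pmax(1L, idx - w)
  hi <- pmin(n, idx + w)
  mask <- logical(n)
  for (k in seq_along(idx)) mask[lo[k]:hi[k]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, 1]; e <- segs[k, 2]
    seg <- s:e
    # model the artifact inside the segment with a smoothing spline
    fit <- if (length(seg) >= 8) {
      stats::smooth.spline(seg, y[seg], spar = spar)$y
    } else rep(stats::median(y[seg]), length(seg))
    # local polynomial baselines on both sides of the segment, extrapolated
    # to the segment midpoint: their difference estimates the artifact's
    # residual level change without mistaking a genuine slow drift for a
    # baseline shift
    mid <- (s + e) / 2
    pre_fit <- local_poly_level(y, max(1L, s - 4L * w), s - 1L, mid)
    post_fit <- local_poly_level(y, e + 1L, min(n, e + 4L * w), mid)
    base <- if (is.na(pre_fit)) post_fit else pre_fit
    if (is.na(base)) base <- stats::median(y[seg])
    y[seg] <- (y[seg] - fit) + base
    if (e < n && !is.na(pre_fit) && !is.na(post_fit)) {
      delta <- post_fit - pre_fit
      y[(e + 1L):n] <- y[(e + 1L):n] - delta
    }
  }
  y
}

# Quadratic (falling back to linear/mean) fit of y over [a, b], evaluated at
# time `at`; NA when the window is empty or outside the series.
local_poly_level <- function(y, a, b, at) {
  if (b < a || b < 1L || a > length(y)) return(NA_real_)
  idx <- max(1L, a):min(length(y), b)
  if (length(idx) < 2) return(mean(y[idx]))
  x <- idx - at  # center so the intercept is the value at `at`
  xmat <- if (length(idx) >= 12) cbind(1, x, x^2) else cbind(1, x)
  stats::coef(stats::lm.fit(xmat, y[idx]))[1]
}

wavelet_correct_channel <- function(y, levels, iqr_mult) {
  n <- length(y)
  half <- 2L^(levels - 1L)
  # even-symmetric extension so the periodized transform sees a continuous
  # circular signal (no spurious boundary coefficients): pad to a multiple
  # of 2^(L-1) by repeating the last sample, then mirror the whole series
  m <- ceiling(n / half) * half
  y1 <- c(y, rep(y[n], m - n))
  y_ext <- c(y1, rev(y1))
  dec <- dwt_db2(y_ext, levels)
  for (j in seq_len(levels)) {
    d <- dec$details[[j]]
    k_orig <- m / 2^j  # coefficients covering the original (first) half
    # coefficients whose support touches the extension junctions respond to
    # the mirror crease, not to artifacts: leave them (and the mirrored
    # half) untouched
    eligible <- seq_len(length(d)) <= k_orig
    eligible[c(1:min(3, length(d)),
               max(1, k_orig - 2):min(length(d), k_orig + 3))] <- FALSE
    q <- stats::quantile(d[eligible], c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    # IQR fences floored at the level's universal threshold
    # (sigma_hat * sqrt(2 log K), sigma_hat = IQR/1.349, 1.5x safety):
    # coefficients consistent with the level's Gaussian bulk are never
    # shrunk, while artifact coefficients sit orders of magnitude outside
    u <- 1.5 * sqrt(2 * log(sum(eligible))) * iqr / 1.349
    lo <- min(q[1] - iqr_mult * iqr, q[2] - u)
    hi <- max(q[3] + iqr_mult * iqr, q[2] + u)
    out <- eligible & (d < lo | d > hi)
    d[out] <- 0
    dec$details[[j]] <- d
  }
  idwt_db2(dec)[seq_len(n)]
}

#' Modified Beer-Lambert inversion to hemoglobin concentrations
#'
#' Solves, per channel and sample, the 2 x 2 linear system
#' `dOD_lambda = (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR) * d * DPF_lambda`
#' for the concentration changes (reported in micromolar), and returns
#' `HbT = HbO + HbR`.
#'
#' @param od760,od850 [ts_run()] optical densities at the two wavelengths,
#'   same shape and channel order.
#' @param cfg an [mbll_config()].
#' @return list of [ts_run()] objects `HbO`, `HbR`, `HbT` (micromolar).
#' @export
mbll <- function(od760, od850, cfg = mbll_config()) {
  stopifnot(inherits(od760, "ts_run"), inherits(od850, "ts_run"))
  if (!all(dim(od760$data) == dim(od850$data)) ||
      !identical(od760$channel_ids, od850$channel_ids))
    stop_invalid("wavelength runs must share shape and channel order")
  e_inv <- solve(cfg$extinction)
  d <- rep_len(cfg$distances, nrow(od760$data))
  a760 <- od760$data / (d * cfg$dpf[1])
  a850 <- od850$data / (d * cfg$dpf[2])
  hbo <- (e_inv[1, 1] * a760 + e_inv[1, 2] * a850) * 1e3  # mM -> uM
  hbr <- (e_inv[2, 1] * a760 + e_inv[2, 2] * a850) * 1e3
  mk <- function(dat, ctr)
    ts_run(dat, od760$sampling_rate, od760$subject_id, od760$run_id, ctr,
           od760$channel_ids, od760$quality_flags)
  list(HbO = mk(hbo, "HbO"), HbR = mk(hbr, "HbR"),
       HbT = mk(hbo + hbr, "HbT"))
}

#' Zero-phase band-pass filter
#'
#' Removes frequencies outside `[low_cut, high_cut]` with the squared
#' Butterworth magnitude response applied in the frequency domain on a
#' reflection-extended series: exactly zero phase, DC fully removed. The
#' squared response matches the magnitude of a forward-backward
#' (`filtfilt`-style) application of an order-`order` Butterworth filter.
#'
#' @param run a [ts_run()].
#' @param spec a [bandpass_spec()]; `high_cut` must be below the run's
#'   Nyquist frequency.
#' @return filtered [ts_run()].
#' @export
bandpass <- function(run, spec = bandpass_spec()) {
  stopifnot(inherits(run, "ts_run"), inherits(spec, "bandpass_spec"))
  fs <- run$sampling_rate
  if (spec$high_cut >= fs / 2)
    stop_invalid("high_cut (", spec$high_cut, " Hz) must be below Nyquist (",
                 fs / 2, " Hz)")
  x <- run$data
  n <- ncol(x)
  m <- rowMeans(x)
  x <- x - m
  # even (reflection) extension halves circular wrap-around artifacts
  ext <- cbind(x, x[, n:1, drop = FALSE])
  n2 <- 2L * n
  f <- (seq_len(n2) - 1) / n2 * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  o2 <- 2L * spec$order
  hp <- (f / spec$low_cut)^o2 / (1 + (f / spec$low_cut)^o2)
  lp <- 1 / (1 + (f / spec$high_cut)^o2)
  h2 <- hp * lp  # squared magnitude: forward-backward Butterworth
  xf <- t(apply(ext, 1L, function(row)
    Re(stats::fft(stats::fft(row) * h2, inverse = TRUE)) / n2))
  with_data(run, xf[, seq_len(n), drop = FALSE])
}

#' Remove global systemic physiology by PCA
#'
#' For each chromophore independently: channels are mean-centered over time,
#' the first principal component across channels is computed, and the data
#' are reconstructed without it. The removed component (shared global
#' physiology) has exactly zero sample covariance with every residual
#' channel. HbT should be recomputed downstream as the sum of the filtered
#' HbO and HbR.
#'
#' @param hbo,hbr [ts_run()] concentration runs with at least 2 channels.
#' @return list of filtered runs `HbO`, `HbR` and the recomputed `HbT`.
#' @export
pca_global_filter <- function(hbo, hbr) {
  stopifnot(inherits(hbo, "ts_run"), inherits(hbr, "ts_run"))
  if (nrow(hbo$data) < 2 || nrow(hbr$data) < 2)
    stop_invalid("PCA global filter needs at least 2 channels")
  strip <- function(run) {
    x <- run$data - rowMeans(run$data)
    u1 <- svd(x, nu = 1L, nv = 0L)$u  # n_channels x 1
    with_data(run, x - u1 %*% crossprod(u1, x))
  }
  hbo_f <- strip(hbo)
  hbr_f <- strip(hbr)
  hbt <- with_data(hbo_f, hbo_f$data + hbr_f$data, contrast = "HbT")
  list(HbO = hbo_f, HbR = hbr_f, HbT = hbt)
}

#' Full fNIRS preprocessing chain for one run pair
#'
#' Raw intensities to cleaned concentrations: optical-density conversion,
#' hybrid motion correction, modified Beer-Lambert inversion, band-pass
#' filtering, and (optionally) PCA removal of the global component, in the
#' fixed order of the underlying pipeline.
#'
#' @param i760,i850 raw-intensity [ts_run()] pairs.
#' @param mbll_cfg an [mbll_config()].
#' @param band a [bandpass_spec()], or `NULL` to skip.
#' @param motion_correct apply [motion_correct_hybrid()] (default `TRUE`).
#' @param pca_filter apply [pca_global_filter()] (default `TRUE`).
#' @return list of [ts_run()]: `HbO`, `HbR`, `HbT`.
#' @export
preprocess_run_pair <- function(i760, i850, mbll_cfg = mbll_config(),
                                band = bandpass_spec(),
                                motion_correct = TRUE, pca_filter = TRUE) {
  od1 <- intensity_to_od(i760)
  od2 <- intensity_to_od(i850)
  if (motion_correct) {
    od1 <- motion_correct_hybrid(od1)
    od2 <- motion_correct_hybrid(od2)
  }
  hb <- mbll(od1, od2, mbll_cfg)
  if (!is.null(band)) {
    hb$HbO <- bandpass(hb$HbO, band)
    hb$HbR <- bandpass(hb$HbR, band)
  }
  if (pca_filter && nrow(hb$HbO$data) >= 2) {
    hb <- pca_global_filter(hb$HbO, hb$HbR)
  } else {
    hb$HbT <- with_data(hb$HbO, hb$HbO$data + hb$HbR$data, contrast = "HbT")
  }
  hb
}
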