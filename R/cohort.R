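#' Configuration of a synthetic resting-state cohort
#'
#' Describes the stated world a synthetic cohort is drawn from. Defaults
#' emulate a simultaneous fNIRS/fMRI resting-state protocol: 6-minute runs,
#' fNIRS hemoglobin series at 7.8 Hz over 48 channels. The generative model
#' for one run is
#' \deqn{x(t) = \sqrt{s}\,L z(t) + \sqrt{g}\, a\, G(t) + \sqrt{1-s-g}\,\eta(t)}
#' where `L` is the Cholesky factor of the subject's target correlation,
#' `z` and `eta` are white Gaussian series temporally colored by a shared
#' AR filter, `G` is one global (systemic physiology) AR series shared by all
#' channels with per-channel gains `a`, `s = signature_strength` and
#' `g = global_amplitude` are variance shares. All three components pass
#' through the same AR filter, so the instantaneous correlation structure of
#' the latent part equals the target correlation exactly.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_runs runs per subject (>= 2).
#' @param duration run length in seconds.
#' @param sampling_rate sampling frequency in Hz.
#' @param n_channels channels (fNIRS) or ROIs (fMRI).
#' @param modality `"fnirs_hb"` (HbO/HbR/HbT concentration series),
#'   `"fmri_roi"` (BOLD ROI series) or `"fnirs_raw"` (dual-wavelength
#'   intensities, with motion artifacts injected).
#' @param signature_strength share of variance carried by the
#'   subject-specific latent correlation structure, in \[0, 1\].
#' @param global_amplitude share of variance carried by the shared global
#'   physiological component, in \[0, 1\]; `signature_strength +
#'   global_amplitude <= 1`.
#' @param ar_coefficients AR coefficients of the temporal coloring filter.
#' @param spike_rate,shift_rate motion-artifact rates (events per minute),
#'   applied in the `fnirs_raw` modality.
#' @param run_jitter_sd sd of the multiplicative per-run jitter applied to
#'   the latent factor loadings (session-to-session variability).
#' @param amplitude_sd overall signal scale: sd of one channel, in
#'   micromolar for hemoglobin, arbitrary units otherwise.
#' @param seed root RNG seed; all subject/run streams derive from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 21, n_runs = 5, duration = 360,
                          sampling_rate = 7.8, n_channels = 48,
                          modality = c("fnirs_hb", "fmri_roi", "fnirs_raw"),
                          signature_strength = 0.25, global_amplitude = 0.15,
                          ar_coefficients = c(0.5, 0.2),
                          spike_rate = 0.5, shift_rate = 0.1,
                          run_jitter_sd = 0.4, amplitude_sd = 0.5,
                          seed = 1L) {
  modality <- match.arg(modality)
  if (n_subjects < 2) stop_invalid("`n_subjects` must be >= 2")
  if (n_runs < 2) stop_invalid("`n_runs` must be >= 2")
  if (sampling_rate <= 0) stop_invalid("`sampling_rate` must be positive")
  if (n_channels < 2) stop_invalid("`n_channels` must be >= 2")
  if (signature_strength < 0 || signature_strength > 1 ||
      global_amplitude < 0 || global_amplitude > 1)
    stop_invalid("variance shares must lie in [0, 1]")
  if (signature_strength + global_amplitude > 1)
    stop_invalid("signature_strength + global_amplitude must be <= 1")
  if (spike_rate < 0 || shift_rate < 0)
    stop_invalid("artifact rates must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         duration = duration, sampling_rate = sampling_rate,
         n_channels = as.integer(n_channels), modality = modality,
         signature_strength = signature_strength,
         global_amplitude = global_amplitude,
         ar_coefficients = ar_coefficients,
         spike_rate = spike_rate, shift_rate = shift_rate,
         run_jitter_sd = run_jitter_sd, amplitude_sd = amplitude_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Rebuild a unit-diagonal correlation matrix from factor loadings:
# C = mix * cov2cor(LL' + delta I) + (1 - mix) * I. Convex in the identity,
# hence SPD for any mix in [0, 1].
signature_from_loadings <- function(loadings, delta, mix) {
  n <- nrow(loadings)
  raw <- tcrossprod(loadings) + diag(delta, n)
  b <- stats::cov2cor(raw)
  c_mat <- mix * b + (1 - mix) * diag(n)
  diag(c_mat) <- 1
  c_mat
}

#' Generate a subject's latent connectivity signature
#'
#' Builds a random symmetric positive-definite correlation matrix from a
#' low-rank factor model: a random loadings matrix of rank
#' `max(2, round(n_channels / 8))` plus a diagonal, renormalized to unit
#' diagonal, then shrunk toward the identity so that `strength`
#' monotonically scales the mean absolute off-diagonal correlation
#' (`strength = 0` gives exactly the identity).
#'
#' @param n_channels matrix dimension (>= 2).
#' @param strength shrinkage mix in \[0, 1\].
#' @param seed RNG seed.
#' @param subject_id label stored with the signature.
#' @return object of class `subject_signature` with fields
#'   `target_correlation` (SPD, unit diagonal), `loadings`, `delta`,
#'   `strength`, `subject_id`.
#' @export
generate_subject_signature <- function(n_channels, strength, seed,
                                       subject_id = "s01") {
  if (!is.numeric(n_channels) || n_channels < 2)
    stop_invalid("`n_channels` must be >= 2")
  if (strength < 0 || strength > 1)
    stop_invalid("`strength` must lie in [0, 1]")
  n_channels <- as.integer(n_channels)
  rank <- max(2L, as.integer(round(n_channels / 8)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  loadings <- matrix(stats::rnorm(n_channels * rank), n_channels, rank)
  delta <- 0.5  # diagonal ridge keeps channel-specific variance realistic
  structure(
    list(subject_id = as.character(subject_id),
         target_correlation = signature_from_loadings(loadings, delta,
                                                      strength),
         loadings = loadings, delta = delta, strength = strength),
    class = "subject_signature")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Color each row of a white-noise matrix with the recursive AR filter
# x_t = sum_k phi_k x_{t-k} + e_t. A burn-in is generated and dropped so the
# series are (approximately) stationary from the first retained sample.
ar_color <- function(white, phi, burn = 200L) {
  if (length(phi) == 0 || all(phi == 0)) return(white)
  n <- ncol(white)
  ext <- cbind(matrix(stats::rnorm(nrow(white) * burn), nrow(white)), white)
  out <- t(apply(ext, 1L, function(row)
    as.numeric(stats::filter(row, phi, method = "recursive"))))
  out[, burn + seq_len(n), drop = FALSE]
}

#' Synthesize one run from a subject signature
#'
#' Draws a channels x samples Gaussian series whose latent correlation is the
#' signature's target matrix, colored in time by the configured AR filter,
#' plus a shared global component and white-in-space noise (see
#' [cohort_config()] for the model). Runs from the same signature differ in
#' realization only.
#'
#' @param signature a [generate_subject_signature()] result.
#' @param config a [cohort_config()]; `signature` dimension must equal
#'   `config$n_channels`.
#' @param run_seed RNG seed for this run.
#' @param run_id,contrast metadata for the returned run.
#' @return a [ts_run()]; the realized target correlation is attached as
#'   attribute `"target_correlation"`.
#' @export
synthesize_run <- function(signature, config, run_seed, run_id = "r01",
                           contrast = "HbO") {
  stopifnot(inherits(signature, "subject_signature"),
            inherits(config, "cohort_config"))
  n_ch <- nrow(signature$target_correlation)
  if (n_ch != config$n_channels)
    stop_invalid("signature dimension (", n_ch,
                 ") != config$n_channels (", config$n_channels, ")")
  n <- floor(config$duration * config$sampling_rate)
  if (n < 10) stop_invalid("duration * sampling_rate must give >= 10 samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(run_seed))
  s <- config$signature_strength
  g <- config$global_amplitude
  phi <- config$ar_coefficients
  l_chol <- t(chol(signature$target_correlation))
  latent <- l_chol %*% ar_color(matrix(stats::rnorm(n_ch * n), n_ch, n), phi)
  x <- sqrt(s) * latent
  if (g > 0) {
    global <- ar_color(matrix(stats::rnorm(n), 1L, n), phi)
    gains <- stats::rnorm(n_ch, mean = 1, sd = 0.2)
    x <- x + sqrt(g) * gains %o% as.numeric(global)
  }
  if (s + g < 1) {
    noise <- ar_color(matrix(stats::rnorm(n_ch * n), n_ch, n), phi)
    x <- x + sqrt(1 - s - g) * noise
  }
  # same AR filter on every component: rescale to the requested channel sd
  gain2 <- if (length(phi)) {
    acf_ar <- ar_acf_var(phi)
    acf_ar
  } else 1
  x <- x * (config$amplitude_sd / sqrt(gain2))
  run <- ts_run(x, config$sampling_rate, signature$subject_id, run_id,
                contrast)
  attr(run, "target_correlation") <- signature$target_correlation
  run
}

# Stationary variance of an AR(p) process with unit innovation variance,
# from the Yule-Walker equations (via the process autocovariances).
ar_acf_var <- function(phi) {
  if (length(phi) == 0 || all(phi == 0)) return(1)
  # variance = 1 / (1 - sum(phi_k * rho_k)); rho from ARMAacf
  rho <- stats::ARMAacf(ar = phi, lag.max = length(phi))[-1]
  1 / (1 - sum(phi * rho))
}

#' Derive anticorrelated HbO/HbR and their HbT sum from a neural series
#'
#' Resting-state oxy- and deoxy-hemoglobin measured in the same channel are
#' expected to be anticorrelated; this helper imposes the linear relation
#' `HbR = -anticorr_scale * HbO + noise` channelwise and returns the total
#' hemoglobin `HbT = HbO + HbR`.
#'
#' @param neural a [ts_run()] (taken as HbO, micromolar) or a numeric
#'   channels x samples matrix.
#' @param anticorr_scale positive scale of the anticorrelation (default 1/3:
#'   HbR fluctuations are smaller than HbO's).
#' @param noise_sd sd of the independent noise added to HbR (micromolar).
#' @param seed RNG seed.
#' @param sampling_rate required when `neural` is a bare matrix.
#' @return list with elements `HbO`, `HbR`, `HbT`, each a [ts_run()].
#' @export
hemoglobin_pair <- function(neural, anticorr_scale = 1 / 3, noise_sd = 0.1,
                            seed = 1L, sampling_rate = NULL) {
  if (anticorr_scale <= 0) stop_invalid("`anticorr_scale` must be positive")
  if (inherits(neural, "ts_run")) {
    base <- neural
  } else {
    if (is.null(sampling_rate))
      stop_invalid("`sampling_rate` required for matrix input")
    base <- ts_run(neural, sampling_rate, contrast = "HbO")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hbo <- base$data
  hbr <- -anticorr_scale * hbo +
    matrix(stats::rnorm(length(hbo), sd = noise_sd), nrow(hbo))
  mk <- function(dat, contrast)
    ts_run(dat, base$sampling_rate, base$subject_id, base$run_id, contrast,
           base$channel_ids, base$quality_flags)
  list(HbO = mk(hbo, "HbO"), HbR = mk(hbr, "HbR"),
       HbT = mk(hbo + hbr, "HbT"))
}

#' Inject spike and baseline-shift motion artifacts
#'
#' Adds transient spikes (Gaussian bumps of width about half a second) and
#' step baseline shifts at Poisson-distributed times, with amplitudes several
#' times the per-channel signal sd — the two artifact families that hybrid
#' spline + wavelet correction targets. Ground-truth event times and
#' amplitudes are returned so corrections can be scored.
#'
#' @param run a [ts_run()].
#' @param spike_rate,shift_rate events per minute (>= 0).
#' @param seed RNG seed.
#' @param spike_amp,shift_amp event amplitude in units of the per-channel sd.
#' @return list with elements `run` (corrupted [ts_run()]), `spikes` and
#'   `shifts` (data frames: `time_s`, `sample`, `amplitude_sd`).
#' @export
inject_motion_artifacts <- function(run, spike_rate, shift_rate, seed = 1L,
                                    spike_amp = 10, shift_amp = 10) {
  stopifnot(inherits(run, "ts_run"))
  if (spike_rate < 0 || shift_rate < 0)
    stop_invalid("artifact rates must be >= 0")
  minutes <- n_samples(run) / run$sampling_rate / 60
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  x <- run$data
  n <- ncol(x)
  ch_sd <- apply(x, 1L, stats::sd)
  n_spikes <- stats::rpois(1L, spike_rate * minutes)
  n_shifts <- stats::rpois(1L, shift_rate * minutes)
  spikes <- data.frame(time_s = numeric(0), sample = integer(0),
                       amplitude_sd = numeric(0))
  shifts <- spikes
  if (n_spikes > 0) {
    at <- sort(sample.int(n, n_spikes))
    width <- pmax(1, round(0.25 * run$sampling_rate))  # ~0.5 s support
    amp <- spike_amp * stats::runif(n_spikes, 0.8, 1.2) *
      sample(c(-1, 1), n_spikes, replace = TRUE)
    tgrid <- seq_len(n)
    for (k in seq_len(n_spikes)) {
      bump <- exp(-0.5 * ((tgrid - at[k]) / width)^2)
      x <- x + (amp[k] * ch_sd) %o% bump
    }
    spikes <- data.frame(time_s = (at - 1) / run$sampling_rate, sample = at,
                         amplitude_sd = amp)
  }
  if (n_shifts > 0) {
    at <- sort(sample.int(n - 1L, n_shifts))
    amp <- shift_amp * stats::runif(n_shifts, 0.8, 1.2) *
      sample(c(-1, 1), n_shifts, replace = TRUE)
    for (k in seq_len(n_shifts)) {
      step <- c(rep(0, at[k]), rep(1, n - at[k]))
      x <- x + (amp[k] * ch_sd) %o% step
    }
    shifts <- data.frame(time_s = (at - 1) / run$sampling_rate, sample = at,
                         amplitude_sd = amp)
  }
  list(run = with_data(run, x), spikes = spikes, shifts = shifts)
}

#' Map hemoglobin concentration changes to raw dual-wavelength intensities
#'
#' Inverse of the optical-density / modified Beer-Lambert chain, used to
#' build raw synthetic recordings with known ground truth. For each channel
#' and wavelength, `dOD = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF`
#' (concentrations in millimolar, extinction coefficients in 1/(mM cm),
#' source-detector distance `d` in cm) and
#' `I(t) = baseline * exp(-dOD(t))`.
#'
#' @param hbo,hbr channels x samples matrices of concentration changes in
#'   micromolar.
#' @param dpf differential pathlength factor (> 0), one value or one per
#'   wavelength.
#' @param distances source-detector distance in cm, scalar or per channel.
#' @param baseline_intensity baseline detector counts (default 1e6).
#' @param extinction 2 x 2 extinction matrix (rows: wavelengths 760/850 nm,
#'   columns: HbO/HbR), 1/(mM cm); defaults to [extinction_coefficients()].
#' @return list with matrices `intensity_760` and `intensity_850`, strictly
#'   positive.
#' @export
to_raw_intensity <- function(hbo, hbr, dpf = 6, distances = 3,
                             baseline_intensity = 1e6,
                             extinction = extinction_coefficients()) {
  if (!all(dim(hbo) == dim(hbr)))
    stop_invalid("`hbo` and `hbr` must have identical shapes")
  if (any(dpf <= 0)) stop_invalid("`dpf` must be positive")
  if (any(distances <= 0)) stop_invalid("`distances` must be positive (cm)")
  dpf <- rep_len(dpf, 2L)
  d <- rep_len(distances, nrow(hbo))
  hbo_mm <- hbo * 1e-3  # uM -> mM
  hbr_mm <- hbr * 1e-3
  od <- lapply(1:2, function(w) {
    (extinction[w, 1] * hbo_mm + extinction[w, 2] * hbr_mm) * d * dpf[w]
  })
  out <- lapply(od, function(o) baseline_intensity * exp(-o))
  if (!all(vapply(out, function(m) all(is.finite(m) & m > 0), logical(1))))
    stop_invalid("concentrations produce non-positive or overflowed intensity")
  names(out) <- c("intensity_760", "intensity_850")
  out
}

#' Simulate a complete multi-subject cohort
#'
#' Draws one latent connectivity signature per subject, then synthesizes
#' `n_runs` runs per subject. Each run uses a jittered copy of the subject's
#' factor loadings (multiplicative Gaussian jitter, sd
#' `config$run_jitter_sd`) so same-subject runs are similar but not
#' identical. Modality `"fnirs_hb"` emits HbO/HbR/HbT concentration runs;
#' `"fmri_roi"` emits BOLD runs; `"fnirs_raw"` emits dual-wavelength
#' intensities with motion artifacts injected at the configured rates.
#' All randomness derives from `config$seed` by counter-based splitting, so
#' identical configs give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: list with `config`, `subjects`,
#'   `signatures` (per subject) and `runs` — `runs[[subject]][[run]]` is a
#'   named list of [ts_run()] objects keyed by contrast.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  signatures <- vector("list", config$n_subjects)
  runs <- vector("list", config$n_subjects)
  names(runs) <- subjects
  for (i in seq_len(config$n_subjects)) {
    sig <- generate_subject_signature(
      config$n_channels, config$signature_strength,
      seed = split_seed(config$seed, i), subject_id = subjects[i])
    signatures[[i]] <- sig
    subj_runs <- vector("list", config$n_runs)
    names(subj_runs) <- sprintf("r%02d", seq_len(config$n_runs))
    for (r in seq_len(config$n_runs)) {
      rseed <- split_seed(config$seed, i * 1000L + r)
      run_sig <- jitter_signature(sig, config$run_jitter_sd, rseed)
      subj_runs[[r]] <- build_run(run_sig, config, rseed,
                                  run_id = names(subj_runs)[r])
    }
    runs[[i]] <- subj_runs
  }
  names(signatures) <- subjects
  structure(list(config = config, subjects = subjects,
                 signatures = signatures, runs = runs),
            class = "cohort")
}

jitter_signature <- function(sig, jitter_sd, seed) {
  if (jitter_sd <= 0) return(sig)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(seed, 7919L))
  loadings <- sig$loadings *
    (1 + matrix(stats::rnorm(length(sig$loadings), sd = jitter_sd),
                nrow(sig$loadings)))
  out <- sig
  out$loadings <- loadings
  out$target_correlation <-
    signature_from_loadings(loadings, sig$delta, sig$strength)
  out
}

build_run <- function(run_sig, config, rseed, run_id) {
  base <- synthesize_run(run_sig, config, rseed, run_id = run_id,
                         contrast = if (config$modality == "fmri_roi")
                           "BOLD" else "HbO")
  if (config$modality == "fmri_roi") return(list(BOLD = base))
  hb <- hemoglobin_pair(base, seed = split_seed(rseed, 13L),
                        noise_sd = 0.3 * config$amplitude_sd)
  if (config$modality == "fnirs_hb") return(hb)
  raw <- to_raw_intensity(hb$HbO$data, hb$HbR$data)
  out <- lapply(names(raw), function(ctr) {
    r <- ts_run(raw[[ctr]], config$sampling_rate, base$subject_id, run_id,
                ctr, base$channel_ids)
    inject_motion_artifacts(r, config$spike_rate, config$shift_rate,
                            seed = split_seed(rseed, 17L))$run
  })
  names(out) <- names(raw)
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects x %d runs, %d channels, modality %s (seed %d)\n",
    x$config$n_subjects, x$config$n_runs, x$config$n_channels,
    x$config$modality, x$config$seed))
  invisible(x)
}
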