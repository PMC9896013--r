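# Shared fixtures, memoized so expensive cohorts are built once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small cohort for module-level tests: 6 subjects x 3 runs, 16 channels, 2 min.
small_cohort <- function() memo("small_cohort", function() {
  simulate_cohort(cohort_config(n_subjects = 6, n_runs = 3, duration = 120,
                                sampling_rate = 7.8, n_channels = 16,
                                seed = 301))
})

small_fcs <- function() memo("small_fcs", function() {
  cohort_fc(small_cohort(), "HbO", max_order = 10)$HbO
})

# Default stated-world fixture at full study scale (21 x 5 x 48); used by the
# acceptance suite. Built once (~30 s).
default_fcs <- function() memo("default_fcs", function() {
  cohort_fc(simulate_cohort(cohort_config(seed = 101)), "HbO")$HbO
})

# One channel of realistic optical density at 7.8 Hz: band-limited slow
# hemodynamics + cardiac pulsation + instrument noise.
od_channel <- function(n = 2808, fs = 7.8, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n), 2)
  slow <- bandpass(ts_run(x, fs), bandpass_spec())$data[1, ]
  slow <- slow / stats::sd(slow)
  tt <- (seq_len(n) - 1) / fs
  slow + 0.3 * sin(2 * pi * 1.1 * tt + stats::runif(1) * 2 * pi) +
    stats::rnorm(n, sd = 0.15)
}

od_run <- function(n_ch = 2, n = 2808, fs = 7.8, seed = 1) {
  ts_run(do.call(rbind, lapply(seq_len(n_ch), function(k)
    od_channel(n, fs, seed * 100 + k))), fs)
}

# Random correlation matrix (unit diagonal, SPD).
random_correlation <- function(n) stats::cov2cor(random_spd(n))

# Exact two-sided permutation p-value for the rank-sum statistic (midranks).
perm_pvalue <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  splits <- utils::combn(length(pool), n1)
  w_all <- colSums(matrix(r[splits], nrow = n1))
  mu <- n1 * (length(pool) + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

kurtosis <- function(v) mean(((v - mean(v)) / stats::sd(v))^4)

# Tiny hand-built raw-intensity cohort for QC tests: `bad` is a list per
# subject of per-run logical bad-channel vectors (TRUE = low SNR).
qc_cohort <- function(bad, n_samples = 50) {
  subjects <- sprintf("s%02d", seq_along(bad))
  runs <- lapply(seq_along(bad), function(i) {
    subj <- lapply(seq_along(bad[[i]]), function(r) {
      flags <- bad[[i]][[r]]
      set.seed(i * 100 + r)
      mk <- function() {
        dat <- do.call(rbind, lapply(seq_along(flags), function(c_idx) {
          # good channel: SNR 100; bad channel: SNR ~2
          if (flags[c_idx]) 100 + stats::rnorm(n_samples, sd = 50)
          else 1000 + stats::rnorm(n_samples, sd = 10)
        }))
        abs(dat) + 1
      }
      list(intensity_760 = ts_run(mk(), 7.8, subjects[i],
                                  sprintf("r%02d", r), "intensity_760"),
           intensity_850 = ts_run(mk(), 7.8, subjects[i],
                                  sprintf("r%02d", r), "intensity_850"))
    })
    names(subj) <- sprintf("r%02d", seq_along(bad[[i]]))
    subj
  })
  names(runs) <- subjects
  structure(list(config = NULL, subjects = subjects, runs = runs),
            class = "cohort")
}
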