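#' Construct an LFP recording container
#'
#' @param data Numeric array `channels x trials x time` (microvolts).
#' @param fs Sampling rate in Hz.
#' @param regions Per-channel region label.
#' @param events Named list of event times in seconds from trial start
#'   (e.g. `precue_on`, `cue_on`).
#' @param stim_triggers Optional vector of stimulation onset times (seconds,
#'   relative to trial start, applied to every stimulated trial).
#' @return Object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, regions,
                          events = list(precue_on = 0, cue_on = 1),
                          stim_triggers = NULL) {
  stopifnot(length(dim(data)) == 3, fs > 0,
            length(regions) == dim(data)[1])
  structure(list(data = data, fs = fs, regions = regions, events = events,
                 stim_triggers = stim_triggers),
            class = "lfp_recording")
}

## FFT analytic signal; the modulus is the instantaneous amplitude.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Remove electrical stimulation artifacts by linear interpolation
#'
#' Samples between 1.5 ms and 50 ms after each stimulation trigger are
#' replaced by the straight line joining the boundary samples.  Overlapping
#' windows are merged; triggers outside the trial window are ignored with a
#' warning.
#'
#' @param rec An [lfp_recording()].
#' @param triggers Trigger onset times (seconds from trial start).  Defaults
#'   to `rec$stim_triggers`.
#' @param window Interpolation window relative to each trigger, seconds
#'   (default `c(0.0015, 0.050)`).
#' @return The cleaned `lfp_recording`.
#' @export
remove_stim_artifacts <- function(rec, triggers = rec$stim_triggers,
                                  window = c(0.0015, 0.050)) {
  if (is.null(triggers) || length(triggers) == 0) return(rec)
  triggers <- sort(triggers)
  nt <- dim(rec$data)[3]
  dur <- nt / rec$fs
  outside <- triggers < 0 | triggers > dur
  if (any(outside)) {
    warning(sum(outside), " trigger(s) outside the recording ignored")
    triggers <- triggers[!outside]
  }
  if (length(triggers) == 0) return(rec)
  ## sample index windows, merged where overlapping
  i0 <- pmax(2L, floor((triggers + window[1]) * rec$fs) + 1L)
  i1 <- pmin(nt - 1L, ceiling((triggers + window[2]) * rec$fs) + 1L)
  keep <- i1 >= i0
  i0 <- i0[keep]; i1 <- i1[keep]
  if (length(i0) > 1) {
    merged0 <- i0[1]; merged1 <- i1[1]; m0 <- c(); m1 <- c()
    for (k in 2:length(i0)) {
      if (i0[k] <= merged1 + 1) merged1 <- max(merged1, i1[k])
      else { m0 <- c(m0, merged0); m1 <- c(m1, merged1)
             merged0 <- i0[k]; merged1 <- i1[k] }
    }
    i0 <- c(m0, merged0); i1 <- c(m1, merged1)
  }
  d <- rec$data
  for (ch in seq_len(dim(d)[1])) for (tr in seq_len(dim(d)[2])) {
    for (k in seq_along(i0)) {
      a <- i0[k] - 1L; b <- i1[k] + 1L
      d[ch, tr, i0[k]:i1[k]] <-
        d[ch, tr, a] + (d[ch, tr, b] - d[ch, tr, a]) *
        (seq.int(i0[k], i1[k]) - a) / (b - a)
    }
  }
  rec$data <- d
  rec
}

#' Local-average re-referencing
#'
#' Subtracts from each channel the mean signal of its electrode group,
#' removing shared noise and volume-conducted potentials.
#'
#' @param rec An [lfp_recording()].
#' @param groups Per-channel group label (default: the region label).
#' @return Re-referenced `lfp_recording`.
#' @export
rereference_local_average <- function(rec, groups = rec$regions) {
  stopifnot(length(groups) == dim(rec$data)[1])
  d <- rec$data
  for (g in unique(groups)) {
    ch <- which(groups == g)
    if (length(ch) == 1) {
      warning("singleton re-reference group '", g, "': channel becomes zero")
      d[ch, , ] <- 0
      next
    }
    m <- apply(d[ch, , , drop = FALSE], c(2, 3), mean)
    for (c1 in ch) d[c1, , ] <- d[c1, , ] - m
  }
  rec$data <- d
  rec
}

#' Anti-aliased downsampling
#'
#' Zero-phase (forward-reverse) 4th-order Butterworth low-pass at 0.45 times
#' the target rate, then decimation by `factor`.
#'
#' @param rec An [lfp_recording()].
#' @param factor Integer decimation factor (default 32).
#' @return Downsampled `lfp_recording`.
#' @export
downsample_lfp <- function(rec, factor = 32) {
  if (factor < 1) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1) return(rec)
  target <- rec$fs / factor
  bf <- signal::butter(4, 0.45 * target / (rec$fs / 2), type = "low")
  dims <- dim(rec$data)
  keep <- seq(1, dims[3], by = factor)
  out <- array(0, c(dims[1], dims[2], length(keep)))
  for (ch in seq_len(dims[1])) for (tr in seq_len(dims[2])) {
    out[ch, tr, ] <- signal::filtfilt(bf, rec$data[ch, tr, ])[keep]
  }
  rec$data <- out
  rec$fs <- target
  rec$events <- rec$events  # event times are in seconds, unchanged
  rec
}

#' Beta-band power time course
#'
#' Two extractors for instantaneous band power.  `"envelope"`: zero-phase
#' band-pass (default 13-30 Hz) then the difference between the upper and
#' lower signal envelopes, computed as twice the analytic-signal modulus.
#' `"squared_hanning"`: forward-only 4th-order band-pass (default 13-28 Hz),
#' squaring, and smoothing with a Hanning kernel 77 ms wide at half height.
#'
#' @param x Numeric vector, or matrix with trials in rows.
#' @param fs Sampling rate (Hz).
#' @param band Passband in Hz; defaults depend on `method`.
#' @param method `"envelope"` or `"squared_hanning"`.
#' @return Power trace(s), same shape as `x`.
#' @export
beta_power_timecourse <- function(x, fs,
                                  band = NULL,
                                  method = c("envelope", "squared_hanning")) {
  method <- match.arg(method)
  if (is.null(band)) band <- if (method == "envelope") c(13, 30) else c(13, 28)
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band must lie inside (0, fs/2)")
  if (is.matrix(x)) return(t(apply(x, 1, beta_power_timecourse,
                                   fs = fs, band = band, method = method)))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  if (method == "envelope") {
    xb <- signal::filtfilt(bf, x)
    2 * Mod(analytic_signal(xb))
  } else {
    xb <- signal::filter(bf, x)
    sq <- as.numeric(xb)^2
    ## Hanning kernel with full width at half maximum = 77 ms:
    ## for a Hanning window of length L the FWHM is L/2 samples.
    L <- max(3L, 2L * round(0.077 * fs))
    k <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
    k <- k / sum(k)
    sm <- as.numeric(stats::filter(sq, k, sides = 2, circular = FALSE))
    ## fill the filter's NA edges with the nearest valid values
    idx <- which(!is.na(sm))
    if (idx[1] > 1) sm[seq_len(idx[1] - 1)] <- sm[idx[1]]
    last <- idx[length(idx)]
    if (last < length(sm)) sm[(last + 1):length(sm)] <- sm[last]
    sm
  }
}

## Discrete prolate spheroidal sequences via the symmetric tridiagonal
## eigenproblem (Percival & Walden).  N: window length; NW: time-bandwidth
## product; k: number of tapers.  Columns are unit-energy tapers.
## For long windows the tapers are computed at a capped length and
## spline-interpolated (then re-orthonormalised): the sequences are smooth,
## so the approximation error is negligible for PSD estimation while the
## dense eigendecomposition stays O(N0^3).  Results are cached per
## (N, NW, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_exact <- function(N, NW, k) {
  W <- NW / N
  d <- ((N - 1 - 2 * (0:(N - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  M <- diag(d)
  M[cbind(1:(N - 1), 2:N)] <- e
  M[cbind(2:N, 1:(N - 1))] <- e
  eg <- eigen(M, symmetric = TRUE)
  eg$vectors[, seq_len(k), drop = FALSE]
}

dpss_tapers <- function(N, NW, k, max_exact = 1024L) {
  key <- paste(N, signif(NW, 10), k, sep = "_")
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  if (N <= max_exact) {
    tap <- dpss_exact(N, NW, k)
  } else {
    base <- dpss_exact(max_exact, NW, k)
    t0 <- seq(0, 1, length.out = max_exact)
    t1 <- seq(0, 1, length.out = N)
    tap <- apply(base, 2, function(v) stats::spline(t0, v, xout = t1)$y)
    tap <- qr.Q(qr(tap))                     # re-orthonormalise
  }
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  assign(key, tap, envir = .dpss_cache)
  tap
}

#' Multitaper power spectral density
#'
#' DPSS multitaper estimate with the package defaults matched to +/-2 Hz
#' spectral smoothing and 4 tapers on a 1.5 s window.  The DC component of
#' each window is removed before tapering.  Spectra are returned on a 1-Hz
#' grid (or finer if `df` is set) with a one-sided normalisation satisfying
#' Parseval: `sum(power) * df ~ var(x)`.
#'
#' @param x Numeric vector, or matrix with trials in rows (one window each).
#' @param fs Sampling rate (Hz).
#' @param halfbandwidth Spectral smoothing half-width in Hz (default 2).
#' @param n_tapers Number of tapers (default 4).
#' @param df Frequency resolution of the returned grid in Hz (default 1).
#' @param fmax Highest returned frequency (default `min(100, fs/2)`).
#' @return Object of class `mt_spectrum`: list with `freqs`, `power` (vector,
#'   or trials x freq matrix), and `taper_meta`.
#' @export
multitaper_spectrum <- function(x, fs, halfbandwidth = 2, n_tapers = 4,
                                df = 1, fmax = min(100, fs / 2)) {
  if (is.matrix(x)) {
    first <- multitaper_spectrum(x[1, ], fs, halfbandwidth, n_tapers, df, fmax)
    pow <- matrix(0, nrow(x), length(first$freqs))
    pow[1, ] <- first$power
    for (i in seq_len(nrow(x))[-1])
      pow[i, ] <- multitaper_spectrum(x[i, ], fs, halfbandwidth,
                                      n_tapers, df, fmax)$power
    first$power <- pow
    return(first)
  }
  N <- length(x)
  if (N < 8) stop("window too short")
  NW <- halfbandwidth * N / fs
  if (NW < 1) NW <- 1
  tap <- dpss_tapers(N, NW, n_tapers)
  x <- x - mean(x)
  ## zero-pad so that the FFT grid is a multiple of df
  nfft <- as.integer(ceiling(N / (fs / df)) * (fs / df))
  eig_spec <- matrix(0, nfft, n_tapers)
  for (j in seq_len(n_tapers)) {
    xt <- c(x * tap[, j], numeric(nfft - N))
    eig_spec[, j] <- Mod(stats::fft(xt))^2
  }
  ## one-sided PSD in units of variance per Hz (zero-padding leaves the
  ## discrete Parseval sum unchanged)
  psd_full <- rowMeans(eig_spec) / fs
  freqs_all <- (0:(nfft - 1)) * fs / nfft
  half <- freqs_all <= fs / 2
  psd <- psd_full[half] * 2
  psd[1] <- psd[1] / 2
  freqs <- freqs_all[half]
  sel <- freqs >= df - 1e-9 & freqs <= fmax + 1e-9 &
    abs(freqs / df - round(freqs / df)) < 1e-6
  structure(list(freqs = freqs[sel], power = psd[sel],
                 taper_meta = list(method = "dpss-multitaper",
                                   halfbandwidth = halfbandwidth,
                                   n_tapers = n_tapers, NW = NW),
                 window_s = N / fs),
            class = "mt_spectrum")
}

#' Fit an analytic pink-noise baseline
#'
#' Ordinary least squares of `log(power)` on `log(frequency)` yields the
#' `p = a * f^b` baseline.  The beta band is excluded from the fit range so a
#' genuine beta peak does not bias the background estimate.
#'
#' @param spec An `mt_spectrum` (vector power), or list with `freqs`, `power`.
#' @param fit_range Frequency range used for the fit (default `c(1, 100)`).
#' @param exclude_band Band excluded from the fit (default `c(13, 30)`);
#'   `NULL` to use every bin.
#' @return Object of class `pink_fit`: list with `a`, `b`, `baseline`
#'   (function of frequency), and `subtract(spec)` results via
#'   [subtract_baseline()].
#' @export
fit_pink_noise_baseline <- function(spec, fit_range = c(1, 100),
                                    exclude_band = c(13, 30)) {
  f <- spec$freqs
  p <- if (is.matrix(spec$power)) colMeans(spec$power) else spec$power
  use <- f >= fit_range[1] & f <= fit_range[2] & f > 0
  if (!is.null(exclude_band))
    use <- use & !(f >= exclude_band[1] & f <= exclude_band[2])
  if (any(p[use] <= 0)) stop("nonpositive power in fit range")
  ft <- stats::lsfit(log(f[use]), log(p[use]))
  a <- exp(ft$coefficients[1]); b <- unname(ft$coefficients[2])
  structure(list(a = unname(a), b = b,
                 baseline = function(freq) unname(a) * freq^b),
            class = "pink_fit")
}

#' Subtract a pink-noise baseline from a spectrum
#' @param spec An `mt_spectrum`.
#' @param fit A `pink_fit`.
#' @return The spectrum with `power` replaced by `power - a f^b`.
#' @export
subtract_baseline <- function(spec, fit) {
  base <- fit$baseline(spec$freqs)
  if (is.matrix(spec$power)) {
    spec$power <- sweep(spec$power, 2, base)
  } else spec$power <- spec$power - base
  spec
}

#' Detect beta oscillations and task-related channels
#'
#' `has_beta`: the cue- or precue-period power exceeds the analytic pink-noise
#' baseline in the 13-28 Hz band (one-sided t-test across trials per 1-Hz
#' bin, Bonferroni-corrected over the 25 bins spanning 5-30 Hz).
#' `task_related`: the cue and precue spectra differ (two-sided paired t-test
#' per bin, same correction).
#'
#' @param cue_spec,precue_spec `mt_spectrum` objects with per-trial power
#'   matrices (trials x freq).
#' @param beta_band Detection band (default `c(13, 28)`).
#' @param test_range Bonferroni range (default `c(5, 30)`, n = 25 bins).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `has_beta`, `task_related`, `pink_fit`, and per-bin
#'   p-values.
#' @export
detect_task_related <- function(cue_spec, precue_spec,
                                beta_band = c(13, 28),
                                test_range = c(5, 30), alpha = 0.05) {
  stopifnot(is.matrix(cue_spec$power), is.matrix(precue_spec$power))
  if (nrow(cue_spec$power) < 10) stop("insufficient data: need >= 10 trials")
  n_bins <- sum(cue_spec$freqs >= test_range[1] &
                  cue_spec$freqs <= test_range[2]) - 1
  if (n_bins < 1) n_bins <- 25
  alpha_c <- alpha / 25
  pool <- list(freqs = cue_spec$freqs,
               power = rbind(cue_spec$power, precue_spec$power))
  pf <- fit_pink_noise_baseline(pool)
  beta_idx <- which(cue_spec$freqs >= beta_band[1] &
                      cue_spec$freqs <= beta_band[2])
  p_beta <- vapply(beta_idx, function(i) {
    base <- pf$baseline(cue_spec$freqs[i])
    p1 <- tryCatch(stats::t.test(cue_spec$power[, i], mu = base,
                                 alternative = "greater")$p.value,
                   error = function(e) 1)
    p2 <- tryCatch(stats::t.test(precue_spec$power[, i], mu = base,
                                 alternative = "greater")$p.value,
                   error = function(e) 1)
    min(p1, p2)
  }, numeric(1))
  has_beta <- any(p_beta < alpha_c)
  test_idx <- which(cue_spec$freqs >= test_range[1] &
                      cue_spec$freqs <= test_range[2])
  paired <- nrow(cue_spec$power) == nrow(precue_spec$power)
  p_task <- vapply(test_idx, function(i) {
    tryCatch(stats::t.test(cue_spec$power[, i], precue_spec$power[, i],
                           paired = paired)$p.value,
             error = function(e) 1)
  }, numeric(1))
  task_related <- any(p_task < alpha_c)
  list(has_beta = has_beta, task_related = task_related, pink_fit = pf,
       p_beta = p_beta, p_task = p_task)
}

#' Beta response matrix of a channel
#'
#' Maps the per-trial decision-period mean beta power onto the decision
#' matrix, stacked and smoothed exactly as the behavioural decision matrix.
#'
#' @param power_per_trial Numeric vector, one mean power per trial.
#' @param trials Trial table aligned with `power_per_trial`.
#' @param task_related Logical; if `FALSE` the function refuses unless
#'   `force = TRUE`.
#' @param force Override the task-related gate.
#' @param smooth,n Smoothing window and grid size.
#' @return A `decision_matrix` with `quantity = "betaPower"`.
#' @export
beta_response_matrix <- function(power_per_trial, trials, task_related = TRUE,
                                 force = FALSE, smooth = 25, n = 100) {
  if (!task_related && !force)
    stop("channel not task-related; pass force = TRUE to override")
  stopifnot(length(power_per_trial) == nrow(trials))
  decision_matrix(trials, "betaPower", values = power_per_trial,
                  smooth = smooth, n = n)
}

#' Approach-avoidance tuning index of a channel
#'
#' The per-frequency difference between the mean cue-period spectrum on
#' approach trials and on avoidance trials, with per-bin two-sample t-tests
#' Bonferroni-corrected over bins.
#'
#' @param spec An `mt_spectrum` with per-trial power (trials x freq).
#' @param choices Character vector of `"AP"`/`"AV"` per trial.
#' @param alpha Family-wise level (default 0.05).
#' @return List with `freqs`, `index`, `p` (per bin), `sig` (Bonferroni).
#' @export
ap_av_tuning_index <- function(spec, choices, alpha = 0.05) {
  stopifnot(is.matrix(spec$power), length(choices) == nrow(spec$power))
  ap <- choices == "AP"; av <- choices == "AV"
  if (sum(ap) < 2 || sum(av) < 2) stop("both choices must be present")
  idx <- colMeans(spec$power[ap, , drop = FALSE]) -
    colMeans(spec$power[av, , drop = FALSE])
  p <- vapply(seq_along(spec$freqs), function(i) {
    tryCatch(stats::t.test(spec$power[ap, i], spec$power[av, i])$p.value,
             error = function(e) 1)
  }, numeric(1))
  list(freqs = spec$freqs, index = idx, p = p,
       sig = p < alpha / length(p))
}
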