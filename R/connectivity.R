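## Pooled least-squares fit of a d-variate VAR(p) across trials.
## trials: list of (time x d) matrices, demeaned per trial.
## Returns coefficient array A[d, d, p], innovation covariance Sigma, n_obs.
fit_var_pooled <- function(trials, p) {
  d <- ncol(trials[[1]])
  Y <- NULL; X <- NULL
  ylist <- list(); xlist <- list()
  for (k in seq_along(trials)) {
    z <- scale(trials[[k]], scale = FALSE)
    Tn <- nrow(z)
    if (Tn <= p + d) stop("trial too short for VAR order ", p)
    idx <- (p + 1):Tn
    ylist[[k]] <- z[idx, , drop = FALSE]
    xl <- lapply(seq_len(p), function(j) z[idx - j, , drop = FALSE])
    xlist[[k]] <- do.call(cbind, xl)
  }
  Y <- do.call(rbind, ylist)
  X <- do.call(rbind, xlist)
  fit <- stats::lm.fit(X, Y)
  B <- as.matrix(fit$coefficients)   # (d*p) x d
  res <- as.matrix(fit$residuals)
  n_obs <- nrow(Y)
  Sigma <- crossprod(res) / (n_obs - d * p)
  A <- array(0, c(d, d, p))
  for (j in seq_len(p)) {
    A[, , j] <- t(B[((j - 1) * d + 1):(j * d), , drop = FALSE])
  }
  ll <- -0.5 * n_obs * (d * log(2 * pi) +
                          determinant(Sigma, logarithm = TRUE)$modulus + d)
  ## per-observation BIC so orders with different effective sample sizes
  ## remain comparable
  bic <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
    (d * d * p) * log(n_obs) / n_obs
  list(A = A, Sigma = Sigma, n_obs = n_obs, loglik = as.numeric(ll), bic = bic)
}

## Select VAR order by BIC over 1..p_max.
select_var_order <- function(trials, p_max = 20) {
  best <- NULL; best_p <- 1L
  for (p in seq_len(p_max)) {
    f <- tryCatch(fit_var_pooled(trials, p), error = function(e) NULL)
    if (is.null(f)) break
    if (is.null(best) || f$bic < best$bic) { best <- f; best_p <- p }
  }
  if (is.null(best)) stop("could not fit any VAR order")
  list(fit = best, p = best_p)
}

## Spectral transfer function and spectral matrix of a fitted VAR at
## frequencies f (Hz).  Returns list of per-frequency lists (H, S).
var_spectral <- function(A, Sigma, fs, freqs) {
  d <- dim(A)[1]; p <- dim(A)[3]
  lapply(freqs, function(f) {
    Af <- diag(d) + 0i
    for (j in seq_len(p)) Af <- Af - A[, , j] * exp(-2i * pi * f * j / fs)
    H <- solve(Af)
    S <- H %*% Sigma %*% Conj(t(H))
    list(H = H, S = S)
  })
}

#' Frequency-domain (Geweke) Granger causality between two signals
#'
#' The parametric estimator fits a pooled bivariate VAR (order selected by
#' BIC) and evaluates Geweke's spectral decomposition
#' `GC_y->x(f) = ln( Sxx / (Sxx - (Syy.e - Sxy.e^2/Sxx.e) |Hxy|^2) )`,
#' where `S` is the model spectral matrix, `H` the transfer function and the
#' `.e` terms the innovation covariance.  The nonparametric estimator builds
#' the multitaper cross-spectral matrix and obtains `H` and the innovation
#' covariance by Wilson's spectral factorization.  Negative numerical values
#' are clipped to zero with a count in `n_clipped`.
#'
#' @param x,y Matrices (trials x time) of the two signals, trial-aligned.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies at which to evaluate (default `5:30` Hz).
#' @param estimator `"parametric_var"` or `"nonparametric_factorization"`.
#' @param order VAR order; `NULL` selects by BIC up to `order_max`.
#' @param order_max Maximum order scanned (default 20).
#' @return List with `freqs`, `gc_xy` (x drives y), `gc_yx`, `order`,
#'   `n_clipped`, and the fitted `Sigma`.
#' @export
spectral_granger <- function(x, y, fs, freqs = 5:30,
                             estimator = c("parametric_var",
                                           "nonparametric_factorization"),
                             order = NULL, order_max = 20) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (estimator == "parametric_var") {
    trials <- lapply(seq_len(nrow(x)), function(i) cbind(x[i, ], y[i, ]))
    if (is.null(order)) {
      sel <- select_var_order(trials, order_max)
      fit <- sel$fit; p <- sel$p
    } else {
      fit <- fit_var_pooled(trials, order); p <- order
    }
    if (max(Mod(eigen(companion_matrix(fit$A), only.values = TRUE)$values)) >= 1)
      stop("estimated VAR unstable; check data conditioning")
    sp <- var_spectral(fit$A, fit$Sigma, fs, freqs)
    Sg <- fit$Sigma
    gc <- geweke_from_spectra(sp, Sg)
    n_clip <- sum(gc$gc_xy < 0) + sum(gc$gc_yx < 0)
    list(freqs = freqs, gc_xy = pmax(gc$gc_xy, 0), gc_yx = pmax(gc$gc_yx, 0),
         order = p, n_clipped = n_clip, Sigma = Sg,
         estimator = estimator)
  } else {
    cs <- cross_spectral_matrix(x, y, fs)
    fac <- wilson_factorize(cs$S, cs$freqs, fs)
    sp <- lapply(seq_along(cs$freqs), function(i)
      list(H = fac$H[, , i], S = cs$S[, , i]))
    gc <- geweke_from_spectra(sp, fac$Sigma)
    sel <- unique(vapply(freqs, function(f) which.min(abs(cs$freqs - f)),
                         integer(1)))
    n_clip <- sum(gc$gc_xy[sel] < 0) + sum(gc$gc_yx[sel] < 0)
    list(freqs = cs$freqs[sel], gc_xy = pmax(gc$gc_xy[sel], 0),
         gc_yx = pmax(gc$gc_yx[sel], 0), order = NA_integer_,
         n_clipped = n_clip, Sigma = fac$Sigma, estimator = estimator)
  }
}

companion_matrix <- function(A) {
  d <- dim(A)[1]; p <- dim(A)[3]
  top <- do.call(cbind, lapply(seq_len(p), function(j) A[, , j]))
  if (p == 1) return(top)
  rbind(top, cbind(diag(d * (p - 1)), matrix(0, d * (p - 1), d)))
}

## Geweke pairwise GC from per-frequency (H, S) and innovation covariance.
geweke_from_spectra <- function(sp, Sigma) {
  gxy <- numeric(length(sp)); gyx <- numeric(length(sp))
  s11 <- Re(Sigma[1, 1]); s22 <- Re(Sigma[2, 2]); s12 <- Re(Sigma[1, 2])
  for (i in seq_along(sp)) {
    H <- sp[[i]]$H; S <- sp[[i]]$S
    Sxx <- Re(S[1, 1]); Syy <- Re(S[2, 2])
    ## y -> x: part of Sxx not explained by x's own innovations
    gyx[i] <- log(Sxx / Re(Sxx - (s22 - s12^2 / s11) * Mod(H[1, 2])^2))
    gxy[i] <- log(Syy / Re(Syy - (s11 - s12^2 / s22) * Mod(H[2, 1])^2))
  }
  list(gc_xy = gxy, gc_yx = gyx)
}

#' Time-domain Granger causality for a signal pair
#'
#' `GC_y->x = ln(var(x | past x) / var(x | past x, past y))`, estimated by
#' pooled AR and VAR fits of the given order.
#'
#' @param x,y Matrices (trials x time).
#' @param order Model order.
#' @return List with `gc_xy`, `gc_yx`.
#' @export
granger_time_domain <- function(x, y, order) {
  trials2 <- lapply(seq_len(nrow(x)), function(i) cbind(x[i, ], y[i, ]))
  full <- fit_var_pooled(trials2, order)
  redx <- fit_var_pooled(lapply(seq_len(nrow(x)),
                                function(i) cbind(x[i, ])), order)
  redy <- fit_var_pooled(lapply(seq_len(nrow(y)),
                                function(i) cbind(y[i, ])), order)
  list(gc_yx = log(redx$Sigma[1, 1] / full$Sigma[1, 1]),
       gc_xy = log(redy$Sigma[1, 1] / full$Sigma[2, 2]))
}

## Averaged multitaper auto- and cross-spectra for trial-matched signal pairs
## on the full FFT half-grid (needed for coherence and factorization).
cross_spectral_matrix <- function(x, y, fs, halfbandwidth = 2, n_tapers = 4) {
  N <- ncol(x)
  NW <- max(1, halfbandwidth * N / fs)
  tap <- dpss_tapers(N, NW, n_tapers)
  nfft <- 2L^ceiling(log2(N))
  nf <- nfft %/% 2 + 1L
  freqs <- (0:(nf - 1)) * fs / nfft
  Sxx <- numeric(nf); Syy <- numeric(nf); Sxy <- complex(nf)
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ] - mean(x[i, ]); yi <- y[i, ] - mean(y[i, ])
    for (j in seq_len(n_tapers)) {
      X <- stats::fft(c(xi * tap[, j], numeric(nfft - N)))[seq_len(nf)]
      Y <- stats::fft(c(yi * tap[, j], numeric(nfft - N)))[seq_len(nf)]
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + X * Conj(Y)
    }
  }
  m <- nrow(x) * n_tapers
  S <- array(0i, c(2, 2, nf))
  S[1, 1, ] <- Sxx / m; S[2, 2, ] <- Syy / m
  S[1, 2, ] <- Sxy / m; S[2, 1, ] <- Conj(Sxy) / m
  list(freqs = freqs, S = S, n_eff = m)
}

#' Magnitude-squared coherence spectrum
#'
#' Multitaper coherence `|Sxy|^2 / (Sxx Syy)` between two trial-matched
#' signals, reported over the requested band (default 5-30 Hz).
#'
#' @param x,y Matrices (trials x time).
#' @param fs Sampling rate (Hz).
#' @param band Frequency range returned (default `c(5, 30)`).
#' @param halfbandwidth,n_tapers Multitaper settings (+/-2 Hz, 4 tapers).
#' @return List with `freqs` and `coherence` in `[0, 1]`.
#' @export
coherence_spectrum <- function(x, y, fs, band = c(5, 30),
                               halfbandwidth = 2, n_tapers = 4) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (nrow(x) < 10) stop("unstable estimate: need >= 10 trials")
  cs <- cross_spectral_matrix(x, y, fs, halfbandwidth, n_tapers)
  coh <- Mod(cs$S[1, 2, ])^2 / (Re(cs$S[1, 1, ]) * Re(cs$S[2, 2, ]))
  sel <- cs$freqs >= band[1] & cs$freqs <= band[2]
  list(freqs = cs$freqs[sel], coherence = pmin(coh[sel], 1))
}

## Wilson's iterative spectral matrix factorization: S(f) = H Sigma H^* with
## H causal and minimum phase.  S: 2x2xnf on the half grid [0, fs/2].
wilson_factorize <- function(S, freqs, fs, max_iter = 100, tol = 1e-9) {
  nf <- dim(S)[3]
  nfft <- 2L * (nf - 1L)
  d <- dim(S)[1]
  ## Hermitian extension to the full circle
  Sf <- array(0i, c(d, d, nfft))
  Sf[, , seq_len(nf)] <- S
  for (k in 2:(nf - 1)) Sf[, , nfft - k + 2] <- Conj(S[, , k])
  ## initial psi: Cholesky of the mean spectrum, constant over frequency
  S0 <- matrix(0i, d, d)
  for (k in seq_len(nfft)) S0 <- S0 + Sf[, , k]
  S0 <- Re(S0) / nfft
  psi <- array(0i, c(d, d, nfft))
  ch <- chol(S0 + diag(1e-12, d))
  for (k in seq_len(nfft)) psi[, , k] <- t(ch)
  plusop <- function(g) {
    ## causal part: FFT each entry over frequency, zero negative lags,
    ## halve lag zero
    out <- array(0i, dim(g))
    for (a in seq_len(d)) for (b in seq_len(d)) {
      gk <- stats::fft(g[a, b, ], inverse = TRUE) / nfft   # lag coefficients
      gk[1] <- gk[1] / 2
      if (a == b) gk[1] <- Re(gk[1])
      gk[(nfft %/% 2 + 1):nfft] <- 0
      out[a, b, ] <- stats::fft(gk)
    }
    out
  }
  for (it in seq_len(max_iter)) {
    g <- array(0i, c(d, d, nfft))
    for (k in seq_len(nfft)) {
      ip <- solve(psi[, , k])
      g[, , k] <- ip %*% Sf[, , k] %*% Conj(t(ip)) + diag(d)
    }
    gp <- plusop(g)
    psi_new <- array(0i, c(d, d, nfft))
    for (k in seq_len(nfft)) psi_new[, , k] <- psi[, , k] %*% gp[, , k]
    err <- max(Mod(psi_new - psi))
    psi <- psi_new
    if (err < tol) break
  }
  ## A0 = lag-zero coefficient of psi
  A0 <- matrix(0i, d, d)
  for (a in seq_len(d)) for (b in seq_len(d)) {
    A0[a, b] <- sum(stats::fft(psi[a, b, ], inverse = TRUE) / nfft *
                      c(1, numeric(nfft - 1)))
  }
  Sigma <- Re(A0 %*% Conj(t(A0)))
  H <- array(0i, c(d, d, nf))
  iA0 <- solve(A0)
  for (k in seq_len(nf)) H[, , k] <- psi[, , k] %*% iA0
  list(H = H, Sigma = Sigma)
}

#' Band-averaged Granger causal influence
#'
#' Arithmetic mean of a GC spectrum over the in-band frequency bins.  Band
#' edges follow the half-open convention alpha = [5, 13), beta = [13, 30].
#'
#' @param gc Numeric GC values per frequency.
#' @param freqs Frequencies (Hz).
#' @param band `c(lo, hi)`; bins with `lo <= f < hi` are used, except the
#'   upper edge is included when `hi` is the overall band ceiling (30 Hz).
#' @return Scalar GCI.
#' @export
band_average_gci <- function(gc, freqs, band) {
  sel <- freqs >= band[1] & (freqs < band[2] | (band[2] >= 30 & freqs <= band[2]))
  if (!any(sel)) stop("empty band")
  mean(gc[sel])
}

#' Directional asymmetry index
#'
#' `DAI = (GC_y->x - GC_x->y) / (GC_y->x + GC_x->y)`, in `[-1, 1]`;
#' `NA` (flagged) where both GCs are zero.
#'
#' @param gc_xy,gc_yx Nonnegative GC values (vectors over frequency).
#' @return Numeric vector of DAI values (direction: y over x positive).
#' @export
dai <- function(gc_xy, gc_yx) {
  stopifnot(all(gc_xy >= 0), all(gc_yx >= 0))
  tot <- gc_xy + gc_yx
  out <- ifelse(tot > 0, (gc_yx - gc_xy) / tot, NA_real_)
  out
}

#' Connectivity between one channel pair
#'
#' Convenience wrapper computing coherence, bidirectional spectral GC,
#' band-averaged GCIs and the DAI spectrum for one channel pair.  The DAI is
#' oriented so that positive values mean net influence from channel `i`
#' (first signal) to channel `j`.
#'
#' @param x,y Matrices (trials x time); `x` is channel `i`, `y` channel `j`.
#' @param fs Sampling rate.
#' @param regions Length-2 character: regions of `i` and `j`.
#' @param freqs Analysis frequencies (default 5:30 Hz).
#' @param ... Passed to [spectral_granger()].
#' @return Object of class `connectivity_result`.
#' @export
pair_connectivity <- function(x, y, fs, regions = c("i", "j"),
                              freqs = 5:30, ...) {
  g <- spectral_granger(x, y, fs, freqs = freqs, ...)
  coh <- tryCatch(coherence_spectrum(x, y, fs, band = range(freqs)),
                  error = function(e) NULL)
  d <- dai(gc_xy = g$gc_yx, gc_yx = g$gc_xy)  # orient: positive = i -> j
  structure(list(regions = regions, freqs = g$freqs,
                 gc_ij = g$gc_xy, gc_ji = g$gc_yx,
                 dai = d, coherence = coh,
                 gci_alpha_ij = band_average_gci(g$gc_xy, g$freqs, c(5, 13)),
                 gci_beta_ij = band_average_gci(g$gc_xy, g$freqs, c(13, 30)),
                 gci_alpha_ji = band_average_gci(g$gc_yx, g$freqs, c(5, 13)),
                 gci_beta_ji = band_average_gci(g$gc_yx, g$freqs, c(13, 30)),
                 dai_alpha = band_average_gci(d, g$freqs, c(5, 13)),
                 dai_beta = band_average_gci(d, g$freqs, c(13, 30)),
                 order = g$order),
            class = "connectivity_result")
}

#' Summarise the directed network over region pairs
#'
#' For every ordered region pair, averages the DAI across contributing
#' channel pairs, tests the band-averaged DAI against zero (two-sided t-test
#' across channel pairs) and flags non-significant edges.  Per-frequency
#' t-tests are Bonferroni-corrected over the analysis bins.
#'
#' @param results List of `connectivity_result` objects.
#' @param band `c(lo, hi)` band to summarise (default beta, `c(13, 30)`).
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per ordered region pair present: mean DAI,
#'   SEM, n pairs, p-value, significance, direction.
#' @export
network_summary <- function(results, band = c(13, 30), alpha = 0.05) {
  key <- vapply(results, function(r) paste(sort(r$regions), collapse = "|"),
                character(1))
  out <- list()
  for (k in unique(key)) {
    rs <- results[key == k]
    regs <- sort(rs[[1]]$regions)
    vals <- vapply(rs, function(r) {
      v <- band_average_gci(r$dai, r$freqs, band)
      if (identical(r$regions, regs)) v else -v
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    n <- length(vals)
    mu <- mean(vals)
    if (n >= 2 && stats::sd(vals) > 0) {
      p <- stats::t.test(vals)$p.value
      s <- sem(vals)
    } else { p <- NA_real_; s <- NA_real_ }
    sig <- !is.na(p) && p < alpha
    out[[k]] <- data.frame(
      from = if (mu >= 0) regs[1] else regs[2],
      to = if (mu >= 0) regs[2] else regs[1],
      mean_dai = mu, sem = s, n_pairs = n, p = p, significant = sig)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contrast DAI between two blocks
#'
#' For matched channel pairs, computes the change in the band-averaged DAI
#' (block 2 minus block 1), tests the distribution of changes against zero,
#' and runs per-frequency t-tests with Bonferroni correction.
#'
#' @param results_a,results_b Lists of `connectivity_result` objects with
#'   identical pair ordering (e.g. Stim-off and Follow-up).
#' @param band Band for the scalar contrast (default `c(5, 30)`, the full
#'   alpha+beta range).
#' @param alpha Significance level.
#' @return List with `by_region_pair` (data frame of mean change, p, n) and
#'   `per_frequency` (matrix of Bonferroni-corrected significance).
#' @export
block_contrast <- function(results_a, results_b, band = c(5, 30),
                           alpha = 0.05) {
  if (length(results_a) != length(results_b))
    stop("pair mismatch between blocks")
  key <- vapply(results_a, function(r) paste(r$regions, collapse = "|"),
                character(1))
  keyb <- vapply(results_b, function(r) paste(r$regions, collapse = "|"),
                 character(1))
  if (!all(key == keyb)) stop("pair mismatch between blocks")
  delta <- vapply(seq_along(results_a), function(i) {
    band_average_gci(results_b[[i]]$dai, results_b[[i]]$freqs, band) -
      band_average_gci(results_a[[i]]$dai, results_a[[i]]$freqs, band)
  }, numeric(1))
  out <- list()
  for (k in unique(key)) {
    dv <- delta[key == k]
    dv <- dv[is.finite(dv)]
    n <- length(dv)
    if (n >= 2 && stats::sd(dv) > 0) p <- stats::t.test(dv)$p.value
    else p <- NA_real_
    out[[k]] <- data.frame(pair = k, mean_delta_dai = mean(dv), n_pairs = n,
                           p = p, significant = !is.na(p) && p < alpha)
  }
  freqs <- results_a[[1]]$freqs
  nb <- length(freqs)
  perf <- t(vapply(unique(key), function(k) {
    ia <- which(key == k)
    vapply(seq_len(nb), function(fi) {
      da <- vapply(ia, function(i)
        results_b[[i]]$dai[fi] - results_a[[i]]$dai[fi], numeric(1))
      da <- da[is.finite(da)]
      if (length(da) >= 2 && stats::sd(da) > 0)
        stats::t.test(da)$p.value < alpha / nb
      else NA
    }, logical(1))
  }, logical(nb)))
  colnames(perf) <- freqs
  res <- do.call(rbind, out); rownames(res) <- NULL
  list(by_region_pair = res, per_frequency = perf)
}

#' Time-domain Granger test between network and behaviour series
#'
#' Bivariate Granger F-tests in both directions between a connectivity
#' change series (e.g. windowed DAI) and a behaviour change series (windowed
#' avoidance rate), with the lag order selected by BIC up to `max_lag`.
#'
#' @param dai_series,av_series Equal-length numeric series (trial-window
#'   resolution).
#' @param max_lag Maximum lag order scanned (default 5).
#' @return Object of class `behavior_coupling`: lag used and, per direction,
#'   F statistic and p-value (`NA` with `degenerate = TRUE` for constant
#'   series).
#' @export
behavior_granger_test <- function(dai_series, av_series, max_lag = 5) {
  stopifnot(length(dai_series) == length(av_series))
  n <- length(dai_series)
  if (n <= 3 * max_lag) stop("series too short for max_lag ", max_lag)
  if (stats::sd(dai_series) == 0 || stats::sd(av_series) == 0) {
    return(structure(list(lag = NA_integer_, degenerate = TRUE,
                          p_dai_to_av = NA_real_, p_av_to_dai = NA_real_),
                     class = "behavior_coupling"))
  }
  one_dir <- function(cause, effect, p) {
    emb <- stats::embed(cbind(effect, cause), p + 1)
    yv <- emb[, 1]
    Xu <- emb[, -(1:2), drop = FALSE]           # lags of both series
    Xr <- Xu[, seq_len(p) * 2 - 1, drop = FALSE] # lags of effect only
    fu <- stats::lm(yv ~ Xu)
    fr <- stats::lm(yv ~ Xr)
    stats::anova(fr, fu)
  }
  ## lag by BIC of the unrestricted dai -> av model
  bics <- vapply(seq_len(max_lag), function(p) {
    emb <- stats::embed(cbind(av_series, dai_series), p + 1)
    stats::BIC(stats::lm(emb[, 1] ~ emb[, -(1:2)]))
  }, numeric(1))
  p <- which.min(bics)
  a1 <- one_dir(dai_series, av_series, p)
  a2 <- one_dir(av_series, dai_series, p)
  structure(list(lag = p, degenerate = FALSE,
                 F_dai_to_av = a1$F[2], p_dai_to_av = a1$`Pr(>F)`[2],
                 F_av_to_dai = a2$F[2], p_av_to_dai = a2$`Pr(>F)`[2]),
            class = "behavior_coupling")
}

#' Windowed change series for behaviour-network coupling
#'
#' Splits a session into consecutive non-overlapping trial windows and
#' returns each window's mean of `values`, referenced to the mean over the
#' reference block.
#'
#' @param values Per-trial numeric values (e.g. `choice == "AV"`).
#' @param blocks Per-trial block labels.
#' @param window Trials per window (default 50).
#' @param reference Reference block label (default `"off"`).
#' @return Data frame with `window`, `block` (majority label), `delta`.
#' @export
trial_window_series <- function(values, blocks, window = 50,
                                reference = "off") {
  stopifnot(length(values) == length(blocks))
  ref_mean <- mean(values[blocks == reference])
  n <- length(values)
  starts <- seq(1, n - window + 1, by = window)
  do.call(rbind, lapply(seq_along(starts), function(i) {
    idx <- starts[i]:(starts[i] + window - 1)
    data.frame(window = i,
               block = names(which.max(table(blocks[idx]))),
               delta = mean(values[idx]) - ref_mean)
  }))
}
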