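# Shared fixtures: small simulated datasets and independent oracles used
# across the test files.  All randomness is seeded.

# Bivariate VAR(1) reference system: x_t = 0.5 x_{t-1} + e_t,
# y_t = 0.5 y_{t-1} + 0.4 x_{t-1} + n_t, unit innovations.
gen_var1_pair <- function(n_trials, n_time, seed, burn = 50) {
  set.seed(seed)
  X <- matrix(0, n_trials, n_time)
  Y <- matrix(0, n_trials, n_time)
  for (i in seq_len(n_trials)) {
    x <- numeric(n_time + burn); y <- numeric(n_time + burn)
    e <- rnorm(n_time + burn); u <- rnorm(n_time + burn)
    for (t in 2:(n_time + burn)) {
      x[t] <- 0.5 * x[t - 1] + e[t]
      y[t] <- 0.5 * y[t - 1] + 0.4 * x[t - 1] + u[t]
    }
    X[i, ] <- x[-(1:burn)]
    Y[i, ] <- y[-(1:burn)]
  }
  list(x = X, y = Y)
}

# Analytic time-domain Granger causality x -> y for the reference system,
# via Kolmogorov's formula applied to y's known univariate spectrum:
# (1 - 0.5 L) y = 0.4 L x + n  with  (1 - 0.5 L) x = e, so
# Sy(w) = 0.16 / |1 - 0.5 e^{-iw}|^4 + 1 / |1 - 0.5 e^{-iw}|^2.
analytic_gc_xy <- function(n_grid = 20000) {
  om <- seq(0, pi, length.out = n_grid + 1)[-1]
  A <- abs(1 - 0.5 * exp(-1i * om))^2
  Sy <- 0.16 / A^2 + 1 / A
  ## reduced innovation variance / full innovation variance (= 1)
  mean(log(Sy))
}

# Analytic spectral GC x -> y at angular frequency w for the same system:
# ln(1 + 0.16 / |1 - 0.5 e^{-iw}|^2).
analytic_gc_xy_spectral <- function(freqs_hz, fs) {
  om <- 2 * pi * freqs_hz / fs
  A <- abs(1 - 0.5 * exp(-1i * om))^2
  log(1 + 0.16 / A)
}

# Brute-force windowed 2x2 Fisher oracle for stim_effect, by direct
# enumeration over trials at every grid point.
brute_force_stim_masks <- function(tr_off, tr_on, n, smooth, alpha = 0.05) {
  half <- (smooth - 1) %/% 2
  cell <- function(v) pmin(n, floor(v * n) + 1L)
  count_win <- function(tr, i, j) {
    tr <- tr[tr$choice %in% c("AP", "AV"), ]
    cx <- cell(tr$x); cy <- cell(tr$y)
    inwin <- abs(cx - i) <= half & abs(cy - j) <= half
    c(av = sum(inwin & tr$choice == "AV"), tot = sum(inwin))
  }
  mask_av <- matrix(FALSE, n, n); mask_ap <- matrix(FALSE, n, n)
  p_grid <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- count_win(tr_off, i, j); b <- count_win(tr_on, i, j)
    if (a["tot"] == 0 || b["tot"] == 0) next
    m <- matrix(c(a["av"], a["tot"] - a["av"], b["av"], b["tot"] - b["av"]),
                2, byrow = TRUE)
    p <- stats::fisher.test(m)$p.value
    p_grid[i, j] <- p
    if (p < alpha) {
      f_off <- a["av"] / a["tot"]; f_on <- b["av"] / b["tot"]
      if (f_on > f_off) mask_av[i, j] <- TRUE
      if (f_on < f_off) mask_ap[i, j] <- TRUE
    }
  }
  list(mask_av_up = mask_av, mask_ap_up = mask_ap, p_grid = p_grid)
}

# Quick two-block session with a given airpuff-weight scaling in block 2.
two_block_session <- function(n_per_block = 250, b_scale = 1, seed = 1) {
  simulate_session(synth_behavior_config(
    n_trials_per_block = n_per_block,
    blocks = c("off", "on"),
    logit_params = list(off = c(a = 6, b = -8, c = -1),
                        on = c(a = 6, b = -8 * b_scale, c = -1)),
    repeat_of = c(on = "off"),
    omission_rate = 0,
    seed = seed))
}
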