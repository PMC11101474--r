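## 1/f^|exponent| noise by spectral shaping of white noise.
pink_noise <- function(n, exponent = -1, seed = NULL) {
  with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)               # symmetric frequency index
    shape <- f^(exponent / 2)
    shape[1] <- 0                          # no DC
    x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
    x / stats::sd(x)
  })
}

#' Configuration for the synthetic LFP network
#'
#' The generator models each region's signal as a beta-resonant AR(2) process
#' (poles at `beta_freq` with modulus `ar_radius`) embedded in a first-order
#' vector-autoregressive network with directed lagged coupling, plus 1/f
#' background noise.  Per-trial beta amplitude on designated channels is
#' scaled by `g0 + g_utility * Eutil(trial)`, creating utility-tuned (P/N
#' type) beta responses.  Stimulation is modelled as a block-wise change of
#' the coupling gains (by default a reduction of the top-down gains).
#'
#' @param regions Ordered region labels.
#' @param fs Sampling rate (Hz; default 250, ample for the 5-30 Hz band).
#' @param trial_window `c(precue_s, cue_s)` seconds.
#' @param beta_freq Resonance frequency (Hz).
#' @param ar_radius Pole modulus per region (0 < radius < 1).
#' @param coupling Named list (one entry per block) of `R x R` matrices;
#'   `coupling[[blk]][i, j]` is the lag-1 gain from region `j` to region `i`.
#' @param pink_exponent,pink_gain 1/f background shape and amplitude.
#' @param response_gain Per-channel list of `c(g0, g_utility)`.
#' @param seed Integer master seed.
#' @return Object of class `synth_lfp_config`.
#' @export
synth_lfp_config <- function(regions = c("dlPFC", "pACC", "sgACC", "striatum"),
                             fs = 250,
                             trial_window = c(precue_s = 1.0, cue_s = 1.5),
                             beta_freq = 20,
                             ar_radius = 0.85,
                             coupling = NULL,
                             pink_exponent = -1,
                             pink_gain = 0.5,
                             response_gain = NULL,
                             seed = 1L) {
  R <- length(regions)
  if (fs <= 2 * 30) stop("fs must exceed 60 Hz (Nyquist for the 5-30 Hz band)")
  ar_radius <- rep_len(ar_radius, R)
  if (any(ar_radius <= 0 | ar_radius >= 1))
    stop("ar_radius must lie in (0, 1) for stationarity")
  if (is.null(coupling)) {
    ## default hierarchy dlPFC -> pACC -> sgACC -> striatum (+ direct
    ## dlPFC -> striatum) with weak reciprocal feedback: without any
    ## bottom-up gain the directional asymmetry saturates at 1 and becomes
    ## insensitive to the top-down gain, so no stimulation effect on DAI
    ## could exist.  Stimulated blocks halve the top-down gains and
    ## moderately strengthen the bottom-up gains, reproducing the observed
    ## combination of reduced feedback and enhanced feedforward influence.
    C_off <- matrix(0, R, R, dimnames = list(regions, regions))
    chain <- cbind(2:R, 1:(R - 1))
    C_off[chain] <- 0.2
    if (R >= 4) C_off[R, 1] <- 0.12
    C_off[cbind(1:(R - 1), 2:R)] <- 0.05          # adjacent feedback
    if (R >= 4) C_off[1, R] <- 0.03               # weak striatal feedback
    C_stim <- C_off
    td <- lower.tri(C_stim) & C_stim > 0
    bu <- upper.tri(C_stim) & C_stim > 0
    C_stim[td] <- C_stim[td] * 0.5
    C_stim[bu] <- C_stim[bu] * 1.5
    coupling <- list(off = C_off, on = C_stim, follow = C_stim)
  }
  if (is.null(response_gain)) {
    response_gain <- rep(list(c(g0 = 1, g_utility = 0.4)), R)
  }
  cfg <- structure(list(regions = regions, fs = fs,
                        trial_window = trial_window, beta_freq = beta_freq,
                        ar_radius = ar_radius, coupling = coupling,
                        pink_exponent = pink_exponent, pink_gain = pink_gain,
                        response_gain = response_gain, seed = as.integer(seed)),
                   class = "synth_lfp_config")
  for (blk in names(coupling)) {
    sr <- var_spectral_radius(cfg, coupling[[blk]])
    if (sr >= 1)
      stop("unstable VAR in block '", blk, "': companion spectral radius ",
           signif(sr, 4))
  }
  cfg
}

## Spectral radius of the companion matrix of the generating VAR(2).
var_spectral_radius <- function(cfg, C) {
  R <- length(cfg$regions)
  theta <- 2 * pi * cfg$beta_freq / cfg$fs
  a1 <- 2 * cfg$ar_radius * cos(theta)
  a2 <- -cfg$ar_radius^2
  A1 <- diag(a1, R) + C
  A2 <- diag(a2, R)
  comp <- rbind(cbind(A1, A2), cbind(diag(R), matrix(0, R, R)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a coupled oscillatory LFP network for a session
#'
#' For every trial, generates the regional VAR(2) network of
#' [synth_lfp_config()] with the coupling matrix of the trial's block, scales
#' the oscillatory component by the channel's utility gain, and adds 1/f
#' background noise.
#'
#' @param lcfg A [synth_lfp_config()].
#' @param session Trial table from [simulate_session()] (its `ground_truth`
#'   attribute provides the per-block logit parameters used to compute the
#'   trial's expected utility).
#' @return An [lfp_recording()] with one channel per region and events
#'   `precue_on = 0`, `cue_on = precue_s`.
#' @export
simulate_lfp_network <- function(lcfg, session) {
  R <- length(lcfg$regions)
  fs <- lcfg$fs
  nt <- as.integer(round(sum(lcfg$trial_window) * fs))
  ntrial <- nrow(session)
  theta <- 2 * pi * lcfg$beta_freq / fs
  a1 <- 2 * lcfg$ar_radius * cos(theta)
  a2 <- -lcfg$ar_radius^2
  gt <- attr(session, "ground_truth")
  ## per-trial expected utility (ChV under the block's generating model),
  ## standardised across the session
  eut <- numeric(ntrial)
  for (blk in unique(session$block)) {
    rows <- session$block == blk
    pr <- if (!is.null(gt) && blk %in% names(gt)) gt[[blk]] else c(6, -8, -1)
    f <- pr[1] * session$x[rows] + pr[2] * session$y[rows] + pr[3]
    p <- stats::plogis(f)
    eut[rows] <- p * (pr[1] * session$x[rows] + pr[2] * session$y[rows]) +
      (1 - p) * (-pr[3])
  }
  eut_z <- as.numeric(scale(eut))
  data <- array(0, c(R, ntrial, nt))
  burn <- 50L
  for (tr in seq_len(ntrial)) {
    blk <- session$block[tr]
    C <- lcfg$coupling[[blk]]
    if (is.null(C)) C <- lcfg$coupling[[1]]
    A1 <- diag(a1, R) + C
    z <- with_seed(split_seed(lcfg$seed, tr), {
      e <- matrix(stats::rnorm(R * (nt + burn)), R)
      zz <- matrix(0, R, nt + burn)
      for (t in 3:(nt + burn)) {
        zz[, t] <- A1 %*% zz[, t - 1] + a2 * zz[, t - 2] + e[, t]
      }
      zz[, (burn + 1):(nt + burn), drop = FALSE]
    })
    for (r in seq_len(R)) {
      g <- lcfg$response_gain[[r]]
      amp <- max(0.05, g[1] + g[2] * eut_z[tr])
      pk <- pink_noise(nt, lcfg$pink_exponent,
                       seed = split_seed(lcfg$seed, 100000L + tr * R + r))
      data[r, tr, ] <- amp * z[r, ] + lcfg$pink_gain * pk
    }
  }
  lfp_recording(data, fs, lcfg$regions,
                events = list(precue_on = 0,
                              cue_on = unname(lcfg$trial_window[1])))
}

#' Generate synthetic beta-response archetypes
#'
#' Builds noisy copies of template beta-response matrices over the decision
#' grid: `P` (power rising with expected utility), `N` (falling), a
#' low-airpuff band, a decision-boundary band, and a reward-extremes band.
#' Ground-truth labels are retained for cluster-recovery tests.
#'
#' @param templates Character subset of
#'   `c("P", "N", "low_airpuff", "boundary", "reward_extremes")`.
#' @param n_per_template Matrices per template.
#' @param noise_sd I.i.d. Gaussian noise added per cell (templates are
#'   z-scored, so this is in template-SD units).
#' @param seed Integer seed.
#' @param n_grid Grid size per axis (default 100).
#' @param params Logit parameters defining the utility surface.
#' @return List with `matrices` (list of `n_grid x n_grid`), `labels`,
#'   `templates` (the noise-free prototypes).
#' @export
gen_beta_response_archetypes <- function(templates = c("P", "N", "low_airpuff",
                                                       "boundary",
                                                       "reward_extremes"),
                                         n_per_template = 40, noise_sd = 0.5,
                                         seed = 1L, n_grid = 100,
                                         params = c(6, -8, -1)) {
  cvm <- choice_value_map(params, n = n_grid)
  g <- grid_centers(n_grid)
  x <- matrix(g, n_grid, n_grid)
  y <- matrix(g, n_grid, n_grid, byrow = TRUE)
  f <- params[1] * x + params[2] * y + params[3]
  zsc <- function(m) (m - mean(m)) / stats::sd(m)
  protos <- list(
    P = zsc(cvm$chv),
    N = zsc(-cvm$chv),
    low_airpuff = zsc(exp(-((y - 0.1) / 0.15)^2)),
    boundary = zsc(exp(-f^2 / 2)),
    reward_extremes = zsc((x - 0.5)^2))
  protos <- protos[templates]
  mats <- list(); labels <- character(0)
  k <- 0L
  for (nm in names(protos)) {
    for (i in seq_len(n_per_template)) {
      k <- k + 1L
      mats[[k]] <- protos[[nm]] +
        with_seed(split_seed(seed, k),
                  matrix(stats::rnorm(n_grid * n_grid, 0, noise_sd),
                         n_grid, n_grid))
      labels <- c(labels, nm)
    }
  }
  list(matrices = mats, labels = labels, templates = protos)
}
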