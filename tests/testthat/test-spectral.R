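make_rec <- function(data, fs, regions = paste0("r", seq_len(dim(data)[1]))) {
  lfp_recording(data, fs, regions)
}

test_that("artifact interpolation is exact and a no-op without triggers", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * tt)
  d <- array(x, c(1, 1, length(x)))
  rec <- make_rec(d, fs)
  expect_identical(remove_stim_artifacts(rec, NULL)$data, rec$data)

  ## inject a spike artifact at 0.5 s inside the interpolation window
  d2 <- d
  spike_idx <- round((0.5 + 0.01) * fs)
  d2[1, 1, spike_idx + (0:5)] <- 40
  rec2 <- make_rec(d2, fs)
  cleaned <- remove_stim_artifacts(rec2, triggers = 0.5)
  i0 <- floor((0.5 + 0.0015) * fs) + 1; i1 <- ceiling((0.5 + 0.05) * fs) + 1
  seg <- cleaned$data[1, 1, i0:i1]
  ## exactly the straight line between the boundary samples
  a <- cleaned$data[1, 1, i0 - 1]; b <- cleaned$data[1, 1, i1 + 1]
  lin <- a + (b - a) * seq_len(i1 - i0 + 1) / (i1 - i0 + 2)
  expect_equal(seg, lin, tolerance = 1e-12)
  expect_warning(remove_stim_artifacts(rec2, triggers = 99), "ignored")
})

test_that("artifact cleaning restores beta power of a contaminated sinusoid", {
  fs <- 1000
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * tt)
  xa <- x
  trig <- 0.9              # one stimulation train onset in the trial
  for (tg in trig) {
    idx <- round((tg + 0.005) * fs):round((tg + 0.03) * fs)
    xa[idx] <- xa[idx] + 30
  }
  rec <- remove_stim_artifacts(make_rec(array(xa, c(1, 1, length(xa))), fs),
                               triggers = trig)
  p_clean <- mean(beta_power_timecourse(rec$data[1, 1, ], fs)[200:1800])
  p_true <- mean(beta_power_timecourse(x, fs)[200:1800])
  expect_lt(abs(p_clean - p_true) / p_true, 0.05)
})

test_that("local-average re-referencing removes shared signals", {
  set.seed(71)
  fs <- 250
  base <- array(rnorm(3 * 4 * 500), c(3, 4, 500))
  common <- matrix(rnorm(4 * 500), 4, 500)
  withc <- base
  for (ch in 1:3) withc[ch, , ] <- withc[ch, , ] + common
  r1 <- rereference_local_average(make_rec(base, fs, rep("g1", 3)))
  r2 <- rereference_local_average(make_rec(withc, fs, rep("g1", 3)))
  expect_equal(r1$data, r2$data, tolerance = 1e-10)

  ## two-channel group: outputs are +/- half the difference
  two <- array(rnorm(2 * 1 * 100), c(2, 1, 100))
  rr <- rereference_local_average(make_rec(two, fs, c("g", "g")))
  expect_equal(rr$data[1, 1, ], (two[1, 1, ] - two[2, 1, ]) / 2,
               tolerance = 1e-12)
  expect_equal(rr$data[1, 1, ], -rr$data[2, 1, ], tolerance = 1e-12)

  three <- array(rnorm(3 * 1 * 100), c(3, 1, 100))
  expect_warning(rereference_local_average(make_rec(three, fs,
                                                    c("a", "a", "b"))),
                 "singleton")
})

test_that("re-referenced independent channels show the -1/(G-1) correlation", {
  set.seed(72)
  G <- 5
  d <- array(rnorm(G * 1 * 20000), c(G, 1, 20000))
  rr <- rereference_local_average(make_rec(d, 250, rep("g", G)))
  cors <- cor(t(rr$data[, 1, ]))
  off <- cors[upper.tri(cors)]
  expect_lt(abs(mean(off) - (-1 / (G - 1))), 0.03)
})

test_that("downsampling preserves the passband and attenuates the stopband", {
  fs <- 8000; factor <- 32          # target 250 Hz, cutoff 112.5 Hz
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mk <- function(f) make_rec(array(sin(2 * pi * f * tt), c(1, 1, length(tt))), fs)
  ds20 <- downsample_lfp(mk(20), factor)
  expect_equal(ds20$fs, 250)
  amp <- (max(ds20$data[1, 1, 100:800]) - min(ds20$data[1, 1, 100:800])) / 2
  expect_lt(abs(amp - 1), 0.01)
  ## stopband tone: > 20 dB down
  ds_hi <- downsample_lfp(mk(200), factor)
  expect_lt(sd(ds_hi$data[1, 1, 100:800]) / (1 / sqrt(2)), 10^(-20 / 20))
  ## DC unchanged
  dc <- downsample_lfp(make_rec(array(1, c(1, 1, length(tt))), fs), factor)
  n_dc <- dim(dc$data)[3]
  expect_equal(mean(dc$data[1, 1, 50:(n_dc - 50)]), 1, tolerance = 1e-6)
  expect_error(downsample_lfp(mk(20), 0), "factor")
})

test_that("envelope power of a pure tone equals twice its amplitude", {
  fs <- 250
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  for (A in c(1, 2.5)) {
    env <- beta_power_timecourse(A * sin(2 * pi * 20 * tt), fs)
    mid <- env[100:(length(env) - 100)]
    expect_lt(max(abs(mid - 2 * A)) / (2 * A), 0.02)
  }
})

test_that("extracted power tracks an amplitude modulator", {
  fs <- 250
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  modu <- 1 + 0.8 * sin(2 * pi * 1 * tt)
  x <- modu * sin(2 * pi * 20 * tt)
  env <- beta_power_timecourse(x, fs)
  sel <- 150:(length(tt) - 150)
  expect_gt(cor(env[sel], modu[sel]), 0.95)
})

test_that("the two power extractors agree in rank on band-limited signals", {
  set.seed(73)
  fs <- 250
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  n <- 30
  gains <- runif(n, 0.5, 3)
  mean_env <- numeric(n); mean_sq <- numeric(n)
  for (i in 1:n) {
    x <- gains[i] * sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi)) + rnorm(length(tt), 0, 0.3)
    mean_env[i] <- mean(beta_power_timecourse(x, fs, method = "envelope"))
    mean_sq[i] <- mean(beta_power_timecourse(x, fs, method = "squared_hanning"))
  }
  expect_gt(cor(mean_env, mean_sq, method = "spearman"), 0.8)
})

test_that("white-noise envelope power has no systematic within-trial trend", {
  ## the envelope is strongly autocorrelated, so per-trial slope p-values are
  ## anticonservative; instead test that slopes across seeds centre on zero
  set.seed(74)
  fs <- 250
  slopes <- sapply(1:25, function(i) {
    x <- rnorm(1000)
    env <- beta_power_timecourse(x, fs)
    sel <- 100:900
    unname(coef(lm(env[sel] ~ seq_along(sel)))[2])
  })
  expect_gt(t.test(slopes)$p.value, 0.05)
})

test_that("multitaper spectrum satisfies Parseval and localises tones", {
  set.seed(75)
  x <- rnorm(1000)
  sp <- multitaper_spectrum(x, fs = 250, fmax = 125)
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$freqs) > 0))
  expect_lt(abs(sum(sp$power) - var(x)) / var(x), 0.05)

  tone <- sin(2 * pi * 20 * seq(0, 1.5, by = 1 / 250))
  spt <- multitaper_spectrum(tone, fs = 250)
  expect_lte(abs(spt$freqs[which.max(spt$power)] - 20), 2)

  ## disjoint windows of a stationary process agree within chi-square bars:
  ## 2 K m estimates per bin -> ratio bounded by F quantiles
  y <- rnorm(4000)
  s1 <- multitaper_spectrum(matrix(y[1:2000], 5, 400, byrow = TRUE), 250)
  s2 <- multitaper_spectrum(matrix(y[2001:4000], 5, 400, byrow = TRUE), 250)
  m1 <- colMeans(s1$power); m2 <- colMeans(s2$power)
  dof <- 2 * 4 * 5
  ratio <- m1 / m2
  inside <- ratio > qf(0.025, dof, dof) & ratio < qf(0.975, dof, dof)
  expect_gt(mean(inside), 0.9)
})

test_that("pink-noise baseline fit is exact on power-law input and null on white", {
  pf <- fit_pink_noise_baseline(list(freqs = 1:100, power = 2 * (1:100)^-1))
  expect_equal(pf$a, 2, tolerance = 1e-10)
  expect_equal(pf$b, -1, tolerance = 1e-10)

  set.seed(76)
  bs <- sapply(1:20, function(i) {
    sp <- multitaper_spectrum(rnorm(5000), fs = 250, fmax = 100)
    fit_pink_noise_baseline(sp)$b
  })
  expect_lt(abs(mean(bs)), 0.1)

  ## simulated 1/f noise recovers the exponent
  bp <- sapply(1:20, function(i) {
    x <- fcsnet:::pink_noise(8192, -1, seed = 100 + i)
    fit_pink_noise_baseline(multitaper_spectrum(x, fs = 250, fmax = 100),
                            fit_range = c(2, 100))$b
  })
  expect_gt(mean(bp), -1.25)
  expect_lt(mean(bp), -0.75)
  expect_error(fit_pink_noise_baseline(list(freqs = 1:10, power = rep(-1, 10))),
               "nonpositive")
})

test_that("baseline subtraction leaves a genuine beta peak in place", {
  set.seed(77)
  fs <- 250
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sapply(1:20, function(i)
    fcsnet:::pink_noise(length(tt), -1, seed = i) +
      0.8 * sin(2 * pi * 20 * tt + runif(1, 0, 6)))
  sp <- multitaper_spectrum(t(x), fs)
  pm <- colMeans(sp$power)
  pf <- fit_pink_noise_baseline(list(freqs = sp$freqs, power = pm))
  corrected <- pm - pf$baseline(sp$freqs)
  sel <- sp$freqs >= 10 & sp$freqs <= 35
  f_raw <- sp$freqs[sel][which.max(pm[sel])]
  f_cor <- sp$freqs[sel][which.max(corrected[sel])]
  expect_equal(f_raw, f_cor)
})

test_that("task-related detection controls type I error and has power", {
  fs <- 250
  tt <- seq(0, 1.5 - 1 / fs, by = 1 / fs)
  n_tr <- 60
  spec_of <- function(burst, seed) {
    set.seed(seed)
    m <- t(sapply(seq_len(n_tr), function(i) {
      x <- fcsnet:::pink_noise(length(tt), -1, seed = seed * 1000 + i)
      if (burst) x <- x + 0.9 * sin(2 * pi * 20 * tt + runif(1, 0, 6))
      x
    }))
    multitaper_spectrum(m, fs)
  }
  null_flags <- sapply(1:10, function(s)
    detect_task_related(spec_of(FALSE, 2 * s), spec_of(FALSE, 2 * s + 1))$task_related)
  expect_lte(mean(null_flags), 0.2)
  hit_flags <- sapply(1:10, function(s) {
    d <- detect_task_related(spec_of(TRUE, 100 + 2 * s), spec_of(FALSE, 101 + 2 * s))
    c(d$task_related, d$has_beta)
  })
  expect_gte(mean(hit_flags[1, ]), 0.9)
  expect_gte(mean(hit_flags[2, ]), 0.9)
  ## pure pink noise rarely flags a beta oscillation
  pp <- sapply(1:10, function(s)
    detect_task_related(spec_of(FALSE, 300 + 2 * s),
                        spec_of(FALSE, 301 + 2 * s))$has_beta)
  expect_lte(mean(pp), 0.2)
  expect_error(detect_task_related(
    multitaper_spectrum(matrix(rnorm(5 * 375), 5), 250),
    multitaper_spectrum(matrix(rnorm(5 * 375), 5), 250)), "insufficient")
})

test_that("beta response matrix inherits stacking conservation", {
  ses <- two_block_session(100, seed = 81)
  off <- ses[ses$block == "off", ]
  pw <- rep(3, nrow(off))
  brm <- beta_response_matrix(pw, off)
  expect_true(all(abs(brm$grid[!is.na(brm$grid)] - 3) < 1e-12))
  expect_equal(sum(brm$counts), nrow(off))
  expect_error(beta_response_matrix(pw, off, task_related = FALSE),
               "task-related")
})

test_that("tuning index is antisymmetric and detects choice-locked power", {
  set.seed(82)
  n_tr <- 200; fs <- 250
  tt <- seq(0, 1.5 - 1 / fs, by = 1 / fs)
  choices <- rep(c("AP", "AV"), each = n_tr / 2)
  mk <- function(boost) {
    t(sapply(seq_len(n_tr), function(i) {
      g <- if (choices[i] == "AP") 1 + boost else 1
      g * sin(2 * pi * 20 * tt + runif(1, 0, 6)) + rnorm(length(tt), 0, 1)
    }))
  }
  sp <- multitaper_spectrum(mk(0.2), fs)
  ti <- ap_av_tuning_index(sp, choices)
  beta_sel <- ti$freqs >= 15 & ti$freqs <= 25
  expect_true(any(ti$sig[beta_sel]))
  expect_gt(mean(ti$index[beta_sel]), 0)
  ## antisymmetry
  ti_rev <- ap_av_tuning_index(sp, ifelse(choices == "AP", "AV", "AP"))
  expect_equal(ti$index, -ti_rev$index, tolerance = 1e-12)
  expect_error(ap_av_tuning_index(sp, rep("AP", n_tr)), "both choices")
})

test_that("preprocessing chain is order-stable under no-op stages", {
  set.seed(83)
  fs <- 1000
  d <- array(rnorm(2 * 3 * 2000), c(2, 3, 2000))
  rec <- make_rec(d, fs, c("a", "a"))
  full <- downsample_lfp(rereference_local_average(
    remove_stim_artifacts(rec, NULL)), 4)
  skip_noops <- downsample_lfp(rereference_local_average(rec), 4)
  expect_identical(full$data, skip_noops$data)
})
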