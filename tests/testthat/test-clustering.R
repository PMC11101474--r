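test_that("correlation distance matches direct Pearson computation", {
  set.seed(91)
  mats <- replicate(4, matrix(rnorm(400), 20), simplify = FALSE)
  D <- correlation_distance(mats)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 2))
  r13 <- cor(as.numeric(mats[[1]]), as.numeric(mats[[3]]))
  expect_equal(D[1, 3], 1 - r13, tolerance = 1e-12)
  ## identical and negated matrices
  D2 <- correlation_distance(list(mats[[1]], mats[[1]], -mats[[1]]))
  expect_equal(D2[1, 2], 0, tolerance = 1e-12)
  expect_equal(D2[1, 3], 2, tolerance = 1e-12)
  expect_error(correlation_distance(list(mats[[1]], matrix(1, 20, 20))),
               "constant matrix")
})

test_that("classical MDS recovers configurations", {
  ## collinear points: first axis carries essentially all inertia
  pts1 <- cbind(1:5, 0)
  D1 <- as.matrix(dist(pts1))
  e1 <- classical_mds(D1, dims = 4)
  ev <- pmax(e1$eigenvalues, 0)
  expect_gt(ev[1] / sum(ev), 0.999)

  ## 3-D round trip
  set.seed(92)
  pts <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(pts))
  emb <- classical_mds(D, dims = 3)
  expect_equal(as.matrix(dist(emb$coords[, 1:3])), unname(D),
               tolerance = 1e-8, ignore_attr = TRUE)

  ## duplicated row -> coincident embedding points
  D3 <- as.matrix(dist(rbind(pts, pts[1, ])))
  emb3 <- classical_mds(D3, dims = 3)
  expect_equal(emb3$coords[11, ], emb3$coords[1, ], tolerance = 1e-8)

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("BIC-selected mixture recovers separated blobs and normalises posteriors", {
  set.seed(93)
  blobs <- rbind(cbind(rnorm(100, 0, 0.1), rnorm(100, 0, 0.1)),
                 cbind(rnorm(100, 10, 0.1), rnorm(100, 10, 0.1)),
                 cbind(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1)))
  truth <- rep(1:3, each = 100)
  cm <- gmm_cluster_bic(blobs, K_range = 1:6, seed = 93)
  expect_equal(cm$K, 3)
  expect_gte(mclust::adjustedRandIndex(cm$assignments, truth), 0.99)
  expect_equal(rowSums(cm$posteriors), rep(1, nrow(blobs)), tolerance = 1e-9)

  ## single Gaussian -> K = 1
  single <- matrix(rnorm(300), , 2)
  expect_equal(gmm_cluster_bic(single, K_range = 1:4, seed = 1)$K, 1)
})

test_that("cluster labels are invariant to input permutation", {
  arch <- gen_beta_response_archetypes(n_per_template = 30, noise_sd = 0.4,
                                       seed = 94, n_grid = 40)
  D <- correlation_distance(arch$matrices)
  co <- classical_mds(D, dims = 10)$coords
  cm1 <- gmm_cluster_bic(co, K_range = 2:7, seed = 5)
  perm <- sample(nrow(co))
  cm2 <- gmm_cluster_bic(co[perm, ], K_range = 2:7, seed = 5)
  expect_equal(mclust::adjustedRandIndex(cm1$assignments,
                                         cm2$assignments[order(perm)]), 1)
})

test_that("archetype set is recovered with high ARI and plausible K", {
  arch <- gen_beta_response_archetypes(n_per_template = 40, noise_sd = 0.5,
                                       seed = 95, n_grid = 50)
  D <- correlation_distance(arch$matrices)
  emb <- classical_mds(D, dims = 10)
  cm <- gmm_cluster_bic(emb$coords, K_range = 1:8, seed = 95)
  expect_gte(mclust::adjustedRandIndex(cm$assignments, arch$labels), 0.9)
  expect_gte(cm$K, 4)
  expect_lte(cm$K, 6)
})

test_that("P/N labelling is anchored by utility and sign-invariant", {
  arch <- gen_beta_response_archetypes(n_per_template = 25, noise_sd = 0.3,
                                       seed = 96, n_grid = 40)
  cvm <- choice_value_map(c(6, -8, -1), n = 40)
  all_mats <- c(arch$matrices, list(cvm$chv, -cvm$chv))
  D <- correlation_distance(all_mats)
  emb <- classical_mds(D, dims = 10)
  n_ch <- length(arch$matrices)
  anchor_idx <- n_ch + 1:2
  cm <- gmm_cluster_bic(emb$coords[seq_len(n_ch), ], K_range = 3:6, seed = 96)
  pn <- label_pn_groups(cm, emb, anchor_idx)
  ## every P-template channel in the P group, N-template in N
  expect_true(all(pn$channel_group[arch$labels == "P"] == "P"))
  expect_true(all(pn$channel_group[arch$labels == "N"] == "N"))
  ## mean PCV(P) < mean PCV(N) after orientation
  expect_lt(mean(pn$pcv[pn$channel_group == "P"]),
            mean(pn$pcv[pn$channel_group == "N"]))
  ## global sign flip leaves labels unchanged
  emb_f <- emb; emb_f$coords <- -emb_f$coords
  pn_f <- label_pn_groups(cm, emb_f, anchor_idx)
  expect_identical(pn$channel_group, pn_f$channel_group)
  expect_error(label_pn_groups(cm, emb, integer(0)), "anchors")
})

test_that("stimulation-shift bookkeeping: identical blocks change nothing", {
  set.seed(97)
  n_ch <- 12
  pcv <- rep(rnorm(n_ch), 2)
  channel <- rep(seq_len(n_ch), 2)
  block <- rep(c("off", "on"), each = n_ch)
  group <- rep(sample(c("P", "N", "other"), n_ch, replace = TRUE), 2)
  sh <- stim_shift_analysis(pcv, channel, block, group)
  expect_equal(sh$delta_pcv$mean_delta_pcv, 0)
  expect_equal(unname(sh$group_counts[, "off"]), unname(sh$group_counts[, "on"]))
  expect_true(all(sh$group_tests$p == 1))
  two_ch <- c(1, 2, n_ch + 1, n_ch + 2)   # channels 1-2 in both blocks
  expect_error(stim_shift_analysis(pcv[two_ch], channel[two_ch],
                                   block[two_ch], group[two_ch]), "3 tracked")
})

test_that("reduced utility gain shifts PCV upward and depletes the P group", {
  ## generate archetype populations where the stim-on block replaces part of
  ## the P population with weaker (noisier) utility coding
  mk <- function(keep_p, seed) {
    arch <- gen_beta_response_archetypes(
      templates = c("P", "N", "boundary"), n_per_template = 15,
      noise_sd = 0.4, seed = seed, n_grid = 40)
    set.seed(seed)
    lapply(seq_along(arch$matrices), function(i) {
      if (arch$labels[i] == "P" && !keep_p) {
        ## positive-utility coding replaced by a conflict-band response
        arch$templates$boundary + matrix(rnorm(1600, 0, 0.4), 40)
      } else arch$matrices[[i]]
    })
  }
  m_off <- mk(TRUE, 981)
  m_on <- mk(FALSE, 982)
  cvm <- choice_value_map(c(6, -8, -1), n = 40)
  all_mats <- c(m_off, m_on, list(cvm$chv, -cvm$chv))
  D <- correlation_distance(all_mats)
  emb <- classical_mds(D, dims = 10)
  n <- length(m_off)
  cm <- gmm_cluster_bic(emb$coords[seq_len(2 * n), ], K_range = 3:6, seed = 98)
  pn <- label_pn_groups(cm, emb, 2 * n + 1:2)
  sh <- stim_shift_analysis(pn$pcv, channel = rep(seq_len(n), 2),
                            block = rep(c("off", "on"), each = n),
                            group = pn$channel_group)
  expect_gt(sh$delta_pcv$mean_delta_pcv, 0)
  counts <- sh$group_counts
  expect_lt(sum(counts["P", "on"]), sum(counts["P", "off"]))
})

test_that("RDMs reflect utility geometry and compare correctly", {
  set.seed(99)
  ses <- two_block_session(1500, seed = 99)[, ]
  off <- ses[ses$block == "off", ]
  params <- c(6, -8, -1)
  cv <- function(x, y) {
    f <- params[1] * x + params[2] * y + params[3]
    p <- plogis(f)
    p * (params[1] * x + params[2] * y) + (1 - p) * (-params[3])
  }
  ut <- cv(off$x, off$y)
  ## channels with Gaussian utility tuning at staggered centres, so the
  ## population pattern drifts smoothly along the utility axis
  cents <- seq(min(ut), max(ut), length.out = 6)
  pow <- sapply(1:6, function(ch)
    exp(-(ut - cents[ch])^2 / (2 * (diff(range(ut)) / 4)^2)) +
      rnorm(nrow(off), 0, 0.02))
  rdm <- build_rdm(pow, off, params)
  expect_true(isSymmetric(rdm$mat))
  expect_true(all(diag(rdm$mat) == 0))
  ## identical patterns for all conditions -> all-zero RDM
  pow0 <- matrix(rep(c(1, 2, 3), each = nrow(off)), nrow(off), 3)
  rdm0 <- build_rdm(pow0, off, params)
  expect_true(all(abs(rdm0$mat) < 1e-9))
  ## monotone-in-utility patterns: dissimilarity grows with rank distance
  nk <- nrow(rdm$mat)
  rank_dist <- abs(outer(seq_len(nk), seq_len(nk), "-"))
  ct <- cor(rdm$mat[lower.tri(rdm$mat)], rank_dist[lower.tri(rank_dist)],
            method = "spearman")
  expect_gt(ct, 0.5)

  cc <- compare_rdms(rdm, rdm)
  expect_equal(cc$kendall_tau, 1)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(compare_rdms(rdm, rdm0)$kendall_tau,
               compare_rdms(rdm0, rdm)$kendall_tau)
  expect_error(compare_rdms(rdm$mat, rdm$mat[1:3, 1:3]), "mismatch")
})

test_that("all-subsets regression selects the generating variables", {
  set.seed(101)
  n <- 500
  X <- data.frame(Rew = runif(n), Ave = runif(n), Eutil = rnorm(n),
                  RT = runif(n), FOE = runif(n))
  ## response driven by reward only, SNR ~ 4
  y <- 2 * scale(X$Rew)[, 1] + rnorm(n, 0, 0.5)
  sr <- subset_regression(y, X)
  expect_equal(sr$best, "Rew")
  ## exact utility response: Eutil selected with R^2 = 1
  y2 <- scale(X$Eutil)[, 1]
  sr2 <- subset_regression(y2, X)
  expect_equal(sr2$best, "Eutil")
  expect_equal(sr2$table$r2[sr2$table$subset == "Eutil"], 1, tolerance = 1e-9)
  ## pure noise: F-gate keeps the winner empty most of the time
  hits <- sapply(1:20, function(i) {
    yy <- rnorm(200)
    XX <- data.frame(matrix(runif(200 * 5), 200))
    is.na(subset_regression(yy, XX)$best)
  })
  expect_gte(mean(hits), 0.6)
})
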