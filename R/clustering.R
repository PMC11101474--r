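#' Correlation distance between beta-response matrices
#'
#' `d_ij = 1 - r_ij` with `r_ij` the Pearson correlation between the
#' vectorised matrices; cells undefined (`NA`) in either matrix of a pair are
#' excluded pairwise.
#'
#' @param matrices List of equal-size numeric matrices (or a matrix with one
#'   flattened response per column).
#' @return Symmetric distance matrix with zero diagonal, values in `[0, 2]`.
#' @export
correlation_distance <- function(matrices) {
  if (is.list(matrices)) {
    V <- vapply(matrices, function(m) as.numeric(m),
                numeric(length(matrices[[1]])))
  } else V <- matrices
  if (ncol(V) < 2) stop("need at least two matrices")
  sds <- apply(V, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("correlation undefined for constant matrix at index ",
         paste(which(!is.finite(sds) | sds == 0), collapse = ", "))
  r <- stats::cor(V, use = "pairwise.complete.obs")
  d <- 1 - r
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix by double-centred Gram eigendecomposition.
#' Coordinates are defined up to orthogonal transform and axis sign.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param dims Number of dimensions kept (default 10).
#' @return Object of class `mds_embedding`: list with `coords`
#'   (`n x dims`), `eigenvalues` (sorted descending).
#' @export
classical_mds <- function(D, dims = 10) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  dims_eff <- min(dims, n - 1)
  ## dimensions beyond the positive-eigenvalue rank are zero-padded below
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = dims_eff, eig = TRUE))
  co <- fit$points
  if (ncol(co) < dims) {
    co <- cbind(co, matrix(0, n, dims - ncol(co)))
  }
  structure(list(coords = co, eigenvalues = fit$eig[order(-fit$eig)]),
            class = "mds_embedding")
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits diagonal-covariance Gaussian mixtures by EM over a range of component
#' counts and keeps the BIC-optimal model.  Assignments are maximum-posterior;
#' the fraction of points with posterior above 0.75 is reported as a
#' confidence benchmark.
#'
#' @param coords `n x d` coordinate matrix (e.g. MDS coordinates).
#' @param K_range Component counts scanned (default `1:12`).
#' @param seed Integer seed for EM initialisation.
#' @return Object of class `cluster_model`: `K`, `assignments`, `posteriors`,
#'   `bic_by_K`, `means`, `frac_confident`, and the fitted mclust object.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_cluster_bic <- function(coords, K_range = 1:12, seed = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) <= max(K_range))
    stop("need more points than the largest K scanned")
  fit <- with_seed(seed, {
    mclust::Mclust(coords, G = K_range,
                   modelNames = c("EII", "VII", "EEI", "VVI"),
                   verbose = FALSE)
  })
  if (is.null(fit)) stop("EM failed for every K in range")
  z <- fit$z
  bic_by_K <- suppressWarnings(apply(fit$BIC, 1, max, na.rm = TRUE))
  bic_by_K[!is.finite(bic_by_K)] <- NA_real_
  structure(list(K = fit$G, assignments = fit$classification,
                 posteriors = z, bic_by_K = bic_by_K,
                 means = t(fit$parameters$mean),
                 frac_confident = mean(apply(z, 1, max) > 0.75),
                 model = fit),
            class = "cluster_model")
}

#' Label clusters as P/N groups via the principal coordinate
#'
#' Orients the first MDS axis (the principal component value, PCV) so that
#' the positive-utility anchor has the minimal coordinate, then labels the
#' two clusters with the lowest mean PCV as the `P` (positive-utility) group
#' and the two with the highest as the `N` (negative-utility) group;
#' remaining clusters are `other`.
#'
#' @param model A `cluster_model`.
#' @param embedding An `mds_embedding` whose rows include the channels
#'   (first) and the anchor matrices (last).
#' @param anchor_idx Integer indices (rows of `embedding$coords`) of the
#'   positive- and negative-utility anchors, in that order.
#' @return List with `pcv` (per channel, oriented), `cluster_group` (named
#'   map cluster -> {P, N, other}), `channel_group`, `sign` (orientation).
#' @export
label_pn_groups <- function(model, embedding, anchor_idx) {
  if (length(anchor_idx) < 2) stop("orientation error: anchors missing")
  co <- embedding$coords
  pcv <- co[, 1]
  sgn <- if (pcv[anchor_idx[1]] <= pcv[anchor_idx[2]]) 1 else -1
  pcv <- sgn * pcv
  ch_idx <- setdiff(seq_len(nrow(co)), anchor_idx)
  pcv_ch <- pcv[ch_idx]
  ## mean PCV per cluster
  cl <- model$assignments
  stopifnot(length(cl) == length(pcv_ch))
  mpcv <- tapply(pcv_ch, cl, mean)
  ord <- order(mpcv)
  ks <- names(mpcv)
  grp <- stats::setNames(rep("other", length(ks)), ks)
  npn <- min(2, floor(length(ks) / 2))
  if (npn >= 1) {
    grp[ks[ord][seq_len(npn)]] <- "P"
    grp[rev(ks[ord])[seq_len(npn)]] <- "N"
  }
  list(pcv = pcv_ch, cluster_group = grp,
       channel_group = unname(grp[as.character(cl)]), sign = sgn,
       mean_pcv_by_cluster = mpcv)
}

#' Stimulation-induced shifts in the beta-response embedding
#'
#' Given a joint embedding of the same channels tracked across blocks,
#' computes the change in PCV relative to the reference block (with t-tests)
#' and the per-group count table per block (with Fisher tests of proportion
#' change).
#'
#' @param pcv Numeric vector of oriented PCVs, one per channel per block.
#' @param channel Channel identifier per row.
#' @param block Block label per row.
#' @param group Cluster-group label per row (e.g. from [label_pn_groups()]).
#' @param reference Reference block (default `"off"`).
#' @return List with `delta_pcv` (per block: mean, SEM, p), `group_counts`
#'   (group x block table) and `group_tests` (Fisher p per group per block
#'   vs reference).
#' @export
stim_shift_analysis <- function(pcv, channel, block, group,
                                reference = "off") {
  blocks <- unique(block)
  chans <- unique(channel)
  if (length(chans) < 3) stop("need >= 3 tracked channels")
  ref <- stats::setNames(pcv[block == reference][
    match(chans, channel[block == reference])], chans)
  dp <- do.call(rbind, lapply(setdiff(blocks, reference), function(b) {
    v <- pcv[block == b][match(chans, channel[block == b])] - ref
    v <- v[is.finite(v)]
    data.frame(block = b, mean_delta_pcv = mean(v), sem = sem(v),
               p = if (stats::sd(v) > 0) stats::t.test(v)$p.value else NA_real_)
  }))
  counts <- table(group, block)
  tests <- NULL
  if (reference %in% colnames(counts)) {
    tot <- colSums(counts)
    tests <- do.call(rbind, lapply(rownames(counts), function(g) {
      do.call(rbind, lapply(setdiff(colnames(counts), reference), function(b) {
        pt <- proportion_test(counts[g, reference], tot[reference],
                              counts[g, b], tot[b])
        data.frame(group = g, block = b, p = pt$p_fisher_two_sided)
      }))
    }))
  }
  list(delta_pcv = dp, group_counts = counts, group_tests = tests)
}

#' Build a representational dissimilarity matrix for a region
#'
#' Offers are discretised into `n_bins x n_bins` conditions; a region's
#' pattern for each condition is the vector of channel mean powers; the RDM
#' holds `1 - r` between condition patterns, with conditions ordered by the
#' rank of the fitted expected utility at the bin centre.
#'
#' @param power Matrix `trials x channels` of per-trial mean beta power for
#'   channels of one region.
#' @param trials Trial table aligned with `power` rows.
#' @param params Logit parameters (for the utility ranking).
#' @param n_bins Bins per offer axis (default 8).
#' @return Object of class `rdm`: `mat` (`n_cond x n_cond`), `condition`
#'   data frame (bin centres, utility, rank), `dropped` conditions.
#' @export
build_rdm <- function(power, trials, params, n_bins = 8) {
  power <- as.matrix(power)
  stopifnot(nrow(power) == nrow(trials))
  if (ncol(power) < 2)
    stop("need >= 2 channels per region to form condition patterns")
  bx <- pmin(n_bins, floor(trials$x * n_bins) + 1L)
  by <- pmin(n_bins, floor(trials$y * n_bins) + 1L)
  cond <- (bx - 1L) * n_bins + by
  conds <- sort(unique(cond))
  pat <- t(vapply(conds, function(cc)
    colMeans(power[cond == cc, , drop = FALSE]), numeric(ncol(power))))
  ## drop conditions with any undefined pattern
  ok <- apply(pat, 1, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  dropped <- conds[!ok]
  if (any(!ok)) warning(length(dropped), " condition(s) dropped")
  conds <- conds[ok]; pat <- pat[ok, , drop = FALSE]
  ## utility at bin centres
  if (inherits(params, "logit_params"))
    params <- c(params$a, params$b, params$c)
  cx <- ((conds - 1) %/% n_bins + 0.5) / n_bins
  cy <- ((conds - 1) %% n_bins + 0.5) / n_bins
  f <- params[1] * cx + params[2] * cy + params[3]
  p <- stats::plogis(f)
  ut <- p * (params[1] * cx + params[2] * cy) + (1 - p) * (-params[3])
  ord <- order(ut)
  pat <- pat[ord, , drop = FALSE]
  r <- stats::cor(t(pat))
  m <- 1 - r
  diag(m) <- 0
  structure(list(mat = m,
                 condition = data.frame(cond = conds[ord], x = cx[ord],
                                        y = cy[ord], utility = ut[ord],
                                        rank = seq_along(ord)),
                 dropped = dropped),
            class = "rdm")
}

#' Compare two representational dissimilarity matrices
#'
#' Kendall and Spearman rank correlations over the lower triangles.
#'
#' @param rdm_a,rdm_b `rdm` objects (or plain matrices) over the same
#'   condition set.
#' @return List with `kendall_tau`, `spearman_rho` and their p-values.
#' @export
compare_rdms <- function(rdm_a, rdm_b) {
  ma <- if (inherits(rdm_a, "rdm")) rdm_a$mat else rdm_a
  mb <- if (inherits(rdm_b, "rdm")) rdm_b$mat else rdm_b
  if (!all(dim(ma) == dim(mb))) stop("RDM size mismatch")
  va <- ma[lower.tri(ma)]
  vb <- mb[lower.tri(mb)]
  kt <- suppressWarnings(stats::cor.test(va, vb, method = "kendall"))
  sp <- suppressWarnings(stats::cor.test(va, vb, method = "spearman"))
  list(kendall_tau = unname(kt$estimate), p_kendall = kt$p.value,
       spearman_rho = unname(sp$estimate), p_spearman = sp$p.value)
}

#' All-possible-subsets regression with BIC selection
#'
#' Exhaustively fits every non-empty subset of the five standardised
#' predictors, keeps models whose overall F-test is significant, and selects
#' the one with the most favourable BIC.  AIC and Mallows' Cp are reported as
#' cross-checks; collinearity is screened by Belsley condition indices
#' (subsets with condition index above 30 are flagged).
#'
#' @param response Per-trial (or per-channel) numeric response.
#' @param predictors Data frame or matrix of explanatory variables, typically
#'   offered reward, offered airpuff, expected utility, reaction time and
#'   omission frequency.
#' @param alpha Overall-F significance level (default 0.05).
#' @return List with `best` (winning subset name, or `NA` if no subset
#'   passes the F-test), `table` (per-subset BIC/AIC/Cp/F p/R2/collinearity
#'   flag), `coefficients` of the winning model.
#' @export
subset_regression <- function(response, predictors, alpha = 0.05) {
  X <- scale(as.matrix(predictors))
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(X)))
  n <- length(response)
  full <- stats::lm(response ~ X)
  s2_full <- sum(stats::residuals(full)^2) / full$df.residual
  subsets <- unlist(lapply(seq_along(nms), function(k)
    utils::combn(seq_along(nms), k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    Xi <- X[, ss, drop = FALSE]
    qrX <- qr(cbind(1, Xi))
    if (qrX$rank < ncol(Xi) + 1)
      return(data.frame(subset = paste(nms[ss], collapse = "+"),
                        k = length(ss), bic = NA, aic = NA, cp = NA,
                        p_F = NA, r2 = NA, collinear = TRUE,
                        rank_deficient = TRUE))
    fit <- stats::lm(response ~ Xi)
    ## exact fits make summary.lm warn about perfect residuals; the
    ## parsimony tie-break below handles that case explicitly
    sm <- suppressWarnings(summary(fit))
    fstat <- sm$fstatistic
    pF <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    rss <- sum(stats::residuals(fit)^2)
    cp <- rss / s2_full - n + 2 * (length(ss) + 1)
    ## Belsley condition index of the scaled design
    Z <- apply(cbind(1, Xi), 2, function(v) v / sqrt(sum(v^2)))
    ci <- {
      sv <- svd(Z)$d
      max(sv) / min(sv)
    }
    data.frame(subset = paste(nms[ss], collapse = "+"), k = length(ss),
               bic = stats::BIC(fit), aic = stats::AIC(fit), cp = cp,
               p_F = unname(pF), r2 = sm$r.squared, collinear = ci > 30,
               rank_deficient = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$p_F) & tab$p_F < alpha
  if (!any(ok)) {
    return(list(best = NA_character_, table = tab, coefficients = NULL))
  }
  ## parsimony tie-break: exact fits differ only by rounding noise in their
  ## residuals, making BIC comparisons between them meaningless -- prefer
  ## the smallest exact subset; otherwise take the BIC optimum
  cand <- which(ok)
  exact <- cand[tab$r2[cand] >= 1 - 1e-10]
  if (length(exact)) {
    win <- exact[which.min(tab$k[exact])]
  } else {
    win <- cand[which.min(tab$bic[cand])]
  }
  ss <- subsets[[win]]
  fit <- stats::lm(response ~ X[, ss, drop = FALSE])
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", nms[ss])
  list(best = tab$subset[win], table = tab, coefficients = cf)
}
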