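#' Fit the conditional-logit choice model
#'
#' Maximum-likelihood fit of
#' `P(AP) = 1 / (1 + exp(-(a x + b y + c)))`
#' to the non-omitted trials of a session, by binomial GLM.  The model reads
#' `a` as the sensitivity to offered reward, `b` as the (negative) sensitivity
#' to offered airpuff, and `c` as a constant bias; the approach and avoidance
#' utilities are `U_AP = a x + b y` and `U_AV = -c`.
#'
#' @param trials Trial table with columns `x`, `y`, `choice`.
#' @return An object of class `logit_params`: list with `a`, `b`, `c`, `se`
#'   (named standard errors), `bic`, `aic`, `n_trials`, `separated` flag and
#'   the underlying `glm` fit.
#' @export
fit_conditional_logit <- function(trials) {
  use <- trials[trials$choice %in% c("AP", "AV"), , drop = FALSE]
  if (nrow(use) == 0) stop("no choice trials to fit")
  yv <- as.integer(use$choice == "AP")
  if (length(unique(yv)) < 2)
    stop("separation: all trials share one choice; logit parameters unbounded")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(yv ~ x + y, family = stats::binomial(), data = use),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(a = unname(cf["x"]), b = unname(cf["y"]),
                 c = unname(cf["(Intercept)"]),
                 se = c(a = unname(se["x"]), b = unname(se["y"]),
                        c = unname(se["(Intercept)"])),
                 bic = stats::BIC(fit), aic = stats::AIC(fit),
                 n_trials = nrow(use), separated = separated, fit = fit),
            class = "logit_params")
}

#' Cost-benefit ratio and decision-boundary slope
#'
#' The cost-benefit ratio `CBR = -b / a` measures the relative sensitivity to
#' punishment versus reward; an increase in CBR quantifies a negative decision
#' bias.  The slope of the decision boundary in offer space, `-a / b`, is its
#' reciprocal.
#'
#' @param params A `logit_params` object or numeric `c(a, b)`.
#' @return List with `cbr` and `boundary_slope`.
#' @export
cost_benefit_ratio <- function(params) {
  if (inherits(params, "logit_params")) {
    a <- params$a; b <- params$b
  } else {
    a <- params[1]; b <- params[2]
  }
  if (a == 0) stop("CBR undefined: reward coefficient a is zero")
  cbr <- unname(-b / a)
  slope <- if (b != 0) unname(-a / b) else NA_real_
  list(cbr = cbr, boundary_slope = slope)
}

## Cell centres of the 100x100 decision matrix on the canonical offer scale.
grid_centers <- function(n = 100) (seq_len(n) - 0.5) / n

## 101-step offers map to the 100-cell axis: cell = min(100, floor(v*100)+1),
## so the top two offer steps share cell 100.
offer_to_cell <- function(v, n = 100) pmin(n, floor(v * n) + 1L)

#' Choice-probability, utility and chosen-value surfaces
#'
#' Evaluates the fitted model over the 100x100 decision matrix:
#' `p_AP`, the utilities `U_AP = a x + b y` and `U_AV = -c`, and the expected
#' chosen value `ChV = p_AP * U_AP + (1 - p_AP) * U_AV`, which also serves as
#' the expected-utility (Eutil) regressor.
#'
#' @param params `logit_params` or numeric `c(a, b, c)`.
#' @param n Grid size per axis (default 100).
#' @return List of `n x n` matrices `p_ap`, `u_ap`, `chv` plus the axis
#'   vectors `x`, `y` (rows index x, columns index y).
#' @export
choice_value_map <- function(params, n = 100) {
  if (inherits(params, "logit_params")) {
    a <- params$a; b <- params$b; cc <- params$c
  } else {
    a <- params[1]; b <- params[2]; cc <- params[3]
  }
  g <- grid_centers(n)
  x <- matrix(g, n, n)        # rows: reward
  y <- matrix(g, n, n, byrow = TRUE)  # cols: airpuff
  u_ap <- a * x + b * y
  u_av <- -cc
  p <- stats::plogis(u_ap - u_av)
  chv <- p * u_ap + (1 - p) * u_av
  list(p_ap = p, u_ap = u_ap, u_av = u_av, chv = chv, x = g, y = g)
}

#' Build a smoothed decision matrix
#'
#' Stacks a per-trial quantity at its offer cell on the 100x100 grid and
#' smooths with a square moving window (default 25x25 points), truncated and
#' renormalised at the borders.  The smoothed value at a point is the
#' count-weighted window mean; points whose window holds no trials are `NA`.
#'
#' @param trials Trial table with `x`, `y`, `choice` (and `rt_s` for RT maps).
#' @param quantity One of `"choiceAvFraction"`, `"RT"`, `"choiceSD"`,
#'   `"betaPower"`.
#' @param values Per-trial numeric values; required for `"betaPower"`,
#'   ignored otherwise.
#' @param smooth Window width in grid points (odd; default 25).
#' @param n Grid size (default 100).
#' @return Object of class `decision_matrix`: list with `grid` (smoothed),
#'   `counts` (raw per-cell trial counts), `win_counts`, `quantity`,
#'   `smooth_window`.
#' @export
decision_matrix <- function(trials, quantity = c("choiceAvFraction", "RT",
                                                 "choiceSD", "betaPower"),
                            values = NULL, smooth = 25, n = 100) {
  quantity <- match.arg(quantity)
  keep <- trials$choice %in% c("AP", "AV")
  if (quantity == "betaPower" && !is.null(values)) {
    values <- values[keep]
  }
  trials <- trials[keep, , drop = FALSE]
  if (nrow(trials) == 0) stop("no usable trials")
  v <- switch(quantity,
              choiceAvFraction = as.numeric(trials$choice == "AV"),
              choiceSD = as.numeric(trials$choice == "AV"),
              RT = trials$rt_s,
              betaPower = {
                if (is.null(values)) stop("values required for betaPower")
                values
              })
  ix <- offer_to_cell(trials$x, n)
  iy <- offer_to_cell(trials$y, n)
  counts <- matrix(0, n, n)
  sums <- matrix(0, n, n)
  idx <- cbind(ix, iy)
  for (k in seq_along(v)) {
    counts[idx[k, 1], idx[k, 2]] <- counts[idx[k, 1], idx[k, 2]] + 1
    sums[idx[k, 1], idx[k, 2]] <- sums[idx[k, 1], idx[k, 2]] + v[k]
  }
  half <- (smooth - 1) %/% 2
  wc <- box_sum2d(counts, half)
  ws <- box_sum2d(sums, half)
  grid <- ifelse(wc > 0, ws / wc, NA_real_)
  if (quantity == "choiceSD") grid <- sqrt(grid * (1 - grid))
  structure(list(grid = grid, counts = counts, win_counts = wc,
                 quantity = quantity, smooth_window = smooth, n = n),
            class = "decision_matrix")
}

## Fast two-sided Fisher exact p for many 2x2 tables (x1 of n1 vs x2 of n2
## successes).  Conditional hypergeometric two-sided rule as in
## stats::fisher.test: sum the probabilities of all tables with fixed margins
## that are no more likely than the observed one (1 + 1e-7 tolerance).
## Duplicate (x1, n1, n2, s) configurations are computed once.
fisher_p_many <- function(x1, n1, x2, n2) {
  s <- x1 + x2
  key <- paste(x1, n1, n2, s)
  up <- !duplicated(key)
  p_u <- vapply(which(up), function(i) {
    si <- s[i]; n1i <- n1[i]; n2i <- n2[i]; xi <- x1[i]
    if (n1i == 0 || n2i == 0) return(NA_real_)
    lo <- max(0L, si - n2i); hi <- min(si, n1i)
    supp <- lo:hi
    d <- stats::dhyper(supp, n1i, n2i, si)
    sum(d[d <= d[supp == xi] * (1 + 1e-7)])
  }, numeric(1))
  p_u[match(key, key[up])]
}

#' Quantify a stimulation effect on the decision matrix
#'
#' At each of the `n^2` grid points, approach/avoidance counts inside the
#' smoothing window are cross-tabulated between the two blocks and tested with
#' a two-sided Fisher exact test.  `%dAv` is the percentage of matrix area
#' where avoidance increased significantly (p < `alpha`), `%dAp` likewise for
#' approach.  A session is labelled `negative_effective` if `%dAv` exceeds
#' `threshold_pct`, `positive_effective` if `%dAp` does (ties broken by the
#' larger area; a tie of exceeding areas falls back to `non_effective` with a
#' warning), else `non_effective`.  Points with an empty window in either
#' block are excluded from both masks.
#'
#' @param trials_off,trials_on Trial tables for the two blocks.
#' @param alpha Pointwise significance level (default 0.05, uncorrected; the
#'   area threshold is the multiplicity control).
#' @param threshold_pct Area threshold in percent (default 5).
#' @param smooth Window width (default 25).
#' @param n Grid size (default 100).
#' @return Object of class `stim_effect`: masks, `pct_delta_av`,
#'   `pct_delta_ap`, `label`, per-block boundary parameters, and the p-value
#'   grid.
#' @export
stim_effect <- function(trials_off, trials_on, alpha = 0.05,
                        threshold_pct = 5, smooth = 25, n = 100) {
  if (nrow(trials_off) == 0 || nrow(trials_on) == 0)
    stop("both blocks must be non-empty")
  half <- (smooth - 1) %/% 2
  wcount <- function(tr) {
    tr <- tr[tr$choice %in% c("AP", "AV"), , drop = FALSE]
    ix <- offer_to_cell(tr$x, n); iy <- offer_to_cell(tr$y, n)
    av <- matrix(0, n, n); tot <- matrix(0, n, n)
    for (k in seq_len(nrow(tr))) {
      tot[ix[k], iy[k]] <- tot[ix[k], iy[k]] + 1
      if (tr$choice[k] == "AV") av[ix[k], iy[k]] <- av[ix[k], iy[k]] + 1
    }
    list(av = box_sum2d(av, half), tot = box_sum2d(tot, half))
  }
  off <- wcount(trials_off); on <- wcount(trials_on)
  valid <- off$tot > 0 & on$tot > 0
  p <- matrix(NA_real_, n, n)
  if (any(valid)) {
    p[valid] <- fisher_p_many(off$av[valid], off$tot[valid],
                              on$av[valid], on$tot[valid])
  }
  frac_off <- ifelse(off$tot > 0, off$av / off$tot, NA)
  frac_on <- ifelse(on$tot > 0, on$av / on$tot, NA)
  sig <- !is.na(p) & p < alpha & valid
  mask_av_up <- sig & (frac_on > frac_off)
  mask_ap_up <- sig & (frac_on < frac_off)
  pct_av <- 100 * sum(mask_av_up) / (n * n)
  pct_ap <- 100 * sum(mask_ap_up) / (n * n)
  label <- "non_effective"
  if (pct_av > threshold_pct || pct_ap > threshold_pct) {
    if (pct_av == pct_ap) {
      warning("tied %dAv and %dAp above threshold; labelling non_effective")
    } else {
      label <- if (pct_av > pct_ap) "negative_effective" else "positive_effective"
    }
  }
  bnd <- function(tr) {
    fit <- tryCatch(fit_conditional_logit(tr), error = function(e) NULL)
    if (is.null(fit)) NULL else c(a = fit$a, b = fit$b, c = fit$c)
  }
  structure(list(mask_av_up = mask_av_up, mask_ap_up = mask_ap_up,
                 pct_delta_av = pct_av, pct_delta_ap = pct_ap,
                 label = label, p_grid = p, valid = valid,
                 boundary_off = bnd(trials_off), boundary_on = bnd(trials_on)),
            class = "stim_effect")
}

#' Summarise stimulation effects across sessions
#'
#' Mean and SEM of `%dAv` and `%dCBR` per block per session group, with
#' two-sample two-sided t-tests between groups within block.
#'
#' @param tab Data frame with columns `session`, `group`, `block`,
#'   `pct_delta_av`, `pct_delta_cbr`.
#' @return List with `summary` (per group x block means and SEMs) and `tests`
#'   (per block t-test p-values for both measures; `NaN` with a
#'   `zero_variance` flag when both groups are degenerate).
#' @export
block_summary <- function(tab) {
  groups <- unique(tab$group)
  blocks <- unique(tab$block)
  if (any(table(tab$group, tab$block) < 2))
    stop("SEM undefined: need >= 2 sessions per group per block")
  summ <- do.call(rbind, lapply(blocks, function(b) {
    do.call(rbind, lapply(groups, function(g) {
      z <- tab[tab$group == g & tab$block == b, ]
      data.frame(block = b, group = g, n = nrow(z),
                 mean_dav = mean(z$pct_delta_av), sem_dav = sem(z$pct_delta_av),
                 mean_dcbr = mean(z$pct_delta_cbr),
                 sem_dcbr = sem(z$pct_delta_cbr))
    }))
  }))
  tests <- NULL
  if (length(groups) == 2) {
    tests <- do.call(rbind, lapply(blocks, function(b) {
      z1 <- tab[tab$group == groups[1] & tab$block == b, ]
      z2 <- tab[tab$group == groups[2] & tab$block == b, ]
      tt <- function(v1, v2) {
        if (stats::sd(v1) == 0 && stats::sd(v2) == 0)
          return(c(p = NaN, zero_variance = 1))
        c(p = stats::t.test(v1, v2)$p.value, zero_variance = 0)
      }
      r1 <- tt(z1$pct_delta_av, z2$pct_delta_av)
      r2 <- tt(z1$pct_delta_cbr, z2$pct_delta_cbr)
      data.frame(block = b, p_dav = r1["p"], zero_var_dav = r1["zero_variance"],
                 p_dcbr = r2["p"], zero_var_dcbr = r2["zero_variance"],
                 row.names = NULL)
    }))
  }
  list(summary = summ, tests = tests)
}

#' Compare two proportions (Fisher exact and Pearson chi-square)
#'
#' Tests `k1/n1` against `k2/n2` with the Fisher exact test (one- and
#' two-sided) and the uncorrected Pearson chi-square test (df = 1).
#'
#' @param k1,n1,k2,n2 Successes and totals in the two groups.
#' @return List with `p_fisher_one_sided` (direction: group 1 proportion
#'   greater), `p_fisher_two_sided`, `p_chisq`.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) stop("group totals must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  p1 <- stats::fisher.test(m, alternative = "greater")$p.value
  p2 <- stats::fisher.test(m)$p.value
  pc <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  list(p_fisher_one_sided = p1, p_fisher_two_sided = p2, p_chisq = pc)
}
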