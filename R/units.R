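#' Classify single units by task correlates
#'
#' For each unit and task period, the per-trial firing rate is correlated
#' (Pearson) with the period's behavioural parameter: upcoming avoidance
#' choice (0/1) for the cue period, delivered airpuff strength for the
#' airpuff period, delivered reward amount for the reward period.  Units are
#' categorised `positive` / `negative` / `none` by correlation sign at
#' `p < alpha`; constant-rate units are `none` with a flag.
#'
#' @param rates Matrix `trials x units` of firing rates for one period.
#' @param parameter Per-trial behavioural parameter for that period.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: unit, `r`, `p`, `category`, `constant` flag.
#' @export
classify_units <- function(rates, parameter, alpha = 0.05) {
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == length(parameter))
  out <- lapply(seq_len(ncol(rates)), function(u) {
    v <- rates[, u]
    if (stats::sd(v) == 0 || stats::sd(parameter) == 0) {
      return(data.frame(unit = u, r = NA_real_, p = NA_real_,
                        category = "none", constant = TRUE))
    }
    ct <- stats::cor.test(v, parameter)
    cat <- if (ct$p.value < alpha) {
      if (ct$estimate > 0) "positive" else "negative"
    } else "none"
    data.frame(unit = u, r = unname(ct$estimate), p = ct$p.value,
               category = cat, constant = FALSE)
  })
  do.call(rbind, out)
}

#' Spatial proportion map of unit categories
#'
#' Bins units into 1-mm zones along the electrode track and tests each bin's
#' proportion of the target category against the aggregate proportion over
#' all units (two-sided Fisher's exact test).
#'
#' @param position_mm Per-unit depth (mm).
#' @param category Per-unit category label.
#' @param target The category of interest (e.g. `"positive"`).
#' @param bin_mm Bin width in mm (default 1).
#' @param origin_mm Bin anchor (default 0; set to an effective-site depth to
#'   centre bins there).
#' @param p_adjust Multiplicity correction across bins (default `"none"`,
#'   with `"bonferroni"` available).
#' @return Data frame per non-empty bin: bin centre, counts, proportion,
#'   Fisher p (vs aggregate), significance.
#' @export
spatial_proportion_map <- function(position_mm, category, target,
                                   bin_mm = 1, origin_mm = 0,
                                   p_adjust = c("none", "bonferroni"),
                                   alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(position_mm) == length(category))
  bins <- floor((position_mm - origin_mm) / bin_mm)
  hit <- category == target
  k_all <- sum(hit); n_all <- length(hit)
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    idx <- bins == b
    k <- sum(hit[idx]); n <- sum(idx)
    pt <- proportion_test(k, n, k_all - k, n_all - n)
    data.frame(bin_center_mm = origin_mm + (b + 0.5) * bin_mm,
               k = k, n = n, proportion = k / n,
               p = pt$p_fisher_two_sided)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adj < alpha
  out
}
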