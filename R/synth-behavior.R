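#' Configuration for synthetic approach-avoidance sessions
#'
#' Bundles the parameters of the behavioural generator: block structure,
#' per-block conditional-logit coefficients, omission rate and a descriptive
#' reaction-time model.  Offers are represented on the canonical `[0, 1]`
#' scale; physical units (reward volume, airpuff pressure) are presentation
#' metadata only.
#'
#' @param n_trials_per_block Trials per block (one number or one per block).
#' @param n_offer_steps Number of offer steps per axis (default 101, i.e. the
#'   grid `{0, 1/100, ..., 1}`).
#' @param blocks Character vector of block labels, default
#'   `c("off", "on", "follow")` for Stim-off / Stim-on / Follow-up.
#' @param logit_params Named list, one `c(a, b, c)` per block: the
#'   conditional-logit coefficients generating choices in that block.  A
#'   stimulation effect is expressed as a change in these coefficients
#'   (typically a more negative airpuff weight `b`).
#' @param repeat_of Named character vector; `repeat_of["on"] == "off"` makes
#'   the Stim-on block reuse the Stim-off cue sequence, mirroring the task's
#'   repeated offer sequences.
#' @param omission_rate Probability that a trial ends as an omission.
#' @param rt_model List with `base_s`, `conflict_gain`, `noise_sd` (seconds):
#'   reaction times are `base_s` plus a conflict bump that peaks at the
#'   decision boundary, plus Gaussian noise.
#' @param seed Integer master seed.
#' @return An object of class `synth_behavior_config`.
#' @export
synth_behavior_config <- function(n_trials_per_block = 250,
                                  n_offer_steps = 101,
                                  blocks = c("off", "on", "follow"),
                                  logit_params = list(
                                    off    = c(a = 6, b = -8, c = -1),
                                    on     = c(a = 6, b = -12, c = -1),
                                    follow = c(a = 6, b = -12, c = -1)),
                                  repeat_of = c(on = "off"),
                                  omission_rate = 0.03,
                                  rt_model = list(base_s = 0.35,
                                                  conflict_gain = 0.15,
                                                  noise_sd = 0.05),
                                  seed = 1L) {
  if (length(blocks) < 1) stop("block list must be non-empty")
  if (n_offer_steps < 2) stop("n_offer_steps must be >= 2")
  if (omission_rate < 0 || omission_rate >= 1)
    stop("omission_rate must be in [0, 1)")
  if (!all(blocks %in% names(logit_params)))
    stop("logit_params must name every block")
  n_trials_per_block <- rep_len(n_trials_per_block, length(blocks))
  structure(list(n_trials_per_block = n_trials_per_block,
                 n_offer_steps = as.integer(n_offer_steps),
                 blocks = blocks, logit_params = logit_params,
                 repeat_of = repeat_of, omission_rate = omission_rate,
                 rt_model = rt_model, seed = as.integer(seed)),
            class = "synth_behavior_config")
}

#' Generate offer sequences for each block
#'
#' Reward (`x`) and airpuff (`y`) offers are drawn independently and uniformly
#' from the `n_offer_steps`-point grid on `[0, 1]`.  Blocks listed in
#' `repeat_of` copy their reference block's cue sequence elementwise.
#'
#' @param config A [synth_behavior_config()].
#' @return A trial table (`data.frame`) with columns `trial`, `block`, `x`, `y`.
#' @export
gen_offers <- function(config) {
  stopifnot(inherits(config, "synth_behavior_config"))
  grid <- seq(0, 1, length.out = config$n_offer_steps)
  out <- vector("list", length(config$blocks))
  names(out) <- config$blocks
  for (i in seq_along(config$blocks)) {
    blk <- config$blocks[i]
    n <- config$n_trials_per_block[i]
    ref <- config$repeat_of[blk]
    if (!is.na(ref) && ref %in% names(out) && !is.null(out[[ref]])) {
      src <- out[[ref]]
      if (nrow(src) < n) stop("repeat block longer than its reference block")
      out[[blk]] <- data.frame(block = blk, x = src$x[seq_len(n)],
                               y = src$y[seq_len(n)])
    } else {
      xy <- with_seed(split_seed(config$seed, i), {
        cbind(sample(grid, n, replace = TRUE), sample(grid, n, replace = TRUE))
      })
      out[[blk]] <- data.frame(block = blk, x = xy[, 1], y = xy[, 2])
    }
  }
  res <- do.call(rbind, out)
  res <- data.frame(trial = seq_len(nrow(res)), res, row.names = NULL)
  res
}

#' Simulate choices and reaction times from a conditional-logit model
#'
#' Each non-omitted trial is an approach (`"AP"`) with probability
#' `1 / (1 + exp(-(a x + b y + c)))`, else avoidance (`"AV"`).  Omissions
#' (`"OM"`) are drawn independently.  Reaction times follow the descriptive
#' model: baseline plus a Gaussian bump in the utility difference
#' `f = a x + b y + c` (longest near the decision boundary, where choice
#' conflict is maximal), plus noise.
#'
#' @param offers Trial table with `x`, `y` columns.
#' @param params Numeric `c(a, b, c)`.
#' @param omission_rate Probability of an omission per trial.
#' @param rt_model List with `base_s`, `conflict_gain`, `noise_sd`.
#' @param seed Integer seed.
#' @return The trial table with `choice` and `rt_s` columns added.
#' @export
simulate_choices <- function(offers, params, omission_rate = 0,
                             rt_model = list(base_s = 0.35,
                                             conflict_gain = 0.15,
                                             noise_sd = 0.05),
                             seed = 1L) {
  stopifnot(all(is.finite(params)), length(params) >= 3)
  f <- params[1] * offers$x + params[2] * offers$y + params[3]
  p_ap <- stats::plogis(f)
  n <- nrow(offers)
  with_seed(seed, {
    ap <- stats::runif(n) < p_ap
    om <- stats::runif(n) < omission_rate
    choice <- ifelse(om, "OM", ifelse(ap, "AP", "AV"))
    rt <- rt_model$base_s +
      rt_model$conflict_gain * exp(-f^2 / 2) +
      stats::rnorm(n, 0, rt_model$noise_sd)
    offers$choice <- choice
    offers$rt_s <- pmax(rt, 0.05)
    offers
  })
}

#' Simulate a full multi-block session
#'
#' Generates offers per [gen_offers()] and choices per [simulate_choices()]
#' with each block's own logit coefficients.  The generating coefficients are
#' stored in `attr(, "ground_truth")` for parameter-recovery tests.
#'
#' @param bcfg A [synth_behavior_config()].
#' @return Trial table with columns `trial`, `block`, `x`, `y`, `choice`,
#'   `rt_s` and a `ground_truth` attribute.
#' @export
simulate_session <- function(bcfg) {
  offers <- gen_offers(bcfg)
  parts <- lapply(seq_along(bcfg$blocks), function(i) {
    blk <- bcfg$blocks[i]
    simulate_choices(offers[offers$block == blk, , drop = FALSE],
                     bcfg$logit_params[[blk]],
                     omission_rate = bcfg$omission_rate,
                     rt_model = bcfg$rt_model,
                     seed = split_seed(bcfg$seed, 1000L + i))
  })
  res <- do.call(rbind, parts)
  res$trial <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "ground_truth") <- bcfg$logit_params
  res
}
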