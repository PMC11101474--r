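#' Write / read a session trial table as CSV
#'
#' Columns: `trial`, `block`, `x`, `y`, `choice` (`AP`/`AV`/`OM`), `rt_s`.
#'
#' @param session Trial table.
#' @param path File path.
#' @return `read_session_csv` returns the trial table.
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(session[, c("trial", "block", "x", "y", "choice", "rt_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an LFP recording as a plain-text store
#'
#' One CSV per channel (trials in rows, samples in columns) plus a JSON
#' sidecar holding the sampling rate, region labels and event times.
#'
#' @param rec An [lfp_recording()].
#' @param dir Directory to write into (created if absent).
#' @return `read_lfp_store` returns the `lfp_recording`.
#' @export
write_lfp_store <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nch <- dim(rec$data)[1]
  files <- sprintf("channel_%02d.csv", seq_len(nch))
  for (ch in seq_len(nch)) {
    utils::write.table(rec$data[ch, , ], file.path(dir, files[ch]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(fs = rec$fs, regions = as.list(rec$regions),
               events = rec$events, channel_files = as.list(files),
               n_trials = dim(rec$data)[2], n_samples = dim(rec$data)[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_lfp_store
#' @export
read_lfp_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nch <- length(meta$channel_files)
  data <- array(0, c(nch, meta$n_trials, meta$n_samples))
  for (ch in seq_len(nch)) {
    data[ch, , ] <- as.matrix(utils::read.table(
      file.path(dir, meta$channel_files[ch]), sep = ",", header = FALSE))
  }
  lfp_recording(data, meta$fs, unlist(meta$regions),
                events = as.list(meta$events))
}

#' Validate a session trial table
#'
#' Schema checks: required columns, known choice tokens, offers on `[0, 1]`,
#' nonnegative reaction times, no missing values.
#'
#' @param session Trial table (or path to a session CSV).
#' @return Character vector of violations (empty when well-formed).
#' @export
validate_inputs <- function(session) {
  if (is.character(session)) session <- read_session_csv(session)
  v <- character(0)
  need <- c("trial", "block", "x", "y", "choice", "rt_s")
  miss <- setdiff(need, names(session))
  if (length(miss)) v <- c(v, paste("missing column(s):",
                                    paste(miss, collapse = ", ")))
  if ("choice" %in% names(session)) {
    bad <- setdiff(unique(session$choice), c("AP", "AV", "OM"))
    if (length(bad)) v <- c(v, paste("unknown choice token(s):",
                                     paste(bad, collapse = ", ")))
  }
  for (cc in intersect(c("x", "y"), names(session))) {
    if (any(!is.finite(session[[cc]])))
      v <- c(v, paste("non-finite values in", cc))
    else if (any(session[[cc]] < 0 | session[[cc]] > 1))
      v <- c(v, paste(cc, "outside [0, 1]"))
  }
  if ("rt_s" %in% names(session) && any(session$rt_s < 0, na.rm = TRUE))
    v <- c(v, "negative reaction times")
  v
}

#' Run the full synthetic pipeline
#'
#' Orchestrates synthesis, behavioural modelling, beta-response extraction,
#' clustering and connectivity on one synthetic session: simulate session and
#' LFP network, fit the conditional logit per block, quantify the
#' stimulation effect on the decision matrix, build beta-response matrices
#' from the decision-period envelope power, embed and cluster them, and
#' estimate the directed network (GC/DAI) per block.
#'
#' @param bcfg A [synth_behavior_config()].
#' @param lcfg A [synth_lfp_config()].
#' @param out_dir Optional directory: writes `session.csv` and
#'   `report.json` (fit parameters, stim effect, DAI summaries).
#' @param stages Character subset of
#'   `c("behavior", "spectral", "clustering", "connectivity")`.
#' @return List with components per stage.
#' @export
run_pipeline <- function(bcfg = synth_behavior_config(),
                         lcfg = synth_lfp_config(seed = bcfg$seed),
                         out_dir = NULL,
                         stages = c("behavior", "spectral", "clustering",
                                    "connectivity")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("clustering", "connectivity") %in% stages) &&
      !("spectral" %in% stages))
    stop("dependency error: clustering/connectivity require the spectral stage")
  session <- simulate_session(bcfg)
  out <- list(session = session)
  if ("behavior" %in% stages) {
    fits <- lapply(split(session, session$block), fit_conditional_logit)
    cbrs <- lapply(fits, cost_benefit_ratio)
    eff <- stim_effect(session[session$block == bcfg$blocks[1], ],
                       session[session$block == bcfg$blocks[2], ])
    out$behavior <- list(fits = fits, cbrs = cbrs, stim_effect = eff)
  }
  rec <- simulate_lfp_network(lcfg, session)
  if ("spectral" %in% stages) {
    fs <- rec$fs
    cue0 <- round(rec$events$cue_on * fs) + 1L
    cue1 <- dim(rec$data)[3]
    power <- lapply(seq_len(dim(rec$data)[1]), function(ch) {
      tc <- beta_power_timecourse(rec$data[ch, , ], fs, method = "envelope")
      rowMeans(tc[, cue0:cue1, drop = FALSE])
    })
    out$spectral <- list(recording = rec, decision_power = power)
  }
  if ("clustering" %in% stages) {
    blocks <- unique(session$block)
    mats <- list(); meta <- list(); k <- 0
    for (ch in seq_along(out$spectral$decision_power)) {
      for (blk in blocks) {
        k <- k + 1
        rows <- session$block == blk
        mats[[k]] <- beta_response_matrix(
          out$spectral$decision_power[[ch]][rows], session[rows, ])$grid
        meta[[k]] <- data.frame(channel = ch, block = blk,
                                region = rec$regions[ch])
      }
    }
    meta <- do.call(rbind, meta)
    fit_off <- out$behavior$fits[[bcfg$blocks[1]]]
    cvm <- choice_value_map(fit_off)
    anchors <- list(pos_eutil = cvm$chv, neg_eutil = -cvm$chv)
    D <- correlation_distance(c(mats, anchors))
    emb <- classical_mds(D, dims = min(10, length(mats)))
    anchor_idx <- length(mats) + 1:2
    cl <- gmm_cluster_bic(emb$coords[seq_along(mats), , drop = FALSE],
                          K_range = 1:min(8, length(mats) - 1),
                          seed = bcfg$seed)
    pn <- label_pn_groups(cl, emb, anchor_idx)
    out$clustering <- list(meta = meta, embedding = emb, model = cl,
                           groups = pn)
  }
  if ("connectivity" %in% stages) {
    fs <- rec$fs
    cue0 <- round(rec$events$cue_on * fs) + 1L
    cue1 <- dim(rec$data)[3]
    blocks <- unique(session$block)
    nch <- dim(rec$data)[1]
    conn <- list()
    for (blk in blocks) {
      rows <- which(session$block == blk)
      res <- list(); k <- 0
      for (i in seq_len(nch - 1)) for (j in (i + 1):nch) {
        k <- k + 1
        res[[k]] <- pair_connectivity(
          rec$data[i, rows, cue0:cue1], rec$data[j, rows, cue0:cue1],
          fs, regions = c(rec$regions[i], rec$regions[j]), order_max = 8)
      }
      conn[[blk]] <- res
    }
    out$connectivity <- list(pairs = conn,
                             summary = lapply(conn, network_summary))
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_session_csv(session, file.path(out_dir, "session.csv"))
    rep <- list(seed = bcfg$seed,
                logit = lapply(out$behavior$fits, function(f)
                  list(a = f$a, b = f$b, c = f$c, bic = f$bic)),
                cbr = lapply(out$behavior$cbrs, `[[`, "cbr"),
                stim_effect = list(
                  pct_delta_av = out$behavior$stim_effect$pct_delta_av,
                  pct_delta_ap = out$behavior$stim_effect$pct_delta_ap,
                  label = out$behavior$stim_effect$label))
    if (!is.null(out$connectivity)) {
      rep$dai <- lapply(out$connectivity$summary, function(s)
        apply(s, 1, function(r) as.list(r)))
    }
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
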