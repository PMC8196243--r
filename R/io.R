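# Tabular IO, trial filtering and epoch-rate extraction.
#
# All times are ms from trial start; all windows are half-open [a, b).
# CSV dialect: comma-separated, UTF-8, header row, '.' decimal.

#' Analysis epoch windows
#'
#' The three analysis periods used throughout: `post_stim` = [100, 400) ms
#' after stimulus onset, `post_cue` = [100, 400) ms after cue onset,
#' `pre_dim` = [-500, 0) ms before the first dimming (whether target or
#' distractor). A `baseline` window ([-300, 0) before stimulus onset) is
#' included for response-type classification.
#'
#' @param include_baseline Include the pre-stimulus baseline window.
#' @return data.frame with columns `epoch`, `anchor`, `offset_start`,
#'   `offset_end` (ms relative to the anchor event).
#' @export
epoch_windows <- function(include_baseline = TRUE) {
  w <- data.frame(
    epoch = c("post_stim", "post_cue", "pre_dim"),
    anchor = c("t_stimulus_on", "t_cue_on", "t_dim1"),
    offset_start = c(100, 100, -500),
    offset_end = c(400, 400, 0),
    stringsAsFactors = FALSE)
  if (include_baseline)
    w <- rbind(data.frame(epoch = "baseline", anchor = "t_stimulus_on",
                          offset_start = -300, offset_end = 0,
                          stringsAsFactors = FALSE), w)
  w
}

#' Filter trials for analysis
#'
#' Retains correct (hit) trials with a within-block index greater than six
#' (the first six trials of every block are contaminated by delayed drug
#' onset/washout). Conditions left with fewer than `min_trials` surviving
#' trials are reported in the `excluded_conditions` attribute; downstream
#' per-unit analyses exclude units whose conditions fall below that bound.
#'
#' @param trials Trial table.
#' @param min_trials Minimum surviving trials per attention x motion x drug
#'   cell. Default 10.
#' @return Filtered trial data.frame with attribute `excluded_conditions`.
#' @export
filter_trials <- function(trials, min_trials = 10L) {
  req <- c("block_id", "within_block_index", "outcome", "attention",
           "motion", "drug")
  if (!all(req %in% names(trials)))
    stop("trial table lacks required columns: ",
         paste(setdiff(req, names(trials)), collapse = ", "))
  keep <- trials$outcome == "hit" & trials$within_block_index > 6L
  out <- trials[keep, , drop = FALSE]
  if (nrow(out)) {
    tab <- stats::aggregate(trial_id ~ attention + motion + drug, out, length)
    excl <- tab[tab$trial_id < min_trials, , drop = FALSE]
  } else {
    excl <- data.frame(attention = character(), motion = character(),
                       drug = character(), trial_id = integer())
  }
  names(excl)[names(excl) == "trial_id"] <- "n_trials"
  attr(out, "excluded_conditions") <- excl
  out
}

#' Epoch spike counts and rates
#'
#' Counts spikes in half-open windows anchored to trial events and converts
#' to rates. Trials lacking the anchor event for a window (e.g. no first
#' dimming on a fixation break) are dropped for that epoch. A spike exactly
#' at the window end is excluded (half-open convention).
#'
#' @param spikes Spike table (`unit_id`, `trial_id`, `spike_time_ms`).
#' @param trials Trial table (typically after [filter_trials()]).
#' @param windows Window table from [epoch_windows()].
#' @return data.frame: `unit_id`, `trial_id`, `epoch`, `spike_count`,
#'   `duration_s`, `rate`.
#' @export
epoch_rates <- function(spikes, trials, windows = epoch_windows()) {
  stopifnot(all(c("unit_id", "trial_id", "spike_time_ms") %in% names(spikes)))
  bad <- setdiff(unique(spikes$trial_id), trials$trial_id)
  # spikes on trials outside the (filtered) table are silently dropped;
  # an unknown anchor column is a configuration error
  if (!all(windows$anchor %in% names(trials)))
    stop("unknown anchor event in window table")
  if (any(windows$offset_end <= windows$offset_start))
    stop("non-positive window duration")
  units <- sort(unique(spikes$unit_id))
  out <- vector("list", nrow(windows))
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi, ]
    anchor <- trials[[w$anchor]]
    ok <- is.finite(anchor)
    tt <- trials[ok, , drop = FALSE]
    a <- anchor[ok] + w$offset_start
    b <- anchor[ok] + w$offset_end
    dur <- (w$offset_end - w$offset_start) / 1000
    grid <- expand.grid(unit_id = units, trial_id = tt$trial_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sp <- spikes[spikes$trial_id %in% tt$trial_id, , drop = FALSE]
    idx <- match(sp$trial_id, tt$trial_id)
    inwin <- sp$spike_time_ms >= a[idx] & sp$spike_time_ms < b[idx]
    sp <- sp[inwin, , drop = FALSE]
    if (nrow(sp)) {
      cnt <- stats::aggregate(spike_time_ms ~ unit_id + trial_id, sp, length)
      names(cnt)[3] <- "spike_count"
      grid <- merge(grid, cnt, by = c("unit_id", "trial_id"), all.x = TRUE)
    } else grid$spike_count <- rep(NA_integer_, nrow(grid))
    grid$spike_count[is.na(grid$spike_count)] <- 0L
    grid$epoch <- rep(w$epoch, nrow(grid))
    grid$duration_s <- rep(dur, nrow(grid))
    grid$rate <- grid$spike_count / dur
    out[[wi]] <- grid[, c("unit_id", "trial_id", "epoch", "spike_count",
                          "duration_s", "rate")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic session to plain-text files
#'
#' Emits `trials.csv`, `spikes.csv`, `waveforms.csv`, `eyes.csv`, `rts.csv`
#' and `ground_truth.json` under `dir`.
#'
#' @param session A `fef_session` from [generate_session()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "fef_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wcsv(session$trials, "trials.csv")
  wcsv(session$spikes, "spikes.csv")
  wf <- data.frame(unit_id = rownames(session$waveforms),
                   session$waveforms, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(wf)[-1] <- paste0("s", seq_len(ncol(session$waveforms)))
  wcsv(wf, "waveforms.csv")
  if (!is.null(session$eyes)) {
    wcsv(session$eyes$traces, "eyes.csv")
    wcsv(session$eyes$injected, "eyes_injected.csv")
  }
  wcsv(session$rts, "rts.csv")
  gt <- list(units = session$units,
             config = unclass(session$config),
             seed = session$seed,
             native_dt = attr(session$waveforms, "native_dt"),
             eye_fs = if (is.null(session$eyes)) NULL else session$eyes$fs,
             eye_noise_sd = if (is.null(session$eyes)) NULL else
               session$eyes$noise_sd,
             eye_duration_ms = if (is.null(session$eyes)) NULL else
               session$eyes$duration_ms)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the session files.
#' @return A list of class `fef_session`.
#' @export
read_session <- function(dir) {
  rcsv <- function(f) utils::read.csv(file.path(dir, f), fileEncoding = "UTF-8",
                                      stringsAsFactors = FALSE)
  trials <- rcsv("trials.csv")
  class(trials) <- c("fef_trials", "data.frame")
  spikes <- rcsv("spikes.csv")
  class(spikes) <- c("fef_spikes", "data.frame")
  wf <- rcsv("waveforms.csv")
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  waveforms <- as.matrix(wf[, -1, drop = FALSE])
  dimnames(waveforms) <- list(wf$unit_id, NULL)
  attr(waveforms, "native_dt") <- gt$native_dt
  eyes <- NULL
  if (file.exists(file.path(dir, "eyes.csv"))) {
    eyes <- structure(list(traces = rcsv("eyes.csv"),
                           injected = rcsv("eyes_injected.csv"),
                           fs = gt$eye_fs, duration_ms = gt$eye_duration_ms,
                           noise_sd = gt$eye_noise_sd),
                      class = "fef_eyes")
  }
  cfg <- gt$config
  cfg$error_rates <- unlist(cfg$error_rates)
  class(cfg) <- "fef_task_config"
  structure(list(trials = trials, spikes = spikes, waveforms = waveforms,
                 eyes = eyes, rts = rcsv("rts.csv"),
                 units = as.data.frame(gt$units), config = cfg,
                 seed = gt$seed),
            class = "fef_session")
}
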