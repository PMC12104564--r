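#' A single-electrode voltage trace
#'
#' Container for one MEA channel: the sampled extracellular voltage (uV),
#' its sampling rate, and the identifiers locating it on the plate and in the
#' experimental timeline (baseline / post-compound / washout phase).
#'
#' @param samples Numeric vector of voltages, uV. Must be non-empty.
#' @param sampling_rate Sampling rate, Hz (> 0). MEA recordings here are
#'   digitised at 20 kHz.
#' @param well_id,electrode_id Labels locating the channel on the plate.
#' @param phase One of `"baseline"`, `"post"`, `"washout"`.
#' @return An object of class `"channel_trace"`.
#' @export
channel_trace <- function(samples, sampling_rate,
                          well_id = "W01", electrode_id = "E01",
                          phase = c("baseline", "post", "washout")) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(samples), length(samples) > 0L, sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 well_id = well_id, electrode_id = electrode_id,
                 phase = phase),
            class = "channel_trace")
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace %s/%s [%s]: %d samples @ %g Hz (%.3g s)>\n",
              x$well_id, x$electrode_id, x$phase, length(x$samples),
              x$sampling_rate, length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Spike-detector configuration
#'
#' Holds every tunable of the extracellular detection chain: the band-pass
#' corners, the threshold multiplier applied to the robust baseline SD, the
#' dead time around each trigger, and the active-channel rate cut-off.
#'
#' @param band_low,band_high Band-pass corner frequencies, Hz. Defaults 1 kHz
#'   and 10 kHz; an upper corner at or above Nyquist is clipped to 0.45 x
#'   sampling rate at filter time, with a warning.
#' @param k_sd Threshold multiplier: spikes are excursions beyond +/- `k_sd`
#'   baseline SDs (default 5).
#' @param dead_pre_ms,dead_post_ms Detector dead time, ms: a 1 ms pre-trigger
#'   lockout and a 2 ms post-trigger skip by default, so detected spikes are
#'   never closer than their sum.
#' @param active_rate_min Rate cut-off, Hz: a channel is "active" when its
#'   mean firing rate strictly exceeds this value (default 0.33 Hz).
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(band_low = 1000, band_high = 10000, k_sd = 5,
                            dead_pre_ms = 1, dead_post_ms = 2,
                            active_rate_min = 0.33) {
  stopifnot(band_low > 0, band_low < band_high, k_sd > 0,
            dead_pre_ms >= 0, dead_post_ms >= 0, active_rate_min >= 0)
  structure(list(band_low = band_low, band_high = band_high, k_sd = k_sd,
                 dead_pre_ms = dead_pre_ms, dead_post_ms = dead_post_ms,
                 active_rate_min = active_rate_min),
            class = "detector_config")
}

#' Zero-phase band-pass filter for extracellular traces
#'
#' Applies a 2nd-order Butterworth band-pass forwards and backwards
#' (zero-phase, so spike timing is preserved) between the configured
#' corners. An upper corner at or above the Nyquist frequency is clipped to
#' 0.45 x sampling rate with a warning.
#'
#' @param trace A [channel_trace()].
#' @param cfg A [detector_config()].
#' @return A `channel_trace` of identical length with filtered samples.
#' @export
bandpass <- function(trace, cfg = detector_config()) {
  stopifnot(inherits(trace, "channel_trace"))
  fs <- trace$sampling_rate
  hi <- cfg$band_high
  if (hi >= 0.5 * fs) {
    hi <- 0.45 * fs
    warning(sprintf(
      "upper band edge %g Hz is at/above Nyquist (%g Hz); clipped to %g Hz",
      cfg$band_high, 0.5 * fs, hi))
  }
  if (cfg$band_low >= hi)
    stop("band degenerate after Nyquist clipping: band_low >= band_high")
  bf <- signal::butter(2, c(cfg$band_low, hi) / (fs / 2), type = "pass")
  out <- trace
  out$samples <- as.numeric(signal::filtfilt(bf, trace$samples))
  out
}

#' Robust baseline noise estimate
#'
#' Estimates the SD of the voltage baseline as 1.4826 x the median absolute
#' deviation of the (band-passed) samples. The MAD scaling makes the
#' estimate consistent for Gaussian noise while remaining essentially
#' unaffected by the spikes themselves.
#'
#' @param trace A band-passed [channel_trace()].
#' @return Baseline SD estimate, uV. Zero for a constant trace (detection is
#'   then disabled downstream).
#' @export
baseline_sd <- function(trace) {
  stopifnot(inherits(trace, "channel_trace"))
  stats::mad(trace$samples) # mad() already applies the 1.4826 factor
}

#' Detect spikes by two-sided threshold crossing with dead time
#'
#' Registers a spike at each sample where the absolute voltage first exceeds
#' `k_sd` x the baseline SD (crossing from below, either polarity). After a
#' trigger the detector skips the post-trigger dead window and will not
#' accept another trigger within the pre-trigger lockout, so no two spikes
#' are closer than `dead_pre_ms + dead_post_ms`.
#'
#' @param trace A band-passed [channel_trace()].
#' @param cfg A [detector_config()].
#' @param sd_est Optional precomputed [baseline_sd()]; computed from the
#'   trace when missing.
#' @return An object of class `"spike_train"`: list with `times` (s,
#'   strictly increasing), `duration` (s), `threshold` (uV) and the channel
#'   identifiers.
#' @export
detect_spikes <- function(trace, cfg = detector_config(), sd_est = NULL) {
  stopifnot(inherits(trace, "channel_trace"))
  fs <- trace$sampling_rate
  v <- trace$samples
  if (is.null(sd_est)) sd_est <- baseline_sd(trace)
  duration <- length(v) / fs
  mk <- function(times, thr) {
    structure(list(times = times, duration = duration, threshold = thr,
                   well_id = trace$well_id, electrode_id = trace$electrode_id,
                   phase = trace$phase),
              class = "spike_train")
  }
  if (sd_est <= 0) {
    warning("baseline SD is 0; spike detection disabled for this channel")
    return(mk(numeric(0), Inf))
  }
  thr <- cfg$k_sd * sd_est
  over <- abs(v) > thr
  # first sample of each supra-threshold run (crossing from below)
  cross <- which(over & !c(FALSE, over[-length(over)]))
  dead <- round((cfg$dead_pre_ms + cfg$dead_post_ms) / 1000 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last >= dead) {
      keep <- c(keep, i)
      last <- i
    }
  }
  mk((keep - 1L) / fs, thr)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s/%s [%s]: %d spikes in %.3g s (%.3g Hz)>\n",
              x$well_id, x$electrode_id, x$phase, length(x$times),
              x$duration, mean_rate(x)))
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' @param train A `spike_train` from [detect_spikes()].
#' @return Spike count divided by recording duration, Hz.
#' @export
mean_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"), train$duration > 0)
  length(train$times) / train$duration
}

#' Active-channel classification
#'
#' A channel is classified as active when its mean firing rate strictly
#' exceeds the configured cut-off (0.33 Hz by default); a channel at exactly
#' the cut-off is inactive.
#'
#' @param rate Mean firing rate(s), Hz.
#' @param cfg A [detector_config()].
#' @return Logical, same length as `rate`.
#' @export
classify_active <- function(rate, cfg = detector_config()) {
  stopifnot(all(rate >= 0))
  rate > cfg$active_rate_min
}

#' Per-channel rate table for a plate
#'
#' Runs the full detection chain (band-pass, robust SD, threshold detection,
#' rate, active label) over every channel and phase of a simulated or loaded
#' plate.
#'
#' @param plate A `simulated_plate` (see [simulate_plate()]) or the
#'   equivalent structure returned by [read_plate()].
#' @param cfg A [detector_config()].
#' @return A data frame with columns `well`, `electrode`, `phase`,
#'   `rate_hz`, `active`.
#' @export
plate_rates <- function(plate, cfg = detector_config()) {
  rows <- list()
  for (ch in names(plate$channels)) {
    for (ph in names(plate$channels[[ch]]$traces)) {
      tr <- plate$channels[[ch]]$traces[[ph]]
      filt <- bandpass(tr, cfg)
      train <- detect_spikes(filt, cfg)
      r <- mean_rate(train)
      rows[[length(rows) + 1L]] <- data.frame(
        well = tr$well_id, electrode = tr$electrode_id, phase = ph,
        rate_hz = r, active = classify_active(r, cfg))
    }
  }
  do.call(rbind, rows)
}
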