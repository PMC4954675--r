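# Frame-level acoustics: RMS volume, autocorrelation pitch, voicing.
# Deliberately content-free: only energy, periodicity and F0 are computed, so
# no representation from which speech could be reconstructed ever exists.

frame_grid <- function(n_samples, sample_rate, frame_s, hop_s) {
  frame_n <- round(frame_s * sample_rate)
  hop_n <- round(hop_s * sample_rate)
  if (hop_n <= 0 || frame_n < hop_n) {
    config_error("need frame_s >= hop_s > 0", field = "hop_s")
  }
  n_frames <- floor((n_samples - frame_n) / hop_n) + 1
  if (n_frames < 1) data_error("audio shorter than one frame")
  list(frame_n = frame_n, hop_n = hop_n, n_frames = n_frames,
       t_s = (seq_len(n_frames) - 1) * hop_s)
}

#' Per-frame RMS volume in dB
#'
#' Computes `20 * log10(RMS(frame))` on a regular frame grid, relative to
#' digital full scale (a full-scale square wave is 0 dBFS; a full-scale sine
#' is -3.01 dBFS). Frames quieter than `floor_db` are clamped to `floor_db`,
#' the documented representation of digital silence. `db_offset` shifts the
#' result onto a calibrated scale (`dB = dBFS + db_offset`).
#'
#' @param samples Numeric audio in \[-1, 1\].
#' @param sample_rate Sample rate (Hz).
#' @param frame_s Frame length (seconds).
#' @param hop_s Hop between frame starts (seconds).
#' @param floor_db Silence floor in dBFS.
#' @param db_offset Calibration offset added to the dBFS values.
#' @return A tibble with columns `t_s` and `volume_db`.
#' @export
#' @examples
#' x <- sin(2 * pi * 440 * seq(0, 0.2, by = 1 / 16000))
#' compute_volume_track(x, 16000)$volume_db[1]  # ~ -3.01 dBFS
compute_volume_track <- function(samples, sample_rate, frame_s = 0.032,
                                 hop_s = 0.016, floor_db = -100,
                                 db_offset = 0) {
  if (length(samples) == 0) data_error("audio is empty")
  if (any(!is.finite(samples))) data_error("audio contains non-finite samples")
  g <- frame_grid(length(samples), sample_rate, frame_s, hop_s)
  cs <- c(0, cumsum(samples^2))
  starts <- (seq_len(g$n_frames) - 1) * g$hop_n
  rms <- sqrt((cs[starts + g$frame_n + 1] - cs[starts + 1]) / g$frame_n)
  vol <- 20 * log10(pmax(rms, 10^(floor_db / 20))) + db_offset
  tibble::tibble(t_s = g$t_s, volume_db = vol)
}

#' Per-frame F0 by autocorrelation
#'
#' Estimates fundamental frequency per frame as the autocorrelation peak in
#' the lag range implied by `f0_range`, refined by parabolic interpolation.
#' `periodicity` is the normalized autocorrelation at the peak (1 for a pure
#' periodic tone, near 0 for noise); frames below `periodicity_threshold`
#' report `NA` pitch. Estimates are invariant to amplitude scaling.
#'
#' @param samples Numeric audio.
#' @param sample_rate Sample rate (Hz).
#' @param frame_s,hop_s Frame grid (seconds); the frame must hold at least
#'   two periods of the lowest admissible F0.
#' @param f0_range Length-2 numeric, F0 search range in Hz within (50, 500).
#' @param periodicity_threshold Minimum normalized autocorrelation for a
#'   frame to report a pitch.
#' @return A tibble with columns `t_s`, `pitch_hz`, `periodicity`.
#' @export
estimate_pitch <- function(samples, sample_rate, frame_s = 0.032,
                           hop_s = 0.016, f0_range = c(65, 300),
                           periodicity_threshold = 0.5) {
  if (length(samples) == 0) data_error("audio is empty")
  if (f0_range[1] <= 50 || f0_range[2] >= 500 || f0_range[1] >= f0_range[2]) {
    config_error("f0_range must be an interval inside (50, 500) Hz",
                 field = "f0_range")
  }
  g <- frame_grid(length(samples), sample_rate, frame_s, hop_s)
  if (g$frame_n < 2 * sample_rate / f0_range[1]) {
    config_error(sprintf(
      "frame of %.0f ms cannot hold two periods of %.0f Hz; lengthen frame_s or raise f0_range[1]",
      frame_s * 1000, f0_range[1]), field = "f0_range")
  }
  lag_min <- max(2L, floor(sample_rate / f0_range[2]))
  lag_max <- ceiling(sample_rate / f0_range[1])
  pad <- nextn(g$frame_n + lag_max + 1, 2)

  pitch <- rep(NA_real_, g$n_frames)
  period <- numeric(g$n_frames)
  chunk <- 2048L
  for (lo in seq(1L, g$n_frames, by = chunk)) {
    hi <- min(lo + chunk - 1L, g$n_frames)
    idx <- lo:hi
    starts <- (idx - 1L) * g$hop_n
    fm <- matrix(0, nrow = pad, ncol = length(idx))
    for (j in seq_along(idx)) {
      x <- samples[(starts[j] + 1):(starts[j] + g$frame_n)]
      fm[seq_len(g$frame_n), j] <- x - mean(x)
    }
    sp <- stats::mvfft(fm)
    ac <- Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / pad
    r0 <- ac[1, ]
    r0[r0 <= 0] <- NA_real_
    acn <- sweep(ac[(lag_min + 1):(lag_max + 1), , drop = FALSE], 2, r0, "/")
    # unbias the rectangular-window estimator: only frame_n - lag sample
    # pairs overlap at each lag, which otherwise tilts and lowers the peak
    acn <- acn * (g$frame_n / (g$frame_n - lag_min:lag_max))
    for (j in seq_along(idx)) {
      if (is.na(r0[j])) next
      v <- acn[, j]
      # local maxima; prefer the smallest lag within 10% of the global peak
      # (octave disambiguation: a periodic signal also peaks at 2x the lag)
      loc <- which(diff(sign(diff(v))) == -2) + 1
      if (length(loc) == 0) loc <- which.max(v)
      pk <- max(v[loc])
      b <- min(loc[v[loc] >= 0.9 * pk])
      period[idx[j]] <- min(pk, 1)
      if (pk < periodicity_threshold) next
      lag <- lag_min + b - 1
      # parabolic refinement around the peak
      if (b > 1 && b < nrow(acn)) {
        y1 <- acn[b - 1, j]; y2 <- acn[b, j]; y3 <- acn[b + 1, j]
        den <- y1 - 2 * y2 + y3
        if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
      }
      pitch[idx[j]] <- sample_rate / lag
    }
  }
  tibble::tibble(t_s = g$t_s, pitch_hz = pitch, periodicity = period)
}

#' Flag voiced frames
#'
#' A frame is voiced when its volume exceeds `energy_threshold_db` and either
#' its periodicity exceeds `periodicity_threshold` or both neighboring frames
#' pass the periodicity test (neighbor-majority rescue for single dropped
#' frames). The result is a pure function of the inputs, so re-applying it
#' changes nothing.
#'
#' @param volume_db Per-frame volume (same scale as the threshold).
#' @param periodicity Per-frame normalized autocorrelation peak.
#' @param energy_threshold_db Minimum volume for voicing.
#' @param periodicity_threshold Minimum periodicity for voicing.
#' @return Logical vector of voiced flags.
#' @export
detect_voiced <- function(volume_db, periodicity, energy_threshold_db = -45,
                          periodicity_threshold = 0.5) {
  if (!is.finite(energy_threshold_db) || !is.finite(periodicity_threshold)) {
    config_error("thresholds must be finite", field = "energy_threshold_db")
  }
  loud <- volume_db > energy_threshold_db
  per <- !is.na(periodicity) & periodicity > periodicity_threshold
  n <- length(loud)
  rescue <- loud & !per &
    c(FALSE, per[-n]) & c(per[-1], FALSE)
  (loud & per) | rescue
}

#' Extract a frame track from audio
#'
#' Runs [compute_volume_track()], [estimate_pitch()] and [detect_voiced()] on
#' one conversation and assembles the frame table the diarizer consumes.
#' Pitch is reported only on voiced frames.
#'
#' @param samples Numeric audio, or a path to a mono PCM-16 WAV file.
#' @param sample_rate Sample rate (ignored when `samples` is a path).
#' @param frame_s,hop_s Frame grid (seconds).
#' @param f0_range F0 search range (Hz).
#' @param db_offset Calibration offset added to dBFS volumes.
#' @param energy_threshold_db,periodicity_threshold Voicing thresholds; the
#'   energy threshold is on the same (offset) scale as `volume_db`.
#' @return A tibble with columns `t_s`, `volume_db`, `pitch_hz`, `voiced`,
#'   with the hop recorded in attribute `frame_hop_s`.
#' @export
extract_frame_track <- function(samples, sample_rate = 16000,
                                frame_s = 0.032, hop_s = 0.016,
                                f0_range = c(65, 300), db_offset = 0,
                                energy_threshold_db = -45 + db_offset,
                                periodicity_threshold = 0.5) {
  if (is.character(samples)) {
    wav <- read_wav(samples)
    samples <- wav$samples
    sample_rate <- wav$sample_rate
  }
  vol <- compute_volume_track(samples, sample_rate, frame_s, hop_s,
                              db_offset = db_offset)
  pit <- estimate_pitch(samples, sample_rate, frame_s, hop_s, f0_range,
                        periodicity_threshold)
  voiced <- detect_voiced(vol$volume_db, pit$periodicity,
                          energy_threshold_db, periodicity_threshold)
  out <- tibble::tibble(t_s = vol$t_s, volume_db = vol$volume_db,
                        pitch_hz = ifelse(voiced, pit$pitch_hz, NA_real_),
                        voiced = voiced)
  attr(out, "frame_hop_s") <- hop_s
  out
}
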