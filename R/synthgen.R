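# Synthetic conversation generator: participants, ground-truth turn
# structure, frame tracks, waveforms, and two-level enjoyment ratings.

#' Sample participant profiles
#'
#' Draws person-level parameters: demographics, Big-Five scores, person F0
#' mean (gender-dependent, truncated to the adult range), within-person F0
#' variability, per-role mean frame volumes (strictly decreasing over
#' clothing noise > participant > partner > silence by construction), and the
#' person-level rating intercept.
#'
#' @param config A [generator_config()].
#' @param n Number of profiles; defaults to `config$n_participants`.
#' @return A tibble with one row per participant.
#' @export
#' @examples
#' set.seed(1)
#' sample_participants(generator_config(), n = 3)
sample_participants <- function(config = generator_config(),
                                n = config$n_participants) {
  stopifnot(inherits(config, "generator_config"))
  gender <- ifelse(runif(n) < config$p_female, "female", "male")
  f0_mu <- unname(config$f0_gender_means_hz[gender])
  rv <- config$role_volume_db
  # role means truncated to disjoint bands so the ordering invariant holds
  lg <- lognorm_from_moments(config$f0_within_mean_hz, config$f0_within_sd_hz)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    gender = gender,
    age = round(rnorm_trunc(n, 20.6, 4.92, 17, 60)),
    big5_o = round(rnorm_trunc(n, 3.5, 0.7, 1, 5), 2),
    big5_c = round(rnorm_trunc(n, 3.4, 0.7, 1, 5), 2),
    big5_e = round(rnorm_trunc(n, 3.2, 0.8, 1, 5), 2),
    big5_a = round(rnorm_trunc(n, 3.7, 0.6, 1, 5), 2),
    big5_n = round(rnorm_trunc(n, 3.0, 0.8, 1, 5), 2),
    f0_mean_hz = rnorm_trunc(n, f0_mu, config$f0_person_sd_hz,
                             config$f0_range_hz[1], config$f0_range_hz[2]),
    f0_sd_hz = pmin(pmax(rlnorm(n, lg$meanlog, lg$sdlog), 5), 80),
    vol_clothing_db = rnorm_trunc(n, rv[["clothing_noise"]],
                                  config$person_role_sd_db,
                                  rv[["clothing_noise"]] - 2,
                                  rv[["clothing_noise"]] + 2),
    vol_participant_db = rnorm_trunc(n, rv[["participant"]],
                                     config$person_volume_sd_db,
                                     rv[["participant"]] - 5,
                                     rv[["participant"]] + 5),
    vol_other_db = rnorm_trunc(n, rv[["other"]], config$person_role_sd_db,
                               rv[["other"]] - 2, rv[["other"]] + 2),
    vol_silence_db = rnorm_trunc(n, rv[["silence"]], config$person_role_sd_db,
                                 rv[["silence"]] - 2, rv[["silence"]] + 2),
    random_intercept = rnorm(n, 0, config$random_intercept_sd)
  )
}

# Fast internal truth generator: returns list(start, end, role) tiling
# [0, realized length + trailing silence]. Alternating participant/other
# turns with lognormal durations (floored), optional silence gaps, and a
# trailing silence segment.
.gen_turns <- function(length_s, fraction, config) {
  floor_s <- config$turn_floor_s
  g <- 2 * config$silence_gap_prob * mean(config$silence_gap_s)
  cycle <- max(2 * config$turn_scale_s + g, floor_s / fraction,
               (floor_s + g) / (1 - fraction))
  if (cycle > length_s + 1e-6) {
    data_error(sprintf(
      "target speaking fraction %.3f is infeasible for a %.0f s conversation given the %.1f s turn floor",
      fraction, length_s, floor_s), class = "convotrace_generation_error")
  }
  d_p <- fraction * cycle
  d_o <- (1 - fraction) * cycle - g
  adj <- -config$turn_sdlog^2 / 2
  dur <- numeric(0); role <- character(0)
  n_cyc <- ceiling(length_s / cycle * 1.6) + 8
  repeat {
    dp <- pmax(floor_s, d_p * rlnorm(n_cyc, adj, config$turn_sdlog))
    do_ <- pmax(floor_s, d_o * rlnorm(n_cyc, adj, config$turn_sdlog))
    g1 <- ifelse(runif(n_cyc) < config$silence_gap_prob,
                 runif(n_cyc, config$silence_gap_s[1], config$silence_gap_s[2]),
                 0)
    g2 <- ifelse(runif(n_cyc) < config$silence_gap_prob,
                 runif(n_cyc, config$silence_gap_s[1], config$silence_gap_s[2]),
                 0)
    d_new <- as.vector(rbind(dp, g1, do_, g2))
    r_new <- rep(c("participant", "silence", "other", "silence"), n_cyc)
    keep <- d_new > 0
    dur <- c(dur, d_new[keep]); role <- c(role, r_new[keep])
    if (sum(dur) >= length_s) break
    n_cyc <- n_cyc * 2
  }
  if (runif(1) < 0.5) { dur <- rev(dur); role <- rev(role) }  # random opener
  cum <- cumsum(dur)
  n_keep <- which(cum >= length_s)[1]
  dur <- dur[seq_len(n_keep)]; role <- role[seq_len(n_keep)]
  # never end the spoken part on an internal gap: the trailing marker must
  # be exactly trailing_silence_s long
  while (length(role) > 1 && role[length(role)] == "silence") {
    dur <- dur[-length(dur)]; role <- role[-length(role)]
  }
  if (config$trailing_silence_s > 0) {
    dur <- c(dur, config$trailing_silence_s)
    role <- c(role, "silence")
  }
  # merge adjacent same-role runs
  same <- c(FALSE, role[-1] == role[-length(role)])
  grp <- cumsum(!same)
  dur <- as.vector(tapply(dur, grp, sum))
  role <- role[!same]
  end <- cumsum(dur)
  list(start = c(0, end[-length(end)]), end = end, role = role)
}

#' Sample a ground-truth turn sequence
#'
#' Generates the alternating two-speaker structure of one conversation as a
#' contiguous, non-overlapping segment table: participant and partner turns
#' with lognormal durations floored at `turn_floor_s`, optional short silence
#' gaps between turns, and a trailing silence of `trailing_silence_s` closing
#' the conversation. Turn-duration means are scaled so the expected
#' participant share of pre-trailing time equals the target fraction.
#'
#' @param config A [generator_config()].
#' @param length_s Target pre-trailing length in seconds; drawn from the
#'   configured length distribution when `NULL`.
#' @param speaking_fraction Target participant speaking fraction in (0, 1);
#'   drawn from the configured distribution when `NULL`.
#' @return A tibble with columns `start_s`, `end_s`, `role`, carrying the
#'   targets as attributes `target_length_s` and `target_fraction`.
#' @export
#' @examples
#' set.seed(7)
#' sample_turn_sequence(generator_config(), length_s = 120,
#'                      speaking_fraction = 0.4)
sample_turn_sequence <- function(config = generator_config(), length_s = NULL,
                                 speaking_fraction = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(length_s)) {
    ll <- config$length_lognorm
    length_s <- min(max(rlnorm(1, ll$meanlog, ll$sdlog), config$length_s$min),
                    config$length_s$max)
  }
  if (is.null(speaking_fraction)) {
    sb <- config$speaking_beta
    sf <- config$speaking_fraction
    speaking_fraction <- min(max(rbeta(1, sb$shape1, sb$shape2), sf$min),
                             sf$max)
    # a drawn target is clamped to what the turn floor permits at this
    # length; an explicitly requested infeasible target errors instead
    g <- 2 * config$silence_gap_prob * mean(config$silence_gap_s)
    speaking_fraction <- min(max(speaking_fraction,
                                 config$turn_floor_s / length_s),
                             1 - (config$turn_floor_s + g) / length_s)
  }
  if (speaking_fraction <= 0 || speaking_fraction >= 1) {
    config_error("speaking_fraction must lie strictly inside (0, 1)",
                 field = "speaking_fraction")
  }
  tt <- .gen_turns(length_s, speaking_fraction, config)
  out <- tibble::tibble(start_s = tt$start, end_s = tt$end, role = tt$role)
  attr(out, "target_length_s") <- length_s
  attr(out, "target_fraction") <- speaking_fraction
  out
}

# per-conversation acoustic parameters drawn around the person profile
.conv_params <- function(profile, config) {
  list(
    vol_mean_db = rnorm(1, profile$vol_participant_db,
                        config$conversation_volume_sd_db),
    vol_jitter_db = config$volume_jitter_db *
      rlnorm(1, -config$jitter_sdlog^2 / 2, config$jitter_sdlog),
    f0_mean_hz = rnorm_trunc(1, profile$f0_mean_hz,
                             config$f0_conversation_sd_hz,
                             config$f0_range_hz[1], config$f0_range_hz[2]),
    f0_sd_hz = profile$f0_sd_hz * rlnorm(1, -0.02, 0.2),
    other_f0_hz = runif(1, config$other_f0_hz[1], config$other_f0_hz[2]),
    vol_clothing_db = profile$vol_clothing_db,
    vol_other_db = profile$vol_other_db,
    vol_silence_db = profile$vol_silence_db
  )
}

#' Render a per-frame track from ground-truth segments
#'
#' Lays a regular frame grid over the conversation and draws each frame's
#' volume from its role's mean with Gaussian jitter. A small fraction of
#' frames (`clothing_burst_rate`) is overwritten with clothing-noise bursts.
#' Pitch follows an AR(1) track around the conversation's F0 mean and is
#' present only on participant frames; the voiced flag is true on participant
#' and partner frames that are not bursts.
#'
#' @param truth Segment tibble from [sample_turn_sequence()].
#' @param profile One-row tibble from [sample_participants()].
#' @param config A [generator_config()].
#' @param params Optional pre-drawn conversation parameters (internal use).
#' @return A tibble with columns `t_s`, `volume_db`, `pitch_hz`, `voiced`,
#'   `role`, `burst`; frame hop and the conversation parameters are attached
#'   as attributes.
#' @export
render_frame_track <- function(truth, profile, config = generator_config(),
                               params = NULL) {
  if (is.null(truth) || nrow(truth) == 0) {
    data_error("truth segment table is empty")
  }
  params <- params %||% .conv_params(profile, config)
  hop <- config$frame_hop_s
  total <- max(truth$end_s)
  n <- floor(total / hop)
  t_s <- (seq_len(n) - 1) * hop
  seg_idx <- findInterval(t_s, truth$start_s)
  role <- truth$role[seg_idx]

  base <- numeric(n)
  base[role == "participant"] <- params$vol_mean_db
  base[role == "other"] <- params$vol_other_db
  base[role == "silence"] <- params$vol_silence_db
  jit <- ifelse(role == "participant", params$vol_jitter_db,
                config$volume_jitter_db)
  volume <- base + rnorm(n, 0, jit)

  burst <- runif(n) < config$clothing_burst_rate
  volume[burst] <- params$vol_clothing_db +
    rnorm(sum(burst), 0, config$volume_jitter_db)

  phi <- config$pitch_ar_phi
  dev <- stats::filter(rnorm(n, 0, params$f0_sd_hz * sqrt(1 - phi^2)), phi,
                       method = "recursive")
  pitch <- params$f0_mean_hz + as.numeric(dev)
  pitch <- pmax(pitch, 55)
  pitch[role != "participant" | burst] <- NA_real_

  out <- tibble::tibble(
    t_s = t_s,
    volume_db = volume,
    pitch_hz = pitch,
    voiced = role %in% c("participant", "other") & !burst,
    role = role,
    burst = burst
  )
  attr(out, "frame_hop_s") <- hop
  attr(out, "conv_params") <- params
  out
}

#' Render a waveform from a frame track
#'
#' Synthesizes 16-bit-style mono audio whose per-frame RMS reproduces the
#' track's volume on the generator's dB scale (`dBFS = dB - db_offset`).
#' Participant frames become harmonic tones at the frame's pitch, partner
#' frames tones at the conversation's partner F0, clothing bursts and silence
#' white noise at the corresponding level. Frames are rendered as
#' non-overlapping cells of one hop each, with phase-continuous tones.
#'
#' @param track Frame track from [render_frame_track()].
#' @param config A [generator_config()].
#' @return A list with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
render_waveform <- function(track, config = generator_config()) {
  if (nrow(track) == 0) data_error("frame track is empty")
  sr <- config$sample_rate
  if (sr < 8000) config_error("sample_rate must be >= 8 kHz", "sample_rate")
  hop <- attr(track, "frame_hop_s") %||% config$frame_hop_s
  params <- attr(track, "conv_params")
  other_f0 <- if (!is.null(params)) params$other_f0_hz else 140
  hop_n <- round(hop * sr)
  n <- nrow(track)

  f0 <- rep(0, n)
  is_part <- track$role == "participant" & !track$burst & !is.na(track$pitch_hz)
  is_other <- track$role == "other" & !track$burst
  f0[is_part] <- track$pitch_hz[is_part]
  f0[is_other] <- other_f0
  tonal <- f0 > 0

  rms_target <- 10^((track$volume_db - config$db_offset) / 20)
  f0_s <- rep(f0, each = hop_n)
  phase <- cumsum(2 * pi * f0_s / sr)
  unit_rms <- sqrt((1 + 0.25 + 0.0625) / 2)
  tone <- (sin(phase) + 0.5 * sin(2 * phase) + 0.25 * sin(3 * phase)) / unit_rms
  gain <- rep(rms_target, each = hop_n)
  noise <- rnorm(n * hop_n)
  samples <- ifelse(rep(tonal, each = hop_n), tone * gain, noise * gain)
  samples <- pmin(pmax(samples, -1), 1)
  list(samples = samples, sample_rate = sr)
}

#' Sample enjoyment ratings from the two-level model
#'
#' Computes the latent rating `rating_mean + random_intercept + sum(beta_k *
#' z_k) + eps` with `eps ~ Normal(0, residual_sd)`, then (by default) rounds
#' to the nearest integer and clips to the 1-7 scale. Discretization slightly
#' attenuates effects recovered from the integer ratings relative to the
#' generating coefficients; fitting the continuous latent rating avoids this.
#'
#' @param z Data frame of z-scored predictors with columns `pct_speaking`,
#'   `length`, `turn_rate`, `vol_sd`, `pitch_sd` (extra columns ignored).
#' @param random_intercept Person-level intercept deviation (scalar or one
#'   value per row).
#' @param config A [generator_config()].
#' @param discretize Round-and-clip to 1-7? Defaults to `config$discretize`.
#' @return A tibble with columns `latent` and `rating`.
#' @export
#' @examples
#' set.seed(2)
#' z <- tibble::tibble(pct_speaking = rnorm(5), length = rnorm(5),
#'                     turn_rate = rnorm(5), vol_sd = rnorm(5),
#'                     pitch_sd = rnorm(5))
#' sample_rating(z, 0, generator_config())
sample_rating <- function(z, random_intercept = 0,
                          config = generator_config(),
                          discretize = config$discretize) {
  beta <- config$fixed_effects
  stopifnot_cols(z, names(beta), "z-scored predictor table")
  zm <- as.matrix(z[, names(beta)])
  latent <- config$rating_mean + random_intercept +
    drop(zm %*% beta) + rnorm(nrow(zm), 0, config$residual_sd)
  rating <- if (discretize) pmin(7L, pmax(1L, as.integer(round(latent))))
            else latent
  tibble::tibble(latent = latent, rating = rating)
}

#' Simulate standalone ratings under the generator's calibration
#'
#' Draws independent standard-normal predictor z-scores and person intercepts
#' and passes them through [sample_rating()]; used to check the marginal
#' rating calibration (mean 4.31, SD 1.25 under defaults).
#'
#' @param n Number of ratings.
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return A tibble with columns `latent` and `rating`.
#' @export
simulate_ratings <- function(n, config = generator_config(), seed = NULL) {
  with_seed(seed, {
    z <- tibble::as_tibble(setNames(
      lapply(names(config$fixed_effects), function(i) rnorm(n)),
      names(config$fixed_effects)))
    ri <- rnorm(n, 0, config$random_intercept_sd)
    sample_rating(z, ri, config)
  })
}

#' Generate a complete synthetic dataset
#'
#' Draws participants, per-person conversation counts, ground-truth turn
#' structure per conversation, conversation-level acoustic parameters, and
#' enjoyment ratings from the two-level model (fixed effects applied to the
#' grand-z-scored ground-truth features). Frame tracks and waveform rendering
#' are opt-in because they dominate run time at full scale.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param render_frames Also render per-frame tracks for every conversation?
#' @param render_wav Also synthesize waveforms (implies frame rendering)?
#' @return A list of class `convo_dataset` with elements `participants`,
#'   `conversations` (id, participant, rating, tie type), `truth_segments`,
#'   `truth_features` (ground-truth predictors plus `latent` and `rating`),
#'   `frames` (tibble or `NULL`), `waveforms` (list or `NULL`), and `config`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_participants = 2, seed = 42))
#' ds$truth_features
generate_dataset <- function(config = generator_config(), seed = config$seed,
                             render_frames = FALSE, render_wav = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, {
    participants <- sample_participants(config)
    ll <- config$length_lognorm
    nl <- config$nconv_lognorm
    cpp <- config$conversations_per_participant
    n_conv <- pmin(pmax(round(rlnorm(nrow(participants), nl$meanlog,
                                     nl$sdlog)), cpp$min), cpp$max)

    total <- sum(n_conv)
    conv_pid <- rep(participants$participant_id, n_conv)
    conv_id <- sprintf("C%04d", seq_len(total))
    sb <- config$speaking_beta
    sf <- config$speaking_fraction
    lengths <- pmin(pmax(rlnorm(total, ll$meanlog, ll$sdlog),
                         config$length_s$min), config$length_s$max)
    fractions <- pmin(pmax(rbeta(total, sb$shape1, sb$shape2), sf$min), sf$max)
    # clamp each target into the range the turn floor makes feasible for the
    # drawn length (a 1% target needs a long conversation to fit one floor
    # -length turn); keeps extreme tail draws generable
    g <- 2 * config$silence_gap_prob * mean(config$silence_gap_s)
    fractions <- pmin(pmax(fractions, config$turn_floor_s / lengths),
                      1 - (config$turn_floor_s + g) / lengths)

    seg_list <- vector("list", total)
    feat <- list(length_min = numeric(total), pct_speaking = numeric(total),
                 turn_count = integer(total), turn_rate = numeric(total),
                 vol_mean = numeric(total), vol_sd = numeric(total),
                 pitch_mean = numeric(total), pitch_sd = numeric(total))
    params_list <- vector("list", total)
    prof_idx <- rep(seq_len(nrow(participants)), n_conv)

    for (i in seq_len(total)) {
      tt <- .gen_turns(lengths[i], fractions[i], config)
      seg_list[[i]] <- tt
      p <- .conv_params(participants[prof_idx[i], ], config)
      params_list[[i]] <- p
      # trimmed ground truth: drop the trailing silence run
      m <- length(tt$role)
      keep <- seq_len(if (tt$role[m] == "silence") m - 1 else m)
      dur <- tt$end[keep] - tt$start[keep]
      len_s <- tt$end[max(keep)] - tt$start[1]
      feat$length_min[i] <- len_s / 60
      feat$pct_speaking[i] <-
        100 * sum(dur[tt$role[keep] == "participant"]) / len_s
      feat$turn_count[i] <-
        sum(tt$role[keep] %in% c("participant", "other"))
      feat$turn_rate[i] <- feat$turn_count[i] / (len_s / 60)
      feat$vol_mean[i] <- p$vol_mean_db
      feat$vol_sd[i] <- p$vol_jitter_db
      feat$pitch_mean[i] <- p$f0_mean_hz
      feat$pitch_sd[i] <- p$f0_sd_hz
    }

    truth_features <- tibble::tibble(
      conversation_id = conv_id, participant_id = conv_pid,
      length_min = feat$length_min, pct_speaking = feat$pct_speaking,
      turn_count = feat$turn_count, turn_rate_per_min = feat$turn_rate,
      vol_mean_db = feat$vol_mean, vol_sd_db = feat$vol_sd,
      pitch_mean_hz = feat$pitch_mean, pitch_sd_hz = feat$pitch_sd)

    z <- tibble::tibble(
      pct_speaking = as.numeric(scale(truth_features$pct_speaking)),
      length = as.numeric(scale(truth_features$length_min)),
      turn_rate = as.numeric(scale(truth_features$turn_rate_per_min)),
      vol_sd = as.numeric(scale(truth_features$vol_sd_db)),
      pitch_sd = as.numeric(scale(truth_features$pitch_sd_hz)))
    ri <- participants$random_intercept[prof_idx]
    rr <- sample_rating(z, ri, config)
    truth_features$latent <- rr$latent
    truth_features$rating <- rr$rating

    conversations <- tibble::tibble(
      conversation_id = conv_id, participant_id = conv_pid,
      rating = rr$rating,
      tie_type = sample(names(config$tie_type_probs), total, replace = TRUE,
                        prob = config$tie_type_probs))

    truth_segments <- tibble::tibble(
      conversation_id = rep(conv_id, vapply(seg_list, function(s)
        length(s$role), integer(1))),
      start_s = unlist(lapply(seg_list, `[[`, "start")),
      end_s = unlist(lapply(seg_list, `[[`, "end")),
      role = unlist(lapply(seg_list, `[[`, "role")))

    frames <- NULL
    waveforms <- NULL
    if (render_frames || render_wav) {
      fr <- vector("list", total)
      if (render_wav) waveforms <- vector("list", total)
      for (i in seq_len(total)) {
        tt <- seg_list[[i]]
        truth_i <- tibble::tibble(start_s = tt$start, end_s = tt$end,
                                  role = tt$role)
        tr <- render_frame_track(truth_i, participants[prof_idx[i], ], config,
                                 params = params_list[[i]])
        if (render_wav) waveforms[[i]] <- render_waveform(tr, config)
        tr$conversation_id <- conv_id[i]
        fr[[i]] <- tr
      }
      frames <- dplyr::bind_rows(fr)
      frames <- dplyr::relocate(frames, "conversation_id")
      if (render_wav) names(waveforms) <- conv_id
    }

    structure(list(participants = participants,
                   conversations = conversations,
                   truth_segments = truth_segments,
                   truth_features = truth_features,
                   frames = frames, waveforms = waveforms,
                   config = config),
              class = "convo_dataset")
  })
}

#' @export
print.convo_dataset <- function(x, ...) {
  cat("<convo_dataset>\n")
  cat("  participants:  ", nrow(x$participants), "\n")
  cat("  conversations: ", nrow(x$conversations), "\n")
  cat("  truth segments:", nrow(x$truth_segments), "\n")
  cat("  frames:        ",
      if (is.null(x$frames)) "not rendered" else nrow(x$frames), "\n")
  invisible(x)
}
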