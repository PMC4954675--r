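#' Configuration for the synthetic conversation generator
#'
#' Builds the full parameter set the generator draws from. Defaults encode the
#' study conditions the pipeline is designed for: 36 participants with a
#' right-skewed number of conversations each (mean 13, SD 12, between 3 and
#' 58), conversation lengths lognormal with mean 8.6 min and SD 15.5 min
#' (floored at 30 s), a target speaking fraction with mean 0.40 and SD 0.22,
#' roughly 7 speaking turns per minute, four frame-volume regimes at
#' 70/57/45/20 dB (clothing noise > participant > conversation partner >
#' silence) with 2 dB within-role frame jitter, adult fundamental frequencies
#' inside 92-253 Hz, a 60 s trailing silence closing every conversation, and
#' 1-7 enjoyment ratings from a two-level linear model with marginal mean 4.31
#' and SD 1.25 whose only non-zero standardized fixed effect is -0.19 on the
#' percentage of speaking time.
#'
#' The residual SD of the rating model is derived so the marginal rating SD
#' equals `rating_sd`: `sqrt(rating_sd^2 - sum(fixed_effects^2) -
#' random_intercept_sd^2)` (predictor z-scores are approximately independent
#' under the defaults).
#'
#' @param n_participants Number of participants.
#' @param conversations_per_participant List with `mean`, `sd`, `min`, `max`
#'   for the per-person conversation count (lognormal, rounded, clamped).
#' @param length_s List with `mean`, `sd`, `min`, `max` (seconds) for the
#'   pre-trailing-silence conversation length (lognormal, clamped).
#' @param speaking_fraction List with `mean`, `sd`, `min`, `max` for the
#'   per-conversation target speaking fraction (beta, clamped).
#' @param turn_scale_s Mean speaking-turn duration in seconds; the default
#'   `60/7` yields about 7 turns per minute.
#' @param turn_sdlog Lognormal sdlog of multiplicative turn-duration noise.
#' @param turn_floor_s Minimum turn duration (seconds); kept at the smoothing
#'   minimum so ground truth is recoverable after smoothing.
#' @param silence_gap_prob Probability of a silence gap after each turn.
#' @param silence_gap_s Length-2 numeric, uniform range of gap durations (s).
#' @param role_volume_db Named numeric: mean frame volume per role, must be
#'   strictly decreasing over clothing_noise, participant, other, silence.
#' @param volume_jitter_db Within-role frame volume SD (dB).
#' @param person_volume_sd_db Between-person SD of the participant role mean.
#' @param person_role_sd_db Between-person SD of the clothing-noise, partner
#'   and silence role means.
#' @param conversation_volume_sd_db Between-conversation SD of the
#'   participant role mean around the person mean.
#' @param jitter_sdlog Lognormal sdlog of the per-conversation jitter
#'   multiplier (spreads within-conversation volume variability).
#' @param f0_range_hz Length-2 numeric, admissible adult F0 range (Hz).
#' @param f0_gender_means_hz Named numeric, person-level F0 means (Hz) for
#'   `female` and `male`.
#' @param f0_person_sd_hz Between-person F0 SD (Hz).
#' @param f0_conversation_sd_hz Between-conversation F0 SD (Hz).
#' @param f0_within_mean_hz,f0_within_sd_hz Across-person mean and SD of the
#'   within-conversation frame-level F0 SD (Hz).
#' @param pitch_ar_phi AR(1) coefficient of the frame-level F0 track.
#' @param other_f0_hz Length-2 numeric, uniform range for the partner's F0.
#' @param p_female Probability a participant is female.
#' @param clothing_burst_rate Fraction of frames overwritten by clothing-noise
#'   bursts.
#' @param fixed_effects Named numeric, standardized fixed effects on the
#'   rating for `pct_speaking`, `length`, `turn_rate`, `vol_sd`, `pitch_sd`.
#' @param rating_mean,rating_sd Marginal mean and SD of the enjoyment rating.
#' @param random_intercept_sd SD of the person-level rating intercept.
#' @param trailing_silence_s Trailing silence appended to each conversation.
#' @param frame_s,frame_hop_s Analysis frame length and hop (seconds).
#' @param sample_rate Waveform sample rate (Hz).
#' @param db_offset Calibration offset mapping the generator's dB scale to
#'   dBFS (`dBFS = dB - db_offset`).
#' @param discretize Should ratings be rounded and clipped to 1-7?
#' @param tie_type_probs Named probabilities for `strong`, `weak`, `other`.
#' @param seed Default RNG seed used by [generate_dataset()].
#'
#' @return A list of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_participants = 4, seed = 1)
#' cfg$residual_sd
generator_config <- function(
    n_participants = 36,
    conversations_per_participant = list(mean = 13, sd = 12, min = 3, max = 58),
    length_s = list(mean = 516, sd = 930, min = 30, max = 7680),
    speaking_fraction = list(mean = 0.40, sd = 0.22, min = 0.01, max = 0.95),
    turn_scale_s = 60 / 7,
    turn_sdlog = 0.5,
    turn_floor_s = 1.5,
    silence_gap_prob = 0.2,
    silence_gap_s = c(1.5, 5),
    role_volume_db = c(clothing_noise = 70, participant = 57, other = 45,
                       silence = 20),
    volume_jitter_db = 2,
    person_volume_sd_db = 3,
    person_role_sd_db = 1,
    conversation_volume_sd_db = 1.5,
    jitter_sdlog = 0.25,
    f0_range_hz = c(92, 253),
    f0_gender_means_hz = c(female = 200, male = 165),
    f0_person_sd_hz = 25,
    f0_conversation_sd_hz = 8,
    f0_within_mean_hz = 39,
    f0_within_sd_hz = 23,
    pitch_ar_phi = 0.95,
    other_f0_hz = c(110, 180),
    p_female = 0.6,
    clothing_burst_rate = 0.03,
    fixed_effects = c(pct_speaking = -0.19, length = 0, turn_rate = 0,
                      vol_sd = 0, pitch_sd = 0),
    rating_mean = 4.31,
    rating_sd = 1.25,
    random_intercept_sd = 0.5,
    trailing_silence_s = 60,
    frame_s = 0.032,
    frame_hop_s = 0.016,
    sample_rate = 16000,
    db_offset = 80,
    discretize = TRUE,
    tie_type_probs = c(strong = 0.444, weak = 0.416, other = 0.140),
    seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)

  # derived quantities
  cfg$length_lognorm <- lognorm_from_moments(length_s$mean, length_s$sd)
  cfg$nconv_lognorm <- lognorm_from_moments(conversations_per_participant$mean,
                                            conversations_per_participant$sd)
  cfg$speaking_beta <- beta_from_moments(speaking_fraction$mean,
                                         speaking_fraction$sd)
  explained <- sum(fixed_effects^2) + random_intercept_sd^2
  if (explained >= rating_sd^2) {
    config_error(paste0(
      "rating_sd^2 must exceed sum(fixed_effects^2) + random_intercept_sd^2 ",
      "so a non-negative residual variance exists"), field = "rating_sd")
  }
  cfg$residual_sd <- sqrt(rating_sd^2 - explained)
  cfg
}

lognorm_from_moments <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

beta_from_moments <- function(mean, sd) {
  k <- mean * (1 - mean) / sd^2 - 1
  if (k <= 0) config_error("speaking_fraction sd too large for its mean",
                           field = "speaking_fraction")
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

validate_generator_config <- function(cfg) {
  check <- function(ok, msg, field) if (!ok) config_error(msg, field = field)
  check(is.numeric(cfg$n_participants) && cfg$n_participants >= 1,
        "n_participants must be a positive count", "n_participants")
  cpp <- cfg$conversations_per_participant
  check(cpp$min >= 1 && cpp$max >= cpp$min,
        "conversations_per_participant min/max invalid",
        "conversations_per_participant")
  check(cfg$length_s$min > 0 && cfg$length_s$max > cfg$length_s$min,
        "length_s min/max invalid", "length_s")
  sf <- cfg$speaking_fraction
  check(sf$min > 0 && sf$max < 1 && sf$max > sf$min,
        "speaking_fraction must stay inside (0, 1)", "speaking_fraction")
  rv <- cfg$role_volume_db
  roles <- c("clothing_noise", "participant", "other", "silence")
  check(all(roles %in% names(rv)), "role_volume_db must name all four roles",
        "role_volume_db")
  check(all(diff(rv[roles]) < 0),
        "role_volume_db must be strictly decreasing over clothing_noise, participant, other, silence",
        "role_volume_db")
  check(cfg$turn_floor_s > 0, "turn_floor_s must be positive", "turn_floor_s")
  check(cfg$f0_range_hz[1] > 50 && cfg$f0_range_hz[2] < 500 &&
          diff(cfg$f0_range_hz) >= 0,
        "f0_range_hz must be an interval inside (50, 500) Hz", "f0_range_hz")
  check(all(cfg$f0_gender_means_hz >= cfg$f0_range_hz[1] &
              cfg$f0_gender_means_hz <= cfg$f0_range_hz[2]),
        "f0_gender_means_hz must lie inside f0_range_hz", "f0_gender_means_hz")
  preds <- c("pct_speaking", "length", "turn_rate", "vol_sd", "pitch_sd")
  check(all(preds %in% names(cfg$fixed_effects)),
        paste("fixed_effects must name:", paste(preds, collapse = ", ")),
        "fixed_effects")
  check(cfg$rating_mean >= 1 && cfg$rating_mean <= 7,
        "rating_mean must lie on the 1-7 scale", "rating_mean")
  check(cfg$rating_sd > 0, "rating_sd must be positive", "rating_sd")
  check(cfg$trailing_silence_s >= 0, "trailing_silence_s must be >= 0",
        "trailing_silence_s")
  check(cfg$frame_s >= cfg$frame_hop_s && cfg$frame_hop_s > 0,
        "need frame_s >= frame_hop_s > 0", "frame_hop_s")
  check(cfg$sample_rate >= 8000, "sample_rate must be at least 8 kHz",
        "sample_rate")
  invisible(cfg)
}
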