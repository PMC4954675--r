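# Conversation-level predictors: length, % speaking, turn rate, and the
# participant's acoustic summary statistics.

#' Conversation length in minutes
#'
#' Span of the (trailing-silence-trimmed) segment table, in minutes. Internal
#' silence counts toward the length; only the end-of-conversation marker is
#' excluded upstream.
#'
#' @param segments Trimmed segment tibble (`start_s`, `end_s`, `role`).
#' @return Length in minutes.
#' @export
#' @examples
#' conversation_length(tibble::tibble(start_s = 0, end_s = 516,
#'                                    role = "participant"))  # 8.6
conversation_length <- function(segments) {
  stopifnot_cols(segments, c("start_s", "end_s"), "segments")
  if (nrow(segments) == 0) data_error("empty segment table")
  (segments$end_s[nrow(segments)] - segments$start_s[1]) / 60
}

#' Percentage of time the participant was speaking
#'
#' Total participant-role time divided by the conversation length, as a
#' percentage (0-100). The denominator is the full trimmed length including
#' internal silence.
#'
#' @inheritParams conversation_length
#' @return Percentage in \[0, 100\].
#' @export
pct_speaking <- function(segments) {
  stopifnot_cols(segments, c("start_s", "end_s", "role"), "segments")
  if (nrow(segments) == 0) data_error("empty segment table")
  len_s <- segments$end_s[nrow(segments)] - segments$start_s[1]
  if (len_s <= 0) data_error("conversation has zero length")
  p <- segments$role == "participant"
  100 * sum(segments$end_s[p] - segments$start_s[p]) / len_s
}

#' Turn count and turn-taking rate
#'
#' A turn is a maximal voiced run attributed to one speaker; the count is the
#' number of segments with role participant or other (so participant, then
#' someone else, then the participant again is 3 turns), and the rate is
#' turns per minute of conversation.
#'
#' @inheritParams conversation_length
#' @return A list with `turn_count` and `turn_rate_per_min`.
#' @export
#' @examples
#' segs <- tibble::tibble(start_s = c(0, 40, 80), end_s = c(40, 80, 120),
#'                        role = c("participant", "other", "participant"))
#' turn_rate(segs)$turn_count  # 3
turn_rate <- function(segments) {
  stopifnot_cols(segments, c("start_s", "end_s", "role"), "segments")
  if (nrow(segments) == 0) data_error("empty segment table")
  n_turns <- sum(segments$role %in% c("participant", "other"))
  list(turn_count = n_turns,
       turn_rate_per_min = n_turns / conversation_length(segments))
}

#' Participant acoustic summary statistics
#'
#' Pools frames lying inside participant-role segments and returns the mean
#' and SD of their volume, and of their pitch over the frames where a pitch
#' is present. When the track carries a `voiced` column, only voiced frames
#' are pooled (clothing-noise bursts inside a speaking segment are unvoiced
#' and would otherwise inflate the volume statistics). Pooling is
#' frame-weighted by default (every frame counts equally);
#' `weighting = "segment"` averages per-segment statistics instead. SDs use
#' the sample (n-1) convention.
#'
#' @param track Frame-track tibble (`t_s`, `volume_db`, `pitch_hz`).
#' @param segments Segment tibble aligned on the same time axis.
#' @param weighting `"frame"` (default) or `"segment"`.
#' @return A list with `vol_mean_db`, `vol_sd_db`, `pitch_mean_hz`,
#'   `pitch_sd_hz` (pitch entries `NA` when no participant frame carries
#'   pitch, and the whole set `NA` when there are no participant frames).
#' @export
participant_acoustics <- function(track, segments,
                                  weighting = c("frame", "segment")) {
  weighting <- match.arg(weighting)
  stopifnot_cols(track, c("t_s", "volume_db"), "frame track")
  stopifnot_cols(segments, c("start_s", "end_s", "role"), "segments")
  p_segs <- segments[segments$role == "participant", , drop = FALSE]
  na_out <- list(vol_mean_db = NA_real_, vol_sd_db = NA_real_,
                 pitch_mean_hz = NA_real_, pitch_sd_hz = NA_real_)
  if (nrow(p_segs) == 0) return(na_out)
  if ("voiced" %in% names(track)) {
    track <- track[track$voiced, , drop = FALSE]
    if (nrow(track) == 0) return(na_out)
  }
  seg_of <- function(t) {
    i <- findInterval(t, p_segs$start_s)
    inside <- i >= 1 & t < p_segs$end_s[pmax(i, 1)]
    ifelse(inside, i, NA_integer_)
  }
  idx <- seg_of(track$t_s)
  if (all(is.na(idx))) return(na_out)
  vol <- track$volume_db[!is.na(idx)]
  pit <- track$pitch_hz[!is.na(idx)]
  pit_seg <- idx[!is.na(idx)][!is.na(pit)]
  pit <- pit[!is.na(pit)]
  if (weighting == "frame") {
    list(vol_mean_db = mean(vol),
         vol_sd_db = if (length(vol) > 1) sd(vol) else 0,
         pitch_mean_hz = if (length(pit)) mean(pit) else NA_real_,
         pitch_sd_hz = if (length(pit) > 1) sd(pit)
                       else if (length(pit) == 1) 0 else NA_real_)
  } else {
    vseg <- idx[!is.na(idx)]
    vm <- tapply(vol, vseg, mean)
    vs <- tapply(vol, vseg, function(x) if (length(x) > 1) sd(x) else 0)
    pm <- if (length(pit)) tapply(pit, pit_seg, mean) else NULL
    ps <- if (length(pit)) {
      tapply(pit, pit_seg, function(x) if (length(x) > 1) sd(x) else 0)
    } else NULL
    list(vol_mean_db = mean(vm), vol_sd_db = mean(vs),
         pitch_mean_hz = if (length(pit)) mean(pm) else NA_real_,
         pitch_sd_hz = if (length(pit)) mean(ps) else NA_real_)
  }
}

#' Conversation-level feature row
#'
#' Combines length, percentage of speaking time, turn-taking rate and the
#' participant's acoustic statistics into the one-row predictor table used by
#' QC and the enjoyment model.
#'
#' @param segments Trimmed, smoothed segment tibble for one conversation.
#' @param track Optional frame track; acoustic columns are `NA` without it.
#' @param conversation_id Identifier copied into the row.
#' @param weighting Passed to [participant_acoustics()].
#' @return A one-row tibble with columns `conversation_id`, `length_min`,
#'   `pct_speaking`, `turn_count`, `turn_rate_per_min`, `vol_mean_db`,
#'   `vol_sd_db`, `pitch_mean_hz`, `pitch_sd_hz`.
#' @export
conversation_features <- function(segments, track = NULL,
                                  conversation_id = NA_character_,
                                  weighting = "frame") {
  tr <- turn_rate(segments)
  ac <- if (is.null(track)) {
    list(vol_mean_db = NA_real_, vol_sd_db = NA_real_,
         pitch_mean_hz = NA_real_, pitch_sd_hz = NA_real_)
  } else {
    participant_acoustics(track, segments, weighting)
  }
  tibble::tibble(conversation_id = conversation_id,
                 length_min = conversation_length(segments),
                 pct_speaking = pct_speaking(segments),
                 turn_count = tr$turn_count,
                 turn_rate_per_min = tr$turn_rate_per_min,
                 vol_mean_db = ac$vol_mean_db, vol_sd_db = ac$vol_sd_db,
                 pitch_mean_hz = ac$pitch_mean_hz,
                 pitch_sd_hz = ac$pitch_sd_hz)
}

#' Features for a batch of diarized conversations
#'
#' @param segments Segment tibble with a `conversation_id` column.
#' @param frames Optional frames tibble with a `conversation_id` column.
#' @param weighting Passed to [participant_acoustics()].
#' @return A tibble with one feature row per conversation.
#' @export
conversation_features_all <- function(segments, frames = NULL,
                                      weighting = "frame") {
  stopifnot_cols(segments, c("conversation_id", "start_s", "end_s", "role"),
                 "segments")
  ids <- unique(segments$conversation_id)
  purrr::map_dfr(ids, function(id) {
    seg <- segments[segments$conversation_id == id, ]
    trk <- if (is.null(frames)) NULL else
      frames[frames$conversation_id == id, ]
    conversation_features(seg, trk, conversation_id = id,
                          weighting = weighting)
  })
}
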