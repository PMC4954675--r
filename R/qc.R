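# Quality control: conversation-level exclusion rules and the
# minimum-conversations participant filter.

#' Apply conversation-level exclusion rules
#'
#' Flags conversations that signal corrupted files or failed diarization:
#' negative computed speaking time, no non-participant time (the participant
#' appears to speak 100% of the time), turn-taking rate or average volume
#' more than `sd_mult` SDs above the batch mean, or an average pitch above
#' the adult maximum (`pitch_max_hz`). All thresholds are computed on the
#' full pre-exclusion batch in a single pass and all five rules are evaluated
#' simultaneously against them; a conversation is excluded iff at least one
#' flag is set.
#'
#' The negative-speaking-time rule cannot fire on features computed by this
#' package (durations are non-negative by construction); it guards feature
#' tables imported from elsewhere, where it historically indicated file
#' corruption.
#'
#' @param features Feature tibble with columns `pct_speaking`,
#'   `turn_rate_per_min`, `vol_mean_db`, `pitch_mean_hz`.
#' @param pitch_max_hz Maximum admissible mean pitch (Hz).
#' @param sd_mult Multiplier for the mean + k*SD outlier thresholds.
#' @param frozen_thresholds Optional list with `turn_rate_max` and
#'   `volume_max` taken from a previous run's `thresholds`; when supplied the
#'   batch statistics are not recomputed, which makes re-application on the
#'   retained rows a no-op.
#' @return A list of class `qc_result`: `retained` (unflagged rows), `flags`
#'   (per-conversation logical rule flags), `counts` (exclusions per rule),
#'   and `thresholds` (the resolved numeric cutoffs).
#' @export
#' @examples
#' f <- tibble::tibble(conversation_id = c("a", "b"),
#'                     pct_speaking = c(40, 100),
#'                     turn_rate_per_min = c(7, 7),
#'                     vol_mean_db = c(57, 57),
#'                     pitch_mean_hz = c(180, 180))
#' apply_exclusion_rules(f)$counts
apply_exclusion_rules <- function(features, pitch_max_hz = 255, sd_mult = 3,
                                  frozen_thresholds = NULL) {
  stopifnot_cols(features, c("pct_speaking", "turn_rate_per_min",
                             "vol_mean_db", "pitch_mean_hz"),
                 "feature table")
  if (nrow(features) == 0) data_error("feature table is empty")
  thr <- list(
    pitch_max_hz = pitch_max_hz,
    sd_mult = sd_mult,
    turn_rate_max = frozen_thresholds$turn_rate_max %||%
      (mean(features$turn_rate_per_min, na.rm = TRUE) +
         sd_mult * sd(features$turn_rate_per_min, na.rm = TRUE)),
    volume_max = frozen_thresholds$volume_max %||%
      (mean(features$vol_mean_db, na.rm = TRUE) +
         sd_mult * sd(features$vol_mean_db, na.rm = TRUE)))
  flags <- tibble::tibble(
    conversation_id = features$conversation_id %||%
      as.character(seq_len(nrow(features))),
    negative_speaking_time = features$pct_speaking < 0,
    no_nonparticipant_time = features$pct_speaking >= 100,
    turn_rate_gt_3sd = features$turn_rate_per_min > thr$turn_rate_max,
    volume_gt_3sd = !is.na(features$vol_mean_db) &
      features$vol_mean_db > thr$volume_max,
    pitch_gt_255 = !is.na(features$pitch_mean_hz) &
      features$pitch_mean_hz > pitch_max_hz)
  rule_cols <- setdiff(names(flags), "conversation_id")
  excluded <- Reduce(`|`, flags[rule_cols])
  structure(list(retained = features[!excluded, , drop = FALSE],
                 flags = flags,
                 counts = vapply(flags[rule_cols], sum, integer(1)),
                 n_excluded = sum(excluded),
                 thresholds = thr),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  cat("  retained:", nrow(x$retained), "of",
      nrow(x$retained) + x$n_excluded, "conversations\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Drop participants with too few conversations
#'
#' The within-person model needs a practical minimum number of conversations
#' per person (default 3); participants below it are dropped with a logged
#' reason. The boundary is inclusive: exactly `min_conversations`
#' conversations is enough.
#'
#' @param conversations Tibble with a `participant_id` column, one row per
#'   retained conversation.
#' @param min_conversations Minimum retained conversations to keep a
#'   participant.
#' @return A list with `retained` (rows of kept participants), `kept_ids`,
#'   and `dropped` (tibble of dropped ids, their counts, and the reason).
#' @export
participant_filter <- function(conversations, min_conversations = 3) {
  stopifnot_cols(conversations, "participant_id", "conversation table")
  counts <- table(conversations$participant_id)
  kept <- names(counts)[counts >= min_conversations]
  dropped_ids <- names(counts)[counts < min_conversations]
  list(retained = conversations[conversations$participant_id %in% kept, ,
                                drop = FALSE],
       kept_ids = kept,
       dropped = tibble::tibble(
         participant_id = dropped_ids,
         n_conversations = as.integer(counts[dropped_ids]),
         reason = sprintf("fewer than %d conversations", min_conversations)))
}

#' QC report as a plain list (for JSON serialization)
#'
#' @param qc A `qc_result` from [apply_exclusion_rules()].
#' @param dropped_participants Optional `dropped` tibble from
#'   [participant_filter()].
#' @return A nested list mirroring the QC outcome.
#' @export
qc_report <- function(qc, dropped_participants = NULL) {
  list(n_input = nrow(qc$retained) + qc$n_excluded,
       n_retained = nrow(qc$retained),
       exclusion_counts = as.list(qc$counts),
       thresholds = qc$thresholds,
       participants_dropped = if (is.null(dropped_participants)) list()
       else dropped_participants)
}
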