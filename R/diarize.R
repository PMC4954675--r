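# Volume-based speaker diarization: k-means on the 1-D frame-volume series
# (k = 4 regimes: clothing noise > participant > partner > silence),
# minimum-duration smoothing, trailing-silence removal.

#' Diarization configuration
#'
#' @param k Number of volume clusters; 4 in role-faithful mode (clothing
#'   noise, participant, other, silence).
#' @param engine `"exact"` (default) computes the guaranteed-optimal 1-D
#'   k-means partition by dynamic programming; `"lloyd"` runs
#'   [stats::kmeans()] with `n_restarts` random starts.
#' @param n_restarts Random restarts for the Lloyd engine.
#' @param seed Seed for the Lloyd engine.
#' @param min_segment_s Minimum segment duration enforced by smoothing
#'   (seconds).
#' @param trailing_silence_window_s Trailing silence duration that marks the
#'   end-of-conversation marker to remove (seconds).
#' @param trailing_tol_s Slack below the window still accepted as the
#'   trailing marker (absorbs frame quantization).
#' @return A list of class `diarization_config`.
#' @export
diarization_config <- function(k = 4, engine = c("exact", "lloyd"),
                               n_restarts = 10, seed = NULL,
                               min_segment_s = 1.5,
                               trailing_silence_window_s = 60,
                               trailing_tol_s = 0.5) {
  engine <- match.arg(engine)
  if (k < 1) config_error("k must be a positive count", field = "k")
  if (min_segment_s <= 0) {
    config_error("min_segment_s must be positive", field = "min_segment_s")
  }
  structure(list(k = k, engine = engine, n_restarts = n_restarts, seed = seed,
                 min_segment_s = min_segment_s,
                 trailing_silence_window_s = trailing_silence_window_s,
                 trailing_tol_s = trailing_tol_s),
            class = "diarization_config")
}

#' Cluster frames by volume
#'
#' Partitions the 1-D frame-volume series into `k` clusters minimizing the
#' within-cluster sum of squares. The default engine solves the 1-D problem
#' exactly (the optimum is an interval partition of the sorted volumes, found
#' by dynamic programming); the `lloyd` engine reproduces classic seeded
#' k-means with restarts.
#'
#' @param track A frame-track tibble with a `volume_db` column, or a numeric
#'   vector of volumes.
#' @param config A [diarization_config()].
#' @param conversation_id Identifier used in error messages.
#' @return A list with `cluster` (1-based index per frame), `centroids` (dB),
#'   `size`, and `wcss`.
#' @export
#' @examples
#' v <- rep(c(70, 57, 45, 20), each = 50)
#' cluster_frames(v)$centroids
cluster_frames <- function(track, config = diarization_config(),
                           conversation_id = NULL) {
  v <- if (is.data.frame(track)) track$volume_db else track
  if (is.null(v)) data_error("track has no volume_db column",
                             class = "convotrace_schema_error")
  n_distinct <- length(unique(v))
  if (n_distinct < config$k) {
    data_error(sprintf(
      "conversation %s has only %d distinct volume values; cannot form k = %d clusters",
      conversation_id %||% "<unnamed>", n_distinct, config$k),
      class = "convotrace_degenerate_error")
  }
  if (config$engine == "exact") {
    fit <- .kmeans1d_dp(v, config$k)
    list(cluster = fit$cluster, centroids = fit$centers, size = fit$size,
         wcss = fit$wcss)
  } else {
    fit <- with_seed(config$seed,
                     stats::kmeans(v, centers = config$k,
                                   nstart = config$n_restarts))
    list(cluster = fit$cluster, centroids = as.numeric(fit$centers),
         size = fit$size, wcss = fit$tot.withinss)
  }
}

#' Map volume clusters to conversational roles
#'
#' Roles are assigned by descending centroid volume: the loudest cluster is
#' clothing noise (phone rubbing against clothing, often above what a
#' microphone-adjacent listener would tolerate), then the participant (the
#' voice closest to the phone), then other speakers, then silence. Centroids
#' closer than 1e-6 dB make the ordering ambiguous and raise an error — this
#' is how a conversation genuinely missing one regime surfaces, rather than
#' being silently relabeled.
#'
#' @param centroids Numeric vector of 4 cluster centroids (dB).
#' @param conversation_id Identifier used in error messages.
#' @return Character vector of roles, one per input centroid.
#' @export
#' @examples
#' assign_roles(c(70, 57, 45, 20))
assign_roles <- function(centroids, conversation_id = NULL) {
  if (length(centroids) != 4 || any(!is.finite(centroids))) {
    data_error("assign_roles expects exactly 4 finite centroids")
  }
  s <- sort(centroids, decreasing = TRUE)
  if (any(abs(diff(s)) < 1e-6)) {
    data_error(sprintf(
      "conversation %s: tied centroids (%s dB) make the role order ambiguous",
      conversation_id %||% "<unnamed>",
      paste(signif(s, 6), collapse = ", ")),
      class = "convotrace_ambiguous_roles_error")
  }
  roles <- c("clothing_noise", "participant", "other", "silence")
  roles[rank(-centroids)]
}

# maximal runs of identical labels -> durations
labels_to_runs <- function(labels, hop_s) {
  r <- rle(labels)
  list(role = r$values, dur = r$lengths * hop_s)
}

#' Smooth frame labels to a minimum segment duration
#'
#' Collapses spurious short segments produced by frame-level clustering (for
#' example a participant's quietest frames falling into the partner cluster).
#' The shortest run below `min_segment_s` is absorbed into its longer
#' neighbor (ties go to the earlier neighbor), adjacent same-role runs are
#' merged, and the step repeats until every run is at least `min_segment_s`
#' long or a single run remains. Total duration is preserved.
#'
#' @param labels Character vector of per-frame role labels, or a list with
#'   `role` and `dur` giving pre-computed runs.
#' @param hop_s Frame hop in seconds (ignored for run input).
#' @param config A [diarization_config()]; `min_segment_s` is used.
#' @return A tibble of segments with `start_s`, `end_s`, `role`.
#' @export
#' @examples
#' smooth_segments(list(role = c("participant", "other", "participant"),
#'                      dur = c(5, 0.8, 5)))
smooth_segments <- function(labels, hop_s = 0.016,
                            config = diarization_config()) {
  if (is.list(labels) && !is.null(labels$role)) {
    role <- labels$role
    dur <- labels$dur
  } else {
    if (length(labels) == 0) data_error("empty label sequence")
    r <- labels_to_runs(labels, hop_s)
    role <- r$role
    dur <- r$dur
  }
  if (length(role) == 0) data_error("empty label sequence")
  # pre-merge adjacent same-role runs, then absorb in compiled code
  same <- c(FALSE, role[-1] == role[-length(role)])
  grp <- cumsum(!same)
  dur <- as.vector(tapply(dur, grp, sum))
  role <- role[!same]
  lev <- unique(role)
  sm <- .smooth_runs_dp(dur, match(role, lev), config$min_segment_s)
  end <- cumsum(sm$dur)
  tibble::tibble(start_s = c(0, end[-length(end)]), end_s = end,
                 role = lev[sm$role])
}

#' Remove the trailing end-of-conversation silence
#'
#' Drops the final silence segment when it is at least
#' `trailing_silence_window_s - trailing_tol_s` long — the silent minute the
#' recording protocol uses to mark that a conversation has ended. Earlier
#' silence segments are untouched and the operation is idempotent.
#'
#' @param segments Segment tibble (`start_s`, `end_s`, `role`).
#' @param config A [diarization_config()].
#' @return The segment tibble without the trailing marker.
#' @export
trim_trailing_silence <- function(segments, config = diarization_config()) {
  stopifnot_cols(segments, c("start_s", "end_s", "role"), "segments")
  if (nrow(segments) == 0) data_error("empty segment table")
  if (all(segments$role == "silence")) {
    data_error("conversation is entirely silence",
               class = "convotrace_empty_conversation_error")
  }
  n <- nrow(segments)
  last_dur <- segments$end_s[n] - segments$start_s[n]
  thr <- config$trailing_silence_window_s - config$trailing_tol_s
  if (segments$role[n] == "silence" && last_dur >= thr) {
    segments <- segments[-n, ]
  }
  segments
}

#' Diarize one conversation's frame track
#'
#' Runs the full per-conversation chain: k-means volume clustering, role
#' assignment by centroid order, minimum-duration smoothing, and
#' trailing-silence removal.
#'
#' @param track Frame-track tibble with `t_s` and `volume_db` (hop read from
#'   the `frame_hop_s` attribute or inferred from `t_s`).
#' @param config A [diarization_config()].
#' @param conversation_id Identifier carried into errors and the report.
#' @return A list of class `diarization`: `segments` (trimmed), `centroids`
#'   (named by role, descending volume), `wcss`, `cluster` (per-frame index),
#'   and `conversation_id`.
#' @export
diarize_track <- function(track, config = diarization_config(),
                          conversation_id = NULL) {
  stopifnot_cols(track, c("t_s", "volume_db"), "frame track")
  hop <- attr(track, "frame_hop_s") %||% stats::median(diff(track$t_s))
  hop <- round(hop * 1e6) / 1e6  # snap to microseconds: text round-trips
                                 # of the time axis must not move boundaries
  cl <- cluster_frames(track, config, conversation_id)
  roles <- assign_roles(cl$centroids, conversation_id)
  frame_roles <- roles[cl$cluster]
  # clothing-noise frames are non-voiced noise: they do not form speaking
  # segments, but they still occupy time; smoothing absorbs the short bursts
  segments <- smooth_segments(frame_roles, hop, config)
  segments <- trim_trailing_silence(segments, config)
  names(cl$centroids) <- roles
  structure(list(segments = segments,
                 centroids = sort(cl$centroids, decreasing = TRUE),
                 wcss = cl$wcss, cluster = cl$cluster,
                 conversation_id = conversation_id),
            class = "diarization")
}

#' @export
print.diarization <- function(x, ...) {
  cat("<diarization>", x$conversation_id %||% "", "\n")
  cat("  centroids (dB):",
      paste(sprintf("%s=%.1f", names(x$centroids), x$centroids),
            collapse = ", "), "\n")
  cat("  WCSS:", format(x$wcss, digits = 6), "\n")
  cat("  segments:", nrow(x$segments), "\n")
  invisible(x)
}

#' Diarize many conversations
#'
#' Applies [diarize_track()] per conversation in a frames table, collecting
#' per-conversation errors (degenerate volume distributions, ambiguous role
#' ties) into a report instead of failing the batch.
#'
#' @param frames Tibble with `conversation_id`, `t_s`, `volume_db`.
#' @param config A [diarization_config()].
#' @return A list with `segments` (bound tibble over successful
#'   conversations) and `report` (tibble of per-conversation centroids, WCSS
#'   and error messages).
#' @export
diarize_frames <- function(frames, config = diarization_config()) {
  stopifnot_cols(frames, c("conversation_id", "t_s", "volume_db"), "frames")
  ids <- unique(frames$conversation_id)
  segs <- vector("list", length(ids))
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- frames[frames$conversation_id == ids[i], ]
    res <- tryCatch(diarize_track(tr, config, conversation_id = ids[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rep_rows[[i]] <- tibble::tibble(conversation_id = ids[i], wcss = NA_real_,
                                      error = conditionMessage(res))
    } else {
      s <- res$segments
      s$conversation_id <- ids[i]
      segs[[i]] <- dplyr::relocate(s, "conversation_id")
      rep_rows[[i]] <- tibble::tibble(conversation_id = ids[i],
                                      wcss = res$wcss, error = NA_character_)
    }
  }
  list(segments = dplyr::bind_rows(segs), report = dplyr::bind_rows(rep_rows))
}
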