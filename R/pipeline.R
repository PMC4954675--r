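# End-to-end orchestration: simulate -> (render/extract) -> diarize ->
# features -> qc -> fit, with every threshold echoed into the manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the QC/inference constants
#' (pitch ceiling 255 Hz, 3-SD outlier multiplier, minimum 3 conversations
#' per participant) into one resolvable document. Every numeric threshold
#' here is echoed into the output manifest, so no default acts silently.
#'
#' @param generator A [generator_config()].
#' @param diarization A [diarization_config()].
#' @param qc List with `pitch_max_hz`, `sd_mult`, `min_conversations`.
#' @param inference List with `standardize`, `reml`, `collinearity`.
#' @param seed Pipeline seed (overrides the generator's).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            diarization = diarization_config(),
                            qc = list(pitch_max_hz = 255, sd_mult = 3,
                                      min_conversations = 3),
                            inference = list(standardize = "grand",
                                             reml = TRUE,
                                             collinearity = "variability"),
                            seed = NULL) {
  structure(list(generator = generator, diarization = diarization, qc = qc,
                 inference = inference, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields mirror the arguments of [pipeline_config()], [generator_config()]
#' and [diarization_config()]; unknown fields raise a configuration error.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(conditionMessage(e)))
  known <- c("generator", "diarization", "qc", "inference", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    config_error(paste("unknown pipeline config field(s):",
                       paste(extra, collapse = ", ")))
  }
  gen <- do.call(generator_config, raw$generator %||% list())
  dia <- do.call(diarization_config, raw$diarization %||% list())
  pipeline_config(generator = gen, diarization = dia,
                  qc = utils::modifyList(
                    list(pitch_max_hz = 255, sd_mult = 3,
                         min_conversations = 3), raw$qc %||% list()),
                  inference = utils::modifyList(
                    list(standardize = "grand", reml = TRUE,
                         collinearity = "variability"),
                    raw$inference %||% list()),
                  seed = raw$seed)
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate, extract, diarize, features, qc,
#' fit — writing each stage's table to `out_dir` and finishing with a
#' manifest that records the seed, the package version, every resolved
#' threshold, and an MD5 per output file. Supplying `frames` (and
#' `conversations`) skips the simulation prefix and runs the pipeline on
#' external data. Reruns with the same configuration and seed reproduce the
#' deterministic stages bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param frames Optional frames tibble or CSV path
#'   (`conversation_id, t_s, volume_db, pitch_hz, voiced`); skips simulation.
#' @param conversations Optional conversation metadata tibble or CSV path
#'   (`conversation_id, participant_id, rating, tie_type`).
#' @param participants Optional participant table or CSV path.
#' @param render_wav Synthesize WAV files and re-extract frame tracks from
#'   them (exercises the acoustics stage end-to-end; slow at full scale).
#' @return A list with the stage outputs (`frames`, `segments`, `features`,
#'   `qc`, `retained`, `fit`, `correlations`, `manifest`), invisibly
#'   writing all files under `out_dir`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   generator = generator_config(
#'     n_participants = 2,
#'     conversations_per_participant = list(mean = 3, sd = 1, min = 3,
#'                                          max = 4),
#'     length_s = list(mean = 60, sd = 20, min = 40, max = 90)),
#'   seed = 7)
#' res <- run_pipeline(cfg, out_dir = tempfile("run"))
#' }
run_pipeline <- function(config = pipeline_config(), out_dir,
                         frames = NULL, conversations = NULL,
                         participants = NULL, render_wav = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% config$generator$seed
  gcfg <- config$generator
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }
  read_if_path <- function(x) {
    if (is.character(x)) tibble::as_tibble(utils::read.csv(x)) else x
  }
  frames <- read_if_path(frames)
  conversations <- read_if_path(conversations)
  participants <- read_if_path(participants)

  truth <- NULL
  if (is.null(frames)) {
    ds <- stage("simulate",
                generate_dataset(gcfg, seed = seed, render_frames = TRUE,
                                 render_wav = render_wav))
    participants <- ds$participants
    conversations <- ds$conversations
    truth <- ds$truth_features
    frames <- ds$frames
    if (render_wav) {
      wav_dir <- file.path(out_dir, "wav")
      dir.create(wav_dir, showWarnings = FALSE)
      frames <- stage("extract", {
        purrr::map_dfr(names(ds$waveforms), function(id) {
          wv <- ds$waveforms[[id]]
          write_wav(wv$samples, file.path(wav_dir, paste0(id, ".wav")),
                    wv$sample_rate)
          tr <- extract_frame_track(
            wv$samples, wv$sample_rate, frame_s = gcfg$frame_s,
            hop_s = gcfg$frame_hop_s, db_offset = gcfg$db_offset,
            f0_range = c(65, 300),
            energy_threshold_db = gcfg$db_offset - 45)
          tr$conversation_id <- id
          dplyr::relocate(tr, "conversation_id")
        })
      })
    }
    outputs <- c(outputs,
                 write_csv_plain(participants,
                                 file.path(out_dir, "participants.csv")),
                 write_csv_plain(conversations,
                                 file.path(out_dir, "conversations.csv")),
                 write_csv_plain(truth, file.path(out_dir, "truth.csv")),
                 write_csv_plain(frames, file.path(out_dir, "frames.csv")))
  }

  dia <- stage("diarize", diarize_frames(frames, config$diarization))
  outputs <- c(outputs,
               write_csv_plain(dia$segments,
                               file.path(out_dir, "segments.csv")))
  jsonlite::write_json(
    list(report = dia$report,
         min_segment_s = config$diarization$min_segment_s,
         trailing_silence_window_s =
           config$diarization$trailing_silence_window_s,
         k = config$diarization$k, engine = config$diarization$engine),
    file.path(out_dir, "diarization_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  outputs <- c(outputs, file.path(out_dir, "diarization_report.json"))

  features <- stage("features",
                    conversation_features_all(dia$segments, frames))
  outputs <- c(outputs,
               write_csv_plain(features, file.path(out_dir, "features.csv")))

  qcr <- stage("qc", apply_exclusion_rules(
    features, pitch_max_hz = config$qc$pitch_max_hz,
    sd_mult = config$qc$sd_mult))
  retained <- qcr$retained
  if (!is.null(conversations)) {
    retained <- dplyr::inner_join(
      retained, conversations, by = "conversation_id")
    pf <- participant_filter(retained, config$qc$min_conversations)
    retained <- pf$retained
  } else {
    pf <- list(dropped = tibble::tibble())
  }
  jsonlite::write_json(qc_report(qcr, pf$dropped),
                       file.path(out_dir, "qc_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  outputs <- c(outputs, file.path(out_dir, "qc_report.json"),
               write_csv_plain(retained, file.path(out_dir, "retained.csv")))

  fit <- NULL
  correlations <- NULL
  if (!is.null(conversations) && nrow(retained) >= 10 &&
      length(unique(retained$participant_id)) >= 2) {
    correlations <- stage("fit", correlation_table(retained))
    guard <- collinearity_guard(retained,
                                mode = config$inference$collinearity)
    fit <- stage("fit", fit_hlm(
      retained, predictors = guard$predictors,
      standardize = config$inference$standardize,
      reml = config$inference$reml))
    outputs <- c(outputs,
                 write_csv_plain(correlations,
                                 file.path(out_dir, "correlations.csv")))
    jsonlite::write_json(
      list(fixed_effects = tidy(fit), glance = glance(fit),
           collinearity = guard$report),
      file.path(out_dir, "model_fit.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA, na = "null")
    outputs <- c(outputs, file.path(out_dir, "model_fit.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("convotrace")),
    seed = seed,
    thresholds = list(
      k = config$diarization$k,
      min_segment_s = config$diarization$min_segment_s,
      trailing_silence_window_s =
        config$diarization$trailing_silence_window_s,
      pitch_max_hz = config$qc$pitch_max_hz,
      sd_mult = config$qc$sd_mult,
      min_conversations = config$qc$min_conversations,
      db_offset = gcfg$db_offset,
      frame_s = gcfg$frame_s, frame_hop_s = gcfg$frame_hop_s),
    generator = gcfg[setdiff(names(gcfg),
                             c("length_lognorm", "nconv_lognorm",
                               "speaking_beta"))],
    inference = config$inference,
    files = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)

  invisible(list(frames = frames, segments = dia$segments,
                 diarization_report = dia$report, features = features,
                 qc = qcr, retained = retained, fit = fit,
                 correlations = correlations, manifest = manifest,
                 out_dir = out_dir))
}
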