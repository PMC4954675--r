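test_that("participant profiles satisfy their invariants", {
  set.seed(11)
  p <- sample_participants(generator_config(), n = 200)
  expect_true(all(p$vol_clothing_db > p$vol_participant_db))
  expect_true(all(p$vol_participant_db > p$vol_other_db))
  expect_true(all(p$vol_other_db > p$vol_silence_db))
  expect_true(all(p$f0_mean_hz >= 92 & p$f0_mean_hz <= 253))
  expect_true(all(p$f0_sd_hz > 0))
})

test_that("a collapsed F0 range pins every profile to that value", {
  set.seed(1)
  cfg <- generator_config(f0_range_hz = c(182, 182),
                          f0_gender_means_hz = c(female = 182, male = 182))
  p <- sample_participants(cfg, n = 50)
  expect_equal(p$f0_mean_hz, rep(182, 50))
})

test_that("empirical F0 mean matches the truncated-normal expectation", {
  set.seed(21)
  cfg <- generator_config()
  p <- sample_participants(cfg, n = 1000)
  # closed-form truncated-normal mean, mixed over gender
  tn_mean <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    mu + s * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  mus <- cfg$f0_gender_means_hz
  expected <- cfg$p_female *
    tn_mean(mus[["female"]], cfg$f0_person_sd_hz, 92, 253) +
    (1 - cfg$p_female) *
    tn_mean(mus[["male"]], cfg$f0_person_sd_hz, 92, 253)
  se <- sd(p$f0_mean_hz) / sqrt(nrow(p))
  expect_lt(abs(mean(p$f0_mean_hz) - expected), 3 * se)
})

test_that("turn sequences tile the conversation and end in trailing silence", {
  set.seed(5)
  for (i in 1:20) {
    ts <- sample_turn_sequence(generator_config())
    expect_equal(ts$start_s[-1], ts$end_s[-nrow(ts)])
    expect_true(all(ts$end_s > ts$start_s))
    expect_true(all(ts$role[-1] != ts$role[-nrow(ts)]))  # maximal runs
    expect_identical(ts$role[nrow(ts)], "silence")
    expect_equal(ts$end_s[nrow(ts)] - ts$start_s[nrow(ts)], 60)
  }
})

test_that("symmetric noise-free construction splits time 50/50", {
  cfg <- generator_config(turn_sdlog = 0, silence_gap_prob = 0)
  cycle <- 2 * cfg$turn_scale_s
  set.seed(2)
  ts <- sample_turn_sequence(cfg, length_s = 2 * cycle,
                             speaking_fraction = 0.5)
  trimmed <- trim_trailing_silence(ts)
  expect_equal(pct_speaking(trimmed), 50)
})

test_that("realized speaking fraction tracks the target", {
  set.seed(31)
  devs <- replicate(500, {
    ts <- sample_turn_sequence(generator_config())
    tr <- ts[-nrow(ts), ]  # drop trailing silence
    p <- sum((tr$end_s - tr$start_s)[tr$role == "participant"]) /
      (max(tr$end_s) - min(tr$start_s))
    p - attr(ts, "target_fraction")
  })
  expect_lt(mean(abs(devs)), 0.05)
  expect_lt(abs(mean(devs)), 0.01)  # unbiased construction
})

test_that("an explicitly infeasible target fraction errors", {
  expect_error(
    sample_turn_sequence(generator_config(), length_s = 60,
                         speaking_fraction = 0.005),
    class = "convotrace_generation_error")
})

test_that("zero jitter reproduces the role means exactly in the frame track", {
  cfg <- generator_config(volume_jitter_db = 0, person_volume_sd_db = 0,
                          person_role_sd_db = 0,
                          conversation_volume_sd_db = 0, jitter_sdlog = 0,
                          clothing_burst_rate = 0)
  set.seed(3)
  prof <- sample_participants(cfg, n = 1)
  ts <- sample_turn_sequence(cfg, length_s = 60, speaking_fraction = 0.4)
  tr <- render_frame_track(ts, prof, cfg)
  expect_setequal(unique(tr$volume_db),
                  unname(cfg$role_volume_db[c("participant", "other",
                                              "silence")]))
  for (r in c("participant", "other", "silence")) {
    expect_equal(unique(tr$volume_db[tr$role == r]),
                 unname(cfg$role_volume_db[[r]]))
  }
  expect_true(all(!is.na(tr$pitch_hz[tr$role == "participant"])))
  expect_true(all(is.na(tr$pitch_hz[tr$role != "participant"])))
  expect_equal(tr$voiced, tr$role %in% c("participant", "other"))
})

test_that("per-role volume regimes separate cleanly at default jitter", {
  set.seed(17)
  cfg <- small_config()
  ds <- generate_dataset(cfg, render_frames = TRUE)
  fr <- ds$frames[!ds$frames$burst, ]
  m <- tapply(fr$volume_db, fr$role, mean)[c("participant", "other",
                                             "silence")]
  s <- tapply(fr$volume_db, fr$role, sd)[c("participant", "other",
                                           "silence")]
  pooled <- sqrt((s[-3]^2 + s[-1]^2) / 2)  # adjacent regime pairs
  expect_true(all(abs(diff(m)) / pooled > 4))
})

test_that("waveform rendering obeys the level and silence contracts", {
  cfg <- generator_config()
  set.seed(4)
  prof <- sample_participants(cfg, n = 1)
  # amplitude halved -> 6.02 dB drop, frame by frame
  ts <- sample_turn_sequence(cfg, length_s = 30, speaking_fraction = 0.5)
  tr <- render_frame_track(ts, prof, cfg)
  wv <- render_waveform(tr, cfg)
  v1 <- compute_volume_track(wv$samples, wv$sample_rate)
  v2 <- compute_volume_track(wv$samples / 2, wv$sample_rate)
  expect_equal(v2$volume_db - v1$volume_db,
               rep(20 * log10(0.5), nrow(v1)), tolerance = 1e-9)
  # all-silence truth -> near-zero samples (silence floor ~ -60 dBFS here)
  cfg0 <- generator_config(clothing_burst_rate = 0)
  silence <- tibble::tibble(start_s = 0, end_s = 10, role = "silence")
  tr0 <- render_frame_track(silence, prof, cfg0)
  wv0 <- render_waveform(tr0, cfg0)
  expect_lt(max(abs(wv0$samples)), 0.01)
})

test_that("rendered participant tones carry the configured pitch", {
  cfg <- generator_config()
  n <- 400
  track <- tibble::tibble(
    t_s = (seq_len(n) - 1) * cfg$frame_hop_s,
    volume_db = 57, pitch_hz = 200,
    voiced = TRUE, role = "participant", burst = FALSE)
  attr(track, "frame_hop_s") <- cfg$frame_hop_s
  wv <- render_waveform(track, cfg)
  pit <- estimate_pitch(wv$samples, wv$sample_rate)
  expect_true(all(abs(pit$pitch_hz - 200) < 1, na.rm = TRUE))
  expect_gt(mean(!is.na(pit$pitch_hz)), 0.99)
})

test_that("the noise-free rating limit returns round(rating_mean)", {
  cfg <- generator_config(
    fixed_effects = c(pct_speaking = 0, length = 0, turn_rate = 0,
                      vol_sd = 0, pitch_sd = 0),
    random_intercept_sd = 0)
  cfg$residual_sd <- 0  # exact noise-free limit
  z <- tibble::tibble(pct_speaking = rnorm(10), length = rnorm(10),
                      turn_rate = rnorm(10), vol_sd = rnorm(10),
                      pitch_sd = rnorm(10))
  r <- sample_rating(z, 0, cfg)
  expect_equal(r$rating, rep(4L, 10))
})

test_that("speaking more maps to lower ratings under the default effect", {
  set.seed(12)
  n <- 20000
  z <- tibble::tibble(pct_speaking = rnorm(n), length = rnorm(n),
                      turn_rate = rnorm(n), vol_sd = rnorm(n),
                      pitch_sd = rnorm(n))
  r <- sample_rating(z, 0, generator_config())
  top <- r$rating[z$pct_speaking > quantile(z$pct_speaking, 0.9)]
  bottom <- r$rating[z$pct_speaking < quantile(z$pct_speaking, 0.1)]
  expect_lt(mean(top), mean(bottom))
})

test_that("datasets are reproducible and internally consistent", {
  cfg <- small_config(seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$truth_features, d2$truth_features)
  expect_identical(d1$truth_segments, d2$truth_segments)
  expect_identical(d1$participants, d2$participants)

  # ground-truth consistency: stored % speaking equals a recount from the
  # stored segments, exactly
  for (id in d1$conversations$conversation_id) {
    seg <- d1$truth_segments[d1$truth_segments$conversation_id == id, ]
    trimmed <- trim_trailing_silence(seg)
    expect_identical(
      d1$truth_features$pct_speaking[d1$truth_features$conversation_id == id],
      pct_speaking(trimmed))
  }
})

test_that("the default configuration yields the expected cohort shape", {
  cfg <- generator_config()
  expect_identical(cfg$n_participants, 36)
  ds <- generate_dataset(cfg, seed = 1)
  expect_identical(nrow(ds$participants), 36L)
  counts <- table(ds$conversations$participant_id)
  expect_true(all(counts >= 3 & counts <= 58))
  expect_true(all(ds$conversations$rating %in% 1:7))
})

test_that("a single participant with three conversations passes the filter", {
  cfg <- generator_config(
    n_participants = 1,
    conversations_per_participant = list(mean = 3, sd = 0.1, min = 3, max = 3),
    length_s = list(mean = 60, sd = 10, min = 45, max = 90))
  ds <- generate_dataset(cfg, seed = 8)
  expect_identical(nrow(ds$conversations), 3L)
  pf <- participant_filter(ds$conversations, min_conversations = 3)
  expect_identical(pf$kept_ids, ds$participants$participant_id)
})
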