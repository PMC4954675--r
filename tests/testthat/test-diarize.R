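test_that("separated point masses cluster perfectly with exact centroids", {
  v <- rep(c(70, 57, 45, 20), each = 100)
  fit <- cluster_frames(v)
  expect_equal(sort(fit$centroids), c(20, 45, 57, 70))
  expect_equal(fit$wcss, 0)
  # zero misassignment: cluster labels constant within each block
  expect_identical(length(unique(fit$cluster[1:100])), 1L)
  expect_identical(length(unique(paste(fit$cluster, rep(1:4, each = 100)))),
                   4L)
})

test_that("the clustering objective matches the exhaustive 1-D optimum", {
  set.seed(7)
  for (i in 1:25) {
    v <- runif(60, 20, 75)
    fit <- cluster_frames(v)
    expect_equal(fit$wcss, oracle_kmeans1d_wcss(v, 4), tolerance = 1e-8)
  }
})

test_that("the Lloyd engine is seed-reproducible and never beats the exact engine", {
  set.seed(8)
  v <- c(rnorm(50, 70, 2), rnorm(80, 57, 2), rnorm(60, 45, 2),
         rnorm(90, 20, 2))
  cfg <- diarization_config(engine = "lloyd", seed = 42)
  f1 <- cluster_frames(v, cfg)
  f2 <- cluster_frames(v, cfg)
  expect_identical(f1$cluster, f2$cluster)
  expect_gte(f1$wcss, cluster_frames(v)$wcss - 1e-8)
  expect_identical(length(f1$centroids), 4L)
})

test_that("too few distinct volumes raise a degenerate-input error", {
  expect_error(cluster_frames(rep(c(60, 30), each = 50),
                              conversation_id = "C0007"),
               "C0007", class = "convotrace_degenerate_error")
})

test_that("roles follow centroid order regardless of input order", {
  expect_identical(assign_roles(c(70, 57, 45, 20)),
                   c("clothing_noise", "participant", "other", "silence"))
  expect_identical(assign_roles(c(45, 70, 20, 57)),
                   c("other", "clothing_noise", "silence", "participant"))
  expect_error(assign_roles(c(50, 50, 30, 10)),
               class = "convotrace_ambiguous_roles_error")
})

test_that("a short spurious run is absorbed into its neighbors", {
  out <- smooth_segments(list(role = c("participant", "other", "participant"),
                              dur = c(5, 0.8, 5)))
  expect_identical(nrow(out), 1L)
  expect_identical(out$role, "participant")
  expect_equal(out$end_s, 10.8)
})

test_that("label sequences already above the minimum are a fixpoint", {
  runs <- list(role = c("participant", "silence", "other"), dur = c(3, 2, 5))
  out <- smooth_segments(runs)
  expect_identical(out$role, runs$role)
  expect_equal(out$end_s - out$start_s, runs$dur)
})

test_that("smoothing equals the brute-force absorb-until-fixpoint oracle", {
  set.seed(10)
  roles <- c("participant", "other", "silence", "clothing_noise")
  for (i in 1:200) {
    n <- sample(3:40, 1)
    role <- sample(roles, n, replace = TRUE)
    dur <- round(runif(n, 0.05, 4), 3)
    got <- smooth_segments(list(role = role, dur = dur))
    want <- oracle_smooth(role, dur, 1.5)
    expect_identical(got$role, want$role)
    expect_equal(got$end_s - got$start_s, want$dur, tolerance = 1e-9)
    # total duration preserved; output runs maximal
    expect_equal(max(got$end_s), sum(dur), tolerance = 1e-9)
    if (nrow(got) > 1) {
      expect_true(all(got$role[-1] != got$role[-nrow(got)]))
      expect_true(all(got$end_s - got$start_s >= 1.5))
    }
  }
})

test_that("trailing silence is trimmed once, idempotently", {
  segs <- seg_tbl(c(120, 60, 60, 60), c("participant", "silence",
                                        "participant", "silence"))
  out <- trim_trailing_silence(segs)
  expect_identical(nrow(out), 3L)
  expect_equal(max(out$end_s), 240)
  expect_identical(out$role[2], "silence")  # internal silence untouched
  expect_identical(trim_trailing_silence(out), out)

  # 5-minute conversation ending in the 60 s marker -> 4 minutes
  segs2 <- seg_tbl(c(240, 60), c("participant", "silence"))
  expect_equal(conversation_length(trim_trailing_silence(segs2)), 4)

  # ends in speech -> unchanged
  segs3 <- seg_tbl(c(100, 50), c("other", "participant"))
  expect_identical(trim_trailing_silence(segs3), segs3)

  # short final silence -> kept
  segs4 <- seg_tbl(c(100, 20), c("participant", "silence"))
  expect_identical(nrow(trim_trailing_silence(segs4)), 2L)

  expect_error(trim_trailing_silence(
    seg_tbl(c(120), "silence")),
    class = "convotrace_empty_conversation_error")
})

test_that("noise-free tracks are diarized without frame errors", {
  cfg <- small_config(volume_jitter_db = 0, person_volume_sd_db = 0,
                      person_role_sd_db = 0, conversation_volume_sd_db = 0,
                      jitter_sdlog = 0, seed = 55)
  ds <- generate_dataset(cfg, render_frames = TRUE)
  for (id in ds$conversations$conversation_id[1:5]) {
    tr <- ds$frames[ds$frames$conversation_id == id, ]
    d <- diarize_track(tr, conversation_id = id)
    truth <- ds$truth_segments[ds$truth_segments$conversation_id == id, ]
    expect_identical(
      sum(d$segments$role %in% c("participant", "other")),
      as.integer(sum(truth$role %in% c("participant", "other"))))
    # per-frame roles recovered near-exactly; the only legitimate
    # mismatches are single boundary frames displaced when a clothing
    # burst straddling a turn edge is absorbed by smoothing
    roles <- d$segments$role[findInterval(tr$t_s, d$segments$start_s)]
    n <- sum(tr$t_s < max(d$segments$end_s))
    clean <- !tr$burst[1:n]
    err <- mean(roles[1:n][clean] != tr$role[1:n][clean])
    expect_lt(err, 0.005)
  }
})

test_that("time-weighted role recovery is at least 0.90 at default noise", {
  cfg <- small_config(seed = 66, n_participants = 4)
  ds <- generate_dataset(cfg, render_frames = TRUE)
  hits <- total <- 0
  for (id in ds$conversations$conversation_id) {
    tr <- ds$frames[ds$frames$conversation_id == id, ]
    d <- diarize_track(tr, conversation_id = id)
    roles <- d$segments$role[findInterval(tr$t_s, d$segments$start_s)]
    keep <- tr$t_s < max(d$segments$end_s) & !tr$burst &
      tr$role %in% c("participant", "other", "silence")
    hits <- hits + sum(roles[keep] == tr$role[keep])
    total <- total + sum(keep)
  }
  expect_gte(hits / total, 0.90)
})

test_that("clustering WCSS never exceeds the ground-truth labeling's", {
  cfg <- small_config(seed = 77)
  ds <- generate_dataset(cfg, render_frames = TRUE)
  id <- ds$conversations$conversation_id[1]
  tr <- ds$frames[ds$frames$conversation_id == id, ]
  fit <- cluster_frames(tr)
  truth_lab <- ifelse(tr$burst, "clothing_noise", tr$role)
  truth_wcss <- sum(tapply(tr$volume_db, truth_lab,
                           function(x) sum((x - mean(x))^2)))
  expect_lte(fit$wcss, truth_wcss)
})

test_that("diarize_frames collects per-conversation failures in the report", {
  good <- tibble::tibble(conversation_id = "ok",
                         t_s = (0:999) * 0.016,
                         volume_db = rep(c(70, 57, 45, 20), 250))
  bad <- tibble::tibble(conversation_id = "flat",
                        t_s = (0:99) * 0.016,
                        volume_db = rep(50, 100))
  res <- diarize_frames(dplyr::bind_rows(good, bad),
                        diarization_config(trailing_silence_window_s = 1e9))
  expect_identical(unique(res$segments$conversation_id), "ok")
  expect_match(res$report$error[res$report$conversation_id == "flat"],
               "distinct volume")
})
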