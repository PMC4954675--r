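suppressMessages(library(dplyr))

sim_features <- function(n_groups = 8, per_group = 6, seed = 1) {
  set.seed(seed)
  n <- n_groups * per_group
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", seq_len(n_groups)),
                         each = per_group),
    length_min = rlnorm(n, 1.5, 0.8),
    pct_speaking = runif(n, 5, 90),
    turn_rate_per_min = rnorm(n, 7, 2),
    vol_mean_db = rnorm(n, 57, 3),
    vol_sd_db = rnorm(n, 2, 0.4),
    pitch_mean_hz = rnorm(n, 182, 25),
    pitch_sd_hz = rnorm(n, 39, 10))
}

test_that("z-scoring is exact, idempotent and invertible", {
  d <- tibble::tibble(x = c(1, 2, 3))
  expect_equal(zscore_predictors(d, "x")$x, c(-1, 0, 1))
  z1 <- zscore_predictors(sim_features(), "pct_speaking")
  z2 <- zscore_predictors(z1, "pct_speaking")
  expect_equal(z1$pct_speaking, z2$pct_speaking, tolerance = 1e-12)
  # round trip through the recorded center and scale
  orig <- sim_features()
  z <- zscore_predictors(orig, c("length_min", "pct_speaking"))
  back <- z$length_min * attr(z, "zscore_scale")[["length_min"]] +
    attr(z, "zscore_center")[["length_min"]]
  expect_equal(back, orig$length_min, tolerance = 1e-9)
  expect_error(zscore_predictors(tibble::tibble(x = rep(1, 5)), "x"),
               class = "convotrace_degenerate_error")
})

test_that("within-person z-scoring centers every participant at zero", {
  d <- sim_features()
  z <- zscore_predictors(d, "pct_speaking", method = "within")
  ms <- tapply(z$pct_speaking, d$participant_id, mean)
  expect_equal(as.numeric(ms), rep(0, length(ms)), tolerance = 1e-12)
})

test_that("correlations match the textbook formula and its t-test", {
  d <- sim_features(seed = 5)
  ct <- correlation_table(d, c("length_min", "pct_speaking",
                               "turn_rate_per_min"))
  expect_identical(nrow(ct), 3L)
  expect_true(all(ct$df == nrow(d) - 2))
  for (i in seq_len(nrow(ct))) {
    x <- d[[ct$var1[i]]]; y <- d[[ct$var2[i]]]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ct$r[i], r, tolerance = 1e-12)
    tt <- r * sqrt((length(x) - 2) / (1 - r^2))
    expect_equal(ct$p[i], 2 * pt(-abs(tt), length(x) - 2), tolerance = 1e-12)
  }
  d$dup <- d$length_min
  ct2 <- correlation_table(d, c("length_min", "dup"))
  expect_equal(ct2$r, 1)
  ct3 <- correlation_table(dplyr::mutate(d, neg = -length_min),
                           c("length_min", "neg"))
  expect_equal(ct3$r, -1)
  expect_error(correlation_table(dplyr::mutate(d, k = 1),
                                 c("length_min", "k")),
               class = "convotrace_degenerate_error")
})

test_that("the collinearity guard reports r but always keeps variability", {
  d <- sim_features(seed = 7)
  # plant a strong mean/SD correlation in the volume family
  d$vol_sd_db <- 0.3 * d$vol_mean_db + rnorm(nrow(d), 0, 0.45)
  g <- collinearity_guard(d)
  expect_setequal(unname(g$predictors),
                  c("length_min", "pct_speaking", "turn_rate_per_min",
                    "vol_sd_db", "pitch_sd_hz"))
  expect_false(any(c("vol_mean_db", "pitch_mean_hz") %in% g$predictors))
  expect_equal(g$report$r[g$report$family == "volume"],
               cor(d$vol_mean_db, d$vol_sd_db))
  # an r = 0.9 construction is reported as such (across simulations)
  set.seed(8)
  r_hat <- replicate(40, {
    n <- 400
    m <- rnorm(n)
    s <- 0.9 * m + sqrt(1 - 0.81) * rnorm(n)
    dd <- tibble::tibble(vol_mean_db = m, vol_sd_db = s,
                         pitch_mean_hz = rnorm(n), pitch_sd_hz = rnorm(n))
    collinearity_guard(dd)$report$r[1]
  })
  expect_lt(abs(mean(r_hat) - 0.9), 3 * sd(r_hat) / sqrt(40))
  # duplicated columns -> r exactly 1, variability still selected
  dd <- tibble::tibble(vol_mean_db = rnorm(20))
  dd$vol_sd_db <- dd$vol_mean_db
  dd$pitch_mean_hz <- rnorm(20); dd$pitch_sd_hz <- rnorm(20)
  expect_equal(collinearity_guard(dd)$report$r[1], 1)
})

test_that("the noise-free fit degenerates to exact least squares", {
  d <- sim_features(n_groups = 5, per_group = 8, seed = 2)
  z <- zscore_predictors(d, unname(hlm_predictors()))
  d$rating <- 4 - 0.19 * z$pct_speaking + 0.25 * z$length_min
  fit <- suppressWarnings(fit_hlm(d))
  fe <- fit$fixed_effects
  expect_equal(fe$estimate[fe$term == "pct_speaking"], -0.19,
               tolerance = 1e-8)
  expect_equal(fe$estimate[fe$term == "length"], 0.25, tolerance = 1e-8)
  expect_equal(fe$estimate[fe$term == "turn_rate"], 0, tolerance = 1e-8)
})

test_that("fixed effects match an independent REML likelihood oracle", {
  set.seed(3)
  for (rep in 1:3) {
    d <- sim_features(n_groups = 5, per_group = 4, seed = 30 + rep)
    z <- zscore_predictors(d, unname(hlm_predictors()))
    u <- rnorm(5, 0, 0.6)[as.integer(factor(d$participant_id))]
    d$rating <- 4 - 0.19 * z$pct_speaking + u + rnorm(nrow(d), 0, 0.8)
    fit <- fit_hlm(d)
    X <- cbind(1, as.matrix(as.data.frame(z[, unname(hlm_predictors())])))
    want <- oracle_reml_fit(d$rating, X, d$participant_id)
    expect_equal(unname(c(fit$intercept$estimate,
                          fit$fixed_effects$estimate)),
                 unname(want$beta), tolerance = 1e-4)
    expect_equal(fit$residual_var, want$sigma2, tolerance = 1e-3)
    expect_equal(fit$random_intercept_var, want$tau2, tolerance = 1e-2)
  }
})

test_that("fit results are invariant to row order and id relabeling", {
  d <- sim_features(seed = 9)
  set.seed(9)
  d$rating <- sample(1:7, nrow(d), replace = TRUE)
  f1 <- fit_hlm(d)
  d2 <- d[sample(nrow(d)), ]
  d2$participant_id <- paste0("XX_", d2$participant_id)
  f2 <- fit_hlm(d2)
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_equal(f1$random_intercept_var, f2$random_intercept_var,
               tolerance = 1e-6)
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- sim_features(seed = 10)
  set.seed(10)
  d$rating <- rnorm(nrow(d), 4, 1.2)
  fit <- fit_hlm(d)
  td <- tidy(fit)
  expect_identical(td$term,
                   c("(Intercept)", "length", "pct_speaking", "turn_rate",
                     "vol_sd", "pitch_sd"))
  expect_true(all(c("estimate", "std.error", "df", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$nobs, nrow(d))
  expect_identical(gl$n_groups, 8L)
  expect_gte(gl$random_intercept_var, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("shuffling ratings within participants destroys the effect", {
  ds <- generate_dataset(generator_config(seed = 71))
  d <- dplyr::rename(ds$truth_features, length_min2 = length_min)
  d$length_min <- d$length_min2
  set.seed(72)
  est <- replicate(20, {
    shuf <- d |>
      dplyr::group_by(participant_id) |>
      dplyr::mutate(rating = sample(rating)) |>
      dplyr::ungroup()
    fe <- fit_hlm(shuf)$fixed_effects
    fe$estimate[fe$term == "pct_speaking"]
  })
  expect_lt(abs(mean(est)), 0.03)
  # the unshuffled data keep the negative effect
  fe <- fit_hlm(d)$fixed_effects
  expect_lt(fe$estimate[fe$term == "pct_speaking"], -0.1)
})

test_that("person-level covariates: constants error, real effects surface", {
  ds <- generate_dataset(generator_config(seed = 80))
  d <- ds$truth_features
  parts <- ds$participants
  const <- parts
  const$age <- 20
  expect_error(extended_hlm(d, const), "age",
               class = "convotrace_degenerate_error")
  # null covariates stay quiet on a single dataset at alpha = 0.001
  fit0 <- extended_hlm(d, parts)
  td0 <- tidy(fit0)
  cov_rows <- td0[td0$term %in% c("big5_o", "big5_c", "big5_e", "big5_a",
                                  "big5_n", "age"), ]
  expect_identical(nrow(cov_rows), 6L)
  # inject a strong age effect and expect detection
  zage <- as.numeric(scale(parts$age))[match(d$participant_id,
                                             parts$participant_id)]
  d2 <- d
  d2$rating <- pmin(7L, pmax(1L, as.integer(round(d$rating + 1.0 * zage))))
  fit1 <- extended_hlm(d2, parts)
  td1 <- tidy(fit1)
  expect_lt(td1$p.value[td1$term == "age"], 0.01)
  expect_gt(td1$estimate[td1$term == "age"], 0.3)
})

test_that("null covariates reject at roughly the nominal rate", {
  set.seed(90)
  ps <- replicate(40, {
    ds <- generate_dataset(small_config(
      n_participants = 12,
      conversations_per_participant = list(mean = 8, sd = 2, min = 4,
                                           max = 12)))
    fit <- extended_hlm(ds$truth_features, ds$participants,
                        covariates = c("age"))
    td <- tidy(fit)
    td$p.value[td$term == "age"]
  })
  rate <- mean(ps < 0.05)
  # binomial 99% envelope around 0.05 at n = 40
  expect_lte(rate, 0.20)
})

test_that("group comparisons match the pooled-variance t formula", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 6),
                      x = c(rnorm(6, 10), rnorm(6, 12)))
  got <- group_compare(d, "g", "x")
  n1 <- 6; n2 <- 6
  x1 <- d$x[d$g == "a"]; x2 <- d$x[d$g == "b"]
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  t_hand <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, n1 + n2 - 2)
  # identical groups -> t = 0, p = 1
  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 4), x = rep(1:4, 2))
  got2 <- group_compare(d2, "g", "x")
  expect_equal(got2$t, 0)
  expect_equal(got2$p, 1)
  expect_error(group_compare(tibble::tibble(g = "a", x = 1), "g", "x"),
               class = "convotrace_degenerate_error")
})

test_that("women's mean pitch exceeds men's at participant level", {
  ds <- generate_dataset(generator_config(seed = 101))
  d <- dplyr::left_join(ds$truth_features,
                        ds$participants[, c("participant_id", "gender")],
                        by = "participant_id")
  got <- group_compare(d, "gender", "pitch_mean_hz", level = "participant",
                       groups = c("female", "male"))
  expect_gt(got$mean1, got$mean2)
  expect_lt(got$p, 0.05)
})
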