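# Within-person inference: predictor standardization, correlation structure,
# the random-intercept mixed model, and auxiliary group comparisons.

#' Canonical predictor set for the enjoyment model
#'
#' Maps the model's five conversational predictors to feature-table columns:
#' conversation length, percentage of speaking time, turn-taking rate, and
#' variability (not average) of volume and pitch.
#'
#' @return Named character vector: names are model terms, values are feature
#'   columns.
#' @export
hlm_predictors <- function() {
  c(length = "length_min", pct_speaking = "pct_speaking",
    turn_rate = "turn_rate_per_min", vol_sd = "vol_sd_db",
    pitch_sd = "pitch_sd_hz")
}

#' Z-score predictor columns
#'
#' Standardizes columns to mean 0, SD 1 (sample convention). Grand-mean
#' scoring (default) uses the whole table; within-person scoring centers and
#' scales inside each participant, which changes the estimand to purely
#' within-person contrasts.
#'
#' @param data Data frame.
#' @param cols Character vector of columns to standardize.
#' @param method `"grand"` or `"within"`.
#' @param group Grouping column for within-person scoring.
#' @return `data` with the columns replaced by z-scores; centers and scales
#'   attached as attributes `zscore_center` / `zscore_scale` (grand method).
#' @export
#' @examples
#' zscore_predictors(tibble::tibble(x = c(1, 2, 3)), "x")$x
zscore_predictors <- function(data, cols, method = c("grand", "within"),
                              group = "participant_id") {
  method <- match.arg(method)
  stopifnot_cols(data, cols, "predictor table")
  centers <- scales <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    if (method == "grand") {
      s <- sd(data[[cl]], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        data_error(sprintf("column '%s' has zero variance; cannot z-score", cl),
                   class = "convotrace_degenerate_error")
      }
      centers[cl] <- mean(data[[cl]], na.rm = TRUE)
      scales[cl] <- s
      data[[cl]] <- (data[[cl]] - centers[cl]) / s
    } else {
      stopifnot_cols(data, group, "predictor table")
      g <- data[[group]]
      mu <- stats::ave(data[[cl]], g, FUN = function(x) mean(x, na.rm = TRUE))
      sg <- stats::ave(data[[cl]], g, FUN = function(x) sd(x, na.rm = TRUE))
      if (any(!is.finite(sg) | sg == 0)) {
        data_error(sprintf(
          "column '%s' has zero within-person variance for some participant",
          cl), class = "convotrace_degenerate_error")
      }
      data[[cl]] <- (data[[cl]] - mu) / sg
    }
  }
  if (method == "grand") {
    attr(data, "zscore_center") <- centers
    attr(data, "zscore_scale") <- scales
  }
  data
}

#' Pairwise Pearson correlations with tests
#'
#' @param data Data frame.
#' @param cols Columns to correlate (default: the five model predictors plus
#'   the acoustic means, intersected with what is present).
#' @return A tibble with `var1`, `var2`, `r`, `df` (n - 2), `p` (two-sided).
#' @export
correlation_table <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- intersect(c(hlm_predictors(), "vol_mean_db", "pitch_mean_hz"),
                      names(data))
  }
  stopifnot_cols(data, cols, "feature table")
  if (nrow(data) < 3) data_error("need at least 3 rows for correlations")
  for (cl in cols) {
    if (sd(data[[cl]], na.rm = TRUE) == 0) {
      data_error(sprintf("column '%s' is constant; correlation undefined", cl),
                 class = "convotrace_degenerate_error")
    }
  }
  pairs <- utils::combn(cols, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ct <- cor.test(data[[a]], data[[b]])
    tibble::tibble(var1 = a, var2 = b, r = unname(ct$estimate),
                   df = unname(ct$parameter), p = ct$p.value)
  })
}

#' Mean-versus-variability collinearity check
#'
#' Reports the correlation between the average and the variability of each
#' acoustic family (volume, pitch). Because average and variability of volume
#' are typically so strongly correlated that entering both would be
#' collinear, the role-faithful default always carries the variability
#' columns into the model, whatever the observed correlation (which is
#' logged); `mode = "auto"` instead keeps both members of a family whose
#' correlation stays below `threshold`.
#'
#' @param data Feature table with `vol_mean_db`, `vol_sd_db`,
#'   `pitch_mean_hz`, `pitch_sd_hz`.
#' @param threshold Absolute correlation above which a family is collapsed in
#'   `auto` mode.
#' @param mode `"variability"` (default) or `"auto"`.
#' @return A list with `report` (tibble family/r) and `predictors` (named
#'   character vector of model columns).
#' @export
collinearity_guard <- function(data, threshold = 0.8,
                               mode = c("variability", "auto")) {
  mode <- match.arg(mode)
  stopifnot_cols(data, c("vol_mean_db", "vol_sd_db", "pitch_mean_hz",
                         "pitch_sd_hz"), "feature table")
  report <- tibble::tibble(
    family = c("volume", "pitch"),
    r = c(cor(data$vol_mean_db, data$vol_sd_db, use = "complete.obs"),
          cor(data$pitch_mean_hz, data$pitch_sd_hz, use = "complete.obs")))
  preds <- hlm_predictors()
  if (mode == "auto") {
    if (abs(report$r[1]) < threshold) preds <- c(preds, vol_mean = "vol_mean_db")
    if (abs(report$r[2]) < threshold) preds <- c(preds, pitch_mean = "pitch_mean_hz")
  }
  list(report = report, predictors = preds)
}

#' Fit the within-person random-intercept enjoyment model
#'
#' Fits `outcome ~ z(predictors) + (1 | participant)` by REML (default) with
#' the five conversational predictors entered simultaneously, conversations
#' at level 1 nested in persons at level 2. Fixed-effect tests use
#' Satterthwaite degrees of freedom. A singular fit (person-level variance
#' estimated at zero) is reported in the convergence status; estimates are
#' still returned.
#'
#' @param data Table with the outcome, grouping column and predictor columns.
#' @param predictors Named character vector mapping model terms to columns;
#'   defaults to [hlm_predictors()].
#' @param outcome Outcome column name.
#' @param group Participant-identifier column.
#' @param standardize `"grand"`, `"within"`, or `"none"` (predictors already
#'   standardized).
#' @param reml Use REML (`TRUE`, default) or ML.
#' @return An object of class `hlm_fit` with `tidy()`, `glance()`, `print()`
#'   and `autoplot()` methods.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_participants = 6, seed = 3))
#' fit <- fit_hlm(dplyr::rename(ds$truth_features, rating2 = rating),
#'                outcome = "rating2")
#' tidy(fit)
fit_hlm <- function(data, predictors = hlm_predictors(), outcome = "rating",
                    group = "participant_id",
                    standardize = c("grand", "within", "none"), reml = TRUE) {
  standardize <- match.arg(standardize)
  stopifnot_cols(data, c(unname(predictors), outcome, group), "model table")
  if (anyNA(data[[group]])) data_error("participant ids contain NA")
  d <- data[, c(group, outcome, unname(predictors))]
  names(d) <- c(".group", ".outcome", names(predictors))
  if (standardize != "none") {
    d <- zscore_predictors(d, names(predictors),
                           method = standardize, group = ".group")
  }
  fml <- stats::as.formula(paste(".outcome ~",
                                 paste(names(predictors), collapse = " + "),
                                 "+ (1 | .group)"))
  fit <- lmerTest::lmer(fml, data = d, REML = reml)
  .hlm_fit_from_lmer(fit, predictors, d)
}

.hlm_fit_from_lmer <- function(fit, predictors, d) {
  sm <- summary(fit)
  co <- sm$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  singular <- lme4::isSingular(fit)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  fixed <- tibble::tibble(
    term = rownames(co), estimate = unname(co[, "Estimate"]),
    std.error = unname(co[, "Std. Error"]), df = unname(co[, "df"]),
    statistic = unname(co[, "t value"]),
    p.value = unname(co[, "Pr(>|t|)"]))
  structure(list(
    fixed_effects = fixed[fixed$term != "(Intercept)", ],
    intercept = fixed[fixed$term == "(Intercept)", ],
    random_intercept_var = vc$vcov[vc$grp == ".group"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    n_obs = stats::nobs(fit),
    n_groups = as.integer(lme4::ngrps(fit)[[1]]),
    convergence = if (singular) "singular"
                  else if (length(msgs)) paste(msgs, collapse = "; ")
                  else "converged",
    reml = lme4::isREML(fit),
    predictors = predictors,
    model = fit), class = "hlm_fit")
}

#' @export
print.hlm_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<hlm_fit> %s, %d conversations in %d participants (%s)\n",
    if (x$reml) "REML" else "ML", x$n_obs, x$n_groups, x$convergence))
  cat(sprintf("  random-intercept var %.4f, residual var %.4f\n",
              x$random_intercept_var, x$residual_var))
  print(as.data.frame(x$fixed_effects), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_hlm
#' @param x An `hlm_fit` object.
#' @param ... Unused.
#' @export
tidy.hlm_fit <- function(x, ...) {
  dplyr::bind_rows(x$intercept, x$fixed_effects)
}

#' @rdname fit_hlm
#' @export
glance.hlm_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_obs, n_groups = x$n_groups,
                 random_intercept_var = x$random_intercept_var,
                 residual_var = x$residual_var,
                 icc = x$random_intercept_var /
                   (x$random_intercept_var + x$residual_var),
                 REMLcrit = if (x$reml) lme4::REMLcrit(x$model) else NA_real_,
                 convergence = x$convergence)
}

#' @rdname fit_hlm
#' @param object An `hlm_fit` object.
#' @export
autoplot.hlm_fit <- function(object, ...) {
  fe <- object$fixed_effects
  fe$term <- factor(fe$term, levels = rev(fe$term))
  ggplot2::ggplot(fe, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "standardized coefficient (95% CI)", y = NULL,
                  title = "Conversation enjoyment: fixed effects") +
    ggplot2::theme_minimal()
}

#' Enjoyment model with person-level covariates
#'
#' Adds level-2 covariates (Big-Five traits, age, gender by default) as fixed
#' effects to the random-intercept model. Numeric covariates are z-scored
#' across participants; categorical covariates become factors. Covariates
#' that are constant cannot be identified and raise an error naming them.
#'
#' @inheritParams fit_hlm
#' @param participants Participant table with `participant_id` and the
#'   covariate columns.
#' @param covariates Covariate column names.
#' @return An `hlm_fit`.
#' @export
extended_hlm <- function(data, participants,
                         covariates = c("big5_o", "big5_c", "big5_e",
                                        "big5_a", "big5_n", "age", "gender"),
                         predictors = hlm_predictors(), outcome = "rating",
                         group = "participant_id",
                         standardize = c("grand", "within", "none"),
                         reml = TRUE) {
  standardize <- match.arg(standardize)
  stopifnot_cols(participants, c(group, covariates), "participant table")
  constant <- covariates[vapply(covariates, function(cl) {
    length(unique(participants[[cl]])) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    data_error(sprintf("covariate(s) constant across participants: %s",
                       paste(constant, collapse = ", ")),
               class = "convotrace_degenerate_error")
  }
  d <- dplyr::left_join(data, participants[, c(group, covariates)],
                        by = group)
  num <- covariates[vapply(d[covariates], is.numeric, logical(1))]
  if (length(num) > 0) d <- zscore_predictors(d, num, method = "grand")
  for (cl in setdiff(covariates, num)) d[[cl]] <- factor(d[[cl]])
  if (standardize != "none") {
    d <- zscore_predictors(d, unname(predictors), method = standardize,
                           group = group)
  }
  all_preds <- c(predictors, setNames(covariates, covariates))
  fit_hlm(d, predictors = all_preds, outcome = outcome, group = group,
          standardize = "none", reml = reml)
}

#' Two-group feature comparisons
#'
#' Equal-variance two-sample t-tests per feature. Between-person contrasts
#' (for example gender) aggregate to participant means first; tie-type
#' contrasts compare at the conversation level.
#'
#' @param data Table with the features, the grouping column, and (for
#'   participant-level tests) `participant_id`.
#' @param group Grouping column name.
#' @param features Feature columns to test.
#' @param level `"conversation"` or `"participant"`.
#' @param groups Optional length-2 character vector selecting the two group
#'   levels to compare (rows in other levels are dropped).
#' @return A tibble with per-feature group means, `t`, `df`, `p`.
#' @export
group_compare <- function(data, group, features,
                          level = c("conversation", "participant"),
                          groups = NULL) {
  level <- match.arg(level)
  stopifnot_cols(data, c(group, features), "comparison table")
  if (level == "participant") {
    stopifnot_cols(data, "participant_id", "comparison table")
    data <- data |>
      dplyr::group_by(.data$participant_id, .data[[group]]) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(features),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  lv <- groups %||% unique(data[[group]])
  if (length(lv) < 2) {
    data_error("grouping has a single level; nothing to compare",
               class = "convotrace_degenerate_error")
  }
  lv <- lv[1:2]
  data <- data[data[[group]] %in% lv, , drop = FALSE]
  if (!all(lv %in% data[[group]])) {
    data_error("one comparison group is empty",
               class = "convotrace_degenerate_error")
  }
  purrr::map_dfr(features, function(f) {
    x <- data[[f]][data[[group]] == lv[1]]
    y <- data[[f]][data[[group]] == lv[2]]
    tt <- t.test(x, y, var.equal = TRUE)
    tibble::tibble(feature = f, group1 = lv[1], group2 = lv[2],
                   mean1 = mean(x, na.rm = TRUE), mean2 = mean(y, na.rm = TRUE),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
}
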