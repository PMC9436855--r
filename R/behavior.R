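#' Two-stage reaction-time trimming
#'
#' Stage 1 removes implausibly fast and slow responses by absolute bounds
#' (defaults: shorter than 400 ms or longer than 5,000 ms). Stage 2
#' computes the mean and SD of the stage-1 survivors and removes responses
#' more than `sd_mult` SDs from that mean. The stage-1 mean/SD are the ones
#' reported, so the SD criterion is reproducible from the report alone.
#' Stage 1 is idempotent; stage 2 need not be, since the mean/SD are
#' recomputed on each application.
#'
#' @param trials data.frame with an `rt_ms` column (all positive).
#' @param low_ms,high_ms absolute bounds in ms (RT strictly below/above is
#'   removed).
#' @param sd_mult SD-criterion multiplier (default 3).
#' @return list with `trials` (the retained rows) and `report` (a
#'   `trim_report`: all removal counts plus the stage-1 mean/SD;
#'   `n_retained` always equals `n_total` minus the removals).
#' @export
trim_rts <- function(trials, low_ms = 400, high_ms = 5000, sd_mult = 3) {
  stopifnot("rt_ms" %in% names(trials))
  if (nrow(trials) == 0L) stop("no trials to trim", call. = FALSE)
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0))
    stop("all RTs must be positive and finite", call. = FALSE)
  n_total <- nrow(trials)
  fast <- trials$rt_ms < low_ms
  slow <- trials$rt_ms > high_ms
  stage1 <- trials[!fast & !slow, , drop = FALSE]
  m <- mean(stage1$rt_ms)
  s <- stats::sd(stage1$rt_ms)
  out_sd <- abs(stage1$rt_ms - m) > sd_mult * s
  out_sd[is.na(out_sd)] <- FALSE
  retained <- stage1[!out_sd, , drop = FALSE]
  report <- structure(list(
    n_total = n_total,
    n_fast_removed = sum(fast),
    n_slow_removed = sum(slow),
    n_sd_removed = sum(out_sd),
    n_incorrect_removed = 0L,
    n_retained = nrow(retained),
    mean_rt_after_absolute_trim = m,
    sd_rt_after_absolute_trim = s,
    low_ms = low_ms, high_ms = high_ms, sd_mult = sd_mult),
    class = "trim_report")
  list(trials = retained, report = report)
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf(
    paste0("<trim_report: %d trials; removed %d fast, %d slow, %d by %g-SD",
           " rule, %d incorrect; %d retained;",
           " post-absolute-trim mean %.1f ms (SD %.1f)>\n"),
    x$n_total, x$n_fast_removed, x$n_slow_removed, x$n_sd_removed,
    x$sd_mult, x$n_incorrect_removed, x$n_retained,
    x$mean_rt_after_absolute_trim, x$sd_rt_after_absolute_trim))
  invisible(x)
}

#' Keep only correct responses
#'
#' @param trials data.frame with a 0/1 `accuracy` column (no missing
#'   values).
#' @return the correct-only rows.
#' @export
filter_correct <- function(trials) {
  stopifnot("accuracy" %in% names(trials))
  if (anyNA(trials$accuracy))
    stop("missing accuracy values", call. = FALSE)
  if (!all(trials$accuracy %in% c(0, 1)))
    stop("accuracy must be coded 0/1", call. = FALSE)
  trials[trials$accuracy == 1, , drop = FALSE]
}

#' Trim RTs and drop incorrect responses in one pass
#'
#' Applies [trim_rts()] then [filter_correct()], in that order (absolute
#' and SD trimming on all responses first, correctness last), and folds the
#' incorrect-response count into the report.
#'
#' @inheritParams trim_rts
#' @return list with `trials` and a combined `trim_report`.
#' @export
preprocess_trials <- function(trials, low_ms = 400, high_ms = 5000,
                              sd_mult = 3) {
  tr <- trim_rts(trials, low_ms, high_ms, sd_mult)
  correct <- filter_correct(tr$trials)
  rep <- tr$report
  rep$n_incorrect_removed <- nrow(tr$trials) - nrow(correct)
  rep$n_retained <- nrow(correct)
  list(trials = correct, report = rep)
}

# Join trials with per-item covariates and set up factors. The metaphor
# level is the sentence-type reference, matching the reporting convention.
prep_model_frame <- function(trials, items = NULL) {
  if (!is.null(items)) {
    keep <- setdiff(names(items), "sentence_type")
    trials <- merge(trials, items[, keep, drop = FALSE],
                    by.x = "statement_id", by.y = "id", sort = FALSE)
  }
  trials$sentence_type <- factor(trials$sentence_type,
                                 levels = c("metaphor", "literal"))
  trials$participant_id <- factor(trials$participant_id)
  trials$order <- factor(trials$order)
  trials
}

new_model_fit <- function(name, formula, fit, data, response) {
  obs <- data[[response]]
  fitted_vals <- stats::fitted(fit)
  r2 <- stats::cor(fitted_vals, obs)^2
  structure(list(
    name = name,
    formula = deparse1(formula),
    fit = fit,
    aic = stats::AIC(fit),
    r2 = r2,
    singular = lme4::isSingular(fit),
    coefficients = satterthwaite_coefs(fit)),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit '%s': AIC %.1f, R2 %.4f%s>\n  %s\n", x$name,
              x$aic, x$r2, if (x$singular) ", singular" else "", x$formula))
  print(x$coefficients, digits = 4)
  invisible(x)
}

fit_lmm <- function(formula, data, reml) {
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
}

#' Mixed model for correct-decision reaction times
#'
#' Fits `rt_ms ~ z_length1 * z_length2 + z_cos * z_relatedness *
#' sentence_type + (1 | participant_id) + (1 | order)` by REML: keyword
#' lengths in interaction, the full Cos x Relatedness x SentenceType
#' crossing, and random intercepts for participant and presentation order.
#' Continuous predictors are expected z-scored over the item set; the
#' sentence-type reference level is metaphor. Pass trimmed, correct-only
#' trials.
#'
#' @param trials trial data.frame (optionally already carrying covariates).
#' @param items per-item covariate table ([merge_item_covariates()]) to
#'   join on `statement_id`; omit if `trials` already has the z columns.
#' @return a `model_fit`: the `lmer` fit plus AIC, R-squared (squared
#'   correlation of fitted and observed), and a Satterthwaite coefficient
#'   table. A singular fit is flagged, not an error.
#' @export
fit_rt_model <- function(trials, items = NULL) {
  data <- prep_model_frame(trials, items)
  f <- rt_ms ~ z_length1 * z_length2 + z_cos * z_relatedness * sentence_type +
    (1 | participant_id) + (1 | order)
  fit <- fit_lmm(f, data, reml = TRUE)
  new_model_fit("rt_full", f, fit, data, "rt_ms")
}

#' Linear mixed model for literality-decision accuracy
#'
#' Fits a linear-probability mixed model on 0/1 accuracy:
#' `accuracy ~ z_cos * z_relatedness * sentence_type + z_length1 +
#' z_logfreq1 + (1 | participant_id)`. A linear rather than logistic link
#' keeps the coefficients on the probability scale, the convention this
#' table mirrors; the order random effect is omitted because it does not
#' survive AIC selection in this design. Pass trimmed trials with both
#' correct and incorrect responses.
#'
#' @inheritParams fit_rt_model
#' @return a `model_fit`.
#' @export
fit_accuracy_model <- function(trials, items = NULL) {
  data <- prep_model_frame(trials, items)
  if (stats::var(data$accuracy) == 0)
    stop("accuracy has zero variance; nothing to model", call. = FALSE)
  f <- accuracy ~ z_cos * z_relatedness * sentence_type + z_length1 +
    z_logfreq1 + (1 | participant_id)
  fit <- fit_lmm(f, data, reml = TRUE)
  new_model_fit("accuracy_full", f, fit, data, "accuracy")
}

#' Ladder specifications for stepwise mixed-model development
#'
#' The RT ladder grows from a participant-intercept-only model through an
#' order intercept, the two keyword lengths (then their interaction), the
#' keyword log frequencies, and finally the full
#' Cos x Relatedness x SentenceType crossing. The accuracy ladder follows
#' the analogous sequence without the order term in its final model.
#'
#' @return list of `list(name, formula)` steps for [fit_model_ladder()].
#' @export
rt_ladder_spec <- function() {
  base <- "rt_ms ~ %s + (1 | participant_id)"
  withord <- "rt_ms ~ %s + (1 | participant_id) + (1 | order)"
  list(
    list(name = "M1", formula = sprintf(base, "1")),
    list(name = "M2", formula = sprintf(withord, "1")),
    list(name = "M3", formula = sprintf(withord, "z_length1")),
    list(name = "M4", formula = sprintf(withord, "z_length1 + z_length2")),
    list(name = "M5", formula = sprintf(withord, "z_length1 * z_length2")),
    list(name = "M6", formula = sprintf(withord,
                                        "z_length1 * z_length2 + z_logfreq1")),
    list(name = "M7", formula = sprintf(withord,
                                        "z_length1 * z_length2 + z_logfreq2")),
    list(name = "M8", formula = sprintf(withord,
      "z_length1 * z_length2 + z_cos * z_relatedness * sentence_type")))
}

#' @rdname rt_ladder_spec
#' @export
accuracy_ladder_spec <- function() {
  base <- "accuracy ~ %s + (1 | participant_id)"
  withord <- "accuracy ~ %s + (1 | participant_id) + (1 | order)"
  list(
    list(name = "M1", formula = sprintf(base, "1")),
    list(name = "M2", formula = sprintf(withord, "1")),
    list(name = "M3", formula = sprintf(base, "z_length1")),
    list(name = "M4", formula = sprintf(base, "z_length1 + z_length2")),
    list(name = "M5", formula = sprintf(base, "z_length1 * z_length2")),
    list(name = "M6", formula = sprintf(base, "z_length1 + z_logfreq1")),
    list(name = "M7", formula = sprintf(base,
                                        "z_length1 + z_logfreq1 + z_logfreq2")),
    list(name = "M8", formula = sprintf(base, "z_length1 * z_logfreq1")),
    list(name = "M9", formula = sprintf(base,
      "z_length1 + z_logfreq1 + z_cos * z_relatedness * sentence_type")))
}

#' Fit an AIC-gated ladder of mixed models
#'
#' Fits the models of `ladder_spec` in order by maximum likelihood (ML, not
#' REML: AIC comparisons across differing fixed effects require ML). A step
#' is accepted when its AIC is lower than the last *accepted* model's; AIC
#' and R-squared differences are always reported against the last accepted
#' model, so a rejected step does not move the baseline. A step that fails
#' to fit is recorded with status `"failed"` and the ladder continues.
#'
#' @param trials trial data.frame.
#' @param ladder_spec list of `list(name, formula)`; see [rt_ladder_spec()].
#' @param items optional per-item covariate table to join.
#' @param acceptance_rule function `(candidate_aic, last_accepted_aic) ->
#'   logical`; default: strict AIC decrease.
#' @return A `model_ladder`: data.frame `steps` (name, formula, aic,
#'   aic_diff, r2, r2_diff, accepted, singular) plus the list of fitted
#'   `model_fit`s.
#' @export
fit_model_ladder <- function(trials, ladder_spec, items = NULL,
                             acceptance_rule = function(aic, last) aic < last) {
  stopifnot(length(ladder_spec) >= 1L)
  data <- prep_model_frame(trials, items)
  fits <- vector("list", length(ladder_spec))
  rows <- vector("list", length(ladder_spec))
  last_aic <- NA_real_; last_r2 <- NA_real_
  for (i in seq_along(ladder_spec)) {
    step <- ladder_spec[[i]]
    f <- stats::as.formula(step$formula)
    response <- all.vars(f)[1L]
    mf <- tryCatch(fit_lmm(f, data, reml = FALSE), error = function(e) e)
    if (inherits(mf, "error")) {
      rows[[i]] <- data.frame(name = step$name, formula = step$formula,
                              aic = NA_real_, aic_diff = NA_real_,
                              r2 = NA_real_, r2_diff = NA_real_,
                              accepted = FALSE, singular = NA,
                              status = "failed")
      next
    }
    m <- new_model_fit(step$name, f, mf, data, response)
    fits[[i]] <- m
    if (i == 1L) {
      accepted <- TRUE
      diff_aic <- NA_real_; diff_r2 <- NA_real_
    } else {
      diff_aic <- m$aic - last_aic
      diff_r2 <- m$r2 - last_r2
      accepted <- isTRUE(acceptance_rule(m$aic, last_aic))
    }
    if (accepted) { last_aic <- m$aic; last_r2 <- m$r2 }
    rows[[i]] <- data.frame(name = step$name, formula = step$formula,
                            aic = m$aic, aic_diff = diff_aic,
                            r2 = m$r2, r2_diff = diff_r2,
                            accepted = accepted, singular = m$singular,
                            status = if (accepted) "accepted" else "rejected")
  }
  structure(list(steps = do.call(rbind, rows), fits = fits),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder>\n")
  print(x$steps[, c("name", "aic", "aic_diff", "r2", "r2_diff", "accepted")],
        digits = 4)
  invisible(x)
}

#' Pairwise literality-advantage analysis over matched stimulus pairs
#'
#' For each matched (literal, metaphor) pair, computes the mean correct RT
#' of both members, classifies the pair as showing a literality advantage
#' (literal faster) or a metaphor advantage (literal slower), and, within
#' each class, tests whether the literal-minus-metaphor Relatedness
#' differences differ from zero (two-tailed one-sample t test). Pairs with
#' no correct trials for either member are excluded with a warning.
#'
#' @param match a `match_result` from [greedy_match()].
#' @param trials trial data.frame (all responses; correctness filtered
#'   internally).
#' @param scores per-item scores from [score_statements()].
#' @return list with `pairs` (per-pair means and differences), counts
#'   `n_metaphor_advantage` / `n_literality_advantage`, and `tests`
#'   (per-group mean Relatedness difference, t, df, p).
#' @export
pairwise_advantage <- function(match, trials, scores) {
  stopifnot(inherits(match, "match_result"))
  correct <- filter_correct(trials)
  mean_rt <- tapply(correct$rt_ms, correct$statement_id, mean)
  rel <- stats::setNames(scores$relatedness, scores$id)
  cos_v <- stats::setNames(scores$cos, scores$id)
  p <- match$pairs
  lit_rt <- unname(mean_rt[p$literal_id])
  met_rt <- unname(mean_rt[p$metaphor_id])
  ok <- !is.na(lit_rt) & !is.na(met_rt)
  if (any(!ok))
    warning(sprintf("excluding %d pair(s) with no correct trials", sum(!ok)),
            call. = FALSE)
  pairs <- data.frame(
    literal_id = p$literal_id[ok], metaphor_id = p$metaphor_id[ok],
    literal_mean_rt = lit_rt[ok], metaphor_mean_rt = met_rt[ok],
    rt_diff = lit_rt[ok] - met_rt[ok],
    relatedness_diff = unname(rel[p$literal_id[ok]] - rel[p$metaphor_id[ok]]),
    cos_diff = unname(cos_v[p$literal_id[ok]] - cos_v[p$metaphor_id[ok]]),
    metaphor_advantage = lit_rt[ok] > met_rt[ok],
    stringsAsFactors = FALSE)
  test_group <- function(d) {
    if (length(d) < 2L || stats::sd(d) < .Machine$double.eps^0.5)
      return(data.frame(n = length(d), mean_diff = mean(d), t = NA_real_,
                        df = NA_real_, p = NA_real_))
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    data.frame(n = length(d), mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  tests <- rbind(
    cbind(group = "metaphor_advantage",
          test_group(pairs$relatedness_diff[pairs$metaphor_advantage])),
    cbind(group = "literality_advantage",
          test_group(pairs$relatedness_diff[!pairs$metaphor_advantage])))
  list(pairs = pairs,
       n_metaphor_advantage = sum(pairs$metaphor_advantage),
       n_literality_advantage = sum(!pairs$metaphor_advantage),
       tests = tests)
}

#' Correlation of model-estimated RTs with a predictor within one type
#'
#' Predicts each item's RT from a fitted model's fixed effects alone
#' (random effects at their mean of zero) and correlates the estimates
#' with Relatedness or Cos within a single sentence type — the per-type
#' effect-direction summary.
#'
#' @param model a `model_fit` from [fit_rt_model()].
#' @param items per-item covariate table ([merge_item_covariates()]).
#' @param sentence_type `"literal"` or `"metaphor"`.
#' @param predictor `"relatedness"` or `"cos"`.
#' @return Pearson correlation coefficient.
#' @export
estimated_rt_correlation <- function(model, items,
                                     sentence_type = c("literal", "metaphor"),
                                     predictor = c("relatedness", "cos")) {
  stopifnot(inherits(model, "model_fit"))
  sentence_type <- match.arg(sentence_type)
  predictor <- match.arg(predictor)
  sub <- items[items$sentence_type == sentence_type, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 items for a correlation", call. = FALSE)
  sub$sentence_type <- factor(sub$sentence_type,
                              levels = c("metaphor", "literal"))
  est <- stats::predict(model$fit, newdata = sub, re.form = NA)
  stats::cor(est, sub[[predictor]])
}
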