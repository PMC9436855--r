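make_trials <- function(rt, accuracy = rep(1, length(rt))) {
  data.frame(participant_id = sprintf("P%02d", seq_along(rt) %% 5),
             order = seq_along(rt), statement_id = sprintf("S%02d",
                                                           seq_along(rt)),
             sentence_type = "literal", rt_ms = rt,
             response = "literal-true", accuracy = accuracy)
}

test_that("trimming counts planted contaminants exactly and reconciles", {
  set.seed(1)
  rt <- c(runif(85, 900, 1100),          # tight in-range block
          runif(10, 100, 399),           # planted fast
          runif(5, 5001, 8000))          # planted slow
  tr <- trim_rts(make_trials(rt))
  rep <- tr$report
  expect_equal(rep$n_fast_removed, 10L)
  expect_equal(rep$n_slow_removed, 5L)
  expect_equal(rep$n_sd_removed, 0L)
  expect_equal(rep$n_retained, 85L)
  expect_equal(rep$n_total - rep$n_fast_removed - rep$n_slow_removed -
                 rep$n_sd_removed - rep$n_incorrect_removed, rep$n_retained)
  expect_equal(rep$mean_rt_after_absolute_trim, mean(rt[1:85]))
  expect_equal(rep$sd_rt_after_absolute_trim, sd(rt[1:85]))
})

test_that("the SD stage uses the post-absolute-trim mean and SD", {
  rt <- c(rep(1000, 50), 1400, 12000)    # 12000 leaves via absolute bound
  tr <- trim_rts(make_trials(rt))
  # survivors: 50 x 1000 and one 1400; 1400 is > 3 SD from the mean
  m <- mean(rt[1:51]); s <- sd(rt[1:51])
  expect_true(abs(1400 - m) > 3 * s)
  expect_equal(tr$report$n_slow_removed, 1L)
  expect_equal(tr$report$n_sd_removed, 1L)
  expect_equal(tr$report$n_retained, 50L)
})

test_that("clean data passes untouched; stage 1 is idempotent", {
  set.seed(2)
  rt <- runif(60, 800, 1200)
  tr <- trim_rts(make_trials(rt))
  expect_equal(tr$report$n_retained, 60L)
  expect_equal(tr$report$n_fast_removed + tr$report$n_slow_removed +
                 tr$report$n_sd_removed, 0L)
  # retrim of retained rows removes nothing at the absolute stage
  again <- trim_rts(tr$trials)
  expect_equal(again$report$n_fast_removed, 0L)
  expect_equal(again$report$n_slow_removed, 0L)
})

test_that("trim counts reconcile on arbitrary random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    rt <- exp(rnorm(300, log(1200), 0.8))
    rep <- trim_rts(make_trials(rt))$report
    expect_equal(rep$n_total - rep$n_fast_removed - rep$n_slow_removed -
                   rep$n_sd_removed, rep$n_retained)
  }
})

test_that("trim_rts validates input", {
  expect_error(trim_rts(data.frame(rt_ms = numeric(0))), "no trials")
  expect_error(trim_rts(make_trials(c(500, -2))), "positive")
})

test_that("filter_correct keeps accuracy == 1 and demands clean coding", {
  tr <- make_trials(runif(10, 500, 900), accuracy = c(rep(1, 7), 0, 0, 0))
  expect_equal(nrow(filter_correct(tr)), 7L)
  expect_identical(filter_correct(tr)$accuracy, rep(1, 7))
  tr$accuracy[1] <- NA
  expect_error(filter_correct(tr), "missing accuracy")
  tr$accuracy[1] <- 2
  expect_error(filter_correct(tr), "0/1")
})

test_that("preprocess_trials folds the incorrect count into the report", {
  # the fast contaminant also carries accuracy 0 but leaves at stage 1, so
  # only the five in-range incorrect rows count as incorrect removals
  tr <- make_trials(c(runif(20, 800, 1000), 200),
                    accuracy = c(rep(1, 15), rep(0, 6)))
  out <- preprocess_trials(tr)
  expect_equal(out$report$n_fast_removed, 1L)
  expect_equal(out$report$n_incorrect_removed, 5L)
  expect_equal(out$report$n_retained, nrow(out$trials))
  expect_equal(out$report$n_total -
                 out$report$n_fast_removed - out$report$n_slow_removed -
                 out$report$n_sd_removed - out$report$n_incorrect_removed,
               out$report$n_retained)
})

test_that("noise-free simulation is exactly invertible by the RT model", {
  items <- make_item_set(seed = 6, n_per_type = 12, words_per_cluster = 40)
  cfg <- noise_free_config(n_participants = 8, seed = 2)
  tr <- simulate_trials(items, cfg)
  fit <- fit_rt_model(tr, items)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  planted <- cfg$fixed_effects
  expect_equal(est[names(planted)], planted, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
})

test_that("rt and accuracy models recover planted effects in one replicate", {
  # single-replicate smoke check (the proper 100-replicate coverage study
  # lives in test-acceptance.R): the large planted slopes must come back
  # with the right sign and within 3 SEs
  items <- make_item_set(seed = 6, n_per_type = 20, words_per_cluster = 60)
  cfg <- simulation_config(n_participants = 40, seed = 31)
  tr <- simulate_trials(items, cfg)
  pt <- preprocess_trials(tr)
  fit <- fit_rt_model(pt$trials, items)
  co <- fit$coefficients
  est <- setNames(co$estimate, co$term); se <- setNames(co$se, co$term)
  planted <- cfg$fixed_effects
  big <- names(planted)[abs(planted) >= 200]
  expect_true(all(sign(est[big]) == sign(planted[big])))
  expect_true(all(abs(est[big] - planted[big]) <= 3 * se[big]))
  acc_fit <- fit_accuracy_model(trim_rts(tr)$trials, items)
  aco <- acc_fit$coefficients
  aest <- setNames(aco$estimate, aco$term); ase <- setNames(aco$se, aco$term)
  aplanted <- cfg$accuracy_fixed_effects
  a_in <- sum(abs(aest[names(aplanted)] - aplanted) <=
                2 * ase[names(aplanted)])
  expect_gte(a_in, length(aplanted) - 1L)
})

test_that("fit_accuracy_model refuses a constant outcome", {
  items <- make_item_set(seed = 6, n_per_type = 6, words_per_cluster = 40)
  tr <- simulate_trials(items, noise_free_config(n_participants = 3,
                                                 seed = 2))
  tr$accuracy <- 1
  expect_error(fit_accuracy_model(tr, items), "zero variance")
})

test_that("a one-model ladder is trivially accepted with base diffs", {
  items <- make_item_set(seed = 6, n_per_type = 8, words_per_cluster = 40)
  tr <- simulate_trials(items, simulation_config(n_participants = 8,
                                                 seed = 3))
  lad <- fit_model_ladder(preprocess_trials(tr)$trials,
                          list(list(name = "M1",
                                    formula = "rt_ms ~ 1 + (1 | participant_id)")),
                          items)
  expect_true(lad$steps$accepted[1])
  expect_true(is.na(lad$steps$aic_diff[1]))
})

test_that("a planted three-way interaction is accepted by the ladder", {
  items <- make_item_set(seed = 6, n_per_type = 20, words_per_cluster = 60)
  tr <- simulate_trials(items, simulation_config(n_participants = 30,
                                                 seed = 13))
  lad <- fit_model_ladder(preprocess_trials(tr)$trials, rt_ladder_spec(),
                          items)
  steps <- lad$steps
  m8 <- steps[steps$name == "M8", ]
  expect_true(m8$accepted)
  expect_lt(m8$aic_diff, 0)
  # diff bookkeeping: every diff is measured against the last accepted AIC
  last <- steps$aic[1]
  for (i in 2:nrow(steps)) {
    expect_equal(steps$aic_diff[i], steps$aic[i] - last, tolerance = 1e-9)
    expect_equal(steps$accepted[i], steps$aic[i] < last)
    if (steps$accepted[i]) last <- steps$aic[i]
  }
})

test_that("pairwise advantage matches a hand-built 4-pair fixture", {
  pairs <- data.frame(literal_id = c("L1", "L2", "L3", "L4"),
                      metaphor_id = c("M1", "M2", "M3", "M4"),
                      summed_difference = rep(0.1, 4))
  match <- structure(list(pairs = pairs, mean_summed_difference = 0.1,
                          sd_summed_difference = 0,
                          max_summed_difference = 0.1),
                     class = "match_result")
  # per-item correct RTs: L1 slower than M1 (metaphor advantage), others
  # faster; L3 has one incorrect trial that must be ignored
  trials <- data.frame(
    participant_id = "P1", order = 1:9,
    statement_id = c("L1", "L1", "M1", "L2", "M2", "L3", "L3", "M3", "M4"),
    sentence_type = "literal",
    rt_ms = c(1500, 1700, 1000, 800, 1200, 900, 5000, 1100, 700),
    response = "x",
    accuracy = c(1, 1, 1, 1, 1, 1, 0, 1, 1))
  trials <- rbind(trials, data.frame(participant_id = "P1", order = 10,
                                     statement_id = "L4",
                                     sentence_type = "literal", rt_ms = 600,
                                     response = "x", accuracy = 1))
  scores <- data.frame(id = c("L1", "L2", "L3", "L4", "M1", "M2", "M3", "M4"),
                       relatedness = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
                       cos = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.15, 0.2, 0.25))
  pw <- pairwise_advantage(match, trials, scores)
  expect_equal(pw$n_metaphor_advantage, 1L)
  expect_equal(pw$n_literality_advantage, 3L)
  p1 <- pw$pairs[pw$pairs$literal_id == "L1", ]
  expect_equal(p1$literal_mean_rt, 1600)      # mean(1500, 1700)
  expect_equal(p1$metaphor_mean_rt, 1000)
  p3 <- pw$pairs[pw$pairs$literal_id == "L3", ]
  expect_equal(p3$literal_mean_rt, 900)       # incorrect 5000 excluded
  expect_equal(pw$pairs$relatedness_diff, c(0.4, 0.4, 0.4, 0.4))
  # literality-advantage group: constant diffs -> t test degenerate, mean ok
  lit_row <- pw$tests[pw$tests$group == "literality_advantage", ]
  expect_equal(lit_row$mean_diff, 0.4)
})

test_that("uniform literal dominance yields zero metaphor-advantage pairs", {
  pairs <- data.frame(literal_id = c("L1", "L2"), metaphor_id = c("M1", "M2"),
                      summed_difference = c(0, 0))
  match <- structure(list(pairs = pairs, mean_summed_difference = 0,
                          sd_summed_difference = 0, max_summed_difference = 0),
                     class = "match_result")
  trials <- data.frame(participant_id = "P1", order = 1:4,
                       statement_id = c("L1", "L2", "M1", "M2"),
                       sentence_type = "literal",
                       rt_ms = c(500, 600, 900, 950), response = "x",
                       accuracy = 1)
  scores <- data.frame(id = c("L1", "L2", "M1", "M2"),
                       relatedness = c(0.9, 0.9, 0.3, 0.35),
                       cos = c(0.5, 0.5, 0.1, 0.1))
  pw <- pairwise_advantage(match, trials, scores)
  expect_equal(pw$n_metaphor_advantage, 0L)
  expect_equal(pw$n_literality_advantage, 2L)
})

test_that("pairs without correct trials are excluded with a warning", {
  pairs <- data.frame(literal_id = c("L1", "L2"), metaphor_id = c("M1", "M2"),
                      summed_difference = c(0, 0))
  match <- structure(list(pairs = pairs, mean_summed_difference = 0,
                          sd_summed_difference = 0, max_summed_difference = 0),
                     class = "match_result")
  trials <- data.frame(participant_id = "P1", order = 1:4,
                       statement_id = c("L1", "L2", "M1", "M2"),
                       sentence_type = "literal",
                       rt_ms = c(500, 600, 900, 950), response = "x",
                       accuracy = c(1, 1, 1, 0))
  scores <- data.frame(id = c("L1", "L2", "M1", "M2"),
                       relatedness = c(0.9, 0.9, 0.3, 0.35),
                       cos = c(0.5, 0.5, 0.1, 0.1))
  expect_warning(pw <- pairwise_advantage(match, trials, scores),
                 "no correct trials")
  expect_equal(nrow(pw$pairs), 1L)
})

test_that("estimated RT correlations recover planted monotonicity", {
  items <- make_item_set(seed = 6, n_per_type = 12, words_per_cluster = 40)
  fe <- c("(Intercept)" = 1500, "z_relatedness" = 200)
  tr <- simulate_trials(items, noise_free_config(fixed_effects = fe,
                                                 n_participants = 5,
                                                 seed = 2))
  fit <- fit_rt_model(tr, items)
  # estimated RT increases strictly in relatedness -> r = 1
  expect_equal(estimated_rt_correlation(fit, items, "literal",
                                        "relatedness"), 1, tolerance = 1e-6)
  expect_equal(estimated_rt_correlation(fit, items, "metaphor",
                                        "relatedness"), 1, tolerance = 1e-6)
  # and matches a hand-computed Pearson on the predictions
  sub <- items[items$sentence_type == "literal", ]
  sub$sentence_type <- factor(sub$sentence_type,
                              levels = c("metaphor", "literal"))
  est <- predict(fit$fit, newdata = sub, re.form = NA)
  expect_equal(estimated_rt_correlation(fit, items, "literal", "relatedness"),
               oracle_pearson(est, sub$relatedness), tolerance = 1e-12)
  expect_error(estimated_rt_correlation(fit, items[1:2, ], "literal"),
               "at least 3")
})
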