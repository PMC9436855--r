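# Run code under a private RNG stream without disturbing the caller's seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic per-operation sub-stream from one global seed.
substream <- function(seed, offset) (as.numeric(seed) * 37 + offset) %% 2147483647

#' Generate a clustered synthetic embedding lexicon
#'
#' Stands in for a real distributional-semantic space: words are unit
#' vectors drawn around `n_clusters` random cluster directions, so that
#' same-cluster pairs have systematically higher expected cosine than
#' cross-cluster pairs. Each word also receives a synthetic log frequency
#' (attribute `"logfreq"`) and a variable-length lowercase token, so that
#' downstream stimulus matching on length and frequency is exercised.
#'
#' A word vector is `normalize(concentration * center + z)` with
#' `z ~ N(0, I_d)`: as `concentration` grows, within-cluster cosines
#' approach 1.
#'
#' @param n_clusters number of cluster directions.
#' @param words_per_cluster words drawn around each direction.
#' @param d embedding dimension (>= 2).
#' @param concentration nonnegative; how tightly words hug their cluster
#'   center (default 4, giving separated but overlapping similarity
#'   distributions).
#' @param seed integer seed; the same seed yields a bit-identical lexicon.
#' @return An [embedding_lexicon()] with attributes `cluster` (named
#'   integer vector) and `logfreq` (named numeric vector).
#' @export
generate_lexicon <- function(n_clusters = 2, words_per_cluster = 50, d = 20,
                             concentration = 4, seed = 1) {
  stopifnot(n_clusters >= 1, words_per_cluster >= 1, d >= 2,
            concentration >= 0)
  n <- n_clusters * words_per_cluster
  with_seed(substream(seed, 11L), {
    words <- make_word_tokens(n)
    centers <- matrix(stats::rnorm(n_clusters * d), n_clusters, d)
    centers <- centers / sqrt(rowSums(centers^2))
    cluster <- rep(seq_len(n_clusters), each = words_per_cluster)
    noise <- matrix(stats::rnorm(n * d), n, d)
    vecs <- concentration * centers[cluster, , drop = FALSE] + noise
    rownames(vecs) <- words
    lex <- embedding_lexicon(vecs, unit_normalize = TRUE, case_folded = TRUE)
    attr(lex, "cluster") <- stats::setNames(cluster, words)
    # right-skewed frequencies on the log scale, like Zipfian corpora
    attr(lex, "logfreq") <- stats::setNames(stats::rnorm(n, 8, 2), words)
    lex
  })
}

# Unique lowercase pseudo-words with lengths spread over 3..10 characters,
# so nchar() is a usable length covariate.
make_word_tokens <- function(n) {
  lens <- sample(3:10, n, replace = TRUE)
  words <- character(n)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    repeat {
      w <- paste(sample(letters, lens[i], replace = TRUE), collapse = "")
      if (is.null(seen[[w]])) { seen[[w]] <- TRUE; words[i] <- w; break }
    }
  }
  words
}

#' Generate matched literal/metaphor statement sets from a clustered lexicon
#'
#' Literal "x is a y" items are drawn as within-cluster word pairs and
#' metaphors as cross-cluster pairs, so that scored Relatedness and Cos
#' distributions for the two types are separated but overlapping — the
#' qualitative signature of real stimulus sets, where almost all literally
#' true statements have very high relatedness. Lengths come from the word
#' tokens themselves and log frequencies from the lexicon's synthetic
#' frequency table, so covariate matching has real variance to work with.
#'
#' @param lex a lexicon from [generate_lexicon()] (its `cluster` and
#'   `logfreq` attributes are required).
#' @param n_literal,n_metaphor item counts (default 40 + 40).
#' @param seed integer seed.
#' @return list with `statements` (data.frame `id`, `text`, `x`, `y`,
#'   `sentence_type`) and `features` (data.frame `id`, `length1`,
#'   `length2`, `logfreq1`, `logfreq2`).
#' @export
generate_statements <- function(lex, n_literal = 40, n_metaphor = 40,
                                seed = 1) {
  cluster <- attr(lex, "cluster")
  logfreq <- attr(lex, "logfreq")
  if (is.null(cluster) || is.null(logfreq))
    stop("lexicon lacks cluster/logfreq attributes; use generate_lexicon()",
         call. = FALSE)
  if (n_literal == 0 && n_metaphor == 0) {
    empty_s <- data.frame(id = character(), text = character(),
                          x = character(), y = character(),
                          sentence_type = character())
    empty_f <- data.frame(id = character(), length1 = integer(),
                          length2 = integer(), logfreq1 = numeric(),
                          logfreq2 = numeric())
    return(list(statements = empty_s, features = empty_f))
  }
  with_seed(substream(seed, 23L), {
    lit <- draw_pairs(cluster, n_literal, within = TRUE)
    met <- draw_pairs(cluster, n_metaphor, within = FALSE)
    ids <- c(sprintf("L%03d", seq_len(n_literal)),
             sprintf("M%03d", seq_len(n_metaphor)))
    xs <- c(lit$x, met$x); ys <- c(lit$y, met$y)
    statements <- data.frame(
      id = ids,
      text = sprintf("A %s is a %s", xs, ys),
      x = xs, y = ys,
      sentence_type = rep(c("literal", "metaphor"), c(n_literal, n_metaphor)),
      stringsAsFactors = FALSE)
    features <- data.frame(
      id = ids,
      length1 = nchar(xs), length2 = nchar(ys),
      logfreq1 = unname(logfreq[xs]), logfreq2 = unname(logfreq[ys]),
      stringsAsFactors = FALSE)
    list(statements = statements, features = features)
  })
}

# Sample n distinct (x, y) pairs, within- or cross-cluster, x != y.
draw_pairs <- function(cluster, n, within) {
  words <- names(cluster)
  pool_ok <- function(x, y) {
    if (within) cluster[[x]] == cluster[[y]] else cluster[[x]] != cluster[[y]]
  }
  xs <- character(n); ys <- character(n)
  seen <- new.env(parent = emptyenv())
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("insufficient vocabulary to draw the requested statement pairs",
           call. = FALSE)
    pair <- sample(words, 2L)
    key <- paste(pair, collapse = "\r")
    if (pair[1L] != pair[2L] && pool_ok(pair[1L], pair[2L]) &&
        is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      xs[i] <- pair[1L]; ys[i] <- pair[2L]
      i <- i + 1L
    }
  }
  list(x = xs, y = ys)
}

# Default RT fixed effects (ms), on z-scored predictors with the metaphor
# level as sentence-type reference; values mirror a published literality-
# decision model of this structure.
default_rt_fixed_effects <- function() {
  c("(Intercept)"                              = 1659.74,
    "z_relatedness"                            = -317.93,
    "z_cos"                                    = 205.69,
    "z_length1"                                = 30.61,
    "z_length2"                                = 56.99,
    "sentence_typeliteral"                     = -55.4,
    "z_length1:z_length2"                      = 30.82,
    "z_cos:z_relatedness"                      = -414.01,
    "z_cos:sentence_typeliteral"               = -274.99,
    "z_relatedness:sentence_typeliteral"       = 341.59,
    "z_cos:z_relatedness:sentence_typeliteral" = 372.7)
}

# Default accuracy fixed effects on the probability scale (linear
# probability model), same contrast coding.
default_accuracy_fixed_effects <- function() {
  c("(Intercept)"                              = 0.718,
    "z_relatedness"                            = 0.290,
    "sentence_typeliteral"                     = 0.109,
    "z_cos"                                    = -0.107,
    "z_length1"                                = -0.034,
    "z_logfreq1"                               = -0.023,
    "z_relatedness:sentence_typeliteral"       = -0.335,
    "z_cos:z_relatedness"                      = 0.163,
    "z_cos:sentence_typeliteral"               = 0.088,
    "z_cos:z_relatedness:sentence_typeliteral" = -0.179)
}

#' Configuration for the behavioral-trial simulator
#'
#' Holds every generative parameter of [simulate_trials()]. Defaults state
#' one fixed simulated world: 66 participants by 40+40 items; RT fixed
#' effects mirroring a published correct-decision RT model (intercept about
#' 1660 ms, a negative Relatedness slope, and a positive three-way
#' Cos x Relatedness x SentenceType interaction); accuracy fixed effects on
#' the probability scale; random intercept SDs and the lognormal residual
#' chosen for realism (the source analyses do not report variance
#' components); and contamination rates matching the fractions of
#' implausibly fast/slow responses that absolute trimming removes in real
#' data (2.3% fast, 2.5% slow).
#'
#' @param n_participants,n_items_per_type design size.
#' @param fixed_effects named vector of RT coefficients (ms); names follow
#'   the model-matrix terms of the RT formula. Missing names mean 0.
#' @param subject_intercept_sd,order_intercept_sd random-intercept SDs (ms).
#' @param residual_sigma sigma of the mean-one multiplicative lognormal
#'   residual (0 = noise-free).
#' @param contamination list with `fast_rate`, `fast_range` (ms, drawn
#'   uniformly in `[low, high)`), `slow_rate`, `slow_range`; defaults put
#'   contaminants exactly where 400/5000 ms absolute trimming catches them.
#' @param accuracy_fixed_effects named vector on the probability scale.
#' @param accuracy_subject_sd SD of the participant intercept in the
#'   accuracy model (probability scale).
#' @param seed integer; drives counter-based sub-streams so any stage can
#'   be reproduced in isolation.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 66, n_items_per_type = 40,
                              fixed_effects = default_rt_fixed_effects(),
                              subject_intercept_sd = 300,
                              order_intercept_sd = 50,
                              residual_sigma = 0.3,
                              contamination = list(
                                fast_rate = 0.023, fast_range = c(100, 400),
                                slow_rate = 0.025, slow_range = c(5000, 8000)),
                              accuracy_fixed_effects =
                                default_accuracy_fixed_effects(),
                              accuracy_subject_sd = 0.08,
                              seed = 1) {
  stopifnot(n_participants >= 1, n_items_per_type >= 0,
            subject_intercept_sd >= 0, order_intercept_sd >= 0,
            residual_sigma >= 0)
  rates <- c(contamination$fast_rate, contamination$slow_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1)
    stop("contamination rates must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    n_items_per_type = as.integer(n_items_per_type),
    fixed_effects = fixed_effects,
    subject_intercept_sd = subject_intercept_sd,
    order_intercept_sd = order_intercept_sd,
    residual_sigma = residual_sigma,
    contamination = contamination,
    accuracy_fixed_effects = accuracy_fixed_effects,
    accuracy_subject_sd = accuracy_subject_sd,
    seed = seed), class = "simulation_config")
}

# Model matrix for the simulator's linear predictors, shared with the
# fitting code so planted and fitted terms line up exactly.
rt_model_matrix <- function(items) {
  items$sentence_type <- factor(items$sentence_type,
                                levels = c("metaphor", "literal"))
  stats::model.matrix(
    ~ z_length1 * z_length2 + z_cos * z_relatedness * sentence_type, items)
}

accuracy_model_matrix <- function(items) {
  items$sentence_type <- factor(items$sentence_type,
                                levels = c("metaphor", "literal"))
  stats::model.matrix(
    ~ z_cos * z_relatedness * sentence_type + z_length1 + z_logfreq1, items)
}

linear_predictor <- function(mm, coefs) {
  beta <- stats::setNames(rep(0, ncol(mm)), colnames(mm))
  unknown <- setdiff(names(coefs), colnames(mm))
  if (length(unknown))
    stop("unknown fixed-effect name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  beta[names(coefs)] <- coefs
  as.vector(mm %*% beta)
}

#' Simulate trial-level literality-decision data
#'
#' Generates one row per participant x item from a generative mixed model:
#'
#' * RT (ms) = (fixed-effect linear predictor on the z-scored item
#'   covariates + participant intercept + presentation-order intercept)
#'   x mean-one lognormal noise. With all SDs and `residual_sigma` at 0
#'   every RT equals its linear predictor exactly.
#' * Accuracy ~ Bernoulli(p), p = linear-probability predictor +
#'   participant intercept, clamped to `[0.01, 0.99]`.
#' * A configurable fraction of trials is overwritten with uniformly drawn
#'   implausibly fast or slow contaminant RTs.
#'
#' Each participant sees every item once in an individually randomized
#' order; `order` is the presentation position (1..n items), the second
#' random factor of the RT model.
#'
#' @param items data.frame with one row per statement carrying `id`,
#'   `sentence_type`, and the z-scored covariates `z_cos`, `z_relatedness`,
#'   `z_length1`, `z_length2`, `z_logfreq1` (merge [score_statements()] and
#'   [normalize_features()] output; see [merge_item_covariates()]).
#' @param config a [simulation_config()].
#' @return data.frame of trials (`participant_id`, `order`, `statement_id`,
#'   `sentence_type`, `rt_ms`, `response`, `accuracy`) with attribute
#'   `generation_log` recording planted contaminant counts and the
#'   random-effect draws.
#' @export
simulate_trials <- function(items, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  need <- c("id", "sentence_type", "z_cos", "z_relatedness", "z_length1",
            "z_length2", "z_logfreq1")
  missing_cols <- setdiff(need, names(items))
  if (length(missing_cols))
    stop("items lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n_items <- nrow(items)
  n_sub <- config$n_participants
  mm_rt <- rt_model_matrix(items)
  mm_acc <- accuracy_model_matrix(items)
  lp_rt_item <- linear_predictor(mm_rt, config$fixed_effects)
  lp_acc_item <- linear_predictor(mm_acc, config$accuracy_fixed_effects)

  with_seed(substream(config$seed, 31L), {
    sub_int <- stats::rnorm(n_sub, 0, config$subject_intercept_sd)
    ord_int <- stats::rnorm(n_items, 0, config$order_intercept_sd)
    acc_int <- stats::rnorm(n_sub, 0, config$accuracy_subject_sd)
    rows <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      ord <- sample.int(n_items)          # item shown at position k
      item_idx <- ord
      position <- seq_len(n_items)
      lp <- lp_rt_item[item_idx] + sub_int[s] + ord_int[position]
      noise <- if (config$residual_sigma > 0)
        exp(stats::rnorm(n_items, 0, config$residual_sigma) -
              config$residual_sigma^2 / 2)
      else rep(1, n_items)
      rt <- pmax(lp * noise, 1)
      p <- pmin(0.99, pmax(0.01, lp_acc_item[item_idx] + acc_int[s]))
      acc <- stats::rbinom(n_items, 1, p)
      st <- items$sentence_type[item_idx]
      correct_resp <- ifelse(st == "literal", "literal-true", "not-literal")
      wrong_resp <- ifelse(st == "literal", "not-literal", "literal-true")
      rows[[s]] <- data.frame(
        participant_id = sprintf("P%03d", s),
        order = position,
        statement_id = items$id[item_idx],
        sentence_type = st,
        rt_ms = rt,
        response = ifelse(acc == 1, correct_resp, wrong_resp),
        accuracy = acc,
        stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, rows)
    n <- nrow(trials)
    u <- stats::runif(n)
    fast <- u < config$contamination$fast_rate
    slow <- !fast & u < config$contamination$fast_rate +
      config$contamination$slow_rate
    fr <- config$contamination$fast_range
    sr <- config$contamination$slow_range
    if (any(fast))
      trials$rt_ms[fast] <- stats::runif(sum(fast), fr[1], fr[2])
    if (any(slow))
      trials$rt_ms[slow] <- stats::runif(sum(slow), sr[1], sr[2])
    attr(trials, "generation_log") <- list(
      n_trials = n,
      n_fast_planted = sum(fast),
      n_slow_planted = sum(slow),
      subject_intercepts = sub_int,
      order_intercepts = ord_int)
    trials
  })
}

#' Merge statement scores and normalized features into one item table
#'
#' Convenience join producing the per-item covariate table that
#' [simulate_trials()] and the model-fitting functions consume.
#'
#' @param scores output of [score_statements()].
#' @param features output of [normalize_features()].
#' @return data.frame with one row per item and all z-scored covariates.
#' @export
merge_item_covariates <- function(scores, features) {
  out <- merge(scores, features, by = "id", sort = TRUE)
  if (nrow(out) != nrow(scores))
    stop("scores and features do not cover the same item ids", call. = FALSE)
  out
}

#' Write simulated trials as CSV
#' @param trials data.frame from [simulate_trials()].
#' @param path output path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
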