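# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops and base arithmetic, sharing no code path with
# the package implementation they check.

oracle_cosine <- function(u, v) {
  num <- 0; su <- 0; sv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    su <- su + u[i]^2
    sv <- sv + v[i]^2
  }
  num / (sqrt(su) * sqrt(sv))
}

# Full-scan neighbor ranking: every candidate scored one at a time, sorted
# by descending cosine then ascending word.
oracle_neighbors <- function(lex, word, m, exclude = character()) {
  sims <- c()
  words <- c()
  qv <- lex$vectors[match(word, lex$vocab), ]
  banned <- c(word, exclude)
  for (w in lex$vocab) {
    if (w %in% banned) next
    words <- c(words, w)
    sims <- c(sims, oracle_cosine(qv, lex$vectors[match(w, lex$vocab), ]))
  }
  ord <- order(-sims, words)
  data.frame(word = words[ord][1:m], rank = 1:m,
             cosine = sims[ord][1:m], stringsAsFactors = FALSE)
}

# Step-by-step predication replay: neighborhood of y, neighbor selection
# under either rule, plain averaging, cosine of the averages.
oracle_relatedness <- function(lex, x, y, k1, k2, m,
                               rule = c("separate", "common")) {
  rule <- match.arg(rule)
  xv <- lex$vectors[match(x, lex$vocab), ]
  yv <- lex$vectors[match(y, lex$vocab), ]
  nb <- oracle_neighbors(lex, y, m, exclude = unique(c(x, y)))
  cx <- sapply(nb$word, function(w)
    oracle_cosine(xv, lex$vectors[match(w, lex$vocab), ]))
  cy <- sapply(nb$word, function(w)
    oracle_cosine(yv, lex$vectors[match(w, lex$vocab), ]))
  pick <- function(key, k) nb$word[order(-key, nb$word)][1:k]
  if (rule == "separate") {
    s1 <- pick(cx, k1); s2 <- pick(cy, k2)
  } else {
    s1 <- s2 <- pick(cx + cy, k1)
  }
  avg_with <- function(v, words) {
    acc <- v
    for (w in words) acc <- acc + lex$vectors[match(w, lex$vocab), ]
    acc / (length(words) + 1)
  }
  oracle_cosine(avg_with(xv, s1), avg_with(yv, s2))
}

# A random unit-normalized lexicon with simple deterministic word names.
random_lexicon <- function(n, d, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  rownames(m) <- sprintf("w%04d", sample.int(9999, n))
  embedding_lexicon(m, unit_normalize = TRUE)
}

# Independent replay of the greedy matcher straight from its definition.
oracle_greedy <- function(literals, metaphors) {
  zc <- c("z_length1", "z_length2", "z_logfreq1", "z_logfreq2")
  lpool <- literals; mpool <- metaphors
  pairs <- NULL
  while (nrow(lpool) > 0) {
    best <- NULL
    for (i in seq_len(nrow(lpool))) {
      for (j in seq_len(nrow(mpool))) {
        d <- 0
        for (cc in zc) d <- d + abs(lpool[[cc]][i] - mpool[[cc]][j])
        better <- is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
             (lpool$id[i] < best$lid ||
                (lpool$id[i] == best$lid && mpool$id[j] < best$mid)))
        if (better) best <- list(d = d, lid = lpool$id[i], mid = mpool$id[j])
      }
    }
    pairs <- rbind(pairs, data.frame(literal_id = best$lid,
                                     metaphor_id = best$mid,
                                     summed_difference = best$d,
                                     stringsAsFactors = FALSE))
    lpool <- lpool[lpool$id != best$lid, ]
    mpool <- mpool[mpool$id != best$mid, ]
  }
  pairs
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# A small scored item set shared by behavioural tests: clustered lexicon,
# 40 + 40 statements, scores and normalized features merged.
make_item_set <- function(seed = 11, n_per_type = 40, words_per_cluster = 150) {
  lex <- generate_lexicon(2, words_per_cluster, 30, 4, seed = seed)
  gen <- generate_statements(lex, n_per_type, n_per_type, seed = seed)
  sc <- suppressWarnings(
    score_statements(lex, gen$statements, predication_params(5, 5, 4500)))
  merge_item_covariates(sc, normalize_features(gen$features))
}

# Noise-free simulation settings: no random effects, no residual, no
# contaminants, deterministic accuracy boundary never binding.
noise_free_config <- function(fixed_effects = NULL, ...) {
  args <- list(subject_intercept_sd = 0, order_intercept_sd = 0,
               residual_sigma = 0,
               contamination = list(fast_rate = 0, fast_range = c(100, 400),
                                    slow_rate = 0, slow_range = c(5000, 8000)),
               accuracy_subject_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  if (!is.null(fixed_effects)) args$fixed_effects <- fixed_effects
  do.call(simulation_config, args)
}

write_w2v_fixture <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
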