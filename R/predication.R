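#' Parameters for the predication-based Relatedness score
#'
#' Relatedness generalizes Kintsch's predication algorithm with three
#' parameters: the size `m` of the source word's cosine neighborhood, and
#' the numbers `k1` and `k2` of neighborhood words averaged into the target
#' and source vectors respectively. The canonical setting in the metaphor
#' literature is 5-5-4500 (`k1 = 5`, `k2 = 5`, `m = 4500`), selected for
#' predicting human judgments of metaphor quality.
#'
#' Two readings of the neighbor-selection step are preserved:
#' * `"separate"` (default): the `k1` neighbors closest to the target x are
#'   averaged into x, and the `k2` neighbors closest to the source y are
#'   averaged into y. Distinct `k1`/`k2` naming implies distinct sets.
#' * `"common"`: a single set of `k1` neighbors with the highest combined
#'   (summed) similarity to x and y is averaged into both. The combination
#'   rule is not pinned down in the literature; the sum is this package's
#'   choice, not an attested formula.
#'
#' @param k1,k2 positive integers, both at most `m`.
#' @param m positive integer; clipped to vocabulary size minus the excluded
#'   words (with a warning) when a lexicon is smaller than `m`.
#' @param selection_rule `"separate"` or `"common"`.
#' @return An object of class `predication_params`.
#' @export
predication_params <- function(k1 = 5, k2 = 5, m = 4500,
                               selection_rule = c("separate", "common")) {
  selection_rule <- match.arg(selection_rule)
  k1 <- as.integer(k1); k2 <- as.integer(k2); m <- as.integer(m)
  if (any(c(k1, k2, m) < 1L))
    stop("k1, k2 and m must be positive integers", call. = FALSE)
  if (k1 > m || k2 > m)
    stop(sprintf("invalid parameters (k1=%d, k2=%d, m=%d): k1 and k2 must not exceed m",
                 k1, k2, m), call. = FALSE)
  structure(list(k1 = k1, k2 = k2, m = m, selection_rule = selection_rule),
            class = "predication_params")
}

#' @export
print.predication_params <- function(x, ...) {
  cat(sprintf("<predication_params %d-%d-%d, rule = %s>\n",
              x$k1, x$k2, x$m, x$selection_rule))
  invisible(x)
}

# Select the first k rows of a neighbor frame by a similarity key,
# ties broken lexicographically by word.
top_k_by <- function(neighbors, key, k) {
  ord <- order(-key, neighbors$word)
  neighbors$word[ord[seq_len(k)]]
}

#' Predication-based Relatedness of an "x is a y" statement
#'
#' Implements the k1-k2-m extension of Kintsch's predication algorithm:
#' (i) the nearest `m` cosine neighbors of the source word y are retrieved
#' (excluding x and y themselves, which would trivially pull the average);
#' (ii) from that neighborhood, `k1` words are selected for the target and
#' `k2` for the source per `params$selection_rule`; (iii) each keyword's
#' vector is averaged with its selected neighbor vectors, and the cosine of
#' the two adjusted vectors is returned. High Relatedness means the
#' contextually aligned meanings of x and y are close.
#'
#' The neighborhood is taken around y, so the score is directional:
#' `relatedness(lex, x, y)` need not equal `relatedness(lex, y, x)`.
#'
#' @param lex a unit-normalized [embedding_lexicon()].
#' @param x target word (the topic of the statement).
#' @param y source word (the vehicle whose category is asserted of x).
#' @param params a [predication_params()].
#' @return Cosine of the two adjusted vectors, in `[-1, 1]`.
#' @export
relatedness <- function(lex, x, y, params = predication_params()) {
  stopifnot(inherits(lex, "embedding_lexicon"),
            inherits(params, "predication_params"))
  if (!isTRUE(lex$unit_normalized))
    stop("relatedness() requires a unit-normalized lexicon", call. = FALSE)
  xv <- lexicon_vector(lex, x)
  yv <- lexicon_vector(lex, y)
  excl <- unique(c(fold_word(lex, x), fold_word(lex, y)))
  n_cand <- length(lex$vocab) - sum(lex$vocab %in% excl)
  m_eff <- params$m
  if (m_eff > n_cand) {
    warning(sprintf("m = %d clipped to %d available candidates", params$m,
                    n_cand), call. = FALSE)
    m_eff <- n_cand
  }
  if (m_eff < max(params$k1, params$k2))
    stop(sprintf("after clipping, m = %d is smaller than max(k1, k2) = %d",
                 m_eff, max(params$k1, params$k2)), call. = FALSE)
  nb <- nearest_neighbors(lex, y, m_eff, exclude = c(x, y))
  nbmat <- lex$vectors[match(nb$word, lex$vocab), , drop = FALSE]
  cos_to_x <- pmin(1, pmax(-1, as.vector(nbmat %*% xv)))
  cos_to_y <- nb$cosine
  if (params$selection_rule == "separate") {
    s1 <- top_k_by(nb, cos_to_x, params$k1)
    s2 <- top_k_by(nb, cos_to_y, params$k2)
  } else {
    s <- top_k_by(nb, cos_to_x + cos_to_y, params$k1)
    s1 <- s2 <- s
  }
  x_adj <- colMeans(rbind(xv, lex$vectors[match(s1, lex$vocab), , drop = FALSE]))
  y_adj <- colMeans(rbind(yv, lex$vectors[match(s2, lex$vocab), , drop = FALSE]))
  cosine(x_adj, y_adj)
}

#' Plain cosine similarity of the two unadjusted keyword vectors
#'
#' The `Cos` covariate: cosine of the raw x and y vectors, before any
#' predication adjustment.
#'
#' @inheritParams relatedness
#' @return a scalar in `[-1, 1]`.
#' @export
plain_cos <- function(lex, x, y) {
  cosine(lexicon_vector(lex, x), lexicon_vector(lex, y))
}

# z-score with sample (n-1) SD; all-equal input maps to 0 rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Score a statement set: Cos, Relatedness, and their z-scores
#'
#' Computes [plain_cos()] and [relatedness()] for every statement whose two
#' keywords are in the vocabulary, then z-scores both measures over the
#' scored set (sample SD; a zero-SD measure z-scores to 0). Statements with
#' out-of-vocabulary keywords are skipped with a warning naming the missing
#' words.
#'
#' @param lex a unit-normalized [embedding_lexicon()].
#' @param statements data.frame with columns `id`, `x`, `y`,
#'   `sentence_type` (`"literal"` or `"metaphor"`), and optionally `text`.
#' @param params a [predication_params()].
#' @return data.frame with columns `id`, `x`, `y`, `sentence_type`, `cos`,
#'   `relatedness`, `z_cos`, `z_relatedness`.
#' @export
score_statements <- function(lex, statements, params = predication_params()) {
  stopifnot(all(c("id", "x", "y", "sentence_type") %in% names(statements)))
  if (anyDuplicated(statements$id))
    stop("duplicate statement ids", call. = FALSE)
  if (!all(statements$sentence_type %in% c("literal", "metaphor")))
    stop("sentence_type must be 'literal' or 'metaphor'", call. = FALSE)
  in_vocab <- function(w) fold_word(lex, w) %in% lex$vocab
  ok <- vapply(statements$x, in_vocab, logical(1)) &
        vapply(statements$y, in_vocab, logical(1))
  if (any(!ok)) {
    miss <- unique(unlist(lapply(which(!ok), function(i) {
      w <- c(statements$x[i], statements$y[i])
      w[!vapply(w, in_vocab, logical(1))]
    })))
    warning(sprintf("skipping %d statement(s) with out-of-vocabulary keyword(s): %s",
                    sum(!ok), paste(miss, collapse = ", ")), call. = FALSE)
  }
  scored <- statements[ok, , drop = FALSE]
  if (nrow(scored) < 2L)
    stop("fewer than 2 scorable statements; z-scoring undefined",
         call. = FALSE)
  # clip m once for the whole set (2 words are excluded per statement) so
  # small synthetic lexicons warn once, not once per statement
  m_max <- length(lex$vocab) - 2L
  if (params$m > m_max) {
    warning(sprintf("m = %d clipped to %d (vocabulary size minus excluded words)",
                    params$m, m_max), call. = FALSE)
    params$m <- m_max
    if (params$m < max(params$k1, params$k2))
      stop(sprintf("after clipping, m = %d is smaller than max(k1, k2) = %d",
                   params$m, max(params$k1, params$k2)), call. = FALSE)
  }
  cos_raw <- mapply(function(x, y) plain_cos(lex, x, y), scored$x, scored$y)
  rel_raw <- mapply(function(x, y) relatedness(lex, x, y, params),
                    scored$x, scored$y)
  data.frame(id = scored$id, x = scored$x, y = scored$y,
             sentence_type = scored$sentence_type,
             cos = unname(cos_raw), relatedness = unname(rel_raw),
             z_cos = zscore(unname(cos_raw)),
             z_relatedness = zscore(unname(rel_raw)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sweep predication parameters over a statement set
#'
#' Runs [score_statements()] once per `(k1, k2, m)` triple and tabulates the
#' mean and SD of Relatedness per triple. A small utility for exploring the
#' parameter space around 5-5-4500, not a re-run of the original full
#' optimization against human judgments.
#'
#' @param lex a unit-normalized [embedding_lexicon()].
#' @param statements as in [score_statements()].
#' @param grid data.frame with columns `k1`, `k2`, `m` and optionally
#'   `selection_rule`.
#' @return data.frame with one row per triple: the parameters plus
#'   `mean_relatedness`, `sd_relatedness`, `mean_cos`, `n_scored`.
#' @export
parameter_sweep <- function(lex, statements, grid) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("k1", "k2", "m") %in% names(grid)))
  if (is.null(grid$selection_rule)) grid$selection_rule <- "separate"
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- tryCatch(
      predication_params(grid$k1[i], grid$k2[i], grid$m[i],
                         grid$selection_rule[i]),
      error = function(e) stop(sprintf("invalid triple %d-%d-%d: %s",
                                       grid$k1[i], grid$k2[i], grid$m[i],
                                       conditionMessage(e)), call. = FALSE))
    sc <- score_statements(lex, statements, p)
    data.frame(k1 = p$k1, k2 = p$k2, m = p$m,
               selection_rule = p$selection_rule,
               mean_relatedness = mean(sc$relatedness),
               sd_relatedness = stats::sd(sc$relatedness),
               mean_cos = mean(sc$cos), n_scored = nrow(sc))
  })
  do.call(rbind, rows)
}
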