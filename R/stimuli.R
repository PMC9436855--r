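#' Normalize lexical covariates over a pooled stimulus set
#'
#' z-scores the four matching covariates — character length and logged
#' frequency of each keyword — over the pooled set passed in (literals and
#' metaphors together, so that summed differences live on a common scale).
#' Frequencies must already be logged by the caller; the log base is a
#' corpus-norm choice, not part of the algorithm.
#'
#' @param features data.frame with columns `id`, `length1`, `length2`,
#'   `logfreq1`, `logfreq2` (keyword 1 = x, keyword 2 = y).
#' @return the input with `z_length1`, `z_length2`, `z_logfreq1`,
#'   `z_logfreq2` columns added.
#' @export
normalize_features <- function(features) {
  measures <- c("length1", "length2", "logfreq1", "logfreq2")
  stopifnot(is.data.frame(features), all(c("id", measures) %in% names(features)))
  if (nrow(features) < 2L)
    stop("need at least 2 items to normalize features", call. = FALSE)
  if (any(features$length1 <= 0) || any(features$length2 <= 0))
    stop("keyword lengths must be positive", call. = FALSE)
  for (m in measures) {
    s <- stats::sd(features[[m]])
    if (is.na(s) || s == 0)
      stop(sprintf("zero variance in measure '%s'; cannot normalize", m),
           call. = FALSE)
    features[[paste0("z_", m)]] <- (features[[m]] - mean(features[[m]])) / s
  }
  features
}

z_feature_cols <- c("z_length1", "z_length2", "z_logfreq1", "z_logfreq2")

# Summed per-measure difference between one literal row and all metaphor rows.
summed_feature_difference <- function(lit_row, metaphors,
                                      distance = c("absolute", "squared")) {
  distance <- match.arg(distance)
  d <- 0
  for (cc in z_feature_cols) {
    delta <- lit_row[[cc]] - metaphors[[cc]]
    d <- d + if (distance == "absolute") abs(delta) else delta^2
  }
  d
}

#' Greedy exhaustive matching of literal statements to metaphors
#'
#' Repeats until every literal item is matched: scan all remaining
#' (literal, metaphor) pairs, take the pair with the smallest summed
#' difference over the four normalized covariates, record it, and remove
#' both items from their pools. Ties are broken by smallest literal id,
#' then smallest metaphor id. The sequential-removal procedure is the
#' method of record here; `method = "optimal"` (minimum-total-cost
#' assignment, exhaustive over permutations, feasible for up to 9 literals)
#' is provided for comparison only.
#'
#' @param literals,metaphors data.frames from [normalize_features()] (the
#'   z-columns must be present and computed over the pooled set). There
#'   must be at least as many metaphors as literals.
#' @param distance `"absolute"` (default; "summed difference" in the field's
#'   usage) or `"squared"`.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return An object of class `match_result`: list with `pairs` (data.frame
#'   `literal_id`, `metaphor_id`, `summed_difference`, in selection order),
#'   `mean_summed_difference`, `sd_summed_difference`,
#'   `max_summed_difference`.
#' @export
greedy_match <- function(literals, metaphors,
                         distance = c("absolute", "squared"),
                         method = c("greedy", "optimal")) {
  distance <- match.arg(distance)
  method <- match.arg(method)
  stopifnot(all(z_feature_cols %in% names(literals)),
            all(z_feature_cols %in% names(metaphors)))
  if (nrow(metaphors) < nrow(literals))
    stop(sprintf("need at least as many metaphors (%d) as literals (%d)",
                 nrow(metaphors), nrow(literals)), call. = FALSE)
  # full cost matrix once; row/col order fixed by id for deterministic ties
  literals <- literals[order(literals$id), , drop = FALSE]
  metaphors <- metaphors[order(metaphors$id), , drop = FALSE]
  cost <- t(vapply(seq_len(nrow(literals)), function(i) {
    summed_feature_difference(literals[i, ], metaphors, distance)
  }, numeric(nrow(metaphors))))
  cost <- matrix(cost, nrow = nrow(literals))
  pairs <- if (method == "greedy") {
    match_greedy(cost, literals$id, metaphors$id)
  } else {
    match_optimal(cost, literals$id, metaphors$id)
  }
  structure(
    list(pairs = pairs,
         mean_summed_difference = mean(pairs$summed_difference),
         sd_summed_difference = stats::sd(pairs$summed_difference),
         max_summed_difference = max(pairs$summed_difference)),
    class = "match_result"
  )
}

match_greedy <- function(cost, lit_ids, met_ids) {
  live_l <- seq_along(lit_ids)
  live_m <- seq_along(met_ids)
  out <- vector("list", length(lit_ids))
  for (step in seq_along(lit_ids)) {
    sub <- cost[live_l, live_m, drop = FALSE]
    best <- min(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    # ids are pre-sorted, so smallest row index = smallest literal id
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], , drop = TRUE]
    li <- live_l[hit[[1L]]]; mi <- live_m[hit[[2L]]]
    out[[step]] <- data.frame(literal_id = lit_ids[li],
                              metaphor_id = met_ids[mi],
                              summed_difference = cost[li, mi],
                              stringsAsFactors = FALSE)
    live_l <- setdiff(live_l, li)
    live_m <- setdiff(live_m, mi)
  }
  do.call(rbind, out)
}

# Exhaustive minimum-total-cost assignment; comparison baseline only.
match_optimal <- function(cost, lit_ids, met_ids) {
  nl <- length(lit_ids)
  if (nl > 9L)
    stop("optimal assignment is exhaustive and limited to 9 literals",
         call. = FALSE)
  perms <- all_injections(nl, length(met_ids))
  totals <- vapply(perms, function(p) sum(cost[cbind(seq_len(nl), p)]),
                   numeric(1))
  best <- perms[[which.min(totals)]]
  data.frame(literal_id = lit_ids,
             metaphor_id = met_ids[best],
             summed_difference = cost[cbind(seq_len(nl), best)],
             stringsAsFactors = FALSE)
}

# All injections from 1..n into 1..m (n <= m), as a list of index vectors.
all_injections <- function(n, m) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in remaining) rec(c(prefix, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(m))
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs, summed difference mean %.3f (SD %.3f), max %.3f>\n",
              nrow(x$pairs), x$mean_summed_difference,
              x$sd_summed_difference, x$max_summed_difference))
  invisible(x)
}

#' Select the n statements with the lowest Relatedness
#'
#' Used to pick literal statements whose keywords are unusually weakly
#' related — the hard cases for a literality decision. Ties at the boundary
#' are broken by ascending id.
#'
#' @param scores data.frame from [score_statements()].
#' @param n number of ids to return; at most `nrow(scores)`.
#' @return character vector of `n` ids, lowest Relatedness first.
#' @export
select_low_relatedness <- function(scores, n) {
  stopifnot(all(c("id", "relatedness") %in% names(scores)))
  n <- as.integer(n)
  if (n < 1L || n > nrow(scores))
    stop(sprintf("n = %d out of range for %d scored statements", n,
                 nrow(scores)), call. = FALSE)
  ord <- order(scores$relatedness, scores$id)
  as.character(scores$id[ord][seq_len(n)])
}
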