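#' Embedding lexicons
#'
#' An `embedding_lexicon` is the vocabulary-to-vector map underlying all
#' similarity computation in this package: a numeric matrix with one row per
#' word (rownames are the vocabulary) plus bookkeeping about normalization
#' and case folding. All vectors share a fixed dimension `d`; unit
#' normalization (every row has Euclidean norm 1) is applied at load and is
#' required by the predication machinery, which averages vectors on the
#' sphere.
#'
#' @param vectors numeric matrix, one row per word, rownames = vocabulary.
#' @param unit_normalize logical; rescale every row to unit norm.
#' @param case_folded logical; whether the vocabulary was lower-cased at
#'   load time (queries are folded the same way).
#' @return An object of class `embedding_lexicon`.
#' @export
embedding_lexicon <- function(vectors, unit_normalize = TRUE,
                              case_folded = FALSE) {
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop("`vectors` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(vectors)))
    stop("`vectors` must have rownames (the vocabulary)", call. = FALSE)
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate words in vocabulary", call. = FALSE)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("zero-norm vector for word(s): ",
         paste(utils::head(rownames(vectors)[norms == 0], 5), collapse = ", "),
         call. = FALSE)
  if (unit_normalize) vectors <- vectors / norms
  structure(
    list(vocab = rownames(vectors), vectors = vectors,
         d = ncol(vectors), unit_normalized = unit_normalize,
         case_folded = case_folded),
    class = "embedding_lexicon"
  )
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cat(sprintf("<embedding_lexicon: %d words, d = %d, %s%s>\n",
              length(x$vocab), x$d,
              if (x$unit_normalized) "unit-normalized" else "raw",
              if (x$case_folded) ", case-folded" else ""))
  invisible(x)
}

#' @export
length.embedding_lexicon <- function(x) length(x$vocab)

# Fold a query word the same way the vocabulary was folded at load.
fold_word <- function(lex, word) {
  if (isTRUE(lex$case_folded)) tolower(word) else word
}

# Look up one word's vector; error carries the missing word.
lexicon_vector <- function(lex, word) {
  w <- fold_word(lex, word)
  i <- match(w, lex$vocab)
  if (is.na(i))
    stop(sprintf("word not in vocabulary: '%s'", word), call. = FALSE)
  lex$vectors[i, ]
}

#' Read a word-embedding space in word2vec text format
#'
#' The word2vec text layout is a header line `"V d"` (vocabulary size and
#' dimension) followed by `V` rows of `word v1 ... vd`. Duplicate words are
#' dropped (first occurrence wins) with a warning; zero-norm vectors,
#' malformed headers, and row arity mismatches are load errors.
#'
#' @param path path to the file.
#' @param case_fold lower-case the vocabulary at load (default `TRUE`:
#'   stimulus words are typically capitalized sentence-initially).
#' @param unit_normalize rescale vectors to unit Euclidean norm (default
#'   `TRUE`; required by [relatedness()]).
#' @return An [embedding_lexicon()].
#' @export
read_word2vec_text <- function(path, case_fold = TRUE, unit_normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("empty embedding file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header))))
    stop("malformed word2vec header (expected 'V d'): '", lines[[1L]], "'",
         call. = FALSE)
  v <- as.integer(header[[1L]]); d <- as.integer(header[[2L]])
  body <- lines[-1L]
  if (length(body) != v)
    stop(sprintf("header declares %d words but file has %d rows", v,
                 length(body)), call. = FALSE)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  arity <- lengths(toks)
  if (any(arity != d + 1L))
    stop(sprintf("row %d has %d fields, expected %d (word + %d values)",
                 which(arity != d + 1L)[1L], arity[arity != d + 1L][1L],
                 d + 1L, d), call. = FALSE)
  words <- vapply(toks, `[[`, character(1), 1L)
  if (case_fold) words <- tolower(words)
  vals <- vapply(toks, function(t) as.numeric(t[-1L]), numeric(d))
  mat <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat))
    stop("non-numeric vector entries in embedding file", call. = FALSE)
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate word(s): %s", sum(dup),
                    paste(unique(words[dup]), collapse = ", ")),
            call. = FALSE)
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(mat) <- words
  embedding_lexicon(mat, unit_normalize = unit_normalize,
                    case_folded = case_fold)
}

#' Write a lexicon in word2vec text format
#'
#' @param lex an [embedding_lexicon()].
#' @param path output path.
#' @param digits significant digits for vector entries (default 6, enough
#'   for a read/write/read round trip to 6 decimals).
#' @export
write_word2vec_text <- function(lex, path, digits = 6) {
  stopifnot(inherits(lex, "embedding_lexicon"))
  header <- sprintf("%d %d", length(lex$vocab), lex$d)
  rows <- vapply(seq_along(lex$vocab), function(i) {
    paste(lex$vocab[i],
          paste(formatC(lex$vectors[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Cosine similarity of two vectors
#'
#' Standard cosine similarity, clamped to `[-1, 1]` against rounding. The
#' literature on this score sometimes says "cosine distance" while treating
#' high values as close; this package computes and names similarity
#' throughout.
#'
#' @param u,v numeric vectors of equal, nonzero length and nonzero norm.
#' @return a scalar in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("dimension mismatch in cosine()", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("zero vector in cosine()", call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Exact nearest-neighbor retrieval by cosine similarity
#'
#' Ranks all candidate vocabulary words by descending cosine similarity to
#' the query word and returns the top `m`. The query word itself is always
#' excluded (a self-neighbor would degenerate the predication averaging);
#' further words can be excluded via `exclude`. Ties are broken by ascending
#' lexicographic word order for determinism across platforms.
#'
#' Search is exact (full scan + sort): the vocabularies this package targets
#' are small enough that approximate indexing would buy nothing.
#'
#' @param lex an [embedding_lexicon()].
#' @param word query word (folded per the lexicon's case convention).
#' @param m number of neighbors to return.
#' @param exclude character vector of words never to return.
#' @return data.frame with columns `word`, `rank`, `cosine`.
#' @export
nearest_neighbors <- function(lex, word, m, exclude = character()) {
  stopifnot(inherits(lex, "embedding_lexicon"))
  qv <- lexicon_vector(lex, word)
  excl <- unique(c(fold_word(lex, word),
                   vapply(exclude, fold_word, character(1), lex = lex)))
  keep <- !(lex$vocab %in% excl)
  cand <- lex$vocab[keep]
  if (m > length(cand))
    stop(sprintf("m = %d exceeds the %d available candidate words", m,
                 length(cand)), call. = FALSE)
  mat <- lex$vectors[keep, , drop = FALSE]
  # rows are unit-normalized iff the lexicon is; normalize defensively
  norms <- sqrt(rowSums(mat^2))
  sims <- as.vector(mat %*% qv) / (norms * sqrt(sum(qv^2)))
  sims <- pmin(1, pmax(-1, sims))
  ord <- order(-sims, cand)
  top <- ord[seq_len(m)]
  data.frame(word = cand[top], rank = seq_len(m), cosine = sims[top],
             stringsAsFactors = FALSE)
}

#' Write a neighbor ranking as TSV
#'
#' @param neighbors data.frame from [nearest_neighbors()].
#' @param path output path.
#' @export
write_neighbors_tsv <- function(neighbors, path) {
  utils::write.table(neighbors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
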