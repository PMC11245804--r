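# Narrative diagnosis preprocessing and count-based embeddings. Tokens are
# lowercased, the special characters , ; : . ( ) / \ - are stripped
# (digits are kept), and each token is reduced by an injected stemmer. The
# corpus -- the ordered list of stems admitted by the minimum-word-frequency
# threshold -- is always built on the training subset only.

#' Identity stemmer
#' @param word character vector of tokens.
#' @return the tokens unchanged.
#' @export
stemmer_identity <- function(word) word

.suffixes <- c("ovima", "evima", "ijama", "ijema", "ijom", "ijeg", "ima",
               "ama", "oga", "ega", "emu", "omu", "om", "em", "og", "eg",
               "oj", "ih", "im", "a", "e", "i", "o", "u")

#' Minimal suffix-stripping stemmer
#'
#' A light inflection reducer for Slavic-style morphology: removes the
#' longest matching suffix from a fixed list provided at least three
#' characters remain. A full rule-based stemmer for the target language can
#' be injected instead wherever a stemmer is accepted.
#'
#' @param word character vector of tokens.
#' @return stemmed tokens.
#' @export
stemmer_suffix <- function(word) {
  vapply(word, function(w) {
    for (s in .suffixes) {
      if (nchar(w) - nchar(s) >= 3L && endsWith(w, s)) {
        return(substr(w, 1L, nchar(w) - nchar(s)))
      }
    }
    w
  }, "", USE.NAMES = FALSE)
}

#' Tokenise and stem one diagnosis text
#'
#' Lowercases, strips the special characters `, ; : . ( ) / \ -`, splits on
#' whitespace, applies the stemmer and drops empty tokens. A pure function:
#' identical input yields identical output.
#'
#' @param text character scalar (empty text gives an empty sequence).
#' @param stemmer a pure word -> stem function, e.g. [stemmer_identity()]
#'   or [stemmer_suffix()].
#' @return character vector of stems.
#' @export
preprocess_text <- function(text, stemmer = stemmer_identity) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  s <- tolower(text)
  s <- gsub("[,;:.()/\\\\-]", " ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  stems <- stemmer(toks)
  stems[nzchar(stems)]
}

#' Build a word corpus from training documents
#'
#' The vocabulary is the lexicographically ordered set of stems whose total
#' training count reaches `min_word_frequency`; stem counts and document
#' frequencies are retained for TF-IDF weighting.
#'
#' @param docs list of stem vectors (training subset only).
#' @param min_word_frequency minimum total occurrences, `>= 1`.
#' @return an object of class `radclust_corpus` with `vocabulary`,
#'   `stem_counts`, `doc_freq`, `doc_count` and `min_word_frequency`.
#' @export
build_corpus <- function(docs, min_word_frequency = 1L) {
  assert_that(min_word_frequency >= 1, "min_word_frequency must be >= 1")
  counts <- table(unlist(docs))
  vocab <- sort(names(counts)[counts >= min_word_frequency])
  assert_that(length(vocab) > 0,
              "empty vocabulary: no stem reaches min_word_frequency")
  df <- table(unlist(lapply(docs, unique)))
  structure(list(
    vocabulary = vocab,
    stem_counts = as.integer(counts[vocab]),
    doc_freq = as.integer(df[vocab]),
    doc_count = length(docs),
    min_word_frequency = as.integer(min_word_frequency)
  ), class = "radclust_corpus")
}

#' @export
print.radclust_corpus <- function(x, ...) {
  cat("<radclust_corpus> ", length(x$vocabulary), " stems from ",
      x$doc_count, " documents (min frequency ", x$min_word_frequency,
      ")\n", sep = "")
  invisible(x)
}

#' Bag-of-words embedding
#'
#' Integer stem counts over the corpus vocabulary order; out-of-vocabulary
#' stems are ignored, so the embedding is order-free in the document's
#' stems.
#'
#' @param doc_stems stem vector of one document, or a list of such vectors.
#' @param corpus a [build_corpus()] result.
#' @return a count vector of length `|vocabulary|`, or a matrix with one
#'   row per document.
#' @export
bow_embed <- function(doc_stems, corpus) {
  stopifnot(inherits(corpus, "radclust_corpus"))
  if (is.list(doc_stems)) {
    return(t(vapply(doc_stems, bow_embed, numeric(length(corpus$vocabulary)),
                    corpus = corpus)))
  }
  idx <- match(doc_stems, corpus$vocabulary)
  tabulate(idx[!is.na(idx)], nbins = length(corpus$vocabulary))
}

#' TF-IDF embedding
#'
#' Raw term frequency weighted by smoothed inverse document frequency,
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1` with `N` the training document
#' count -- the smoothing floors idf at 1 for a term present in every
#' training document, and rarer terms get strictly larger idf.
#'
#' @inheritParams bow_embed
#' @return a numeric vector (or matrix) in vocabulary order.
#' @export
tfidf_embed <- function(doc_stems, corpus) {
  stopifnot(inherits(corpus, "radclust_corpus"))
  idf <- log((1 + corpus$doc_count) / (1 + corpus$doc_freq)) + 1
  if (is.list(doc_stems)) {
    tf <- bow_embed(doc_stems, corpus)
    return(sweep(tf, 2, idf, "*"))
  }
  bow_embed(doc_stems, corpus) * idf
}
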