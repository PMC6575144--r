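#' Fit a tf-idf vectorizer on a set of narratives
#'
#' Standard bag-of-words featurization: lowercase, strip punctuation,
#' tokenize on word boundaries, count unigrams and bigrams, drop terms
#' appearing in fewer than `min_df` documents, and weight counts by inverse
#' document frequency, `idf(t) = log(N / df(t))`.  Terms present in every
#' fitting document have idf 0 and are pruned (they carry no signal), so no
#' fitted vocabulary column is ever all-zero.  Transforming new text uses
#' the frozen vocabulary; out-of-vocabulary terms are dropped.
#'
#' @param texts Character vector of narratives to fit on.
#' @param ids Record ids aligned with `texts`.
#' @param min_df Document-frequency floor (default 2).
#' @param ngram_max 1 = unigrams only, 2 = unigrams + bigrams.
#' @return Object of class `ltc_vectorizer` with the fitted vocabulary and
#'   idf weights.
#' @export
fit_vectorizer <- function(texts, ids = NULL, min_df = 2L, ngram_max = 2L) {
  if (length(texts) == 0L) stop("cannot fit a vectorizer on an empty text set")
  toks <- tokenize_narratives(texts, ngram_max)
  n_doc <- length(texts)
  # document frequency: unique terms per document
  doc_id <- rep.int(seq_len(n_doc), vapply(toks, length, integer(1)))
  term <- unlist(toks, use.names = FALSE)
  if (!length(term)) stop("no tokens found in fitting texts")
  dt <- data.table::data.table(doc = doc_id, term = term)
  dfreq <- data.table::setDF(unique(dt)[, list(df = .N), by = "term"])
  keep <- dfreq$df >= min_df & dfreq$df < n_doc
  ord <- order(dfreq$term[keep])
  vocab <- dfreq$term[keep][ord]
  if (!length(vocab)) stop("vocabulary empty after document-frequency pruning")
  idf <- log(n_doc / dfreq$df[keep][ord])
  structure(list(vocabulary = vocab, idf = idf, min_df = as.integer(min_df),
                 ngram_max = as.integer(ngram_max), n_fit_docs = n_doc,
                 fingerprint = vocab_fingerprint(vocab)),
            class = "ltc_vectorizer")
}

#' Transform narratives into a tf-idf feature matrix
#'
#' @param vectorizer A fitted [fit_vectorizer()] object.
#' @param texts Character vector of narratives.
#' @param ids Row ids (default seq along texts).
#' @return A sparse `dgCMatrix` (rows = narratives, columns = vocabulary
#'   terms) with tf-idf weights; row names are the ids, and the vectorizer
#'   fingerprint rides along as the `"fingerprint"` attribute.
#' @export
transform_texts <- function(vectorizer, texts, ids = NULL) {
  stopifnot(inherits(vectorizer, "ltc_vectorizer"))
  if (is.null(ids)) ids <- as.character(seq_along(texts))
  n <- length(texts)
  vocab <- vectorizer$vocabulary
  if (n == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, length(vocab)),
                              dimnames = list(NULL, vocab))
    attr(m, "fingerprint") <- vectorizer$fingerprint
    return(m)
  }
  toks <- tokenize_narratives(texts, vectorizer$ngram_max)
  doc_id <- rep.int(seq_len(n), vapply(toks, length, integer(1)))
  term <- unlist(toks, use.names = FALSE)
  j <- match(term, vocab)
  ok <- !is.na(j)
  m <- Matrix::sparseMatrix(i = doc_id[ok], j = j[ok], x = 1,
                            dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  # counts accumulated by sparseMatrix; scale columns by idf
  m <- m %*% Matrix::Diagonal(x = vectorizer$idf)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(ids, vocab)
  attr(m, "fingerprint") <- vectorizer$fingerprint
  m
}

# Lowercase, strip punctuation to spaces, split on whitespace; append
# bigrams joined with "_" when ngram_max >= 2.
tokenize_narratives <- function(texts, ngram_max = 2L) {
  txt <- tolower(texts)
  txt <- gsub("[^a-z0-9]+", " ", txt)
  uni <- strsplit(trimws(txt), " +")
  uni[vapply(uni, function(t) length(t) == 1L && !nzchar(t[1]), logical(1))] <-
    list(character())
  if (ngram_max >= 2L) {
    lapply(uni, function(t) {
      if (length(t) < 2L) return(t)
      c(t, paste(t[-length(t)], t[-1], sep = "_"))
    })
  } else {
    uni
  }
}
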